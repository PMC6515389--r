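---
title: "Detecting MDA chimeric reads: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting MDA chimeric reads: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The artifact and the detection model

Multiple displacement amplification (MDA) uses phi29 DNA polymerase,
whose strand-displacement activity builds a hyperbranched amplification
intermediate. When a displaced 3' end dissociates from its template it
can re-anneal at a nearby locus wherever a short stretch of sequence —
a microhomology of a few bases — is shared between the two sites, and
elongation then continues from the new locus. The product is a chimera:
a molecule whose two parts derive from loci that are close on a
chromosome but not contiguous, optionally with a strand flip.

In paired-end sequencing data this artifact leaves two distinct
signatures, and the package calls them as three chimera types:

* **Single-end chimeras** — the junction falls inside one read. The
  aligner maps one part of the read and soft-clips the rest. If the two
  parts map to the same strand the chimera is **direct**; if to
  opposite strands it is **inverted**. Inverted chimeras dominate in
  real MDA libraries and are the main source of false-positive
  inversion calls in structural-variant analysis.
* **Insertion chimeras** — the junction falls in the unsequenced
  insert between the mates. Neither read is split; the signature is a
  pair whose mates map to the *same* strand, which a normal convergent
  library never produces.

Detection proceeds in three stages.

**Stage A: pair classification.** Raw read pairs containing any `N`
base are removed before alignment. Each aligned pair is then assigned
exactly one category from its FLAG-derived facts: pairs with an
unmapped mate are removed; same-chromosome same-strand pairs are called
insertion chimeras; pairs in which either mate carries a usable
terminal soft clip become single-end candidates (this includes pairs
flagged proper by the aligner — split reads are routinely
proper-paired); remaining proper pairs are removed; the rest are
discarded as other discordance. Insertion classification wins over the
soft-clip route so the pair-level rate denominator stays clean.

**Stage B: splitting and realignment.** A candidate read is cut exactly
at its soft-clip boundary into a *former* and a *following* subsection
(in the stored read orientation). A clipped fragment shorter than

$$\min(L_{\text{soft-clipped}}) = \lfloor \log_4 L_{\text{chromosome}} \rfloor + 1$$

is expected to recur by chance on a chromosome of length
$L_{\text{chromosome}}$, so any read whose shorter subsection is below
this bound — or below an absolute 8 bp floor — is dropped. For human
chromosome 1 (249,250,621 bp) the bound is 14 bp. The bound is
evaluated per chromosome (the chromosome the aligned part mapped to),
and by exact integer comparison against powers of 4 rather than through
floating-point logarithms, so the step at each power of 4 is exact. We
apply the bound to *both* subsections, not only the clipped one: a
too-short mapped remainder is exactly as ambiguous on realignment as a
too-short clip. The two subsections of each surviving read are
reconstructed as a pseudo paired-end record (under a lossless derived
name) and realigned: either with the built-in exact-match aligner,
which scans both strands of every chromosome and keeps only unique
occurrences, or through a subprocess adapter around an external aligner
for real genomes. Multi-mapped subsections are discarded rather than
placed at a random hit; randomness in hit reporting is a known source
of irreproducible counts, and the pipeline is deterministic end to end.

**Stage C: junction-overlap search and validity filters.** A realigned
subsection pair whose hits share a strand is a potential direct
chimera; opposite strands, a potential inverted chimera. The
microhomology that mediated the template switch must appear at the
junction, and it may sit at either end, so the search is two-sided:

* *tail side* — the last 31 nt of the former subsection (N-padded in
  front when shorter) are compared with the 31 reference bases
  immediately preceding the following subsection's first aligned base,
  read in the following subsection's orientation;
* *head side* — the first 31 nt of the following subsection are
  compared with the 31 reference bases immediately after the former
  subsection's last aligned base, in the former subsection's
  orientation.

Each comparison is cyclical: starting from the longest accepted length
(30 bp) the candidate overlap is shortened one nucleotide per loop
until a match is found or the minimum (3 bp) is passed. One mismatch is
tolerated inside a candidate overlap, but never at its first base; `N`
on either side counts as a mismatch. If both sides find an overlap the
longer one is kept (ties go to the tail side, and the side is recorded
in the output). A candidate becomes a valid chimera call only if both
subsections are at least 30 bp long, the genomic distance between the
two hits is 25–5000 bp, and an overlap of at least 3 bases was found;
failures are attributed to a single dominant reason in the fixed order
subsection, distance, overlap.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hard_floor` | 8 bp | absolute minimum subsection length at the split stage |
| `window` | 31 nt | junction comparison window on each side |
| `max_overlap` | 30 bp | longest accepted overlap (the 31st base only supports mismatch-position evaluation) |
| `min_overlap` | 3 bp | shortest accepted overlap ("longer than two bases") |
| `max_mismatches` | 1 | tolerated mismatches per candidate overlap, never at its first base |
| `min_subsection` | 30 bp | minimum subsection length for a *valid* chimera |
| `distance_min`, `distance_max` | 25, 5000 bp | accepted genomic distance between subsection starts |
| `max_insertion_distance` | unlimited | optional ceiling for calling same-strand pairs insertion chimeras |

All of these are arguments of `chimera_params()` and flags of the
command-line wrapper. The defaults are the validity thresholds used for
the published MDA analyses and should only be changed with a reason:
e.g. lowering `distance_max` trades sensitivity for specificity against
genuine small SVs.

## Numerical and design choices

Several points are under-determined by the verbal description of the
method; the package pins them down as follows.

* **Coordinates.** Everything internal is 0-based half-open;
  conversion to SAM's 1-based convention happens only at the I/O
  boundary. Distances are between the two subsections' reference
  *start* coordinates — symmetric, cheap, and consistent with the
  5000 bp local-window framing of earlier pipelines. A `distance`
  column is emitted, so other conventions can be recomputed from the
  table.
* **Genomic distance gate vs. insertion chimeras.** The distance gate
  applies to single-end chimeras only; insertion chimeras are called
  from strand topology alone, with an optional configurable ceiling.
  Inter-chromosomal same-strand pairs are *not* insertion chimeras
  (chimera parts lie on one chromosome) and fall through to the other
  branches.
* **First-base rule.** "No mismatch at the beginning of the overlap"
  is implemented as: the first (5'-most, in read orientation) base of
  the candidate k-mer must match exactly. For the tail-side suffix
  comparison this base moves as the loop shortens; for the head-side
  prefix comparison it is always the following subsection's first
  base. A practical consequence of the one-mismatch tolerance is that
  an exact k-base junction agreement is often reported as k+1 when the
  next base happens to be the single tolerated mismatch; planted-truth
  tests therefore assert *reported ≥ planted*.
* **Acceptance order.** The loop accepts the first (longest) length
  that satisfies the rules, not the best-scoring one.
* **Hard clips** carry no sequence, so records whose only clip is `H`
  count as full-length mapped. Reads soft-clipped at both ends are
  split at the longer clip by default (the shorter clip's bases stay
  attached to the aligned part; `both_ends_policy = "skip"` drops such
  reads instead).
* **Secondary and supplementary alignments** (FLAG 0x100/0x800) are
  discarded on ingest. The pipeline realigns clipped parts itself
  instead of consuming the aligner's split records, so a
  supplementary-aware aligner and a backtrack-style aligner yield the
  same candidate stream.
* **Degenerate inputs.** An empty SAM produces empty outputs and a
  rate of 0 with a warning; unknown chromosomes, interior soft clips,
  and malformed CIGAR tokens raise errors naming the offending input.

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates a uniform random reference (one
synthetic chromosome, default 200 kb) and plants chimeras by the same
mechanism the artifact arises from: for each single-end chimera it
chooses two loci a junction distance apart and *writes the
microhomology into the reference* — the o-mer ending the first locus's
read-oriented slice is copied immediately upstream, in read
orientation, of the second locus. The chimeric read is then an exact
concatenation of two reference slices, so realignment and the overlap
search see a self-consistent world. The read is emitted together with
a convergent normal mate, a truth table row, and a truth-derived SAM
record (the second part as a terminal soft clip at the first locus), so
the whole pipeline runs with no aligner at all. Insertion chimeras are
two same-strand slices at nearby loci; normal pairs are convergent
slices at the configured insert size.

Default condition: 700 normal, 100 direct, 100 inverted, and 100
insertion pairs of 2 × 101 bp reads on 200 kb, overlaps 3–30 bp,
subsections 30 to read length − 30, junction distances within
25–5000 bp. Two geometric constraints are the generator's own: plant
footprints are kept at least two comparison windows apart so junctions
cannot interact, and each plant's junction distance is drawn with its
lower bound raised to $l_1 + \text{window}$ so the written
microhomology can never intersect the first locus's slice. Both keep
every planted truth value exactly recoverable, which is what the
recovery tests assert (100% recall and precision, reported distance
equal to planted distance, reported overlap at least the planted
length).

What the simulator does **not** model — and hence what passing tests do
not show about real data: amplification bias and coverage waviness,
sequencing quality profiles, repetitive and low-complexity sequence
(the random reference makes unique realignment of ≥30 bp subsections
near-certain, which hg19 does not), indels at junctions, more than two
chimeric segments per molecule, and multi-chromosome references. The
optional uniform substitution-error rate (`error_rate`) exercises the
one-mismatch tolerance and mismatch-tolerant external realignment; the
built-in realigner is exact-match by design, so errored subsections are
dropped rather than misplaced.

## Problem sizes used in the checks

The bundled tests run entirely on synthetic data: the recovery check
uses the default 1000-pair, 200 kb simulation; the overlap searches are
checked against a brute-force enumeration oracle on 1000 randomized
references of up to 10 kb; everything else runs on references of
0.3–70 kb. These sizes make every expected value computable
independently (by enumeration or construction) while exercising the
same code paths a genome-scale run uses. Correct but memory-unbounded
streaming is an accepted limitation: a whole SAM is loaded at once,
which is fine up to millions of records but is not a constant-memory
design.

## Known limitations

* The distance gate's convention (start-to-start) and the both-ends
  split policy are documented choices, not uniquely determined by the
  method's description; both are configurable.
* Overlap comparison is substitution-only; indel-containing junctions
  are not found.
* The chromosome-length minimum uses each subsection's own chromosome;
  for a multi-chromosome reference a clipped fragment realigning to a
  different, larger chromosome is still accepted by its origin
  chromosome's gate.
* Overlaps spanning chromosome ends rely on N-padding and therefore
  never extend past a boundary.
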