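# Stage B part 2: map reconstructed subsection pairs back to the
# reference.  A built-in exact-match aligner covers small synthetic
# references and all tests; an adapter runs an external aligner for
# real data.

#' Exact-match alignment of one query against the whole reference
#'
#' Scans both strands of every chromosome for exact occurrences of the
#' query (via [Biostrings::matchPattern()], with N matching nothing in an
#' ACGT reference).  Exactly one occurrence across all chromosomes and
#' strands gives a unique hit; zero gives status `"unmapped"`; two or
#' more give status `"multi"` (discarded downstream — multi-mapped
#' subsections are dropped rather than randomly placed, so the pipeline
#' stays deterministic).
#'
#' @param query DNA string (length >= 1).
#' @param ref a [reference_genome()].
#' @return a list with `status` (`"unique"`, `"unmapped"`, or `"multi"`)
#'   and, for unique hits, `chrom`, `ref_start` (0-based), `ref_end`
#'   (exclusive), `strand`, `unique = TRUE`.
#' @examples
#' ref <- reference_genome(c(c1 = "AAAAGATTACAAAAA"))
#' naive_align("GATTACA", ref)
#' @export
naive_align <- function(query, ref) {
  if (length(ref$sequences) == 0L) {
    stop("configuration error: empty reference")
  }
  stopifnot(nzchar(query))
  q <- Biostrings::DNAString(query)
  qr <- Biostrings::reverseComplement(q)
  hits <- list()
  for (chrom in names(ref$sequences)) {
    subj <- ref$dna[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") q else qr
      st <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = TRUE))
      for (s in st) {
        hits[[length(hits) + 1L]] <- list(
          chrom = chrom, ref_start = s - 1L,
          ref_end = s - 1L + nchar(query), strand = strand
        )
        if (length(hits) > 1L) {
          return(list(status = "multi"))
        }
      }
    }
  }
  if (length(hits) == 0L) return(list(status = "unmapped"))
  c(list(status = "unique", unique = TRUE), hits[[1]])
}

#' Realign both subsections of every split read with the naive aligner
#'
#' @param splits list of `subsection_pair` objects.
#' @param ref a [reference_genome()].
#' @return a list of triples `list(split, former_hit, following_hit)`
#'   for every origin whose two subsections both realigned uniquely;
#'   attribute `dropped` counts the discarded origins.
#' @export
align_subsections <- function(splits, ref) {
  out <- list()
  dropped <- 0L
  for (sp in splits) {
    fh <- naive_align(sp$former$seq, ref)
    lh <- naive_align(sp$following$seq, ref)
    if (fh$status == "unique" && lh$status == "unique") {
      out[[length(out) + 1L]] <- list(split = sp, former_hit = fh,
                                      following_hit = lh)
    } else {
      dropped <- dropped + 1L
    }
  }
  attr(out, "dropped") <- dropped
  out
}

#' Run an external aligner on reconstructed pseudo pairs
#'
#' Substitutes the `{ref}`, `{fq1}`, `{fq2}` and `{sam}` placeholders of
#' a shell command template, runs it, and returns the path of the SAM it
#' produced.  The adapter never parses aligner-specific logs; a nonzero
#' exit raises a realignment error carrying the captured stderr.
#'
#' @param fq1,fq2 pseudo paired FASTQ paths (from [write_pseudo_fastq()]).
#' @param ref_path reference FASTA path.
#' @param command_template shell command containing all four
#'   placeholders, e.g.
#'   `"bwa aln ... {ref} {fq1} {fq2} > {sam}"`.
#' @return path of the SAM file written by the aligner.
#' @export
external_align <- function(fq1, fq2, ref_path, command_template) {
  needed <- c("{ref}", "{fq1}", "{fq2}", "{sam}")
  missing <- needed[!vapply(needed, grepl, logical(1),
                            x = command_template, fixed = TRUE)]
  if (length(missing)) {
    stop("configuration error: aligner command template lacks placeholder(s) ",
         paste(missing, collapse = ", "))
  }
  sam <- tempfile(fileext = ".sam")
  cmd <- command_template
  for (sub in list(c("{ref}", ref_path), c("{fq1}", fq1),
                   c("{fq2}", fq2), c("{sam}", sam))) {
    cmd <- gsub(sub[1], sub[2], cmd, fixed = TRUE)
  }
  err <- tempfile()
  status <- suppressWarnings(
    system2("/bin/sh", c("-c", shQuote(cmd)), stdout = FALSE, stderr = err)
  )
  if (!identical(status, 0L) || !file.exists(sam) || file.size(sam) == 0) {
    diag <- if (file.exists(err)) paste(readLines(err, warn = FALSE),
                                        collapse = "\n") else ""
    stop("realignment error: aligner exited with status ", status,
         if (nzchar(diag)) paste0("\n", diag) else "")
  }
  sam
}

#' Join realignment hits back to their origin subsection pairs
#'
#' Parses the pseudo-pair names of a realignment SAM, takes each
#' subsection's primary record, and joins former and following hits to
#' the origin split.  Origins where either subsection is unmapped, or
#' where the realigner left no primary record for one side, are dropped
#' (counted in the `dropped` attribute).
#'
#' @param sam_path realignment SAM produced from pseudo pairs named by
#'   [reconstruct_pairs()].
#' @param splits the list of `subsection_pair` objects that generated
#'   the pseudo pairs.
#' @return as [align_subsections()].
#' @export
collate_hits <- function(sam_path, splits) {
  aln <- read_alignments(sam_path)
  keys <- vapply(splits, function(sp) {
    encode_pseudo_name(sp$origin_read_id, sp$origin_mate, sp$split_pos,
                       nchar(sp$former$seq), nchar(sp$following$seq))
  }, character(1))
  for (nm in aln$read_id) decode_pseudo_name(nm)  # validate names early
  out <- list()
  dropped <- 0L
  for (i in seq_along(splits)) {
    rows <- aln[aln$read_id == keys[i], , drop = FALSE]
    f <- rows[rows$mate == 1L & rows$mapped, , drop = FALSE]
    l <- rows[rows$mate == 2L & rows$mapped, , drop = FALSE]
    if (nrow(f) != 1L || nrow(l) != 1L) {
      dropped <- dropped + 1L
      next
    }
    as_hit <- function(r) list(status = "unique", unique = TRUE,
                               chrom = r$chrom, ref_start = r$ref_start,
                               ref_end = r$ref_end, strand = r$strand)
    out[[length(out) + 1L]] <- list(split = splits[[i]],
                                    former_hit = as_hit(as.list(f)),
                                    following_hit = as_hit(as.list(l)))
  }
  attr(out, "dropped") <- dropped
  out
}
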