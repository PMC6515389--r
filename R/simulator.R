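# Ground-truth simulator: a synthetic reference plus paired-end reads
# containing planted direct, inverted, and insertion chimeras with
# engineered junction microhomology, emulating the template-switch
# mechanism of phi29 MDA.  Every pipeline stage is testable against the
# emitted truth table without any external data or aligner.

# uniform integer in [lo, hi] that never falls into sample()'s
# scalar-expansion trap
rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation parameters
#'
#' Defaults describe one synthetic chromosome of 200 kb with 2 x 101 bp
#' reads: 700 normal pairs, 100 direct, 100 inverted and 100 insertion
#' chimeras.  Planted overlaps span the full accepted range (3–30 bp)
#' and subsection lengths the full detectable range (30 bp up to read
#' length − 30).  Junction distances are drawn from `distance_range`
#' with the lower bound raised to `l1 + window` for each plant so the
#' microhomology written upstream of the second locus can never
#' intersect the first locus.
#'
#' @param seed RNG seed; every simulation quantity derives from it.
#' @param ref_length reference length in bp (default 200,000).
#' @param chrom_name name of the single synthetic chromosome.
#' @param read_length read length in bp (default 101).
#' @param insert_mean,insert_sd insert-size distribution for normal
#'   mates (defaults 300 and 30).
#' @param n_normal,n_direct,n_inverted,n_insertion pair counts per
#'   class.
#' @param distance_range junction distance range in bp (default
#'   `c(25, 5000)`).
#' @param overlap_range planted overlap length range in bp (default
#'   `c(3, 30)`).
#' @param subsection_range length range of the first chimera subsection
#'   in bp (default `c(30, read_length - 30)`).
#' @param error_rate per-base substitution error probability applied to
#'   the emitted reads (default 0; nonzero rates are intended for
#'   exercising mismatch-tolerant external realignment — the built-in
#'   aligner is exact-match).
#' @param window overlap-search comparison window the plants are spaced
#'   against (default 31, matching [overlap_params()]).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ref_length = 200000L, chrom_name = "chrS",
                       read_length = 101L, insert_mean = 300L,
                       insert_sd = 30L, n_normal = 700L, n_direct = 100L,
                       n_inverted = 100L, n_insertion = 100L,
                       distance_range = c(25L, 5000L),
                       overlap_range = c(3L, 30L),
                       subsection_range = c(30L, read_length - 30L),
                       error_rate = 0, window = 31L) {
  if (ref_length < 10L * read_length) {
    stop("config error: reference shorter than 10 read lengths")
  }
  stopifnot(subsection_range[1] >= 1L,
            subsection_range[2] <= read_length - 1L,
            overlap_range[1] >= 1L,
            overlap_range[2] <= min(window - 1L, subsection_range[1]),
            distance_range[1] >= 1L, distance_range[2] >= distance_range[1],
            error_rate >= 0, error_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate the synthetic reference
#'
#' Uniform random A/C/G/T of the configured length; deterministic for a
#' given seed.
#'
#' @param config a [sim_config()].
#' @return a [reference_genome()] with one chromosome.
#' @export
make_reference <- function(config) {
  set.seed(config$seed)
  reference_genome(stats::setNames(random_dna(config$ref_length),
                                   config$chrom_name))
}

# is [s, e) at least `margin` away from every reserved interval?
interval_free <- function(occ, s, e, margin) {
  if (nrow(occ) == 0L) return(TRUE)
  all(e + margin <= occ[, 1] | s >= occ[, 2] + margin)
}

#' Simulate a reference and read set with planted chimeras
#'
#' Plants each single-end chimera by choosing two loci a junction
#' distance apart and *writing the overlap into the reference*: the
#' o-mer that ends the first locus's read-oriented slice is copied
#' immediately upstream (in read orientation) of the second locus's
#' start.  The chimeric read is then the exact concatenation of two
#' reference slices — realignment and overlap search see a
#' self-consistent world, mirroring a template switch at a shared
#' sequence.  Plant footprints are kept at least `2 * window` apart so
#' junctions cannot interact; placement failure after 1000 attempts per
#' plant raises an error.
#'
#' Each single-end chimeric read is paired with a normal convergent
#' mate near its anchor locus, so all counts are in read-pair units.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_dataset`: `config`, `ref` (the mutated
#'   [reference_genome()]), `reads` (data.frame: `read_id`, `mate`,
#'   `seq`, `qual` in sequencing orientation), `truth` (data.frame: one
#'   row per pair with `read_id`, `class`, `breakpoint`, locus
#'   coordinates, `distance`, `overlap_len`, `overlap_seq`), and `aln`
#'   (truth-derived alignment records, ready for [write_sam()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$ref_length
  rl <- config$read_length
  w <- config$window
  chrom <- config$chrom_name
  refseq <- random_dna(L)

  slc <- function(s, e) substr(refseq, s + 1L, e)
  oriented <- function(s, e, strand) if (strand == "+") slc(s, e) else rc(slc(s, e))

  occ <- matrix(numeric(0), ncol = 2)
  margin <- 2L * w

  plants <- list()
  classes <- c(rep("DIRECT", config$n_direct),
               rep("INVERTED", config$n_inverted))
  for (cls in classes) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      l1 <- rint(config$subsection_range[1], config$subsection_range[2])
      l2 <- rl - l1
      o <- rint(config$overlap_range[1], config$overlap_range[2])
      strand1 <- c("+", "-")[rint(1L, 2L)]
      strand2 <- if (cls == "DIRECT") strand1 else setdiff(c("+", "-"), strand1)
      dmin <- max(config$distance_range[1], l1 + w)
      if (dmin > config$distance_range[2]) next
      d <- rint(dmin, config$distance_range[2])
      lo <- w + margin
      hi <- L - (d + l2 + w + margin)
      if (hi <= lo) next
      s1 <- rint(lo, hi)
      s2 <- s1 + d
      i1 <- c(s1 - w, s1 + l1 + w)
      i2 <- c(s2 - w, s2 + l2 + w)
      if (interval_free(occ, i1[1], i1[2], margin) &&
          interval_free(occ, i2[1], i2[2], margin)) {
        occ <- rbind(occ, i1, i2)
        # write the microhomology into the reference
        omer <- substr(oriented(s1, s1 + l1, strand1), l1 - o + 1L, l1)
        if (strand2 == "+") {
          substr(refseq, s2 - o + 1L, s2) <- omer
        } else {
          substr(refseq, s2 + l2 + 1L, s2 + l2 + o) <- rc(omer)
        }
        plants[[length(plants) + 1L]] <- list(
          class = cls, l1 = l1, l2 = l2, o = o, d = d,
          s1 = s1, s2 = s2, strand1 = strand1, strand2 = strand2
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: could not place a ", cls,
           " plant after 1000 attempts; enlarge the reference")
    }
  }

  # reference is final from here on; build all reads against it
  qual <- strrep("I", rl)
  reads <- list(); truth <- list(); aln <- list()
  add_read <- function(id, mate, seq) {
    reads[[length(reads) + 1L]] <<- data.frame(
      read_id = id, mate = mate, seq = seq, qual = qual,
      stringsAsFactors = FALSE)
  }
  add_aln <- function(id, mate, flag, pos, cigar, seq) {
    aln[[length(aln) + 1L]] <<- data.frame(
      read_id = id, mate = mate, flag = flag, chrom = chrom,
      ref_start = pos, cigar = cigar, seq = seq, qual = qual,
      stringsAsFactors = FALSE)
  }

  clamp <- function(x, lo, hi) max(lo, min(hi, x))
  draw_insert <- function() {
    clamp(round(stats::rnorm(1, config$insert_mean, config$insert_sd)),
          rl + 10L, 4L * config$insert_mean)
  }

  for (i in seq_along(plants)) {
    p <- plants[[i]]
    id <- sprintf("%s%03d", if (p$class == "DIRECT") "dir" else "inv", i)
    read <- paste0(oriented(p$s1, p$s1 + p$l1, p$strand1),
                   oriented(p$s2, p$s2 + p$l2, p$strand2))
    add_read(id, 1L, read)
    if (p$strand1 == "+") {
      add_aln(id, 1L, 97L, p$s1, paste0(p$l1, "M", p$l2, "S"), read)
    } else {
      add_aln(id, 1L, 81L, p$s1, paste0(p$l2, "S", p$l1, "M"), rc(read))
    }
    # convergent normal partner anchored at locus1
    ins <- draw_insert()
    if (p$strand1 == "+") {
      m2s <- clamp(p$s1 + ins - rl, 0L, L - rl)
      add_read(id, 2L, rc(slc(m2s, m2s + rl)))
      add_aln(id, 2L, 145L, m2s, paste0(rl, "M"), slc(m2s, m2s + rl))
    } else {
      m2s <- clamp(p$s1 + p$l1 - ins, 0L, L - rl)
      add_read(id, 2L, slc(m2s, m2s + rl))
      add_aln(id, 2L, 161L, m2s, paste0(rl, "M"), slc(m2s, m2s + rl))
    }
    omer <- substr(oriented(p$s1, p$s1 + p$l1, p$strand1),
                   p$l1 - p$o + 1L, p$l1)
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = id, class = p$class, breakpoint = p$l1,
      chrom1 = chrom, start1 = p$s1, end1 = p$s1 + p$l1, strand1 = p$strand1,
      chrom2 = chrom, start2 = p$s2, end2 = p$s2 + p$l2, strand2 = p$strand2,
      distance = p$d, overlap_len = p$o, overlap_seq = omer,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(config$n_insertion)) {
    id <- sprintf("ins%03d", i)
    strand <- c("+", "-")[rint(1L, 2L)]
    d <- rint(config$distance_range[1], config$distance_range[2])
    p1 <- rint(0L, L - (d + rl) - 1L)
    p2 <- p1 + d
    for (m in 1:2) {
      s <- if (m == 1L) p1 else p2
      fwd <- slc(s, s + rl)
      add_read(id, m, if (strand == "+") fwd else rc(fwd))
      flag <- if (strand == "+") c(65L, 129L)[m] else c(113L, 177L)[m]
      add_aln(id, m, flag, s, paste0(rl, "M"), fwd)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = id, class = "INSERTION", breakpoint = NA_integer_,
      chrom1 = chrom, start1 = p1, end1 = p1 + rl, strand1 = strand,
      chrom2 = chrom, start2 = p2, end2 = p2 + rl, strand2 = strand,
      distance = d, overlap_len = NA_integer_, overlap_seq = "",
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(config$n_normal)) {
    id <- sprintf("norm%03d", i)
    ins <- draw_insert()
    p1 <- rint(0L, L - ins - 1L)
    p2 <- p1 + ins - rl
    add_read(id, 1L, slc(p1, p1 + rl))
    add_aln(id, 1L, 99L, p1, paste0(rl, "M"), slc(p1, p1 + rl))
    add_read(id, 2L, rc(slc(p2, p2 + rl)))
    add_aln(id, 2L, 147L, p2, paste0(rl, "M"), slc(p2, p2 + rl))
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = id, class = "NORMAL", breakpoint = NA_integer_,
      chrom1 = chrom, start1 = p1, end1 = p1 + rl, strand1 = "+",
      chrom2 = chrom, start2 = p2, end2 = p2 + rl, strand2 = "-",
      distance = NA_integer_, overlap_len = NA_integer_, overlap_seq = "",
      stringsAsFactors = FALSE)
  }

  reads <- do.call(rbind, reads)
  aln <- do.call(rbind, aln)
  truth <- do.call(rbind, truth)

  if (config$error_rate > 0) {
    mutate_read <- function(seq) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(chars)) < config$error_rate)
      for (j in hit) {
        chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
      }
      paste(chars, collapse = "")
    }
    reads$seq <- vapply(reads$seq, mutate_read, character(1),
                        USE.NAMES = FALSE)
    # keep the truth SAM consistent with the errored reads
    stored <- ifelse(flag_bit(aln$flag, 0x10), rc(reads$seq), reads$seq)
    aln$seq <- stored
  }

  aln$mapped <- TRUE
  aln$proper <- flag_bit(aln$flag, 0x2)
  aln$strand <- ifelse(flag_bit(aln$flag, 0x10), "-", "+")
  aln$mate_strand <- ifelse(flag_bit(aln$flag, 0x20), "-", "+")
  aln$ref_end <- aln$ref_start +
    vapply(aln$cigar, function(cg) cigar_ref_span(parse_cigar(cg)),
           integer(1), USE.NAMES = FALSE)

  structure(
    list(config = config,
         ref = reference_genome(stats::setNames(refseq, chrom)),
         reads = reads, truth = truth, aln = aln),
    class = "sim_dataset"
  )
}

#' Write a simulated dataset to disk
#'
#' Emits the reference FASTA, the paired FASTQ files (reads in
#' sequencing orientation), the truth table TSV, and a truth-derived SAM
#' in which each single-end chimeric read appears as a soft-clipped
#' record at its first locus — so the pipeline can be run end to end
#' with no aligner at all.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param prefix output path prefix; writes `<prefix>.fa`,
#'   `<prefix>_1.fq`, `<prefix>_2.fq`, `<prefix>.truth.tsv`,
#'   `<prefix>.sam`.
#' @return named character vector of the five paths, invisibly.
#' @export
emit_simulation <- function(dataset, prefix) {
  paths <- c(fasta = paste0(prefix, ".fa"),
             fq1 = paste0(prefix, "_1.fq"),
             fq2 = paste0(prefix, "_2.fq"),
             truth = paste0(prefix, ".truth.tsv"),
             sam = paste0(prefix, ".sam"))
  Biostrings::writeXStringSet(dataset$ref$dna, paths["fasta"])
  for (m in 1:2) {
    sub <- dataset$reads[dataset$reads$mate == m, , drop = FALSE]
    dna <- Biostrings::DNAStringSet(sub$seq)
    names(dna) <- sub$read_id
    Biostrings::writeXStringSet(dna, paths[[paste0("fq", m)]],
                                format = "fastq",
                                qualities = Biostrings::BStringSet(sub$qual))
  }
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  write_sam(dataset$aln, dataset$ref, paths["sam"])
  invisible(paths)
}
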