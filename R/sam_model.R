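#' mdachimera: chimeric-read detection for MDA sequencing data
#'
#' Multiple displacement amplification (MDA) with phi29 DNA polymerase
#' produces chimeric reads when a displaced 3' end anneals to a nearby
#' template at a short shared sequence (microhomology) and elongation
#' continues from the new locus.  The resulting reads join two genomic
#' segments that are close on a chromosome but not contiguous, and they
#' inflate false positives in downstream analyses, most visibly inversion
#' calls in structural-variant detection.
#'
#' The package classifies chimeras into three types:
#' \describe{
#'   \item{direct}{single-end chimera whose two subsections map to the
#'     same strand;}
#'   \item{inverted}{single-end chimera whose two subsections map to
#'     opposite strands;}
#'   \item{insertion}{paired-end chimera whose junction lies in the
#'     unsequenced insert, detected as both mates mapping to the same
#'     strand.}
#' }
#'
#' The detection pipeline has three stages: (A) pair classification from
#' SAM FLAG values ([classify_pair()]), (B) splitting of soft-clipped
#' reads into subsections and realignment ([split_read()],
#' [naive_align()]), and (C) a two-sided cyclical overlap search for the
#' junction microhomology followed by validity filtering
#' ([search_overlap_tail()], [validate_candidate()]).  [detect_chimeras()]
#' runs all three stages end to end; [simulate_dataset()] generates
#' references and reads with planted ground-truth chimeras for testing.
#'
#' @keywords internal
"_PACKAGE"

# ---- reference genome ------------------------------------------------------

#' Build an in-memory reference genome
#'
#' Holds each chromosome as an uppercase DNA string together with its
#' length.  Bases outside A/C/G/T/N are replaced by N (with a warning),
#' matching the rule that N never matches any base during overlap
#' comparison or exact realignment.
#'
#' @param sequences named character vector or named list of DNA strings,
#'   one element per chromosome.
#' @return an object of class `reference_genome` with elements
#'   `sequences` (named character), `lengths` (named integer) and `dna`
#'   (a [Biostrings::DNAStringSet] used for pattern matching).
#' @examples
#' ref <- reference_genome(c(chrA = "ACGTACGT"))
#' ref$lengths
#' @export
reference_genome <- function(sequences) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all reference sequences must be named by chromosome")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicated chromosome names in reference")
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    warning("non-ACGTN characters in reference replaced by N")
    sequences[bad] <- gsub("[^ACGTN]", "N", sequences[bad])
  }
  structure(
    list(
      sequences = sequences,
      lengths = stats::setNames(nchar(sequences), names(sequences)),
      dna = Biostrings::DNAStringSet(sequences)
    ),
    class = "reference_genome"
  )
}

#' Read a reference genome from a FASTA file
#'
#' Whole-load of a (small) FASTA reference; sequence names are truncated
#' at the first whitespace, as aligners do.
#'
#' @param path FASTA file path.
#' @return a [reference_genome()] object.
#' @export
read_reference <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  reference_genome(stats::setNames(as.character(dna), names(dna)))
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$sequences), "sequence(s),",
      sum(as.numeric(x$lengths)), "bp total\n")
  invisible(x)
}

# reverse complement that preserves N
rc <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Fetch an oriented, N-padded slice of the reference
#'
#' Coordinates are 0-based half-open.  Positions outside
#' `[0, chromosome length)` are padded with `N` so the returned string
#' always has length `end - start`; strand `"-"` returns the reverse
#' complement of the (padded) forward slice.  This is the primitive used
#' to read the reference context around a junction when searching for the
#' overlap microhomology.
#'
#' @param ref a [reference_genome()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval (may extend out of range).
#' @param strand `"+"` or `"-"`.
#' @return a character scalar of length `end - start`.
#' @examples
#' ref <- reference_genome(c(c1 = "ACGTAC"))
#' fetch_oriented(ref, "c1", 1, 4, "+")  # "CGT"
#' fetch_oriented(ref, "c1", 1, 4, "-")  # "ACG"
#' fetch_oriented(ref, "c1", -2, 2, "+") # "NNAC"
#' @export
fetch_oriented <- function(ref, chrom, start, end, strand = "+") {
  stopifnot(inherits(ref, "reference_genome"))
  if (!chrom %in% names(ref$sequences)) {
    stop("unknown chromosome: ", chrom)
  }
  stopifnot(end >= start, strand %in% c("+", "-"))
  L <- ref$lengths[[chrom]]
  s <- max(start, 0L)
  e <- min(end, L)
  core <- if (s < e) substr(ref$sequences[[chrom]], s + 1L, e) else ""
  left_pad <- max(0L, min(end, 0L) - start)        # positions below 0
  right_pad <- (end - start) - left_pad - nchar(core)  # positions >= L
  out <- paste0(strrep("N", left_pad), core, strrep("N", right_pad))
  if (strand == "-") out <- rc(out)
  out
}

# ---- CIGAR -----------------------------------------------------------------

CIGAR_OPS <- c("M", "I", "D", "S", "H", "N", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string
#'
#' @param text a CIGAR string, or `"*"` for an unmapped record.
#' @return a data.frame with columns `op` (one of M,I,D,S,H,N,=,X) and
#'   `len` (positive integer); zero rows for `"*"`.
#' @examples
#' parse_cigar("70M31S")
#' @export
parse_cigar <- function(text) {
  empty <- data.frame(op = character(), len = integer())
  if (is.na(text) || identical(text, "*")) return(empty)
  m <- gregexpr("([0-9]+)([MIDSHN=X])", text)[[1]]
  toks <- if (m[1] == -1L) character() else regmatches(text, gregexpr("([0-9]+)([MIDSHN=X])", text))[[1]]
  if (sum(nchar(toks)) != nchar(text)) {
    # locate the first span not covered by a valid token
    covered <- rep(FALSE, nchar(text))
    if (m[1] != -1L) {
      for (i in seq_along(m)) {
        covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
      }
    }
    at <- which(!covered)[1]
    stop(sprintf("malformed CIGAR %s: unparseable at position %d ('%s')",
                 text, at, substr(text, at, min(nchar(text), at + 4L))))
  }
  len <- as.integer(sub("[MIDSHN=X]$", "", toks))
  op <- substr(toks, nchar(toks), nchar(toks))
  if (any(len < 1L)) {
    stop(sprintf("malformed CIGAR %s: zero-length operation '%s'",
                 text, toks[which(len < 1L)[1]]))
  }
  data.frame(op = op, len = len)
}

#' Query and reference lengths implied by a CIGAR
#'
#' `cigar_query_length()` sums the query-consuming operations
#' (M, I, S, =, X); `cigar_ref_span()` sums the reference-consuming
#' operations (M, D, N, =, X).
#'
#' @param cigar a parsed CIGAR data.frame from [parse_cigar()].
#' @return integer scalar.
#' @export
cigar_query_length <- function(cigar) {
  sum(cigar$len[cigar$op %in% QUERY_OPS])
}

#' @rdname cigar_query_length
#' @export
cigar_ref_span <- function(cigar) {
  sum(cigar$len[cigar$op %in% REF_OPS])
}

#' Terminal soft-clip profile of a CIGAR
#'
#' Hard clips carry no sequence and are ignored; after dropping them, a
#' soft clip (S) is only legal at the first and/or last position.
#'
#' @param cigar a parsed CIGAR data.frame (nonempty).
#' @return a list with `leading` and `trailing` soft-clip lengths (0 when
#'   absent) and `aligned_query_len`, the summed M/I/=/X length.
#' @examples
#' soft_clip_profile(parse_cigar("64M37S"))
#' @export
soft_clip_profile <- function(cigar) {
  if (nrow(cigar) == 0L) stop("empty CIGAR has no clip profile")
  core <- cigar[cigar$op != "H", , drop = FALSE]
  if (nrow(core) == 0L) stop("CIGAR contains only hard clips")
  s_at <- which(core$op == "S")
  interior <- setdiff(s_at, c(1L, nrow(core)))
  if (length(interior)) {
    stop("unsupported CIGAR: soft clip in interior position")
  }
  leading <- if (1L %in% s_at) core$len[1L] else 0L
  trailing <- if (nrow(core) > 1L && nrow(core) %in% s_at) core$len[nrow(core)] else 0L
  list(
    leading = as.integer(leading),
    trailing = as.integer(trailing),
    aligned_query_len = as.integer(sum(core$len[core$op %in% c("M", "I", "=", "X")]))
  )
}

# ---- SAM ingest / emission -------------------------------------------------

flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read primary alignments from a SAM/BAM file
#'
#' Loads all primary records (FLAG bits 0x100 and 0x800 excluded) into a
#' data.frame, converting positions to the package's internal 0-based
#' half-open convention.  Sequences are kept exactly as stored in the SAM
#' record (i.e. reverse-complemented by the aligner for minus-strand
#' alignments).  Plain SAM is converted through [Rsamtools::asBam()].
#'
#' @param path a SAM (or BAM) file.
#' @return a data.frame with one row per primary record and columns
#'   `read_id`, `mate` (1 or 2), `flag`, `mapped`, `proper`, `strand`,
#'   `mate_strand` (NA when the mate is unmapped), `chrom`, `ref_start`
#'   (0-based), `ref_end` (exclusive), `cigar`, `seq`, `qual`.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  if (n == 0L) {
    return(data.frame(
      read_id = character(), mate = integer(), flag = integer(),
      mapped = logical(), proper = logical(), strand = character(),
      mate_strand = character(), chrom = character(), ref_start = integer(),
      ref_end = integer(), cigar = character(), seq = character(),
      qual = character(), stringsAsFactors = FALSE
    ))
  }
  flag <- x$flag
  mapped <- !flag_bit(flag, 0x4)
  cig <- as.character(x$cigar)
  cig[!mapped | is.na(cig)] <- "*"
  ref_start <- ifelse(mapped, x$pos - 1L, NA_integer_)
  span <- vapply(cig, function(cg) cigar_ref_span(parse_cigar(cg)),
                 integer(1), USE.NAMES = FALSE)
  data.frame(
    read_id = x$qname,
    mate = ifelse(flag_bit(flag, 0x80), 2L, 1L),
    flag = flag,
    mapped = mapped,
    proper = flag_bit(flag, 0x1) & flag_bit(flag, 0x2),
    strand = ifelse(flag_bit(flag, 0x10), "-", "+"),
    mate_strand = ifelse(!flag_bit(flag, 0x1) | flag_bit(flag, 0x8),
                         NA_character_,
                         ifelse(flag_bit(flag, 0x20), "-", "+")),
    chrom = ifelse(mapped, as.character(x$rname), NA_character_),
    ref_start = ref_start,
    ref_end = ifelse(mapped, ref_start + span, NA_integer_),
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    cigar = cig,
    stringsAsFactors = FALSE
  )
}

#' Write alignment records as a SAM text file
#'
#' The converse of [read_alignments()]: emits a minimal, valid SAM file
#' (with `@SQ` header lines taken from the reference) from an alignment
#' data.frame carrying `read_id`, `flag`, `chrom`, `ref_start` (0-based),
#' `cigar`, `seq` and `qual` columns.  Mate position fields (RNEXT/PNEXT)
#' are filled from the other record with the same `read_id` when present.
#'
#' @param aln alignment data.frame (see [read_alignments()] for columns).
#' @param ref a [reference_genome()] supplying the header.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref$lengths), ref$lengths)
  )
  lines <- character(nrow(aln))
  pos1 <- ifelse(is.na(aln$ref_start), 0L, aln$ref_start + 1L)
  for (i in seq_len(nrow(aln))) {
    mate_rows <- which(aln$read_id == aln$read_id[i] & seq_len(nrow(aln)) != i)
    rnext <- "*"; pnext <- 0L
    if (length(mate_rows)) {
      j <- mate_rows[1]
      if (!is.na(aln$chrom[j])) {
        rnext <- if (!is.na(aln$chrom[i]) && aln$chrom[j] == aln$chrom[i]) "=" else aln$chrom[j]
        pnext <- pos1[j]
      }
    }
    lines[i] <- paste(
      aln$read_id[i], aln$flag[i],
      ifelse(is.na(aln$chrom[i]), "*", aln$chrom[i]),
      pos1[i],
      ifelse(is.na(aln$chrom[i]), 0L, 60L),
      aln$cigar[i], rnext, pnext, 0L, aln$seq[i], aln$qual[i],
      sep = "\t"
    )
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
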