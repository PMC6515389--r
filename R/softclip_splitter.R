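# Stage B part 1: minimum-length rule, splitting soft-clipped reads at
# the clip boundary, and reconstruction of pseudo paired-end reads for
# realignment.

#' Minimum allowed soft-clipped subsection length for a chromosome
#'
#' A clipped fragment shorter than `floor(log4(L)) + 1` bases is expected
#' to occur by chance somewhere on a chromosome of length `L`, so such
#' subsections tend to be multi-aligned and are removed.  For human
#' chromosome 1 (249,250,621 bp) the minimum is 14 bp.  The floor is
#' evaluated by exact integer comparison against powers of 4, never
#' through floating-point logarithms.
#'
#' @param chromosome_length chromosome length(s) in bp (vectorised).
#' @return integer vector of minimum subsection lengths in bp.
#' @examples
#' min_softclip_length(249250621)  # 14
#' min_softclip_length(4)          # 2
#' @export
min_softclip_length <- function(chromosome_length) {
  if (any(is.na(chromosome_length)) || any(chromosome_length < 1)) {
    stop("chromosome length must be a positive number")
  }
  vapply(chromosome_length, function(L) {
    k <- 0L
    p <- 1
    while (p * 4 <= L) {
      p <- p * 4
      k <- k + 1L
    }
    k + 1L
  }, integer(1))
}

#' Splitting parameters
#'
#' @param hard_floor absolute minimum subsection length in bp; clipped
#'   reads with a subsection shorter than this are removed regardless of
#'   chromosome length (default 8).
#' @param both_ends_policy what to do with reads soft-clipped at both
#'   ends: `"longer"` splits at the longer clip, leaving the shorter
#'   clip's bases attached to the aligned part; `"skip"` drops the read.
#' @return a list of class `split_params`.
#' @export
split_params <- function(hard_floor = 8L, both_ends_policy = c("longer", "skip")) {
  stopifnot(hard_floor >= 1L)
  structure(
    list(hard_floor = as.integer(hard_floor),
         both_ends_policy = match.arg(both_ends_policy)),
    class = "split_params"
  )
}

#' Split a soft-clipped read into its two subsections
#'
#' Cuts the stored read sequence exactly at the soft-clip boundary into a
#' `former` and a `following` subsection (read coordinates, 0-based
#' half-open, former before following in the stored orientation).  The
#' read is rejected (`NULL`) when it carries no terminal soft clip, or
#' when the shorter subsection is below
#' `max(hard_floor, min_softclip_length(L))` for the chromosome the
#' aligned part mapped to.  Both subsections face the same gate: a
#' too-short mapped remainder is as ambiguous on realignment as a
#' too-short clip.
#'
#' @param record a mapped primary alignment record (list or one-row
#'   data.frame with `read_id`, `mate`, `seq`, `qual`, `cigar`, `chrom`,
#'   `ref_start`, `ref_end`, `strand`).
#' @param ref a [reference_genome()].
#' @param params a [split_params()] (or [chimera_params()]) list.
#' @return a list of class `subsection_pair` with elements
#'   `origin_read_id`, `origin_mate`, `origin_sequence`, `origin_qual`,
#'   `split_pos`, `former` and `following` (each `list(seq, read_start,
#'   read_end, qual)`), and `anchor` (`list(role, chrom, start, end,
#'   strand)` describing the originally mapped part) — or `NULL` when the
#'   read does not qualify.
#' @export
split_read <- function(record, ref, params = split_params()) {
  record <- as.list(record)
  if (!isTRUE(record$mapped) || is.na(record$seq) || !nzchar(record$seq)) {
    stop("split_read requires a mapped primary record with sequence")
  }
  prof <- soft_clip_profile(parse_cigar(record$cigar))
  if (prof$leading == 0L && prof$trailing == 0L) return(NULL)
  clip_side <- if (prof$leading >= prof$trailing) "leading" else "trailing"
  if (prof$leading > 0L && prof$trailing > 0L) {
    if (params$both_ends_policy == "skip") return(NULL)
    # "longer": split at the longer clip (ties go to the leading clip)
  } else {
    clip_side <- if (prof$leading > 0L) "leading" else "trailing"
  }
  read_len <- nchar(record$seq)
  clip_len <- if (clip_side == "leading") prof$leading else prof$trailing
  min_len <- max(params$hard_floor,
                 min_softclip_length(ref$lengths[[record$chrom]]))
  if (min(clip_len, read_len - clip_len) < min_len) return(NULL)
  split_pos <- if (clip_side == "leading") clip_len else read_len - clip_len
  piece <- function(a, b) list(
    seq = substr(record$seq, a + 1L, b),
    read_start = as.integer(a),
    read_end = as.integer(b),
    qual = substr(record$qual, a + 1L, b)
  )
  former <- piece(0L, split_pos)
  following <- piece(split_pos, read_len)
  anchor_role <- if (clip_side == "leading") "following" else "former"
  structure(
    list(
      origin_read_id = as.character(record$read_id),
      origin_mate = as.integer(record$mate),
      origin_sequence = record$seq,
      origin_qual = record$qual,
      split_pos = as.integer(split_pos),
      former = former,
      following = following,
      anchor = list(role = anchor_role, chrom = record$chrom,
                    start = record$ref_start, end = record$ref_end,
                    strand = record$strand)
    ),
    class = "subsection_pair"
  )
}

# lossless name encoding for pseudo pairs: '%' and '|' in the read id are
# percent-escaped so '|' can delimit the five fields unambiguously
encode_pseudo_name <- function(read_id, mate, split_pos, len_former, len_following) {
  id <- gsub("|", "%7C", gsub("%", "%25", read_id, fixed = TRUE), fixed = TRUE)
  paste(id, mate, split_pos, len_former, len_following, sep = "|")
}

decode_pseudo_name <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)[[1]]
  if (length(parts) != 5L) {
    stop("join error: unparseable pseudo-pair name '", name, "'")
  }
  id <- gsub("%25", "%", gsub("%7C", "|", parts[1], fixed = TRUE), fixed = TRUE)
  list(read_id = id, mate = as.integer(parts[2]),
       split_pos = as.integer(parts[3]),
       len_former = as.integer(parts[4]),
       len_following = as.integer(parts[5]))
}

#' Reconstruct pseudo paired-end reads from subsection pairs
#'
#' Each split read becomes one pseudo pair: mate 1 is the former
#' subsection, mate 2 the following subsection, under a derived name that
#' encodes the origin read id, mate, split position and subsection
#' lengths, and is parseable back without ambiguity.  Qualities are the
#' corresponding slices of the origin read's quality string.
#'
#' @param splits a list of `subsection_pair` objects from [split_read()].
#' @return a data.frame with columns `name`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, in input order.
#' @export
reconstruct_pairs <- function(splits) {
  if (length(splits) == 0L) {
    return(data.frame(name = character(), seq1 = character(),
                      qual1 = character(), seq2 = character(),
                      qual2 = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(splits, function(sp) {
    data.frame(
      name = encode_pseudo_name(sp$origin_read_id, sp$origin_mate,
                                sp$split_pos, nchar(sp$former$seq),
                                nchar(sp$following$seq)),
      seq1 = sp$former$seq, qual1 = sp$former$qual,
      seq2 = sp$following$seq, qual2 = sp$following$qual,
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(out$name)) {
    stop("pseudo-pair name collision; origin records are not unique")
  }
  rownames(out) <- NULL
  out
}

#' Write pseudo pairs as paired FASTQ files
#'
#' @param pairs data.frame from [reconstruct_pairs()].
#' @param out1,out2 output FASTQ paths (former subsections in `out1`,
#'   following in `out2`).
#' @return `c(out1, out2)`, invisibly.
#' @export
write_pseudo_fastq <- function(pairs, out1, out2) {
  wr <- function(seqs, quals, names, path) {
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- names
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(pairs$seq1, pairs$qual1, pairs$name, out1)
  wr(pairs$seq2, pairs$qual2, pairs$name, out2)
  invisible(c(out1, out2))
}
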