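# Stage C: orient realigned subsection pairs, search both sides of the
# junction for the overlap microhomology with a cyclical shortening
# loop, and apply the validity filters.

#' Overlap-search and validity parameters
#'
#' The comparison window is 31 nt while the accepted overlap is capped at
#' 30 bp: the 31st base supports mismatch-position evaluation.  One
#' mismatch is tolerated inside a candidate overlap but never at its
#' first (5'-most, read-orientation) base; N on either side counts as a
#' mismatch.  Validity requires both subsections at least 30 bp, a
#' genomic distance between the subsection start coordinates of
#' 25–5000 bp, and an overlap longer than two bases.
#'
#' @param window comparison window in bp (default 31).
#' @param max_overlap longest accepted overlap in bp (default 30).
#' @param min_overlap shortest accepted overlap in bp (default 3).
#' @param max_mismatches tolerated mismatches per candidate overlap
#'   (default 1).
#' @param min_subsection minimum subsection length in bp for a valid
#'   chimera (default 30).
#' @param distance_min,distance_max accepted genomic distance range in
#'   bp (defaults 25 and 5000).
#' @return a list of class `overlap_params`.
#' @export
overlap_params <- function(window = 31L, max_overlap = 30L, min_overlap = 3L,
                           max_mismatches = 1L, min_subsection = 30L,
                           distance_min = 25L, distance_max = 5000L) {
  p <- list(window = as.integer(window), max_overlap = as.integer(max_overlap),
            min_overlap = as.integer(min_overlap),
            max_mismatches = as.integer(max_mismatches),
            min_subsection = as.integer(min_subsection),
            distance_min = as.integer(distance_min),
            distance_max = as.integer(distance_max))
  stopifnot(p$min_overlap >= 1L, p$min_overlap <= p$max_overlap,
            p$max_overlap <= p$window, p$distance_min <= p$distance_max,
            p$max_mismatches >= 0L)
  structure(p, class = "overlap_params")
}

#' Genomic distance between two realignment hits
#'
#' The absolute difference between the two hits' 0-based reference start
#' coordinates; `NA` when the hits lie on different chromosomes.
#'
#' @param former_hit,following_hit unique hits as returned by
#'   [naive_align()].
#' @return distance in bp, or `NA`.
#' @export
genomic_distance <- function(former_hit, following_hit) {
  if (!identical(former_hit$chrom, following_hit$chrom)) return(NA_integer_)
  abs(former_hit$ref_start - following_hit$ref_start)
}

# mismatch profile of two equal-length strings: TRUE where the bases
# differ or either base is N
mismatch_profile <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  av != bv | av == "N" | bv == "N"
}

# pad/trim x to exactly w characters, keeping the end given by side
fit_window <- function(x, w, side = c("tail", "head")) {
  side <- match.arg(side)
  n <- nchar(x)
  if (n >= w) {
    if (side == "tail") substr(x, n - w + 1L, n) else substr(x, 1L, w)
  } else {
    pad <- strrep("N", w - n)
    if (side == "tail") paste0(pad, x) else paste0(x, pad)
  }
}

#' Search for the junction overlap at the tail of the former subsection
#'
#' Assumes the overlap lies at the end of the former subsection.  The
#' last `window` bases of the former subsection (N-padded at the front
#' when shorter) are compared against the `window` reference bases
#' immediately preceding the following subsection's first aligned base
#' in its reading orientation (plus strand: positions
#' `[start - window, start)` forward; minus strand: `[end, end + window)`
#' reverse-complemented; out-of-range positions are N).  The comparison
#' is cyclical: starting from `max_overlap` the candidate length is
#' shortened one nucleotide per loop until a suffix with at most
#' `max_mismatches` mismatches — and an exact match at its first base —
#' is found, or `min_overlap` is passed.
#'
#' @param former `list(seq = subsection DNA, hit = unique hit)` for the
#'   former subsection.
#' @param following same structure for the following subsection.
#' @param ref a [reference_genome()].
#' @param p an [overlap_params()] list.
#' @return `list(seq, length, side = "tail")` for the longest accepted
#'   overlap (sequence reported in read orientation), or `NULL`.
#' @export
search_overlap_tail <- function(former, following, ref, p = overlap_params()) {
  w <- p$window
  tail_seq <- fit_window(former$seq, w, "tail")
  hit <- following$hit
  ext <- if (hit$strand == "+") {
    fetch_oriented(ref, hit$chrom, hit$ref_start - w, hit$ref_start, "+")
  } else {
    fetch_oriented(ref, hit$chrom, hit$ref_end, hit$ref_end + w, "-")
  }
  mm <- mismatch_profile(tail_seq, ext)
  for (k in seq(p$max_overlap, p$min_overlap)) {
    first <- w - k + 1L
    if (!mm[first] && sum(mm[first:w]) <= p$max_mismatches) {
      return(list(seq = substr(tail_seq, first, w), length = k,
                  side = "tail"))
    }
  }
  NULL
}

#' Search for the junction overlap at the head of the following subsection
#'
#' Mirror of [search_overlap_tail()]: the first `window` bases of the
#' following subsection (N-padded at the back when shorter) are compared
#' against the `window` reference bases immediately after the former
#' subsection's last aligned base in its reading orientation (plus
#' strand: `[end, end + window)` forward; minus strand:
#' `[start - window, start)` reverse-complemented).  The first-base
#' exact-match rule applies to the k-mer's first base, which for
#' prefixes is the first base of the following subsection.
#'
#' @inheritParams search_overlap_tail
#' @return `list(seq, length, side = "head")`, or `NULL`.
#' @export
search_overlap_head <- function(former, following, ref, p = overlap_params()) {
  w <- p$window
  head_seq <- fit_window(following$seq, w, "head")
  hit <- former$hit
  ext <- if (hit$strand == "+") {
    fetch_oriented(ref, hit$chrom, hit$ref_end, hit$ref_end + w, "+")
  } else {
    fetch_oriented(ref, hit$chrom, hit$ref_start - w, hit$ref_start, "-")
  }
  mm <- mismatch_profile(head_seq, ext)
  for (k in seq(p$max_overlap, p$min_overlap)) {
    if (!mm[1L] && sum(mm[1:k]) <= p$max_mismatches) {
      return(list(seq = substr(head_seq, 1L, k), length = k, side = "head"))
    }
  }
  NULL
}

#' Pick the final overlap from the two one-sided searches
#'
#' When both sides discovered an overlap the longer one is selected;
#' on a tie the tail-side result is kept (and so recorded in the
#' output).
#'
#' @param tail_result,head_result results of [search_overlap_tail()] and
#'   [search_overlap_head()] (either may be `NULL`).
#' @return the selected overlap, or `NULL` when neither side found one.
#' @export
resolve_overlap <- function(tail_result, head_result) {
  if (is.null(tail_result)) return(head_result)
  if (is.null(head_result)) return(tail_result)
  if (head_result$length > tail_result$length) head_result else tail_result
}

#' Assemble a candidate chimera from a realigned subsection pair
#'
#' Derives the orientation class from the two hits' strands (equal
#' strands: direct; opposite: inverted), computes the genomic distance,
#' and, when both hits share a chromosome, runs the two-sided overlap
#' search and resolves the final overlap.
#'
#' @param triple `list(split, former_hit, following_hit)` as produced by
#'   [align_subsections()] or [collate_hits()].
#' @param ref a [reference_genome()].
#' @param p an [overlap_params()] list.
#' @return a list of class `candidate_chimera`.
#' @export
build_candidate <- function(triple, ref, p = overlap_params()) {
  sp <- triple$split
  fh <- triple$former_hit
  lh <- triple$following_hit
  overlap <- NULL
  if (identical(fh$chrom, lh$chrom)) {
    tl <- search_overlap_tail(list(seq = sp$former$seq, hit = fh),
                              list(seq = sp$following$seq, hit = lh), ref, p)
    hd <- search_overlap_head(list(seq = sp$former$seq, hit = fh),
                              list(seq = sp$following$seq, hit = lh), ref, p)
    overlap <- resolve_overlap(tl, hd)
  }
  structure(
    list(
      read_id = sp$origin_read_id,
      mate = sp$origin_mate,
      former = list(seq = sp$former$seq, hit = fh),
      following = list(seq = sp$following$seq, hit = lh),
      orientation = if (identical(fh$strand, lh$strand)) "DIRECT" else "INVERTED",
      genomic_distance = genomic_distance(fh, lh),
      overlap = overlap
    ),
    class = "candidate_chimera"
  )
}

#' Apply the validity filters to a candidate chimera
#'
#' A candidate is valid when both subsections are at least
#' `min_subsection` bp, the genomic distance is defined and lies in
#' `[distance_min, distance_max]`, and an overlap of at least
#' `min_overlap` bases was discovered.  A failing candidate gets a
#' single dominant rejection reason in fixed precedence:
#' subsection, then distance, then overlap.
#'
#' @param cand a `candidate_chimera` from [build_candidate()].
#' @param p an [overlap_params()] list.
#' @return `list(valid = TRUE, type = orientation)` or
#'   `list(valid = FALSE, reason = "subsection"|"distance"|"overlap")`.
#' @export
validate_candidate <- function(cand, p = overlap_params()) {
  if (nchar(cand$former$seq) < p$min_subsection ||
      nchar(cand$following$seq) < p$min_subsection) {
    return(list(valid = FALSE, reason = "subsection"))
  }
  d <- cand$genomic_distance
  if (is.na(d) || d < p$distance_min || d > p$distance_max) {
    return(list(valid = FALSE, reason = "distance"))
  }
  if (is.null(cand$overlap) || cand$overlap$length < p$min_overlap) {
    return(list(valid = FALSE, reason = "overlap"))
  }
  list(valid = TRUE, type = cand$orientation)
}
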