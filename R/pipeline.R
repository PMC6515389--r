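# Orchestration: the end-to-end detect() run, report arithmetic, and
# the read-id filter list for downstream SV workflows.

TSV_COLUMNS <- c("read_id", "type", "chrom", "former_start", "former_end",
                 "former_strand", "following_start", "following_end",
                 "following_strand", "distance", "overlap_len",
                 "overlap_seq", "overlap_side")

#' Full parameter set for a detection run
#'
#' Combines the splitting gates, the overlap-search settings, and the
#' pair-classification options into one flat list accepted by every
#' stage.
#'
#' @inheritParams split_params
#' @inheritParams overlap_params
#' @param max_insertion_distance genomic-distance ceiling for calling a
#'   same-strand pair an insertion chimera (default `Inf`: the
#'   same-strand criterion alone decides).
#' @return a list of class `chimera_params` that also satisfies the
#'   `split_params` and `overlap_params` interfaces.
#' @export
chimera_params <- function(hard_floor = 8L,
                           both_ends_policy = c("longer", "skip"),
                           window = 31L, max_overlap = 30L, min_overlap = 3L,
                           max_mismatches = 1L, min_subsection = 30L,
                           distance_min = 25L, distance_max = 5000L,
                           max_insertion_distance = Inf) {
  sp <- split_params(hard_floor, both_ends_policy)
  op <- overlap_params(window, max_overlap, min_overlap, max_mismatches,
                       min_subsection, distance_min, distance_max)
  structure(c(unclass(sp), unclass(op),
              list(max_insertion_distance = max_insertion_distance)),
            class = c("chimera_params", "split_params", "overlap_params"))
}

#' Pair-level chimeric rate
#'
#' Chimeric read pairs divided by total read pairs; 0 when no pairs were
#' seen.
#'
#' @param chimeric_pair_count,total_pairs non-negative pair counts with
#'   `chimeric_pair_count <= total_pairs`.
#' @return a fraction in `[0, 1]`.
#' @export
chimeric_rate <- function(chimeric_pair_count, total_pairs) {
  if (chimeric_pair_count < 0 || total_pairs < 0) {
    stop("counts must be non-negative")
  }
  if (total_pairs < chimeric_pair_count) {
    stop("total pairs smaller than chimeric pairs")
  }
  if (total_pairs == 0) return(0)
  chimeric_pair_count / total_pairs
}

#' Share of inverted chimeras among single-end chimeras
#'
#' @param direct_count,inverted_count chimera counts.
#' @return percentage `100 * inverted / (direct + inverted)`, or `NA`
#'   when both counts are zero.
#' @export
inverted_share <- function(direct_count, inverted_count) {
  if (direct_count < 0 || inverted_count < 0) stop("counts must be non-negative")
  tot <- direct_count + inverted_count
  if (tot == 0) return(NA_real_)
  100 * inverted_count / tot
}

#' Build a chimera report from per-type counts
#'
#' The report layer behind the summary statistics: per-type counts (in
#' read-pair units), their sum, the pair-level chimeric rate, and the
#' inverted share of single-end chimeras.
#'
#' @param direct,inverted,insertion per-type chimera counts.
#' @param total_pairs total read pairs in the input.
#' @param chimeric_pairs distinct read pairs contributing at least one
#'   chimera (defaults to the sum of the three counts, which is exact
#'   when every pair contributes one call).
#' @param stage_counters optional named list of per-stage counters.
#' @param params optional parameter snapshot.
#' @return a list of class `chimera_report`.
#' @export
chimera_report <- function(direct, inverted, insertion, total_pairs,
                           chimeric_pairs = direct + inverted + insertion,
                           stage_counters = list(), params = NULL) {
  structure(
    list(
      counts = list(direct = direct, inverted = inverted,
                    insertion = insertion),
      total_chimeras = direct + inverted + insertion,
      chimeric_pairs = chimeric_pairs,
      total_pairs = total_pairs,
      chimeric_rate = chimeric_rate(chimeric_pairs, total_pairs),
      inverted_share = inverted_share(direct, inverted),
      stage_counters = stage_counters,
      params = if (is.null(params)) NULL else unclass(params)
    ),
    class = "chimera_report"
  )
}

#' @export
print.chimera_report <- function(x, ...) {
  cat("chimera report\n")
  cat(sprintf("  total pairs:     %d\n", x$total_pairs))
  cat(sprintf("  direct:          %d\n", x$counts$direct))
  cat(sprintf("  inverted:        %d\n", x$counts$inverted))
  cat(sprintf("  insertion:       %d\n", x$counts$insertion))
  cat(sprintf("  chimeric pairs:  %d\n", x$chimeric_pairs))
  cat(sprintf("  chimeric rate:   %.4f\n", x$chimeric_rate))
  if (!is.na(x$inverted_share)) {
    cat(sprintf("  inverted share:  %.2f%%\n", x$inverted_share))
  }
  invisible(x)
}

empty_calls <- function() {
  data.frame(
    read_id = character(), type = character(), chrom = character(),
    former_start = integer(), former_end = integer(),
    former_strand = character(), following_start = integer(),
    following_end = integer(), following_strand = character(),
    distance = integer(), overlap_len = integer(),
    overlap_seq = character(), overlap_side = character(),
    stringsAsFactors = FALSE
  )
}

#' Detect and classify chimeric reads from a SAM file
#'
#' Runs the full three-stage pipeline: pair classification (insertion
#' chimeras from same-strand pairs), soft-clip splitting with the
#' chromosome-length minimum rule, realignment of the reconstructed
#' subsection pairs, and the two-sided junction-overlap search with the
#' validity filters.  The pipeline is fully deterministic: two runs on
#' identical inputs produce byte-identical outputs.
#'
#' @param sam_path SAM (or BAM) file of primary paired-end alignments.
#' @param ref a [reference_genome()], or a FASTA path.
#' @param params a [chimera_params()] list.
#' @param aligner `"naive"` (built-in exact-match realignment, the
#'   default) or `"external"` (subprocess adapter; see
#'   [external_align()]).
#' @param aligner_cmd command template for `aligner = "external"`.
#' @param ref_path reference FASTA path, required only for the external
#'   aligner.
#' @param out_prefix when given, writes `<prefix>.chimeras.tsv`,
#'   `<prefix>.filterlist.txt` and `<prefix>.report.json`.
#' @return a list with `calls` (the chimera table, one row per call,
#'   columns `read_id`, `type`, `chrom`, `former_start`, `former_end`,
#'   `former_strand`, `following_start`, `following_end`,
#'   `following_strand`, `distance`, `overlap_len`, `overlap_seq`,
#'   `overlap_side`; coordinates 0-based half-open), `report` (a
#'   [chimera_report()]), `filter_list` (sorted unique read ids), and
#'   `dispositions` (the per-pair classification table).
#' @export
detect_chimeras <- function(sam_path, ref, params = chimera_params(),
                            aligner = c("naive", "external"),
                            aligner_cmd = NULL, ref_path = NULL,
                            out_prefix = NULL) {
  aligner <- match.arg(aligner)
  if (is.character(ref)) {
    if (is.null(ref_path)) ref_path <- ref
    ref <- read_reference(ref)
  }
  aln <- read_alignments(sam_path)
  counters <- list(records_in = nrow(aln))
  if (nrow(aln) == 0L) {
    warning("empty SAM input: chimeric rate reported as 0")
    disp <- classify_pairs(aln, ref, params)
    report <- chimera_report(0L, 0L, 0L, 0L, 0L,
                             stage_counters = counters, params = params)
    res <- list(calls = empty_calls(), report = report,
                filter_list = character(), dispositions = disp)
    if (!is.null(out_prefix)) write_outputs(res, out_prefix)
    return(res)
  }

  disp <- classify_pairs(aln, ref, params)
  counters$pairs_in <- nrow(disp)
  counters$proper_removed <- sum(disp$category == "PROPER_PAIR_REMOVED")
  counters$unmapped_removed <- sum(disp$category == "UNMAPPED_REMOVED")
  counters$insertion_pairs <- sum(disp$category == "INSERTION_CHIMERA")
  counters$softclip_candidates <- sum(disp$category == "SOFTCLIP_CANDIDATE")
  counters$other_discordant <- sum(disp$category == "OTHER_DISCORDANT")

  # stage B: split every qualifying mate of the soft-clip candidate pairs
  cand_ids <- disp$read_id[disp$category == "SOFTCLIP_CANDIDATE"]
  sub <- aln[aln$read_id %in% cand_ids & aln$mapped, , drop = FALSE]
  sub <- sub[order(sub$read_id, sub$mate), , drop = FALSE]
  splits <- list()
  for (i in seq_len(nrow(sub))) {
    sp <- split_read(as.list(sub[i, ]), ref, params)
    if (!is.null(sp)) splits[[length(splits) + 1L]] <- sp
  }
  counters$splits <- length(splits)

  # realignment
  triples <- if (aligner == "naive") {
    align_subsections(splits, ref)
  } else {
    if (is.null(aligner_cmd) || is.null(ref_path)) {
      stop("external aligner requires aligner_cmd and ref_path")
    }
    pairs <- reconstruct_pairs(splits)
    fq1 <- tempfile(fileext = "_1.fq"); fq2 <- tempfile(fileext = "_2.fq")
    write_pseudo_fastq(pairs, fq1, fq2)
    collate_hits(external_align(fq1, fq2, ref_path, aligner_cmd), splits)
  }
  counters$realigned <- length(triples)
  counters$realign_dropped <- attr(triples, "dropped")

  # stage C: overlap search + validity filters
  se_rows <- list()
  for (tr in triples) {
    cand <- build_candidate(tr, ref, params)
    v <- validate_candidate(cand, params)
    if (!isTRUE(v$valid)) next
    fh <- cand$former$hit; lh <- cand$following$hit
    se_rows[[length(se_rows) + 1L]] <- data.frame(
      read_id = cand$read_id, type = v$type, chrom = fh$chrom,
      former_start = fh$ref_start, former_end = fh$ref_end,
      former_strand = fh$strand, following_start = lh$ref_start,
      following_end = lh$ref_end, following_strand = lh$strand,
      distance = cand$genomic_distance,
      overlap_len = cand$overlap$length, overlap_seq = cand$overlap$seq,
      overlap_side = cand$overlap$side, stringsAsFactors = FALSE
    )
  }

  ins <- disp[disp$category == "INSERTION_CHIMERA", , drop = FALSE]
  ins_rows <- if (nrow(ins)) data.frame(
    read_id = ins$read_id, type = "INSERTION", chrom = ins$chrom1,
    former_start = ins$pos1, former_end = NA_integer_,
    former_strand = ins$strand1, following_start = ins$pos2,
    following_end = NA_integer_, following_strand = ins$strand2,
    distance = abs(ins$pos1 - ins$pos2), overlap_len = NA_integer_,
    overlap_seq = "", overlap_side = "", stringsAsFactors = FALSE
  ) else NULL

  calls <- do.call(rbind, c(se_rows, list(ins_rows)))
  if (is.null(calls)) calls <- empty_calls()
  calls <- calls[order(calls$read_id, calls$type, calls$former_start,
                       method = "radix"), , drop = FALSE]
  rownames(calls) <- NULL

  single_ids <- unique(calls$read_id[calls$type %in% c("DIRECT", "INVERTED")])
  chimeric_pairs <- length(unique(c(single_ids, ins$read_id)))
  report <- chimera_report(
    direct = sum(calls$type == "DIRECT"),
    inverted = sum(calls$type == "INVERTED"),
    insertion = sum(calls$type == "INSERTION"),
    total_pairs = nrow(disp), chimeric_pairs = chimeric_pairs,
    stage_counters = counters, params = params
  )
  res <- list(calls = calls, report = report,
              filter_list = emit_filter_list(calls),
              dispositions = disp)
  if (!is.null(out_prefix)) write_outputs(res, out_prefix)
  res
}

#' Read-id filter list from a chimera table
#'
#' Unique origin read ids of all valid chimeras (pair-level ids, so an
#' insertion chimera's two mates contribute one line), sorted.  Suitable
#' as input to read-filtering tools that remove both mates of a listed
#' pair before SV calling.
#'
#' @param calls chimera table (data.frame with `read_id` column) or a
#'   TSV path written by [write_chimera_tsv()].
#' @return sorted character vector of read ids.
#' @export
emit_filter_list <- function(calls) {
  if (is.character(calls)) calls <- read_chimera_tsv(calls)
  sort(unique(as.character(calls$read_id)), method = "radix")
}

#' Write / read the chimera call table
#'
#' Fixed column order, tab-separated, with a header line.
#'
#' @param calls chimera table from [detect_chimeras()].
#' @param path TSV file path.
#' @return `path` (write) or the table (read).
#' @export
write_chimera_tsv <- function(calls, path) {
  stopifnot(identical(names(calls), TSV_COLUMNS))
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_chimera_tsv
#' @export
read_chimera_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                           colClasses = c(read_id = "character",
                                          overlap_seq = "character"),
                           stringsAsFactors = FALSE)
  bad <- setdiff(TSV_COLUMNS, names(out))
  if (length(bad)) stop("malformed chimera TSV: missing column(s) ",
                        paste(bad, collapse = ", "))
  out$overlap_seq[is.na(out$overlap_seq)] <- ""
  out$overlap_side[is.na(out$overlap_side)] <- ""
  out
}

write_outputs <- function(res, prefix) {
  write_chimera_tsv(res$calls, paste0(prefix, ".chimeras.tsv"))
  writeLines(res$filter_list, paste0(prefix, ".filterlist.txt"))
  rep <- res$report
  if (!is.null(rep$params) &&
      !is.finite(rep$params$max_insertion_distance)) {
    rep$params$max_insertion_distance <- "unlimited"
  }
  jsonlite::write_json(unclass(rep), paste0(prefix, ".report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' Summarise an existing chimera table
#'
#' Recomputes the per-type counts and single-end inverted share from a
#' chimera TSV, independent of the run that produced it.
#'
#' @param path chimera TSV path.
#' @param total_pairs optional denominator for the chimeric rate; when
#'   absent the rate is reported over the distinct chimeric pairs only.
#' @return a [chimera_report()].
#' @export
summarize_chimeras <- function(path, total_pairs = NULL) {
  calls <- read_chimera_tsv(path)
  pairs <- length(unique(calls$read_id))
  chimera_report(
    direct = sum(calls$type == "DIRECT"),
    inverted = sum(calls$type == "INVERTED"),
    insertion = sum(calls$type == "INSERTION"),
    total_pairs = if (is.null(total_pairs)) pairs else total_pairs,
    chimeric_pairs = pairs
  )
}
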