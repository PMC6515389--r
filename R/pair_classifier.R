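# Stage A: pre-filter raw reads, partition aligned pairs, and call
# insertion chimeras from same-strand pairs.

PAIR_CATEGORIES <- c("PROPER_PAIR_REMOVED", "UNMAPPED_REMOVED",
                     "INSERTION_CHIMERA", "SOFTCLIP_CANDIDATE",
                     "OTHER_DISCORDANT")

#' Drop raw read pairs containing N bases
#'
#' A pair is removed when either mate's sequence contains at least one
#' `N`; surviving pairs are unchanged.  This is the cleaning step applied
#' before alignment.
#'
#' @param seq1,seq2 character vectors of mate-1 and mate-2 sequences, in
#'   pair order.
#' @return a list with `keep` (logical vector over pairs) and `dropped`
#'   (count of removed pairs).
#' @examples
#' prefilter_pairs(c("ACGT", "ACNT"), c("TTTT", "TTTT"))
#' @export
prefilter_pairs <- function(seq1, seq2) {
  if (length(seq1) != length(seq2)) {
    stop("mate streams have different lengths (", length(seq1), " vs ",
         length(seq2), ")")
  }
  keep <- !grepl("N", seq1, fixed = TRUE) & !grepl("N", seq2, fixed = TRUE)
  list(keep = keep, dropped = sum(!keep))
}

#' Pre-filter paired FASTQ files, removing pairs with N bases
#'
#' File-level wrapper around [prefilter_pairs()].
#'
#' @param fq1,fq2 input FASTQ paths (mate 1, mate 2).
#' @param out1,out2 output FASTQ paths for the surviving pairs.
#' @return the dropped-pair count, invisibly.
#' @export
prefilter_fastq <- function(fq1, fq2, out1, out2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  res <- prefilter_pairs(as.character(r1), as.character(r2))
  k <- res$keep
  Biostrings::writeXStringSet(r1[k], out1, format = "fastq",
                              qualities = S4Vectors::mcols(r1)$qualities[k])
  Biostrings::writeXStringSet(r2[k], out2, format = "fastq",
                              qualities = S4Vectors::mcols(r2)$qualities[k])
  invisible(res$dropped)
}

# does this record carry a terminal soft clip that survives the
# length gates (hard floor and the chromosome-length minimum)?
has_qualifying_clip <- function(record, ref, params) {
  if (!isTRUE(record$mapped)) return(FALSE)
  !is.null(split_read(record, ref, params))
}

#' Classify an aligned read pair
#'
#' Partition rule, applied in order: either mate unmapped ->
#' `UNMAPPED_REMOVED`; both mates mapped to the same chromosome and the
#' same strand -> `INSERTION_CHIMERA` (the paired-end chimera signature);
#' either mate carries a terminal soft clip passing the length gates of
#' [split_read()] -> `SOFTCLIP_CANDIDATE` (this includes proper pairs
#' with such a clip); proper pair -> `PROPER_PAIR_REMOVED`; anything
#' else -> `OTHER_DISCORDANT`.  Insertion classification wins over soft
#' clips so each pair lands in exactly one category.
#'
#' Inter-chromosomal same-strand pairs are not called insertion chimeras
#' (chimera parts lie close on one chromosome); they fall through to the
#' soft-clip / discordant branches.
#'
#' @param r1,r2 single alignment records (one-row data.frames or lists
#'   with the columns of [read_alignments()]), both primary, same
#'   `read_id`.
#' @param ref a [reference_genome()] (used for the soft-clip length
#'   gates).
#' @param params a [chimera_params()] list.
#' @return category string, one of
#'   `r paste(PAIR_CATEGORIES, collapse = ", ")`.
#' @export
classify_pair <- function(r1, r2, ref, params = chimera_params()) {
  if (!identical(as.character(r1$read_id), as.character(r2$read_id))) {
    stop("pairing error: read ids differ (", r1$read_id, " vs ",
         r2$read_id, ")")
  }
  if (!isTRUE(r1$mapped) || !isTRUE(r2$mapped)) {
    return("UNMAPPED_REMOVED")
  }
  if (identical(r1$chrom, r2$chrom) && identical(r1$strand, r2$strand)) {
    d <- abs(r1$ref_start - r2$ref_start)
    if (d <= params$max_insertion_distance) {
      return("INSERTION_CHIMERA")
    }
  }
  if (has_qualifying_clip(r1, ref, params) ||
      has_qualifying_clip(r2, ref, params)) {
    return("SOFTCLIP_CANDIDATE")
  }
  if (isTRUE(r1$proper) && isTRUE(r2$proper)) {
    return("PROPER_PAIR_REMOVED")
  }
  "OTHER_DISCORDANT"
}

#' Classify every pair in an alignment table
#'
#' Groups primary records by read id (expecting one record per mate) and
#' applies [classify_pair()].  Read ids with anything other than exactly
#' one mate-1 and one mate-2 primary record are dropped with a warning.
#'
#' @param aln alignment data.frame from [read_alignments()].
#' @inheritParams classify_pair
#' @return a data.frame with one row per pair: `read_id`, `category`,
#'   and per-mate `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2` (positions 0-based, NA when unmapped).
#' @export
classify_pairs <- function(aln, ref, params = chimera_params()) {
  empty <- data.frame(
    read_id = character(), category = character(),
    chrom1 = character(), pos1 = integer(), strand1 = character(),
    chrom2 = character(), pos2 = integer(), strand2 = character(),
    stringsAsFactors = FALSE
  )
  if (nrow(aln) == 0L) return(empty)
  groups <- split(seq_len(nrow(aln)), aln$read_id)
  ok <- vapply(groups, function(ix) {
    length(ix) == 2L && setequal(aln$mate[ix], c(1L, 2L))
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " read id(s) without exactly one primary record",
            " per mate were dropped")
    groups <- groups[ok]
  }
  if (length(groups) == 0L) return(empty)
  rows <- lapply(names(groups), function(id) {
    ix <- groups[[id]]
    ix <- ix[order(aln$mate[ix])]
    r1 <- as.list(aln[ix[1], ])
    r2 <- as.list(aln[ix[2], ])
    data.frame(
      read_id = id,
      category = classify_pair(r1, r2, ref, params),
      chrom1 = r1$chrom, pos1 = r1$ref_start, strand1 = r1$strand,
      chrom2 = r2$chrom, pos2 = r2$ref_start, strand2 = r2$strand,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$read_id, method = "radix"), , drop = FALSE]
}
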