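# Independent oracles and fixture builders.  The oracles are written as
# literal character-by-character procedures, deliberately sharing no
# code with the package implementation they check.

oracle_rc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) return("")
  paste(rev(unname(comp[chars])), collapse = "")
}

# 0-based half-open slice of a plain string, N outside [0, nchar)
oracle_slice <- function(seqstr, start, end) {
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  out <- character(max(0, end - start))
  for (i in seq_along(out)) {
    p <- start + i  # 1-based
    out[i] <- if (p >= 1 && p <= length(chars)) chars[p] else "N"
  }
  paste(out, collapse = "")
}

# enumerate every k in [min_overlap, max_overlap] and apply the
# mismatch rules literally; return the longest passing k (0 = none)
oracle_enumerate <- function(a31, b31, p, anchor = c("suffix", "prefix")) {
  anchor <- match.arg(anchor)
  av <- strsplit(a31, "", fixed = TRUE)[[1]]
  bv <- strsplit(b31, "", fixed = TRUE)[[1]]
  w <- length(av)
  best <- 0L
  for (k in p$min_overlap:p$max_overlap) {
    idx <- if (anchor == "suffix") (w - k + 1):w else 1:k
    bad <- 0L
    first_bad <- FALSE
    for (j in seq_along(idx)) {
      x <- av[idx[j]]; y <- bv[idx[j]]
      is_bad <- x != y || x == "N" || y == "N"
      if (j == 1 && is_bad) first_bad <- TRUE
      if (is_bad) bad <- bad + 1L
    }
    if (!first_bad && bad <= p$max_mismatches) best <- max(best, k)
  }
  best
}

oracle_overlap_tail <- function(former_seq, following_hit, refstr, p) {
  w <- p$window
  n <- nchar(former_seq)
  t31 <- if (n >= w) substr(former_seq, n - w + 1, n) else
    paste0(strrep("N", w - n), former_seq)
  e31 <- if (following_hit$strand == "+") {
    oracle_slice(refstr, following_hit$ref_start - w, following_hit$ref_start)
  } else {
    oracle_rc(oracle_slice(refstr, following_hit$ref_end,
                           following_hit$ref_end + w))
  }
  oracle_enumerate(t31, e31, p, "suffix")
}

oracle_overlap_head <- function(following_seq, former_hit, refstr, p) {
  w <- p$window
  n <- nchar(following_seq)
  h31 <- if (n >= w) substr(following_seq, 1, w) else
    paste0(following_seq, strrep("N", w - n))
  e31 <- if (former_hit$strand == "+") {
    oracle_slice(refstr, former_hit$ref_end, former_hit$ref_end + w)
  } else {
    oracle_rc(oracle_slice(refstr, former_hit$ref_start - w,
                           former_hit$ref_start))
  }
  oracle_enumerate(h31, e31, p, "prefix")
}

# literal exact-occurrence scan of every position on both strands
oracle_align <- function(query, refs) {
  n <- nchar(query)
  qrc <- oracle_rc(query)
  found <- list()
  for (chrom in names(refs)) {
    s <- refs[[chrom]]
    for (pos in seq_len(max(0, nchar(s) - n + 1))) {
      win <- substr(s, pos, pos + n - 1)
      if (win == query && !grepl("N", win)) {
        found[[length(found) + 1]] <- list(chrom = chrom, start = pos - 1,
                                           strand = "+")
      }
      if (win == qrc && !grepl("N", win) && !grepl("N", qrc)) {
        found[[length(found) + 1]] <- list(chrom = chrom, start = pos - 1,
                                           strand = "-")
      }
    }
  }
  if (length(found) == 0) return(list(status = "unmapped"))
  if (length(found) > 1) return(list(status = "multi"))
  c(list(status = "unique"), found[[1]])
}

# ---- fixture builders ------------------------------------------------------

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# a single primary alignment record as the pipeline sees it
make_record <- function(read_id = "r1", mate = 1L, seq = strrep("A", 101),
                        cigar = "101M", chrom = "c1", ref_start = 0L,
                        strand = "+", mapped = TRUE, proper = FALSE,
                        mate_strand = "-", flag = 0L) {
  list(read_id = read_id, mate = mate, flag = flag, mapped = mapped,
       proper = proper, strand = strand, mate_strand = mate_strand,
       chrom = if (mapped) chrom else NA_character_,
       ref_start = if (mapped) as.integer(ref_start) else NA_integer_,
       ref_end = if (mapped) {
         as.integer(ref_start) + cigar_ref_span(parse_cigar(cigar))
       } else NA_integer_,
       seq = seq, qual = strrep("I", nchar(seq)), cigar = cigar)
}

# minimal candidate_chimera for gate tests
make_candidate <- function(len_former = 50, len_following = 50,
                           distance = 300, overlap_len = 7,
                           orientation = "DIRECT") {
  structure(
    list(read_id = "c", mate = 1L,
         former = list(seq = strrep("A", len_former), hit = NULL),
         following = list(seq = strrep("A", len_following), hit = NULL),
         orientation = orientation,
         genomic_distance = distance,
         overlap = if (is.null(overlap_len)) NULL else
           list(seq = strrep("A", overlap_len), length = overlap_len,
                side = "tail")),
    class = "candidate_chimera"
  )
}
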