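test_that("minimum subsection length follows the log4 chromosome rule", {
  expect_equal(min_softclip_length(249250621), 14L)  # human chr1
  expect_equal(min_softclip_length(4), 2L)
  expect_equal(min_softclip_length(16777216), 13L)   # 4^12 exactly
  expect_equal(min_softclip_length(59373566), 13L)
  expect_equal(min_softclip_length(1), 1L)
  expect_error(min_softclip_length(0), "positive")
  expect_error(min_softclip_length(c(10, -1)), "positive")
})

test_that("minimum length is non-decreasing and steps at powers of 4", {
  for (k in 2:15) {
    expect_equal(min_softclip_length(4^k - 1), k)
    expect_equal(min_softclip_length(4^k), k + 1L)
  }
  set.seed(4)
  L <- sort(sample.int(3e9, 200))
  v <- min_softclip_length(L)
  expect_true(all(diff(v) >= 0))
})

# 70,000 bp chromosome: Eq-style minimum is 9 (> the 8 bp hard floor),
# so the chromosome-length rule, not the floor, is the active gate
ref70k <- reference_genome(c(cL = {set.seed(8); rand_dna(70000)}))

test_that("reads split exactly at the clip boundary with the anchor on the aligned part", {
  rec <- make_record(seq = rand_dna(101), cigar = "64M37S", chrom = "cL",
                     ref_start = 500)
  sp <- split_read(rec, ref70k)
  expect_s3_class(sp, "subsection_pair")
  expect_equal(nchar(sp$former$seq), 64L)
  expect_equal(nchar(sp$following$seq), 37L)
  expect_equal(sp$split_pos, 64L)
  expect_equal(sp$anchor$role, "former")
  expect_equal(sp$anchor$start, 500L)
  expect_equal(c(sp$former$read_start, sp$former$read_end), c(0L, 64L))
  expect_equal(c(sp$following$read_start, sp$following$read_end), c(64L, 101L))

  lead <- make_record(seq = rand_dna(101), cigar = "14S87M", chrom = "cL")
  spl <- split_read(lead, ref70k)
  expect_equal(nchar(spl$former$seq), 14L)
  expect_equal(spl$anchor$role, "following")
})

test_that("length gates remove unusable clips", {
  # below the 8 bp hard floor
  expect_null(split_read(make_record(seq = rand_dna(101), cigar = "95M6S",
                                     chrom = "cL"), ref70k))
  # 8 bp clip passes the floor but not the 9 bp chromosome minimum
  expect_null(split_read(make_record(seq = rand_dna(101), cigar = "93M8S",
                                     chrom = "cL"), ref70k))
  expect_false(is.null(split_read(make_record(seq = rand_dna(101),
                                              cigar = "92M9S",
                                              chrom = "cL"), ref70k)))
  # the aligned remainder faces the same gate
  expect_null(split_read(make_record(seq = rand_dna(101), cigar = "8M93S",
                                     chrom = "cL"), ref70k))
  # no terminal soft clip at all
  expect_null(split_read(make_record(seq = rand_dna(101), cigar = "101M",
                                     chrom = "cL"), ref70k))
})

test_that("reads clipped at both ends follow the configured policy", {
  rec <- make_record(seq = rand_dna(101), cigar = "20S60M21S", chrom = "cL")
  sp <- split_read(rec, ref70k)  # default: split at the longer clip
  expect_equal(nchar(sp$former$seq), 80L)
  expect_equal(nchar(sp$following$seq), 21L)
  expect_null(split_read(rec, ref70k,
                         split_params(both_ends_policy = "skip")))
})

test_that("subsections always reconstruct the original read byte-for-byte", {
  set.seed(31)
  for (i in 1:30) {
    rl <- sample(60:150, 1)
    clip <- sample(9:(rl - 9), 1)
    lead <- runif(1) > 0.5
    cigar <- if (lead) paste0(clip, "S", rl - clip, "M") else
      paste0(rl - clip, "M", clip, "S")
    rec <- make_record(seq = rand_dna(rl), cigar = cigar, chrom = "cL",
                       ref_start = sample(0:60000, 1))
    sp <- split_read(rec, ref70k)
    if (is.null(sp)) next
    expect_identical(paste0(sp$former$seq, sp$following$seq),
                     rec$seq)
    expect_identical(paste0(sp$former$qual, sp$following$qual), rec$qual)
    expect_gte(min(nchar(sp$former$seq), nchar(sp$following$seq)), 9L)
  }
})

test_that("pseudo pair names encode and decode losslessly", {
  recs <- list(
    make_record(read_id = "r7", seq = rand_dna(101), cigar = "64M37S",
                chrom = "cL"),
    make_record(read_id = "weird|id%1", seq = rand_dna(101),
                cigar = "40S61M", chrom = "cL")
  )
  splits <- lapply(recs, split_read, ref = ref70k)
  pairs <- reconstruct_pairs(splits)
  expect_equal(nrow(pairs), 2L)
  expect_identical(paste0(pairs$seq1, pairs$seq2),
                   vapply(splits, function(s) s$origin_sequence, ""))
  dec <- mdachimera:::decode_pseudo_name(pairs$name[2])
  expect_equal(dec$read_id, "weird|id%1")
  expect_equal(dec$split_pos, 40L)
  expect_equal(c(dec$len_former, dec$len_following), c(40L, 61L))
})

test_that("pseudo pair reconstruction preserves order and handles empty input", {
  expect_equal(nrow(reconstruct_pairs(list())), 0L)
  set.seed(12)
  recs <- lapply(1:10, function(i) {
    make_record(read_id = sprintf("r%02d", i), seq = rand_dna(101),
                cigar = "50M51S", chrom = "cL")
  })
  splits <- lapply(recs, split_read, ref = ref70k)
  pairs <- reconstruct_pairs(splits)
  expect_equal(nrow(pairs), 10L)
  ids <- vapply(pairs$name,
                function(n) mdachimera:::decode_pseudo_name(n)$read_id, "")
  expect_equal(unname(ids), sprintf("r%02d", 1:10))
  fq1 <- tempfile(fileext = ".fq"); fq2 <- tempfile(fileext = ".fq")
  write_pseudo_fastq(pairs, fq1, fq2)
  expect_equal(length(Biostrings::readDNAStringSet(fq1, format = "fastq")),
               10L)
})
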