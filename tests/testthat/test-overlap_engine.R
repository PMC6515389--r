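p_def <- overlap_params()

# build a (former, following, reference) triple with an agreement of
# exactly `agree` bases planted at the junction, tail side, both loci
# on the plus strand
plant_tail_triple <- function(agree, ref_len = 600, l1 = 50, l2 = 51,
                              s1 = 60, s2 = 320) {
  refstr <- rand_dna(ref_len)
  former_seq <- substr(refstr, s1 + 1, s1 + l1)
  omer <- substr(former_seq, l1 - agree + 1, l1)
  substr(refstr, s2 - agree + 1, s2) <- omer
  # force a mismatch immediately before the agreement so it cannot extend
  pre_t <- substr(former_seq, l1 - agree, l1 - agree)
  bases <- setdiff(c("A", "C", "G", "T"), pre_t)
  substr(refstr, s2 - agree, s2 - agree) <- sample(bases, 1)
  # and a second mismatch one base further out, so the 1-mismatch
  # tolerance cannot bridge the break either
  pre2 <- substr(former_seq, l1 - agree - 1, l1 - agree - 1)
  substr(refstr, s2 - agree - 1, s2 - agree - 1) <-
    sample(setdiff(c("A", "C", "G", "T"), pre2), 1)
  following_seq <- substr(refstr, s2 + 1, s2 + l2)
  ref <- reference_genome(c(cT = refstr))
  list(ref = ref, refstr = refstr,
       former = list(seq = former_seq,
                     hit = list(chrom = "cT", ref_start = s1,
                                ref_end = s1 + l1, strand = "+")),
       following = list(seq = following_seq,
                        hit = list(chrom = "cT", ref_start = s2,
                                   ref_end = s2 + l2, strand = "+")))
}

test_that("genomic distance is start-to-start and undefined across chromosomes", {
  h <- function(chrom, s) list(chrom = chrom, ref_start = s, ref_end = s + 50,
                               strand = "+")
  expect_equal(genomic_distance(h("c1", 1000), h("c1", 1025)), 25)
  expect_equal(genomic_distance(h("c1", 1000), h("c1", 1000)), 0)
  expect_true(is.na(genomic_distance(h("c1", 1000), h("c2", 1000))))
})

test_that("tail search finds a planted junction overlap of known length", {
  set.seed(41)
  tr <- plant_tail_triple(agree = 7)
  want <- oracle_overlap_tail(tr$former$seq, tr$following$hit, tr$refstr,
                              p_def)
  expect_equal(want, 7L)  # the oracle confirms the construction
  got <- search_overlap_tail(tr$former, tr$following, tr$ref, p_def)
  expect_equal(got$length, 7L)
  expect_equal(got$side, "tail")
  expect_equal(got$seq, substr(tr$former$seq, 44, 50))
})

test_that("agreements of two or fewer bases are not overlaps", {
  set.seed(43)
  for (i in 1:5) {
    tr <- plant_tail_triple(agree = 2)
    if (oracle_overlap_tail(tr$former$seq, tr$following$hit, tr$refstr,
                            p_def) != 0) next  # accidental longer agreement
    expect_null(search_overlap_tail(tr$former, tr$following, tr$ref, p_def))
  }
  tr3 <- plant_tail_triple(agree = 3)
  got <- search_overlap_tail(tr3$former, tr3$following, tr3$ref, p_def)
  expect_equal(got$length,
               oracle_overlap_tail(tr3$former$seq, tr3$following$hit,
                                   tr3$refstr, p_def))
})

test_that("a mismatch at the first overlap base rejects that length only", {
  set.seed(47)
  # agreement of 10 whose first base is then corrupted in the reference:
  # k = 10 violates the first-base rule, k = 9 has no mismatch at all
  repeat {
    tr <- plant_tail_triple(agree = 10)
    base10 <- oracle_overlap_tail(tr$former$seq, tr$following$hit,
                                  tr$refstr, p_def)
    if (base10 == 10) break
  }
  refstr <- tr$refstr
  s2 <- tr$following$hit$ref_start
  first_pos <- s2 - 10 + 1  # 1-based reference position of the k=10 first base
  old <- substr(refstr, first_pos, first_pos)
  substr(refstr, first_pos, first_pos) <-
    sample(setdiff(c("A", "C", "G", "T"), old), 1)
  tr$refstr <- refstr
  tr$ref <- reference_genome(c(cT = refstr))
  want <- oracle_overlap_tail(tr$former$seq, tr$following$hit, refstr, p_def)
  expect_equal(want, 9L)
  got <- search_overlap_tail(tr$former, tr$following, tr$ref, p_def)
  expect_equal(got$length, 9L)
})

test_that("head search mirrors tail search on planted prefix agreements", {
  set.seed(53)
  refstr <- rand_dna(600)
  s1 <- 100; l1 <- 50; s2 <- 350; l2 <- 51
  following_seq <- substr(refstr, s2 + 1, s2 + l2)
  # plant the first 5 bases of the following subsection right after the
  # former subsection's aligned end
  substr(refstr, s1 + l1 + 1, s1 + l1 + 5) <- substr(following_seq, 1, 5)
  # break any accidental extension
  b6 <- substr(following_seq, 6, 6)
  substr(refstr, s1 + l1 + 6, s1 + l1 + 6) <-
    sample(setdiff(c("A", "C", "G", "T"), b6), 1)
  b7 <- substr(following_seq, 7, 7)
  substr(refstr, s1 + l1 + 7, s1 + l1 + 7) <-
    sample(setdiff(c("A", "C", "G", "T"), b7), 1)
  former <- list(seq = substr(refstr, s1 + 1, s1 + l1),
                 hit = list(chrom = "cH", ref_start = s1, ref_end = s1 + l1,
                            strand = "+"))
  following <- list(seq = substr(refstr, s2 + 1, s2 + l2),
                    hit = list(chrom = "cH", ref_start = s2,
                               ref_end = s2 + l2, strand = "+"))
  ref <- reference_genome(c(cH = refstr))
  # a trailing mismatch is tolerated, so the exact 5-base agreement is
  # reported as a 6-base overlap (one mismatch, not at the first base)
  want <- oracle_overlap_head(following$seq, former$hit, refstr, p_def)
  expect_equal(want, 6L)
  got <- search_overlap_head(former, following, ref, p_def)
  expect_equal(got$length, 6L)
  expect_equal(got$side, "head")
  expect_equal(got$seq, substr(following$seq, 1, 6))
})

test_that("minus-strand extensions are read in the subsection's orientation", {
  set.seed(59)
  # former on the minus strand: the head-side extension comes from
  # [start - w, start) reverse-complemented
  refstr <- rand_dna(600)
  s1 <- 300; l1 <- 50; s2 <- 100; l2 <- 51
  former_seq <- oracle_rc(substr(refstr, s1 + 1, s1 + l1))
  following_seq <- substr(refstr, s2 + 1, s2 + l2)
  # in former's reading orientation, the bases after its last aligned
  # base are rc(ref[s1-31, s1)); plant the following head there
  planted <- substr(following_seq, 1, 6)
  substr(refstr, s1 - 6 + 1, s1) <- oracle_rc(planted)
  b7 <- substr(following_seq, 7, 7)
  substr(refstr, s1 - 7 + 1, s1 - 7 + 1) <-
    sample(setdiff(c("A", "C", "G", "T"), oracle_rc(b7)), 1)
  b8 <- substr(following_seq, 8, 8)
  substr(refstr, s1 - 8 + 1, s1 - 8 + 1) <-
    sample(setdiff(c("A", "C", "G", "T"), oracle_rc(b8)), 1)
  former <- list(seq = former_seq,
                 hit = list(chrom = "cM", ref_start = s1, ref_end = s1 + l1,
                            strand = "-"))
  following <- list(seq = substr(refstr, s2 + 1, s2 + l2),
                    hit = list(chrom = "cM", ref_start = s2,
                               ref_end = s2 + l2, strand = "+"))
  ref <- reference_genome(c(cM = refstr))
  # planted 6 exact + one tolerated trailing mismatch = 7
  want <- oracle_overlap_head(following$seq, former$hit, refstr, p_def)
  expect_equal(want, 7L)
  got <- search_overlap_head(former, following, ref, p_def)
  expect_equal(got$length, 7L)
})

test_that("tail and head searches agree with the enumeration oracle on random triples", {
  set.seed(61)
  for (i in 1:300) {
    refstr <- rand_dna(sample(200:1500, 1))
    L <- nchar(refstr)
    lf <- sample(c(5:40, 50), 1)
    ll <- sample(c(5:40, 50), 1)
    former_seq <- rand_dna(lf)
    fs <- sample(0:(L - lf), 1)
    ss <- sample(0:(L - ll), 1)
    former <- list(seq = former_seq,
                   hit = list(chrom = "cR", ref_start = fs,
                              ref_end = fs + lf,
                              strand = sample(c("+", "-"), 1)))
    following <- list(seq = rand_dna(ll),
                      hit = list(chrom = "cR", ref_start = ss,
                                 ref_end = ss + ll,
                                 strand = sample(c("+", "-"), 1)))
    # half the time, plant a junction agreement to cover positives
    if (i %% 2 == 0) {
      o <- sample(3:20, 1)
      if (following$hit$strand == "+" && ss - o >= 0 && o <= lf) {
        omer <- substr(former_seq, lf - o + 1, lf)
        substr(refstr, ss - o + 1, ss) <- omer
        following$seq <- substr(refstr, ss + 1, ss + ll)
      }
    }
    ref <- reference_genome(c(cR = refstr))
    t_impl <- search_overlap_tail(former, following, ref, p_def)
    t_want <- oracle_overlap_tail(former$seq, following$hit, refstr, p_def)
    expect_equal(if (is.null(t_impl)) 0L else t_impl$length, t_want)
    h_impl <- search_overlap_head(former, following, ref, p_def)
    h_want <- oracle_overlap_head(following$seq, former$hit, refstr, p_def)
    expect_equal(if (is.null(h_impl)) 0L else h_impl$length, h_want)
  }
})

test_that("the longer of two discovered overlaps wins, tail on ties", {
  tl <- list(seq = "AAAAAAA", length = 7L, side = "tail")
  hd <- list(seq = "CCCCCCCCC", length = 9L, side = "head")
  expect_equal(resolve_overlap(tl, NULL), tl)
  expect_equal(resolve_overlap(NULL, hd), hd)
  expect_equal(resolve_overlap(tl, hd), hd)
  tie <- list(seq = "GGGGGGG", length = 7L, side = "head")
  expect_equal(resolve_overlap(tl, tie)$side, "tail")
  expect_null(resolve_overlap(NULL, NULL))
})

test_that("validity gates apply in subsection, distance, overlap precedence", {
  expect_true(validate_candidate(make_candidate())$valid)
  expect_equal(validate_candidate(make_candidate(len_former = 29,
                                                 distance = 10))$reason,
               "subsection")
  expect_equal(validate_candidate(make_candidate(distance = 24,
                                                 overlap_len = NULL))$reason,
               "distance")
  expect_equal(validate_candidate(make_candidate(distance = NA))$reason,
               "distance")
  expect_equal(validate_candidate(make_candidate(overlap_len = NULL))$reason,
               "overlap")
  v <- validate_candidate(make_candidate(orientation = "INVERTED"))
  expect_equal(v$type, "INVERTED")
})

test_that("relaxing the gates never decreases the number of valid calls", {
  set.seed(67)
  cands <- lapply(1:200, function(i) {
    make_candidate(len_former = sample(20:70, 1),
                   len_following = sample(20:70, 1),
                   distance = sample(0:6000, 1),
                   overlap_len = if (runif(1) < 0.2) NULL else sample(3:30, 1))
  })
  n_valid <- function(p) sum(vapply(cands, function(cc)
    isTRUE(validate_candidate(cc, p)$valid), logical(1)))
  base <- n_valid(overlap_params())
  expect_gte(n_valid(overlap_params(min_overlap = 3, distance_min = 10,
                                    distance_max = 6000)), base)
  expect_gte(n_valid(overlap_params(min_subsection = 20)), base)
  expect_lte(n_valid(overlap_params(distance_min = 100,
                                    distance_max = 1000)), base)
})

test_that("orientation classes follow the subsection strands", {
  set.seed(71)
  refstr <- rand_dna(500)
  ref <- reference_genome(c(cO = refstr))
  for (st in list(c("+", "+"), c("-", "-"), c("+", "-"), c("-", "+"))) {
    sp <- structure(list(origin_read_id = "x", origin_mate = 1L,
                         former = list(seq = rand_dna(40)),
                         following = list(seq = rand_dna(40))),
                    class = "subsection_pair")
    tr <- list(split = sp,
               former_hit = list(chrom = "cO", ref_start = 50, ref_end = 90,
                                 strand = st[1]),
               following_hit = list(chrom = "cO", ref_start = 300,
                                    ref_end = 340, strand = st[2]))
    cand <- build_candidate(tr, ref)
    expect_equal(cand$orientation,
                 if (st[1] == st[2]) "DIRECT" else "INVERTED")
    expect_equal(cand$genomic_distance, 250)
  }
})
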