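mk_features <- function(contig_len, mds_start, mds_end) {
  n <- length(mds_start)
  gr <- GenomicRanges::GRanges(
    rep("ctg", n),
    IRanges::IRanges(mds_start, mds_end),
    seqlengths = c(ctg = contig_len))
  gr$type <- rep("MDS", n)
  gr$ID <- sprintf("m%d", seq_len(n))
  gr
}

test_that("germline-limited space is the bounded complement of MDS space", {
  f <- mk_features(100L, c(11L, 16L), c(20L, 30L))
  out <- germline_limited_space(f)
  expect_identical(GenomicRanges::start(out), c(1L, 31L))
  expect_identical(GenomicRanges::end(out), c(10L, 100L))

  ## no MDSs: the whole contig
  f0 <- mk_features(100L, integer(0), integer(0))
  whole <- germline_limited_space(f0)
  expect_identical(GenomicRanges::start(whole), 1L)
  expect_identical(GenomicRanges::end(whole), 100L)
})

test_that("the complement matches a per-base mask oracle on random annotations", {
  set.seed(12)
  for (rep_i in 1:25) {
    L <- sample(500:2000, 1)
    n <- sample(1:50, 1)
    s <- sample(L, n, replace = TRUE)
    e <- pmin(s + sample(0:100, n, replace = TRUE), L)
    out <- germline_limited_space(mk_features(L, s, e))
    mask <- rep(TRUE, L)
    for (i in seq_len(n)) mask[s[i]:e[i]] <- FALSE
    got <- logical(L)
    if (length(out)) {
      for (i in seq_along(out)) {
        got[GenomicRanges::start(out)[i]:GenomicRanges::end(out)[i]] <- TRUE
      }
    }
    expect_identical(got, mask)
  }
})

test_that("shuffled placements preserve lengths and stay inside the space", {
  space <- GenomicRanges::GRanges("ctg",
                                  IRanges::IRanges(c(1L, 500L),
                                                   c(200L, 1200L)),
                                  seqlengths = c(ctg = 1500L))
  cand <- GenomicRanges::GRanges("ctg",
                                 IRanges::IRanges(c(1, 10, 30),
                                                  width = c(50, 120, 333)))
  cand$ID <- c("a", "b", "c")
  for (seed in 1:20) {
    pl <- shuffle_loci(cand, space, shuffle_config(n_shuffles = 10,
                                                   seed = seed))
    expect_identical(length(pl), 30L)
    ## multiset of widths preserved per shuffle
    for (sh in 1:10) {
      expect_setequal(GenomicRanges::width(pl[pl$shuffle == sh]),
                      c(50L, 120L, 333L))
    }
    ## entirely within one space interval
    within <- GenomicRanges::countOverlaps(pl, space, type = "within")
    expect_true(all(within == 1L))
  }
})

test_that("a candidate as large as the only interval has a forced placement", {
  space <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1L, 1000L),
                                  seqlengths = c(ctg = 1000L))
  cand <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1L, 1000L))
  cand$ID <- "big"
  pl <- shuffle_loci(cand, space, shuffle_config(n_shuffles = 5, seed = 1))
  expect_true(all(GenomicRanges::start(pl) == 1L))
  expect_true(all(GenomicRanges::width(pl) == 1000L))

  ## too-long candidates error, naming the offender
  cand2 <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1L, 1001L))
  cand2$ID <- "toolong"
  expect_error(shuffle_loci(cand2, space), "toolong")
})

test_that("placement starts are uniform over the legal range", {
  space <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1L, 1000L),
                                  seqlengths = c(ctg = 1000L))
  cand <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1L, 100L))
  cand$ID <- "c"
  pl <- shuffle_loci(cand, space, shuffle_config(n_shuffles = 10000,
                                                 seed = 99))
  starts <- GenomicRanges::start(pl)
  expect_true(all(starts >= 1 & starts <= 901))
  bins <- cut(starts, breaks = seq(0.5, 901.5, length.out = 11))
  p <- suppressWarnings(chisq.test(table(bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("non-overlapping placement mode keeps placements disjoint", {
  space <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1L, 2000L),
                                  seqlengths = c(ctg = 2000L))
  cand <- GenomicRanges::GRanges("ctg",
                                 IRanges::IRanges(rep(1, 5),
                                                  width = rep(150L, 5)))
  cand$ID <- sprintf("c%d", 1:5)
  pl <- shuffle_loci(cand, space,
                     shuffle_config(n_shuffles = 5, seed = 2,
                                    allow_overlap_between_placements = FALSE))
  for (sh in 1:5) {
    p <- pl[pl$shuffle == sh]
    expect_identical(
      length(GenomicRanges::findOverlaps(p, drop.self = TRUE)), 0L)
  }
})

test_that("background distributions count placed loci like real candidates", {
  sl <- c(ctg = 1500L)
  space <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1L, 1500L),
                                  seqlengths = sl)
  cand <- GenomicRanges::GRanges("ctg",
                                 IRanges::IRanges(c(1, 50), width = 100L))
  cand$ID <- c("a", "b")
  pl <- shuffle_loci(cand, space, shuffle_config(n_shuffles = 50, seed = 3))

  ## zero alignments -> all zero
  empty <- GenomicRanges::GRanges(seqlengths = sl)
  empty$read_id <- character(0)
  expect_true(all(background_distribution(pl, empty) == 0L))

  ## random alignments: oracle recount
  set.seed(4)
  rs <- sample(1400, 300, TRUE)
  aln <- GenomicRanges::GRanges("ctg", IRanges::IRanges(rs, width = 80L),
                                read_id = sprintf("r%d", 1:300),
                                seqlengths = sl)
  got <- background_distribution(pl, aln)
  want <- naive_counts(rs, rs + 79L, GenomicRanges::start(pl),
                       GenomicRanges::end(pl))
  expect_identical(got, as.integer(want))

  ## doubling the shuffles doubles the multiset size exactly
  pl2 <- shuffle_loci(cand, space, shuffle_config(n_shuffles = 100,
                                                  seed = 3))
  expect_identical(length(background_distribution(pl2, aln)),
                   2L * length(got))
})

test_that("nearest-rank thresholds are attained integer counts", {
  expect_identical(percentile_threshold(c(rep(0L, 96), 1:4), 0.05), 0L)
  expect_identical(percentile_threshold(0:99, 0.95), 94L)  # value with ECDF >= 0.95
  expect_identical(percentile_threshold(rep(7L, 10), 0.31), 7L)
  expect_error(percentile_threshold(integer(0), 0.5), "empty")
  expect_error(percentile_threshold(1:3, 1), "0, 1")

  ## monotone in q
  set.seed(5)
  x <- rpois(500, 3)
  qs <- seq(0.05, 0.95, by = 0.05)
  th <- vapply(qs, function(q) percentile_threshold(x, q), integer(1))
  expect_true(all(diff(th) >= 0L))
})

test_that("the 0.95 nearest-rank threshold converges to the Poisson quantile", {
  set.seed(6)
  for (lambda in c(0.1, 1.5, 5)) {
    x <- rpois(10000, lambda)
    expect_identical(percentile_threshold(x, 0.95),
                     as.integer(qpois(0.95, lambda)))
  }
})

test_that("calibrate_thresholds assembles per-library DNA and pooled RNA cutoffs", {
  sim <- small_sim(seed = 41)
  space <- germline_limited_space(sim$genome)
  orfs <- find_orfs(sim$genome, min_aa = 45)
  sl <- GenomeInfoDb::seqlengths(sim$genome$features)
  empty <- GenomicRanges::GRanges(seqlengths = sl)
  empty$read_id <- character(0)
  cal <- calibrate_thresholds(orfs, space,
                              dna_alignments = list(a = empty, b = empty),
                              rna_alignments = list(t1 = empty),
                              config = shuffle_config(n_shuffles = 5,
                                                      seed = 8))
  expect_identical(unname(cal$dna_threshold), c(0L, 0L))
  expect_identical(cal$rna_threshold_high, 0L)
  expect_identical(cal$rna_threshold_low, 2L)
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, p)
  j <- jsonlite::read_json(p)
  expect_identical(j$provenance$n_shuffles, 5L)
  expect_named(j$dna_threshold, c("a", "b"))
})
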