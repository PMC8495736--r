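test_that("median-of-ratios size factors have their closed-form values", {
  a <- matrix(c(10L, 20L, 30L, 40L), ncol = 1,
              dimnames = list(sprintf("f%d", 1:4), "A"))
  ## a single library normalizes to 1
  expect_equal(unname(size_factors(a)), 1)

  two <- cbind(A = c(10L, 20L, 30L, 40L), B = c(10L, 20L, 30L, 40L))
  expect_equal(unname(size_factors(two)), c(1, 1))

  doubled <- cbind(A = c(10L, 20L, 30L, 40L), B = c(20L, 40L, 60L, 80L))
  sf <- size_factors(doubled)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  ## scale equivariance of factor ratios (the geometric-mean reference
  ## rescales too, so only ratios between libraries are identified)
  set.seed(71)
  m <- matrix(rpois(60, 40) + 1L, ncol = 3)
  sf1 <- size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 5L
  sf2 <- size_factors(m2)
  expect_equal(unname((sf2[2] / sf2[1]) / (sf1[2] / sf1[1])), 5)

  ## all-zero-feature failure suggests the pseudocount escape hatch
  z <- cbind(A = c(0L, 5L), B = c(3L, 0L))
  expect_error(size_factors(z), "pseudocount")
  expect_length(size_factors(z, pseudocount = 0.5), 2)
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(72)
  ## odd feature count: the median is a single ratio, so the arithmetic
  ## median of ratios and DESeq2's exponentiated median of log ratios
  ## coincide exactly
  m <- matrix(rpois(404, 60) + 1L, ncol = 4,
              dimnames = list(sprintf("g%03d", 1:101), sprintf("s%d", 1:4)))
  ours <- size_factors(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("log2 matrices follow their definition elementwise", {
  m <- matrix(c(0L, 7L, 3L, 1L), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  lm <- log2_matrix(m, factors = c(1, 1), pseudocount = 1)
  expect_equal(lm["a", "x"], 0)
  expect_equal(lm["b", "x"], 3)        # log2(7 + 1)
  f <- c(2, 0.5)
  expect_equal(log2_matrix(m, f, 1), log2(sweep(m, 2, f, "/") + 1))
})

test_that("row clustering merges duplicates first and isolates outliers", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(10, 10, 10))
  cl <- cluster_rows(m)
  expect_equal(cl$hclust$height[1], 0)
  ## the outlier joins last: it is at one end of the leaf order
  expect_true(cl$order[1] == "c" || cl$order[3] == "c")

  ## hand-computed three-point example: d(a,b)=1, d(a,c)=10, d(b,c)=9
  m2 <- rbind(a = 0, b = 1, c = 10)
  cl2 <- cluster_rows(m2)
  expect_equal(sort(cl2$hclust$height), c(1, 10))

  ## permuting rows leaves the tree heights invariant
  set.seed(73)
  m3 <- matrix(rnorm(40), 8, 5,
               dimnames = list(letters[1:8], NULL))
  h1 <- sort(cluster_rows(m3)$hclust$height)
  h2 <- sort(cluster_rows(m3[sample(8), ])$hclust$height)
  expect_equal(h1, h2)

  expect_error(cluster_rows(rbind(a = c(1, NA), b = c(0, 1))), "NA")
  expect_error(cluster_rows(matrix(1, 1, 3)), ">= 2 rows")
})

test_that("RPKM matches its closed form and homogeneity", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(20, 1000, 2e6), rpkm(10, 1000, 1e6))
  expect_equal(rpkm(3, 250, 12345), 3 / 0.25 / (12345 / 1e6))
  expect_error(rpkm(1, 0, 1e6), "length")
})

test_that("the KS statistic equals the brute-force ECDF gap", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)

  set.seed(74)
  a <- rnorm(23); b <- rnorm(31, 0.6)
  got <- ks_two_sample(a, b)
  grid <- sort(c(a, b))
  want <- max(abs(vapply(grid, function(x) mean(a <= x), 0) -
                    vapply(grid, function(x) mean(b <= x), 0)))
  expect_equal(got$D, want)

  ## symmetry and invariance under monotone transforms
  expect_equal(got$D, ks_two_sample(b, a)$D)
  expect_equal(ks_two_sample(exp(a), exp(b))$D, got$D)

  ## agreement with the stats::ks.test oracle
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(got$D, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-5)

  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("the exact permutation p-value enumerates all splits", {
  set.seed(1)
  a <- runif(5); b <- runif(5)
  ex <- ks_two_sample(a, b, method = "exact")
  ## independent enumeration over all choose(10, 5) splits
  pool <- c(a, b)
  splits <- combn(10, 5)
  dd <- apply(splits, 2, function(ix) {
    x <- pool[ix]; y <- pool[-ix]
    grid <- sort(pool)
    max(abs(vapply(grid, function(v) mean(x <= v), 0) -
              vapply(grid, function(v) mean(y <= v), 0)))
  })
  expect_equal(ex$p, mean(dd >= ex$D - 1e-12))
  ## asymptotic approximation stays within the documented band here
  asym <- ks_two_sample(a, b)
  expect_lt(abs(asym$p - ex$p), 0.05)
  expect_error(ks_two_sample(1:20, 1:20, method = "exact"), "n <= 10")
})

test_that("feature-class comparison detects planted small-RNA enrichment", {
  sim <- small_sim(seed = 53)
  srna <- simulate_reads(sim$genome,
                         read_sim_config("small_rna", depth = 3, seed = 9))
  aln <- map_reads_exact(srna, sim$genome, require_unique = TRUE)
  f <- sim$genome$features
  mds <- f[f$type == "MDS"]
  tr <- sim$truth$orfs
  tg <- tr[tr$class %in% c("tglo_high", "tglo_low"), ]
  tglo <- GenomicRanges::GRanges(tg$contig,
                                 IRanges::IRanges(tg$start, tg$end),
                                 seqlengths =
                                   GenomeInfoDb::seqlengths(f))
  tglo$ID <- tg$ID
  res <- compare_feature_classes(aln, mds, tglo, name_a = "MDS",
                                 name_b = "TGLO")
  expect_identical(res$higher, "MDS")
  expect_true(all(res$rpkm_b == 0))
  expect_lt(res$p, 0.05)

  ## identical classes: no separation
  res0 <- compare_feature_classes(aln, mds, mds)
  expect_equal(res0$D, 0)
  expect_error(compare_feature_classes(aln, mds[0], mds), "nonempty")
})

test_that("a planted 10x enrichment is detected in at least 95% of replicates", {
  set.seed(75)
  hits <- 0
  for (i in 1:100) {
    lenA <- sample(300:1500, 50, TRUE); lenB <- sample(300:1500, 50, TRUE)
    cA <- rpois(50, lenA * 0.05); cB <- rpois(50, lenB * 0.005)
    p <- ks_two_sample(rpkm(cA, lenA, 1e5), rpkm(cB, lenB, 1e5))$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("strain retention calls mirror the threshold logic", {
  counts <- rbind(g111288_like = c(A = 0L, B = 500L),
                  gl = c(A = 0L, B = 0L),
                  som = c(A = 40L, B = 60L))
  thr <- c(A = 0L, B = 0L)
  out <- classify_strain_retention(counts, thr)
  expect_identical(out$call,
                   c("strain_specific_somatic", "germline_limited",
                     "somatic"))
  expect_identical(out$retained_in[1], "B")
  expect_error(classify_strain_retention(counts, c(A = 0L)), "missing")
  expect_error(classify_strain_retention(counts[, 1, drop = FALSE], thr),
               "2 strains")
})

test_that("count matrices and TSV export are coherent", {
  sl <- c(ctg = 2000L)
  feats <- GenomicRanges::GRanges("ctg",
                                  IRanges::IRanges(c(1, 1001),
                                                   width = c(500, 800)),
                                  seqlengths = sl)
  feats$ID <- c("f1", "f2")
  aln1 <- GenomicRanges::GRanges("ctg", IRanges::IRanges(c(10, 1100),
                                                         width = 50),
                                 read_id = c("a", "b"), seqlengths = sl)
  aln2 <- GenomicRanges::GRanges("ctg", IRanges::IRanges(20, width = 50),
                                 read_id = "c", seqlengths = sl)
  cm <- build_count_matrix(feats, list(l1 = aln1, l2 = aln2))
  expect_identical(cm$counts, matrix(c(1L, 1L, 1L, 0L), 2, 2,
                                     dimnames = list(c("f1", "f2"),
                                                     c("l1", "l2"))))
  expect_identical(unname(cm$feature_len), c(500L, 800L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(log2_matrix(cm$counts, c(1, 1)), p,
                   row_order = c("f2", "f1"))
  tab <- read.table(p, header = TRUE, sep = "\t")
  expect_identical(tab$feature, c("f2", "f1"))
})
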