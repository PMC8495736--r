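paper_cal <- list(dna_threshold = c(wc = 0L), rna_threshold_high = 4L,
                  rna_threshold_low = 2L)

test_that("classification boundaries follow the published rules exactly", {
  sup <- mk_support(rna_reads = c(4, 2, 50, 4, 1, 2),
                    rna_cov = c(0.85, 0.25, 1.0, 0.80, 0.9, 0.20),
                    dna = c(0, 0, 1, 0, 0, 0))
  calls <- classify_candidates(sup, paper_cal)
  cls <- function(id) {
    if (id %in% calls$high$ID) return("high")
    if (id %in% calls$low$ID) return("low")
    calls$rejected$reason[calls$rejected$ID == id]
  }
  expect_identical(cls("cand_001"), "high")        # 4 reads, 85% covered
  expect_identical(cls("cand_002"), "low")         # 2 reads, 25% covered
  expect_identical(cls("cand_003"), "dna_present") # somatic DNA trumps RNA
  expect_identical(cls("cand_004"), "low")         # 80% exactly is NOT > 80%
  expect_identical(cls("cand_005"), "under_transcribed") # 1 read < 2
  expect_identical(cls("cand_006"), "under_transcribed") # 20% is NOT > 20%
})

test_that("high/low/rejected partition the candidates", {
  set.seed(61)
  n <- 200L
  sup <- mk_support(rna_reads = rpois(n, 3), rna_cov = runif(n),
                    dna = rpois(n, 0.5))
  calls <- classify_candidates(sup, paper_cal)
  ids <- c(calls$high$ID, calls$low$ID, calls$rejected$ID)
  expect_identical(sort(ids), sort(sup$orfs$ID))
  expect_identical(length(ids), n)
  expect_length(intersect(calls$high$ID, calls$low$ID), 0)
})

test_that("raising a DNA count never rescues a candidate (monotone rejection)", {
  set.seed(62)
  n <- 500
  reads <- rpois(n, 4); cov <- runif(n); dna <- rpois(n, 1)
  sup <- mk_support(reads, cov, dna)
  base <- classify_candidates(sup, paper_cal)
  kept_base <- c(base$high$ID, base$low$ID)
  bumped <- mk_support(reads, cov, dna + sample(1:5, n, TRUE))
  after <- classify_candidates(bumped, paper_cal)
  kept_after <- c(after$high$ID, after$low$ID)
  expect_true(all(kept_after %in% kept_base))
})

test_that("missing support for a configured DNA library is an error", {
  sup <- mk_support(4, 0.9, 0)
  cal <- list(dna_threshold = c(other_lib = 0L), rna_threshold_high = 4L,
              rna_threshold_low = 2L)
  expect_error(classify_candidates(sup, cal), "other_lib")
})

test_that("sum mode pools read counts across RNA libraries", {
  sup <- mk_support(3, 0.9, 0)
  sup$rna_count <- cbind(sup$rna_count,
                         matrix(2L, 1, 1, dimnames = list(NULL, "rna2")))
  sup$rna_covfrac <- cbind(sup$rna_covfrac,
                           matrix(0.1, 1, 1, dimnames = list(NULL, "rna2")))
  max_mode <- classify_candidates(sup, paper_cal, combine_rna = "max")
  expect_length(max_mode$high, 0)        # no single library reaches 4
  sum_mode <- classify_candidates(sup, paper_cal, combine_rna = "sum")
  expect_length(sum_mode$high, 1)        # 3 + 2 >= 4 and max cov > 0.8
})

test_that("greedy clustering merges identical and family sequences only", {
  ## identical pair -> one representative with a size-2 cluster
  cl <- cluster_redundant(c(a = strrep("ACGTTGCA", 20),
                            b = strrep("ACGTTGCA", 20)))
  expect_identical(cl$representatives, "a")
  expect_setequal(cl$clusters[["a"]], c("a", "b"))

  ## no shared 8-mers -> singletons
  set.seed(63)
  x <- c(s1 = strrep("AC", 60), s2 = strrep("AG", 60))
  cl2 <- cluster_redundant(x)
  expect_identical(sort(cl2$representatives), c("s1", "s2"))

  ## 10 mutated families (5% divergence) recovered at identity 0.9
  set.seed(64)
  fams <- replicate(10, rand_dna(400))
  seqs <- character(0)
  for (fi in 1:10) {
    for (m in 1:5) {
      s <- strsplit(fams[fi], "")[[1]]
      hit <- sample(400, 20)
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(c("A", "C", "G",
                                                            "T"), b), 1),
                       character(1))
      seqs[sprintf("f%02d_m%d", fi, m)] <- paste(s, collapse = "")
    }
  }
  cl3 <- cluster_redundant(seqs, identity = 0.9)
  expect_identical(length(cl3$representatives), 10L)
  ## every cluster is one family, agreeing with the all-pairs oracle
  for (rep_id in cl3$representatives) {
    members <- cl3$clusters[[rep_id]]
    expect_identical(length(unique(substr(members, 1, 3))), 1L)
    for (m in members) {
      expect_gte(naive_identity(seqs[[m]], seqs[[rep_id]]), 0.9)
    }
  }

  ## reverse-complement redundancy is detected
  s <- rand_dna(300)
  cl4 <- cluster_redundant(c(fwd = s, rev = rc1(s)))
  expect_identical(length(cl4$representatives), 1L)
})

test_that("repeat filtering removes tandem arrays but keeps random sequence", {
  x <- c(tandem = strrep("AC", 300))
  rf <- repeat_filter(x, max_masked_fraction = 0.5)
  expect_identical(rf$removed, "tandem")

  set.seed(65)
  fracs <- vapply(1:100, function(i) {
    repeat_filter(c(s = rand_dna(500)))$masked_fraction
  }, numeric(1))
  expect_lt(max(fracs), 0.05)

  ## empty input
  empty <- repeat_filter(character(0))
  expect_length(empty$kept, 0)
  expect_length(empty$removed, 0)
})

test_that("intron fractions count multi-exon models", {
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(1:20 * 100,
                                                     width = 50))
  gr$ID <- sprintf("g%d", 1:20)
  gr$n_exons <- c(rep(2L, 2), rep(1L, 18))
  expect_equal(intron_fraction(gr), 0.10)
  gr$n_exons <- rep(1L, 20)
  expect_equal(intron_fraction(gr), 0)
  set.seed(66)
  gr$n_exons <- sample(1:3, 20, TRUE)
  expect_equal(intron_fraction(gr), mean(gr$n_exons >= 2))
  expect_error(intron_fraction(gr[0]), "empty")
})

test_that("redundancy filters keep one best-supported model per locus", {
  sim <- small_sim(seed = 43)
  mic <- sim$genome
  truth <- sim$truth
  mac <- derive_mac_genome(mic)
  rna <- lapply(c(36, 48), function(tp) {
    map_reads_exact(simulate_reads(mic, read_sim_config(
      "rna_timepoint", read_len = 75, timepoint = tp, seed = 70 + tp),
      truth = truth), mic)
  })
  names(rna) <- c("t36", "t48")
  dna <- list(mac = map_reads_exact(simulate_reads(
    config = read_sim_config("dna_mac", read_len = 100, depth = 20,
                             seed = 71), mac = mac), mic,
    require_unique = TRUE))
  orfs <- find_orfs(mic, min_aa = 45)
  sup <- attach_support(orfs, rna, dna)
  cal <- list(dna_threshold = c(mac = 0L), rna_threshold_high = 4L,
              rna_threshold_low = 2L)
  calls <- apply_redundancy_filters(classify_candidates(sup, cal), mic)
  kept <- c(calls$high, calls$low)
  ## no two kept calls overlap on the same strand
  expect_identical(
    length(GenomicRanges::findOverlaps(kept, drop.self = TRUE,
                                       ignore.strand = FALSE)), 0L)
  ## the partition survives filtering
  ids <- c(calls$high$ID, calls$low$ID, calls$rejected$ID)
  expect_identical(sort(ids), sort(orfs$ID))
})

test_that("call evaluation scores a perfect synthetic recovery as 1.0", {
  sim <- small_sim(seed = 47)
  tr <- sim$truth$orfs
  mk_calls <- function(classes) {
    sel <- tr[tr$class %in% classes, ]
    gr <- GenomicRanges::GRanges(sel$contig,
                                 IRanges::IRanges(sel$start, sel$end),
                                 strand = sel$strand)
    gr$ID <- sel$ID
    gr
  }
  calls <- structure(list(high = mk_calls("tglo_high"),
                          low = mk_calls("tglo_low"),
                          rejected = mk_calls(c("silent_orf", "mac_gene"))),
                     class = "TgloCallSet")
  ev <- evaluate_calls(calls, sim$truth)
  expect_equal(ev$high_precision, 1)
  expect_equal(ev$high_recall, 1)
  expect_equal(ev$low_precision, 1)
  expect_equal(ev$low_recall, 1)
  expect_identical(ev$n_false_silent, 0L)
  expect_identical(ev$n_false_mac, 0L)
  ## swapping the classes destroys per-class scores but not pooled ones
  swapped <- structure(list(high = calls$low, low = calls$high,
                            rejected = calls$rejected),
                       class = "TgloCallSet")
  ev2 <- evaluate_calls(swapped, sim$truth)
  expect_equal(ev2$high_recall, 0)
  expect_equal(ev2$overall_recall, 1)
})
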