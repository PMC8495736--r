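test_that("a minimal one-locus genome has the expected architecture", {
  cfg <- genome_sim_config(n_precursor_loci = 1, mds_per_locus = c(2, 2),
                           n_tglo_high = 0, n_tglo_low = 0,
                           n_silent_germline_orfs = 0, n_mac_genes = 0,
                           n_contigs = 1, spacer_len = c(500, 800),
                           seed = 3)
  sim <- simulate_mic_genome(cfg)
  f <- sim$genome$features
  expect_identical(sum(f$type == "MDS"), 2L)
  expect_identical(sum(f$type == "IES"), 1L)
  expect_identical(sum(f$type == "locus"), 1L)
  expect_identical(sum(f$type == "spacer"), 2L)
  ## spacer MDS1 IES MDS2 spacer tiles the contig
  ord <- f[order(GenomicRanges::start(f))]
  ord <- ord[ord$type != "locus"]
  expect_identical(as.character(ord$type),
                   c("spacer", "MDS", "IES", "MDS", "spacer"))
  expect_identical(GenomicRanges::start(ord)[-1],
                   GenomicRanges::end(ord)[-length(ord)] + 1L)
  expect_identical(GenomicRanges::end(ord)[length(ord)],
                   Biostrings::width(sim$genome$seq)[1])
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- genome_sim_config(n_precursor_loci = 3, n_contigs = 1,
                           n_tglo_high = 2, n_tglo_low = 2,
                           n_silent_germline_orfs = 1, n_mac_genes = 1,
                           spacer_len = c(2000, 3000), seed = 11)
  s1 <- simulate_mic_genome(cfg)
  s2 <- simulate_mic_genome(cfg)
  expect_identical(as.character(s1$genome$seq), as.character(s2$genome$seq))
  expect_identical(as.data.frame(s1$genome$features),
                   as.data.frame(s2$genome$features))
  expect_identical(s1$truth$expression, s2$truth$expression)
  ## and the FASTA bytes on disk agree
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_fasta(s1$genome$seq, p1); write_fasta(s2$genome$seq, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted germline-limited ORFs never touch MDS space", {
  cfg <- genome_sim_config(n_precursor_loci = 10, n_contigs = 2,
                           n_tglo_high = 15, n_tglo_low = 15,
                           n_silent_germline_orfs = 0, n_mac_genes = 0,
                           spacer_len = c(4000, 8000), seed = 21)
  sim <- simulate_mic_genome(cfg)
  f <- sim$genome$features
  mds <- f[f$type == "MDS"]
  tr <- sim$truth$orfs
  expect_identical(nrow(tr), 30L)
  ## per-base interval intersection oracle
  for (i in seq_len(nrow(tr))) {
    m <- mds[as.character(GenomeInfoDb::seqnames(mds)) == tr$contig[i]]
    overlap <- sum(pmin(GenomicRanges::end(m), tr$end[i]) -
                     pmax(GenomicRanges::start(m), tr$start[i]) + 1 > 0)
    expect_identical(overlap, 0L)
  }
})

test_that("infeasible sizing requests raise an informative error", {
  cfg <- genome_sim_config(n_precursor_loci = 1, n_contigs = 1,
                           spacer_len = c(60, 80), ies_len = c(50, 60),
                           n_tglo_high = 40, n_tglo_low = 0,
                           n_silent_germline_orfs = 0, n_mac_genes = 0,
                           tglo_len = c(600, 600), seed = 1)
  expect_error(simulate_mic_genome(cfg), "germline-limited space")
})

test_that("MAC derivation joins MDSs, drops IESs, descrambles, adds telomeres", {
  ## hand-built two-MDS locus: MDS1=AAAA, IES=GGGG, MDS2=TTTT
  mk <- function(somatic_order, somatic_strand) {
    seqs <- Biostrings::DNAStringSet(c(mic = "CCAAAAGGGGTTTTCC"))
    gr <- GenomicRanges::GRanges("mic",
                                 IRanges::IRanges(c(3L, 7L, 11L),
                                                  c(6L, 10L, 14L)))
    gr$type <- c("MDS", "IES", "MDS")
    gr$ID <- c("L1_MDS1", "L1_IES1", "L1_MDS2")
    gr$locus <- "L1"
    gr$mds_index <- c(1L, NA, 2L)
    gr$somatic_order <- c(somatic_order[1], NA, somatic_order[2])
    gr$somatic_strand <- c(somatic_strand[1], NA, somatic_strand[2])
    annotated_genome(seqs, gr)
  }
  mac <- derive_mac_genome(mk(c(1L, 2L), c("+", "+")), telomere_units = 5)
  s <- as.character(mac$seq[[1]])
  expect_identical(s, paste0(strrep("CCCCAAAA", 5), "AAAATTTT",
                             strrep("TTTTGGGG", 5)))
  expect_false(grepl("GGGGTTTTGGGGG", s))  # no IES leakage

  ## scrambled somatic order (2,1): core = MDS2 + MDS1
  mac2 <- derive_mac_genome(mk(c(2L, 1L), c("+", "+")), telomere_units = 1)
  expect_identical(as.character(mac2$seq[[1]]),
                   paste0("CCCCAAAA", "TTTTAAAA", "TTTTGGGG"))

  ## inversion: MDS1 on the minus strand in the product
  mac3 <- derive_mac_genome(mk(c(1L, 2L), c("-", "+")), telomere_units = 1)
  expect_identical(as.character(mac3$seq[[1]]),
                   paste0("CCCCAAAA", "TTTTTTTT", "TTTTGGGG"))

  ## incomplete somatic order is a structural error
  bad <- mk(c(1L, 1L), c("+", "+"))
  expect_error(derive_mac_genome(bad), "permutation")
})

test_that("MAC derivation is lossless for MDSs and total for IESs", {
  sim <- small_sim(seed = 13)
  mac <- derive_mac_genome(sim$genome)
  mic_chr <- as.character(sim$genome$seq)
  ## concatenating each nanochromosome's MDS blocks reproduces its core
  for (nano in names(mac$seq)) {
    f <- mac$features[as.character(GenomeInfoDb::seqnames(mac$features)) ==
                        nano]
    mds <- f[f$type == "MDS"]
    mds <- mds[order(GenomicRanges::start(mds))]
    tel <- f[f$type == "telomere"]
    core <- substr(as.character(mac$seq[[nano]]),
                   max(GenomicRanges::end(tel[1])) + 1L,
                   GenomicRanges::start(tel[2]) - 1L)
    blocks <- vapply(seq_along(mds), function(i) {
      substr(as.character(mac$seq[[nano]]), GenomicRanges::start(mds[i]),
             GenomicRanges::end(mds[i]))
    }, character(1))
    expect_identical(paste(blocks, collapse = ""), core)
  }
  ## no planted TGLO sequence appears in any nanochromosome
  tr <- sim$truth$orfs
  gl <- tr[tr$class != "mac_gene", ]
  gr <- GenomicRanges::GRanges(gl$contig, IRanges::IRanges(gl$start, gl$end),
                               strand = gl$strand)
  gr$ID <- gl$ID
  seqs <- orf_sequences(sim$genome, gr)
  for (s in as.character(seqs)) {
    expect_identical(sum(Biostrings::vcountPattern(s, mac$seq)), 0L)
    expect_identical(sum(Biostrings::vcountPattern(rc1(s), mac$seq)), 0L)
  }
})

test_that("error-free reads are exact substrings of their source", {
  sim <- small_sim(seed = 17)
  mac <- derive_mac_genome(sim$genome)
  reads <- simulate_reads(config = read_sim_config("dna_mac",
                                                   read_len = 100,
                                                   depth = 2, seed = 2),
                          mac = mac)
  expect_gt(length(reads), 50)
  joined_fwd <- as.character(mac$seq)
  for (r in as.character(reads[sample(length(reads), 25)])) {
    hit <- any(vapply(joined_fwd, function(ctg) {
      grepl(r, ctg, fixed = TRUE) || grepl(rc1(r), ctg, fixed = TRUE)
    }, logical(1)))
    expect_true(hit)
  }
})

test_that("small-RNA libraries are 27 nt drawn entirely from MDS intervals", {
  sim <- small_sim(seed = 19)
  reads <- simulate_reads(sim$genome,
                          read_sim_config("small_rna", depth = 2, seed = 3))
  expect_true(all(Biostrings::width(reads) == 27L))
  aln <- map_reads_exact(reads, sim$genome)
  mds <- sim$genome$features[sim$genome$features$type == "MDS"]
  ov <- GenomicRanges::findOverlaps(aln, mds, type = "within",
                                    ignore.strand = TRUE)
  expect_identical(length(unique(S4Vectors::queryHits(ov))), length(aln))
  ## every simulated read maps somewhere
  expect_identical(attr(aln, "mapping_stats")$n_unmapped, 0L)
})

test_that("RNA libraries honour planted expression, including zero", {
  sim <- small_sim(seed = 23)
  ## 0 h: TGLOs are planted silent before 24 h
  r0 <- simulate_reads(sim$genome,
                       read_sim_config("rna_timepoint", read_len = 75,
                                       timepoint = 0, seed = 4),
                       truth = sim$truth)
  aln0 <- map_reads_exact(r0, sim$genome)
  tr <- sim$truth$orfs
  tg <- tr[tr$class %in% c("tglo_high", "tglo_low"), ]
  gr <- GenomicRanges::GRanges(tg$contig, IRanges::IRanges(tg$start, tg$end))
  gr$ID <- tg$ID
  expect_identical(sum(coverage_from_alignments(aln0, gr)$counts), 0L)
  ## unknown time point is rejected
  expect_error(simulate_reads(sim$genome,
                              read_sim_config("rna_timepoint",
                                              timepoint = 7, seed = 1),
                              truth = sim$truth), "grid")
})

test_that("mean simulated RNA counts track the planted expectation", {
  sim <- small_sim(seed = 29)
  tr <- sim$truth$orfs
  hi <- tr[tr$class == "tglo_high", ][1, ]
  mu <- sim$truth$expression[hi$ID, "48"]
  n_rep <- 50
  g <- GenomicRanges::GRanges(hi$contig, IRanges::IRanges(hi$start, hi$end))
  g$ID <- hi$ID
  counts <- vapply(seq_len(n_rep), function(i) {
    r <- simulate_reads(sim$genome,
                        read_sim_config("rna_timepoint", read_len = 75,
                                        timepoint = 48, seed = 1000 + i),
                        truth = sim$truth)
    aln <- map_reads_exact(r, sim$genome)
    unname(coverage_from_alignments(aln, g)$counts)
  }, numeric(1))
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - mu), 3 * se + 1e-9)
})

test_that("the truth table round-trips through TSV", {
  sim <- small_sim(seed = 31)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(sim$truth, p)
  tab <- read.table(p, header = TRUE, sep = "\t")
  expect_identical(nrow(tab), nrow(sim$truth$orfs))
  expect_true(all(c("ID", "class", "contig", "start", "end", "strand") %in%
                    names(tab)))
  expect_identical(sum(grepl("^expected_", names(tab))),
                   length(sim$truth$time_points))
})
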