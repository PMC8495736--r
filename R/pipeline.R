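## End-to-end orchestration: simulate (or load) -> map -> scan ORFs ->
## calibrate -> classify -> assemble -> quantify/enrich, as one seeded,
## reproducible run with a machine-readable funnel report.

#' Pipeline configuration
#'
#' Defaults reproduce the screen's published decision logic at desk scale:
#' 100 shuffles, 5th/95th percentile thresholds, the 4-read/>80% high rule
#' and 2-read/>20% low rule, three whole-cell DNA libraries (both parental
#' strains and a pooled-progeny library) at 30x MAC coverage with a 100:1
#' MAC:MIC template ratio, and one RNA library per developmental time
#' point.
#'
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it.
#' @param simulate a [genome_sim_config()]; set to `NULL` when real inputs
#'   are supplied.
#' @param inputs optional list of real input paths (`mic_fasta`,
#'   `features_gff3`, plus named FASTQ paths under `dna` and `rna`);
#'   exactly one of `simulate`/`inputs` must be given.
#' @param dna list: `strains`, `depth`, `read_len`, `mac_mic_ratio`.
#' @param rna list: `read_len`, `timepoints` (defaults to the simulation
#'   grid).
#' @param small_rna,template_rna list: `depth` (set `NULL` to skip the
#'   enrichment stage).
#' @param orf list: `min_aa`, `code`.
#' @param shuffle a [shuffle_config()] (its seed is derived from `seed`).
#' @param classify list: `cov_high`, `cov_low`, `rna_threshold_low`,
#'   `combine_rna`.
#' @param cluster list: `identity`, `max_masked_fraction`.
#' @param assemble list: `min_overlap`, or `NULL` to skip the assembly
#'   demonstration stage.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = genome_sim_config(seed = seed),
                            inputs = NULL,
                            dna = list(strains = c("parent_a", "parent_b",
                                                   "f1_pool"),
                                       depth = 30, read_len = 250L,
                                       mac_mic_ratio = 100),
                            rna = list(read_len = 75L, timepoints = NULL),
                            small_rna = list(depth = 5),
                            template_rna = list(depth = 5),
                            orf = list(min_aa = 45L, code = "ciliate"),
                            shuffle = shuffle_config(),
                            classify = list(cov_high = 0.80, cov_low = 0.20,
                                            rna_threshold_low = 2L,
                                            combine_rna = "max"),
                            cluster = list(identity = 0.9,
                                           max_masked_fraction = 0.5),
                            assemble = list(min_overlap = 30L)) {
  check_that(xor(is.null(simulate), is.null(inputs)),
             "exactly one of 'simulate' or 'inputs' must be given")
  structure(list(seed = as.integer(seed), simulate = simulate,
                 inputs = inputs, dna = dna, rna = rna,
                 small_rna = small_rna, template_rna = template_rna,
                 orf = orf, shuffle = shuffle, classify = classify,
                 cluster = cluster, assemble = assemble),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- as.integer(y$seed)
  if (!is.null(y$simulate)) {
    args$simulate <- do.call(genome_sim_config, y$simulate)
  }
  if (!is.null(y$inputs)) {
    args$inputs <- y$inputs
    args$simulate <- NULL
  }
  if (!is.null(y$shuffle)) args$shuffle <- do.call(shuffle_config, y$shuffle)
  for (k in c("dna", "rna", "small_rna", "template_rna", "orf", "classify",
              "cluster", "assemble")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

#' Run the TGLO discovery pipeline
#'
#' Executes the configured stages in order and returns the funnel report.
#' All stage seeds derive from the global seed, so identical configurations
#' produce identical reports. When run on simulated data the report also
#' carries the evaluation of the final call set against the planted truth.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory; when given, every interface
#'   artifact (genome FASTA, annotation GFF3, call table/FASTA/GFF3,
#'   calibration JSON, clustered log2 matrix, strain calls, run report) is
#'   written there.
#' @param verbose log one line per stage.
#' @return a `RunReport`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  report <- list(seed = config$seed, stages = character(0))
  seed_base <- config$seed

  ## ---- stage: genome ---------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_mic_genome(config$simulate)
    mic <- sim$genome; truth <- sim$truth
    mac <- derive_mac_genome(mic, config$simulate$telomere_units)
    say("simulate: %d contigs, %s bp MIC; %d nanochromosomes",
        length(mic$seq), format(sum(Biostrings::width(mic$seq)),
                                big.mark = ","), length(mac$seq))
  } else {
    mic <- annotated_genome(read_fasta(config$inputs$mic_fasta),
                            read_gff3(config$inputs$features_gff3))
    mac <- NULL; truth <- NULL
  }

  ## ---- stage: libraries ------------------------------------------------
  dna_reads <- list()
  if (!is.null(config$inputs)) {
    for (nm in names(config$inputs$dna %||% list())) {
      dna_reads[[nm]] <- read_fastq(config$inputs$dna[[nm]])
    }
  } else {
    dna_kind <- config$dna$kind %||% "dna_wholecell"
    for (i in seq_along(config$dna$strains)) {
      nm <- config$dna$strains[i]
      dna_reads[[nm]] <- simulate_reads(
        mic, read_sim_config(dna_kind,
                             read_len = config$dna$read_len,
                             depth = config$dna$depth,
                             mac_mic_ratio = config$dna$mac_mic_ratio,
                             seed = seed_base + 100L + i),
        mac = mac)
    }
  }
  rna_reads <- list()
  if (!is.null(config$inputs)) {
    for (nm in names(config$inputs$rna %||% list())) {
      rna_reads[[nm]] <- read_fastq(config$inputs$rna[[nm]])
    }
  } else {
    tps <- config$rna$timepoints %||% truth$time_points
    for (i in seq_along(tps)) {
      nm <- sprintf("rna_%02dh", as.integer(tps[i]))
      rna_reads[[nm]] <- simulate_reads(
        mic, read_sim_config("rna_timepoint",
                             read_len = config$rna$read_len,
                             depth = 1, timepoint = tps[i],
                             seed = seed_base + 200L + i),
        truth = truth)
    }
  }
  say("libraries: %d DNA (%s reads), %d RNA (%s reads)",
      length(dna_reads),
      format(sum(vapply(dna_reads, length, integer(1))), big.mark = ","),
      length(rna_reads),
      format(sum(vapply(rna_reads, length, integer(1))), big.mark = ","))

  ## ---- stage: map ------------------------------------------------------
  check_that(length(rna_reads) > 0,
             "classify stage needs RNA libraries (role 'rna_timepoint'), but none are configured")
  dna_aln <- lapply(dna_reads, map_reads_exact, reference = mic,
                    require_unique = TRUE)
  rna_aln <- lapply(rna_reads, map_reads_exact, reference = mic,
                    require_unique = FALSE)
  say("map: done (%d libraries)", length(dna_aln) + length(rna_aln))

  ## ---- stage: ORF scan -------------------------------------------------
  orfs <- find_orfs(mic, min_aa = config$orf$min_aa, code = config$orf$code)
  say("orf scan: %d candidates (min %d aa, %s code)", length(orfs),
      config$orf$min_aa, config$orf$code)

  ## ---- stage: calibrate ------------------------------------------------
  space <- germline_limited_space(mic)
  shuf <- config$shuffle
  shuf$seed <- seed_base + 300L
  calibration <- calibrate_thresholds(
    orfs, space, dna_aln, rna_aln, config = shuf,
    rna_threshold_low = config$classify$rna_threshold_low)
  say("calibrate: DNA thresholds [%s], RNA high >= %d, low >= %d",
      paste(calibration$dna_threshold, collapse = ", "),
      calibration$rna_threshold_high, calibration$rna_threshold_low)

  ## ---- stage: classify -------------------------------------------------
  support <- attach_support(orfs, rna_aln, dna_aln)
  calls0 <- classify_candidates(support, calibration,
                                cov_high = config$classify$cov_high,
                                cov_low = config$classify$cov_low,
                                combine_rna = config$classify$combine_rna)
  calls <- apply_redundancy_filters(
    calls0, mic, identity = config$cluster$identity,
    max_masked_fraction = config$cluster$max_masked_fraction)
  n_dna_rejected <- sum(calls0$rejected$reason == "dna_present")
  funnel <- list(
    candidates = length(orfs),
    dna_pass = length(orfs) - n_dna_rejected,
    classified_high = length(calls0$high),
    classified_low = length(calls0$low),
    final_high = length(calls$high),
    final_low = length(calls$low))
  say("classify: %d candidates -> %d germline-limited -> high %d / low %d -> final %d / %d",
      funnel$candidates, funnel$dna_pass, funnel$classified_high,
      funnel$classified_low, funnel$final_high, funnel$final_low)

  ## ---- stage: assemble (demonstration locus) ---------------------------
  assembly <- NULL
  if (!is.null(config$assemble) && !is.null(mac) && length(dna_aln)) {
    assembly <- tryCatch(
      assemble_demo_locus(mic, mac, dna_reads[[length(dna_reads)]],
                          dna_aln[[length(dna_aln)]], space,
                          min_overlap = config$assemble$min_overlap),
      error = function(e) list(status = "failed",
                               error = conditionMessage(e)))
    if (!is.null(assembly$decomposition)) {
      say("assemble: locus %s -> %s, %d MDS block(s)",
          assembly$locus, assembly$assembly$status,
          nrow(assembly$decomposition$blocks))
    }
  }

  ## ---- stage: quantify / enrich ---------------------------------------
  heat <- NULL
  if (length(rna_aln) >= 2) {
    sel <- c(calls$high, calls$low)
    rej_dna <- calls0$rejected[calls0$rejected$reason == "dna_present"]
    if (length(rej_dna) > 50) rej_dna <- rej_dna[seq_len(50)]
    feats <- c(sel, rej_dna)
    if (length(feats) >= 2) {
      cnt <- support$rna_count[feats$ID, , drop = FALSE]
      sf <- tryCatch(size_factors(cnt),
                     error = function(e) size_factors(cnt, pseudocount = 0.5))
      lm <- log2_matrix(cnt, sf)
      cl <- tryCatch(cluster_rows(lm), error = function(e) NULL)
      heat <- list(log2 = lm, size_factors = sf,
                   row_order = if (!is.null(cl)) cl$order else rownames(lm))
    }
  }
  enrichment <- list()
  if (!is.null(config$small_rna$depth) && !is.null(mac)) {
    srna <- simulate_reads(mic, read_sim_config(
      "small_rna", depth = config$small_rna$depth,
      seed = seed_base + 400L))
    srna_aln <- map_reads_exact(srna, mic, require_unique = TRUE)
    mds <- mic$features[mic$features$type == "MDS"]
    tglos <- c(calls$high, calls$low)
    if (length(tglos) > 0) {
      enrichment$small_rna <- compare_feature_classes(
        srna_aln, mds, tglos, name_a = "MDS", name_b = "TGLO")
    }
  }
  if (!is.null(config$template_rna$depth) && !is.null(mac)) {
    trna <- simulate_reads(mic, read_sim_config(
      "template_rna", depth = config$template_rna$depth,
      read_len = config$rna$read_len, seed = seed_base + 500L), mac = mac)
    trna_aln <- map_reads_exact(trna, mic, require_unique = TRUE)
    mds <- mic$features[mic$features$type == "MDS"]
    tglos <- c(calls$high, calls$low)
    if (length(tglos) > 0) {
      enrichment$template_rna <- compare_feature_classes(
        trna_aln, mds, tglos, name_a = "MDS", name_b = "TGLO")
    }
  }
  if (length(enrichment)) {
    for (nm in names(enrichment)) {
      say("enrich (%s): KS D=%.3f p=%.3g, higher in %s", nm,
          enrichment[[nm]]$D, enrichment[[nm]]$p, enrichment[[nm]]$higher)
    }
  }

  ## ---- strain retention over final calls + somatic-rejected ------------
  strain_calls <- NULL
  strains <- setdiff(names(dna_aln), "f1_pool")
  if (length(strains) >= 2) {
    loci <- c(calls$high, calls$low,
              calls0$rejected[calls0$rejected$reason == "dna_present"])
    if (length(loci) > 0) {
      cnts <- support$dna_count[loci$ID, strains, drop = FALSE]
      strain_calls <- classify_strain_retention(
        cnts, calibration$dna_threshold[strains])
    }
  }

  ## ---- evaluation against planted truth --------------------------------
  evaluation <- if (!is.null(truth)) evaluate_calls(calls, truth) else NULL
  if (!is.null(evaluation)) {
    say("evaluate: precision high/low = %.3f/%.3f, recall = %.3f/%.3f",
        evaluation$high_precision, evaluation$low_precision,
        evaluation$high_recall, evaluation$low_recall)
  }

  report <- structure(list(
    seed = config$seed,
    config = config,
    funnel = funnel,
    calibration = calibration,
    calls = calls,
    support = support,
    assembly = assembly,
    heatmap = heat,
    enrichment = enrichment,
    strain_calls = strain_calls,
    evaluation = evaluation,
    truth = truth,
    genome = mic,
    mac = mac,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "RunReport")

  if (!is.null(outdir)) write_run_artifacts(report, outdir)
  report
}

## Pick a demonstration locus (prefer a scrambled one), gather its somatic
## reads plus everything not uniquely placed in germline-limited space, and
## assemble/decompose its nanochromosome.
assemble_demo_locus <- function(mic, mac, reads, alignments, space,
                                min_overlap = 30L) {
  f <- mic$features
  loci <- f[f$type == "locus"]
  mds <- f[f$type == "MDS"]
  scram <- unique(mds$locus[!is.na(mds$somatic_strand) &
                              mds$somatic_strand == "-"])
  locus_id <- if (length(scram)) sort(scram)[1] else sort(loci$ID)[1]
  locus <- loci[loci$ID == locus_id]
  locus_mds <- mds[mds$locus == locus_id]
  on_mds <- unique(alignments$read_id[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(alignments, locus_mds,
                                ignore.strand = TRUE))])
  placed <- unique(alignments$read_id)
  pool_ids <- union(on_mds, setdiff(names(reads), placed))
  pool <- reads[pool_ids]
  check_that(length(on_mds) > 0, "no reads on the demonstration locus")
  seed_id <- sort(on_mds)[1]
  asm <- assemble_from_seed(seed_id, pool, min_overlap = min_overlap)
  locus_seq <- as.character(Biostrings::subseq(
    mic$seq[[as.character(GenomeInfoDb::seqnames(locus))]],
    GenomicRanges::start(locus), GenomicRanges::end(locus)))
  dec <- tryCatch(decompose_into_mds(asm, locus_seq),
                  error = function(e) NULL)
  list(locus = locus_id, assembly = asm, decomposition = dec)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("TGLO screen run report\n")
  cat(sprintf("  seed %d, runtime %.1f s\n", x$seed, x$runtime_sec))
  f <- x$funnel
  cat(sprintf(
    "  funnel: %d candidates -> %d germline-limited -> %d high / %d low -> final %d / %d\n",
    f$candidates, f$dna_pass, f$classified_high, f$classified_low,
    f$final_high, f$final_low))
  print(x$calibration)
  if (!is.null(x$evaluation)) {
    e <- x$evaluation
    cat(sprintf(
      "  vs planted truth: precision %0.3f/%0.3f, recall %0.3f/%0.3f (high/low); FP silent=%d mac=%d novel=%d\n",
      e$high_precision, e$low_precision, e$high_recall, e$low_recall,
      e$n_false_silent, e$n_false_mac, e$n_false_novel))
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' @param report a `RunReport`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_fasta(report$genome$seq, p("mic_genome.fasta"))
  write_gff3(report$genome$features, p("mic_features.gff3"))
  if (!is.null(report$mac)) {
    write_fasta(report$mac$seq, p("mac_genome.fasta"))
  }
  if (!is.null(report$truth)) {
    write_truth_table(report$truth, p("truth.tsv"))
  }
  write_call_table(report$calls, p("calls.tsv"))
  kept <- c(report$calls$high, report$calls$low)
  if (length(kept)) {
    write_fasta(orf_sequences(report$genome, kept), p("tglo_calls.fasta"))
    write_gff3(kept, p("tglo_calls.gff3"))
  }
  write_calibration_json(report$calibration, p("calibration.json"))
  if (!is.null(report$heatmap)) {
    write_matrix_tsv(report$heatmap$log2, p("log2_matrix.tsv"),
                     row_order = report$heatmap$row_order)
  }
  if (!is.null(report$strain_calls)) {
    utils::write.table(report$strain_calls, p("strain_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_run_report_json(report, p("run_report.json"))
  invisible(outdir)
}

#' Serialize the funnel report as JSON
#'
#' @param report a `RunReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report_json <- function(report, path) {
  payload <- list(
    seed = report$seed,
    funnel = report$funnel,
    thresholds = list(
      dna = as.list(report$calibration$dna_threshold),
      rna_high = report$calibration$rna_threshold_high,
      rna_low = report$calibration$rna_threshold_low),
    call_sets = list(high = length(report$calls$high),
                     low = length(report$calls$low),
                     rejected = length(report$calls$rejected)),
    enrichment = lapply(report$enrichment, function(e) {
      list(D = e$D, p = e$p, higher = e$higher,
           median_a = e$median_a, median_b = e$median_b)
    }),
    evaluation = report$evaluation,
    runtime_sec = report$runtime_sec)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
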