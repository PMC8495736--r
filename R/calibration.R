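## Monte Carlo shuffle null for coverage over germline-limited space.
##
## Sequencing depth varies between libraries, so absolute read-count cutoffs
## are meaningless. The screen instead shuffles every candidate locus
## through the germline-limited portion of the genome (default 100 times),
## records per-locus read counts under each library, and extracts
## nearest-rank percentile thresholds: a lower-tail (5th percentile) DNA
## threshold a true germline-limited locus must not exceed, and an
## upper-tail (95th percentile) RNA threshold a highly transcribed locus
## must reach.

#' Shuffle configuration
#'
#' @param n_shuffles number of whole-set shuffles (default 100).
#' @param percentile_dna lower-tail DNA quantile level (default 0.05).
#' @param percentile_rna upper-tail RNA quantile level (default 0.95).
#' @param allow_overlap_between_placements may placements within one shuffle
#'   overlap each other (default `TRUE`).
#' @param seed integer seed.
#' @return a `ShuffleConfig` list.
#' @export
shuffle_config <- function(n_shuffles = 100L, percentile_dna = 0.05,
                           percentile_rna = 0.95,
                           allow_overlap_between_placements = TRUE,
                           seed = 1L) {
  check_that(n_shuffles >= 1, "n_shuffles must be >= 1")
  check_that(percentile_dna > 0 && percentile_dna < 1 &&
               percentile_rna > 0 && percentile_rna < 1,
             "percentiles must lie in (0, 1)")
  structure(list(n_shuffles = as.integer(n_shuffles),
                 percentile_dna = percentile_dna,
                 percentile_rna = percentile_rna,
                 allow_overlap_between_placements =
                   isTRUE(allow_overlap_between_placements),
                 seed = as.integer(seed)),
            class = "ShuffleConfig")
}

#' Germline-limited space
#'
#' The complement of the union of MDS intervals within contig bounds,
#' merged and sorted — the sequence eliminated from the somatic genome.
#'
#' @param features GRanges carrying MDS rows (`type == "MDS"`) with
#'   seqlengths set, or an [annotated_genome()].
#' @return GRanges of merged germline-limited intervals.
#' @export
germline_limited_space <- function(features) {
  if (inherits(features, "AnnotatedGenome")) features <- features$features
  check_that(methods::is(features, "GRanges"), "'features' must be a GRanges")
  sl <- GenomeInfoDb::seqlengths(features)
  check_that(!anyNA(sl) && length(sl) > 0,
             "features must carry seqlengths to bound the complement")
  whole <- GenomicRanges::GRanges(
    seqnames = names(sl), ranges = IRanges::IRanges(1L, sl),
    seqlengths = sl)
  mds <- features[features$type == "MDS"]
  out <- GenomicRanges::setdiff(whole, mds, ignore.strand = TRUE)
  sort(GenomicRanges::reduce(out))
}

#' Shuffle candidate loci through an interval set
#'
#' Each shuffle places every candidate independently and uniformly at
#' random so that the placed interval lies entirely within one interval of
#' `space`; candidate lengths are preserved exactly. Placement is uniform
#' over all legal start positions across intervals.
#'
#' @param candidates GRanges of candidate loci (lengths are what matters).
#' @param space GRanges of allowed intervals ([germline_limited_space()]).
#' @param config a [shuffle_config()].
#' @return GRanges of placements with columns `candidate_id` and `shuffle`.
#' @export
shuffle_loci <- function(candidates, space, config = shuffle_config()) {
  stopifnot(inherits(config, "ShuffleConfig"))
  check_that(length(space) > 0, "empty placement space")
  widths <- GenomicRanges::width(candidates)
  ids <- candidates$ID %||% as.character(seq_along(candidates))
  W <- GenomicRanges::width(space)
  too_long <- widths > max(W)
  if (any(too_long)) {
    stop(sprintf("candidate(s) longer than every space interval: %s",
                 paste(utils::head(ids[too_long], 5), collapse = ", ")),
         call. = FALSE)
  }
  ns <- config$n_shuffles
  sp_start <- GenomicRanges::start(space)
  sp_ctg <- as.character(GenomeInfoDb::seqnames(space))
  with_seed(config$seed, {
    if (config$allow_overlap_between_placements) {
      total <- length(widths) * ns
      res_ctg <- character(total)
      res_start <- integer(total)
      res_w <- integer(total)
      res_id <- character(total)
      res_sh <- integer(total)
      pos <- 0L
      for (w in sort(unique(widths))) {
        idx <- which(widths == w)
        m <- length(idx) * ns
        legal <- pmax(W - w + 1L, 0L)
        pick <- sample.int(length(W), m, replace = TRUE, prob = legal)
        start <- sp_start[pick] + as.integer(floor(runif(m) * legal[pick]))
        sel <- pos + seq_len(m)
        res_ctg[sel] <- sp_ctg[pick]
        res_start[sel] <- start
        res_w[sel] <- w
        res_id[sel] <- rep(ids[idx], times = ns)
        res_sh[sel] <- rep(seq_len(ns), each = length(idx))
        pos <- pos + m
      }
      gr <- GenomicRanges::GRanges(
        seqnames = res_ctg,
        ranges = IRanges::IRanges(res_start, width = res_w),
        candidate_id = res_id, shuffle = res_sh,
        seqlengths = GenomeInfoDb::seqlengths(space))
    } else {
      ## sequential rejection placement within each shuffle
      rows <- list()
      for (sh in seq_len(ns)) {
        placed <- GenomicRanges::GRanges(
          seqlengths = GenomeInfoDb::seqlengths(space))
        for (i in order(widths, decreasing = TRUE)) {
          w <- widths[i]
          legal <- pmax(W - w + 1L, 0L)
          done <- FALSE
          for (try in seq_len(200L)) {
            pick <- sample.int(length(W), 1L, prob = legal)
            start <- sp_start[pick] +
              as.integer(floor(runif(1) * legal[pick]))
            cand <- GenomicRanges::GRanges(sp_ctg[pick],
                                           IRanges::IRanges(start,
                                                            width = w))
            if (!length(GenomicRanges::findOverlaps(cand, placed))) {
              placed <- c(placed, cand)
              rows[[length(rows) + 1L]] <- data.frame(
                contig = sp_ctg[pick], start = start, width = w,
                candidate_id = ids[i], shuffle = sh,
                stringsAsFactors = FALSE)
              done <- TRUE
              break
            }
          }
          if (!done) {
            stop(sprintf(
              "could not place candidate %s without overlap in shuffle %d",
              ids[i], sh), call. = FALSE)
          }
        }
      }
      df <- do.call(rbind, rows)
      gr <- GenomicRanges::GRanges(
        seqnames = df$contig,
        ranges = IRanges::IRanges(df$start, width = df$width),
        candidate_id = df$candidate_id, shuffle = df$shuffle,
        seqlengths = GenomeInfoDb::seqlengths(space))
    }
    gr
  })
}

#' Background count distribution over shuffled placements
#'
#' One count per placed locus per shuffle, using the same counting mode as
#' the real candidates.
#'
#' @param placements GRanges from [shuffle_loci()].
#' @param alignments GRanges of read alignments.
#' @param mode overlap counting mode (see [coverage_from_alignments()]).
#' @return integer vector (the per-locus count multiset).
#' @export
background_distribution <- function(placements, alignments,
                                    mode = c("any", "contained")) {
  mode <- match.arg(mode)
  if (mode == "any") {
    as.integer(GenomicRanges::countOverlaps(placements, alignments,
                                            ignore.strand = TRUE))
  } else {
    ov <- GenomicRanges::findOverlaps(alignments, placements,
                                      type = "within", ignore.strand = TRUE)
    tabulate(S4Vectors::subjectHits(ov), nbins = length(placements))
  }
}

#' Nearest-rank percentile of a count multiset
#'
#' Type-1 (inverse ECDF) quantile: the smallest attained value whose
#' empirical CDF is at least `q`. Always an attained integer count, so
#' thresholds are realizable.
#'
#' @param counts integer vector (nonempty).
#' @param q quantile level in (0, 1).
#' @return integer.
#' @export
percentile_threshold <- function(counts, q) {
  check_that(length(counts) > 0, "empty count distribution")
  check_that(q > 0 && q < 1, "q must lie in (0, 1)")
  as.integer(stats::quantile(counts, probs = q, type = 1, names = FALSE))
}

#' Calibrate DNA and RNA thresholds by locus shuffling
#'
#' Shuffles the candidate loci through germline-limited space once, then
#' derives per-DNA-library lower-tail thresholds (a candidate must not
#' exceed any of them) and a pooled upper-tail RNA threshold for the
#' high-transcription rule. The low-transcription read threshold is not a
#' percentile — it is the permissive floor the screen design fixes (default
#' 2 reads) so that weakly expressed loci are not discarded outright.
#'
#' @param candidates GRanges of candidate loci.
#' @param space GRanges from [germline_limited_space()].
#' @param dna_alignments,rna_alignments named lists of alignment GRanges.
#' @param config a [shuffle_config()].
#' @param rna_threshold_low integer floor for the low-transcription rule.
#' @param pool_rna pool RNA libraries into one background (default) or
#'   keep per-library upper-tail thresholds.
#' @param mode overlap counting mode.
#' @return a `ThresholdCalibration`: per-library `dna_threshold`,
#'   `rna_threshold_high`, `rna_threshold_low`, the background multisets,
#'   and provenance (seed, n_shuffles, percentiles).
#' @export
calibrate_thresholds <- function(candidates, space, dna_alignments,
                                 rna_alignments, config = shuffle_config(),
                                 rna_threshold_low = 2L, pool_rna = TRUE,
                                 mode = "any") {
  placements <- shuffle_loci(candidates, space, config)
  dna_bg <- lapply(dna_alignments, function(a)
    background_distribution(placements, a, mode))
  rna_bg <- lapply(rna_alignments, function(a)
    background_distribution(placements, a, mode))
  dna_threshold <- vapply(dna_bg, percentile_threshold,
                          integer(1), q = config$percentile_dna)
  if (pool_rna) {
    pooled <- unlist(rna_bg, use.names = FALSE) %||% integer(0)
    rna_high <- percentile_threshold(pooled, config$percentile_rna)
  } else {
    rna_high <- max(vapply(rna_bg, percentile_threshold, integer(1),
                           q = config$percentile_rna))
  }
  structure(list(
    dna_threshold = dna_threshold,
    rna_threshold_high = as.integer(rna_high),
    rna_threshold_low = as.integer(rna_threshold_low),
    background = list(dna = dna_bg, rna = rna_bg, pooled_rna = pool_rna),
    provenance = list(seed = config$seed, n_shuffles = config$n_shuffles,
                      percentile_dna = config$percentile_dna,
                      percentile_rna = config$percentile_rna,
                      n_candidates = length(candidates))),
    class = "ThresholdCalibration")
}

#' @export
print.ThresholdCalibration <- function(x, ...) {
  cat("ThresholdCalibration\n")
  cat(sprintf("  shuffles: %d over %d candidates (seed %d)\n",
              x$provenance$n_shuffles, x$provenance$n_candidates,
              x$provenance$seed))
  cat(sprintf("  DNA thresholds (q=%.2f): %s\n", x$provenance$percentile_dna,
              paste(sprintf("%s=%d", names(x$dna_threshold),
                            x$dna_threshold), collapse = ", ")))
  cat(sprintf("  RNA thresholds: high >= %d (q=%.2f), low >= %d\n",
              x$rna_threshold_high, x$provenance$percentile_rna,
              x$rna_threshold_low))
  invisible(x)
}

#' Export a calibration report as JSON
#'
#' Thresholds, provenance and per-library count histograms.
#'
#' @param calibration a `ThresholdCalibration`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(calibration, path) {
  hist_of <- function(x) {
    t <- table(x)
    list(count = as.integer(names(t)), n = as.integer(t))
  }
  payload <- list(
    dna_threshold = as.list(calibration$dna_threshold),
    rna_threshold_high = calibration$rna_threshold_high,
    rna_threshold_low = calibration$rna_threshold_low,
    provenance = calibration$provenance,
    histograms = list(
      dna = lapply(calibration$background$dna, hist_of),
      rna = lapply(calibration$background$rna, hist_of)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
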