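## TGLO classification: germline-limited and transcription filters,
## redundancy clustering, repeat masking.
##
## The decision logic mirrors the published screen: a candidate is rejected
## outright if any whole-cell DNA library places more reads on it than that
## library's calibrated lower-tail threshold (somatic presence); survivors
## join the high-transcription set if some RNA library gives at least the
## calibrated upper-tail read count AND covers more than 80% of the CDS,
## else the low-transcription set at the permissive floor (2 reads, > 20%
## covered), else they are rejected as under-transcribed. Read-count rules
## are inclusive ("at least"), coverage rules strict ("greater than").

#' Classify candidate ORFs into high/low TGLO sets
#'
#' @param support a `CandidateOrfSet` from [attach_support()].
#' @param calibration a `ThresholdCalibration` (or a list with elements
#'   `dna_threshold`, `rna_threshold_high`, `rna_threshold_low`).
#' @param cov_high,cov_low strict coverage-fraction cutoffs for the high
#'   and low rules (defaults 0.80 and 0.20).
#' @param combine_rna `"max"`: a single RNA library must satisfy the joint
#'   (reads, coverage) rule — transcription in at least one time point;
#'   `"sum"`: read counts are summed across libraries and coverage taken as
#'   the per-library maximum.
#' @return a `TgloCallSet`: GRanges `high`, `low`, `rejected` (with a
#'   `reason` column: `dna_present` or `under_transcribed`), plus the
#'   calibration snapshot and the support object. The three sets partition
#'   the input.
#' @export
classify_candidates <- function(support, calibration,
                                cov_high = 0.80, cov_low = 0.20,
                                combine_rna = c("max", "sum")) {
  combine_rna <- match.arg(combine_rna)
  stopifnot(inherits(support, "CandidateOrfSet"))
  orfs <- support$orfs
  n <- length(orfs)
  dna_thr <- calibration$dna_threshold
  check_that(!is.null(dna_thr), "calibration lacks DNA thresholds")
  dlibs <- names(dna_thr)
  check_that(all(dlibs %in% colnames(support$dna_count)),
             sprintf("missing DNA support for configured library: %s",
                     paste(setdiff(dlibs, colnames(support$dna_count)),
                           collapse = ", ")))
  dna_reject <- rep(FALSE, n)
  for (lib in dlibs) {
    dna_reject <- dna_reject | (support$dna_count[, lib] > dna_thr[[lib]])
  }
  thr_hi <- calibration$rna_threshold_high
  thr_lo <- calibration$rna_threshold_low
  if (ncol(support$rna_count) == 0) {
    hi <- lo <- rep(FALSE, n)
  } else if (combine_rna == "max") {
    hi <- rowSums(support$rna_count >= thr_hi &
                    support$rna_covfrac > cov_high) > 0
    lo <- rowSums(support$rna_count >= thr_lo &
                    support$rna_covfrac > cov_low) > 0
  } else {
    tot <- rowSums(support$rna_count)
    maxcov <- apply(support$rna_covfrac, 1L, max)
    hi <- tot >= thr_hi & maxcov > cov_high
    lo <- tot >= thr_lo & maxcov > cov_low
  }
  class_of <- rep("rejected", n)
  reason <- rep(NA_character_, n)
  reason[dna_reject] <- "dna_present"
  keep <- !dna_reject
  class_of[keep & hi] <- "high"
  class_of[keep & !hi & lo] <- "low"
  reason[keep & !hi & !lo] <- "under_transcribed"
  rejected <- orfs[class_of == "rejected"]
  rejected$reason <- reason[class_of == "rejected"]
  structure(list(high = orfs[class_of == "high"],
                 low = orfs[class_of == "low"],
                 rejected = rejected,
                 calibration = calibration,
                 support = support),
            class = "TgloCallSet")
}

#' @export
print.TgloCallSet <- function(x, ...) {
  rtab <- table(x$rejected$reason)
  cat(sprintf("TgloCallSet: %d high, %d low, %d rejected (%s)\n",
              length(x$high), length(x$low), length(x$rejected),
              paste(sprintf("%s=%d", names(rtab), as.integer(rtab)),
                    collapse = ", ")))
  invisible(x)
}

#' Extract candidate/call sequences from the genome
#'
#' Minus-strand intervals are reverse complemented, so every returned
#' sequence reads 5'->3' in coding orientation.
#'
#' @param genome [annotated_genome()] or named DNAStringSet.
#' @param orfs GRanges with an `ID` column.
#' @return named [Biostrings::DNAStringSet].
#' @export
orf_sequences <- function(genome, orfs) {
  if (inherits(genome, "AnnotatedGenome")) genome <- genome$seq
  if (!length(orfs)) return(Biostrings::DNAStringSet())
  ctg <- as.character(GenomeInfoDb::seqnames(orfs))
  s <- as.character(Biostrings::subseq(genome[ctg],
                                       GenomicRanges::start(orfs),
                                       GenomicRanges::end(orfs)))
  minus <- as.character(GenomicRanges::strand(orfs)) == "-"
  s[minus] <- revcomp(s[minus])
  out <- Biostrings::DNAStringSet(s)
  names(out) <- orfs$ID %||% as.character(seq_along(orfs))
  out
}

## Best ungapped identity between two sequences via k-mer diagonal seeding.
## Among the top-voted diagonals whose aligned span covers at least
## `min_cover` of the shorter sequence, returns c(identity, cover);
## c(0, 0) when no shared k-mer or no sufficiently covering diagonal.
ungapped_identity <- function(a, b, k = 8L, min_cover = 0.7) {
  if (nchar(a) < k || nchar(b) < k) return(c(0, 0))
  swapped <- nchar(a) > nchar(b)
  s <- if (swapped) b else a
  l <- if (swapped) a else b
  ns <- nchar(s); nl <- nchar(l)
  lk <- substring(l, seq_len(nl - k + 1L), seq_len(nl - k + 1L) + k - 1L)
  sk <- substring(s, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
  hit <- match(sk, lk)            # first hit per s k-mer is enough to vote
  ok <- which(!is.na(hit))
  if (!length(ok)) return(c(0, 0))
  diag <- hit[ok] - ok
  votes <- table(diag)
  dd <- as.integer(names(votes))
  ## only diagonals whose aligned span can reach min_cover are candidates;
  ## rank those by k-mer votes and evaluate the best few
  span <- pmin(ns, nl - dd) - pmax(1L, 1L - dd) + 1L
  keep <- span / ns >= min_cover
  if (!any(keep)) return(c(0, 0))
  dd <- dd[keep][order(-as.integer(votes)[keep])]
  best <- c(0, 0)
  sv <- strsplit(s, "")[[1]]
  lv <- strsplit(l, "")[[1]]
  for (d in utils::head(dd, 5L)) {
    i1 <- max(1L, 1L - d); i2 <- min(ns, nl - d)
    if (i2 <= i1) next
    idx <- i1:i2
    cover <- length(idx) / ns
    ident <- mean(sv[idx] == lv[idx + d])
    if (ident > best[1] || (ident == best[1] && cover > best[2])) {
      best <- c(ident, cover)
    }
  }
  best
}

#' Greedy redundancy clustering of sequences
#'
#' Longest-first greedy clustering in the CD-HIT style: a sequence joins
#' the first representative with which its best ungapped k-mer-chained
#' identity reaches `identity` over at least `min_cover` of the shorter
#' sequence (both orientations are tried); otherwise it founds a new
#' cluster. Input order is fixed (length descending, id ascending), so the
#' result is deterministic.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @param identity identity threshold in (0.5, 1].
#' @param k k-mer size for diagonal seeding.
#' @param min_cover minimum aligned fraction of the shorter sequence.
#' @return list with `representatives` (ids), `assignment` (named vector:
#'   id -> representative id) and `clusters` (list of member ids per
#'   representative).
#' @export
cluster_redundant <- function(sequences, identity = 0.9, k = 8L,
                              min_cover = 0.7) {
  check_that(identity > 0.5 && identity <= 1,
             "identity must lie in (0.5, 1]")
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!length(sequences)) {
    return(list(representatives = character(0),
                assignment = stats::setNames(character(0), character(0)),
                clusters = list()))
  }
  check_that(!is.null(names(sequences)) && !anyDuplicated(names(sequences)),
             "sequences must have unique names")
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character(0)
  assignment <- stats::setNames(character(length(sequences)),
                                names(sequences))
  for (id in names(sequences)) {
    s <- sequences[[id]]
    placed_rep <- NA_character_
    for (rp in reps) {
      r <- sequences[[rp]]
      m <- ungapped_identity(s, r, k, min_cover)
      if (m[1] < identity || m[2] < min_cover) {
        m <- ungapped_identity(revcomp(s), r, k, min_cover)
      }
      if (m[1] >= identity && m[2] >= min_cover) {
        placed_rep <- rp
        break
      }
    }
    if (is.na(placed_rep)) {
      reps <- c(reps, id)
      assignment[id] <- id
    } else {
      assignment[id] <- placed_rep
    }
  }
  list(representatives = reps, assignment = assignment,
       clusters = split(names(assignment), assignment)[reps])
}

#' Mask and remove repeat-dominated sequences
#'
#' A stand-in for RepeatMasker-style filtering at desk scale: bases are
#' masked when they sit in an exact tandem repeat (unit sizes 1-6, at least
#' three copies) or in a low-complexity window (Shannon entropy of the base
#' composition below `entropy_threshold` bits over `entropy_window` bases).
#' A sequence is removed when more than `max_masked_fraction` of its length
#' is masked.
#'
#' @param sequences named character vector or DNAStringSet.
#' @param max_masked_fraction removal cutoff in (0, 1].
#' @param entropy_window,entropy_threshold low-complexity window size (bp)
#'   and entropy cutoff (bits; random DNA sits near 1.9).
#' @param max_unit largest tandem unit size checked.
#' @param min_copies minimum tandem copy number.
#' @param min_array smallest tandem array masked (bp); keeps incidental
#'   3-base homopolymers of random sequence unmasked.
#' @return list with `kept`, `removed` (ids) and `masked_fraction` (named
#'   numeric).
#' @export
repeat_filter <- function(sequences, max_masked_fraction = 0.5,
                          entropy_window = 20L, entropy_threshold = 1.2,
                          max_unit = 6L, min_copies = 3L,
                          min_array = 10L) {
  check_that(max_masked_fraction > 0 && max_masked_fraction <= 1,
             "max_masked_fraction must lie in (0, 1]")
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!length(sequences)) {
    return(list(kept = character(0), removed = character(0),
                masked_fraction = numeric(0)))
  }
  frac <- vapply(sequences, function(s) {
    n <- nchar(s)
    if (n == 0) return(0)
    x <- strsplit(s, "")[[1]]
    mask <- logical(n)
    ## exact tandem repeats
    for (u in seq_len(min(max_unit, n - 1L))) {
      eq <- x[(u + 1L):n] == x[seq_len(n - u)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      long <- which(r$values & r$lengths >= u * (min_copies - 1L) &
                      r$lengths + u >= min_array)
      for (j in long) {
        mask[starts[j]:(ends[j] + u)] <- TRUE
      }
    }
    ## low-complexity windows
    if (n >= entropy_window) {
      ws <- seq(1L, n - entropy_window + 1L, by = max(1L,
                                                      entropy_window %/% 4L))
      for (i in ws) {
        tab <- tabulate(factor(x[i:(i + entropy_window - 1L)],
                               levels = c("A", "C", "G", "T")), nbins = 4L)
        p <- tab[tab > 0] / entropy_window
        if (-sum(p * log2(p)) < entropy_threshold) {
          mask[i:(i + entropy_window - 1L)] <- TRUE
        }
      }
    }
    mean(mask)
  }, numeric(1))
  removed <- names(sequences)[frac > max_masked_fraction]
  list(kept = setdiff(names(sequences), removed), removed = removed,
       masked_fraction = frac)
}

## One model per transcribed locus: same-strand overlapping calls are
## grouped into single-linkage components, and each component keeps its
## best-supported model — highest RNA read count, then highest coverage
## fraction, then longest, then smallest id. A six-frame scan emits several
## frame-shifted ORFs over one transcript; a hint-based gene predictor (the
## stage the scanner stands in for) reports one model there, and the
## maximal-support model is the one whose CDS best matches the transcript.
collapse_overlapping_calls <- function(kept, support) {
  if (length(kept) < 2) return(character(0))
  comp_ranges <- GenomicRanges::reduce(kept, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(kept, comp_ranges,
                                    ignore.strand = FALSE)
  comp <- integer(length(kept))
  comp[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  ids <- kept$ID
  rna_max <- if (ncol(support$rna_count)) {
    apply(support$rna_count[ids, , drop = FALSE], 1L, max)
  } else rep(0, length(ids))
  cov_max <- if (ncol(support$rna_covfrac)) {
    apply(support$rna_covfrac[ids, , drop = FALSE], 1L, max)
  } else rep(0, length(ids))
  drop <- character(0)
  for (cp in unique(comp[duplicated(comp)])) {
    sel <- which(comp == cp)
    o <- order(-rna_max[sel], -cov_max[sel],
               -GenomicRanges::width(kept)[sel], ids[sel])
    drop <- c(drop, ids[sel[o[-1]]])
  }
  drop
}

#' Apply redundancy clustering and repeat masking to a call set
#'
#' Three deterministic reductions on the union of high and low calls:
#' same-strand genomically overlapping calls are collapsed to the longest
#' call per locus; the survivors are clustered by sequence identity
#' (longest first) and cluster members other than the representative
#' rejected as `redundant`; repeat-dominated representatives are rejected
#' as `repeat`. Classes are retained from the classification step, so the
#' final high and low sets stay mutually exclusive.
#'
#' @param calls a `TgloCallSet`.
#' @param genome the germline genome the calls live on.
#' @param identity clustering identity (see [cluster_redundant()]).
#' @param max_masked_fraction see [repeat_filter()].
#' @return the filtered `TgloCallSet`.
#' @export
apply_redundancy_filters <- function(calls, genome, identity = 0.9,
                                     max_masked_fraction = 0.5) {
  stopifnot(inherits(calls, "TgloCallSet"))
  kept <- c(calls$high, calls$low)
  if (!length(kept)) return(calls)
  stacked <- collapse_overlapping_calls(kept, calls$support)
  kept <- kept[!(kept$ID %in% stacked)]
  seqs <- orf_sequences(genome, kept)
  cl <- cluster_redundant(seqs, identity = identity)
  redundant <- c(stacked, setdiff(names(seqs), cl$representatives))
  rf <- repeat_filter(seqs[cl$representatives],
                      max_masked_fraction = max_masked_fraction)
  drop_reason <- c(stats::setNames(rep("redundant", length(redundant)),
                                   redundant),
                   stats::setNames(rep("repeat", length(rf$removed)),
                                   rf$removed))
  move <- function(gr) {
    hit <- gr$ID %in% names(drop_reason)
    dropped <- gr[hit]
    if (length(dropped)) dropped$reason <- drop_reason[dropped$ID]
    list(keep = gr[!hit], dropped = dropped)
  }
  hi <- move(calls$high); lo <- move(calls$low)
  rej <- calls$rejected
  extra <- c(hi$dropped, lo$dropped)
  if (length(extra)) {
    ## align mcols before concatenating
    if (!length(rej)) {
      rej <- extra
    } else {
      rej <- c(rej, extra[, names(S4Vectors::mcols(rej))])
    }
  }
  structure(list(high = hi$keep, low = lo$keep, rejected = rej,
                 calibration = calls$calibration, support = calls$support),
            class = "TgloCallSet")
}

#' Fraction of gene models containing introns
#'
#' The number of multi-exon models over the number of models. Computed
#' only over models that carry exon structure (`n_exons`), i.e. models
#' imported from a gene-prediction GFF3; internally scanned ORFs are
#' single-exon by construction.
#'
#' @param x a GRanges with an `n_exons` (or logical `has_intron`) column, a
#'   `CandidateOrfSet`, or a `TgloCallSet` (uses high + low).
#' @return fraction in `[0, 1]`.
#' @export
intron_fraction <- function(x) {
  if (inherits(x, "TgloCallSet")) x <- c(x$high, x$low)
  if (inherits(x, "CandidateOrfSet")) x <- x$orfs
  check_that(length(x) > 0, "empty model set")
  if (!is.null(x$n_exons)) return(mean(x$n_exons >= 2L))
  if (!is.null(x$has_intron)) return(mean(x$has_intron))
  stop("models carry no exon structure", call. = FALSE)
}

#' Evaluate a call set against the planted truth
#'
#' A call matches a planted ORF when they overlap on the same strand by at
#' least half of the planted interval. Precision is the fraction of calls
#' matching a planted TGLO of the call's class; recall the fraction of
#' planted TGLOs recovered in the right class; `overall_*` pools both
#' classes against high + low truth. False-positive counts are reported by
#' planted class (silent ORFs, MAC genes, or no planted feature).
#'
#' @param calls a `TgloCallSet`.
#' @param truth a `TruthSet`.
#' @return list of precision/recall values and false-positive counts.
#' @export
evaluate_calls <- function(calls, truth) {
  planted <- truth$orfs
  pg <- GenomicRanges::GRanges(planted$contig,
                               IRanges::IRanges(planted$start, planted$end),
                               strand = planted$strand)
  pg$ID <- planted$ID
  pg$class <- planted$class
  match_ids <- function(callgr) {
    if (!length(callgr)) return(character(0))
    ov <- GenomicRanges::findOverlaps(callgr, pg, ignore.strand = FALSE)
    if (!length(ov)) return(rep(NA_character_, length(callgr)))
    w <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(callgr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(pg)[S4Vectors::subjectHits(ov)]))
    frac <- w / GenomicRanges::width(pg)[S4Vectors::subjectHits(ov)]
    ok <- frac >= 0.5
    out <- rep(NA_character_, length(callgr))
    hit <- S4Vectors::queryHits(ov)[ok]
    out[hit] <- pg$ID[S4Vectors::subjectHits(ov)[ok]]
    out
  }
  eval_class <- function(callgr, truth_ids) {
    m <- match_ids(callgr)
    tp_ids <- intersect(m, truth_ids)
    precision <- if (!length(callgr)) NA_real_ else
      mean(!is.na(m) & m %in% truth_ids)
    recall <- if (!length(truth_ids)) NA_real_ else
      length(tp_ids) / length(truth_ids)
    list(precision = precision, recall = recall, matched = m)
  }
  hi <- eval_class(calls$high, truth$tglo_ids_high)
  lo <- eval_class(calls$low, truth$tglo_ids_low)
  both_gr <- c(calls$high, calls$low)
  all_true <- c(truth$tglo_ids_high, truth$tglo_ids_low)
  ov <- eval_class(both_gr, all_true)
  m_all <- ov$matched
  cls_all <- pg$class[match(m_all, pg$ID)]
  list(high_precision = hi$precision, high_recall = hi$recall,
       low_precision = lo$precision, low_recall = lo$recall,
       overall_precision = ov$precision, overall_recall = ov$recall,
       n_false_silent = sum(cls_all %in% "silent_orf", na.rm = TRUE),
       n_false_mac = sum(cls_all %in% "mac_gene", na.rm = TRUE),
       n_false_novel = sum(is.na(m_all)))
}

#' Write a call table as TSV
#'
#' One row per candidate with class, rejection reason and per-library
#' support.
#'
#' @param calls a `TgloCallSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  sup <- calls$support
  rows <- function(gr, cls, reason = NA_character_) {
    if (!length(gr)) return(NULL)
    data.frame(orf_id = gr$ID, class = cls,
               contig = as.character(GenomeInfoDb::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               reason = if (is.null(gr$reason)) reason else gr$reason,
               stringsAsFactors = FALSE)
  }
  df <- rbind(rows(calls$high, "high"), rows(calls$low, "low"),
              rows(calls$rejected, "rejected"))
  idx <- match(df$orf_id, rownames(sup$rna_count))
  if (ncol(sup$rna_count)) {
    df$rna_reads_max <- apply(sup$rna_count, 1L, max)[idx]
    df$rna_cov_max <- round(apply(sup$rna_covfrac, 1L, max)[idx], 4)
  }
  if (ncol(sup$dna_count)) {
    df$dna_reads_max <- apply(sup$dna_count, 1L, max)[idx]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
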