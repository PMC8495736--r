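## Per-feature read counting and per-base depth.

#' Count reads per feature and compute per-base depth
#'
#' A read is counted for a feature if its alignment overlaps the feature by
#' at least one base (`mode = "any"`, the featureCounts-like default) or only
#' if it lies entirely inside the feature (`mode = "contained"`, the strict
#' variant for germline-limited tests). The per-base depth of each contig
#' sums to the total aligned bases on that contig.
#'
#' @param alignments GRanges of read alignments (e.g. [map_reads_exact()]).
#' @param features GRanges of features; metadata column `ID` names the
#'   returned counts (falling back to positional names).
#' @param mode `"any"` or `"contained"`.
#' @param same_strand count only alignments on the feature's strand
#'   (default `FALSE`; used for stranded RNA support).
#' @return list with `counts` (named integer vector, one per feature) and
#'   `depth` (RleList of per-base coverage per contig).
#' @export
coverage_from_alignments <- function(alignments, features,
                                     mode = c("any", "contained"),
                                     same_strand = FALSE) {
  mode <- match.arg(mode)
  check_that(methods::is(alignments, "GRanges") &&
               methods::is(features, "GRanges"),
             "alignments and features must be GRanges")
  sl <- GenomeInfoDb::seqlengths(alignments)
  if (length(features)) {
    unknown <- !(as.character(GenomeInfoDb::seqnames(features)) %in%
                   GenomeInfoDb::seqlevels(alignments))
    check_that(!any(unknown), sprintf(
      "feature(s) on unknown contig: %s",
      paste(unique(as.character(
        GenomeInfoDb::seqnames(features)[unknown])), collapse = ", ")))
  }
  ignore_strand <- !isTRUE(same_strand)
  if (mode == "any") {
    counts <- GenomicRanges::countOverlaps(features, alignments,
                                           ignore.strand = ignore_strand)
  } else {
    ov <- GenomicRanges::findOverlaps(alignments, features, type = "within",
                                      ignore.strand = ignore_strand)
    counts <- tabulate(S4Vectors::subjectHits(ov), nbins = length(features))
  }
  ids <- features$ID %||% as.character(seq_along(features))
  names(counts) <- ids
  depth <- GenomicRanges::coverage(alignments)
  list(counts = as.integer(counts) |> stats::setNames(ids), depth = depth)
}

#' Fraction of feature bases covered at depth >= 1
#'
#' @param depth RleList of per-base coverage (see
#'   [coverage_from_alignments()]).
#' @param features GRanges.
#' @return numeric vector in `[0, 1]`, one value per feature.
#' @export
covered_fraction <- function(depth, features) {
  if (!length(features)) return(numeric(0))
  out <- numeric(length(features))
  ctgs <- as.character(GenomeInfoDb::seqnames(features))
  for (ctg in unique(ctgs)) {
    sel <- which(ctgs == ctg)
    if (!ctg %in% names(depth)) {
      out[sel] <- 0
      next
    }
    mask <- S4Vectors::Rle(as.integer(depth[[ctg]] > 0))
    v <- IRanges::Views(mask, IRanges::ranges(features[sel]))
    out[sel] <- IRanges::viewSums(v) / GenomicRanges::width(features[sel])
  }
  stats::setNames(out, features$ID %||% as.character(seq_along(features)))
}
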