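## Count matrices, normalization, RPKM, enrichment statistics and strain
## retention calls.

#' Build a per-feature count matrix over libraries
#'
#' @param features GRanges with an `ID` column.
#' @param alignments named list of alignment GRanges (one per library).
#' @param mode overlap counting mode (see [coverage_from_alignments()]).
#' @param meta optional data.frame of library metadata (kind, timepoint,
#'   strain); row order must follow `names(alignments)`.
#' @return a `CountMatrix`: integer matrix `counts` (features x libraries),
#'   `feature_len` (bp) and `meta`.
#' @export
build_count_matrix <- function(features, alignments, mode = "any",
                               meta = NULL) {
  check_that(length(alignments) > 0 && !is.null(names(alignments)),
             "alignments must be a named list")
  counts <- vapply(alignments, function(a) {
    coverage_from_alignments(a, features, mode = mode)$counts
  }, integer(length(features)))
  counts <- matrix(counts, nrow = length(features),
                   dimnames = list(features$ID, names(alignments)))
  structure(list(counts = counts,
                 feature_len = stats::setNames(
                   GenomicRanges::width(features), features$ID),
                 meta = meta),
            class = "CountMatrix")
}

#' Median-of-ratios size factors
#'
#' The estimator DESeq-style normalization defines: the reference for each
#' feature is the geometric mean of its counts across libraries, computed
#' over features with nonzero counts in every library; each library's size
#' factor is the median of its count/reference ratios. Size factors are
#' scale-equivariant: doubling a library's counts doubles its factor.
#'
#' @param counts integer matrix (features x libraries) or `CountMatrix`.
#' @param pseudocount added to all counts before estimation (default 0;
#'   use a positive value when no feature is nonzero in all libraries).
#' @return positive numeric vector, one factor per library.
#' @export
size_factors <- function(counts, pseudocount = 0) {
  if (inherits(counts, "CountMatrix")) counts <- counts$counts
  m <- counts + pseudocount
  all_nonzero <- rowSums(m > 0) == ncol(m)
  if (!any(all_nonzero)) {
    stop("no feature has nonzero counts in all libraries; ",
         "re-run with a positive 'pseudocount'", call. = FALSE)
  }
  logref <- rowMeans(log(m[all_nonzero, , drop = FALSE]))
  apply(m[all_nonzero, , drop = FALSE], 2L, function(col) {
    stats::median(exp(log(col) - logref))
  })
}

#' Log2-normalized matrix
#'
#' `log2(count / factor + pseudocount)`, elementwise.
#'
#' @param counts matrix or `CountMatrix`.
#' @param factors per-library size factors (> 0).
#' @param pseudocount stabilizing offset (default 1).
#' @return numeric matrix.
#' @export
log2_matrix <- function(counts, factors = NULL, pseudocount = 1) {
  if (inherits(counts, "CountMatrix")) counts <- counts$counts
  if (is.null(factors)) factors <- size_factors(counts)
  check_that(all(factors > 0), "size factors must be positive")
  log2(sweep(counts, 2L, factors, "/") + pseudocount)
}

#' Hierarchically cluster matrix rows
#'
#' Agglomerative clustering (Euclidean distance, complete linkage by
#' default) as used for expression/copy-number heatmaps; returns the leaf
#' order so the clustered matrix can be written or drawn.
#'
#' @param mat numeric matrix with >= 2 rows and rownames.
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list with `order` (rownames in leaf order), `hclust` (the tree)
#'   and `matrix` (rows reordered).
#' @export
cluster_rows <- function(mat, metric = "euclidean", linkage = "complete") {
  check_that(is.matrix(mat) && nrow(mat) >= 2, "need a matrix with >= 2 rows")
  check_that(!anyNA(mat), "matrix contains NA/NaN rows")
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat, method = metric), method = linkage)
  ord <- rownames(mat)[hc$order]
  list(order = ord, hclust = hc, matrix = mat[ord, , drop = FALSE])
}

#' Reads per kilobase per million mapped reads
#'
#' @param count reads on the feature.
#' @param feature_len_bp feature length (>= 1).
#' @param library_total total mapped reads in the library (>= 1).
#' @return RPKM value(s); vectorized.
#' @export
rpkm <- function(count, feature_len_bp, library_total) {
  check_that(all(feature_len_bp >= 1), "feature length must be >= 1")
  check_that(all(library_total >= 1), "library total must be >= 1")
  count / (feature_len_bp / 1e3) / (library_total / 1e6)
}

## Asymptotic two-sided Kolmogorov distribution tail:
## P(sqrt(n) D > x) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 x^2)
kolmogorov_tail <- function(x) {
  if (x <= 0) return(1)
  j <- seq_len(101L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * x^2))
  min(1, max(p, 0))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the maximum absolute difference between the two empirical CDFs;
#' the two-sided p-value uses the asymptotic Kolmogorov distribution at
#' `D * sqrt(n_a n_b / (n_a + n_b))`. For small samples
#' (`method = "exact"`, both n <= 10) the p-value is the exact permutation
#' tail: the fraction of all splits whose D is at least the observed one.
#'
#' @param a,b numeric samples (nonempty).
#' @param method `"asymptotic"` (default) or `"exact"`.
#' @return list with `D`, `p`, `n_a`, `n_b`, `method`.
#' @export
ks_two_sample <- function(a, b, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  check_that(length(a) >= 1 && length(b) >= 1, "empty sample")
  ks_stat <- function(a, b) {
    all_v <- sort(unique(c(a, b)))
    Fa <- vapply(all_v, function(v) mean(a <= v), numeric(1))
    Fb <- vapply(all_v, function(v) mean(b <= v), numeric(1))
    max(abs(Fa - Fb))
  }
  D <- ks_stat(a, b)
  n_a <- length(a); n_b <- length(b)
  if (method == "exact") {
    check_that(n_a <= 10 && n_b <= 10,
               "exact permutation mode supports n <= 10 per sample")
    pool <- c(a, b)
    splits <- utils::combn(n_a + n_b, n_a)
    d_perm <- apply(splits, 2L, function(idx) ks_stat(pool[idx],
                                                      pool[-idx]))
    p <- mean(d_perm >= D - 1e-12)
  } else {
    p <- kolmogorov_tail(D * sqrt(n_a * n_b / (n_a + n_b)))
    if (p <= 0) p <- .Machine$double.xmin   # keep p in (0, 1]
  }
  list(D = D, p = p, n_a = n_a, n_b = n_b, method = method)
}

#' Compare read enrichment between two feature classes
#'
#' Computes per-feature RPKM in each class from one alignment set (e.g.
#' 27-nt small RNAs, or template RNAs) and compares the two RPKM
#' distributions with the two-sample KS test, reporting which class has
#' the greater median — the analysis behind "piRNAs map to MDSs more
#' heavily than TGLOs".
#'
#' @param alignments GRanges of mapped reads.
#' @param features_a,features_b GRanges of the two classes (e.g. MDSs vs
#'   TGLO calls); both nonempty.
#' @param name_a,name_b labels for reporting.
#' @param library_total total mapped reads (default: distinct read ids in
#'   `alignments`).
#' @param mode overlap counting mode.
#' @param ks_method see [ks_two_sample()].
#' @return an `EnrichmentResult`: `D`, `p`, per-class RPKM vectors,
#'   medians, sample sizes and the label of the enriched class.
#' @export
compare_feature_classes <- function(alignments, features_a, features_b,
                                    name_a = "A", name_b = "B",
                                    library_total = NULL, mode = "any",
                                    ks_method = "asymptotic") {
  check_that(length(features_a) > 0 && length(features_b) > 0,
             "both feature classes must be nonempty")
  if (is.null(library_total)) {
    library_total <- if (!is.null(alignments$read_id))
      length(unique(alignments$read_id)) else length(alignments)
    library_total <- max(1L, library_total)
  }
  ca <- coverage_from_alignments(alignments, features_a, mode = mode)$counts
  cb <- coverage_from_alignments(alignments, features_b, mode = mode)$counts
  ra <- rpkm(ca, GenomicRanges::width(features_a), library_total)
  rb <- rpkm(cb, GenomicRanges::width(features_b), library_total)
  ks <- ks_two_sample(ra, rb, method = ks_method)
  structure(list(D = ks$D, p = ks$p, n_a = length(ra), n_b = length(rb),
                 rpkm_a = ra, rpkm_b = rb,
                 median_a = stats::median(ra), median_b = stats::median(rb),
                 name_a = name_a, name_b = name_b,
                 higher = if (stats::median(ra) >= stats::median(rb))
                   name_a else name_b),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: %s (n=%d, median RPKM %.3g) vs %s (n=%d, median RPKM %.3g)\n",
    x$name_a, x$n_a, x$median_a, x$name_b, x$n_b, x$median_b))
  cat(sprintf("  KS D = %.4f, p = %.3g; higher coverage: %s\n",
              x$D, x$p, x$higher))
  invisible(x)
}

#' Classify somatic retention per strain
#'
#' A locus is `somatic` when its whole-cell DNA count exceeds the strain's
#' calibrated threshold in every strain, `germline_limited` when in none,
#' and `strain_specific_somatic` otherwise (listing the retaining
#' strains) — the pattern of a nanochromosome kept in only one parental
#' strain.
#'
#' @param dna_counts matrix (loci x strains) of whole-cell DNA read counts.
#' @param thresholds named per-strain thresholds (a
#'   `ThresholdCalibration`'s `dna_threshold`, or a bare named vector).
#' @return data.frame with `locus`, `call`, `retained_in`.
#' @export
classify_strain_retention <- function(dna_counts, thresholds) {
  if (inherits(thresholds, "ThresholdCalibration")) {
    thresholds <- thresholds$dna_threshold
  }
  check_that(is.matrix(dna_counts) && ncol(dna_counts) >= 2,
             "need counts for at least 2 strains")
  missing <- setdiff(colnames(dna_counts), names(thresholds))
  check_that(length(missing) == 0,
             sprintf("missing threshold for strain(s): %s",
                     paste(missing, collapse = ", ")))
  thr <- thresholds[colnames(dna_counts)]
  present <- sweep(dna_counts, 2L, unlist(thr), ">")
  call <- ifelse(rowSums(present) == ncol(present), "somatic",
                 ifelse(rowSums(present) == 0, "germline_limited",
                        "strain_specific_somatic"))
  retained <- apply(present, 1L, function(r) {
    paste(colnames(dna_counts)[r], collapse = ",")
  })
  data.frame(locus = rownames(dna_counts) %||%
               as.character(seq_len(nrow(dna_counts))),
             call = unname(call), retained_in = unname(retained),
             stringsAsFactors = FALSE)
}

#' Write a (clustered) matrix as TSV
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @param row_order optional row order (e.g. from [cluster_rows()]).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, row_order = NULL) {
  if (!is.null(row_order)) mat <- mat[row_order, , drop = FALSE]
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
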