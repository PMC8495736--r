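## Candidate ORF prediction and RNA/DNA support statistics.
##
## The ciliate nuclear genetic code (NCBI translation table 6) reassigns
## TAA/TAG to glutamine, leaving TGA as the sole stop codon — an Oxytricha
## ORF scan under the standard code would truncate most genes. The scanner
## reports maximal start-to-stop ORFs in all six frames and is the
## desk-scale stand-in for a trained gene predictor; externally produced
## gene models can be supplied as GFF3 instead (see
## [candidate_orfs_from_gff3()]).

GENETIC_CODES <- list(
  ciliate = c("TGA"),                  # table 6: TAA/TAG read as Gln
  standard = c("TAA", "TAG", "TGA"))

#' Find ORFs in all six frames
#'
#' Maximal start-to-stop ORFs: for each stop codon, the ORF beginning at the
#' first ATG after the previous in-frame stop (the longest-ORF-per-stop
#' rule; `longest_only = FALSE` reports every ATG sharing the stop).
#' Reported intervals include the stop codon, so widths are multiples of 3.
#'
#' @param genome [annotated_genome()] or named [Biostrings::DNAStringSet].
#' @param min_aa minimum protein length in amino acids (stop excluded).
#'   The default 45 aa covers the shortest coding class the simulator
#'   plants.
#' @param code `"ciliate"` (translation table 6, default) or `"standard"`.
#' @param longest_only reduce nested ORFs sharing a stop to the longest.
#' @return [GenomicRanges::GRanges] with columns `ID` and `type = "ORF"`,
#'   deterministically ordered by (contig, start, end, strand).
#' @export
find_orfs <- function(genome, min_aa = 45L, code = c("ciliate", "standard"),
                      longest_only = TRUE) {
  code <- match.arg(code)
  stops_set <- GENETIC_CODES[[code]]
  if (inherits(genome, "AnnotatedGenome")) genome <- genome$seq
  check_that(methods::is(genome, "DNAStringSet") && !is.null(names(genome)),
             "genome must be a named DNAStringSet or AnnotatedGenome")
  check_that(min_aa >= 1, "min_aa must be >= 1")
  rows <- list()
  for (ctg in names(genome)) {
    L <- Biostrings::width(genome[ctg])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") as.character(genome[[ctg]]) else
        revcomp(as.character(genome[[ctg]]))
      for (f in 0:2) {
        n_codons <- (L - f) %/% 3L
        if (n_codons < min_aa + 1L) next
        starts <- f + 1L + 3L * (seq_len(n_codons) - 1L)
        codons <- substring(s, starts, starts + 2L)
        stop_idx <- which(codons %in% stops_set)
        if (!length(stop_idx)) next
        atg_idx <- which(codons == "ATG")
        atg_idx <- atg_idx[atg_idx < max(stop_idx)]
        if (!length(atg_idx)) next
        seg <- findInterval(atg_idx, stop_idx)        # stops before each ATG
        keep <- if (longest_only) !duplicated(seg) else rep(TRUE,
                                                            length(seg))
        a <- atg_idx[keep]
        nxt <- stop_idx[seg[keep] + 1L]
        ok <- !is.na(nxt) & (nxt - a) >= min_aa
        a <- a[ok]; nxt <- nxt[ok]
        if (!length(a)) next
        sb <- f + 1L + 3L * (a - 1L)                   # 1-based on s
        eb <- f + 3L * nxt
        if (strand == "+") {
          gs <- sb; ge <- eb
        } else {
          gs <- L - eb + 1L; ge <- L - sb + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = gs, end = ge, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges(seqlengths = stats::setNames(
      Biostrings::width(genome), names(genome)))
    gr$ID <- character(0); gr$type <- character(0)
    return(gr)
  }
  df <- do.call(rbind, rows)
  ord <- order(factor(df$contig, levels = names(genome)), df$start, df$end,
               df$strand)
  df <- df[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$contig, levels = names(genome)),
    ranges = IRanges::IRanges(df$start, df$end), strand = df$strand,
    seqlengths = stats::setNames(Biostrings::width(genome), names(genome)))
  gr$ID <- sprintf("orf_%06d", seq_along(gr))
  gr$type <- "ORF"
  gr$has_intron <- FALSE
  gr$n_exons <- 1L
  gr
}

#' Build candidate ORFs from externally supplied gene models
#'
#' Accepts a GFF3-derived GRanges (e.g. [read_gff3()]) carrying `CDS`/`exon`
#' rows grouped by a `Parent` (or `ID`) attribute, so output from an external
#' gene predictor can be dropped into the screen in place of [find_orfs()].
#' Multi-exon models keep their exon count and set `has_intron`.
#'
#' @param features GRanges of gene-model rows.
#' @return GRanges of candidate intervals (model spans) with `ID`,
#'   `has_intron` and `n_exons`.
#' @export
candidate_orfs_from_gff3 <- function(features) {
  sel <- features[features$type %in% c("CDS", "exon")]
  check_that(length(sel) > 0, "no CDS/exon rows in the supplied models")
  parent <- sel$Parent %||% sel$ID
  if (methods::is(parent, "List")) {
    parent <- vapply(as.list(parent), function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, character(1))
  }
  parent <- as.character(parent)
  if (anyNA(parent)) {
    stop("gene-model rows need a Parent or ID attribute", call. = FALSE)
  }
  df <- data.frame(parent = parent,
                   contig = as.character(GenomeInfoDb::seqnames(sel)),
                   start = GenomicRanges::start(sel),
                   end = GenomicRanges::end(sel),
                   strand = as.character(GenomicRanges::strand(sel)),
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$parent), function(g) {
    check_that(length(unique(g$contig)) == 1 &&
                 length(unique(g$strand)) == 1,
               sprintf("model %s spans contigs or strands", g$parent[1]))
    data.frame(parent = g$parent[1], contig = g$contig[1],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1], n_exons = nrow(g),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$contig, agg$start, agg$end), , drop = FALSE]
  gr <- GenomicRanges::GRanges(agg$contig,
                               IRanges::IRanges(agg$start, agg$end),
                               strand = agg$strand)
  gr$ID <- agg$parent
  gr$type <- "ORF"
  gr$n_exons <- as.integer(agg$n_exons)
  gr$has_intron <- gr$n_exons >= 2L
  gr
}

#' Attach per-library RNA/DNA support statistics to candidate ORFs
#'
#' For each RNA library: the any-overlap read count and the fraction of CDS
#' bases with depth >= 1 (from that library alone). For each DNA library:
#' the read count. With `stranded = TRUE` (default) RNA reads support a
#' candidate only on the candidate's strand, matching a stranded RNA-seq
#' protocol; DNA counting is always unstranded.
#'
#' @param orfs GRanges of candidates ([find_orfs()] /
#'   [candidate_orfs_from_gff3()]).
#' @param rna_alignments named list of alignment GRanges, one per RNA
#'   library.
#' @param dna_alignments named list of alignment GRanges, one per DNA
#'   library.
#' @param stranded count RNA support strand-specifically.
#' @return a `CandidateOrfSet`: list with `orfs` (the GRanges), and
#'   matrices `rna_count`, `rna_covfrac`, `dna_count` (candidates x
#'   libraries; zero-column when no library of that role is given).
#' @export
attach_support <- function(orfs, rna_alignments = list(),
                           dna_alignments = list(), stranded = TRUE) {
  check_that(methods::is(orfs, "GRanges"), "'orfs' must be a GRanges")
  rna_ids <- names(rna_alignments) %||% character(0)
  dna_ids <- names(dna_alignments) %||% character(0)
  all_ids <- c(rna_ids, dna_ids)
  check_that(!anyDuplicated(all_ids),
             sprintf("library id collision: %s",
                     paste(unique(all_ids[duplicated(all_ids)]),
                           collapse = ", ")))
  n <- length(orfs)
  ids <- orfs$ID %||% as.character(seq_len(n))
  rna_count <- matrix(0L, n, length(rna_ids), dimnames = list(ids, rna_ids))
  rna_cov <- matrix(0, n, length(rna_ids), dimnames = list(ids, rna_ids))
  dna_count <- matrix(0L, n, length(dna_ids), dimnames = list(ids, dna_ids))
  for (lib in rna_ids) {
    aln <- rna_alignments[[lib]]
    cf <- coverage_from_alignments(aln, orfs, mode = "any",
                                   same_strand = stranded)
    rna_count[, lib] <- cf$counts
    if (stranded) {
      st <- as.character(GenomicRanges::strand(aln))
      cov_p <- GenomicRanges::coverage(aln[st == "+"])
      cov_m <- GenomicRanges::coverage(aln[st == "-"])
      o_st <- as.character(GenomicRanges::strand(orfs))
      out <- numeric(n)
      plus <- o_st != "-"
      if (any(plus)) out[plus] <- covered_fraction(cov_p, orfs[plus])
      if (any(!plus)) out[!plus] <- covered_fraction(cov_m, orfs[!plus])
      rna_cov[, lib] <- out
    } else {
      rna_cov[, lib] <- covered_fraction(cf$depth, orfs)
    }
  }
  for (lib in dna_ids) {
    cf <- coverage_from_alignments(dna_alignments[[lib]], orfs, mode = "any",
                                   same_strand = FALSE)
    dna_count[, lib] <- cf$counts
  }
  structure(list(orfs = orfs, rna_count = rna_count, rna_covfrac = rna_cov,
                 dna_count = dna_count),
            class = "CandidateOrfSet")
}

#' @export
print.CandidateOrfSet <- function(x, ...) {
  cat(sprintf("CandidateOrfSet: %d candidates, %d RNA + %d DNA libraries\n",
              length(x$orfs), ncol(x$rna_count), ncol(x$dna_count)))
  invisible(x)
}
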