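## Exact read mapping.
##
## Reads are placed at every position where they match the reference or its
## reverse complement exactly (ungapped). This stands in for a short-read
## aligner at desk scale: with error-free reads over unique sequence it
## recovers the same placements, and it keeps the whole pipeline dependency
## free. Matching uses Biostrings' Aho-Corasick dictionaries, so mapping a
## library is a handful of passes over the genome.

#' Map reads to a reference by exact matching
#'
#' Every exact occurrence of a read (either orientation) in the reference is
#' reported. With `require_unique = TRUE` reads matching more than one
#' position genome-wide are dropped and tallied — the conservative default
#' for DNA-presence screening, where a repeat-borne match must not count as
#' somatic signal.
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param reference named [Biostrings::DNAStringSet] or [annotated_genome()].
#' @param require_unique drop multi-mapping reads (default `FALSE`).
#' @return [GenomicRanges::GRanges] with metadata column `read_id`, sorted by
#'   (contig, start, read_id). Attribute `mapping_stats` carries
#'   `n_reads`, `n_unmapped`, `n_multi` (reads with > 1 placement) and
#'   `multi_dropped`.
#' @export
map_reads_exact <- function(reads, reference, require_unique = FALSE) {
  if (inherits(reference, "AnnotatedGenome")) reference <- reference$seq
  check_that(methods::is(reference, "DNAStringSet") && length(reference) > 0,
             "empty or invalid reference")
  if (!methods::is(reads, "DNAStringSet")) {
    reads <- Biostrings::DNAStringSet(reads)
  }
  check_that(!is.null(names(reads)) && !anyDuplicated(names(reads)),
             "reads must have unique ids")
  contig_len <- stats::setNames(Biostrings::width(reference), names(reference))

  ## PDict needs a constant width and a clean ACGT alphabet.
  clean <- !grepl("[^ACGT]", as.character(reads))
  hits <- list()
  for (w in unique(Biostrings::width(reads)[clean])) {
    sel <- clean & Biostrings::width(reads) == w
    sub <- reads[sel]
    pd <- Biostrings::PDict(sub)
    for (ctg in names(reference)) {
      subject <- reference[[ctg]]
      L <- contig_len[[ctg]]
      if (L < w) next
      m <- Biostrings::matchPDict(pd, subject)
      n <- S4Vectors::elementNROWS(m)
      if (sum(n) > 0) {
        ir <- unlist(m, use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          read_id = rep(names(sub), n), contig = ctg,
          start = IRanges::start(ir), width = w, strand = "+",
          stringsAsFactors = FALSE)
      }
      m <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subject))
      n <- S4Vectors::elementNROWS(m)
      if (sum(n) > 0) {
        ir <- unlist(m, use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          read_id = rep(names(sub), n), contig = ctg,
          start = L - IRanges::end(ir) + 1L, width = w, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }

  df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(read_id = character(), contig = character(),
               start = integer(), width = integer(), strand = character(),
               stringsAsFactors = FALSE)
  placements <- table(df$read_id)
  multi_ids <- names(placements)[placements > 1L]
  n_multi <- length(multi_ids)
  if (require_unique && n_multi > 0) {
    df <- df[!(df$read_id %in% multi_ids), , drop = FALSE]
  }
  n_unmapped <- length(reads) - length(placements)

  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$contig, levels = names(reference)),
    ranges = IRanges::IRanges(start = df$start, width = df$width),
    strand = df$strand,
    read_id = df$read_id,
    seqlengths = contig_len)
  ord <- order(as.integer(GenomeInfoDb::seqnames(gr)),
               GenomicRanges::start(gr), gr$read_id)
  gr <- gr[ord]
  attr(gr, "mapping_stats") <- list(
    n_reads = length(reads), n_unmapped = n_unmapped, n_multi = n_multi,
    multi_dropped = isTRUE(require_unique))
  gr
}

#' Export ungapped alignments as SAM
#'
#' Minimal plain-text SAM (header plus one line per alignment, CIGAR
#' `<len>M`, MAPQ 255) for interoperability with samtools/IGV-style tooling.
#'
#' @param alignments GRanges from [map_reads_exact()].
#' @param reads the reads that were mapped (for the SEQ column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, path) {
  sl <- GenomeInfoDb::seqlengths(alignments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl), con)
  if (length(alignments)) {
    seqs <- as.character(reads[alignments$read_id])
    minus <- as.character(GenomicRanges::strand(alignments)) == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       alignments$read_id, ifelse(minus, 16L, 0L),
                       as.character(GenomeInfoDb::seqnames(alignments)),
                       GenomicRanges::start(alignments),
                       GenomicRanges::width(alignments), seqs), con)
  }
  invisible(path)
}
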