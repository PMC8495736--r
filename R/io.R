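## Sequence and annotation I/O.
##
## All coordinates inside the package follow the Bioconductor convention:
## GRanges/IRanges, 1-based, closed intervals. GFF3 shares that convention
## (identity map); BED (0-based half-open) is converted at the file boundary
## by rtracklayer. Sequences are held as Biostrings::DNAStringSet and are
## uppercased on import.

#' Construct an annotated genome
#'
#' Bundles a set of contig sequences with typed feature intervals (MDS, IES,
#' spacer, telomere, ORF). Features live on a [GenomicRanges::GRanges] whose
#' metadata columns carry at least `type` and `ID`; MDS features additionally
#' carry `locus` (precursor locus id), `mds_index` (order along the germline)
#' and `somatic_order` / `somatic_strand` (order and orientation in the
#' somatic product, which differ from the germline order at scrambled loci).
#'
#' @param seq named [Biostrings::DNAStringSet] of contigs.
#' @param features [GenomicRanges::GRanges] of typed features, possibly empty.
#' @return an object of class `AnnotatedGenome`.
#' @export
annotated_genome <- function(seq, features = GenomicRanges::GRanges()) {
  check_that(methods::is(seq, "DNAStringSet"), "'seq' must be a DNAStringSet")
  check_that(!is.null(names(seq)) && !anyDuplicated(names(seq)),
             "contigs must have unique names")
  check_that(methods::is(features, "GRanges"), "'features' must be a GRanges")
  if (length(features)) {
    check_that(all(as.character(GenomeInfoDb::seqnames(features)) %in%
                     names(seq)),
               "feature on unknown contig")
    lens <- stats::setNames(Biostrings::width(seq), names(seq))
    check_that(all(GenomicRanges::end(features) <=
                     lens[as.character(GenomeInfoDb::seqnames(features))]) &&
                 all(GenomicRanges::start(features) >= 1L),
               "feature outside contig bounds")
    check_that(!is.null(features$type) &&
                 all(nzchar(as.character(features$type))),
               "features must carry a nonempty 'type'")
  }
  GenomeInfoDb::seqlevels(features) <- names(seq)
  GenomeInfoDb::seqlengths(features) <- Biostrings::width(seq)
  structure(list(seq = seq, features = features), class = "AnnotatedGenome")
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat(sprintf("AnnotatedGenome: %d contig(s), %s bp total\n",
              length(x$seq), format(sum(Biostrings::width(x$seq)),
                                    big.mark = ",")))
  if (length(x$features)) {
    tab <- table(x$features$type)
    cat("features:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
  } else {
    cat("features: none\n")
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are uppercased; duplicate ids or non-IUPAC characters are
#' format errors. An empty file yields an empty set.
#'
#' @param path file path.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (file.exists(path) && file.size(path) == 0) {
    return(Biostrings::DNAStringSet())
  }
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("malformed FASTA: ",
                                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  s <- toupper(as.character(x))
  iupac <- setdiff(Biostrings::DNA_ALPHABET, c("-", "+", "."))
  bad <- grepl(sprintf("[^%s]", paste(iupac, collapse = "")), s)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(s)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named [Biostrings::DNAStringSet] or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  check_that(!is.null(names(sequences)), "sequences must be named")
  Biostrings::writeXStringSet(sequences, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' @param path file path.
#' @return named [Biostrings::DNAStringSet]; qualities are discarded.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write reads to FASTQ with constant dummy quality
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!methods::is(reads, "DNAStringSet")) {
    reads <- Biostrings::DNAStringSet(reads)
  }
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w) {
    strrep("I", w)
  }, character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read/write feature annotations
#'
#' `read_gff3()`/`read_bed()` return a [GenomicRanges::GRanges] in the
#' package-internal 1-based closed convention; `write_gff3()`/`write_bed()`
#' perform the reverse conversion. GFF3 coordinates map 1:1; BED's 0-based
#' half-open coordinates are shifted at the boundary. The GFF3 `type` column
#' holds the feature kind and attributes (`ID`, `locus`, `mds_index`,
#' `somatic_order`, ...) travel as GRanges metadata columns.
#'
#' @param path file path.
#' @param features [GenomicRanges::GRanges] to write.
#' @return a GRanges (readers) or `path` invisibly (writers).
#' @export
read_gff3 <- function(path) {
  gr <- GenomicRanges::GRanges(rtracklayer::import(path, format = "gff3"))
  if (!is.null(gr$type)) gr$type <- as.character(gr$type)
  gr
}

#' @rdname read_gff3
#' @export
write_gff3 <- function(features, path) {
  check_that(methods::is(features, "GRanges"), "'features' must be a GRanges")
  if (is.null(features$source)) features$source <- "tgloscreen"
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' @rdname read_gff3
#' @export
read_bed <- function(path) {
  GenomicRanges::GRanges(rtracklayer::import(path, format = "bed"))
}

#' @rdname read_gff3
#' @export
write_bed <- function(features, path) {
  check_that(methods::is(features, "GRanges"), "'features' must be a GRanges")
  rtracklayer::export(features, path, format = "bed")
  invisible(path)
}
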