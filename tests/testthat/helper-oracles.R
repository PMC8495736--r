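## Shared fixtures and independent oracles used across the suite. The
## oracles deliberately re-derive results by brute force (per-base masks,
## all-position scans, O(n*m) loops) so they share no code path with the
## implementation they check.

rc1 <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## small simulated genome for fast tests
small_sim <- function(seed = 5, ...) {
  simulate_mic_genome(genome_sim_config(
    n_precursor_loci = 6, n_contigs = 2, n_tglo_high = 3, n_tglo_low = 3,
    n_silent_germline_orfs = 3, n_mac_genes = 3,
    spacer_len = c(2500L, 5000L), seed = seed, ...))
}

## deterministic even tiling of a sequence with fixed-length reads,
## alternating strands, always covering both ends
tile_reads <- function(truth, read_len = 100L, depth = 20L) {
  L <- nchar(truth)
  stride <- max(1L, round(read_len / depth))
  starts <- unique(c(seq(1L, L - read_len + 1L, by = stride),
                     L - read_len + 1L))
  reads <- substring(truth, starts, starts + read_len - 1L)
  strand <- rep(c("+", "-"), length.out = length(reads))
  reads[strand == "-"] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads[strand == "-"])))
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("r%05d", seq_along(out))
  out
}

## brute-force all-position exact matcher (both strands), 1-based closed
naive_map <- function(read, contig) {
  hits <- list()
  L <- nchar(contig); w <- nchar(read)
  if (w > L) return(hits)
  for (i in seq_len(L - w + 1L)) {
    seg <- substr(contig, i, i + w - 1L)
    if (seg == read) hits[[length(hits) + 1L]] <- c(start = i, strand = 1L)
    if (seg == rc1(read)) hits[[length(hits) + 1L]] <- c(start = i,
                                                         strand = -1L)
  }
  hits
}

## O(n*m) per-feature overlap counter
naive_counts <- function(aln_start, aln_end, f_start, f_end,
                         contained = FALSE) {
  vapply(seq_along(f_start), function(j) {
    if (contained) {
      sum(aln_start >= f_start[j] & aln_end <= f_end[j])
    } else {
      sum(aln_start <= f_end[j] & aln_end >= f_start[j])
    }
  }, numeric(1))
}

## independent six-frame ORF scanner: plain loops, includes the stop codon
naive_orfs <- function(seq, min_aa, stops) {
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc1(seq)
    for (f in 0:2) {
      i <- f + 1L
      codons <- character(0)
      while (i + 2L <= L) {
        codons <- c(codons, substr(s, i, i + 2L))
        i <- i + 3L
      }
      prev_stop <- 0L
      j <- 1L
      while (j <= length(codons)) {
        if (codons[j] %in% stops) {
          ## first ATG after prev_stop
          seg <- (prev_stop + 1L):(j)
          atg <- seg[codons[seg] == "ATG"]
          atg <- atg[atg < j]
          if (length(atg) && (j - atg[1]) >= min_aa) {
            a <- atg[1]
            sb <- f + 1L + 3L * (a - 1L)
            eb <- f + 3L * j
            if (strand == "+") {
              out[[length(out) + 1L]] <- c(sb, eb, 1L)
            } else {
              out[[length(out) + 1L]] <- c(L - eb + 1L, L - sb + 1L, -1L)
            }
          }
          prev_stop <- j
        }
        j <- j + 1L
      }
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

## build a CandidateOrfSet by hand for rule-level tests
mk_support <- function(rna_reads, rna_cov, dna) {
  n <- length(rna_reads)
  sl <- c(ctg = 1000000L)
  orfs <- GenomicRanges::GRanges("ctg",
                                 IRanges::IRanges(seq(1, by = 1000,
                                                      length.out = n),
                                                  width = 300L),
                                 strand = "+", seqlengths = sl)
  orfs$ID <- sprintf("cand_%03d", seq_len(n))
  structure(list(
    orfs = orfs,
    rna_count = matrix(as.integer(rna_reads), ncol = 1,
                       dimnames = list(orfs$ID, "rna")),
    rna_covfrac = matrix(rna_cov, ncol = 1,
                         dimnames = list(orfs$ID, "rna")),
    dna_count = matrix(as.integer(dna), ncol = 1,
                       dimnames = list(orfs$ID, "wc"))),
    class = "CandidateOrfSet")
}

## a hand-built scrambled locus with a known somatic product
build_locus <- function(seed = 1, n_mds = 3, mds_len = 400,
                        somatic_order = NULL, somatic_strand = NULL,
                        orf_in_mds1 = FALSE, telomere_units = 2L) {
  set.seed(seed)
  mds <- replicate(n_mds, rand_dna(mds_len))
  if (orf_in_mds1) {
    cassette <- tgloscreen:::plant_orf_seq(210, 0.4)
    substr(mds[1], 50, 50 + nchar(cassette) - 1) <- cassette
  }
  ies <- replicate(n_mds - 1, rand_dna(80))
  locus <- mds[1]
  for (i in seq_len(n_mds - 1)) locus <- paste0(locus, ies[i], mds[i + 1])
  if (is.null(somatic_order)) somatic_order <- seq_len(n_mds)
  if (is.null(somatic_strand)) somatic_strand <- rep("+", n_mds)
  pieces <- vapply(seq_len(n_mds), function(k) {
    m <- mds[somatic_order[k]]
    if (somatic_strand[k] == "-") rc1(m) else m
  }, character(1))
  nano <- paste0(strrep("CCCCAAAA", telomere_units),
                 paste(pieces, collapse = ""),
                 strrep("TTTTGGGG", telomere_units))
  list(locus = locus, nano = nano, mds = mds,
       somatic_order = somatic_order, somatic_strand = somatic_strand)
}

## all-pairs ungapped identity for clustering oracle (same length or
## global alignment-free: compares over the shorter prefix alignment of
## best shift is unnecessary for the mutated-family fixture where family
## members share coordinates)
naive_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  mean(strsplit(substr(a, 1, n), "")[[1]] == strsplit(substr(b, 1, n),
                                                      "")[[1]])
}
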