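## Synthetic MIC/MAC genome pairs and sequencing libraries.
##
## The generator emulates the genome architecture the screen assumes: a
## germline (MIC) genome in which nanochromosome precursor loci — ordered,
## optionally scrambled MDSs separated by IESs — are embedded in
## germline-limited spacer sequence; TGLOs and silent ORFs planted in
## germline-limited space; MAC genes planted inside MDSs; a somatic (MAC)
## genome of telomere-capped nanochromosomes derived from the precursors;
## and DNA / RNA time-course / small-RNA / template-RNA read sets.

TELOMERE_UNIT_5P <- "CCCCAAAA"   # C4A4 repeat, top strand, 5' end
TELOMERE_UNIT_3P <- "TTTTGGGG"   # reverse complement at the 3' end

DEFAULT_TIME_POINTS <- c(0, 12, 18, 24, 36, 48, 60, 72)  # hours post mixing

#' Configuration for the germline genome simulator
#'
#' Length arguments are inclusive integer ranges `c(min, max)`. Defaults
#' describe the standard study conditions used throughout the package's
#' tests: a ~1 Mb germline genome of 50 precursor loci on 5 contigs, 15
#' high- and 15 low-transcription TGLOs, 30 silent germline ORFs and 20
#' MAC genes, AT-rich sequence (GC 0.31), one fifth of loci scrambled.
#'
#' @param n_precursor_loci number of nanochromosome precursor loci.
#' @param mds_per_locus range of MDS counts per locus.
#' @param mds_len,ies_len,spacer_len,tglo_len,mac_gene_len length ranges (bp).
#' @param n_tglo_high,n_tglo_low,n_silent_germline_orfs,n_mac_genes planted
#'   ORF counts by class.
#' @param gc_content GC fraction in (0, 1).
#' @param scramble_fraction fraction of loci whose somatic MDS order /
#'   orientation is permuted.
#' @param n_contigs number of germline contigs (capped at the locus count).
#' @param telomere_units tandem C4A4 units added at each nanochromosome end.
#' @param time_points RNA time grid in hours.
#' @param rna_read_len,rna_peak_depth used to translate the peak fold
#'   coverage into planted expected read counts per transcript.
#' @param low_fragment_fraction fraction of a low-transcription TGLO's CDS
#'   covered by its transcript (see the methods vignette).
#' @param seed integer seed.
#' @return a `GenomeSimConfig` list.
#' @export
genome_sim_config <- function(n_precursor_loci = 50L,
                              mds_per_locus = c(3L, 8L),
                              mds_len = c(200L, 800L),
                              ies_len = c(50L, 200L),
                              spacer_len = c(8000L, 16000L),
                              n_tglo_high = 15L,
                              n_tglo_low = 15L,
                              n_silent_germline_orfs = 30L,
                              n_mac_genes = 20L,
                              tglo_len = c(300L, 600L),
                              mac_gene_len = c(150L, 450L),
                              gc_content = 0.31,
                              scramble_fraction = 0.2,
                              n_contigs = 5L,
                              telomere_units = 5L,
                              time_points = DEFAULT_TIME_POINTS,
                              rna_read_len = 75L,
                              rna_peak_depth = 20,
                              low_fragment_fraction = 0.5,
                              seed = 1L) {
  cfg <- list(
    n_precursor_loci = as.integer(n_precursor_loci),
    mds_per_locus = check_range(mds_per_locus, "mds_per_locus"),
    mds_len = check_range(mds_len, "mds_len"),
    ies_len = check_range(ies_len, "ies_len"),
    spacer_len = check_range(spacer_len, "spacer_len"),
    n_tglo_high = as.integer(n_tglo_high),
    n_tglo_low = as.integer(n_tglo_low),
    n_silent_germline_orfs = as.integer(n_silent_germline_orfs),
    n_mac_genes = as.integer(n_mac_genes),
    tglo_len = check_range(tglo_len, "tglo_len", min_allowed = 9L),
    mac_gene_len = check_range(mac_gene_len, "mac_gene_len", min_allowed = 9L),
    gc_content = gc_content,
    scramble_fraction = scramble_fraction,
    n_contigs = max(1L, min(as.integer(n_contigs),
                            as.integer(n_precursor_loci))),
    telomere_units = as.integer(telomere_units),
    time_points = as.numeric(time_points),
    rna_read_len = as.integer(rna_read_len),
    rna_peak_depth = rna_peak_depth,
    low_fragment_fraction = low_fragment_fraction,
    seed = as.integer(seed))
  check_that(cfg$n_precursor_loci >= 1, "need at least one precursor locus")
  check_that(all(c(cfg$n_tglo_high, cfg$n_tglo_low,
                   cfg$n_silent_germline_orfs, cfg$n_mac_genes) >= 0),
             "planted ORF counts must be >= 0")
  check_that(cfg$gc_content > 0 && cfg$gc_content < 1,
             "gc_content must lie in (0, 1)")
  check_that(cfg$scramble_fraction >= 0 && cfg$scramble_fraction <= 1,
             "scramble_fraction must lie in [0, 1]")
  check_that(cfg$low_fragment_fraction > 0 && cfg$low_fragment_fraction <= 1,
             "low_fragment_fraction must lie in (0, 1]")
  class(cfg) <- "GenomeSimConfig"
  cfg
}

## A planted ORF cassette, built to be the unique maximal supported model
## at its locus:
## * an in-frame stop immediately upstream of the ATG pins the scanner's
##   reported start to the planted start;
## * the body is drawn from non-stop codons of the ciliate code (TGA is the
##   only stop), so the reported ORF equals the planted interval exactly;
## * a stop-seeding motif is written into the body every STOP_SEED_STRIDE
##   codons. The motif has TGA at offsets 1 and 2 mod 3 and TCA (reverse-
##   strand TGA) at all three offsets, with no frame-0 TGA/ATG, so every
##   alternative reading frame is terminated regularly and no alternative-
##   frame ORF of screening length can nest inside or span a cassette —
##   without this, the planted truth would be ambiguous (several maximal
##   ORFs could explain the same transcription evidence).
STOP_SEED_MOTIF <- c("CTG", "ACT", "GAC", "TCA", "CTC", "ACT", "CAA")
STOP_SEED_STRIDE <- 18L

plant_orf_seq <- function(len, gc) {
  stopifnot(len %% 3 == 0, len >= 9)
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  body_codons <- setdiff(all_codons, c("TGA", "ATG"))
  w <- vapply(strsplit(body_codons, ""), function(b) {
    prod(ifelse(b %in% c("G", "C"), gc / 2, (1 - gc) / 2))
  }, numeric(1))
  n_body <- len / 3 - 2
  body <- sample(body_codons, n_body, replace = TRUE, prob = w)
  nm <- length(STOP_SEED_MOTIF)
  if (n_body - nm >= 8L) {
    at <- seq.int(8L, n_body - nm, by = STOP_SEED_STRIDE)
    for (a in at) body[a:(a + nm - 1L)] <- STOP_SEED_MOTIF
  }
  paste0("TGA", "ATG", paste(body, collapse = ""), "TGA")
}

## Choose a placement interval of width m inside the free segments,
## uniformly over all legal start positions; returns the updated free table.
place_in_free <- function(free, m, what) {
  room <- free$end - free$start + 1L - m + 1L
  ok <- which(room > 0L)
  if (!length(ok)) {
    stop(sprintf(
      "cannot fit %s of %d bp into the remaining germline-limited space; ",
      what, m), "increase spacer_len or reduce planted feature counts",
      call. = FALSE)
  }
  i <- ok[sample.int(length(ok), 1L, prob = room[ok])]
  start <- free$start[i] + sample.int(room[i], 1L) - 1L
  seg <- free[i, ]
  rest <- free[-i, , drop = FALSE]
  left <- data.frame(contig = seg$contig, start = seg$start,
                     end = start - 1L, stringsAsFactors = FALSE)
  right <- data.frame(contig = seg$contig, start = start + m,
                      end = seg$end, stringsAsFactors = FALSE)
  keep <- rbind(left, right)
  keep <- keep[keep$end - keep$start + 1L >= 12L, , drop = FALSE]
  list(contig = seg$contig, start = start,
       free = rbind(rest, keep))
}

#' Simulate a germline (MIC) genome with planted features
#'
#' Builds `n_contigs` germline contigs, each an alternation of
#' germline-limited spacers and precursor loci (MDSs separated by IESs).
#' A configurable fraction of loci is scrambled: their somatic MDS order is
#' a random non-identity permutation and a random subset of MDSs is
#' inverted. TGLOs (high/low transcription), silent germline ORFs and MAC
#' genes are planted as exact start-to-stop ORF cassettes under the ciliate
#' code — TGLOs and silent ORFs inside germline-limited space (spacers, or
#' IESs when long enough), MAC genes wholly inside single MDSs. Planted
#' expression profiles follow the developmental time grid: TGLO transcription
#' is near zero before 24 h and peaks at 36-60 h; MAC genes get diverse
#' profiles (constitutive, early, declining, mid-peak).
#'
#' @param config a [genome_sim_config()].
#' @return list with `genome` (an [annotated_genome()]) and `truth`
#'   (a `TruthSet`: planted ids by class, planted intervals with transcript
#'   sub-intervals, per-locus somatic order/orientation, and the expected
#'   read count matrix over time points).
#' @export
simulate_mic_genome <- function(config = genome_sim_config()) {
  stopifnot(inherits(config, "GenomeSimConfig"))
  with_seed(config$seed, {
    n_loci <- config$n_precursor_loci
    contig_of_locus <- rep(seq_len(config$n_contigs), length.out = n_loci)
    contig_names <- sprintf("mic_%02d", seq_len(config$n_contigs))

    seqs <- character(config$n_contigs)
    feats <- list()
    loci_tab <- list()
    for (ci in seq_len(config$n_contigs)) {
      loci_here <- which(contig_of_locus == ci)
      parts <- character(0)
      pos <- 1L
      add_feat <- function(type, start, end, id, ...) {
        feats[[length(feats) + 1L]] <<- data.frame(
          contig = contig_names[ci], start = start, end = end,
          strand = "+", type = type, ID = id, ...,
          stringsAsFactors = FALSE)
      }
      for (li in loci_here) {
        sp <- draw_range(config$spacer_len)
        parts <- c(parts, random_dna(sp, config$gc_content))
        add_feat("spacer", pos, pos + sp - 1L,
                 sprintf("spacer_%s_%d", contig_names[ci], length(parts)))
        pos <- pos + sp
        k <- draw_range(config$mds_per_locus)
        locus_id <- sprintf("L%03d", li)
        locus_start <- pos
        ## somatic order / orientation
        scrambled <- runif(1) < config$scramble_fraction && k >= 2L
        somatic_order <- seq_len(k)
        somatic_strand <- rep("+", k)
        if (scrambled) {
          repeat {
            somatic_order <- sample(k)
            if (any(somatic_order != seq_len(k))) break
          }
          inv <- runif(k) < 0.5
          if (!any(inv)) inv[sample.int(k, 1L)] <- TRUE
          somatic_strand[inv] <- "-"
        }
        ## somatic_order[i] = somatic position of germline MDS i
        somatic_pos <- integer(k)
        somatic_pos[somatic_order] <- seq_len(k)
        for (mi in seq_len(k)) {
          ml <- draw_range(config$mds_len)
          parts <- c(parts, random_dna(ml, config$gc_content))
          add_feat("MDS", pos, pos + ml - 1L,
                   sprintf("%s_MDS%d", locus_id, mi),
                   locus = locus_id, mds_index = mi,
                   somatic_order = somatic_pos[mi],
                   somatic_strand = somatic_strand[mi])
          pos <- pos + ml
          if (mi < k) {
            il <- draw_range(config$ies_len)
            parts <- c(parts, random_dna(il, config$gc_content))
            add_feat("IES", pos, pos + il - 1L,
                     sprintf("%s_IES%d", locus_id, mi), locus = locus_id)
            pos <- pos + il
          }
        }
        add_feat("locus", locus_start, pos - 1L, locus_id, locus = locus_id)
        loci_tab[[length(loci_tab) + 1L]] <- data.frame(
          locus = locus_id, contig = contig_names[ci], n_mds = k,
          mds_index = seq_len(k), somatic_order = somatic_pos,
          somatic_strand = somatic_strand, stringsAsFactors = FALSE)
      }
      sp <- draw_range(config$spacer_len)
      parts <- c(parts, random_dna(sp, config$gc_content))
      add_feat("spacer", pos, pos + sp - 1L,
               sprintf("spacer_%s_%d", contig_names[ci], length(parts)))
      seqs[ci] <- paste(parts, collapse = "")
    }

    fd <- do.call(function(...) rbind(...), lapply(feats, function(f) {
      for (col in c("locus", "mds_index", "somatic_order", "somatic_strand")) {
        if (is.null(f[[col]])) f[[col]] <- NA
      }
      f
    }))
    seq_set <- Biostrings::DNAStringSet(seqs)
    names(seq_set) <- contig_names

    ## ---- plant ORFs ---------------------------------------------------
    spacer_rows <- fd[fd$type %in% c("spacer", "IES"), , drop = FALSE]
    free <- data.frame(contig = spacer_rows$contig,
                       start = spacer_rows$start, end = spacer_rows$end,
                       stringsAsFactors = FALSE)
    seq_chr <- stats::setNames(as.character(seq_set), contig_names)

    classes <- c(rep("tglo_high", config$n_tglo_high),
                 rep("tglo_low", config$n_tglo_low),
                 rep("silent_orf", config$n_silent_germline_orfs))
    orf_rows <- list()
    idx_by_class <- c(tglo_high = 0L, tglo_low = 0L, silent_orf = 0L,
                      mac_gene = 0L)
    for (cls in classes) {
      idx_by_class[cls] <- idx_by_class[cls] + 1L
      len <- draw_range(config$tglo_len)
      len <- len - (len %% 3L)
      cassette <- plant_orf_seq(len, config$gc_content)
      m <- nchar(cassette)                 # len + 3 (leading stop)
      minus <- runif(1) < 0.5
      if (minus) cassette <- revcomp(cassette)
      pl <- place_in_free(free, m, "planted ORF")
      free <- pl$free
      substr(seq_chr[[pl$contig]], pl$start, pl$start + m - 1L) <- cassette
      ## ORF interval excludes the pinning stop codon
      if (!minus) {
        ostart <- pl$start + 3L; oend <- pl$start + m - 1L; strand <- "+"
      } else {
        ostart <- pl$start; oend <- pl$start + m - 4L; strand <- "-"
      }
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        contig = pl$contig, start = ostart, end = oend, strand = strand,
        type = "ORF", ID = sprintf("%s_%03d", cls, idx_by_class[cls]),
        class = cls, stringsAsFactors = FALSE)
    }

    ## MAC genes: wholly inside single MDSs, at most one per MDS
    mds_rows <- fd[fd$type == "MDS", , drop = FALSE]
    if (config$n_mac_genes > 0) {
      max_need <- max(config$mac_gene_len) + 3L
      big <- mds_rows[mds_rows$end - mds_rows$start + 1L >= max_need, ,
                      drop = FALSE]
      check_that(nrow(big) >= config$n_mac_genes,
                 "not enough MDSs large enough to host the requested MAC genes; increase mds_len or n_precursor_loci")
      host <- big[sample.int(nrow(big), config$n_mac_genes), , drop = FALSE]
      for (gi in seq_len(config$n_mac_genes)) {
        len <- draw_range(config$mac_gene_len)
        len <- len - (len %% 3L)
        cassette <- plant_orf_seq(len, config$gc_content)
        m <- nchar(cassette)
        room <- (host$end[gi] - host$start[gi] + 1L) - m + 1L
        start <- host$start[gi] + sample.int(room, 1L) - 1L
        substr(seq_chr[[host$contig[gi]]], start, start + m - 1L) <- cassette
        orf_rows[[length(orf_rows) + 1L]] <- data.frame(
          contig = host$contig[gi], start = start + 3L,
          end = start + m - 1L, strand = "+", type = "ORF",
          ID = sprintf("mac_gene_%03d", gi), class = "mac_gene",
          stringsAsFactors = FALSE)
      }
    }

    orfd <- if (length(orf_rows)) do.call(rbind, orf_rows) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 strand = character(), type = character(), ID = character(),
                 class = character(), stringsAsFactors = FALSE)

    ## ---- expression truth ---------------------------------------------
    tp <- config$time_points
    rl <- config$rna_read_len
    expr <- matrix(0, nrow = nrow(orfd), ncol = length(tp),
                   dimnames = list(orfd$ID, as.character(tp)))
    tr_start <- orfd$start
    tr_end <- orfd$end
    profile_of <- function(kind) {
      switch(kind,
             tglo = c(0, 0, 0, 0.05, 1, 1, 1, 0.2)[seq_along(tp)],
             constitutive = rep(1, length(tp)),
             early = c(1, 1, 0.6, 0.3, 0.1, 0.05, 0.05, 0.05)[seq_along(tp)],
             declining = seq(1, 0.1, length.out = length(tp)),
             mid = c(0.1, 0.3, 0.8, 1, 1, 0.6, 0.3, 0.1)[seq_along(tp)])
    }
    for (i in seq_len(nrow(orfd))) {
      cls <- orfd$class[i]
      L <- orfd$end[i] - orfd$start[i] + 1L
      if (cls == "tglo_high") {
        peak <- config$rna_peak_depth * L / rl
        expr[i, ] <- peak * profile_of("tglo")
      } else if (cls == "tglo_low") {
        ## transcript restricted to a sub-interval of the CDS: sparse,
        ## partial coverage is what distinguishes low transcription
        frag <- max(rl + 1L, as.integer(round(L * config$low_fragment_fraction)))
        if (orfd$strand[i] == "+") {
          tr_end[i] <- orfd$start[i] + frag - 1L
        } else {
          tr_start[i] <- orfd$end[i] - frag + 1L
        }
        peak <- config$rna_peak_depth * frag / rl
        expr[i, ] <- peak * profile_of("tglo")
      } else if (cls == "mac_gene") {
        kind <- c("constitutive", "early", "declining", "mid")[
          (i %% 4L) + 1L]
        peak <- 10 * L / rl
        expr[i, ] <- pmax(peak * profile_of(kind), 0)
      }
    }
    orfd$transcript_start <- tr_start
    orfd$transcript_end <- tr_end

    ## ---- assemble outputs ---------------------------------------------
    all_feats <- fd[, c("contig", "start", "end", "strand", "type", "ID",
                        "locus", "mds_index", "somatic_order",
                        "somatic_strand")]
    if (nrow(orfd)) {
      all_feats <- rbind(
        all_feats,
        cbind(orfd[, c("contig", "start", "end", "strand", "type", "ID")],
              locus = NA, mds_index = NA, somatic_order = NA,
              somatic_strand = NA))
    }
    gr <- GenomicRanges::GRanges(
      seqnames = factor(all_feats$contig, levels = contig_names),
      ranges = IRanges::IRanges(all_feats$start, all_feats$end),
      strand = all_feats$strand)
    gr$type <- all_feats$type
    gr$ID <- all_feats$ID
    gr$locus <- all_feats$locus
    gr$mds_index <- suppressWarnings(as.integer(all_feats$mds_index))
    gr$somatic_order <- suppressWarnings(as.integer(all_feats$somatic_order))
    gr$somatic_strand <- all_feats$somatic_strand
    orf_class <- rep(NA_character_, length(gr))
    orf_class[gr$type == "ORF"] <- orfd$class
    gr$orf_class <- orf_class

    genome <- annotated_genome(Biostrings::DNAStringSet(seq_chr), gr)

    truth <- structure(list(
      tglo_ids_high = orfd$ID[orfd$class == "tglo_high"],
      tglo_ids_low = orfd$ID[orfd$class == "tglo_low"],
      silent_orf_ids = orfd$ID[orfd$class == "silent_orf"],
      mac_gene_ids = orfd$ID[orfd$class == "mac_gene"],
      orfs = orfd,
      loci = do.call(rbind, loci_tab),
      expression = expr,
      time_points = tp,
      config = config), class = "TruthSet")
    list(genome = genome, truth = truth)
  })
}

#' @export
print.TruthSet <- function(x, ...) {
  cat(sprintf(
    "TruthSet: %d high + %d low TGLOs, %d silent ORFs, %d MAC genes, %d loci\n",
    length(x$tglo_ids_high), length(x$tglo_ids_low),
    length(x$silent_orf_ids), length(x$mac_gene_ids),
    length(unique(x$loci$locus))))
  invisible(x)
}

#' Derive the somatic (MAC) genome from a germline genome
#'
#' One telomere-capped nanochromosome per precursor locus: the locus' MDSs
#' concatenated in somatic order and orientation (scrambled loci are
#' descrambled, inverted MDSs reverse-complemented), flanked by tandem C4A4
#' telomere repeats. No IES or germline-limited base enters any
#' nanochromosome.
#'
#' @param mic an [annotated_genome()] from [simulate_mic_genome()].
#' @param telomere_units tandem telomere units per end.
#' @return an `AnnotatedGenome` of nanochromosomes, with telomere and MDS
#'   block features (MDS blocks keep their germline provenance columns).
#' @export
derive_mac_genome <- function(mic, telomere_units = 5L) {
  stopifnot(inherits(mic, "AnnotatedGenome"))
  f <- mic$features
  mds <- f[f$type == "MDS"]
  check_that(length(mds) > 0, "no MDS features on the germline genome")
  tel5 <- strrep(TELOMERE_UNIT_5P, telomere_units)
  tel3 <- strrep(TELOMERE_UNIT_3P, telomere_units)
  seqs <- character(0)
  feats <- list()
  for (locus in unique(mds$locus)) {
    m <- mds[mds$locus == locus]
    k <- length(m)
    so <- m$somatic_order
    check_that(!anyNA(so) && setequal(so, seq_len(k)),
               sprintf("locus %s: somatic order is not a complete permutation",
                       locus))
    m <- m[order(so)]
    pieces <- character(k)
    for (i in seq_len(k)) {
      s <- as.character(Biostrings::subseq(
        mic$seq[[as.character(GenomeInfoDb::seqnames(m[i]))]],
        GenomicRanges::start(m[i]), GenomicRanges::end(m[i])))
      if (identical(m$somatic_strand[i], "-")) s <- revcomp(s)
      pieces[i] <- s
    }
    core <- paste(pieces, collapse = "")
    nano <- paste0(tel5, core, tel3)
    name <- sprintf("nano_%s", locus)
    seqs[name] <- nano
    pos <- nchar(tel5) + 1L
    feats[[length(feats) + 1L]] <- data.frame(
      contig = name, start = 1L, end = nchar(tel5), strand = "+",
      type = "telomere", ID = sprintf("%s_tel5", name), locus = locus,
      mds_index = NA, somatic_order = NA, somatic_strand = NA,
      stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      w <- nchar(pieces[i])
      feats[[length(feats) + 1L]] <- data.frame(
        contig = name, start = pos, end = pos + w - 1L,
        strand = "+", type = "MDS",
        ID = sprintf("%s_block%d", name, i), locus = locus,
        mds_index = m$mds_index[i], somatic_order = i,
        somatic_strand = m$somatic_strand[i], stringsAsFactors = FALSE)
      pos <- pos + w
    }
    feats[[length(feats) + 1L]] <- data.frame(
      contig = name, start = pos, end = pos + nchar(tel3) - 1L,
      strand = "+", type = "telomere", ID = sprintf("%s_tel3", name),
      locus = locus, mds_index = NA, somatic_order = NA,
      somatic_strand = NA, stringsAsFactors = FALSE)
  }
  fd <- do.call(rbind, feats)
  seq_set <- Biostrings::DNAStringSet(seqs)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(fd$contig, levels = names(seq_set)),
    ranges = IRanges::IRanges(fd$start, fd$end), strand = fd$strand)
  gr$type <- fd$type; gr$ID <- fd$ID; gr$locus <- fd$locus
  gr$mds_index <- fd$mds_index; gr$somatic_order <- fd$somatic_order
  gr$somatic_strand <- fd$somatic_strand
  annotated_genome(seq_set, gr)
}

#' Configuration for the read simulator
#'
#' @param library_kind one of `dna_wholecell`, `dna_mac`, `rna_timepoint`,
#'   `small_rna`, `template_rna`.
#' @param read_len read length (bp); ignored for `small_rna`.
#' @param depth fold coverage of the library's target (the MAC genome for
#'   whole-cell and MAC DNA, the transcript for RNA — see
#'   [simulate_reads()]).
#' @param error_free if `TRUE` (default) reads are exact substrings.
#' @param error_rate per-base substitution rate when `error_free = FALSE`.
#' @param timepoint hours (RNA libraries only; must sit on the truth grid).
#' @param small_rna_len small-RNA length (fixed 27 nt by default).
#' @param mac_mic_ratio per-copy MAC:MIC template ratio in whole-cell
#'   libraries (reads are drawn length-and-copy-number weighted).
#' @param positions `"random"` start positions, or `"tile"` for a
#'   deterministic even tiling at the requested depth.
#' @param seed integer seed.
#' @return a `ReadSimConfig` list.
#' @export
read_sim_config <- function(library_kind = c("dna_wholecell", "dna_mac",
                                             "rna_timepoint", "small_rna",
                                             "template_rna"),
                            read_len = 100L, depth = 10,
                            error_free = TRUE, error_rate = 0.0,
                            timepoint = NULL, small_rna_len = 27L,
                            mac_mic_ratio = 100,
                            positions = c("random", "tile"),
                            seed = 1L) {
  library_kind <- match.arg(library_kind)
  positions <- match.arg(positions)
  check_that(read_len >= 20, "read_len must be >= 20")
  check_that(depth > 0, "depth must be > 0")
  if (library_kind == "rna_timepoint") {
    check_that(!is.null(timepoint), "rna_timepoint libraries need a timepoint")
  }
  structure(list(library_kind = library_kind, read_len = as.integer(read_len),
                 depth = depth, error_free = isTRUE(error_free),
                 error_rate = error_rate, timepoint = timepoint,
                 small_rna_len = as.integer(small_rna_len),
                 mac_mic_ratio = mac_mic_ratio, positions = positions,
                 seed = as.integer(seed)),
            class = "ReadSimConfig")
}

## Draw n read start positions over a set of sequences, weighted by the
## number of legal starts per sequence.
draw_starts <- function(widths, read_len, n) {
  legal <- pmax(widths - read_len + 1L, 0L)
  check_that(sum(legal) > 0, "source too short for the requested read length")
  src <- sample.int(length(widths), n, replace = TRUE, prob = legal)
  start <- 1L + floor(runif(n) * legal[src])
  data.frame(src = src, start = as.integer(start))
}

extract_reads <- function(seqs, src, start, len, strand, prefix,
                          error_rate = 0) {
  reads <- as.character(Biostrings::subseq(seqs[src], start, start + len - 1L))
  minus <- strand == "-"
  if (any(minus)) reads[minus] <- revcomp(reads[minus])
  if (error_rate > 0) {
    reads <- vapply(reads, function(r) {
      hit <- which(runif(nchar(r)) < error_rate)
      if (length(hit)) {
        ch <- strsplit(r, "")[[1]]
        ch[hit] <- vapply(ch[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
        r <- paste(ch, collapse = "")
      }
      r
    }, character(1), USE.NAMES = FALSE)
  }
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("%s_%06d", prefix, seq_along(out))
  out
}

#' Simulate a sequencing library
#'
#' * `dna_mac`: reads uniformly from the MAC genome at `depth` fold coverage.
#' * `dna_wholecell`: a MAC/MIC mixture. The MAC pool is weighted
#'   `mac_mic_ratio` copies per MIC copy (length-weighted within each
#'   genome), and the library size is set so the MAC genome reaches `depth`
#'   fold coverage — the MIC contribution follows from the ratio, emulating
#'   the high somatic ploidy of whole-cell DNA.
#' * `rna_timepoint`: per planted transcript, a Poisson number of reads with
#'   mean equal to the planted expected count at `timepoint`, drawn
#'   uniformly along the transcript, sense strand (stranded protocol).
#' * `small_rna`: fixed-length (27 nt) reads drawn only from inside MDS
#'   intervals, both strands.
#' * `template_rna`: reads drawn across nanochromosome cores (telomeres
#'   excluded), both strands — long RNAs spanning parental nanochromosomes.
#'
#' @param mic germline [annotated_genome()] (needed for `dna_wholecell`,
#'   `rna_timepoint`, `small_rna`).
#' @param config a [read_sim_config()].
#' @param mac somatic genome (needed for `dna_wholecell`, `dna_mac`,
#'   `template_rna`).
#' @param truth `TruthSet` (needed for `rna_timepoint`).
#' @return named [Biostrings::DNAStringSet] of reads.
#' @export
simulate_reads <- function(mic = NULL, config = read_sim_config(),
                           mac = NULL, truth = NULL) {
  stopifnot(inherits(config, "ReadSimConfig"))
  kind <- config$library_kind
  with_seed(config$seed, {
    switch(kind,
      dna_mac = {
        check_that(!is.null(mac), "dna_mac library needs the MAC genome")
        sim_dna_reads(mac$seq, config, prefix = "macdna")
      },
      dna_wholecell = {
        check_that(!is.null(mic) && !is.null(mac),
                   "dna_wholecell library needs MIC and MAC genomes")
        sim_wholecell_reads(mic, mac, config)
      },
      rna_timepoint = {
        check_that(!is.null(mic) && !is.null(truth),
                   "rna_timepoint library needs the MIC genome and truth set")
        sim_rna_reads(mic, truth, config)
      },
      small_rna = {
        check_that(!is.null(mic), "small_rna library needs the MIC genome")
        sim_small_rna_reads(mic, config)
      },
      template_rna = {
        check_that(!is.null(mac), "template_rna library needs the MAC genome")
        sim_template_rna_reads(mac, config)
      })
  })
}

sim_dna_reads <- function(seqs, config, prefix) {
  check_that(length(seqs) > 0 && sum(Biostrings::width(seqs)) > 0,
             "empty source")
  r <- config$read_len
  widths <- Biostrings::width(seqs)
  if (config$positions == "tile") {
    src <- integer(0); start <- integer(0)
    stride <- max(1L, as.integer(round(r / config$depth)))
    for (i in seq_along(seqs)) {
      if (widths[i] < r) next
      s <- unique(c(seq.int(1L, widths[i] - r + 1L, by = stride),
                    widths[i] - r + 1L))
      src <- c(src, rep(i, length(s))); start <- c(start, s)
    }
    strand <- rep(c("+", "-"), length.out = length(src))
  } else {
    n <- max(1L, as.integer(round(config$depth * sum(widths) / r)))
    d <- draw_starts(widths, r, n)
    src <- d$src; start <- d$start
    strand <- sample(c("+", "-"), length(src), replace = TRUE)
  }
  extract_reads(seqs, src, start, r, strand, prefix,
                if (config$error_free) 0 else config$error_rate)
}

sim_wholecell_reads <- function(mic, mac, config) {
  r <- config$read_len
  l_mac <- sum(Biostrings::width(mac$seq))
  l_mic <- sum(Biostrings::width(mic$seq))
  n_mac <- max(1L, as.integer(round(config$depth * l_mac / r)))
  ## per-copy ratio, length weighted: reads hit the single-copy MIC in
  ## proportion to its share of the template mass
  lambda_mic <- as.numeric(n_mac) * l_mic / (config$mac_mic_ratio * l_mac)
  n_mic <- stats::rpois(1L, lambda_mic)
  mac_reads <- sim_dna_reads(mac$seq, modifyList(config, list(
    positions = "random", depth = config$depth)), prefix = "wc_mac")
  mac_reads <- mac_reads[seq_len(min(n_mac, length(mac_reads)))]
  out <- mac_reads
  if (n_mic > 0) {
    d <- draw_starts(Biostrings::width(mic$seq), r, n_mic)
    strand <- sample(c("+", "-"), n_mic, replace = TRUE)
    mic_reads <- extract_reads(mic$seq, d$src, d$start, r, strand, "wc_mic",
                               if (config$error_free) 0 else config$error_rate)
    out <- c(mac_reads, mic_reads)
  }
  names(out) <- sprintf("wc_%06d", seq_along(out))
  out
}

sim_rna_reads <- function(mic, truth, config) {
  tp <- as.character(config$timepoint)
  check_that(tp %in% colnames(truth$expression),
             sprintf("timepoint %s is not on the simulated grid (%s)",
                     tp, paste(colnames(truth$expression), collapse = ", ")))
  mu <- truth$expression[, tp]
  orfs <- truth$orfs
  reads <- character(0)
  r <- config$read_len
  for (i in seq_len(nrow(orfs))) {
    if (mu[orfs$ID[i]] <= 0) next
    n <- stats::rpois(1L, mu[orfs$ID[i]])
    if (n == 0) next
    ts <- orfs$transcript_start[i]; te <- orfs$transcript_end[i]
    w <- te - ts + 1L
    rl <- min(r, w)
    start <- ts + floor(runif(n) * (w - rl + 1L))
    s <- as.character(Biostrings::subseq(
      rep(mic$seq[orfs$contig[i]], n), as.integer(start),
      as.integer(start) + rl - 1L))
    if (orfs$strand[i] == "-") s <- revcomp(s)
    reads <- c(reads, s)
  }
  out <- Biostrings::DNAStringSet(reads)
  if (length(out)) {
    names(out) <- sprintf("rna%s_%06d", tp, seq_along(out))
  }
  out
}

sim_small_rna_reads <- function(mic, config) {
  mds <- mic$features[mic$features$type == "MDS"]
  check_that(length(mds) > 0, "small_rna library needs MDS features")
  len <- config$small_rna_len
  widths <- GenomicRanges::width(mds)
  n <- max(1L, as.integer(round(config$depth * sum(widths) / len)))
  legal <- pmax(widths - len + 1L, 0L)
  src <- sample.int(length(mds), n, replace = TRUE, prob = legal)
  offset <- floor(runif(n) * legal[src])
  start <- GenomicRanges::start(mds)[src] + as.integer(offset)
  ctg <- as.character(GenomeInfoDb::seqnames(mds))[src]
  strand <- sample(c("+", "-"), n, replace = TRUE)
  s <- as.character(Biostrings::subseq(mic$seq[ctg], start, start + len - 1L))
  minus <- strand == "-"
  s[minus] <- revcomp(s[minus])
  out <- Biostrings::DNAStringSet(s)
  names(out) <- sprintf("sRNA_%06d", seq_along(out))
  out
}

sim_template_rna_reads <- function(mac, config) {
  tel <- mac$features[mac$features$type == "telomere"]
  cores <- GenomicRanges::setdiff(
    GenomicRanges::GRanges(GenomeInfoDb::seqinfo(tel)), tel,
    ignore.strand = TRUE)
  check_that(length(cores) > 0, "empty source")
  r <- config$read_len
  widths <- GenomicRanges::width(cores)
  n <- max(1L, as.integer(round(config$depth * sum(widths) / r)))
  legal <- pmax(widths - r + 1L, 0L)
  src <- sample.int(length(cores), n, replace = TRUE, prob = legal)
  start <- GenomicRanges::start(cores)[src] +
    as.integer(floor(runif(n) * legal[src]))
  ctg <- as.character(GenomeInfoDb::seqnames(cores))[src]
  strand <- sample(c("+", "-"), n, replace = TRUE)
  s <- as.character(Biostrings::subseq(mac$seq[ctg], start, start + r - 1L))
  minus <- strand == "-"
  s[minus] <- revcomp(s[minus])
  out <- Biostrings::DNAStringSet(s)
  names(out) <- sprintf("tRNA_%06d", seq_along(out))
  out
}

#' Write the planted truth table
#'
#' Tab-separated: id, class, contig, start, end, strand, transcript bounds,
#' then one column of expected read counts per time point.
#'
#' @param truth a `TruthSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  df <- truth$orfs
  expr <- truth$expression[df$ID, , drop = FALSE]
  colnames(expr) <- sprintf("expected_%sh", colnames(expr))
  out <- cbind(df[, c("ID", "class", "contig", "start", "end", "strand",
                      "transcript_start", "transcript_end")], expr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
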