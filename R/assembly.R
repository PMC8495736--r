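## Telomere-seeded greedy assembly of nanochromosomes from reads, MDS
## decomposition against the germline locus, and telomere-addition-site
## detection.
##
## The assembly procedure formalizes an iterative manual one: starting from
## an arbitrary read at the locus, repeatedly search the remaining reads
## for one whose end matches the current contig end exactly, extend, and
## stop a side once the contig terminates in tandem telomere repeats
## (C4A4 units). The free choices are fixed deterministically: the
## extension taken is the one adding the most new sequence (ties broken by
## read id), overlaps are exact, and a side closes at two tandem units.

## --- telomere helpers -------------------------------------------------

## Length of the telomeric run at the start (unit5) or end (unit3) of s,
## allowing a partial leading/trailing unit; returns run length in bases
## and the number of complete units.
telomere_run_5p <- function(s, unit = TELOMERE_UNIT_5P) {
  u <- nchar(unit)
  ## optional partial unit = a proper suffix of the unit
  best <- c(len = 0L, units = 0L)
  for (off in 0:(u - 1L)) {
    lead <- if (off > 0) substr(unit, u - off + 1L, u) else ""
    if (off > 0 && substr(s, 1L, off) != lead) next
    n_units <- 0L
    pos <- off + 1L
    while (substr(s, pos, pos + u - 1L) == unit) {
      n_units <- n_units + 1L
      pos <- pos + u
    }
    if (n_units > 0 && off + n_units * u > best["len"]) {
      best <- c(len = off + n_units * u, units = n_units)
    }
  }
  best
}

telomere_run_3p <- function(s, unit = TELOMERE_UNIT_3P) {
  r <- telomere_run_5p(revcomp(s), unit = revcomp(unit))
  r
}

## --- read collection ---------------------------------------------------

#' Collect reads mapping to a locus
#'
#' Reads whose alignments overlap the locus extended by `padding` bases on
#' each side, deduplicated by read id.
#'
#' @param alignments GRanges with a `read_id` column.
#' @param locus a GRanges of length 1 (or a feature `ID` present in
#'   `features`).
#' @param padding bp added to each side.
#' @param features optional GRanges to resolve a locus given by id.
#' @return character vector of read ids.
#' @export
collect_locus_reads <- function(alignments, locus, padding = 0L,
                                features = NULL) {
  if (is.character(locus)) {
    check_that(!is.null(features), "resolving a locus id needs 'features'")
    locus <- features[which(features$ID == locus)]
  }
  check_that(methods::is(locus, "GRanges") && length(locus) == 1,
             "'locus' must be a single interval")
  padded <- GenomicRanges::resize(locus,
                                  GenomicRanges::width(locus) + 2L * padding,
                                  fix = "center")
  padded <- GenomicRanges::trim(padded)
  ov <- GenomicRanges::findOverlaps(alignments, padded, ignore.strand = TRUE)
  unique(alignments$read_id[S4Vectors::queryHits(ov)])
}

## --- greedy end extension ----------------------------------------------

#' Assemble a telomere-capped nanochromosome from reads
#'
#' Greedy exact-overlap end extension from a seed read. At each step, among
#' unused reads (either orientation) whose prefix (for 3' extension) or
#' suffix (for 5' extension) matches the current contig end with exact
#' overlap of at least `min_overlap`, the read extending the contig
#' furthest is taken, ties broken by lexicographically smallest read id. A
#' side closes once the contig end carries at least `min_tail_units` tandem
#' telomere units (a partial terminal unit is tolerated); assembly stops
#' when both sides are closed or no extension exists.
#'
#' @param seed_read id of the seed read (must be in `reads`).
#' @param reads named [Biostrings::DNAStringSet] or character vector.
#' @param min_overlap minimum exact overlap in bp (>= 10).
#' @param telomere_unit 5' telomere unit on the top strand.
#' @param min_tail_units tandem units that close a side.
#' @return a `NanochromosomeAssembly`: `contig` (character), `status`
#'   (`complete`, `partial_5p`, `partial_3p`, `failed`), telomere run
#'   lengths, the seed id and the extension trace (read id, side, overlap,
#'   orientation, per step).
#' @export
assemble_from_seed <- function(seed_read, reads, min_overlap = 30L,
                               telomere_unit = TELOMERE_UNIT_5P,
                               min_tail_units = 2L) {
  if (methods::is(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  check_that(min_overlap >= 10, "min_overlap must be >= 10")
  check_that(seed_read %in% names(reads), "seed read not in read set")
  check_that(nchar(reads[[seed_read]]) >= min_overlap,
             "seed read shorter than min_overlap")
  unit3 <- revcomp(telomere_unit)
  k <- as.integer(min_overlap)

  ## orientation-expanded read table
  ids <- names(reads)
  fwd <- unname(reads)
  rc <- revcomp(fwd)
  key_id <- c(ids, ids)
  key_orient <- rep(c("+", "-"), each = length(ids))
  key_seq <- c(fwd, rc)
  key_len <- nchar(key_seq)

  ## hash read prefixes/suffixes of length k
  pref <- substr(key_seq, 1L, k)
  suff <- substr(key_seq, key_len - k + 1L, key_len)
  pref_map <- split(seq_along(key_seq), pref)
  suff_map <- split(seq_along(key_seq), suff)

  used <- stats::setNames(rep(FALSE, length(ids)), ids)
  used[seed_read] <- TRUE
  contig <- reads[[seed_read]]
  trace <- list()

  closed_5p <- function() telomere_run_5p(contig, telomere_unit)["units"] >=
    min_tail_units
  closed_3p <- function() telomere_run_3p(contig, unit3)["units"] >=
    min_tail_units

  ## A candidate's overlap is its MAXIMAL exact overlap with the contig end
  ## (scanning o from large to small and keeping each read's first
  ## validation); among candidates the extension gaining the most sequence
  ## wins, ties by smallest read id.
  find_ext <- function(side) {
    L <- nchar(contig)
    o_hi <- min(L, max(key_len) - 1L)
    if (o_hi < k) return(NULL)
    best <- NULL
    seen <- integer(0)
    for (o in seq.int(o_hi, k)) {
      if (side == "3p") {
        kmer <- substr(contig, L - o + 1L, L - o + k)
        cand <- pref_map[[kmer]]
        if (is.null(cand)) next
        for (ci in cand) {
          if (ci %in% seen || used[[key_id[ci]]] || key_len[ci] <= o) next
          if (substr(key_seq[ci], 1L, o) == substr(contig, L - o + 1L, L)) {
            seen <- c(seen, ci)
            ext <- key_len[ci] - o
            if (is.null(best) || ext > best$ext ||
                (ext == best$ext && key_id[ci] < best$id)) {
              best <- list(id = key_id[ci], idx = ci, o = o, ext = ext)
            }
          }
        }
      } else {
        kmer <- substr(contig, o - k + 1L, o)
        cand <- suff_map[[kmer]]
        if (is.null(cand)) next
        for (ci in cand) {
          if (ci %in% seen || used[[key_id[ci]]] || key_len[ci] <= o) next
          if (substr(key_seq[ci], key_len[ci] - o + 1L, key_len[ci]) ==
                substr(contig, 1L, o)) {
            seen <- c(seen, ci)
            ext <- key_len[ci] - o
            if (is.null(best) || ext > best$ext ||
                (ext == best$ext && key_id[ci] < best$id)) {
              best <- list(id = key_id[ci], idx = ci, o = o, ext = ext)
            }
          }
        }
      }
    }
    best
  }

  repeat {
    did <- FALSE
    if (!closed_3p()) {
      b <- find_ext("3p")
      if (!is.null(b)) {
        contig <- paste0(contig,
                         substr(key_seq[b$idx], b$o + 1L, key_len[b$idx]))
        used[[b$id]] <- TRUE
        trace[[length(trace) + 1L]] <- data.frame(
          read_id = b$id, side = "3p", overlap = b$o,
          orientation = key_orient[b$idx], stringsAsFactors = FALSE)
        did <- TRUE
      }
    }
    if (!closed_5p()) {
      b <- find_ext("5p")
      if (!is.null(b)) {
        contig <- paste0(substr(key_seq[b$idx], 1L, b$ext), contig)
        used[[b$id]] <- TRUE
        trace[[length(trace) + 1L]] <- data.frame(
          read_id = b$id, side = "5p", overlap = b$o,
          orientation = key_orient[b$idx], stringsAsFactors = FALSE)
        did <- TRUE
      }
    }
    if ((closed_5p() && closed_3p()) || !did) break
  }

  c5 <- closed_5p(); c3 <- closed_3p()
  status <- if (c5 && c3) "complete" else if (c5) "partial_3p" else
    if (c3) "partial_5p" else "failed"
  structure(list(
    contig = contig,
    status = status,
    telomere_5p = unname(telomere_run_5p(contig, telomere_unit)["len"]),
    telomere_3p = unname(telomere_run_3p(contig, unit3)["len"]),
    seed_read_id = seed_read,
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(read_id = character(), side = character(),
                 overlap = integer(), orientation = character(),
                 stringsAsFactors = FALSE)),
    class = "NanochromosomeAssembly")
}

#' @export
print.NanochromosomeAssembly <- function(x, ...) {
  cat(sprintf(
    "NanochromosomeAssembly: %d bp, status %s (telomere runs %d / %d bp), %d extensions\n",
    nchar(x$contig), x$status, x$telomere_5p, x$telomere_3p, nrow(x$trace)))
  invisible(x)
}

## --- MDS decomposition -------------------------------------------------

## All maximal exact matches >= min_len between q and s (plus strand of s),
## found by grouping shared k-mer anchors into runs along diagonals.
maximal_matches <- function(q, s, min_len = 20L) {
  k <- as.integer(min_len)
  nq <- nchar(q); ns <- nchar(s)
  if (nq < k || ns < k) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      len = integer()))
  }
  qk <- substring(q, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
  sk <- substring(s, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
  sk_map <- split(seq_len(ns - k + 1L), sk)
  anchors_q <- integer(0); anchors_s <- integer(0)
  hits <- sk_map[qk]
  n_per <- vapply(hits, function(h) if (is.null(h)) 0L else length(h),
                  integer(1))
  anchors_q <- rep(seq_len(nq - k + 1L), n_per)
  anchors_s <- unlist(hits[n_per > 0L], use.names = FALSE)
  if (!length(anchors_q)) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      len = integer()))
  }
  d <- anchors_s - anchors_q
  out <- list()
  for (dg in unique(d)) {
    qs <- sort(anchors_q[d == dg])
    ## runs of consecutive anchor positions = maximal exact matches
    brk <- c(0L, which(diff(qs) != 1L), length(qs))
    for (j in seq_len(length(brk) - 1L)) {
      a <- qs[brk[j] + 1L]; b <- qs[brk[j + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        q_start = a, q_end = b + k - 1L,
        s_start = a + dg, s_end = b + k - 1L + dg,
        len = b - a + k)
    }
  }
  do.call(rbind, out)
}

#' Decompose an assembled nanochromosome into MDS blocks
#'
#' Finds maximal exact-match blocks between the contig core (terminal
#' telomere runs trimmed) and the germline locus, on both strands, and
#' selects them greedily longest-first without double-using contig bases.
#' Blocks are reported in contig order with their germline span and
#' orientation — for a nanochromosome from a scrambled locus this recovers
#' the somatic permutation and inversions. Telomere addition sites are the
#' germline coordinates flanking the first and last blocks.
#'
#' @param assembly a `NanochromosomeAssembly`, or a plain contig sequence.
#' @param germline_locus locus sequence (character/DNAString), e.g. from
#'   [orf_sequences()] on a `locus` feature.
#' @param min_block smallest exact block reported (bp).
#' @param telomere_unit 5' telomere unit.
#' @return an `MdsDecomposition`: `blocks` (contig order, contig/locus
#'   spans, orientation, length), `unmatched` contig spans,
#'   `telomere_addition` (side, germline coordinate), and the core span in
#'   contig coordinates.
#' @export
decompose_into_mds <- function(assembly, germline_locus, min_block = 20L,
                               telomere_unit = TELOMERE_UNIT_5P) {
  contig <- if (inherits(assembly, "NanochromosomeAssembly"))
    assembly$contig else as.character(assembly)
  locus <- as.character(germline_locus)
  t5 <- telomere_run_5p(contig, telomere_unit)["len"]
  t3 <- telomere_run_3p(contig, revcomp(telomere_unit))["len"]
  core_start <- unname(t5) + 1L
  core_end <- nchar(contig) - unname(t3)
  check_that(core_end >= core_start, "empty contig core")
  core <- substr(contig, core_start, core_end)

  fwd <- maximal_matches(core, locus, min_block)
  if (nrow(fwd)) fwd$strand <- "+"
  rc <- maximal_matches(core, revcomp(locus), min_block)
  if (nrow(rc)) {
    nl <- nchar(locus)
    tmp <- rc
    rc$s_start <- nl - tmp$s_end + 1L
    rc$s_end <- nl - tmp$s_start + 1L
    rc$strand <- "-"
  }
  mm <- rbind(fwd, rc)
  check_that(!is.null(mm) && nrow(mm) > 0,
             "no exact match between contig core and locus")
  mm <- mm[order(-mm$len, mm$q_start, mm$strand), , drop = FALSE]
  ## greedy longest-first without double-using contig bases; a candidate
  ## overlapping already-claimed bases is trimmed to its longest unused
  ## sub-span (maximal exact matches can exceed the annotated block by a
  ## few coincidentally matching junction bases, and discarding the whole
  ## candidate for a one-base collision would lose true blocks)
  used <- logical(nchar(core))
  picked <- list()
  for (i in seq_len(nrow(mm))) {
    span <- mm$q_start[i]:mm$q_end[i]
    free_run <- rle(!used[span])
    if (!any(free_run$values)) next
    ends <- cumsum(free_run$lengths)
    starts <- ends - free_run$lengths + 1L
    j <- which(free_run$values)[which.max(free_run$lengths[free_run$values])]
    len2 <- free_run$lengths[j]
    if (len2 < min_block) next
    da <- starts[j] - 1L                    # bases trimmed on the left
    db <- length(span) - ends[j]            # bases trimmed on the right
    b <- mm[i, , drop = FALSE]
    b$q_start <- b$q_start + da
    b$q_end <- b$q_end - db
    if (b$strand == "+") {
      b$s_start <- b$s_start + da
      b$s_end <- b$s_end - db
    } else {
      b$s_start <- b$s_start + db
      b$s_end <- b$s_end - da
    }
    b$len <- len2
    used[b$q_start:b$q_end] <- TRUE
    picked[[length(picked) + 1L]] <- b
  }
  blocks <- do.call(rbind, picked)
  check_that(!is.null(blocks) && nrow(blocks) > 0,
             "no exact match between contig core and locus")
  blocks <- blocks[order(blocks$q_start), , drop = FALSE]
  blocks$order <- seq_len(nrow(blocks))
  rownames(blocks) <- NULL
  ## unmatched contig core spans
  r <- rle(used)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  unmatched <- data.frame(q_start = starts[!r$values],
                          q_end = ends[!r$values])
  first <- blocks[1, ]; last <- blocks[nrow(blocks), ]
  tas <- data.frame(
    side = c("5p", "3p"),
    germline_pos = c(if (first$strand == "+") first$s_start else first$s_end,
                     if (last$strand == "+") last$s_end else last$s_start),
    stringsAsFactors = FALSE)
  structure(list(blocks = blocks, unmatched = unmatched,
                 telomere_addition = tas,
                 core = c(start = core_start, end = core_end)),
            class = "MdsDecomposition")
}

#' @export
print.MdsDecomposition <- function(x, ...) {
  cat(sprintf("MdsDecomposition: %d block(s), %d unmatched span(s)\n",
              nrow(x$blocks), nrow(x$unmatched)))
  print(x$blocks[, c("order", "q_start", "q_end", "s_start", "s_end",
                     "strand", "len")], row.names = FALSE)
  invisible(x)
}

## --- telomere addition sites from raw reads ----------------------------

#' Detect telomere addition sites from telomere-bearing reads
#'
#' Scans each read (both orientations) for a leading run of at least
#' `min_tail` tandem telomere units; the remaining portion (>= `min_anchor`
#' bp) must match the locus exactly and uniquely. The junction coordinate
#' is reported on the germline locus with the side the telomere extends
#' toward, aggregated with read support counts.
#'
#' @param reads named DNAStringSet or character vector.
#' @param locus germline locus sequence.
#' @param telomere_unit 5' telomere unit.
#' @param min_tail minimum complete tandem units (>= 2).
#' @param min_anchor minimum anchor length into the locus (bp).
#' @return data.frame (coordinate, side, support), one row per site,
#'   sorted by coordinate.
#' @export
detect_telomere_addition_sites <- function(reads, locus,
                                           telomere_unit = TELOMERE_UNIT_5P,
                                           min_tail = 2L, min_anchor = 20L) {
  check_that(min_tail >= 2, "min_tail must be >= 2 telomere units")
  if (methods::is(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  locus <- as.character(locus)
  nl <- nchar(locus)
  locus_rc <- revcomp(locus)
  sites <- list()
  for (orient_seq in list(reads, stats::setNames(revcomp(reads),
                                                 names(reads)))) {
    for (ri in seq_along(orient_seq)) {
      s <- orient_seq[[ri]]
      run <- telomere_run_5p(s, telomere_unit)
      if (run["units"] < min_tail) next
      rest <- substr(s, run["len"] + 1L, nchar(s))
      if (nchar(rest) < min_anchor) next
      fwd_hits <- gregexpr(rest, locus, fixed = TRUE)[[1]]
      rc_hits <- gregexpr(rest, locus_rc, fixed = TRUE)[[1]]
      n_f <- if (fwd_hits[1] == -1L) 0L else length(fwd_hits)
      n_r <- if (rc_hits[1] == -1L) 0L else length(rc_hits)
      if (n_f + n_r != 1L) next      # unmapped or ambiguous anchor
      if (n_f == 1L) {
        ## telomere sits 5' of the anchor on the top strand
        sites[[length(sites) + 1L]] <- data.frame(
          coordinate = as.integer(fwd_hits[1]), side = "5p",
          stringsAsFactors = FALSE)
      } else {
        ## anchor on the bottom strand: junction at the right edge
        start_rc <- as.integer(rc_hits[1])
        coord <- nl - start_rc + 1L
        sites[[length(sites) + 1L]] <- data.frame(
          coordinate = coord, side = "3p", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(sites)) {
    return(data.frame(coordinate = integer(), side = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, sites)
  agg <- stats::aggregate(list(support = rep(1L, nrow(df))),
                          by = list(coordinate = df$coordinate,
                                    side = df$side), FUN = sum)
  agg[order(agg$coordinate), , drop = FALSE]
}
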