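#' Partition two ChIP peak sets into shared and cell-type-specific sites
#'
#' A peak of one condition overlapping (>= 1 bp) any peak of the other is
#' shared; overlapping peaks are merged so that each shared cluster is
#' counted once.  Peaks without a partner are condition-specific.  Swapping
#' the inputs swaps `a_specific` and `b_specific` and preserves `shared`.
#'
#' @param peaks_a,peaks_b interval data.frames on the same genome.
#' @return list of class `chip_partition` with `shared` (merged cluster
#'   intervals), `a_specific`, `b_specific`.
#' @export
partition_peaks <- function(peaks_a, peaks_b) {
  validate_intervals(peaks_a, "peaks_a"); validate_intervals(peaks_b, "peaks_b")
  a_hit <- overlaps_any(peaks_a, peaks_b)
  b_hit <- overlaps_any(peaks_b, peaks_a)
  both <- rbind(peaks_a[a_hit, c("chrom", "start", "end"), drop = FALSE],
                peaks_b[b_hit, c("chrom", "start", "end"), drop = FALSE])
  shared <- if (nrow(both)) {
    A <- .ir_by_chrom(both)
    out <- do.call(rbind, lapply(names(A$ir), function(chr) {
      red <- IRanges::reduce(A$ir[[chr]])
      data.frame(chrom = chr, start = IRanges::start(red) - 1,
                 end = IRanges::end(red), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  } else data.frame(chrom = character(), start = numeric(), end = numeric())
  structure(list(shared = shared,
                 a_specific = `rownames<-`(peaks_a[!a_hit, , drop = FALSE], NULL),
                 b_specific = `rownames<-`(peaks_b[!b_hit, , drop = FALSE], NULL)),
            class = "chip_partition")
}

#' DAR-ChIP overlap rates stratified by TAD direction
#'
#' For each stratum (gained/lost DARs in up/down TADs) the percentage of DARs
#' overlapping (>= 1 bp) a ChIP peak, with the two-proportion test comparing
#' gained versus lost within each TAD-direction class.  Empty strata yield NA
#' percentages and are excluded from testing.
#'
#' @param dars a `dar_set`.
#' @param chip_peaks interval data.frame of binding sites.
#' @param strata a `dar_strata` from [link_dars_to_tads()].
#' @return list with `table` (per-stratum counts and percentages) and
#'   `tests` (named list of [proportion_test()] results, per TAD direction).
#' @export
dar_chip_overlap <- function(dars, chip_peaks, strata) {
  stopifnot(inherits(strata, "dar_strata"))
  hit_g <- overlaps_any(dars$gained, chip_peaks)
  hit_l <- overlaps_any(dars$lost, chip_peaks)
  rows <- list()
  for (dar_class in c("gained", "lost")) {
    hits <- if (dar_class == "gained") hit_g else hit_l
    str <- strata[[dar_class]]
    for (tad_dir in c("up", "down")) {
      sel <- str == tad_dir
      n <- sum(sel); k <- sum(hits[sel])
      rows[[paste(dar_class, tad_dir)]] <- data.frame(
        dar_class = dar_class, tad_direction = tad_dir, n = n, k = k,
        pct = if (n) 100 * k / n else NA_real_, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tests <- list()
  for (tad_dir in c("up", "down")) {
    g <- tab[tab$dar_class == "gained" & tab$tad_direction == tad_dir, ]
    l <- tab[tab$dar_class == "lost" & tab$tad_direction == tad_dir, ]
    tests[[tad_dir]] <- if (g$n > 0 && l$n > 0)
      proportion_test(g$k, g$n, l$k, l$n) else NULL
  }
  list(table = tab, tests = tests)
}

#' Fraction of binding loci overlapping lost DARs
#'
#' The fraction of ChIP loci with >= 1 bp overlap to a lost DAR, with a
#' companion two-proportion test against either a reference rate or a
#' reference locus set.
#'
#' @param loci interval data.frame of binding sites (non-empty).
#' @param dars a `dar_set`.
#' @param reference either a single rate in [0, 1], a reference interval set
#'   to compute the comparison rate from, or NULL for no test.
#' @return list with `fraction`, `k`, `n` and `test` (or NULL).
#' @export
chip_dar_fraction <- function(loci, dars, reference = NULL) {
  if (!nrow(loci)) stop("chip_dar_fraction: empty loci")
  hit <- overlaps_any(loci, dars$lost)
  k <- sum(hit); n <- nrow(loci)
  test <- NULL
  if (is.numeric(reference) && length(reference) == 1) {
    test <- proportion_test(k, n, round(reference * n), n)
  } else if (is.data.frame(reference) && nrow(reference)) {
    k2 <- sum(overlaps_any(reference, dars$lost))
    test <- proportion_test(k, n, k2, nrow(reference))
  }
  list(fraction = k / n, k = k, n = n, test = test)
}

#' Read-count matrix around peak summits
#'
#' One row per peak, centred on the summit midpoint, spanning +/-`flank` bp in
#' `bin`-bp bins; each cell is the number of track points in that bin, so a
#' row sums to the number of points within the flank.
#'
#' @param peaks `peaks` data.frame with `summit_start`, `summit_end` (falls
#'   back to the interval midpoint when absent).
#' @param track a [coverage_track()].
#' @param flank half-window, bp (default 2000: 4 kb displayed in total).
#' @param bin bin width, bp (default 50; must divide `2 * flank`).
#' @return numeric matrix `nrow(peaks)` x `2 * flank / bin`.
#' @export
signal_matrix <- function(peaks, track, flank = 2000, bin = 50) {
  if ((2 * flank) %% bin != 0) stop("signal_matrix: bin must divide 2*flank")
  centers <- if (all(c("summit_start", "summit_end") %in% names(peaks)))
    floor((peaks$summit_start + peaks$summit_end) / 2)
  else floor((peaks$start + peaks$end) / 2)
  ncol <- 2 * flank / bin
  m <- matrix(0, nrow = nrow(peaks), ncol = ncol)
  edges <- seq(-flank, flank, by = bin)
  for (i in seq_len(nrow(peaks))) {
    pos <- track$positions[[peaks$chrom[i]]]
    if (is.null(pos)) next
    m[i, ] <- .count_between(pos, centers[i] + edges[-length(edges)],
                             centers[i] + edges[-1])
  }
  rownames(m) <- if ("name" %in% names(peaks)) peaks$name else
    paste0(peaks$chrom, ":", format_coord(peaks$start), "-", format_coord(peaks$end))
  m
}

#' Deterministic k-means ordering of a signal matrix
#'
#' Rows are scaled to unit total (all-zero rows are left as zeros), k-means is
#' run from a seeded farthest-point initialisation (first centre drawn at
#' random, each further centre the row farthest from all chosen ones),
#' clusters are relabelled by decreasing mean raw row signal, and the row
#' order sorts by cluster then original position.  The returned order can be
#' applied to a second matrix (e.g. accessibility signal at the same loci).
#'
#' @param m numeric matrix (rows = loci).
#' @param k number of clusters, `1 <= k <= nrow(m)`.
#' @param seed RNG seed.
#' @param iter_max maximal k-means iterations.
#' @return list with `labels` (1 = strongest cluster) and `order` (row
#'   permutation).
#' @export
kmeans_order <- function(m, k = 2, seed = 1, iter_max = 100) {
  if (k < 1) stop("kmeans_order: k must be >= 1")
  if (k > nrow(m)) stop("kmeans_order: k exceeds number of rows")
  rs <- rowSums(m)
  scaled <- m / ifelse(rs == 0, 1, rs)
  if (k == 1) {
    labels <- rep(1L, nrow(m))
  } else {
    set.seed(seed)
    centers <- matrix(0, nrow = k, ncol = ncol(m))
    first <- sample.int(nrow(m), 1)
    centers[1, ] <- scaled[first, ]
    d2 <- colSums((t(scaled) - centers[1, ])^2)
    for (j in seq_len(k - 1)) {
      nxt <- which.max(d2)
      centers[j + 1, ] <- scaled[nxt, ]
      d2 <- pmin(d2, colSums((t(scaled) - centers[j + 1, ])^2))
    }
    km <- suppressWarnings(stats::kmeans(scaled, centers = centers,
                                         iter.max = iter_max))
    labels <- km$cluster
  }
  strength <- tapply(rs, labels, mean)
  rank_map <- rank(-strength, ties.method = "first")
  labels <- as.integer(rank_map[as.character(labels)])
  ord <- order(labels, seq_along(labels))
  list(labels = labels, order = ord)
}

#' Sliding-window 4C contact profile
#'
#' Sums per-restriction-site read counts in sliding windows (default 50 kb
#' with 25-kb steps).  Window starts are the multiples of `step` from 0 up to
#' the last site (or `chrom_len` when given), so the final, possibly partial,
#' window still covers the chromosome end.  The profile is linear in the
#' counts.
#'
#' @param sites data.frame with `chrom`, `pos` (restriction-site position,
#'   bp) and `count` (reads on that site).
#' @param window window width, bp.
#' @param step step between window starts, bp.
#' @param chrom_len optional named vector of chromosome lengths.
#' @return data.frame with `chrom`, `start`, `end`, `value`, one row per
#'   window, ordered by chromosome and start.
#' @export
fourc_profile <- function(sites, window = 50000, step = 25000, chrom_len = NULL) {
  stopifnot(all(c("chrom", "pos", "count") %in% names(sites)),
            window > 0, step > 0)
  out <- list()
  for (chr in unique(sites$chrom)) {
    s <- sites[sites$chrom == chr, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    last <- if (!is.null(chrom_len) && chr %in% names(chrom_len))
      chrom_len[[chr]] else max(s$pos) + 1
    starts <- seq(0, max(0, last - 1), by = step)
    cum <- c(0, cumsum(s$count))
    upto <- function(x) cum[findInterval(x - 0.5, s$pos) + 1]
    value <- upto(starts + window) - upto(starts)
    out[[chr]] <- data.frame(chrom = chr, start = starts,
                             end = starts + window, value = value,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
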