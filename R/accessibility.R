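#' Coverage track of adjusted read-start points
#'
#' A light container holding, per chromosome, the sorted positions of
#' transposase-insertion centers (or any read-start points).
#'
#' @param points data.frame with `chrom`, `pos` (0-based bp).
#' @param condition,replicate optional labels.
#' @return list of class `coverage_track` with `positions` (named list of
#'   sorted numeric vectors), `total`, `condition`, `replicate`.
#' @export
coverage_track <- function(points, condition = NA_character_, replicate = NA_character_) {
  stopifnot(all(c("chrom", "pos") %in% names(points)))
  if (any(points$pos < 0)) stop("coverage_track: negative position")
  positions <- lapply(split(points$pos, points$chrom), sort)
  structure(list(positions = positions,
                 total = nrow(points),
                 condition = condition, replicate = replicate),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$total, "points on", length(x$positions),
      "chromosome(s)")
  if (!is.na(x$condition)) cat(" [", x$condition, "]", sep = "")
  cat("\n")
  invisible(x)
}

# combine tracks (e.g. replicates) into one
track_merge <- function(..., condition = NA_character_) {
  tracks <- list(...)
  pts <- do.call(rbind, lapply(tracks, function(t)
    data.frame(chrom = rep(names(t$positions), lengths(t$positions)),
               pos = unlist(t$positions, use.names = FALSE))))
  coverage_track(pts, condition = condition)
}

# seeded subsample without replacement to n points
track_subsample <- function(track, n, seed) {
  if (n > track$total) stop("track_subsample: n exceeds track total")
  set.seed(seed)
  chrom <- rep(names(track$positions), lengths(track$positions))
  pos <- unlist(track$positions, use.names = FALSE)
  keep <- sample.int(length(pos), n)
  coverage_track(data.frame(chrom = chrom[keep], pos = pos[keep]),
                 condition = track$condition, replicate = track$replicate)
}

#' Adjust raw reads to transposase insertion centers
#'
#' Shifts each read start to the center of the transposition event: on the
#' plus strand the adjusted point is `start + shift_plus`; on the minus strand
#' `end - shift_minus` (defaults +4/-5, the Tn5 dyad convention).  Adjusted
#' positions below 0 are clamped to 0.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param shift_plus,shift_minus strand-specific offsets in bp; `(0, 0)`
#'   applied to 1-bp reads leaves positions unchanged.
#' @param condition,replicate labels for the resulting track.
#' @return a [coverage_track()].
#' @export
adjust_reads <- function(reads, shift_plus = 4L, shift_minus = 5L,
                         condition = NA_character_, replicate = NA_character_) {
  validate_intervals(reads, "reads")
  if (!"strand" %in% names(reads) || any(!reads$strand %in% c("+", "-")))
    stop("adjust_reads: every read needs strand + or -")
  pos <- ifelse(reads$strand == "+", reads$start + shift_plus,
                reads$end - shift_minus)
  n_clamp <- sum(pos < 0)
  if (n_clamp > 0) {
    message("adjust_reads: clamped ", n_clamp, " position(s) below 0")
    pos <- pmax(pos, 0)
  }
  coverage_track(data.frame(chrom = reads$chrom, pos = pos),
                 condition = condition, replicate = replicate)
}

#' Upper tail of the Poisson distribution
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`, computed stably for very small tail
#' probabilities.  `k = 0` returns 1 for any rate.
#'
#' @param k non-negative integer count (vectorised).
#' @param lam positive expectation (vectorised).
#' @return tail probability.
#' @export
poisson_tail <- function(k, lam) {
  if (any(lam <= 0)) stop("poisson_tail: lam must be > 0")
  if (any(k < 0) || any(k != floor(k))) stop("poisson_tail: k must be a non-negative integer")
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

#' Peak-calling parameters
#'
#' Defaults mirror an accessibility analysis run with a 150-bp scanning
#' window, reads extended +/-75 bp (shift), a 25-kb span for the local
#' background rate, and a Poisson tail threshold of 1e-4.
#'
#' @param window scanning window, bp (also the summit width).
#' @param local_lambda_span span for the local background estimate, bp.
#' @param p_threshold Poisson tail probability below which a window is
#'   significant.
#' @param shift half-extension of each read point for window counting, bp.
#' @param merge_gap maximal gap between significant windows merged into one
#'   peak, bp.
#' @return list of class `peak_call_params`.
#' @export
peak_call_params <- function(window = 150, local_lambda_span = 25000,
                             p_threshold = 1e-4, shift = 75, merge_gap = 100) {
  stopifnot(window > 0, local_lambda_span > 0, shift > 0, merge_gap > 0,
            p_threshold > 0, p_threshold < 1)
  structure(list(window = window, local_lambda_span = local_lambda_span,
                 p_threshold = p_threshold, shift = shift,
                 merge_gap = merge_gap),
            class = "peak_call_params")
}

# count of sorted points p with lo <= p < hi (vectorised over lo/hi)
.count_between <- function(pos, lo, hi) {
  findInterval(hi - 0.5, pos) - findInterval(lo - 0.5, pos)
}

# Window scan shared by solo and comparative calling.  Counts come from
# track_fg; the expectation comes from track_lam (equal to track_fg for solo
# calls), depth-scaled to the foreground.  In comparative mode
# (window_lambda = TRUE) the background's count in the window itself also
# enters the expectation, so regions equally covered in both tracks are not
# called; solo calls must not do this (the window would explain itself away).
.scan_regions <- function(track_fg, track_lam, chrom_sizes, params,
                          window_lambda = FALSE) {
  w <- params$window; sh <- params$shift; ll <- params$local_lambda_span
  step <- max(1, floor(w / 2))
  genome_len <- sum(chrom_sizes)
  if (track_lam$total == 0) stop("peak calling: empty background track")
  ratio <- track_fg$total / track_lam$total
  rate_g <- track_lam$total / genome_len * ratio
  span <- w + 2 * sh
  out <- list()
  for (chr in names(chrom_sizes)) {
    pos <- track_fg$positions[[chr]]
    if (is.null(pos) || !length(pos)) next
    lpos <- track_lam$positions[[chr]]
    if (is.null(lpos)) lpos <- numeric(0)
    starts <- seq(0, max(0, chrom_sizes[[chr]] - w), by = step)
    k <- .count_between(pos, starts - sh, starts + w + sh)
    centers <- starts + w / 2
    k_loc <- .count_between(lpos, centers - ll / 2, centers + ll / 2)
    lam_loc <- k_loc / ll * ratio * span
    lam <- pmax(rate_g * span, lam_loc)
    if (window_lambda) {
      k_win <- .count_between(lpos, starts - sh, starts + w + sh)
      lam <- pmax(lam, k_win * ratio)
    }
    p <- poisson_tail(k, lam)
    sig <- which(p < params$p_threshold & k > 0)
    if (!length(sig)) next
    s <- starts[sig]; e <- s + w; pv <- p[sig]
    grp <- cumsum(c(1, (s[-1] - e[-length(e)]) > params$merge_gap))
    out[[chr]] <- data.frame(
      chrom = chr,
      start = tapply(s, grp, min),
      end = tapply(e, grp, max),
      p_value = tapply(pv, grp, min),
      row.names = NULL)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      p_value = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# leftmost maximal-count window of width `w` inside [pk_start, pk_end)
.summit <- function(pos, pk_start, pk_end, w) {
  lo <- pk_start; hi <- max(pk_start, pk_end - w)
  inside <- pos[pos >= pk_start & pos < pk_end]
  cand <- sort(unique(pmin(pmax(c(lo, inside - (w - 1), hi), lo), hi)))
  cnt <- .count_between(sort(inside), cand, cand + w)
  s <- cand[which.max(cnt)]  # which.max is leftmost on ties
  c(s, s + w)
}

#' Call peaks with a fixed-window local-Poisson scan
#'
#' Slides a `window`-bp window in half-window steps; each read point is
#' extended +/-`shift` bp for counting.  The window expectation is the larger
#' of the genome-wide rate and the local rate over `local_lambda_span`, and a
#' window is significant when its Poisson upper-tail probability falls below
#' `p_threshold`.  Significant windows closer than `merge_gap` are merged into
#' one peak, whose summit is the leftmost maximal-count window of width
#' `window` (computed from unextended points).
#'
#' @param track a [coverage_track()].
#' @param chrom_sizes named numeric vector of chromosome lengths, bp.
#' @param params a [peak_call_params()].
#' @return data.frame of class `peaks`: `chrom`, `start`, `end`,
#'   `summit_start`, `summit_end`, `read_count`, `p_value`, `condition`.
#' @export
call_peaks <- function(track, chrom_sizes, params = peak_call_params()) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$total == 0)
    return(.regions_to_peaks(data.frame(chrom = character(), start = numeric(),
                                        end = numeric(), p_value = numeric()),
                             track, params))
  reg <- .scan_regions(track, track, chrom_sizes, params)
  .regions_to_peaks(reg, track, params)
}

.regions_to_peaks <- function(reg, track, params) {
  n <- nrow(reg)
  summit_start <- summit_end <- read_count <- numeric(n)
  for (i in seq_len(n)) {
    pos <- track$positions[[reg$chrom[i]]]
    sm <- .summit(pos, reg$start[i], reg$end[i], params$window)
    summit_start[i] <- sm[1]; summit_end[i] <- sm[2]
    read_count[i] <- .count_between(pos, reg$start[i], reg$end[i])
  }
  out <- data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                    summit_start = summit_start, summit_end = summit_end,
                    read_count = read_count, p_value = reg$p_value,
                    condition = rep(track$condition, n),
                    stringsAsFactors = FALSE)
  out <- out[out$read_count >= 1, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  out
}

#' Call differentially accessible regions (DARs)
#'
#' Runs the comparative scan of each condition against the other (counts from
#' one sample, expectation from the other, depth-scaled) and intersects it
#' with the per-condition solo peak calls: a transformed-condition peak
#' overlapping (>= 1 bp) a significant transformed-over-parental region is a
#' *gained* DAR; the symmetric case is *lost*; every remaining solo peak of
#' either condition is *shared*.
#'
#' @param peaks_parental,peaks_transformed solo [call_peaks()] results.
#' @param track_parental,track_transformed the corresponding tracks.
#' @param chrom_sizes named chromosome lengths.
#' @param params a [peak_call_params()] (used for the comparative scans).
#' @return list of class `dar_set` with `gained`, `lost`, `shared` peak
#'   data.frames; gained/lost peaks carry the comparative `p_comparative`.
#' @export
call_dars <- function(peaks_parental, peaks_transformed,
                      track_parental, track_transformed,
                      chrom_sizes, params = peak_call_params()) {
  comp_gain <- .scan_regions(track_transformed, track_parental, chrom_sizes,
                             params, window_lambda = TRUE)
  comp_loss <- .scan_regions(track_parental, track_transformed, chrom_sizes,
                             params, window_lambda = TRUE)
  gained_hit <- overlaps_any(peaks_transformed, comp_gain)
  lost_hit <- overlaps_any(peaks_parental, comp_loss)
  attach_p <- function(peaks, mask, comp) {
    sel <- peaks[mask, , drop = FALSE]
    sel$p_comparative <- rep(NA_real_, nrow(sel))
    if (nrow(sel) && nrow(comp)) {
      pr <- intersect_sets(sel, comp)
      if (nrow(pr))
        sel$p_comparative[] <- vapply(seq_len(nrow(sel)), function(i) {
          j <- pr$b_idx[pr$a_idx == i]
          if (length(j)) min(comp$p_value[j]) else NA_real_
        }, numeric(1))
    }
    rownames(sel) <- NULL
    sel
  }
  gained <- attach_p(peaks_transformed, gained_hit, comp_gain)
  lost <- attach_p(peaks_parental, lost_hit, comp_loss)
  shared <- rbind(peaks_parental[!lost_hit, , drop = FALSE],
                  peaks_transformed[!gained_hit, , drop = FALSE])
  rownames(shared) <- NULL
  structure(list(gained = gained, lost = lost, shared = shared),
            class = "dar_set")
}

#' @export
print.dar_set <- function(x, ...) {
  cat("dar_set: ", nrow(x$gained), " gained, ", nrow(x$lost), " lost, ",
      nrow(x$shared), " shared\n", sep = "")
  invisible(x)
}

#' Peak annotation parameters
#'
#' @param promoter_upstream,promoter_downstream promoter window around the
#'   TSS, bp (strand-aware; defaults 1000 up / 500 down).
#' @param midrange span of the distal regulatory window on each side of the
#'   TSS, bp (default 100 kb).
#' @return list of class `annotation_params`.
#' @export
annotation_params <- function(promoter_upstream = 1000, promoter_downstream = 500,
                              midrange = 100000) {
  stopifnot(promoter_upstream > 0, promoter_downstream > 0, midrange > 0)
  structure(list(promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 midrange = midrange),
            class = "annotation_params")
}

# strand-aware TSS (0-based position of the first transcribed base)
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

# strand-aware windows around the TSS; `up`/`down` in transcription sense.
# The TSS base itself is inside the downstream part on both strands.
.tss_windows <- function(genes, up, down) {
  tss <- gene_tss(genes)
  b <- ifelse(genes$strand == "+", tss, tss + 1)
  start <- ifelse(genes$strand == "+", b - up, b - down)
  end <- ifelse(genes$strand == "+", b + down, b + up)
  data.frame(chrom = genes$chrom, start = pmax(0, start), end = end,
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}

#' Annotate peaks relative to gene features
#'
#' Labels each peak exactly once with priority promoter > midrange > far: a
#' peak overlapping (>= 1 bp) any promoter window (`promoter_upstream` bp
#' upstream to `promoter_downstream` bp downstream of a TSS, strand-aware) is
#' `promoter`; otherwise a peak overlapping any +/-`midrange` TSS window is
#' `midrange`; otherwise `far`.
#'
#' @param peaks interval data.frame.
#' @param genes gene table with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param params an [annotation_params()].
#' @return list of class `peak_annotation` with `labels` (per-peak character)
#'   and `proportions` (named, sums to 1).
#' @export
annotate_location <- function(peaks, genes, params = annotation_params()) {
  if (!"strand" %in% names(genes) || any(!genes$strand %in% c("+", "-")))
    stop("annotate_location: every gene needs strand + or -")
  prom <- .tss_windows(genes, params$promoter_upstream, params$promoter_downstream)
  mid <- .tss_windows(genes, params$midrange, params$midrange)
  labels <- rep("far", nrow(peaks))
  labels[overlaps_any(peaks, mid)] <- "midrange"
  labels[overlaps_any(peaks, prom)] <- "promoter"
  props <- if (nrow(peaks)) {
    tab <- table(factor(labels, levels = c("promoter", "midrange", "far")))
    as.numeric(tab) / nrow(peaks)
  } else rep(NA_real_, 3)
  names(props) <- c("promoter", "midrange", "far")
  structure(list(labels = labels, proportions = props, params = params),
            class = "peak_annotation")
}

#' Promoter accessibility change versus expression direction
#'
#' Counts gained and lost DARs that overlap the promoter of an up- or a
#' down-regulated gene (each DAR counted once, assigned to the DE-gene
#' promoter it overlaps most; ties to the lexicographically smallest gene id)
#' and tests whether the up-gene share differs between gained and lost with
#' the two-proportion test.
#'
#' @param dars a `dar_set` from [call_dars()].
#' @param genes gene table with strand.
#' @param de named DE status vector from [classify_de()].
#' @param params an [annotation_params()].
#' @return list with `counts` (2x2 matrix gained/lost x up/down),
#'   `proportions` (up-gene share per DAR class), `test`
#'   (a [proportion_test()] or NULL) and `flagged`.
#' @export
promoter_direction_table <- function(dars, genes, de, params = annotation_params()) {
  prom <- .tss_windows(genes, params$promoter_upstream, params$promoter_downstream)
  prom$status <- unname(de[prom$gene_id])
  prom_de <- prom[prom$status %in% c("up", "down"), , drop = FALSE]
  count_class <- function(peaks) {
    if (!nrow(peaks) || !nrow(prom_de)) return(c(up = 0, down = 0))
    pr <- intersect_sets(peaks, prom_de)
    if (!nrow(pr)) return(c(up = 0, down = 0))
    # one DE-gene promoter per DAR: largest overlap, then smallest gene id
    pr$gene_id <- prom_de$gene_id[pr$b_idx]
    pr <- pr[order(pr$a_idx, -pr$overlap_bp, pr$gene_id), ]
    pr <- pr[!duplicated(pr$a_idx), ]
    st <- prom_de$status[pr$b_idx]
    c(up = sum(st == "up"), down = sum(st == "down"))
  }
  cg <- count_class(dars$gained); cl <- count_class(dars$lost)
  counts <- rbind(gained = cg, lost = cl)
  n_g <- sum(cg); n_l <- sum(cl)
  flagged <- n_g == 0 || n_l == 0
  proportions <- c(gained = if (n_g) cg["up"] / n_g else NA_real_,
                   lost = if (n_l) cl["up"] / n_l else NA_real_)
  names(proportions) <- c("gained", "lost")
  test <- if (!flagged) proportion_test(cg["up"], n_g, cl["up"], n_l) else NULL
  list(counts = counts, proportions = proportions, test = test, flagged = flagged)
}

#' Replicate correlation QC
#'
#' Subsamples each replicate (without replacement) to the same depth, calls
#' peaks in each, merges the two peak sets into union intervals, counts
#' subsampled reads of each replicate in every merged interval, and returns
#' the Pearson correlation of the two count vectors.
#'
#' @param rep1,rep2 [coverage_track()]s of the two replicates.
#' @param chrom_sizes named chromosome lengths.
#' @param n_subsample target depth; default the smaller replicate total.
#' @param seed subsampling seed.
#' @param params a [peak_call_params()].
#' @return list with `r` (NA and `flagged = TRUE` when fewer than 2 merged
#'   peaks), `n_peaks`, `counts1`, `counts2`.
#' @export
replicate_correlation <- function(rep1, rep2, chrom_sizes, n_subsample = NULL,
                                  seed = 1, params = peak_call_params()) {
  if (is.null(n_subsample)) n_subsample <- min(rep1$total, rep2$total)
  s1 <- if (n_subsample < rep1$total) track_subsample(rep1, n_subsample, seed) else rep1
  s2 <- if (n_subsample < rep2$total) track_subsample(rep2, n_subsample, seed + 1) else rep2
  p1 <- call_peaks(s1, chrom_sizes, params)
  p2 <- call_peaks(s2, chrom_sizes, params)
  both <- rbind(p1[c("chrom", "start", "end")], p2[c("chrom", "start", "end")])
  if (!nrow(both))
    return(list(r = NA_real_, n_peaks = 0L, counts1 = numeric(), counts2 = numeric(),
                flagged = TRUE))
  A <- .ir_by_chrom(both)
  merged <- do.call(rbind, lapply(names(A$ir), function(chr) {
    red <- IRanges::reduce(A$ir[[chr]])
    data.frame(chrom = chr, start = IRanges::start(red) - 1, end = IRanges::end(red))
  }))
  if (nrow(merged) < 2)
    return(list(r = NA_real_, n_peaks = nrow(merged), counts1 = numeric(),
                counts2 = numeric(), flagged = TRUE))
  count_track <- function(track) {
    vapply(seq_len(nrow(merged)), function(i) {
      pos <- track$positions[[merged$chrom[i]]]
      if (is.null(pos)) 0 else .count_between(pos, merged$start[i], merged$end[i])
    }, numeric(1))
  }
  c1 <- count_track(s1); c2 <- count_track(s2)
  list(r = stats::cor(c1, c2), n_peaks = nrow(merged), counts1 = c1, counts2 = c2,
       flagged = FALSE)
}
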