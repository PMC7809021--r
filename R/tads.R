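#' Merge per-cell-line TAD sets into one dataset
#'
#' Concatenates the TAD lists of several cell lines, keeping the source label
#' of each domain (no union-flattening: nested and overlapping domains from
#' different sources are retained, which is what makes smallest-TAD
#' assignment meaningful).  Exact duplicates on `(chrom, start, end)` are
#' kept once (first source wins).
#'
#' @param tad_sets named list of interval data.frames, one per cell line.
#' @return interval data.frame with a `source` column.
#' @export
merge_tad_sets <- function(tad_sets) {
  stopifnot(is.list(tad_sets), length(tad_sets) >= 1)
  if (is.null(names(tad_sets)) || any(!nzchar(names(tad_sets))))
    names(tad_sets) <- paste0("cellline", seq_along(tad_sets))
  parts <- lapply(names(tad_sets), function(src) {
    df <- tad_sets[[src]]
    validate_intervals(df, paste0("TADs[", src, "]"))
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               source = src, stringsAsFactors = FALSE)
  })
  all_tads <- do.call(rbind, parts)
  key <- paste(all_tads$chrom, all_tads$start, all_tads$end)
  out <- all_tads[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign each gene to its smallest overlapping TAD
#'
#' Among the TADs that overlap a gene body by at least 1 bp, the gene is
#' assigned the one of minimal length; ties break to the leftmost start, then
#' to the lexicographically smallest source label.  Genes overlapping no TAD
#' are unassigned (NA).
#'
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, ...).
#' @param tads merged TAD table from [merge_tad_sets()].
#' @return list of class `tad_assignment` with `tad` (named integer vector of
#'   row indices into `tads`, NA when unassigned), `genes`, `tads`.
#' @export
assign_smallest_tad <- function(genes, tads) {
  validate_intervals(genes, "genes"); validate_intervals(tads, "tads")
  src <- if ("source" %in% names(tads)) tads$source else rep("", nrow(tads))
  assignment <- rep(NA_integer_, nrow(genes))
  pr <- intersect_sets(genes, tads)
  if (nrow(pr)) {
    len <- tads$end[pr$b_idx] - tads$start[pr$b_idx]
    o <- order(pr$a_idx, len, tads$start[pr$b_idx], src[pr$b_idx])
    pr <- pr[o, , drop = FALSE]
    first <- pr[!duplicated(pr$a_idx), , drop = FALSE]
    assignment[first$a_idx] <- first$b_idx
  }
  names(assignment) <- genes$gene_id
  structure(list(tad = assignment, genes = genes, tads = tads),
            class = "tad_assignment")
}

#' Declare the expression direction of each TAD
#'
#' A TAD is `up` when it contains at least one up-regulated gene and no
#' down-regulated one; `down` symmetrically; `mixed` when it contains both;
#' `none` when it contains neither.
#'
#' @param assignment a [assign_smallest_tad()] result.
#' @param de named DE status vector from [classify_de()].
#' @return character vector over `c("up","down","mixed","none")`, one entry
#'   per row of `assignment$tads`.
#' @export
declare_direction <- function(assignment, de) {
  stopifnot(inherits(assignment, "tad_assignment"))
  status <- unname(de[names(assignment$tad)])
  .direction_from_labels(assignment$tad, status, nrow(assignment$tads))
}

# core direction logic, reused by the permutation loop
.direction_from_labels <- function(tad_idx, status, n_tads) {
  keep <- !is.na(tad_idx) & !is.na(status)
  has_up <- has_down <- logical(n_tads)
  up_t <- unique(tad_idx[keep & status == "up"])
  down_t <- unique(tad_idx[keep & status == "down"])
  has_up[up_t] <- TRUE; has_down[down_t] <- TRUE
  dir <- rep("none", n_tads)
  dir[has_up & !has_down] <- "up"
  dir[!has_up & has_down] <- "down"
  dir[has_up & has_down] <- "mixed"
  dir
}

#' Genomic overlap (in Mb) between two TAD footprints
#'
#' Each set's footprint is the union of its member intervals; the statistic is
#' the total bp of the intersection of the two footprints, divided by 1e6.
#' The sets may share members (a mixed-direction TAD belongs to both).
#'
#' @param tads_up,tads_down interval data.frames.
#' @return overlap in Mb.
#' @export
tad_overlap_mb <- function(tads_up, tads_down) {
  footprint_intersect_bp(tads_up, tads_down) / 1e6
}

# vectorised base-R interval union (sorted, disjoint)
.union_intervals <- function(s, e) {
  n <- length(s)
  if (!n) return(list(s = numeric(0), e = numeric(0)))
  o <- order(s); s <- s[o]; e <- e[o]
  cme <- cummax(e)
  idx <- which(c(TRUE, s[-1] > cme[-n]))
  list(s = s[idx], e = cme[c(idx[-1] - 1L, n)])
}

# bp of intersection of two interval unions (half-open; sweep line)
.inter_len <- function(a, b) {
  if (!length(a$s) || !length(b$s)) return(0)
  ev <- c(a$s, b$s, a$e, b$e)
  step <- rep(c(1, -1), c(length(a$s) + length(b$s), length(a$e) + length(b$e)))
  o <- order(ev, step)  # ends before starts at equal coordinates (half-open)
  ev <- ev[o]
  cov <- cumsum(step[o])
  sum(diff(ev) * (utils::head(cov, -1) == 2))
}

#' Permutation test for the genomic segregation of up and down domains
#'
#' The observed statistic is the Mb overlap between the footprint of up TADs
#' and the footprint of down TADs (mixed TADs enter both footprints).  Each
#' permutation shuffles the up/down labels over the fixed set of DE genes
#' (preserving the up and down counts and the gene-to-TAD memberships),
#' re-declares TAD directions and recomputes the overlap.  The empirical
#' lower-tail p-value is `(1 + #[null <= observed]) / (n_perm + 1)`: small
#' when the real up and down domains overlap less than expected by chance.
#'
#' @param assignment a [assign_smallest_tad()] result.
#' @param de named DE status vector.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `permutation_result` with `observed_mb`, `null_mb`,
#'   `p_lower`, `n_perm`, `seed`.
#' @export
segregation_permutation <- function(assignment, de, n_perm = 1000, seed) {
  stopifnot(inherits(assignment, "tad_assignment"))
  if (n_perm < 1) stop("segregation_permutation: n_perm must be >= 1")
  if (missing(seed)) stop("segregation_permutation: seed is required")
  status <- unname(de[names(assignment$tad)])
  de_idx <- which(status %in% c("up", "down"))
  if (!any(status[de_idx] == "up") || !any(status[de_idx] == "down")) {
    # single-direction (or empty) DE set: overlap is 0 observed and in every
    # permutation, so the test is degenerate; flag rather than fail
    return(structure(list(observed_mb = 0, null_mb = rep(0, n_perm),
                          p_lower = 1, n_perm = n_perm, seed = seed,
                          flagged = TRUE),
                     class = "permutation_result"))
  }
  tads <- assignment$tads
  n_tads <- nrow(tads)
  # the permutation loop avoids the S4 interval machinery: footprints are
  # intersected with a base-R sweep (cross-checked against tad_overlap_mb
  # by the enumeration tests)
  chrom_idx <- split(seq_len(n_tads), tads$chrom)
  overlap_of <- function(lab_full) {
    dir <- .direction_from_labels(assignment$tad, lab_full, n_tads)
    up <- dir == "up" | dir == "mixed"
    down <- dir == "down" | dir == "mixed"
    bp <- 0
    for (i in chrom_idx) {
      iu <- i[up[i]]; id <- i[down[i]]
      if (!length(iu) || !length(id)) next
      bp <- bp + .inter_len(.union_intervals(tads$start[iu], tads$end[iu]),
                            .union_intervals(tads$start[id], tads$end[id]))
    }
    bp / 1e6
  }
  observed <- overlap_of(status)
  labels_de <- status[de_idx]
  set.seed(seed)
  null_mb <- vapply(seq_len(n_perm), function(i) {
    perm <- status
    perm[de_idx] <- sample(labels_de)
    overlap_of(perm)
  }, numeric(1))
  structure(list(observed_mb = observed, null_mb = null_mb,
                 p_lower = empirical_p(observed, null_mb, "lower"),
                 n_perm = n_perm, seed = seed, flagged = FALSE),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("segregation permutation: observed %.3f Mb, null mean %.3f Mb, p_lower = %.4g (n_perm = %d)\n",
              x$observed_mb, mean(x$null_mb), x$p_lower, x$n_perm))
  invisible(x)
}

#' Peak density in up versus down TADs
#'
#' Density of a TAD is the number of peaks overlapping it (>= 1 bp) divided by
#' its length in Mb.  Densities of up TADs and down TADs (mixed excluded) are
#' compared with the two-sided Mann-Whitney test.
#'
#' @param peaks interval data.frame.
#' @param tads merged TAD table.
#' @param direction per-TAD direction from [declare_direction()].
#' @return list with `density` (per-TAD data.frame), `test`
#'   (a [mann_whitney()] or NULL) and `flagged` (TRUE when either class is
#'   empty, in which case no test is run).
#' @export
peak_density_by_tad <- function(peaks, tads, direction) {
  stopifnot(length(direction) == nrow(tads))
  n_ov <- integer(nrow(tads))
  pr <- intersect_sets(tads, peaks)
  if (nrow(pr)) {
    tab <- table(pr$a_idx[!duplicated(paste(pr$a_idx, pr$b_idx))])
    n_ov[as.integer(names(tab))] <- as.integer(tab)
  }
  density <- data.frame(tad = seq_len(nrow(tads)), direction = direction,
                        n_peaks = n_ov,
                        density = n_ov / ((tads$end - tads$start) / 1e6))
  x <- density$density[direction == "up"]
  y <- density$density[direction == "down"]
  flagged <- !length(x) || !length(y)
  test <- if (!flagged) mann_whitney(x, y) else NULL
  list(density = density, test = test, flagged = flagged)
}

#' Stratify DARs by the direction of their TAD
#'
#' Each gained or lost DAR overlapping (>= 1 bp) an up- or down-directed TAD
#' receives that stratum; a DAR overlapping both directions (possible with
#' merged nested TADs) goes to the smallest overlapping directional TAD;
#' mixed TADs are not directional; everything else is `outside`.
#'
#' @param dars a `dar_set`.
#' @param tads merged TAD table.
#' @param direction per-TAD direction vector.
#' @return list of class `dar_strata` with `gained` and `lost` character
#'   vectors over `c("up", "down", "outside")`.
#' @export
link_dars_to_tads <- function(dars, tads, direction) {
  stopifnot(length(direction) == nrow(tads))
  dir_idx <- which(direction %in% c("up", "down"))
  dir_tads <- tads[dir_idx, , drop = FALSE]
  strat <- function(peaks) {
    out <- rep("outside", nrow(peaks))
    if (!nrow(peaks) || !nrow(dir_tads)) return(out)
    pr <- intersect_sets(peaks, dir_tads)
    if (!nrow(pr)) return(out)
    len <- dir_tads$end[pr$b_idx] - dir_tads$start[pr$b_idx]
    pr <- pr[order(pr$a_idx, len, dir_tads$start[pr$b_idx]), , drop = FALSE]
    first <- pr[!duplicated(pr$a_idx), , drop = FALSE]
    out[first$a_idx] <- direction[dir_idx][first$b_idx]
    out
  }
  structure(list(gained = strat(dars$gained), lost = strat(dars$lost)),
            class = "dar_strata")
}
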