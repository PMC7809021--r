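#' Planted-truth recovery metrics for one simulated dataset
#'
#' Runs the analysis stages that have planted counterparts in the generator
#' and measures how well each planted quantity is recovered: the DAR
#' region-level Jaccard against the planted intervals, the segregation
#' permutation p-value, the enrichment p-values of the gained-direction and
#' lost-direction motifs in their matching DAR summits, the overall ChIP
#' co-location rates of gained and lost DARs, and the treatment-response
#' contrast of the motif-bearing down-regulated group against all expressed
#' genes.
#'
#' @param params a [sim_params()] object.
#' @param n_perm permutations for the segregation test.
#' @return named numeric vector with `dar_jaccard`, `n_gained`, `n_lost`,
#'   `segregation_p`, `motif_gained_p`, `motif_lost_p`, `chip_gained_rate`,
#'   `chip_lost_rate`, `nutlin_p`.
#' @export
planted_recovery_metrics <- function(params, n_perm = 1000) {
  d <- simulate_dataset(params)
  de <- classify_de(d$expression)
  tracks <- lapply(stats::setNames(nm = names(d$reads)), function(cond) {
    reps <- lapply(d$reads[[cond]], adjust_reads, condition = cond)
    do.call(track_merge, c(reps, list(condition = cond)))
  })
  pk <- lapply(tracks, call_peaks, chrom_sizes = d$chrom_sizes)
  dars <- call_dars(pk$parental, pk$transformed, tracks$parental,
                    tracks$transformed, d$chrom_sizes)
  assignment <- assign_smallest_tad(d$genes, merge_tad_sets(d$tads))
  seg <- segregation_permutation(assignment, de, n_perm,
                                 seed = derive_seed(params$seed, "segregation"))
  sw_g <- summit_windows(dars$gained); sw_l <- summit_windows(dars$lost)
  enr <- function(pwm, fg, bg) {
    thr <- calibrate_threshold(pwm)
    hf <- .window_has_hit(fg, d$genome, pwm, thr)
    hb <- .window_has_hit(bg, d$genome, pwm, thr)
    list(p = hypergeom_enrichment(sum(hf), length(hf), sum(hb),
                                  length(hb))$p_one_sided,
         fg_hits = hf, bg_hits = hb)
  }
  e_gain <- enr(d$pwms$gained_tf, sw_g, sw_l)
  e_lost <- enr(d$pwms$p53_like, sw_l, sw_g)
  chip_tf <- d$chip$transformed
  chip_g <- mean(overlaps_any(dars$gained, chip_tf))
  chip_l <- mean(overlaps_any(dars$lost, chip_tf))
  groups <- build_groups(de, assignment, dars, e_lost$fg_hits)
  cmp <- compare_response(groups, d$nutlin)
  nut_p <- if (!is.null(cmp$tests)) {
    row <- cmp$tests[cmp$tests$group == "hras_down_p53" &
                       cmp$tests$reference == "all_expressed", ]
    if (nrow(row)) row$p else NA_real_
  } else NA_real_
  c(dar_jaccard = dar_recovery_jaccard(dars, d$truth$dars),
    n_gained = nrow(dars$gained), n_lost = nrow(dars$lost),
    segregation_p = seg$p_lower,
    motif_gained_p = e_gain$p, motif_lost_p = e_lost$p,
    chip_gained_rate = chip_g, chip_lost_rate = chip_l,
    nutlin_p = nut_p)
}
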