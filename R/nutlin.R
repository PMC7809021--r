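#' Build the p53-responsiveness gene groups
#'
#' Derives the four nested gene groups used to probe p53 responsiveness:
#' all expressed genes, genes up-regulated after transformation, genes
#' down-regulated after transformation, and the down-regulated genes whose
#' assigned TAD contains at least one lost DAR whose summit window carries a
#' p53 motif hit.
#'
#' @param de named DE status vector from [classify_de()].
#' @param assignment a [assign_smallest_tad()] result.
#' @param dars a `dar_set`.
#' @param lost_has_motif logical vector, one per lost DAR: does its summit
#'   window contain a motif hit (e.g. from [scan_pwm()] on the 150-bp
#'   summits).
#' @return list of class `response_groups` with `all_expressed`, `hras_up`,
#'   `hras_down`, `hras_down_p53` gene-id vectors
#'   (`hras_down_p53` is always a subset of `hras_down`).
#' @export
build_groups <- function(de, assignment, dars, lost_has_motif) {
  if (missing(de) || is.null(de)) stop("build_groups: missing stage: de classification")
  if (missing(assignment) || is.null(assignment)) stop("build_groups: missing stage: tad assignment")
  if (missing(dars) || is.null(dars)) stop("build_groups: missing stage: dars")
  if (missing(lost_has_motif) || is.null(lost_has_motif))
    stop("build_groups: missing stage: motif scan of lost summits")
  stopifnot(inherits(assignment, "tad_assignment"),
            length(lost_has_motif) == nrow(dars$lost))
  all_expressed <- names(de)
  hras_up <- names(de)[de == "up"]
  hras_down <- names(de)[de == "down"]
  motif_dars <- dars$lost[lost_has_motif, , drop = FALSE]
  hras_down_p53 <- character(0)
  if (length(hras_down) && nrow(motif_dars)) {
    tad_idx <- assignment$tad[hras_down]
    ok <- !is.na(tad_idx)
    if (any(ok)) {
      tad_hit <- overlaps_any(assignment$tads, motif_dars)
      hras_down_p53 <- hras_down[ok][tad_hit[tad_idx[ok]]]
    }
  }
  structure(list(all_expressed = all_expressed, hras_up = hras_up,
                 hras_down = hras_down, hras_down_p53 = hras_down_p53),
            class = "response_groups")
}

#' Compare treatment-response magnitudes between gene groups
#'
#' The response statistic is the absolute log2 fold change after treatment.
#' Each group is compared to all expressed genes, plus the focal contrast of
#' the motif-bearing down-regulated subgroup against all down-regulated
#' genes, with the two-sided Mann-Whitney test.  Groups with fewer than two
#' members are excluded and flagged.
#'
#' @param groups a [build_groups()] result.
#' @param nutlin data.frame with `gene_id` and `log2fc` (post-treatment).
#' @return list with `responses` (named list of |log2fc| vectors), `tests`
#'   (data.frame of comparisons with n's and p) and `excluded` (group names
#'   with < 2 covered members).
#' @export
compare_response <- function(groups, nutlin) {
  stopifnot(inherits(groups, "response_groups"),
            all(c("gene_id", "log2fc") %in% names(nutlin)))
  lut <- stats::setNames(abs(nutlin$log2fc), nutlin$gene_id)
  responses <- lapply(unclass(groups), function(ids) unname(lut[ids[ids %in% names(lut)]]))
  excluded <- names(responses)[vapply(responses, length, integer(1)) < 2]
  pairs <- list(c("hras_up", "all_expressed"),
                c("hras_down", "all_expressed"),
                c("hras_down_p53", "all_expressed"),
                c("hras_down_p53", "hras_down"))
  rows <- lapply(pairs, function(pr) {
    if (pr[1] %in% excluded || pr[2] %in% excluded) return(NULL)
    mw <- mann_whitney(responses[[pr[1]]], responses[[pr[2]]])
    data.frame(group = pr[1], reference = pr[2],
               n_group = length(responses[[pr[1]]]),
               n_reference = length(responses[[pr[2]]]),
               median_group = stats::median(responses[[pr[1]]]),
               median_reference = stats::median(responses[[pr[2]]]),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  if (!is.null(tests)) rownames(tests) <- NULL
  list(responses = responses, tests = tests, excluded = excluded)
}
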