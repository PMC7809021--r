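#' Differential-expression thresholds
#'
#' Defaults follow the operational definition used throughout the package:
#' a gene is differentially expressed when `fdr < 0.05` and `|log2fc| > 0.5`
#' (both inequalities strict, so boundary genes are stable).
#'
#' @param fdr_max maximum FDR (exclusive), default 0.05.
#' @param abs_lfc_min minimum absolute log2 fold change (exclusive), default 0.5.
#' @return list of class `de_thresholds`.
#' @export
de_thresholds <- function(fdr_max = 0.05, abs_lfc_min = 0.5) {
  stopifnot(fdr_max > 0, abs_lfc_min > 0)
  structure(list(fdr_max = fdr_max, abs_lfc_min = abs_lfc_min),
            class = "de_thresholds")
}

#' Classify genes as up-, down-regulated or stable
#'
#' Partitions an expression table into `up` (`fdr < fdr_max` and
#' `log2fc > abs_lfc_min`), `down` (`fdr < fdr_max` and
#' `log2fc < -abs_lfc_min`) and `stable` (everything else).  The partition is
#' exhaustive and disjoint.
#'
#' @param records expression data.frame with `gene_id`, `log2fc`, `fdr`
#'   (one row per gene; duplicates are rejected).
#' @param thr a [de_thresholds()] object.
#' @return named character vector (`names` = gene ids) over
#'   `c("up", "down", "stable")`.
#' @export
classify_de <- function(records, thr = de_thresholds()) {
  stopifnot(inherits(thr, "de_thresholds"),
            all(c("gene_id", "log2fc", "fdr") %in% names(records)))
  if (anyDuplicated(records$gene_id))
    stop("classify_de: duplicate gene_id ",
         records$gene_id[anyDuplicated(records$gene_id)])
  sig <- records$fdr < thr$fdr_max
  status <- rep("stable", nrow(records))
  status[sig & records$log2fc > thr$abs_lfc_min] <- "up"
  status[sig & records$log2fc < -thr$abs_lfc_min] <- "down"
  names(status) <- records$gene_id
  status
}
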