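#' Two-proportion test
#'
#' Two-sample test of equal proportions, by default the chi-square test with
#' continuity correction (classic `prop.test` behaviour: equal observed
#' proportions give statistic 0 and p = 1).  Fisher's exact test is available
#' as a fallback for small counts.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param method `"chisq"` (default, continuity-corrected) or `"fisher"`.
#' @param correct apply the continuity correction (chisq method only).
#' @return list of class `proportion_test` with `k1,n1,k2,n2`, `statistic`
#'   (NA for Fisher), `p`, `p1`, `p2`, `method`.
#' @export
proportion_test <- function(k1, n1, k2, n2, method = c("chisq", "fisher"),
                            correct = TRUE) {
  method <- match.arg(method)
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0)
  if (k1 > n1 || k2 > n2) stop("proportion_test: k must not exceed n")
  if (method == "chisq") {
    if (k1 * n2 == k2 * n1) {
      # equal observed proportions: the corrected statistic collapses to 0
      # (prop.test itself yields NaN in the all-success/all-failure case)
      statistic <- 0
      p <- 1
    } else {
      ht <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2), correct = correct))
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  } else {
    ht <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2))
    statistic <- NA_real_
    p <- ht$p.value
  }
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 p1 = k1 / n1, p2 = k2 / n2,
                 statistic = statistic, p = p, method = method),
            class = "proportion_test")
}

#' One-sided hypergeometric enrichment
#'
#' Over-representation p-value for seeing at least `k_fg` marked elements in a
#' foreground of size `n_fg`, against a background with `k_bg` of `n_bg`
#' marked: `p = P(X >= k_fg)` for X hypergeometric with population
#' `n_fg + n_bg`, `k_fg + k_bg` successes and `n_fg` draws.
#'
#' @param k_fg,n_fg marked / total in the foreground.
#' @param k_bg,n_bg marked / total in the background.
#' @return list of class `enrichment_result` with counts, `fg_fraction`,
#'   `bg_fraction` and `p_one_sided`.
#' @export
hypergeom_enrichment <- function(k_fg, n_fg, k_bg, n_bg) {
  stopifnot(k_fg >= 0, k_bg >= 0, n_fg >= 1, n_bg >= 0)
  if (k_fg > n_fg || k_bg > n_bg) stop("hypergeom_enrichment: k must not exceed n")
  p <- stats::phyper(k_fg - 1, m = k_fg + k_bg,
                     n = (n_fg + n_bg) - (k_fg + k_bg), k = n_fg,
                     lower.tail = FALSE)
  structure(list(k_fg = k_fg, n_fg = n_fg, k_bg = k_bg, n_bg = n_bg,
                 fg_fraction = k_fg / n_fg,
                 bg_fraction = if (n_bg > 0) k_bg / n_bg else NA_real_,
                 p_one_sided = p),
            class = "enrichment_result")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  With a combined sample size of at most 12 and no
#' ties the exact null distribution of U is used; otherwise the normal
#' approximation with tie correction and continuity correction.  Identical
#' samples give p = 1; `U + U' = |x||y|` always.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact_max combined size up to which the exact distribution is used
#'   (default 12).
#' @return list of class `mann_whitney` with `U` (for `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("mann_whitney: empty input")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (n1 + n2 <= exact_max && !ties) {
    # exact two-sided p from the (symmetric) Wilcoxon U distribution
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      z <- max(0, z)
      p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal_approx"
  }
  structure(list(U = U, p = min(p, 1), n1 = n1, n2 = n2, method = method),
            class = "mann_whitney")
}

#' Empirical p-value from a permutation null
#'
#' `(1 + #[null at or beyond the observed value]) / (length(null) + 1)`, so
#' the p-value is never 0 and never exceeds 1.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics (non-empty).
#' @param tail `"lower"` (beyond = `<= observed`) or `"upper"` (`>=`).
#' @return empirical p-value.
#' @export
empirical_p <- function(observed, null, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (!length(null)) stop("empirical_p: empty null")
  extreme <- if (tail == "lower") sum(null <= observed) else sum(null >= observed)
  (1 + extreme) / (length(null) + 1)
}
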