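#' Spearman rank correlation with Bonferroni adjustment
#'
#' Used to relate per-ear neural-synchrony indices (PLV) to per-ear IPG
#' effect measures when `m` such associations are tested in a family.
#'
#' @param x,y paired finite vectors (n >= 4).
#' @param m number of tests in the family (Bonferroni multiplier).
#' @return List with `rho`, `p`, `p_adjusted = min(1, m * p)`, `n`, and
#'   `degenerate` (TRUE when a constant vector makes rho undefined).
#' @export
spearman_bonferroni <- function(x, y, m = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop_config("need >= 4 complete pairs")
  if (m < 1) stop_config("`m` must be >= 1")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, p_adjusted = NA_real_,
                n = length(x), degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       p_adjusted = min(1, m * ct$p.value), n = length(x),
       degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups with tie
#' handling; `U` is oriented as the number of (a, b) pairs in which the
#' first group's value is larger (so complete separation with every a below
#' every b gives U = 0).
#'
#' @param a,b numeric value vectors (each non-empty).
#' @return List with `U`, `p`, and the group sizes.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop_config("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues p-values in \[0, 1\].
#' @return Adjusted p-values in the input order, capped at 1.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop_config("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
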