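# Aggregator-side inference: empirical-Bayes variance moderation, moderated
# t-statistics, BH adjustment and DE calling. These steps see only global
# per-gene statistics (beta, unscaled SE, sigma), so they need no federation.

#' Inverse of the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by a monotone Newton iteration
#' (relative tolerance 1e-8). Used to fit the prior degrees of freedom of the
#' scaled inverse-chi-square variance prior.
#'
#' @param y positive value(s).
#' @return x with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  out <- y
  large <- y > 1e7          # trigamma(x) ~ 1/x for tiny x
  out[large] <- 1 / sqrt(y[large])
  small <- y < 1e-6         # trigamma(x) ~ 1/x + 1/(2x^2) for large x
  out[small] <- 1 / y[small]
  mid <- !large & !small
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes squeezing of residual variances
#'
#' Fits a scaled inverse-chi-square prior to the per-gene residual variances
#' by the closed-form moment method on `z = log(sigma_sq)`:
#' `e = z - digamma(df/2) + log(df/2)`; `evar = var(e) - trigamma(df/2)`.
#' If `evar > 0`, the prior degrees of freedom are `d0 =
#' 2 * trigamma_inverse(evar)` and the prior variance is
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`; otherwise the prior is
#' degenerate (`d0 = Inf`, `s0_sq = mean(sigma_sq)`). Posterior variances are
#' the df-weighted average `(d0*s0_sq + df*sigma_sq) / (d0 + df)`.
#'
#' All genes share one residual df here (no missing observations), so the
#' scalar-df moment estimator applies.
#'
#' @param sigma_sq per-gene residual variances (>= 2 genes, not all zero).
#' @param df_residual residual degrees of freedom (scalar, >= 1).
#' @return list with `d0`, `s0_sq`, `s_post_sq`.
#' @export
squeeze_var <- function(sigma_sq, df_residual) {
  if (length(sigma_sq) < 2L) stop("need at least 2 genes to moderate variances")
  if (all(sigma_sq == 0)) stop("all residual variances are zero: nothing to moderate")
  if (df_residual < 1) stop("residual df must be >= 1")
  z <- log(pmax(sigma_sq, 1e-300))
  e <- z - digamma(df_residual / 2) + log(df_residual / 2)
  evar <- stats::var(e) - trigamma(df_residual / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s_post_sq <- (d0 * s0_sq + df_residual * sigma_sq) / (d0 + df_residual)
  } else {
    # degenerate prior: no excess variability beyond sampling noise; the
    # prior collapses onto the average observed variance
    d0 <- Inf
    s0_sq <- mean(sigma_sq)
    s_post_sq <- rep(s0_sq, length(sigma_sq))
  }
  list(d0 = d0, s0_sq = s0_sq, s_post_sq = s_post_sq)
}

#' Moderated t-statistics and two-sided p-values
#'
#' `t = beta / (unscaled_se * sqrt(s_post_sq))` referred to a Student t
#' distribution with `d0 + df_residual` degrees of freedom (normal tail in
#' the `d0 = Inf` limit, which `pt` handles via `df = Inf`).
#'
#' @param beta tested coefficient per gene.
#' @param unscaled_se unscaled standard error per gene.
#' @param s_post_sq posterior variance per gene from [squeeze_var()].
#' @param d0 prior degrees of freedom.
#' @param df_residual residual degrees of freedom.
#' @return list with `t` and `p`.
#' @export
moderated_t <- function(beta, unscaled_se, s_post_sq, d0, df_residual) {
  t <- beta / (unscaled_se * sqrt(s_post_sq))
  p <- 2 * stats::pt(-abs(t), df = d0 + df_residual)
  list(t = t, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, delegated to `stats::p.adjust(method = "BH")`
#' after range validation.
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is called DE iff `|logFC| > lfc_threshold` AND
#' `adj.P.Val < alpha` — both inequalities strict.
#'
#' @param table `fv_results` table (needs `gene`, `logFC`, `adj.P.Val`).
#' @param lfc_threshold absolute log2-fold-change threshold (default 1).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return character vector of DE gene ids.
#' @export
de_calls <- function(table, lfc_threshold = 1, alpha = 0.05) {
  table$gene[abs(table$logFC) > lfc_threshold & table$adj.P.Val < alpha]
}
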