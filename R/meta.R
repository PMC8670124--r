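# Meta-analysis baselines: the classical alternatives to federation, all
# operating on per-cohort DE summaries (local p-values, fold changes, effect
# standard errors) rather than on raw data; plus the metric report used to
# compare any privacy-aware method against the pooled oracle.
#
# Fisher / Stouffer / rank product combine directionally: the two-sided local
# p is split into one-sided halves by the sign of the local fold change, the
# two directions are combined separately, and the smaller combined tail is
# doubled. This prevents opposite-direction effects from reinforcing.

P_FLOOR <- 1e-300

#' Per-cohort DE summaries for meta-analysis
#'
#' Runs the single-site pipeline independently on each cohort and collects
#' per-gene local statistics on the cohorts' common gene universe.
#'
#' @param cohorts list of [fv_client()] objects.
#' @param config [fv_config()].
#' @return list with `genes`, matrices `lfc`, `p`, `se` (genes x cohorts),
#'   vector `n` of cohort sizes, and `tables` (the per-cohort result tables).
#' @export
cohort_results <- function(cohorts, config) {
  tabs <- lapply(cohorts, function(cl) run_fedvoom(list(cl), config))
  genes <- Reduce(intersect, lapply(tabs, `[[`, "gene"))
  if (length(genes) == 0L) stop("no genes shared by all cohort results")
  K <- length(tabs)
  lfc <- p <- se <- matrix(NA_real_, length(genes), K,
                           dimnames = list(genes, NULL))
  for (i in seq_len(K)) {
    t_i <- tabs[[i]]
    m <- attr(t_i, "model")
    idx <- match(genes, t_i$gene)
    lfc[, i] <- t_i$logFC[idx]
    p[, i] <- t_i$P.Value[idx]
    j <- match(config$coefficient, colnames(m$beta))
    midx <- match(genes, m$gene)
    se[, i] <- (m$unscaled_se[midx, j] * sqrt(m$s_post_sq[midx]))
  }
  n <- vapply(cohorts, function(cl) ncol(cl$counts), numeric(1))
  list(genes = genes, lfc = lfc, p = p, se = se, n = n, tables = tabs)
}

split_onesided <- function(p, signs) {
  p <- pmax(p, P_FLOOR)
  if (any(p > 1)) stop("p-values must lie in [0, 1]")
  up <- ifelse(signs >= 0, p / 2, 1 - p / 2)
  list(up = pmax(up, P_FLOOR), down = pmax(1 - up, P_FLOOR))
}

#' Fisher's combined probability test (directional)
#'
#' Per direction, `chi2 = -2 * sum(log p_one_sided)` with `2K` degrees of
#' freedom; the final two-sided p is `min(1, 2 * min(p_up, p_down))`. Input
#' p-values equal to zero are floored at 1e-300 with a warning.
#'
#' @param p_mat genes x cohorts matrix of local two-sided p-values.
#' @param sign_mat matching matrix of local log-fold-change signs.
#' @return combined two-sided p per gene.
#' @export
fisher_combine <- function(p_mat, sign_mat) {
  p_mat <- as.matrix(p_mat); sign_mat <- as.matrix(sign_mat)
  if (ncol(p_mat) < 2L) stop("Fisher combination needs at least 2 cohorts")
  if (any(p_mat == 0)) warning("zero p-value floored at 1e-300")
  os <- split_onesided(p_mat, sign_mat)
  K2 <- 2 * ncol(p_mat)
  p_up <- stats::pchisq(-2 * rowSums(log(os$up)), df = K2, lower.tail = FALSE)
  p_dn <- stats::pchisq(-2 * rowSums(log(os$down)), df = K2, lower.tail = FALSE)
  pmin(1, 2 * pmin(p_up, p_dn))
}

#' Stouffer's z-method (directional, sqrt-n weighted)
#'
#' `z_i = qnorm(1 - p_i/2) * sign_i`, combined as
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))` with `w_i = sqrt(n_i)`;
#' `p = 2 * pnorm(-|Z|)`.
#'
#' @param p_mat genes x cohorts local two-sided p-values.
#' @param sign_mat local fold-change signs.
#' @param n cohort sample sizes.
#' @return combined two-sided p per gene.
#' @export
stouffer_combine <- function(p_mat, sign_mat, n) {
  p_mat <- as.matrix(p_mat); sign_mat <- as.matrix(sign_mat)
  if (any(p_mat == 0)) warning("zero p-value floored at 1e-300")
  p_mat <- pmax(p_mat, P_FLOOR)
  z <- stats::qnorm(1 - p_mat / 2) * ifelse(sign_mat >= 0, 1, -1)
  w <- sqrt(n)
  Z <- as.numeric(z %*% w) / sqrt(sum(w^2))
  2 * stats::pnorm(-abs(Z))
}

#' DerSimonian-Laird random-effects combination
#'
#' Fixed weights `w_i = 1/v_i`; heterogeneity `Q = sum w_i (e_i - ebar)^2`;
#' `tau2 = max(0, (Q - (K-1)) / (sum w - sum w^2 / sum w))`; random weights
#' `1/(v_i + tau2)` give the pooled effect, its SE, and a two-sided normal
#' p-value.
#'
#' @param effect_mat genes x cohorts local effects (log2 fold changes).
#' @param var_mat matching effect variances (> 0).
#' @return list with per-gene `effect`, `se`, `tau2`, `p`.
#' @export
rem_combine <- function(effect_mat, var_mat) {
  effect_mat <- as.matrix(effect_mat); var_mat <- as.matrix(var_mat)
  K <- ncol(effect_mat)
  if (K < 2L) stop("random-effects combination needs at least 2 cohorts")
  if (any(var_mat <= 0)) stop("effect variances must be positive")
  w <- 1 / var_mat
  sw <- rowSums(w)
  ebar <- rowSums(w * effect_mat) / sw
  Q <- rowSums(w * (effect_mat - ebar)^2)
  cc <- sw - rowSums(w^2) / sw
  tau2 <- pmax(0, (Q - (K - 1)) / cc)
  ws <- 1 / (var_mat + tau2)
  eff <- rowSums(ws * effect_mat) / rowSums(ws)
  se <- 1 / sqrt(rowSums(ws))
  p <- 2 * stats::pnorm(-abs(eff / se))
  list(effect = eff, se = se, tau2 = tau2, p = p)
}

#' Rank product meta-statistic with permutation p-values
#'
#' Genes are ranked within each cohort by log fold change (descending for the
#' up direction, ascending for down; ties get average ranks); the rank
#' product is the geometric mean of ranks. Significance per direction is the
#' add-one-corrected fraction of null rank products (from within-cohort
#' shuffles of the rank vectors, pooled over genes) at or below the observed
#' one.
#'
#' @param lfc_mat genes x cohorts local log fold changes.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @return list with per-gene `rp_up`, `rp_down`, `p_up`, `p_down`.
#' @export
rank_product <- function(lfc_mat, n_perm = 1000) {
  lfc_mat <- as.matrix(lfc_mat)
  G <- nrow(lfc_mat); K <- ncol(lfc_mat)
  if (n_perm < 100) stop("n_perm must be >= 100")
  rank_dir <- function(m, up) apply(m, 2, function(x)
    rank(if (up) -x else x, ties.method = "average"))
  obs_up <- rank_dir(lfc_mat, TRUE)
  obs_dn <- rank_dir(lfc_mat, FALSE)
  lrp_up <- rowMeans(log(obs_up))
  lrp_dn <- rowMeans(log(obs_dn))
  null_lrp <- function(obs) {
    out <- numeric(n_perm * G)
    for (b in seq_len(n_perm)) {
      perm <- vapply(seq_len(K), function(j) obs[sample.int(G), j], numeric(G))
      out[((b - 1) * G + 1):(b * G)] <- rowMeans(log(perm))
    }
    sort(out)
  }
  p_of <- function(lrp, null_sorted)
    (1 + findInterval(lrp, null_sorted)) / (1 + length(null_sorted))
  nu <- null_lrp(obs_up)
  nd <- null_lrp(obs_dn)
  list(rp_up = exp(lrp_up), rp_down = exp(lrp_dn),
       p_up = p_of(lrp_up, nu), p_down = p_of(lrp_dn, nd))
}

#' Global fold change as the mean of local fold changes
#'
#' Used by all combiners except the random-effects model, which reports its
#' own weighted effect.
#'
#' @param lfc_mat genes x cohorts local log fold changes.
#' @return per-gene mean.
#' @export
combine_fold_changes <- function(lfc_mat) rowMeans(as.matrix(lfc_mat))

#' Run a meta-analysis baseline over cohorts
#'
#' @param cohorts list of [fv_client()] objects.
#' @param config [fv_config()].
#' @param method one of `"fisher"`, `"stouffer"`, `"rem"`, `"rankprod"`.
#' @param n_perm permutations for `rankprod`.
#' @return `fv_results`-style table (the `t` column is `NA`: combiners return
#'   p-values, not t-statistics).
#' @export
run_meta <- function(cohorts, config, method = c("fisher", "stouffer", "rem", "rankprod"),
                     n_perm = 1000) {
  method <- match.arg(method)
  cr <- cohort_results(cohorts, config)
  signs <- sign(cr$lfc)
  lfc <- combine_fold_changes(cr$lfc)
  p <- switch(method,
    fisher = fisher_combine(cr$p, signs),
    stouffer = stouffer_combine(cr$p, signs, cr$n),
    rem = { r <- rem_combine(cr$lfc, cr$se^2); lfc <- r$effect; r$p },
    rankprod = { r <- rank_product(cr$lfc, n_perm)
                 pmin(1, 2 * pmin(r$p_up, r$p_down)) })
  ave <- rowMeans(vapply(cr$tables, function(t_i)
    t_i$AveExpr[match(cr$genes, t_i$gene)], numeric(length(cr$genes))))
  new_results_table(gene = cr$genes, logFC = lfc, AveExpr = ave,
                    t = rep(NA_real_, length(p)), P.Value = p,
                    adj.P.Val = bh_adjust(p))
}

#' Compare a candidate result table against the pooled oracle
#'
#' RMSE and Pearson/Spearman correlations are computed on -log10-transformed
#' raw p-values; precision, recall, F1 and FP/FN counts on the DE-call sets
#' (`|logFC| > lfc_threshold` and `adj.P.Val < alpha`, strict) with the
#' oracle's calls as truth.
#'
#' @param candidate result table to score.
#' @param truth pooled-oracle result table (same gene universe).
#' @param lfc_threshold,alpha DE-call thresholds.
#' @return list of class `fv_metrics`: `rmse`, `pearson_r`, `spearman_rho`,
#'   `precision`, `recall`, `f1`, `fp`, `fn`, `tp`.
#' @export
evaluate_results <- function(candidate, truth, lfc_threshold = 1, alpha = 0.05) {
  if (!setequal(candidate$gene, truth$gene))
    stop("gene universe mismatch between candidate and truth")
  idx <- match(truth$gene, candidate$gene)
  lp_c <- -log10(pmax(candidate$P.Value[idx], P_FLOOR))
  lp_t <- -log10(pmax(truth$P.Value, P_FLOOR))
  calls_c <- de_calls(candidate, lfc_threshold, alpha)
  calls_t <- de_calls(truth, lfc_threshold, alpha)
  tp <- length(intersect(calls_c, calls_t))
  fp <- length(setdiff(calls_c, calls_t))
  fn <- length(setdiff(calls_t, calls_c))
  precision <- if (tp + fp == 0) as.numeric(fn == 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) as.numeric(fp == 0) else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(rmse = sqrt(mean((lp_c - lp_t)^2)),
                 pearson_r = stats::cor(lp_c, lp_t),
                 spearman_rho = stats::cor(lp_c, lp_t, method = "spearman"),
                 precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn),
            class = "fv_metrics")
}

#' @export
print.fv_metrics <- function(x, ...) {
  cat(sprintf("RMSE(-log10 p) %.4g | r %.4f | rho %.4f | precision %.3f | recall %.3f | F1 %.3f | FP %d | FN %d\n",
              x$rmse, x$pearson_r, x$spearman_rho, x$precision, x$recall,
              x$f1, x$fp, x$fn))
  invisible(x)
}
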