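# Federated per-gene (weighted) linear modeling and the voom mean-variance
# trend.
#
# Clients share Gaussian-masked normal-equation pieces X^T W X and X^T W Y
# per gene; the aggregator solves for coefficients and unscaled standard
# errors, broadcasts the coefficients, and collects masked weighted residual
# sums of squares to form per-gene residual standard deviations. The LOWESS
# trend of sqrt residual SD against average log2 count is fitted wholly on
# the aggregator from global statistics; clients turn it into per-observation
# precision weights locally.

KAPPA_MAX <- 1e12  # reciprocal-condition threshold for declaring singularity

#' Local normal-equation pieces for the federated fit
#'
#' For each gene, `X^T W X` (flattened k x k) and `X^T W Y`. Unit weights
#' give the plain pass-1 equations; pass 2 supplies per-gene voom weights.
#'
#' @param X local design matrix (samples x k).
#' @param Y local log2-CPM matrix (genes x samples).
#' @param W per-gene per-sample weight matrix (same shape as `Y`) or NULL for
#'   unit weights.
#' @return list with `xtwx` (genes x k^2, row-major flattening) and `xtwy`
#'   (genes x k).
#' @export
local_normal_equations <- function(X, Y, W = NULL) {
  k <- ncol(X)
  G <- nrow(Y)
  if (is.null(W)) {
    xtx <- crossprod(X)
    xtwx <- matrix(rep(as.numeric(xtx), each = G), G, k * k)
    xtwy <- Y %*% X
  } else {
    if (any(!is.finite(W)) || any(W <= 0)) stop("weights must be finite and positive")
    xtwx <- matrix(0, G, k * k)
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (b < a) { xtwx[, (a - 1) * k + b] <- xtwx[, (b - 1) * k + a]; next }
      xtwx[, (a - 1) * k + b] <- W %*% (X[, a] * X[, b])
    }
    xtwy <- (W * Y) %*% X
  }
  list(xtwx = xtwx, xtwy = xtwy)
}

#' Solve the aggregated normal equations per gene
#'
#' `beta = (X^T W X)^{-1} X^T W Y` and unscaled standard errors
#' `sqrt(diag((X^T W X)^{-1}))` per gene. A system whose reciprocal condition
#' number falls below `1e-12` is reported as singular with the offending
#' genes named.
#'
#' @param xtwx genes x k^2 aggregated Gram matrices (row-major).
#' @param xtwy genes x k aggregated moment vectors.
#' @param genes optional gene ids for error messages.
#' @return list with `beta` and `unscaled_se`, both genes x k.
#' @export
global_fit <- function(xtwx, xtwy, genes = NULL) {
  G <- nrow(xtwy); k <- ncol(xtwy)
  beta <- matrix(NA_real_, G, k)
  use <- matrix(NA_real_, G, k)
  bad <- logical(G)
  for (g in seq_len(G)) {
    A <- matrix(xtwx[g, ], k, k)
    A <- (A + t(A)) / 2
    if (!all(is.finite(A)) || rcond(A) < 1 / KAPPA_MAX) { bad[g] <- TRUE; next }
    Ai <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
    if (is.null(Ai)) { bad[g] <- TRUE; next }
    beta[g, ] <- Ai %*% xtwy[g, ]
    use[g, ] <- sqrt(diag(Ai))
  }
  if (any(bad)) {
    ids <- if (is.null(genes)) which(bad) else genes[bad]
    stop("singular or ill-conditioned normal equations for gene(s): ",
         paste(utils::head(ids, 5), collapse = ", "),
         if (sum(bad) > 5) ", ..." else "",
         " — check the pooled design for collinear columns")
  }
  list(beta = beta, unscaled_se = use)
}

#' Local (weighted) residual sum of squares per gene
#'
#' @param X local design matrix.
#' @param beta global coefficients (genes x k), broadcast by the aggregator.
#' @param Y local log2-CPM matrix.
#' @param W per-gene per-sample weights or NULL for unit weights.
#' @return one-column matrix of per-gene local SSE contributions.
#' @export
local_sse <- function(X, beta, Y, W = NULL) {
  res <- Y - beta %*% t(X)
  if (is.null(W)) cbind(rowSums(res^2)) else cbind(rowSums(W * res^2))
}

#' Residual standard deviation from aggregated SSE
#'
#' @param sse denoised pooled per-gene SSE.
#' @param n_total pooled sample count.
#' @param k number of design columns.
#' @return list with `sigma` per gene and `df_residual = n_total - k`.
#' @export
global_sigma <- function(sse, n_total, k) {
  df <- n_total - k
  if (df < 1) stop("pooled sample count must exceed the number of design columns")
  list(sigma = sqrt(pmax(as.numeric(sse), 0) / df), df_residual = df)
}

#' Fit the voom mean-variance trend
#'
#' LOWESS (span 0.5, 3 robustifying iterations) of `sqrt(sigma)` against
#' average log2 count (`amean` shifted by the global mean log2 effective
#' library size). If all x-coordinates coincide the trend degenerates to the
#' constant `median(sqrt(sigma))`. Fitted values are floored at 1e-6 so
#' precision weights stay finite.
#'
#' @param amean per-gene mean log2-CPM.
#' @param sigma per-gene residual standard deviation.
#' @param mean_log2_lib global mean of `log2(effective library size + 1)`.
#' @return list of class `fv_trend` with knot vectors `x`, `y`.
#' @export
fit_trend <- function(amean, sigma, mean_log2_lib) {
  if (length(amean) < 10L) stop("too few genes to fit a mean-variance trend")
  sx <- amean + mean_log2_lib - log2(1e6)
  sy <- sqrt(sigma)
  if (diff(range(sx)) < 1e-10) {
    tr <- list(x = range(sx) + c(-1, 1), y = rep(max(stats::median(sy), 1e-6), 2))
  } else {
    l <- stats::lowess(sx, sy, f = 0.5, iter = 3)
    tr <- list(x = l$x, y = pmax(l$y, 1e-6))
  }
  structure(tr, class = "fv_trend")
}

trend_interp <- function(trend, xout) {
  f <- stats::approxfun(trend$x, trend$y, rule = 2, ties = list("ordered", mean))
  f(xout)
}

#' Per-observation voom precision weights
#'
#' Each observation's fitted log2 count is `x_s' beta_g + log2(eff_lib_s + 1)
#' - log2(1e6)`; the trend is interpolated there (clamped to the knot range)
#' and inverted to the fourth power. Weights are finite and strictly
#' positive.
#'
#' @param X local design matrix.
#' @param beta global pass-1 coefficients (genes x k).
#' @param eff_lib per-sample effective library sizes (`lib_size * factor`).
#' @param trend [fit_trend()] output.
#' @return genes x samples weight matrix.
#' @export
local_voom_weights <- function(X, beta, eff_lib, trend) {
  fitted_logcpm <- beta %*% t(X)
  lambda <- sweep(fitted_logcpm, 2, log2(eff_lib + 1) - log2(1e6), "+")
  w <- trend_interp(trend, lambda)^(-4)
  dim(w) <- dim(lambda)
  w
}

# Two-pass federated fit: pass 1 unweighted -> sigma, amean, trend, weights;
# pass 2 weighted -> final beta, unscaled SE, sigma.
fed_two_pass <- function(X, Y, eff_lib, n_total, bus, config, genes = NULL) {
  K <- length(X)
  k <- ncol(X[[1]])
  G <- nrow(Y[[1]])

  eq1 <- lapply(seq_len(K), function(i) local_normal_equations(X[[i]], Y[[i]]))
  # pass 1 Gram matrix is sample-level only, identical for all genes: share once
  xtx <- exchange_round(bus, "pass1_xtx",
                        lapply(seq_len(K), function(i)
                          matrix(eq1[[i]]$xtwx[1, ], 1, k * k)),
                        "gaussian", config)
  xty <- exchange_round(bus, "pass1_xty",
                        lapply(eq1, `[[`, "xtwy"), "gaussian", config)
  fit1 <- global_fit(matrix(rep(as.numeric(xtx), each = G), G, k * k), xty, genes)

  sse1 <- exchange_round(bus, "pass1_sse",
                         lapply(seq_len(K), function(i)
                           local_sse(X[[i]], fit1$beta, Y[[i]])),
                         "gaussian", config)
  sg1 <- global_sigma(sse1, n_total, k)

  rowsums <- exchange_round(bus, "y_rowsums",
                            lapply(Y, function(y) cbind(rowSums(y))),
                            "gaussian", config)
  amean <- as.numeric(rowsums) / n_total

  loglib <- exchange_round(bus, "log2_libsize_sum",
                           lapply(eff_lib, function(l)
                             matrix(sum(log2(l + 1)), 1, 1)),
                           "gaussian", config)
  mean_log2_lib <- as.numeric(loglib) / n_total

  trend <- fit_trend(amean, sg1$sigma, mean_log2_lib)
  W <- lapply(seq_len(K), function(i)
    local_voom_weights(X[[i]], fit1$beta, eff_lib[[i]], trend))

  eq2 <- lapply(seq_len(K), function(i)
    local_normal_equations(X[[i]], Y[[i]], W[[i]]))
  xtwx <- exchange_round(bus, "pass2_xtwx",
                         lapply(eq2, `[[`, "xtwx"), "gaussian", config)
  xtwy <- exchange_round(bus, "pass2_xtwy",
                         lapply(eq2, `[[`, "xtwy"), "gaussian", config)
  fit2 <- global_fit(xtwx, xtwy, genes)

  sse2 <- exchange_round(bus, "pass2_sse",
                         lapply(seq_len(K), function(i)
                           local_sse(X[[i]], fit2$beta, Y[[i]], W[[i]])),
                         "gaussian", config)
  sg2 <- global_sigma(sse2, n_total, k)

  colnames(fit2$beta) <- colnames(fit2$unscaled_se) <- colnames(X[[1]])
  list(beta = fit2$beta, unscaled_se = fit2$unscaled_se,
       sigma = sg2$sigma, amean = amean, df_residual = sg2$df_residual,
       trend = trend, weights = W,
       pass1 = list(beta = fit1$beta, sigma = sg1$sigma))
}
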