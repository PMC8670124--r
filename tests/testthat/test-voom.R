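# Federated linear modeling and the mean-variance trend.

test_that("aggregated normal equations reproduce pooled matrix products", {
  set.seed(31)
  for (i in 1:10) {
    n <- 12; k <- 3; G <- 20
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
    colnames(X) <- c("intercept", "x1", "x2")
    Y <- matrix(rnorm(G * n, sd = 2), G, n)
    W <- matrix(runif(G * n, 0.2, 5), G, n)
    parts <- split(seq_len(n), rep(1:3, each = 4))
    eqs <- lapply(parts, function(ix)
      local_normal_equations(X[ix, , drop = FALSE], Y[, ix, drop = FALSE],
                             W[, ix, drop = FALSE]))
    xtwx <- Reduce(`+`, lapply(eqs, `[[`, "xtwx"))
    xtwy <- Reduce(`+`, lapply(eqs, `[[`, "xtwy"))
    g <- sample.int(G, 1)
    expect_equal(matrix(xtwx[g, ], k, k), t(X) %*% (W[g, ] * X),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(xtwy[g, ], as.numeric(t(X) %*% (W[g, ] * Y[g, ])),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # unit weights reduce to the unweighted equations
    eq_u <- local_normal_equations(X, Y)
    eq_1 <- local_normal_equations(X, Y, matrix(1, G, n))
    expect_equal(eq_u$xtwx, eq_1$xtwx, tolerance = 1e-12)
    expect_equal(eq_u$xtwy, eq_1$xtwy, tolerance = 1e-12)
  }
})

test_that("global_fit matches weighted least squares and flags singular systems", {
  set.seed(37)
  n <- 12; k <- 3; G <- 30
  X <- cbind(intercept = 1, grp = rep(0:1, 6), age = rnorm(n))
  Y <- matrix(rnorm(G * n), G, n)
  W <- matrix(runif(G * n, 0.5, 4), G, n)
  eq <- local_normal_equations(X, Y, W)
  fit <- global_fit(eq$xtwx, eq$xtwy)
  for (g in c(1, 17, 30)) {
    lmf <- stats::lm.wfit(X, Y[g, ], W[g, ])
    expect_equal(unname(fit$beta[g, ]), unname(lmf$coefficients), tolerance = 1e-8)
    XtWXi <- solve(t(X) %*% (W[g, ] * X))
    expect_equal(fit$unscaled_se[g, ], sqrt(diag(XtWXi)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # orthonormal design -> identity Gram matrix -> unit unscaled SEs
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  eqo <- local_normal_equations(Q, matrix(rnorm(8), 2, 4))
  fo <- global_fit(eqo$xtwx, eqo$xtwy)
  expect_equal(as.numeric(fo$unscaled_se), rep(1, 8), tolerance = 1e-10)
  # duplicated column -> singular, genes named
  Xs <- cbind(intercept = 1, a = X[, 2], b = X[, 2])
  eqs <- local_normal_equations(Xs, Y)
  expect_error(global_fit(eqs$xtwx, eqs$xtwy, genes = paste0("g", 1:G)),
               "singular|ill-conditioned")
})

test_that("intercept-only fit returns the pooled mean", {
  X <- matrix(1, 8, 1, dimnames = list(NULL, "intercept"))
  Y <- matrix(rnorm(16), 2, 8)
  eq <- local_normal_equations(X, Y)
  fit <- global_fit(eq$xtwx, eq$xtwy)
  expect_equal(as.numeric(fit$beta), rowMeans(Y), tolerance = 1e-12)
})

test_that("local SSE sums to the pooled residual sum of squares", {
  # hand cases
  X <- cbind(intercept = 1)[rep(1, 2), , drop = FALSE]
  beta <- matrix(0, 1, 1)
  Y <- matrix(c(1, -1), 1, 2)
  expect_equal(as.numeric(local_sse(X, beta, Y)), 2)
  expect_equal(as.numeric(local_sse(X, matrix(1, 1, 1), matrix(1, 1, 2))), 0)
  expect_equal(global_sigma(8, 10, 2)$sigma, 1)
  expect_equal(global_sigma(8, 10, 2)$df_residual, 8)
  expect_error(global_sigma(8, 3, 3), "exceed")
  # pooled-oracle property
  set.seed(41)
  n <- 15; k <- 2; G <- 12
  X2 <- cbind(1, rnorm(n))
  Y2 <- matrix(rnorm(G * n), G, n)
  W2 <- matrix(runif(G * n, 0.3, 3), G, n)
  eq <- local_normal_equations(X2, Y2, W2)
  fit <- global_fit(eq$xtwx, eq$xtwy)
  parts <- split(seq_len(n), rep(1:3, each = 5))
  sse_fed <- Reduce(`+`, lapply(parts, function(ix)
    local_sse(X2[ix, , drop = FALSE], fit$beta, Y2[, ix, drop = FALSE],
              W2[, ix, drop = FALSE])))
  sse_pool <- vapply(seq_len(G), function(g) {
    r <- Y2[g, ] - X2 %*% fit$beta[g, ]
    sum(W2[g, ] * r^2)
  }, numeric(1))
  expect_equal(as.numeric(sse_fed), sse_pool, tolerance = 1e-8)
})

test_that("trend fitting is monotone on decreasing-variance data and handles degeneracy", {
  # constant sigma -> flat curve at sqrt(c)
  tr <- fit_trend(seq(0, 8, length.out = 50), rep(2.25, 50), mean_log2_lib = 20)
  expect_equal(unique(round(tr$y, 10)), sqrt(2.25))
  # decreasing mean-variance relation -> decreasing fitted curve over the bulk
  set.seed(43)
  am <- sort(runif(300, 0, 10))
  sg <- (2 - 0.15 * am) + rnorm(300, sd = 0.05)
  tr2 <- fit_trend(am, pmax(sg, 0.05), mean_log2_lib = 20)
  mid <- tr2$y[tr2$x > quantile(tr2$x, 0.1) & tr2$x < quantile(tr2$x, 0.9)]
  expect_true(mean(diff(mid) <= 1e-8) > 0.95)
  # degenerate x-range falls back to the median
  tr3 <- fit_trend(rep(3, 20), seq(0.5, 2, length.out = 20), 20)
  expect_equal(unique(tr3$y), median(sqrt(seq(0.5, 2, length.out = 20))))
  expect_error(fit_trend(1:5, 1:5, 20), "too few genes")
})

test_that("precision weights invert the interpolated trend to the fourth power", {
  X <- cbind(intercept = 1, grp = c(0, 1))
  beta <- matrix(c(5, 1), 1, 2)
  flat <- structure(list(x = c(0, 10), y = c(0.5, 0.5)), class = "fv_trend")
  w <- local_voom_weights(X, beta, eff_lib = c(1e6, 1e6), flat)
  expect_equal(as.numeric(w), rep(0.5^-4, 2))
  # decreasing trend: larger fitted count -> larger weight
  dec <- structure(list(x = c(0, 10), y = c(2, 0.5)), class = "fv_trend")
  w2 <- local_voom_weights(X, beta, eff_lib = c(1e6, 1e6), dec)
  expect_gt(w2[1, 2], w2[1, 1])
  # clamped outside the knot range; all weights bounded by (min y)^-4
  beta_ext <- matrix(c(-30, 100), 1, 2)
  w3 <- local_voom_weights(X, beta_ext, eff_lib = c(1e6, 1e6), dec)
  expect_true(all(is.finite(w3) & w3 > 0))
  expect_true(all(w3 <= 0.5^-4 + 1e-12))
  # matches direct interpolation of the trend
  lam <- beta %*% t(X) + log2(1e6 + 1) - log2(1e6)
  expect_equal(as.numeric(w2),
               approx(dec$x, dec$y, xout = as.numeric(lam), rule = 2)$y^-4,
               tolerance = 1e-12)
})

test_that("the full pipeline reproduces the reference voom/limma analysis on pooled data", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  d <- toy_dataset(G = 400, n = 24, seed = 3)
  res <- run_fedvoom(pooled_client(d), cfg_off())
  m <- attr(res, "model")
  lib <- colSums(d$counts)
  ck <- d$counts[m$keep, ]
  uq <- apply(sweep(ck, 2, lib, "/"), 2, stats::quantile, probs = 0.75,
              names = FALSE)
  nf <- uq / exp(mean(log(uq)))
  v <- limma::voom(ck, d$design, lib.size = lib * nf)
  fit <- limma::eBayes(limma::lmFit(v, d$design))
  tt <- limma::topTable(fit, coef = "group", number = Inf, sort.by = "none")
  idx <- match(rownames(tt), res$gene)
  expect_lt(max(abs(tt$t - res$t[idx])), 1e-8)
  expect_lt(max(abs(tt$P.Value - res$P.Value[idx])), 1e-8)
  expect_lt(max(abs(tt$logFC - res$logFC[idx])), 1e-8)
  expect_lt(max(abs(tt$adj.P.Val - res$adj.P.Val[idx])), 1e-8)
  expect_equal(m$d0, fit$df.prior, tolerance = 1e-6)
})

test_that("planted fold changes are recovered on a well-powered simulation", {
  d <- toy_dataset(G = 800, n = 150, seed = 19)
  res <- run_fedvoom(pooled_client(d), cfg_off())
  truth <- d$truth$genes
  de <- truth$gene[truth$is_de]
  de <- intersect(de, res$gene)
  est <- res$logFC[match(de, res$gene)]
  tru <- truth$true_lfc[match(de, truth$gene)]
  expect_gt(cor(est, tru), 0.98)
  expect_lt(mean(abs(est - tru)), 0.3)
  expect_true(all(is.finite(res$t)) && all(is.finite(res$logFC)))
})
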