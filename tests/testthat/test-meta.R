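# Meta-analysis combiners against closed-form and package oracles, plus the
# metric report.

test_that("Fisher combination matches the chi-square tail oracle", {
  # two cohorts, both one-sided p = 0.025, same direction
  p <- matrix(c(0.05, 0.05), 1)
  s <- matrix(c(1, 1), 1)
  chi_up <- -2 * sum(log(c(0.025, 0.025)))
  chi_dn <- -2 * sum(log(c(0.975, 0.975)))
  expect_equal(fisher_combine(p, s),
               min(1, 2 * min(pchisq(chi_up, 4, lower.tail = FALSE),
                              pchisq(chi_dn, 4, lower.tail = FALSE))),
               tolerance = 1e-12)
  # all p = 1, consistent direction
  expect_equal(fisher_combine(matrix(1, 1, 3), matrix(1, 1, 3)), 1)
  # cohort-order invariance
  set.seed(73)
  pm <- matrix(runif(12), 3)
  sm <- matrix(sample(c(-1, 1), 12, TRUE), 3)
  perm <- c(3, 1, 4, 2)
  expect_equal(fisher_combine(pm, sm), fisher_combine(pm[, perm], sm[, perm]))
  expect_warning(fisher_combine(matrix(c(0, 0.5), 1), matrix(1, 1, 2)), "floored")
})

test_that("Stouffer combination matches the direct formula and degenerates correctly", {
  # two equal cohorts with cancelling z-scores
  p196 <- 2 * pnorm(-1.96)
  expect_equal(stouffer_combine(matrix(c(p196, p196), 1),
                                matrix(c(1, -1), 1), c(30, 30)), 1,
               tolerance = 1e-12)
  # single cohort returns its own p
  expect_equal(stouffer_combine(matrix(0.037, 1, 1), matrix(1, 1, 1), 20),
               0.037, tolerance = 1e-12)
  # three unequal cohorts against the formula written out
  p <- c(0.01, 0.2, 0.6); s <- c(1, 1, -1); n <- c(10, 30, 90)
  z <- qnorm(1 - p / 2) * s
  Z <- sum(sqrt(n) * z) / sqrt(sum(n))
  expect_equal(stouffer_combine(matrix(p, 1), matrix(s, 1), n),
               2 * pnorm(-abs(Z)), tolerance = 1e-12)
})

test_that("random-effects combination follows DerSimonian-Laird and matches metafor", {
  # printed toy: e = (1, 3), v = (1, 1)
  r <- rem_combine(matrix(c(1, 3), 1), matrix(c(1, 1), 1))
  # w = (1,1); ebar = 2; Q = 2; c = 2 - 2/2 = 1; tau2 = (2-1)/1 = 1
  expect_equal(r$tau2, 1)
  expect_equal(r$effect, 2)
  expect_equal(r$se, 1 / sqrt(2 * (1 / 2)))
  expect_equal(r$p, 2 * pnorm(-2), tolerance = 1e-12)
  # identical effects -> tau2 = 0, effect = common value
  r0 <- rem_combine(matrix(c(1.4, 1.4, 1.4), 1), matrix(c(1, 2, 3), 1))
  expect_equal(r0$tau2, 0)
  expect_equal(r0$effect, 1.4)
  expect_true(all(rem_combine(matrix(rnorm(30), 10),
                              matrix(runif(30, 0.5, 2), 10))$tau2 >= 0))
  skip_if_not_installed("metafor")
  set.seed(79)
  for (i in 1:5) {
    e <- rnorm(4); v <- runif(4, 0.2, 2)
    ours <- rem_combine(matrix(e, 1), matrix(v, 1))
    ref <- metafor::rma(yi = e, vi = v, method = "DL")
    expect_equal(ours$effect, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$se, ref$se, tolerance = 1e-8)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
  }
})

test_that("rank product p-values agree with exhaustive enumeration on a tiny toy", {
  set.seed(83)
  lfc <- cbind(c(3, 2, 1, -1, -2), c(2.5, 1.5, 0.5, -0.5, -3))
  rp <- rank_product(lfc, n_perm = 2000)
  # under within-cohort shuffling a gene's ranks are independent uniform on
  # 1..5 per cohort: exact null distribution of mean log rank over 25 pairs
  pairs <- expand.grid(r1 = 1:5, r2 = 1:5)
  null_lrp <- (log(pairs$r1) + log(pairs$r2)) / 2
  obs_up <- rowMeans(log(cbind(rank(-lfc[, 1]), rank(-lfc[, 2]))))
  exact <- vapply(obs_up, function(o) mean(null_lrp <= o + 1e-12), numeric(1))
  expect_lt(max(abs(rp$p_up - exact)), 0.03)
  # gene ranked first everywhere has the minimal rank product
  expect_equal(which.min(rp$rp_up), 1L)
  # up and down are computed on reversed rankings (no ties here, so the
  # down-rank is 6 minus the up-rank in each cohort)
  up_ranks <- cbind(rank(-lfc[, 1]), rank(-lfc[, 2]))
  expect_equal(rp$rp_down, exp(rowMeans(log(6 - up_ranks))), tolerance = 1e-12)
  expect_error(rank_product(lfc, n_perm = 10), ">= 100")
})

test_that("consistent evidence across cohorts amplifies significance", {
  set.seed(89)
  for (i in 1:20) {
    p <- runif(1, 1e-6, 0.04)
    pm <- matrix(p, 1, 3); sm <- matrix(1, 1, 3)
    expect_lt(fisher_combine(pm, sm), p)
    expect_lt(stouffer_combine(pm, sm, c(20, 20, 20)), p)
  }
})

test_that("fold-change combination is the unweighted mean", {
  expect_equal(combine_fold_changes(matrix(c(1, 3), 1)), 2)
  expect_equal(combine_fold_changes(matrix(5, 1, 1)), 5)
  m <- matrix(rnorm(12), 3)
  expect_equal(combine_fold_changes(m), combine_fold_changes(m[, c(3, 1, 2, 4)[1:4]]))
})

test_that("the metric report matches a hand-computed confusion matrix", {
  truth <- data.frame(gene = paste0("g", 1:6),
                      logFC = c(2, -2, 2, 0.2, 0.1, -0.3),
                      P.Value = c(1e-8, 1e-7, 1e-6, 0.2, 0.5, 0.9),
                      adj.P.Val = c(1e-6, 1e-6, 1e-5, 0.3, 0.6, 0.9))
  cand <- truth
  cand$logFC <- c(2, -2, 0.5, 2, 0.1, -0.3)      # misses g3, adds g4
  cand$P.Value <- c(1e-7, 1e-6, 1e-5, 0.01, 0.5, 0.9)
  cand$adj.P.Val <- c(1e-5, 1e-5, 1e-4, 0.04, 0.6, 0.9)
  m <- evaluate_results(cand, truth)
  # truth calls {g1,g2,g3}; candidate calls {g1,g2,g4}
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 1, 1))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$rmse,
               sqrt(mean((-log10(cand$P.Value) + log10(truth$P.Value))^2)))
  # identical tables are perfect
  perf <- evaluate_results(truth, truth)
  expect_equal(c(perf$rmse, perf$fp, perf$fn), c(0, 0, 0))
  expect_equal(c(perf$f1, perf$pearson_r, perf$spearman_rho), c(1, 1, 1))
  # inverted ranking flips Spearman
  inv <- truth; inv$P.Value <- rev(sort(truth$P.Value))[rank(truth$P.Value)]
  expect_equal(evaluate_results(inv, truth)$spearman_rho, -1)
  expect_error(evaluate_results(truth[1:5, ], truth), "gene universe")
})

test_that("meta baselines run end-to-end on split cohorts and p-values are valid", {
  d <- toy_dataset(G = 250, n = 48, seed = 97)
  cl <- split_cohorts(d, c(1, 1, 1), seed = 5)
  cfg <- cfg_off()
  for (meth in c("fisher", "stouffer", "rem")) {
    tab <- run_meta(cl, cfg, meth)
    expect_true(all(tab$P.Value >= 0 & tab$P.Value <= 1))
    expect_true(all(tab$adj.P.Val >= tab$P.Value))
  }
  tab <- run_meta(cl, cfg, "rankprod", n_perm = 100)
  expect_true(all(tab$P.Value > 0 & tab$P.Value <= 1))
})
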