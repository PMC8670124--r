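# Federated filtering and normalization against direct pooled oracles.

test_that("federated median library size equals the pooled median", {
  cfg <- cfg_off()
  cl <- clients_with_libsizes(list(10, 20, 30))
  expect_equal(federated_median_lib_size(cl, cfg), 20)
  cl2 <- clients_with_libsizes(list(c(10, 40), c(20, 30)))
  expect_equal(federated_median_lib_size(cl2, cfg), 25)
  # one client holding everything reduces to its local median
  cl3 <- clients_with_libsizes(list(c(12, 99, 7, 45, 23)))
  expect_equal(federated_median_lib_size(cl3, cfg),
               stats::median(c(12, 99, 7, 45, 23)))
  # random property: exact match with sort-and-pick on the pooled list
  set.seed(5)
  for (i in 1:10) {
    libs <- split(sample.int(5e5, 13), rep(1:3, c(4, 4, 5)))
    cl4 <- clients_with_libsizes(libs)
    expect_equal(federated_median_lib_size(cl4, cfg),
                 stats::median(unlist(libs)))
  }
})

test_that("federated expression filter equals the centralized filter and is partition-invariant", {
  set.seed(17)
  cfg <- cfg_off()
  for (i in 1:25) {
    d <- toy_dataset(G = 30, n = 12, seed = 1000 + i,
                     baseline_mean = stats::runif(1, 0, 6), baseline_sd = 3)
    expected <- oracle_filter(d$counts, d$design, "group")
    split <- split_cohorts(d, c(1, 1, 1), seed = i)
    got <- federated_filter_by_expr(split, cfg)
    expect_identical(got$keep, unname(expected))
    got1 <- federated_filter_by_expr(pooled_client(d), cfg)
    expect_identical(got1$keep, got$keep)
  }
})

test_that("an all-zero gene is always dropped and empty groups are refused", {
  d <- toy_dataset(G = 40, n = 12, seed = 9)
  d$counts["g0001", ] <- 0
  got <- federated_filter_by_expr(pooled_client(d), cfg_off())
  expect_false(got$keep[1])
  d2 <- d
  d2$design[, "group"] <- 0
  expect_error(federated_filter_by_expr(list(fv_client(d2$counts, d2$design)),
                                        cfg_off()),
               "empty group")
})

test_that("upper-quartile factors match the pooled formula and multiply to one", {
  cfg <- cfg_off()
  # identical samples -> all factors exactly 1
  counts <- matrix(rep(c(5, 50, 500, 20), 4), 4, 4,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  des <- cbind(intercept = 1, group = c(0, 0, 1, 1))
  rownames(des) <- colnames(counts)
  cl <- list(fv_client(validate_counts(counts), validate_design(des, "group")))
  f <- federated_uq_factors(cl, cfg)[[1]]
  expect_equal(unname(f), rep(1, 4))

  # 4-sample toy against the direct pooled computation
  set.seed(2)
  counts2 <- matrix(rpois(40, 60), 10, 4,
                    dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  rownames(des) <- colnames(counts2)
  cl2a <- fv_client(validate_counts(counts2[, 1:2]),
                    validate_design(des[1:2, ], "group"))
  cl2b <- fv_client(validate_counts(counts2[, 3:4]),
                    validate_design(des[3:4, ], "group"))
  fed <- unlist(federated_uq_factors(list(cl2a, cl2b), cfg))
  lib <- colSums(counts2)
  uq <- apply(sweep(counts2, 2, lib, "/"), 2, stats::quantile, probs = 0.75,
              names = FALSE)
  expect_equal(unname(fed), unname(uq / exp(mean(log(uq)))), tolerance = 1e-12)
  expect_equal(prod(fed), 1, tolerance = 1e-12)

  # a sample with zero upper quartile is named
  counts3 <- counts2; counts3[3:10, 2] <- 0
  expect_error(federated_uq_factors(
    list(fv_client(validate_counts(counts3), validate_design(`rownames<-`(des[rep(1, 4), ], colnames(counts3)), "group"))),
    cfg), "s2")
})

test_that("log-CPM follows the offset formula and is monotone in counts", {
  counts <- matrix(c(0, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  got <- log_cpm(counts, lib_size = 1e6 - 1, factor = 1)
  expect_equal(got["g1", 1], log2(0.5), tolerance = 1e-12)
  expect_equal(got["g2", 1], log2(10.5), tolerance = 1e-12)
  x <- matrix(0:50, ncol = 1, dimnames = list(paste0("g", 0:50), "s1"))
  expect_true(all(diff(log_cpm(x, 5e5, 1)[, 1]) > 0))
  # doubling counts and library size leaves large-count CPM nearly unchanged
  big <- matrix(c(1e4, 1e5), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  a <- log_cpm(big, 1e6, 1)
  b <- log_cpm(2 * big, 2e6, 1)
  expect_equal(a, b, tolerance = 1e-3)
})

test_that("preprocessing rounds exchange only aggregates, never per-gene-per-sample values", {
  d <- toy_dataset(G = 80, n = 18, seed = 21)
  cl <- split_cohorts(d, c(1, 1, 1), seed = 4)
  res <- suppressWarnings(run_fedvoom(cl, cfg_on()))
  bus <- attr(res, "bus")
  expect_true(all(vapply(bus$agg_inbox, function(m)
    identical(m$class, "fv_masked_message"), logical(1))))
  expect_true(all(vapply(bus$comp_inbox, function(m)
    identical(m$class, "fv_noise_share"), logical(1))))
  # every exchanged matrix has at most one column of per-gene or scalar
  # aggregates, or is a small model-level block (k x k, 1 x k)
  G <- sum(attr(res, "model")$keep)
  n <- 18
  for (r in bus$log) {
    expect_true(r$shape[2] <= ncol(d$design)^2)
    expect_true(r$shape[1] <= max(G, nrow(d$counts)))
    expect_false(all(r$shape == c(G, n)))  # never a full expression matrix
  }
})
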