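# Federated preprocessing: expression filtering, upper-quartile
# normalization, and local log2-CPM.
#
# Everything exchanged here is either a per-gene aggregate (masked integer
# totals and pass counts) or a per-sample scalar (library size quantile
# factors), never a per-sample expression value.

# Pooled median of integer values by bisection: each iteration exchanges only
# the masked count of samples at or below the pivot. Search range covers any
# realistic library size (column sums < 2^40).
fed_median_libsize <- function(lib_sizes, n_total, bus, config, hi_bound = 2^40) {
  if (n_total < 1) stop("no samples in the pooled study")
  order_stat <- function(k, tag) {
    lo <- 0; hi <- hi_bound; iter <- 0L
    while (lo < hi) {
      mid <- floor((lo + hi) / 2)
      cnt <- as.numeric(exchange_round(
        bus, sprintf("median_bisect_%s_%02d", tag, iter),
        lapply(lib_sizes, function(x) matrix(sum(x < mid + 1), 1, 1)),
        "modular", config))
      if (cnt >= k) hi <- mid else lo <- mid + 1
      iter <- iter + 1L
    }
    lo
  }
  k1 <- floor((n_total + 1) / 2)
  k2 <- ceiling((n_total + 1) / 2)
  v1 <- order_stat(k1, "k1")
  v2 <- if (k2 == k1) v1 else order_stat(k2, "k2")
  (v1 + v2) / 2
}

#' Federated median library size
#'
#' Exact median of the pooled per-sample library sizes (column sums over all
#' genes), computed by binary search on the integer value range; each
#' iteration exchanges only a masked count of samples below the pivot, never
#' the library sizes themselves. For an even pooled sample count the mean of
#' the two middle values is returned.
#'
#' @param clients list of [fv_client()] objects.
#' @param config [fv_config()].
#' @return pooled median library size (scalar).
#' @export
federated_median_lib_size <- function(clients, config = fv_config("group", masking = FALSE)) {
  clients <- harmonize_clients(clients)
  bus <- fv_bus()
  lib_sizes <- lapply(clients, function(cl) colSums(cl$counts))
  n_total <- sum(lengths(lib_sizes))
  fed_median_libsize(lib_sizes, n_total, bus, config)
}

fed_filter_by_expr <- function(clients, lib_sizes, med_lib, n_total, bus, config) {
  cpm_cutoff <- config$min_count / med_lib * 1e6
  gc <- attr(clients[[1]]$design, "group_columns")

  group_sums <- exchange_round(bus, "group_sizes",
                               lapply(clients, function(cl)
                                 matrix(colSums(cl$design[, gc, drop = FALSE]), nrow = 1)),
                               "modular", config)
  sizes <- as.numeric(group_sums)
  if (length(gc) == 1L) sizes <- c(sizes, n_total - sizes)
  min_n_samples <- min(sizes)
  if (min_n_samples == 0) stop("empty group: a target class has no samples pooled")

  totals <- exchange_round(bus, "gene_totals",
                           lapply(clients, function(cl) cbind(rowSums(cl$counts))),
                           "modular", config)

  pass_counts <- exchange_round(bus, "cpm_pass_counts",
                                lapply(seq_along(clients), function(i) {
                                  cpm <- sweep(clients[[i]]$counts, 2,
                                               lib_sizes[[i]] / 1e6, "/")
                                  cbind(rowSums(cpm >= cpm_cutoff))
                                }),
                                "modular", config)

  keep <- as.numeric(totals) > config$min_total_count &
    as.numeric(pass_counts) >= min_n_samples
  list(keep = keep, cpm_cutoff = cpm_cutoff, min_n_samples = min_n_samples,
       median_lib_size = med_lib, totals = as.numeric(totals),
       pass_counts = as.numeric(pass_counts))
}

#' Federated expression filter
#'
#' A gene is kept iff its pooled total count strictly exceeds
#' `min_total_count` AND at least `min_n_samples` pooled samples express it at
#' or above the CPM cutoff `min_count / median_lib_size * 1e6` (CPM computed
#' against each sample's own raw library size). `min_n_samples` is the
#' smallest pooled group size derived from the design's group indicator
#' columns. Per-gene totals, per-gene pass counts and group sizes travel as
#' masked integers only.
#'
#' @param clients list of [fv_client()] objects.
#' @param config [fv_config()].
#' @return list with `keep` (logical per gene), `cpm_cutoff`,
#'   `min_n_samples`, `median_lib_size`.
#' @export
federated_filter_by_expr <- function(clients, config) {
  clients <- harmonize_clients(clients)
  bus <- fv_bus()
  lib_sizes <- lapply(clients, function(cl) colSums(cl$counts))
  n_total <- sum(lengths(lib_sizes))
  med <- fed_median_libsize(lib_sizes, n_total, bus, config)
  fed_filter_by_expr(clients, lib_sizes, med, n_total, bus, config)
}

fed_uq_factors <- function(counts_kept, lib_sizes, n_total, bus, config) {
  K <- length(counts_kept)
  uq <- vector("list", K)
  for (i in seq_len(K)) {
    rel <- sweep(counts_kept[[i]], 2, lib_sizes[[i]], "/")
    uq[[i]] <- apply(rel, 2, stats::quantile, probs = 0.75, names = FALSE)
    if (any(uq[[i]] == 0))
      stop("upper-quartile statistic is zero for sample '",
           colnames(counts_kept[[i]])[which(uq[[i]] == 0)[1]],
           "': sample too sparse after filtering")
  }
  sum_log <- as.numeric(exchange_round(bus, "uq_log_sum",
                                       lapply(uq, function(u) matrix(sum(log(u)), 1, 1)),
                                       "gaussian", config))
  gm <- exp(sum_log / n_total)
  factors <- lapply(uq, function(u) u / gm)
  list(uq = uq, factors = factors, geo_mean = gm)
}

#' Federated upper-quartile normalization factors
#'
#' Per sample, the 75th percentile (linear-interpolation quantile) of counts
#' divided by library size over the kept genes, rescaled so that the
#' geometric mean of the factors over all pooled samples is 1. Only the sum
#' of log quantile statistics is exchanged (Gaussian-masked), matching the
#' property that scaled normalization factors cannot reveal private data.
#'
#' @param clients list of [fv_client()] objects whose counts are already
#'   restricted to the kept genes.
#' @param config [fv_config()].
#' @return list over clients of per-sample scaled normalization factors.
#' @export
federated_uq_factors <- function(clients, config) {
  clients <- harmonize_clients(clients)
  bus <- fv_bus()
  lib_sizes <- lapply(clients, function(cl) colSums(cl$counts))
  n_total <- sum(lengths(lib_sizes))
  fed_uq_factors(lapply(clients, `[[`, "counts"), lib_sizes, n_total,
                 bus, config)$factors
}

#' Log2 counts per million
#'
#' `log2((count + 0.5) / (lib_size * factor + 1) * 1e6)`, the standard voom
#' transformation with normalized effective library sizes. Purely local;
#' nothing is exchanged.
#'
#' @param counts gene x sample count matrix.
#' @param lib_size per-sample raw library sizes (column sums over all genes).
#' @param factor per-sample scaled normalization factors (default 1).
#' @return matrix of log2-CPM values, same shape as `counts`.
#' @export
log_cpm <- function(counts, lib_size = colSums(counts), factor = 1) {
  eff <- lib_size * factor
  t(log2(t(counts + 0.5) / (eff + 1) * 1e6))
}
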