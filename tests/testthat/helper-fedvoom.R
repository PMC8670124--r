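# Shared fixtures. Everything is generated in code at test time; seeds are
# fixed so the suite is deterministic.

cfg_off <- function(...) fv_config("group", masking = FALSE, ...)
cfg_on <- function(seed = 7, ...) fv_config("group", masking = TRUE, seed = seed, ...)

# small two-class dataset used across files
toy_dataset <- function(G = 200, n = 24, seed = 3, ...) {
  generate_dataset(simulation_spec(n_genes = G, n_samples = n, seed = seed, ...))
}

# clients whose library sizes are exactly the given values
# (single gene holding the whole library)
clients_with_libsizes <- function(libs_per_client) {
  lapply(seq_along(libs_per_client), function(i) {
    libs <- libs_per_client[[i]]
    counts <- matrix(libs, nrow = 1,
                     dimnames = list("g1", sprintf("c%d_s%d", i, seq_along(libs))))
    design <- cbind(intercept = 1, group = rep_len(c(0, 1), length(libs)))
    rownames(design) <- colnames(counts)
    fv_client(validate_counts(counts), validate_design(design, "group"))
  })
}

# centralized expression filter, written directly from its definition:
# the independent oracle for the federated version
oracle_filter <- function(pooled_counts, pooled_design, group_columns,
                          min_count = 10, min_total_count = 15) {
  lib <- colSums(pooled_counts)
  med <- stats::median(lib)
  cutoff <- min_count / med * 1e6
  sizes <- colSums(pooled_design[, group_columns, drop = FALSE])
  if (length(group_columns) == 1L) sizes <- c(sizes, nrow(pooled_design) - sizes)
  min_n <- min(sizes)
  cpm <- sweep(pooled_counts, 2, lib / 1e6, "/")
  rowSums(pooled_counts) > min_total_count & rowSums(cpm >= cutoff) >= min_n
}

# brute-force BH step-up, independent of stats::p.adjust
oracle_bh <- function(p) {
  G <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * G / seq_len(G))
  q <- rev(cummin(rev(q)))
  out <- numeric(G)
  out[o] <- q
  out
}

pooled_client <- function(dataset) list(fv_client(dataset$counts, dataset$design))
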