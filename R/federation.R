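# Three-party protocol plumbing.
#
# Clients send masked parameter matrices to the aggregator and the matching
# noise shares to the compensator; the compensator only ever sees noise, the
# aggregator only ever sees masked values plus the compensator's aggregate
# noise. Role separation is enforced structurally: each channel rejects
# payloads of the wrong type. Transport is an in-process synchronous bus; a
# network transport could be substituted behind the same two send functions.

#' Create an in-process protocol bus
#'
#' @return environment with aggregator/compensator channels and a round log
#'   (round name, scheme, payload shape only — never raw data).
#' @export
fv_bus <- function() {
  bus <- new.env(parent = emptyenv())
  bus$agg_inbox <- list()
  bus$comp_inbox <- list()
  bus$log <- list()
  class(bus) <- "fv_bus"
  bus
}

bus_send_to_aggregator <- function(bus, msg, round_name, client_id) {
  if (!inherits(msg, "fv_masked_message"))
    stop("protocol error: aggregator channel accepts only masked messages (round '",
         round_name, "')")
  bus$agg_inbox[[length(bus$agg_inbox) + 1L]] <-
    list(round = round_name, client = client_id, class = class(msg),
         scheme = msg$scheme, shape = msg$shape)
  invisible(msg)
}

bus_send_to_compensator <- function(bus, share, round_name, client_id) {
  if (!inherits(share, "fv_noise_share"))
    stop("protocol error: compensator channel accepts only noise shares (round '",
         round_name, "')")
  bus$comp_inbox[[length(bus$comp_inbox) + 1L]] <-
    list(round = round_name, client = client_id, class = class(share),
         scheme = share$scheme, shape = share$shape)
  invisible(share)
}

# deterministic per-(seed, client, round) noise stream
stream_seed <- function(seed, client_id, round_name) {
  u <- utf8ToInt(round_name)
  h <- sum(u * seq_along(u)) %% 65521
  as.integer((as.numeric(seed) * 48271 + client_id * 16807 + h * 131) %% 2147483647)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Execute one masked aggregation round
#'
#' Each client masks its local payload (modular scheme for non-negative
#' integer parameters, Gaussian scheme for real parameters), sends the masked
#' message to the aggregator and the noise share to the compensator; the
#' denoised elementwise sum over clients is returned. With `config$masking =
#' FALSE` the same round runs with zero noise.
#'
#' @param bus protocol bus from [fv_bus()].
#' @param round_name unique name of the round (used for logging and for
#'   deriving the per-client noise stream).
#' @param payloads list over clients of numeric matrices, identical shapes.
#' @param scheme `"modular"` or `"gaussian"`.
#' @param config [fv_config()].
#' @return numeric matrix: the exact (modular) or near-exact (Gaussian) sum
#'   of the payloads.
#' @export
exchange_round <- function(bus, round_name, payloads, scheme, config) {
  stopifnot(scheme %in% c("modular", "gaussian"))
  shapes <- lapply(payloads, dim)
  if (length(unique(shapes)) > 1L)
    stop("protocol error in round '", round_name, "': payload shape mismatch")
  messages <- vector("list", length(payloads))
  shares <- vector("list", length(payloads))
  for (i in seq_along(payloads)) {
    M <- as.matrix(payloads[[i]])
    if (config$masking) {
      mk <- with_seed(stream_seed(config$seed, i, round_name), {
        if (scheme == "modular") mask_integer(M, config$modulus)
        else mask_real(M, config$gauss_var)
      })
    } else {
      mk <- if (scheme == "modular")
        mask_integer(M, config$modulus,
                     noise = zp_from_num(matrix(0, nrow(M), ncol(M))))
      else mask_real(M, config$gauss_var, noise = matrix(0, nrow(M), ncol(M)))
    }
    bus_send_to_aggregator(bus, mk$message, round_name, i)
    bus_send_to_compensator(bus, mk$share, round_name, i)
    messages[[i]] <- mk$message
    shares[[i]] <- mk$share
  }
  bus$log[[length(bus$log) + 1L]] <-
    list(round = round_name, scheme = scheme,
         shape = dim(as.matrix(payloads[[1]])), n_clients = length(payloads))
  aggregate_denoise(messages, shares, config$modulus)
}

## ---- gene universe and design harmonization ------------------------------

harmonize_clients <- function(clients) {
  stopifnot(length(clients) >= 1L)
  clients <- lapply(clients, function(cl) {
    if (!inherits(cl, "fv_client")) fv_client(cl$counts, cl$design) else cl
  })
  universe <- rownames(clients[[1]]$counts)
  for (cl in clients[-1]) universe <- intersect(universe, rownames(cl$counts))
  dropped <- unique(unlist(lapply(clients, function(cl)
    setdiff(rownames(cl$counts), universe))))
  if (length(dropped))
    warning("dropping ", length(dropped),
            " gene(s) absent from some clients: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (length(universe) == 0L) stop("empty common gene universe across clients")
  cn <- colnames(clients[[1]]$design)
  gc <- attr(clients[[1]]$design, "group_columns")
  for (cl in clients[-1]) {
    if (!identical(colnames(cl$design), cn))
      stop("design columns differ across clients (must match in name and order)")
    if (!identical(attr(cl$design, "group_columns"), gc))
      stop("group columns differ across clients")
  }
  lapply(clients, function(cl) {
    cl$counts <- cl$counts[universe, , drop = FALSE]
    cl
  })
}

#' Append dataset-indicator columns for batch modeling
#'
#' Models cohort-level batch effects by adding `m - 1` binary dataset
#' indicator columns (one per cohort except the first) consistently to every
#' client's design matrix.
#'
#' @param clients list of [fv_client()] objects, one per dataset/batch.
#' @return list of clients with augmented designs.
#' @export
add_batch_indicators <- function(clients) {
  m <- length(clients)
  if (m < 2L) return(clients)
  for (i in seq_along(clients)) {
    d <- clients[[i]]$design
    gc <- attr(d, "group_columns")
    ind <- matrix(0, nrow(d), m - 1L,
                  dimnames = list(rownames(d), paste0("batch", 2:m)))
    if (i > 1L) ind[, i - 1L] <- 1
    d2 <- cbind(d, ind)
    clients[[i]]$design <- validate_design(d2, gc)
  }
  clients
}

## ---- top-level workflow --------------------------------------------------

#' Federated voom differential expression analysis
#'
#' Runs the full privacy-aware workflow over `K` clients: federated
#' expression filtering, federated upper-quartile normalization, local
#' log2-CPM, a two-pass federated voom + weighted linear fit, and
#' aggregator-side empirical-Bayes moderated t-statistics with BH adjustment.
#' With a single client the same code path is the centralized (pooled)
#' reference pipeline.
#'
#' @param clients list of [fv_client()] objects (or lists with `counts` and
#'   `design`).
#' @param config [fv_config()] naming the tested coefficient.
#' @param verbose log one line per protocol round to stderr (round name and
#'   payload shape only; raw data is never logged).
#' @return `fv_results` data frame with columns `gene, logFC, AveExpr, t,
#'   P.Value, adj.P.Val`, sorted by p-value; attributes `model` (per-gene fit
#'   state in input gene order) and `bus` (the protocol round log).
#' @examples
#' sim <- generate_dataset(simulation_spec(n_genes = 120, n_samples = 24, seed = 5))
#' res <- run_fedvoom(list(fv_client(sim$counts, sim$design)),
#'                    fv_config("group", masking = FALSE))
#' head(res)
#' @export
run_fedvoom <- function(clients, config, verbose = FALSE) {
  clients <- harmonize_clients(clients)
  K <- length(clients)
  if (K < 3L && K > 1L && config$masking)
    warning("fewer than three clients: the non-collusion privacy assumption is weak")
  if (!(config$coefficient %in% colnames(clients[[1]]$design)))
    stop("tested coefficient '", config$coefficient, "' not found in design")
  bus <- fv_bus()

  m_i <- vapply(clients, function(cl) ncol(cl$counts), integer(1))
  n_total <- as.numeric(exchange_round(bus, "n_samples",
                                       lapply(m_i, function(x) matrix(x, 1, 1)),
                                       "modular", config))

  # privacy refusal: a design column nonzero in exactly one pooled sample
  # would let X^T Y reveal that sample's expression profile
  nz <- exchange_round(bus, "design_nonzero_counts",
                       lapply(clients, function(cl)
                         matrix(colSums(cl$design != 0), nrow = 1)),
                       "modular", config)
  if (any(nz == 1)) {
    bad <- colnames(clients[[1]]$design)[which(nz == 1)]
    stop("privacy refusal: design column(s) nonzero in exactly one sample: ",
         paste(bad, collapse = ", "),
         " (X^T Y would disclose that sample's expression profile)")
  }

  lib_sizes <- lapply(clients, function(cl) colSums(cl$counts))

  med_lib <- fed_median_libsize(lib_sizes, n_total, bus, config)
  filt <- fed_filter_by_expr(clients, lib_sizes, med_lib, n_total, bus, config)
  if (verbose) round_log(bus)
  kept <- filt$keep
  if (sum(kept) < 10L) stop("fewer than 10 genes pass the expression filter")

  counts_kept <- lapply(clients, function(cl) cl$counts[kept, , drop = FALSE])
  nf <- fed_uq_factors(counts_kept, lib_sizes, n_total, bus, config)
  eff_lib <- lapply(seq_len(K), function(i) lib_sizes[[i]] * nf$factors[[i]])

  Y <- lapply(seq_len(K), function(i)
    log_cpm(counts_kept[[i]], lib_sizes[[i]], nf$factors[[i]]))
  X <- lapply(clients, function(cl) cl$design)

  fit <- fed_two_pass(X, Y, eff_lib, n_total, bus, config)
  if (verbose) round_log(bus)

  sq <- squeeze_var(fit$sigma^2, fit$df_residual)
  j <- match(config$coefficient, colnames(clients[[1]]$design))
  mt <- moderated_t(fit$beta[, j], fit$unscaled_se[, j],
                    sq$s_post_sq, sq$d0, fit$df_residual)
  adj <- bh_adjust(mt$p)

  out <- new_results_table(gene = rownames(clients[[1]]$counts)[kept],
                           logFC = fit$beta[, j], AveExpr = fit$amean,
                           t = mt$t, P.Value = mt$p, adj.P.Val = adj)
  attr(out, "model") <- list(gene = rownames(clients[[1]]$counts)[kept],
                             beta = fit$beta, unscaled_se = fit$unscaled_se,
                             sigma = fit$sigma, amean = fit$amean,
                             df_residual = fit$df_residual,
                             d0 = sq$d0, s0_sq = sq$s0_sq,
                             s_post_sq = sq$s_post_sq,
                             n_samples = n_total, keep = kept,
                             trend = fit$trend, coefficient = config$coefficient)
  attr(out, "bus") <- bus
  out
}

round_log <- function(bus) {
  for (r in bus$log)
    message(sprintf("[round] %-28s scheme=%-8s shape=%s x %d clients",
                    r$round, r$scheme, paste(r$shape, collapse = "x"), r$n_clients))
  bus$log <- list()
  invisible(NULL)
}
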