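# Negative-binomial count simulator with planted differential expression,
# covariates, batch effects, and cohort splits of configurable imbalance.
# This is the package's test bed: it emulates a bulk RNA-seq two-class study
# distributed over cohorts of unequal size, class composition and confounder
# distribution.

#' Simulation specification
#'
#' Counts are drawn as `NB(mean = lib_size/1e6 * 2^eta, Var = mu + phi*mu^2)`
#' with `eta = baseline + class*lfc + age/sex terms`; gene-wise dispersions
#' `phi` are log-normal around 0.1, the typical bulk RNA-seq regime, which
#' makes the mean-variance trend non-trivial.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_samples number of samples (default 150).
#' @param de_fraction fraction of genes with planted differential expression
#'   (default 0.1).
#' @param lfc planted absolute log2 fold change (default 2); sign random per
#'   gene.
#' @param lfc_sd if > 0, planted log2 fold changes are drawn from
#'   `Normal(±lfc, lfc_sd)` instead of a point mass.
#' @param baseline_mean,baseline_sd normal distribution of baseline log2-CPM
#'   (defaults 5 and 2).
#' @param dispersion_meanlog,dispersion_sdlog log-normal gene dispersion
#'   parameters (defaults `log(0.1)` and 0.4).
#' @param lib_size_range uniform range of per-sample library sizes (default
#'   1e6..3e6).
#' @param class_fraction fraction of samples in the target class (default 0.5).
#' @param covariate_fraction fraction of genes carrying age/sex covariate
#'   effects (default 0.1).
#' @param seed RNG seed.
#' @return validated list of class `fv_sim_spec`.
#' @export
simulation_spec <- function(n_genes = 2000, n_samples = 150,
                            de_fraction = 0.1, lfc = 2, lfc_sd = 0,
                            baseline_mean = 5, baseline_sd = 2,
                            dispersion_meanlog = log(0.1), dispersion_sdlog = 0.4,
                            lib_size_range = c(1e6, 3e6),
                            class_fraction = 0.5,
                            covariate_fraction = 0.1,
                            seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must lie in [0, 1]")
  if (class_fraction <= 0 || class_fraction >= 1)
    stop("class_fraction must lie strictly in (0, 1)")
  if (any(lib_size_range <= 0) || diff(lib_size_range) < 0)
    stop("lib_size_range must be positive and increasing")
  if (n_genes < 2 || n_samples < 4) stop("infeasible spec: too few genes or samples")
  structure(as.list(environment()), class = "fv_sim_spec")
}

#' Generate a synthetic RNA-seq dataset with planted signal
#'
#' @param spec a [simulation_spec()].
#' @return list with `counts` (genes x samples), `design` (intercept, group,
#'   age, sex; `group` is the group column), `truth` (per-gene `is_de`,
#'   `true_lfc`; per-sample class/covariates), and `sim_params` (per-cell NB
#'   means and gene dispersions, used for batch-effect injection).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "fv_sim_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes; n <- spec$n_samples
  genes <- sprintf("g%04d", seq_len(G))
  samples <- sprintf("s%03d", seq_len(n))

  n_pos <- round(n * spec$class_fraction)
  cls <- numeric(n); cls[sample.int(n, n_pos)] <- 1
  age <- stats::rnorm(n, 50, 10)
  sex <- stats::rbinom(n, 1, 0.5)
  lib <- round(stats::runif(n, spec$lib_size_range[1], spec$lib_size_range[2]))

  baseline <- stats::rnorm(G, spec$baseline_mean, spec$baseline_sd)
  is_de <- logical(G)
  is_de[sample.int(G, round(G * spec$de_fraction))] <- TRUE
  lfc <- numeric(G)
  sgn <- sample(c(-1, 1), sum(is_de), replace = TRUE)
  lfc[is_de] <- if (spec$lfc_sd > 0)
    sgn * abs(stats::rnorm(sum(is_de), spec$lfc, spec$lfc_sd))
  else sgn * spec$lfc

  age_coef <- sex_coef <- numeric(G)
  ncov <- round(G * spec$covariate_fraction)
  age_coef[sample.int(G, ncov)] <- stats::rnorm(ncov, 0, 0.02)
  sex_coef[sample.int(G, ncov)] <- stats::rnorm(ncov, 0, 0.5)

  eta <- outer(baseline, rep(1, n)) +
    outer(lfc, cls) + outer(age_coef, age - 50) + outer(sex_coef, sex)
  mu <- sweep(2^eta, 2, lib / 1e6, "*")
  if (any(!is.finite(mu))) stop("infeasible spec: non-finite NB means")
  phi <- stats::rlnorm(G, spec$dispersion_meanlog, spec$dispersion_sdlog)

  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / phi, n)),
                   G, n, dimnames = list(genes, samples))
  design <- cbind(intercept = 1, group = cls, age = age, sex = sex)
  rownames(design) <- samples
  design <- validate_design(design, "group")

  list(counts = validate_counts(counts), design = design,
       truth = list(genes = data.frame(gene = genes, is_de = is_de,
                                       true_lfc = lfc),
                    samples = data.frame(sample = samples, class = cls,
                                         age = age, sex = sex)),
       sim_params = list(mu = `dimnames<-`(mu, list(genes, samples)),
                         phi = phi, spec = spec))
}

# apportion n into parts proportional to ratios (largest remainder)
apportion <- function(n, ratios) {
  raw <- n * ratios / sum(ratios)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Split a dataset into cohorts with controlled imbalance
#'
#' Samples are assigned without replacement so that realized cohort sizes
#' follow `ratios` (largest-remainder apportionment) and realized per-cohort
#' class fractions match the requested ones within one sample. A non-zero
#' `confounder_shift` biases a cohort's assignment toward samples whose
#' continuous covariate (age) lies near the global mean plus the shift,
#' emulating cohort-level confounding such as differing ischemic times.
#'
#' @param dataset output of [generate_dataset()].
#' @param ratios cohort size ratios, e.g. `c(1, 3, 9)`.
#' @param class_fractions optional per-cohort target-class fractions.
#' @param confounder_shift optional per-cohort shifts of the age mean.
#' @param seed RNG seed for the assignment.
#' @return list of [fv_client()] objects; attribute `assignment` maps sample
#'   id to cohort, attribute `sim` carries per-cohort NB parameters.
#' @export
split_cohorts <- function(dataset, ratios, class_fractions = NULL,
                          confounder_shift = NULL, seed = 1L) {
  set.seed(seed)
  n <- ncol(dataset$counts)
  K <- length(ratios)
  sizes <- apportion(n, ratios)
  if (any(sizes < 2)) stop("infeasible split: a cohort would have fewer than 2 samples")
  cls <- dataset$truth$samples$class
  P <- sum(cls == 1)

  if (is.null(class_fractions)) {
    pos <- apportion(P, ratios)
  } else {
    stopifnot(length(class_fractions) == K)
    target <- sizes * class_fractions
    pos <- round(target)
    deficit <- P - sum(pos)
    ord <- order(abs(target - pos))
    i <- 1L
    while (deficit != 0 && i <= K) {
      cand <- pos[ord[i]] + sign(deficit)
      if (abs(cand - target[ord[i]]) <= 1 && cand >= 0 && cand <= sizes[ord[i]]) {
        pos[ord[i]] <- cand
        deficit <- deficit - sign(deficit)
      } else i <- i + 1L
    }
    if (deficit != 0)
      stop("infeasible class fractions: ", abs(deficit),
           " class-", if (deficit > 0) 1 else 0,
           " sample(s) cannot be placed within one sample of the requested fractions")
  }
  if (any(pos > sizes)) stop("infeasible class fractions: more positives than cohort size")

  age <- dataset$truth$samples$age
  shift <- if (is.null(confounder_shift)) rep(0, K) else confounder_shift
  stopifnot(length(shift) == K, all(is.finite(shift)))

  assign_from <- function(pool, m, c_idx) {
    if (m == 0) return(integer(0))
    # sharp kernel so cohort covariate means land near the requested shift
    w <- stats::dnorm(age[pool], mean(age) + shift[c_idx],
                      stats::sd(age) / 3) + 1e-12
    pool[sample.int(length(pool), m, prob = w)]
  }
  cohort <- integer(n)
  pool1 <- which(cls == 1); pool0 <- which(cls == 0)
  # strongly shifted cohorts pick first, before the pool is depleted
  for (c_idx in order(-abs(shift))) {
    take1 <- assign_from(pool1, pos[c_idx], c_idx)
    pool1 <- setdiff(pool1, take1)
    take0 <- assign_from(pool0, sizes[c_idx] - pos[c_idx], c_idx)
    pool0 <- setdiff(pool0, take0)
    cohort[c(take1, take0)] <- c_idx
  }
  if (any(cohort == 0)) stop("internal error: unassigned samples")

  gc <- attr(dataset$design, "group_columns")
  out <- lapply(seq_len(K), function(c_idx) {
    idx <- sort(which(cohort == c_idx))
    d <- dataset$design[idx, , drop = FALSE]
    cl <- fv_client(dataset$counts[, idx, drop = FALSE],
                    validate_design(d, gc))
    attr(cl, "sim") <- list(mu = dataset$sim_params$mu[, idx, drop = FALSE],
                            phi = dataset$sim_params$phi)
    cl
  })
  attr(out, "assignment") <- stats::setNames(cohort,
                                             dataset$truth$samples$sample)
  out
}

#' Inject cohort-level batch effects and the covariates that absorb them
#'
#' Multiplies the NB means of a random fraction of genes by `2^shift` in each
#' shifted cohort and regenerates those counts, then appends `m - 1` binary
#' dataset-indicator columns to every cohort's design so the linear model can
#' absorb the effect. Cohorts with zero shift keep their counts unchanged.
#'
#' @param cohorts list of cohorts from [split_cohorts()].
#' @param shifts per-cohort log2 shifts.
#' @param affected_fraction fraction of genes subject to the batch effect
#'   (default 0.2).
#' @param seed RNG seed.
#' @return list of cohorts with perturbed counts and augmented designs.
#' @export
inject_batch_effect <- function(cohorts, shifts, affected_fraction = 0.2,
                                seed = 1L) {
  stopifnot(length(shifts) == length(cohorts), all(is.finite(shifts)))
  set.seed(seed)
  G <- nrow(cohorts[[1]]$counts)
  affected <- sample.int(G, round(G * affected_fraction))
  for (i in seq_along(cohorts)) {
    if (shifts[i] == 0) next
    sim <- attr(cohorts[[i]], "sim")
    if (is.null(sim)) stop("cohorts must carry simulation parameters (use split_cohorts)")
    mu <- sim$mu[affected, , drop = FALSE] * 2^shifts[i]
    counts <- cohorts[[i]]$counts
    counts[affected, ] <- matrix(
      stats::rnbinom(length(mu), mu = mu,
                     size = rep(1 / sim$phi[affected], ncol(mu))),
      nrow(mu), ncol(mu))
    sim2 <- attr(cohorts[[i]], "sim")
    cohorts[[i]] <- fv_client(validate_counts(counts), cohorts[[i]]$design)
    attr(cohorts[[i]], "sim") <- sim2
  }
  add_batch_indicators(cohorts)
}

#' Write a simulated, split dataset to per-cohort TSV directories
#'
#' @param cohorts list from [split_cohorts()].
#' @param truth the `truth` element of [generate_dataset()].
#' @param out_dir output directory; one `cohortN/` subdirectory per cohort
#'   with `counts.tsv` and `design.tsv`, plus `truth.tsv`.
#' @export
write_cohorts <- function(cohorts, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohorts)) {
    d <- file.path(out_dir, sprintf("cohort%d", i))
    dir.create(d, showWarnings = FALSE)
    write_counts(cohorts[[i]]$counts, file.path(d, "counts.tsv"))
    write_design(cohorts[[i]]$design, file.path(d, "design.tsv"))
  }
  utils::write.table(truth$genes, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
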