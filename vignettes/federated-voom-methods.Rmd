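---
title: "Methods: federated differential expression with voom precision weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated differential expression with voom precision weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedvoom)
```

## The problem

Differential expression studies gain power with sample size, but patient
RNA-seq profiles often cannot be pooled across institutions: expression data
combined with clinical covariates can identify donors, and data-protection
law restricts transfer of raw profiles. The alternatives are meta-analysis —
each site analyses its own cohort and only summary statistics are combined —
or federated computation, in which sites jointly evaluate the *pooled*
analysis without any site revealing its raw data. Meta-analysis is known to
degrade when cohorts differ in size, class composition, or confounder
distributions. fedvoom implements the federated route for the standard
voom/limma RNA-seq workflow, and ships the meta-analysis baselines so the two
can be compared on controlled synthetic data.

The design goal is *exact* equivalence: the federated result should match the
pooled centralized analysis to numerical noise, not approximate it.

## Parties and masking

Three roles participate:

* **clients** hold private counts `Y^i` (genes × samples) and designs `X^i`
  (samples × covariates);
* the **aggregator** combines masked local statistics and runs all
  gene-level inference on global aggregates;
* the **compensator** receives only the masking noise and returns its sum to
  the aggregator.

Every exchanged statistic is additively masked. Non-negative integer
parameters (sample counts, per-gene totals, CPM pass counts, group sizes)
use modular additive secret sharing over `Z_p` with `p = 2^54 − 33`, the
largest prime below `2^54`: the client sends `(M_i + N_i) mod p` with `N_i`
uniform on `Z_p` to the aggregator and `N_i` to the compensator. A masked
value is marginally uniform whatever the parameter, so the leakage is
exactly zero bits, and the reconstruction `(ΣM'_i − ΣN_i) mod p` is exact
provided `Σ M_i < p`. Real-valued parameters (normal-equation blocks,
residual sums of squares, log-scale aggregates) use Gaussian masking
`M_i + N_i`, `N_i ~ N(0, σ²)` with `σ² = 10^12`; the mutual information
between a local parameter and its masked version is then at most
`½·log2(1 + var(M_i)/σ²)` bits (`mi_bound()`), about `7·10^-13` bits for
parameters of magnitude `10^3`.

Numerical choices:

* Residues mod `p` exceed the 53-bit exact range of doubles, so modular
  arithmetic uses a two-limb base-`2^27` representation in which every
  intermediate (limb sums below `2^28`) is exactly representable; round
  trips are bit-exact by construction, without big-integer dependencies.
  Supported moduli are small test primes (≤ `2^26`, convenient for
  distributional tests) or production primes in `(2^53, 2^54)`.
* Gaussian masking costs ~`10^6 · ε ≈ 2·10^-10` absolute rounding error per
  aggregated entry. Propagated through the pipeline this stays below
  `10^-8` on t-statistics and p-values, which the masked-vs-unmasked
  acceptance test enforces. Larger `σ²` would raise this floor
  proportionally.
* Noise streams are derived deterministically from
  `(seed, client id, round name)`, so any run is reproducible; with
  `masking = FALSE` the identical protocol runs with zero noise.

All parties are assumed honest-but-curious and non-colluding. Two structural
safeguards are implemented: channels reject payloads of the wrong type (the
aggregator can never receive a noise share, the compensator never a masked
message), and the run is refused if any pooled design column is nonzero in
exactly one sample, because `X^T Y` would then reveal that sample's profile.

## The federated workflow

The pipeline reproduces the voom/limma count workflow step by step; with one
client it *is* the centralized pipeline (same code path), which defines the
oracle used throughout the tests.

1. **Gene universe.** Clients agree on the intersection of their gene
   identifiers, in the first client's order; dropped genes are reported. The
   protocol for this agreement is a design choice — the field's usual
   practice of sharing identifier lists reveals only gene names.
2. **Expression filtering.** A gene is kept iff its pooled total count
   strictly exceeds `min_total_count` (default 15) *and* at least
   `min_n_samples` pooled samples reach the CPM cutoff
   `min_count / median(lib) · 10^6` (default `min_count` 10), with CPM
   computed against each sample's own raw library size. `min_n_samples` is
   the smallest pooled group size; with a single 0/1 group column the
   reference group's size (`n − Σ`) is included in the minimum, since the
   smallest group may be either class. The pooled median library size is
   found by bisection on the integer range, each step exchanging one masked
   below-pivot count per client; totals and pass counts travel as masked
   integers. The reference implementation's large-sample `min.prop`
   adjustment is deliberately not replicated; only the two filters above
   are.
3. **Upper-quartile normalization.** Per sample, the type-7 75th percentile
   of `counts/lib` over kept genes, rescaled to geometric mean one across
   all pooled samples via one masked sum of logs. TMM is not offered: its
   reference-sample scheme would require disclosing a full expression
   profile. Library sizes are computed over all genes *before* filtering;
   quantiles over kept genes only.
4. **log-CPM.** `log2((y + 0.5)/(lib·f + 1)·10^6)`, locally.
5. **Pass 1 (unweighted fit).** Clients share Gaussian-masked `X^T X` (one
   sample-level block) and per-gene `X^T Y`; the aggregator solves
   `β = (X^T X)^{-1} X^T Y`, broadcasts `β`, and collects masked per-gene
   residual sums of squares, giving `σ = sqrt(SSE/(n − k))`. Per-gene mean
   log-CPM and the mean log2 effective library size each cost one more
   masked round.
6. **Mean-variance trend.** LOWESS (span 0.5, 3 robustness iterations) of
   `sqrt(σ)` on average log2 count, fitted wholly on the aggregator;
   degenerate x-ranges fall back to a constant median trend, and fitted
   values are floored at `10^-6` so weights stay finite. Clients
   interpolate the trend at each observation's fitted log2 count (clamped
   to the knot range — no extrapolation, preventing exploding weights) and
   invert to the fourth power: the voom precision weights.
7. **Pass 2 (weighted fit).** The same masked rounds with per-gene
   `X^T W X` / `X^T W Y` yield the final `β`, unscaled standard errors
   `sqrt(diag((X^T W X)^{-1}))`, and *weighted* residual variances. The
   weighted SSE is used in pass 2 (pass 1 uses the plain sum of squares) so
   that `σ` matches the weighted-regression definition the moderated
   t-statistic requires.
8. **Inference.** Everything downstream uses only global per-gene
   statistics: the scaled inverse-chi-square prior is fitted by the moment
   method on log variances (Newton inversion of the trigamma function,
   relative tolerance `10^-8`; if the excess log-variance is non-positive
   the prior degenerates to `d0 = ∞` with the mean observed variance),
   posterior variances are the df-weighted average, `t = β/(uSE · s_post)`
   with `d0 + n − k` degrees of freedom, and BH adjustment gives FDR
   q-values. A gene is called DE iff `|log2FC| > 1` and adjusted `p < 0.05`
   (strict inequalities). The empirical-Bayes fit uses no variance trend
   (`trend = FALSE` behaviour) and no fold-change shrinkage.

One deliberate correction: the unscaled standard error is
`sqrt(diag((X^T W X)^{-1}))`, the standard definition, not the Gram-matrix
diagonal sometimes (mis)printed for this workflow — only the former makes
the downstream moderated t equal the reference implementation's, which the
test suite verifies directly against limma on pooled data (agreement ~1e-13
on t, p, logFC and the prior df).

Design columns are supplied explicitly (including the intercept) and must
match across clients in name and order; the pooled model is therefore
unambiguous. Batch effects between cohorts are modeled by `m − 1` binary
dataset indicators appended consistently by `add_batch_indicators()` /
`inject_batch_effect()`.

Condition handling: a per-gene system with reciprocal condition number below
`10^-12` is reported as singular with the offending genes named — a safety
margin appropriate for double precision.

## Meta-analysis baselines

Each cohort runs the single-site pipeline; per-gene local p-values, fold
changes and moderated standard errors feed four combiners:

* **Fisher**: directional — two-sided p split into one-sided halves by the
  local fold-change sign, `χ² = −2Σ ln p` with `2K` df per direction, final
  `p = min(1, 2·min(p_up, p_down))`; p floored at `10^-300`.
* **Stouffer**: `z_i = Φ^{-1}(1 − p_i/2)·sign_i`, weights `sqrt(n_i)`
  (the weighting inside the published implementations is not specified;
  sqrt-n is the conventional choice and is documented as ours).
* **Random effects (DerSimonian–Laird)**: between-study `τ²` from the Q
  statistic, truncated at zero; per-cohort effect variance is the squared
  moderated standard error from that cohort's own fit — the natural local
  uncertainty available.
* **Rank product**: geometric mean of within-cohort ranks per direction;
  permutation p-values pool the null rank products across genes within each
  within-cohort rank shuffle, with add-one correction
  (`p = (1 + #{null ≤ obs}) / (1 + n_perm·G)`).

Directional combination is used throughout so that opposite-direction
effects cannot reinforce. The metric report (`evaluate_results()`) scores a
candidate against the pooled oracle: RMSE and Pearson/Spearman on
`−log10 p`, and precision/recall/F1/FP/FN on the strict DE-call sets.

## The synthetic test bed

`generate_dataset()` draws counts from a negative binomial with
`Var = μ + φμ²`:

* baseline log2-CPM `~ N(5, 2)` — spans weakly to highly expressed genes so
  the expression filter and the mean-variance trend are both exercised;
* gene dispersions `φ ~ logNormal(log 0.1, 0.4)` — the typical bulk RNA-seq
  regime, making voom's trend non-trivial;
* library sizes uniform on 1–3 million, de-correlating counts from CPM;
* 10% of genes carry a planted `|log2 FC|` of 2 with random sign; sparse
  age/sex covariate effects are added and the covariates included in the
  design.

`split_cohorts()` partitions samples into cohorts matching requested size
ratios (largest-remainder apportionment) and per-cohort class fractions
(realized within one sample, else an error states the deficit), optionally
biasing assignment by a covariate kernel to shift cohort means — emulating
unknown-confounder scenarios such as differing tissue ischemic times.
`inject_batch_effect()` multiplies a gene subset's NB means by `2^shift` per
cohort and regenerates those counts, with the absorbing indicator columns
appended.

What the generator does *not* emulate: gene–gene correlation, outlier
samples, varying sequencing depth–expression interactions, isoform-level
structure, or single-cell zero inflation. Equivalence results (federated =
pooled) are purely algorithmic and transfer to real data; power and
calibration figures from this test bed should be read as idealized.

## Problem sizes and checks

The equivalence checks run at 2000 genes × 150 samples over three clients
(seconds per run): masked vs unmasked differences on t and p stay below
`10^-8`; three-client vs pooled differences below `10^-6` on `−log10 p` and
log2FC (bounded at 0.1 in the acceptance criterion); under a strongly
imbalanced 1:3:9 split with class fractions 0.25/0.50/0.09 the federated DE
calls match the pooled oracle exactly (F1 = 1, FP = FN = 0) while
meta-analysis baselines may not. Property suites cover bit-exact modular
round trips (200 randomized cases), partition invariance for K ∈ {2, 3, 5},
brute-force oracles for the filter and BH, prior recovery for the
empirical-Bayes fit (5000 simulated genes), type-I calibration under a
global null (2000 genes, 40 samples), and closed-form oracles for the
combiners. `scripts/acceptance.R` recomputes the headline quantities from
scratch with a caller-supplied seed.

## Known limitations

* Single-coefficient tests only; no contrast matrices, no TREAT, no robust
  empirical Bayes, no sample-quality weights.
* No client dropout or fault tolerance; the bus is synchronous and
  in-process (a network transport can be substituted behind the same
  two send functions, but none is shipped).
* The masked-median bisection runs ~40 rounds per order statistic; over a
  real network its latency would dominate that step.
* Gaussian masking is privacy-*aware*, not differentially private: the MI
  bound quantifies leakage but no formal per-sample guarantee is provided.
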