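# Hybrid additive secret sharing.
#
# Non-negative integer parameters are hidden by the classical modular scheme
# over Z_p (noise uniform on Z_p, addition mod p); the masked values leak zero
# information.  Real-valued parameters are hidden by additive Gaussian noise
# N(0, sigma2); the leakage is bounded by the mutual-information formula
# implemented in mi_bound().
#
# Exact arithmetic mod p for p up to 2^54 is done in a two-limb base-2^27
# representation: a residue x is stored as (hi, lo) doubles with
# x = hi * 2^27 + lo, 0 <= lo < 2^27.  Every intermediate quantity (limb sums
# up to 2^28, products of 26-bit values) stays inside the exactly-representable
# double range, so modular round trips are bit-exact by construction.

ZP_BASE <- 2^27

#' Modulus for the integer secret-sharing scheme
#'
#' Constructs a validated prime modulus. Supported sizes are small test moduli
#' (p <= 2^26, convenient for distributional tests) and production-scale
#' moduli (2^53 < p < 2^54). The default production modulus is 2^54 - 33, the
#' largest prime below 2^54; it cannot be represented as a single double, so
#' it is stored in two 27-bit limbs.
#'
#' @param value modulus as a plain number (small moduli only, p <= 2^26),
#'   or NULL for the default 2^54 - 33.
#' @return object of class `fv_modulus` with fields `hi`, `lo`.
#' @examples
#' p <- fv_modulus(101)
#' p_default <- fv_modulus()
#' @export
fv_modulus <- function(value = NULL) {
  if (is.null(value)) {
    # 2^54 - 33 = (2^27 - 1) * 2^27 + (2^27 - 33)
    m <- structure(list(hi = ZP_BASE - 1, lo = ZP_BASE - 33), class = "fv_modulus")
  } else {
    if (length(value) != 1L || !is.finite(value) || value != round(value) || value < 3)
      stop("modulus must be a single integer >= 3")
    if (value > 2^26)
      stop("explicit moduli are supported only up to 2^26; use fv_modulus() for the production modulus")
    m <- structure(list(hi = 0, lo = as.numeric(value)), class = "fv_modulus")
  }
  if (!is_prime_small_or_limb(m))
    stop("modulus is not prime")
  m
}

# approximate numeric value (exact for p < 2^53)
modulus_value <- function(p) p$hi * ZP_BASE + p$lo

#' @export
print.fv_modulus <- function(x, ...) {
  if (x$hi == 0) cat("secret-sharing modulus p =", format(x$lo), "\n")
  else cat(sprintf("secret-sharing modulus p = %.0f*2^27 + %.0f (~%.6g)\n",
                   x$hi, x$lo, modulus_value(x)))
  invisible(x)
}

## ---- limb matrices -------------------------------------------------------

zp_from_num <- function(M) {
  M <- as.matrix(M)
  if (any(!is.finite(M)) || any(M < 0) || any(M != round(M)))
    stop("modular scheme requires finite non-negative integer entries")
  if (any(M >= 2^53))
    stop("integer parameter too large for exact conversion (>= 2^53)")
  hi <- M %/% ZP_BASE
  structure(list(hi = hi, lo = M - hi * ZP_BASE, dim = dim(M)), class = "zp_mat")
}

zp_to_num <- function(z) {
  if (any(z$hi >= 2^26))
    stop("aggregate exceeds 2^53 and cannot be returned exactly as a double")
  out <- z$hi * ZP_BASE + z$lo
  dim(out) <- z$dim
  out
}

zp_check_lt <- function(z, p) {
  all(z$hi < p$hi | (z$hi == p$hi & z$lo < p$lo))
}

# (a + b) mod p; a, b already reduced mod p
zp_add <- function(a, b, p) {
  lo <- a$lo + b$lo
  carry <- lo >= ZP_BASE
  lo[carry] <- lo[carry] - ZP_BASE
  hi <- a$hi + b$hi + carry
  ge <- hi > p$hi | (hi == p$hi & lo >= p$lo)
  lo[ge] <- lo[ge] - p$lo
  hi[ge] <- hi[ge] - p$hi
  borrow <- lo < 0
  lo[borrow] <- lo[borrow] + ZP_BASE
  hi[borrow] <- hi[borrow] - 1
  structure(list(hi = hi, lo = lo, dim = a$dim), class = "zp_mat")
}

# (a - b) mod p
zp_sub <- function(a, b, p) {
  lo <- a$lo - b$lo
  hi <- a$hi - b$hi
  borrow <- lo < 0
  lo[borrow] <- lo[borrow] + ZP_BASE
  hi[borrow] <- hi[borrow] - 1
  neg <- hi < 0
  lo[neg] <- lo[neg] + p$lo
  hi[neg] <- hi[neg] + p$hi
  carry <- lo >= ZP_BASE
  lo[carry] <- lo[carry] - ZP_BASE
  hi[carry] <- hi[carry] + 1
  structure(list(hi = hi, lo = lo, dim = a$dim), class = "zp_mat")
}

# uniform draw over Z_p, elementwise, using R's RNG stream
zp_sample <- function(nrow, ncol, p) {
  n <- nrow * ncol
  if (p$hi == 0) {
    v <- sample.int(p$lo, n, replace = TRUE) - 1
    hi <- v %/% ZP_BASE
    lo <- v - hi * ZP_BASE
  } else {
    hi <- floor(stats::runif(n) * ZP_BASE)
    lo <- floor(stats::runif(n) * ZP_BASE)
    bad <- which(hi > p$hi | (hi == p$hi & lo >= p$lo))
    while (length(bad)) {
      hi[bad] <- floor(stats::runif(length(bad)) * ZP_BASE)
      lo[bad] <- floor(stats::runif(length(bad)) * ZP_BASE)
      bad <- bad[hi[bad] > p$hi | (hi[bad] == p$hi & lo[bad] >= p$lo)]
    }
  }
  dim(hi) <- dim(lo) <- c(nrow, ncol)
  structure(list(hi = hi, lo = lo, dim = c(nrow, ncol)), class = "zp_mat")
}

## ---- message containers --------------------------------------------------

new_masked_message <- function(scheme, noisy, shape) {
  structure(list(scheme = scheme, noisy = noisy, shape = shape),
            class = "fv_masked_message")
}

new_noise_share <- function(scheme, noise, shape) {
  structure(list(scheme = scheme, noise = noise, shape = shape),
            class = "fv_noise_share")
}

#' Mask a non-negative integer matrix with modular additive secret sharing
#'
#' Computes `noisy = (M + N) mod p` elementwise with `N` uniform over `Z_p`,
#' in exact two-limb integer arithmetic. The masked message alone carries zero
#' information about `M`; `M` is recoverable only by whoever holds both the
#' message and the noise share.
#'
#' @param M matrix of non-negative integers, all entries `< p`.
#' @param p an [fv_modulus()].
#' @param noise optional `zp_mat` noise override (test hook; e.g. forced
#'   zeros). Default: fresh uniform noise from the current RNG stream.
#' @return list with `message` (`fv_masked_message`) and `share`
#'   (`fv_noise_share`).
#' @export
mask_integer <- function(M, p = fv_modulus(), noise = NULL) {
  M <- as.matrix(M)
  z <- zp_from_num(M)
  if (!zp_check_lt(z, p))
    stop("integer parameter entry >= modulus p: masking would overflow")
  N <- if (is.null(noise)) zp_sample(nrow(M), ncol(M), p) else noise
  noisy <- zp_add(z, N, p)
  list(message = new_masked_message("modular", noisy, dim(M)),
       share = new_noise_share("modular", N, dim(M)))
}

#' Mask a real-valued matrix with Gaussian additive noise
#'
#' `noisy = M + N` with `N` i.i.d. `Normal(0, sigma2)`. The mean of the noise
#' generator is zero; leakage is bounded by [mi_bound()].
#'
#' @param M finite real matrix.
#' @param sigma2 noise variance (> 0); default `1e12`.
#' @param noise optional numeric noise override (test hook).
#' @return list with `message` and `share` as in [mask_integer()].
#' @export
mask_real <- function(M, sigma2 = 1e12, noise = NULL) {
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("real parameter contains non-finite entries")
  if (!is.null(sigma2) && sigma2 < 0) stop("sigma2 must be positive")
  N <- if (is.null(noise))
    matrix(stats::rnorm(length(M), 0, sqrt(sigma2)), nrow(M), ncol(M))
  else noise
  list(message = new_masked_message("gaussian", M + N, dim(M)),
       share = new_noise_share("gaussian", N, dim(M)))
}

#' Aggregate masked messages and remove the global noise
#'
#' Implements the aggregator/compensator recombination: the compensator sums
#' the noise shares to the global noise `N`, the aggregator sums the noisy
#' parameters and subtracts `N`. For the modular scheme the result is the
#' exact integer sum of the original parameters (provided the caller
#' guarantees `sum_i M_i < p`); for the Gaussian scheme it equals the plain
#' sum up to floating-point rounding.
#'
#' @param messages list of `fv_masked_message`, one per client.
#' @param shares list of `fv_noise_share`, same order.
#' @param p modulus (modular scheme only).
#' @return numeric matrix, the denoised aggregate.
#' @export
aggregate_denoise <- function(messages, shares, p = fv_modulus()) {
  if (length(messages) == 0L) stop("no messages to aggregate")
  if (length(messages) != length(shares))
    stop("protocol error: message/share count mismatch")
  scheme <- messages[[1]]$scheme
  shape <- messages[[1]]$shape
  for (i in seq_along(messages)) {
    if (messages[[i]]$scheme != scheme || shares[[i]]$scheme != scheme)
      stop("protocol error: mixed masking schemes in one round")
    if (!identical(messages[[i]]$shape, shape) || !identical(shares[[i]]$shape, shape))
      stop("protocol error: payload shape mismatch")
  }
  if (scheme == "modular") {
    noisy <- Reduce(function(a, b) zp_add(a, b, p), lapply(messages, `[[`, "noisy"))
    noise <- Reduce(function(a, b) zp_add(a, b, p), lapply(shares, `[[`, "noise"))
    zp_to_num(zp_sub(noisy, noise, p))
  } else {
    noisy <- Reduce(`+`, lapply(messages, `[[`, "noisy"))
    noise <- Reduce(`+`, lapply(shares, `[[`, "noise"))
    noisy - noise
  }
}

#' Mutual-information leakage bound of a masked message
#'
#' For the Gaussian scheme the mutual information between a local parameter
#' and its noisy version is at most `0.5 * log2(1 + var_local / sigma2)` bits.
#' For the modular scheme the masked value is uniform on `Z_p` regardless of
#' the parameter, so the leakage is exactly zero.
#'
#' @param var_local variance of the local parameter values (>= 0).
#' @param sigma2 masking noise variance (> 0).
#' @param scheme `"gaussian"` or `"modular"`.
#' @return upper bound in bits.
#' @export
mi_bound <- function(var_local, sigma2 = 1e12, scheme = c("gaussian", "modular")) {
  scheme <- match.arg(scheme)
  if (any(var_local < 0)) stop("variance must be non-negative")
  if (scheme == "modular") return(0)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  0.5 * log2(1 + var_local / sigma2)
}

## ---- primality (exact, limb arithmetic) ----------------------------------

# scalar limb helpers operating on c(hi, lo) pairs, numbers < 2^55
limb1 <- function(x) { hi <- x %/% ZP_BASE; c(hi, x - hi * ZP_BASE) }
limb_cmp <- function(a, b) {
  if (a[1] != b[1]) sign(a[1] - b[1]) else sign(a[2] - b[2])
}
limb_addmod <- function(a, b, m) {
  lo <- a[2] + b[2]; hi <- a[1] + b[1]
  if (lo >= ZP_BASE) { lo <- lo - ZP_BASE; hi <- hi + 1 }
  if (hi > m[1] || (hi == m[1] && lo >= m[2])) {
    lo <- lo - m[2]; hi <- hi - m[1]
    if (lo < 0) { lo <- lo + ZP_BASE; hi <- hi - 1 }
  }
  c(hi, lo)
}
# a*b mod m via double-and-add (b scanned bitwise); a, b reduced mod m
limb_mulmod <- function(a, b, m) {
  res <- c(0, 0)
  bb <- b
  while (bb[1] > 0 || bb[2] > 0) {
    odd <- bb[2] %% 2 == 1
    if (odd) res <- limb_addmod(res, a, m)
    a <- limb_addmod(a, a, m)
    # bb <- bb >> 1
    lo <- bb[2] %/% 2
    if (bb[1] %% 2 == 1) lo <- lo + ZP_BASE / 2
    bb <- c(bb[1] %/% 2, lo)
  }
  res
}
limb_powmod <- function(a, e, m) {
  res <- limb1(1)
  base <- a
  ee <- e
  while (ee[1] > 0 || ee[2] > 0) {
    if (ee[2] %% 2 == 1) res <- limb_mulmod(res, base, m)
    base <- limb_mulmod(base, base, m)
    lo <- ee[2] %/% 2
    if (ee[1] %% 2 == 1) lo <- lo + ZP_BASE / 2
    ee <- c(ee[1] %/% 2, lo)
  }
  res
}
limb_sub1 <- function(a) { # a - 1, a >= 1
  if (a[2] >= 1) c(a[1], a[2] - 1) else c(a[1] - 1, ZP_BASE - 1)
}

# deterministic Miller-Rabin for n < 2^64 (witness set from Sinclair)
is_prime_small_or_limb <- function(m) {
  n <- m
  if (!inherits(m, "fv_modulus")) n <- list(hi = limb1(m)[1], lo = limb1(m)[2])
  nv <- n$hi * ZP_BASE + n$lo      # approximate; exact for small n
  if (n$hi == 0) {
    x <- n$lo
    if (x < 2) return(FALSE)
    if (x %in% c(2, 3)) return(TRUE)
    if (x %% 2 == 0) return(FALSE)
    d <- 3
    while (d * d <= x) { if (x %% d == 0) return(FALSE); d <- d + 2 }
    return(TRUE)
  }
  nn <- c(n$hi, n$lo)
  if (nn[2] %% 2 == 0) return(FALSE)
  # n - 1 = d * 2^s
  d <- limb_sub1(nn); s <- 0
  while (d[2] %% 2 == 0) {
    lo <- d[2] %/% 2
    if (d[1] %% 2 == 1) lo <- lo + ZP_BASE / 2
    d <- c(d[1] %/% 2, lo)
    s <- s + 1
  }
  n1 <- limb_sub1(nn)
  for (a in c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)) {
    if (nv <= a) next
    x <- limb_powmod(limb1(a), d, nn)
    if (limb_cmp(x, limb1(1)) == 0 || limb_cmp(x, n1) == 0) next
    ok <- FALSE
    for (r in seq_len(s - 1)) {
      x <- limb_mulmod(x, x, nn)
      if (limb_cmp(x, n1) == 0) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Largest prime strictly below a power of two
#'
#' Descending search with deterministic Miller-Rabin primality testing in
#' exact limb arithmetic. Used to validate that the default secret-sharing
#' modulus is the largest prime fitting in 54 bits.
#'
#' @param bits exponent; the search runs downward from `2^bits - 1`.
#' @return an [fv_modulus()]-compatible list with `hi`, `lo` limbs and the
#'   offset below `2^bits`.
#' @export
largest_prime_below_2pow <- function(bits = 54) {
  stopifnot(bits > 28, bits <= 54)
  top_hi <- 2^(bits - 27)
  cand <- c(top_hi - 1, ZP_BASE - 1)   # 2^bits - 1
  off <- 1
  repeat {
    m <- structure(list(hi = cand[1], lo = cand[2]), class = "fv_modulus")
    if (is_prime_small_or_limb(m)) return(structure(list(hi = cand[1], lo = cand[2], offset = off),
                                                    class = "fv_modulus"))
    cand <- limb_sub1(limb_sub1(cand))
    off <- off + 2
  }
}
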