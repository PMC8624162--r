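# Base densities over the latent space. Two choices: the standard
# n-dimensional normal, and a radial Gaussian whose radius follows a
# half-normal and whose direction is uniform on the unit hypersphere.
# In high dimension the radial density concentrates its mass where its
# typical set lies, which is the motivation for offering it.

#' Construct a base distribution
#'
#' @param kind `"normal"` (standard n-dimensional Gaussian) or
#'   `"radial"` (half-normal radius, uniform direction).
#' @param n latent dimension (positive integer).
#' @return object of class `base_distribution`.
#' @export
base_distribution <- function(kind = c("normal", "radial"), n) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("n must be a positive integer", call. = FALSE)
  structure(list(kind = kind, n = n), class = "base_distribution")
}

#' Surface area of the n-dimensional unit sphere
#'
#' `S_n = 2 * pi^(n/2) / Gamma(n/2)`, computed in log space so large
#' `n` does not overflow.
#'
#' @param n dimension (>= 1).
#' @param log if `TRUE` return `log(S_n)`.
#' @return positive real (or its log).
#' @export
sphere_surface <- function(n, log = FALSE) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  ls <- log(2) + (n / 2) * log(pi) - lgamma(n / 2)
  if (log) ls else exp(ls)
}

z_as_matrix <- function(z, n) {
  if (is.null(dim(z))) {
    if (length(z) != n) stop("z has wrong dimension", call. = FALSE)
    z <- matrix(z, 1L, n)
  } else if (length(dim(z)) == 2L) {
    if (ncol(z) != n) stop("z has wrong dimension", call. = FALSE)
  } else {
    stop("z must be a vector or a samples-by-n matrix", call. = FALSE)
  }
  z
}

#' Log-density of a base distribution
#'
#' Full normalized log-densities (nothing constant is dropped), so
#' negative log-likelihoods are comparable across base distributions.
#' For the radial distribution with `n >= 2` the density has an
#' integrable singularity at the origin; `z = 0` is rejected rather than
#' clamped because a silent clamp would corrupt likelihood bookkeeping.
#'
#' @param dist a [base_distribution()].
#' @param z length-`n` vector or a samples-by-`n` matrix.
#' @return one log-density per sample (natural log).
#' @export
log_prob <- function(dist, z) {
  stopifnot(inherits(dist, "base_distribution"))
  n <- dist$n
  z <- z_as_matrix(z, n)
  r2 <- rowSums(z^2)
  if (dist$kind == "normal") {
    -r2 / 2 - (n / 2) * log(2 * pi)
  } else if (n == 1L) {
    # S_1 = 2 makes the radial density coincide with the standard normal
    -r2 / 2 - 0.5 * log(2 * pi)
  } else {
    if (any(r2 < 1e-60))
      stop("radial log-density is singular at z = 0", call. = FALSE)
    # half-normal radius (2 * dnorm(r)) spread over the sphere r^(n-1)*S_n
    log(2) - 0.5 * log(2 * pi) - sphere_surface(n, log = TRUE) -
      (n - 1) / 2 * log(r2) - r2 / 2
  }
}

# Gradient of log_prob wrt z (rows of the matrix z); used by training
# and by sample refinement.
log_prob_grad <- function(dist, z) {
  n <- dist$n
  z <- z_as_matrix(z, n)
  if (dist$kind == "normal" || n == 1L) {
    -z
  } else {
    r2 <- rowSums(z^2)
    if (any(r2 < 1e-60))
      stop("radial log-density is singular at z = 0", call. = FALSE)
    -z * (1 + (n - 1) / r2)
  }
}

#' Sample from a base distribution
#'
#' Normal: i.i.d. standard-normal entries. Radial: a standard-normal
#' vector is normalized to a uniform direction, then scaled by
#' `r = |r_hat|` with `r_hat ~ N(0, 1)` (half-normal radius).
#'
#' @param dist a [base_distribution()].
#' @param count number of samples.
#' @param seed optional integer seed (deterministic draws).
#' @return `count x n` matrix.
#' @export
base_sample <- function(dist, count, seed = NULL) {
  stopifnot(inherits(dist, "base_distribution"))
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  n <- dist$n
  with_seed(seed, {
    g <- matrix(stats::rnorm(count * n), count, n)
    if (dist$kind == "normal") {
      g
    } else {
      nrm <- sqrt(rowSums(g^2))
      nrm[nrm == 0] <- 1
      r <- abs(stats::rnorm(count))
      g / nrm * r
    }
  })
}
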