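# Shared oracles and fixture builders. The finite-difference Jacobian
# is the independent reference for every analytic log-determinant.

# Sign-log-determinant of the full Jacobian of f at x, by central
# differences. f maps a numeric vector to a numeric vector of the same
# length.
fd_logdet <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    J[, i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  as.numeric(determinant(J, logarithm = TRUE)$modulus)
}

# A coupling spec with randomized (non-identity) subnetwork weights.
random_coupling <- function(kind, c1, c2, seed, hidden = 8L,
                            conditional = FALSE, cond_channels = 0L,
                            sd = 0.2, clamp = 2.0) {
  sp <- coupling_spec(kind, c(c1, c2), clamp = clamp, hidden = hidden,
                      conditional = conditional,
                      cond_channels = cond_channels, seed = seed)
  withr::with_seed(seed + 1L, {
    for (li in seq_along(sp$net$layers)) {
      l <- sp$net$layers[[li]]
      if (l$op == "conv") {
        sp$net$layers[[li]]$W <- l$W +
          matrix(rnorm(length(l$W), sd = sd), nrow(l$W))
      }
    }
  })
  sp
}

# A small flow with randomized weights (identity-breaking).
random_flow <- function(cfg, sd = 0.1, seed = 99L) {
  m <- build_flow(cfg)
  th <- cinnflow:::flow_params(m)
  th <- th + withr::with_seed(seed, rnorm(length(th), sd = sd))
  cinnflow:::flow_set_params(m, th)
}

# Anti-aliased centered disc (pixel values = sub-pixel coverage).
aa_disc <- function(size, radius, ss = 4L) {
  n2 <- size * ss
  gy <- (matrix(rep(seq_len(n2), n2), n2) - (n2 + 1) / 2) / ss
  gx <- t(gy)
  fine <- (gx^2 + gy^2 <= radius^2) * 1
  coarse <- matrix(0, size, size)
  for (i in seq_len(size)) {
    strip <- fine[(i - 1L) * ss + seq_len(ss), , drop = FALSE]
    coarse[i, ] <- vapply(seq_len(size), function(j)
      mean(strip[, (j - 1L) * ss + seq_len(ss)]), numeric(1))
  }
  out <- array(0, c(1L, size, size, 1L))
  out[1L, , , 1L] <- coarse
  out
}

# Gaussian-smoothed ellipse phantom (a smooth test image for FBP).
smooth_phantom <- function(size, seed = 4L) {
  ph <- make_phantoms(1L, size = size, kind = "ellipses", seed = seed)
  m <- ph[1L, , , 1L]
  for (k in 1:4) {
    m <- (m + m[c(1, 1:(size - 1)), ] + m[c(2:size, size), ] +
            m[, c(1, 1:(size - 1))] + m[, c(2:size, size)]) / 5
  }
  ph[1L, , , 1L] <- m
  ph
}
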