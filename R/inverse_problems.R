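# Linear forward operators y = A x + noise, their exact adjoints, and
# the synthetic-data generator that makes the whole package testable
# without external downloads. Three operator families are provided:
# dense Gaussian compressed-sensing matrices, the discrete parallel-beam
# Radon transform, and masked centered 2-D Fourier transforms (MRI).

#' Dense Gaussian compressed-sensing operator
#'
#' An `m x n` matrix with i.i.d. `N(0, 1/m)` entries. The default
#' `(m, n) = (196, 784)` corresponds to 4x undersampling of a 28x28
#' image.
#'
#' @param m number of measurements (rows), `1 <= m <= n`.
#' @param n image dimension (columns).
#' @param seed optional integer seed; the matrix is deterministic per seed.
#' @param image_shape optional `(c, h, w)` the operator acts on;
#'   defaults to a square single-channel image with `h*w = n`.
#' @return object of class `forward_model`.
#' @export
make_gaussian_cs <- function(m = 196L, n = 784L, seed = NULL,
                             image_shape = NULL) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 1L || m > n)
    stop("need 1 <= m <= n (undersampling assumed)", call. = FALSE)
  A <- with_seed(seed, matrix(stats::rnorm(m * n, sd = sqrt(1 / m)), m, n))
  if (is.null(image_shape)) {
    side <- as.integer(round(sqrt(n)))
    image_shape <- if (side * side == n) c(1L, side, side) else c(1L, 1L, n)
  }
  structure(list(kind = "gaussian_cs", A = A,
                 domain_shape = as.integer(image_shape),
                 range_shape = c(m, 1L), m = m, n = n),
            class = "forward_model")
}

#' Apply a forward model / its adjoint
#'
#' `forward_apply` maps an image batch to a measurement batch;
#' `forward_adjoint` applies the exact transpose operator. Every
#' operator pair passes the adjoint dot-product test
#' `<Ax, y> = <x, A^T y>`.
#'
#' @param fm a `forward_model`.
#' @param x image batch (for `forward_apply`).
#' @param y measurement batch: a matrix with one column per sample
#'   (gaussian_cs), a sinogram array `(n_angles, n_det, n)` (radon), or
#'   a complex k-space array `(h, w, n)` (fourier_masked).
#' @return measurements, or an image batch for the adjoint.
#' @export
forward_apply <- function(fm, x) {
  x <- as_image_batch(x)
  switch(fm$kind,
    gaussian_cs = {
      n <- batch_size(x)
      fm$A %*% matrix(x, fm$n, n)
    },
    radon = radon_apply(fm$geometry, x),
    fourier_masked = fourier_masked_apply(x, fm$mask),
    stop("unknown forward model kind"))
}

#' @rdname forward_apply
#' @export
forward_adjoint <- function(fm, y) {
  switch(fm$kind,
    gaussian_cs = {
      y <- as.matrix(y)
      x <- crossprod(fm$A, y)
      array(x, c(fm$domain_shape, ncol(y)))
    },
    radon = radon_adjoint(fm$geometry, y),
    fourier_masked = fourier_masked_adjoint(y, fm$mask),
    stop("unknown forward model kind"))
}

# ---------------------------------------------------------------------------
# Radon transform (parallel beam)
#
# Ray-driven discretization via image rotation: the image is embedded in
# a square canvas covering its diagonal, rotated by each projection
# angle with bilinear interpolation, and summed along columns (pixel
# units, step = 1 pixel). The adjoint reverses both steps with identical
# interpolation weights, so the operator pair is an exact transpose.

#' Parallel-beam Radon geometry
#'
#' @param size image side length (square images).
#' @param n_angles number of projection angles, uniform on `[0, pi)`.
#' @param n_det number of detector bins; default `ceiling(size * sqrt(2))`
#'   rounded up to even, which covers the image diagonal.
#' @return object of class `radon_geometry` with fields `angles`
#'   (radians) and `detector_offsets` (pixel units, centered).
#' @export
radon_geometry <- function(size, n_angles = 60L, n_det = NULL) {
  size <- as.integer(size)
  if (is.null(n_det)) {
    n_det <- as.integer(ceiling(size * sqrt(2)))
    if (n_det %% 2L == 1L) n_det <- n_det + 1L
  }
  n_det <- as.integer(n_det)
  if (n_det < size) stop("detector span must cover the image diagonal",
                         call. = FALSE)
  angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  ctr <- (n_det + 1) / 2
  structure(list(size = size, n_angles = as.integer(n_angles), n_det = n_det,
                 angles = angles,
                 detector_offsets = seq_len(n_det) - ctr,
                 rot = radon_rotation_maps(size, n_det, angles)),
            class = "radon_geometry")
}

# For each angle, a bilinear gather map from the canvas onto its rotated
# copy: 4 index vectors + 4 weight vectors over the n_det^2 canvas.
radon_rotation_maps <- function(size, D, angles) {
  ctr <- (D + 1) / 2
  gi <- rep(seq_len(D), times = D) - ctr   # canvas row coords (y)
  gj <- rep(seq_len(D), each = D) - ctr    # canvas col coords (x)
  lapply(angles, function(a) {
    # target pixel (gi, gj) samples the source at the rotation by -a
    si <- cos(a) * gi - sin(a) * gj + ctr
    sj <- sin(a) * gi + cos(a) * gj + ctr
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    inb <- function(i, j) i >= 1 & i <= D & j >= 1 & j <= D
    mk <- function(i, j, w) {
      ok <- inb(i, j) & w != 0
      idx <- as.integer(ifelse(ok, i + (j - 1) * D, 1L))
      w <- ifelse(ok, w, 0)
      # split active positions into rounds with unique target indices,
      # so the scatter (exact transpose) can accumulate vectorized
      pos <- which(ok)
      o <- order(idx[pos])
      idxs <- idx[pos][o]
      occ <- sequence(rle(idxs)$lengths)
      rounds <- split(pos[o], occ)
      list(idx = idx, w = w, rounds = rounds)
    }
    list(mk(i0,     j0,     (1 - fi) * (1 - fj)),
         mk(i0 + 1, j0,     fi * (1 - fj)),
         mk(i0,     j0 + 1, (1 - fi) * fj),
         mk(i0 + 1, j0 + 1, fi * fj))
  })
}

embed_canvas <- function(geom, x) {
  d <- dim(x)
  D <- geom$n_det
  off <- (D - geom$size) %/% 2L
  canvas <- matrix(0, D, D)
  rows <- off + seq_len(geom$size)
  out <- array(0, c(D, D, d[4L]))
  for (b in seq_len(d[4L])) {
    canvas[rows, rows] <- x[1L, , , b]
    out[, , b] <- canvas
  }
  out
}

extract_canvas <- function(geom, canvas) {
  D <- geom$n_det
  off <- (D - geom$size) %/% 2L
  rows <- off + seq_len(geom$size)
  nb <- dim(canvas)[3L]
  out <- array(0, c(1L, geom$size, geom$size, nb))
  for (b in seq_len(nb)) out[1L, , , b] <- canvas[rows, rows, b]
  out
}

rotate_gather <- function(map, v) {
  # v: canvas as vector (length D^2); returns rotated canvas vector
  map[[1L]]$w * v[map[[1L]]$idx] + map[[2L]]$w * v[map[[2L]]$idx] +
    map[[3L]]$w * v[map[[3L]]$idx] + map[[4L]]$w * v[map[[4L]]$idx]
}

rotate_scatter <- function(map, g, D) {
  # exact transpose of rotate_gather
  out <- numeric(D * D)
  for (kq in 1:4) {
    mq <- map[[kq]]
    v <- g * mq$w
    for (p in mq$rounds) out[mq$idx[p]] <- out[mq$idx[p]] + v[p]
  }
  out
}

#' Discrete 2-D Radon transform and filtered back-projection
#'
#' `radon_transform` computes line integrals of a (single-channel,
#' square) image batch over the geometry's angles and detector offsets,
#' in pixel units. `fbp_reconstruct` applies a Ram-Lak (ramp) filter in
#' detector frequency followed by back-projection (the exact adjoint),
#' scaled by `pi / n_angles`.
#'
#' @param x image batch (square, single channel).
#' @param geom a [radon_geometry()].
#' @param sino sinogram array `(n_angles, n_det, n)` or matrix
#'   `(n_angles, n_det)`.
#' @param filter filter name; `"ram-lak"` is the only built-in.
#' @param cutoff fractional frequency cutoff in (0, 1]; frequencies
#'   above `cutoff * Nyquist` are zeroed.
#' @return `radon_transform`: sinogram array `(n_angles, n_det, n)`;
#'   `fbp_reconstruct`: image batch.
#' @export
radon_transform <- function(x, geom) {
  x <- as_image_batch(x)
  if (n_channels(x) != 1L || dim(x)[2L] != geom$size ||
      dim(x)[3L] != geom$size)
    stop("image must be single-channel and match the geometry size",
         call. = FALSE)
  radon_apply(geom, x)
}

radon_apply <- function(geom, x) {
  D <- geom$n_det
  canvas <- embed_canvas(geom, x)
  nb <- dim(canvas)[3L]
  sino <- array(0, c(geom$n_angles, D, nb))
  for (b in seq_len(nb)) {
    v <- as.vector(canvas[, , b])
    for (a in seq_len(geom$n_angles)) {
      rot <- rotate_gather(geom$rot[[a]], v)
      sino[a, , b] <- colSums(matrix(rot, D, D))
    }
  }
  sino
}

radon_adjoint <- function(geom, sino) {
  if (length(dim(sino)) == 2L) dim(sino) <- c(dim(sino), 1L)
  D <- geom$n_det
  nb <- dim(sino)[3L]
  canvas <- array(0, c(D, D, nb))
  for (b in seq_len(nb)) {
    acc <- numeric(D * D)
    for (a in seq_len(geom$n_angles)) {
      spread <- rep(sino[a, , b], each = D)   # adjoint of colSums
      acc <- acc + rotate_scatter(geom$rot[[a]], spread, D)
    }
    canvas[, , b] <- acc
  }
  extract_canvas(geom, canvas)
}

# Discrete Ram-Lak: DFT of the band-limited spatial ramp (avoids the
# DC bias / cupping of sampling |f| directly), zero-padded against
# circular convolution.
ramlak_response <- function(n_det, cutoff = 1) {
  P <- 2L^ceiling(log2(2L * n_det))
  h <- numeric(P)
  h[1L] <- 0.25
  n_odd <- seq(1L, P %/% 2L, 2L)
  h[1L + n_odd] <- -1 / (pi * n_odd)^2
  h[P + 1L - n_odd] <- -1 / (pi * n_odd)^2
  H <- 2 * Re(stats::fft(h))
  freqs <- c(seq(0L, P %/% 2L), seq(-P %/% 2L + 1L, -1L)) / P
  H[abs(freqs) > cutoff / 2] <- 0
  H
}

#' @rdname radon_transform
#' @export
fbp_reconstruct <- function(sino, geom, filter = "ram-lak", cutoff = 1) {
  if (!identical(filter, "ram-lak"))
    stop("only the Ram-Lak filter is implemented", call. = FALSE)
  if (length(dim(sino)) == 2L) dim(sino) <- c(dim(sino), 1L)
  H <- ramlak_response(geom$n_det, cutoff)
  P <- length(H)
  filt <- sino
  for (b in seq_len(dim(sino)[3L])) {
    for (a in seq_len(geom$n_angles)) {
      p <- c(sino[a, , b], numeric(P - geom$n_det))
      fp <- Re(stats::fft(stats::fft(p) * H, inverse = TRUE)) / P
      filt[a, , b] <- fp[seq_len(geom$n_det)]
    }
  }
  (pi / (2 * geom$n_angles)) * radon_adjoint(geom, filt)
}

#' Build a Radon forward model
#'
#' Wraps a [radon_geometry()] as a `forward_model` usable with
#' [forward_apply()] / [forward_adjoint()].
#'
#' @inheritParams radon_geometry
#' @return object of class `forward_model`.
#' @export
make_radon <- function(size, n_angles = 60L, n_det = NULL) {
  geom <- radon_geometry(size, n_angles, n_det)
  structure(list(kind = "radon", geometry = geom,
                 domain_shape = c(1L, geom$size, geom$size),
                 range_shape = c(geom$n_angles, geom$n_det)),
            class = "forward_model")
}

# ---------------------------------------------------------------------------
# Masked Fourier (MRI) operator

#' Cartesian undersampling mask
#'
#' Keeps `round(center_fraction * width)` center (lowest-frequency)
#' columns, then adds uniformly chosen higher-frequency columns until
#' `round(width / acceleration)` columns are kept in total. Frequencies
#' are centered (zero frequency at the array center).
#'
#' @param width k-space width (number of frequency columns).
#' @param acceleration acceleration factor (default 4: keep 25%).
#' @param center_fraction fraction of lowest frequencies always kept
#'   (default 0.08).
#' @param seed optional integer seed.
#' @return object of class `sampling_mask` with a logical `keep` vector.
#' @export
make_mri_mask <- function(width, acceleration = 4, center_fraction = 0.08,
                          seed = NULL) {
  width <- as.integer(width)
  n_keep <- as.integer(round(width / acceleration))
  n_center <- as.integer(round(center_fraction * width))
  if (n_center >= n_keep || n_keep > width || n_center < 1L)
    stop("infeasible acceleration/center_fraction for this width",
         call. = FALSE)
  ctr <- width %/% 2L + 1L
  half <- n_center %/% 2L
  center_cols <- seq(ctr - half, length.out = n_center)
  keep <- logical(width)
  keep[center_cols] <- TRUE
  extra <- n_keep - n_center
  pool <- which(!keep)
  chosen <- with_seed(seed, sample(pool, extra))
  keep[chosen] <- TRUE
  structure(list(keep = keep, width = width, acceleration = acceleration,
                 center_fraction = center_fraction,
                 center_cols = center_cols),
            class = "sampling_mask")
}

fftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq(d[1L] %/% 2L + 1L, d[1L]), seq_len(d[1L] %/% 2L))
  j <- c(seq(d[2L] %/% 2L + 1L, d[2L]), seq_len(d[2L] %/% 2L))
  m[i, j, drop = FALSE]
}

ifftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq(d[1L] - d[1L] %/% 2L + 1L, d[1L]), seq_len(d[1L] - d[1L] %/% 2L))
  j <- c(seq(d[2L] - d[2L] %/% 2L + 1L, d[2L]), seq_len(d[2L] - d[2L] %/% 2L))
  m[i, j, drop = FALSE]
}

# Orthonormal centered 2-D DFT of one matrix.
cfft2 <- function(m) fftshift2(stats::fft(m)) / sqrt(length(m))
cifft2 <- function(k) stats::fft(ifftshift2(k), inverse = TRUE) / sqrt(length(k))

#' Masked Fourier forward operator (accelerated MRI)
#'
#' Centered orthonormal 2-D discrete Fourier transform of each image
#' with unmeasured frequency columns zeroed.
#'
#' @param x single-channel image batch.
#' @param mask a [make_mri_mask()] whose width matches the image width.
#' @return complex k-space array `(h, w, n)`.
#' @export
fourier_masked_forward <- function(x, mask) {
  x <- as_image_batch(x)
  fourier_masked_apply(x, mask)
}

fourier_masked_apply <- function(x, mask) {
  d <- dim(x)
  if (d[3L] != mask$width) stop("mask width must equal image width",
                                call. = FALSE)
  out <- array(complex(real = 0), c(d[2L], d[3L], d[4L]))
  for (b in seq_len(d[4L])) {
    k <- cfft2(x[1L, , , b])
    k[, !mask$keep] <- 0
    out[, , b] <- k
  }
  out
}

fourier_masked_adjoint <- function(y, mask) {
  if (length(dim(y)) == 2L) dim(y) <- c(dim(y), 1L)
  d <- dim(y)
  out <- array(0, c(1L, d[1L], d[2L], d[3L]))
  for (b in seq_len(d[3L])) {
    k <- y[, , b]
    k[, !mask$keep] <- 0
    out[1L, , , b] <- Re(cifft2(k))
  }
  out
}

#' Build a masked-Fourier forward model
#'
#' @param h,w image height and width.
#' @param mask a [make_mri_mask()] of width `w`.
#' @return object of class `forward_model`.
#' @export
make_fourier_masked <- function(h, w, mask) {
  structure(list(kind = "fourier_masked", mask = mask,
                 domain_shape = c(1L, as.integer(h), as.integer(w)),
                 range_shape = c(as.integer(h), as.integer(w))),
            class = "forward_model")
}

#' Adjoint dot-product test
#'
#' Checks `<Ax, y> = <x, A^T y>` on random inputs; the relative
#' discrepancy should be at numerical precision for every operator.
#'
#' @param fm a `forward_model`.
#' @param seed integer seed for the random test vectors.
#' @return the relative discrepancy (a nonnegative scalar).
#' @export
adjoint_dot_test <- function(fm, seed = 1L) {
  with_seed(seed, {
    x <- array(stats::rnorm(prod(fm$domain_shape)), c(fm$domain_shape, 1L))
    Ax <- forward_apply(fm, x)
    y <- array(stats::rnorm(length(Ax)), dim(Ax))
    if (is.complex(Ax)) y <- y + 1i * array(stats::rnorm(length(Ax)), dim(Ax))
    Aty <- forward_adjoint(fm, y)
    lhs <- sum(Re(Conj(Ax) * y))
    rhs <- sum(x * Aty)
    abs(lhs - rhs) / max(abs(lhs), abs(rhs), 1e-300)
  })
}

# ---------------------------------------------------------------------------
# Noise models

#' Add measurement noise
#'
#' Relative Gaussian noise: `y + level * (||y|| / sqrt(m)) * g` with `g`
#' i.i.d. standard normal and `m` the number of measurement entries per
#' sample, so the expected noise norm is `level * ||y||` per sample.
#' Poisson noise follows a photon-count model on exponentiated line
#' integrals: `counts ~ Pois(N0 * exp(-y))`, returned as
#' `-log(counts / N0)` (counts floored at 1).
#'
#' @param y measurement batch (matrix with one column per sample, or an
#'   array whose last dimension indexes samples).
#' @param spec noise specification: `list(kind = "gaussian", level = 0.1)`
#'   or `list(kind = "poisson", n0 = 4096)`.
#' @param seed optional integer seed.
#' @return noisy measurements, same shape as `y`.
#' @export
add_noise <- function(y, spec, seed = NULL) {
  if (is.null(spec) || identical(spec$kind, "none")) return(y)
  with_seed(seed, {
    if (spec$kind == "gaussian") {
      level <- spec$level
      if (level < 0) stop("noise level must be >= 0", call. = FALSE)
      if (level == 0) return(y)
      d <- if (is.null(dim(y))) c(length(y), 1L) else dim(y)
      ym <- matrix(y, prod(d[-length(d)]), d[length(d)])
      m <- nrow(ym)
      norms <- sqrt(colSums(ym^2))
      g <- matrix(stats::rnorm(length(ym)), m)
      out <- ym + g * rep(level * norms / sqrt(m), each = m)
      dim(out) <- dim(y) %||% NULL
      if (is.null(dim(y))) out <- as.vector(out)
      out
    } else if (spec$kind == "poisson") {
      n0 <- spec$n0 %||% 4096
      counts <- pmax(stats::rpois(length(y), n0 * exp(-as.vector(y))), 1)
      out <- -log(counts / n0)
      dim(out) <- dim(y)
      out
    } else stop("unknown noise kind", call. = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dequantization-style training noise
#'
#' Adds i.i.d. `N(0, variance)` noise per pixel; drawn fresh at each
#' call so training epochs see different perturbations.
#'
#' @param x image batch.
#' @param variance noise variance (default 0.005).
#' @param seed optional integer seed.
#' @return perturbed image batch.
#' @export
add_training_noise <- function(x, variance = 0.005, seed = NULL) {
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  if (variance == 0) return(x)
  with_seed(seed, x + array(stats::rnorm(length(x), sd = sqrt(variance)),
                            dim(x)))
}

# ---------------------------------------------------------------------------
# Phantom generator

#' Random phantom images
#'
#' `"ellipses"`: superpositions of 3-8 random ellipses (random centers,
#' axes, orientations, intensities), clipped to `[0, 1]` - a stand-in
#' for anatomical CT slices. `"digits_like"`: sparse bright stroke
#' patterns (random polylines with thickness) on a dark background,
#' emulating handwritten-digit statistics.
#'
#' @param count number of images.
#' @param size image side length (>= 16).
#' @param kind `"ellipses"` or `"digits_like"`.
#' @param seed optional integer seed (stacks are reproducible per seed).
#' @return image batch `(1, size, size, count)` with values in `[0, 1]`.
#' @export
make_phantoms <- function(count, size = 32L, kind = c("ellipses", "digits_like"),
                          seed = NULL) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 16L) stop("size must be >= 16", call. = FALSE)
  with_seed(seed, {
    out <- array(0, c(1L, size, size, count))
    gy <- matrix(rep(seq_len(size), size), size) / size - 0.5       # rows
    gx <- matrix(rep(seq_len(size), each = size), size) / size - 0.5 # cols
    for (b in seq_len(count)) {
      if (kind == "ellipses") {
        img <- matrix(0, size, size)
        for (e in seq_len(sample(3:8, 1L))) {
          cx <- stats::runif(1, -0.3, 0.3); cy <- stats::runif(1, -0.3, 0.3)
          ax <- stats::runif(1, 0.08, 0.35); ay <- stats::runif(1, 0.08, 0.35)
          th <- stats::runif(1, 0, pi); amp <- stats::runif(1, -0.4, 0.8)
          xr <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
          yr <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
          img <- img + amp * ((xr / ax)^2 + (yr / ay)^2 <= 1)
        }
        out[1L, , , b] <- pmin(pmax(img, 0), 1)
      } else {
        img <- matrix(0, size, size)
        n_str <- sample(2:4, 1L)
        for (s in seq_len(n_str)) {
          npt <- sample(3:5, 1L)
          pts <- cbind(stats::runif(npt, 0.15, 0.85),
                       stats::runif(npt, 0.15, 0.85)) * size
          for (k in seq_len(npt - 1L)) {
            tseq <- seq(0, 1, length.out = 3L * size)
            px <- pts[k, 1] + tseq * (pts[k + 1, 1] - pts[k, 1])
            py <- pts[k, 2] + tseq * (pts[k + 1, 2] - pts[k, 2])
            ii <- pmin(pmax(round(py), 1), size)
            jj <- pmin(pmax(round(px), 1), size)
            img[cbind(ii, jj)] <- 1
          }
        }
        # thicken strokes by one-pixel dilation and soften edges
        dil <- img
        dil[-1, ] <- pmax(dil[-1, ], img[-size, ])
        dil[, -1] <- pmax(dil[, -1], img[, -size])
        out[1L, , , b] <- pmin(pmax(dil * stats::runif(1, 0.75, 1), 0), 1)
      }
    }
    out
  })
}

# ---------------------------------------------------------------------------
# Synthetic dataset plumbing

#' Generate a paired (image, measurement) dataset
#'
#' Draws phantoms, applies the forward model and the noise model.
#' Measurements regenerate bit-identically from the same seed.
#'
#' @param fm a `forward_model`.
#' @param count number of image/measurement pairs.
#' @param kind phantom kind (see [make_phantoms()]).
#' @param noise noise spec for [add_noise()] (default 10% relative
#'   Gaussian).
#' @param seed integer seed controlling both phantoms and noise.
#' @return object of class `synthetic_dataset` with fields `images`,
#'   `measurements`, `fm`, `noise`, `seed`.
#' @export
synthetic_dataset <- function(fm, count, kind = "ellipses",
                              noise = list(kind = "gaussian", level = 0.1),
                              seed = 1L) {
  size <- fm$domain_shape[2L]
  images <- make_phantoms(count, size = size, kind = kind,
                          seed = derive_seed(seed, 1L))
  y <- forward_apply(fm, images)
  y <- add_noise(y, noise, seed = derive_seed(seed, 2L))
  structure(list(images = images, measurements = y, fm = fm, noise = noise,
                 seed = seed, kind = kind),
            class = "synthetic_dataset")
}

#' Linear-Gaussian reference problem with closed-form posterior
#'
#' A fully analytic benchmark: images are draws from a Gaussian prior
#' `N(mu0, Sigma0)` over `h x w` pixels (squared-exponential spatial
#' covariance), measured through a Gaussian compressed-sensing operator
#' with additive `N(0, sigma^2 I)` noise. The posterior is Gaussian with
#' mean `mu0 + Sigma0 A^T (A Sigma0 A^T + sigma^2 I)^{-1} (y - A mu0)`,
#' attached as a function of `y` together with the posterior covariance.
#'
#' @param side image side (images are `side x side`).
#' @param m number of measurements.
#' @param sigma measurement noise standard deviation.
#' @param ell prior correlation length (in pixels).
#' @param prior_sd marginal prior standard deviation.
#' @param seed integer seed (fixes the operator).
#' @return list with the forward model, prior moments, noise level,
#'   `posterior_mean(y)`, `posterior_cov` and a `sample_pairs(count,
#'   seed)` generator returning images `(1, side, side, n)` and
#'   measurements `(m x n)`.
#' @export
linear_gaussian_reference <- function(side = 4L, m = 8L, sigma = 0.05,
                                      ell = 1.5, prior_sd = 0.3, seed = 1L) {
  side <- as.integer(side)
  n <- side * side
  fm <- make_gaussian_cs(m, n, seed = derive_seed(seed, 11L),
                         image_shape = c(1L, side, side))
  # squared-exponential prior over the pixel grid
  ii <- rep(seq_len(side), times = side)
  jj <- rep(seq_len(side), each = side)
  d2 <- outer(ii, ii, "-")^2 + outer(jj, jj, "-")^2
  Sigma0 <- prior_sd^2 * exp(-d2 / (2 * ell^2))
  mu0 <- rep(0.5, n)
  A <- fm$A
  S <- A %*% Sigma0 %*% t(A) + sigma^2 * diag(m)
  K <- Sigma0 %*% t(A) %*% solve(S)          # Kalman gain
  post_cov <- Sigma0 - K %*% A %*% Sigma0
  R0 <- chol(Sigma0)
  list(
    fm = fm, mu0 = mu0, Sigma0 = Sigma0, sigma = sigma, side = side, m = m,
    posterior_mean = function(y) as.vector(mu0 + K %*% (as.vector(y) - A %*% mu0)),
    posterior_cov = post_cov,
    sample_pairs = function(count, seed = NULL) {
      with_seed(seed, {
        z <- matrix(stats::rnorm(count * n), count, n)
        X <- sweep(z %*% R0, 2L, mu0, "+")          # count x n images
        eps <- matrix(stats::rnorm(count * m, sd = sigma), m, count)
        Y <- A %*% t(X) + eps
        list(images = array(t(X), c(1L, side, side, count)),
             measurements = Y)
      })
    })
}
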