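# Invertible building blocks. Every forward op returns the transformed
# array together with its exact per-sample log-Jacobian-determinant
# (natural log); inverses are analytic. The log-determinant is always
# accumulated in double precision.

#' Create a coupling-layer specification
#'
#' A coupling layer splits its input channels into two groups
#' `(c1, c2)`, leaves the first unchanged and transforms the second with
#' parameters produced by a subnetwork applied to the first group (plus,
#' optionally, conditioning features). Additive couplings translate only
#' and have unit Jacobian determinant; affine couplings also rescale,
#' with the raw log-scale bounded through `clamp * tanh(s / clamp)` so
#' the inverse pass cannot explode.
#'
#' @param kind `"affine"` or `"additive"`.
#' @param split_sizes integer pair `(c1, c2)`; both must be >= 1.
#' @param clamp positive bound on the effective affine log-scale.
#' @param hidden hidden width of the coupling subnetwork.
#' @param kernel convolution kernel size of the subnetwork.
#' @param conditional logical; if `TRUE` the subnetwork also receives
#'   `cond_channels` conditioning channels (same spatial size as the
#'   first input group).
#' @param cond_channels number of conditioning channels.
#' @param net optional replacement for the built-in subnetwork: an R
#'   function taking the (c1 + cond) array and returning the subnetwork
#'   output (`2*c2` channels for affine - log-scale then shift - or `c2`
#'   for additive). Function nets are for analysis/stubbing and carry no
#'   trainable parameters.
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(kind = c("affine", "additive"), split_sizes,
                          clamp = 2.0, hidden = 64L, kernel = 3L,
                          conditional = FALSE, cond_channels = 0L,
                          net = NULL, seed = NULL) {
  kind <- match.arg(kind)
  split_sizes <- as.integer(split_sizes)
  if (length(split_sizes) != 2L || any(split_sizes < 1L))
    stop("split_sizes must be two integers >= 1", call. = FALSE)
  if (clamp <= 0) stop("clamp must be positive", call. = FALSE)
  if (conditional && cond_channels < 1L)
    stop("conditional couplings need cond_channels >= 1", call. = FALSE)
  c1 <- split_sizes[1L]; c2 <- split_sizes[2L]
  cin <- c1 + if (conditional) as.integer(cond_channels) else 0L
  cout <- if (kind == "affine") 2L * c2 else c2
  if (is.null(net)) {
    net <- with_seed(seed, make_subnet(cin, cout, hidden = hidden, k = kernel))
  }
  structure(list(kind = kind, c1 = c1, c2 = c2, clamp = clamp,
                 conditional = conditional,
                 cond_channels = as.integer(cond_channels), net = net),
            class = "coupling_spec")
}

coupling_check <- function(x, cond, spec) {
  if (n_channels(x) != spec$c1 + spec$c2)
    stop("channel count does not match split_sizes", call. = FALSE)
  check_finite(x)
  if (spec$conditional) {
    if (is.null(cond)) stop("conditional coupling requires cond", call. = FALSE)
    if (!all(dim(cond)[2:3] == dim(x)[2:3]))
      stop("cond spatial size must match the input's", call. = FALSE)
  } else if (!is.null(cond)) {
    stop("cond supplied to an unconditional coupling", call. = FALSE)
  }
  invisible(NULL)
}

# Run the coupling subnetwork on (x1 [, cond]); returns output + cache.
coupling_net_fwd <- function(spec, x1, cond) {
  z <- if (spec$conditional) concat_channels(x1, cond) else x1
  if (is.function(spec$net)) {
    list(y = spec$net(z), cache = NULL, fun = TRUE)
  } else {
    r <- subnet_fwd(spec$net, z)
    list(y = r$y, cache = r$caches, fun = FALSE)
  }
}

coupling_fwd <- function(spec, x, cond = NULL, cache = FALSE) {
  c1 <- spec$c1
  x1 <- x[seq_len(c1), , , , drop = FALSE]
  x2 <- x[c1 + seq_len(spec$c2), , , , drop = FALSE]
  nf <- coupling_net_fwd(spec, x1, cond)
  if (spec$kind == "affine") {
    raw_s <- nf$y[seq_len(spec$c2), , , , drop = FALSE]
    t_shift <- nf$y[spec$c2 + seq_len(spec$c2), , , , drop = FALSE]
    s <- spec$clamp * tanh(raw_s / spec$clamp)
    es <- exp(s)
    y2 <- x2 * es + t_shift
    logdet <- per_sample_sum(s)
  } else {
    t_shift <- nf$y
    s <- NULL; es <- NULL
    y2 <- x2 + t_shift
    logdet <- numeric(batch_size(x))
  }
  y <- x
  y[c1 + seq_len(spec$c2), , , ] <- y2
  out <- list(y = y, logdet = logdet)
  if (cache) out$cache <- list(x1 = x1, x2 = x2, s = s, es = es,
                               net_cache = nf$cache)
  out
}

coupling_inv <- function(spec, y, cond = NULL) {
  c1 <- spec$c1
  y1 <- y[seq_len(c1), , , , drop = FALSE]
  y2 <- y[c1 + seq_len(spec$c2), , , , drop = FALSE]
  nf <- coupling_net_fwd(spec, y1, cond)
  if (spec$kind == "affine") {
    raw_s <- nf$y[seq_len(spec$c2), , , , drop = FALSE]
    t_shift <- nf$y[spec$c2 + seq_len(spec$c2), , , , drop = FALSE]
    s <- spec$clamp * tanh(raw_s / spec$clamp)
    x2 <- (y2 - t_shift) * exp(-s)
  } else {
    x2 <- y2 - nf$y
  }
  x <- y
  x[c1 + seq_len(spec$c2), , , ] <- x2
  x
}

# Backward pass in the normalizing (x -> z) direction.
# gy: gradient wrt output; gld: per-sample gradient wrt logdet.
# Returns gx, gcond and the subnetwork parameter gradients.
coupling_bwd <- function(spec, cache, gy, gld) {
  c1 <- spec$c1; c2 <- spec$c2
  gy1 <- gy[seq_len(c1), , , , drop = FALSE]
  gy2 <- gy[c1 + seq_len(c2), , , , drop = FALSE]
  if (spec$kind == "affine") {
    es <- cache$es; s <- cache$s
    gx2 <- gy2 * es
    gs <- gy2 * cache$x2 * es
    # logdet = sum(s): broadcast the per-sample logdet gradient
    gs <- gs + rep(gld, each = length(gs) / length(gld))
    graw_s <- gs * (1 - (s / spec$clamp)^2)
    gnet <- array(0, c(2L * c2, dim(gy)[2L], dim(gy)[3L], dim(gy)[4L]))
    gnet[seq_len(c2), , , ] <- graw_s
    gnet[c2 + seq_len(c2), , , ] <- gy2
  } else {
    gx2 <- gy2
    gnet <- gy2
  }
  if (is.null(cache$net_cache))
    stop("cannot backpropagate through a function-valued coupling net",
         call. = FALSE)
  sb <- subnet_bwd(spec$net, cache$net_cache, gnet)
  gin <- sb$gx
  gx1 <- gy1 + gin[seq_len(c1), , , , drop = FALSE]
  gcond <- if (spec$conditional)
    gin[c1 + seq_len(spec$cond_channels), , , , drop = FALSE] else NULL
  gx <- gy
  gx[seq_len(c1), , , ] <- gx1
  gx[c1 + seq_len(c2), , , ] <- gx2
  list(gx = gx, gcond = gcond, gnet = sb$grads)
}

#' Apply a coupling layer in the forward direction
#'
#' @param x image batch with `c1 + c2` channels.
#' @param cond conditioning array (or `NULL` for unconditional specs).
#' @param spec a [coupling_spec()].
#' @return list with `output` (same shape as `x`) and `logdet`
#'   (one value per batch sample; exactly 0 for additive couplings).
#' @export
coupling_forward <- function(x, cond = NULL, spec) {
  x <- as_image_batch(x)
  if (!is.null(cond)) cond <- as_image_batch(cond)
  coupling_check(x, cond, spec)
  r <- coupling_fwd(spec, x, cond)
  list(output = r$y, logdet = r$logdet)
}

#' Invert a coupling layer
#'
#' Exact analytic inverse of [coupling_forward()] (same clamping of the
#' affine log-scale applied).
#'
#' @inheritParams coupling_forward
#' @param y output of the forward pass.
#' @return the reconstructed input array.
#' @export
coupling_inverse <- function(y, cond = NULL, spec) {
  y <- as_image_batch(y)
  if (!is.null(cond)) cond <- as_image_batch(cond)
  coupling_check(y, cond, spec)
  coupling_inv(spec, y, cond)
}

#' Create a fixed channel-mixing matrix
#'
#' Mixing after each coupling lets all channels influence one another.
#' The default is a random orthogonal matrix (a fixed 1x1 convolution,
#' `|det Q| = 1` so the log-determinant contribution is zero); a plain
#' random channel permutation is available for ablation. The matrix is
#' fixed at initialization and never trained.
#'
#' @param n_channels matrix side length (= channel count).
#' @param kind `"orthogonal"` or `"permutation"`.
#' @param seed optional integer seed.
#' @return invertible `n_channels x n_channels` matrix.
#' @export
make_mixing_matrix <- function(n_channels, kind = c("orthogonal", "permutation"),
                               seed = NULL) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "orthogonal") {
      qrd <- qr(matrix(stats::rnorm(n_channels^2), n_channels))
      Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))), n_channels)
    } else {
      Q <- diag(n_channels)[sample.int(n_channels), , drop = FALSE]
    }
    Q
  })
}

#' Mix channels with a fixed invertible matrix
#'
#' Multiplies every pixel's channel vector by `Q`. The log-determinant is
#' `h * w * log|det Q|` per sample.
#'
#' @param x image batch.
#' @param Q invertible square matrix with side = channel count.
#' @return list with `output` and `logdet`.
#' @export
mix_channels <- function(x, Q) {
  x <- as_image_batch(x)
  d <- dim(x)
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || nrow(Q) != d[1L])
    stop("Q must be square with side = channel count", call. = FALSE)
  ldQ <- determinant(Q, logarithm = TRUE)
  if (!is.finite(ldQ$modulus)) stop("Q is singular", call. = FALSE)
  y <- Q %*% matrix(x, d[1L], prod(d[2:4]))
  dim(y) <- d
  list(output = y, logdet = rep(d[2L] * d[3L] * as.numeric(ldQ$modulus), d[4L]))
}

mix_inverse <- function(y, Q) {
  d <- dim(y)
  x <- solve(Q, matrix(y, d[1L], prod(d[2:4])))
  dim(x) <- d
  x
}

mix_bwd <- function(gy, Q) {
  d <- dim(gy)
  gx <- crossprod(Q, matrix(gy, d[1L], prod(d[2:4])))
  dim(gx) <- d
  gx
}

check_even_spatial <- function(x) {
  d <- dim(x)
  if (d[2L] %% 2L != 0L || d[3L] %% 2L != 0L)
    stop("height and width must be even for invertible downsampling",
         call. = FALSE)
  invisible(NULL)
}

#' Checkerboard (space-to-depth) downsampling
#'
#' Rearranges each 2x2 pixel block into four channels:
#' `(c, h, w) -> (4c, h/2, w/2)`. A pure permutation, so the
#' log-determinant is exactly zero and the upsampling inverse is
#' bit-exact.
#'
#' @param x image batch with even height and width.
#' @return list with `output` and `logdet` (all zeros).
#' @export
checkerboard_downsample <- function(x) {
  x <- as_image_batch(x)
  check_even_spatial(x)
  d <- dim(x)
  cc <- d[1L]
  i1 <- seq(1L, d[2L], 2L); j1 <- seq(1L, d[3L], 2L)
  y <- array(0, c(4L * cc, d[2L] %/% 2L, d[3L] %/% 2L, d[4L]))
  y[seq_len(cc), , , ] <- x[, i1, j1, , drop = FALSE]
  y[cc + seq_len(cc), , , ] <- x[, i1 + 1L, j1, , drop = FALSE]
  y[2L * cc + seq_len(cc), , , ] <- x[, i1, j1 + 1L, , drop = FALSE]
  y[3L * cc + seq_len(cc), , , ] <- x[, i1 + 1L, j1 + 1L, , drop = FALSE]
  list(output = y, logdet = numeric(d[4L]))
}

#' @rdname checkerboard_downsample
#' @export
checkerboard_upsample <- function(x) {
  x <- as_image_batch(x)
  d <- dim(x)
  if (d[1L] %% 4L != 0L) stop("channel count must be divisible by 4",
                              call. = FALSE)
  cc <- d[1L] %/% 4L
  y <- array(0, c(cc, 2L * d[2L], 2L * d[3L], d[4L]))
  i1 <- seq(1L, 2L * d[2L], 2L); j1 <- seq(1L, 2L * d[3L], 2L)
  y[, i1, j1, ] <- x[seq_len(cc), , , , drop = FALSE]
  y[, i1 + 1L, j1, ] <- x[cc + seq_len(cc), , , , drop = FALSE]
  y[, i1, j1 + 1L, ] <- x[2L * cc + seq_len(cc), , , , drop = FALSE]
  y[, i1 + 1L, j1 + 1L, ] <- x[3L * cc + seq_len(cc), , , , drop = FALSE]
  list(output = y, logdet = numeric(d[4L]))
}

# Orthonormal 2D Haar block matrix acting on (p00, p10, p01, p11);
# rows: average, horizontal, vertical, diagonal. Symmetric involution.
haar_block_matrix <- function() {
  0.5 * matrix(c(1,  1,  1,  1,
                 1,  1, -1, -1,
                 1, -1,  1, -1,
                 1, -1, -1,  1), 4L, 4L, byrow = TRUE)
}

haar_mix <- function(y) {
  d <- dim(y)
  cc <- d[1L] %/% 4L
  M <- haar_block_matrix() %x% diag(cc)
  z <- M %*% matrix(y, d[1L], prod(d[2:4]))
  dim(z) <- d
  z
}

#' Orthonormal Haar downsampling
#'
#' Decomposes every 2x2 block of each channel into average, horizontal,
#' vertical and diagonal coefficients under the orthonormal 2-D Haar
#' transform: `(c, h, w) -> (4c, h/2, w/2)`. Orthonormality makes the
#' log-determinant exactly zero and the transform an isometry.
#'
#' @param x image batch with even height and width.
#' @return list with `output` and `logdet` (all zeros).
#' @export
haar_downsample <- function(x) {
  r <- checkerboard_downsample(x)
  list(output = haar_mix(r$output), logdet = r$logdet)
}

#' @rdname haar_downsample
#' @export
haar_upsample <- function(x) {
  x <- as_image_batch(x)
  if (dim(x)[1L] %% 4L != 0L) stop("channel count must be divisible by 4",
                                   call. = FALSE)
  checkerboard_upsample(haar_mix(x))  # Haar block matrix is an involution
}

#' Split / merge channels
#'
#' `split_channels` partitions the channels into a kept part (the first
#' `size` channels, split off to the latent output in multi-scale flows)
#' and a forwarded part; `merge_channels` is its exact inverse. Both are
#' volume-preserving with zero log-determinant.
#'
#' @param x image batch with >= 2 channels.
#' @param size channels in the kept part; default half (floor).
#' @return `split_channels`: list with `kept` and `forwarded`;
#'   `merge_channels`: the merged array.
#' @export
split_channels <- function(x, size = NULL) {
  x <- as_image_batch(x)
  cc <- n_channels(x)
  if (cc < 2L) stop("need at least 2 channels to split", call. = FALSE)
  if (is.null(size)) size <- cc %/% 2L
  size <- as.integer(size)
  if (size < 1L || size >= cc)
    stop("split size must be in [1, channels-1]", call. = FALSE)
  list(kept = x[seq_len(size), , , , drop = FALSE],
       forwarded = x[size + seq_len(cc - size), , , , drop = FALSE])
}

#' @rdname split_channels
#' @param kept,forwarded the two channel groups to merge.
#' @export
merge_channels <- function(kept, forwarded) {
  concat_channels(as_image_batch(kept), as_image_batch(forwarded))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[2:4] == db[2:4]))
    stop("spatial/batch dims must match for channel concat", call. = FALSE)
  out <- array(0, c(da[1L] + db[1L], da[2L], da[3L], da[4L]))
  out[seq_len(da[1L]), , , ] <- a
  out[da[1L] + seq_len(db[1L]), , , ] <- b
  out
}
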