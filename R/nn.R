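# Minimal convolutional building blocks with analytic backward passes.
# These power the coupling subnetworks and the conditioning networks; all
# arrays use the (c, h, w, n) layout. Gradients are exact (no autodiff
# framework is used anywhere in the package).

# Precompute the im2col gather map for a kxk convolution. Maps are
# cached per geometry since the same shapes recur every training step.
.map_cache <- new.env(parent = emptyenv())

conv_index_map <- function(h, w, k, pad, stride, n = NULL) {
  key <- paste(h, w, k, pad, stride, n %||% 0L, sep = "_")
  hit <- .map_cache[[key]]
  if (!is.null(hit)) return(hit)
  map <- conv_index_map_build(h, w, k, pad, stride)
  if (!is.null(n)) {
    samp_off <- (seq_len(n) - 1L) * (map$H * map$W)
    map$cidx <- lapply(seq_len(k * k), function(kk)
      as.vector(outer(map$idx[kk, ], samp_off, "+")))
  }
  .map_cache[[key]] <- map
  map
}

conv_index_map_build <- function(h, w, k, pad, stride) {
  H <- h + 2L * pad
  W <- w + 2L * pad
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  top <- (oi - 1L) * stride   # padded row above the patch
  left <- (oj - 1L) * stride
  idx <- matrix(0L, k * k, ho * wo)
  kk <- 0L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      kk <- kk + 1L
      idx[kk, ] <- (top + di) + (left + dj - 1L) * H
    }
  }
  list(idx = idx, H = H, W = W, ho = ho, wo = wo)
}

conv_init <- function(cin, cout, k = 3L, stride = 1L, zero_init = FALSE,
                      gain = 1) {
  fan_in <- cin * k * k
  W <- if (zero_init) matrix(0, cout, fan_in)
       else matrix(stats::rnorm(cout * fan_in, sd = gain * sqrt(2 / fan_in)),
                   cout, fan_in)
  list(op = "conv", W = W, b = numeric(cout),
       cin = cin, cout = cout, k = as.integer(k), stride = as.integer(stride),
       pad = as.integer((k - 1L) %/% 2L))
}

conv_im2col <- function(x, k, pad, stride) {
  d <- dim(x)
  c_in <- d[1L]; h <- d[2L]; w <- d[3L]; n <- d[4L]
  map <- conv_index_map(h, w, k, pad, stride, n)
  if (pad > 0L) {
    xp <- array(0, c(c_in, map$H, map$W, n))
    xp[, pad + seq_len(h), pad + seq_len(w), ] <- x
  } else xp <- x
  xpm <- matrix(xp, c_in, map$H * map$W * n)
  k2 <- k * k
  cols <- matrix(0, c_in * k2, map$ho * map$wo * n)
  for (kk in seq_len(k2)) {
    cols[(kk - 1L) * c_in + seq_len(c_in), ] <-
      xpm[, map$cidx[[kk]], drop = FALSE]
  }
  list(cols = cols, map = map, c_in = c_in, h = h, w = w, n = n)
}

conv_fwd <- function(p, x) {
  ic <- conv_im2col(x, p$k, p$pad, p$stride)
  y <- p$W %*% ic$cols + p$b
  dim(y) <- c(p$cout, ic$map$ho, ic$map$wo, ic$n)
  list(y = y, cache = ic)
}

conv_bwd <- function(p, cache, gy) {
  map <- cache$map
  gym <- matrix(gy, p$cout, map$ho * map$wo * cache$n)
  gW <- tcrossprod(gym, cache$cols)
  gb <- rowSums(gym)
  gcols <- crossprod(p$W, gym)
  k2 <- p$k * p$k
  c_in <- cache$c_in
  gxpm <- matrix(0, c_in, map$H * map$W * cache$n)
  for (kk in seq_len(k2)) {
    cidx <- map$cidx[[kk]]
    gxpm[, cidx] <- gxpm[, cidx] + gcols[(kk - 1L) * c_in + seq_len(c_in), ,
                                         drop = FALSE]
  }
  gxp <- array(gxpm, c(c_in, map$H, map$W, cache$n))
  gx <- gxp[, p$pad + seq_len(cache$h), p$pad + seq_len(cache$w), ,
            drop = FALSE]
  list(gx = gx, gW = gW, gb = gb)
}

LRELU_SLOPE <- 0.1

lrelu_fwd <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- LRELU_SLOPE * y[neg]
  list(y = y, cache = neg)
}
lrelu_bwd <- function(cache, gy) {
  gy[cache] <- LRELU_SLOPE * gy[cache]
  gy
}

# 2x2 average pooling (used by conditioning pyramids).
avgpool_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[2L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[3L], 2L); j2 <- j1 + 1L
  y <- (x[, i1, j1, , drop = FALSE] + x[, i2, j1, , drop = FALSE] +
        x[, i1, j2, , drop = FALSE] + x[, i2, j2, , drop = FALSE]) / 4
  y
}

avgpool_bwd <- function(gy, h, w) {
  d <- dim(gy)
  gx <- array(0, c(d[1L], h, w, d[4L]))
  g <- gy / 4
  i1 <- seq(1L, h, 2L); j1 <- seq(1L, w, 2L)
  gx[, i1, j1, ] <- g; gx[, i1 + 1L, j1, ] <- g
  gx[, i1, j1 + 1L, ] <- g; gx[, i1 + 1L, j1 + 1L, ] <- g
  gx
}

# Nearest-neighbour 2x upsampling (conditioning UNet decoder).
nnup_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1L], 2L * d[2L], 2L * d[3L], d[4L]))
  i1 <- seq(1L, 2L * d[2L], 2L); j1 <- seq(1L, 2L * d[3L], 2L)
  y[, i1, j1, ] <- x; y[, i1 + 1L, j1, ] <- x
  y[, i1, j1 + 1L, ] <- x; y[, i1 + 1L, j1 + 1L, ] <- x
  y
}

nnup_bwd <- function(gy) {
  d <- dim(gy)
  i1 <- seq(1L, d[2L], 2L); j1 <- seq(1L, d[3L], 2L)
  gy[, i1, j1, , drop = FALSE] + gy[, i1 + 1L, j1, , drop = FALSE] +
    gy[, i1, j1 + 1L, , drop = FALSE] + gy[, i1 + 1L, j1 + 1L, , drop = FALSE]
}

# A sequential subnetwork: list of conv / lrelu ops.
make_subnet <- function(cin, cout, hidden = 64L, k = 3L, depth = 3L) {
  stopifnot(depth >= 2L)
  layers <- list()
  cprev <- cin
  for (i in seq_len(depth - 1L)) {
    layers[[length(layers) + 1L]] <- conv_init(cprev, hidden, k = k)
    layers[[length(layers) + 1L]] <- list(op = "lrelu")
    cprev <- hidden
  }
  # zero-initialized final layer: every coupling starts as the identity
  layers[[length(layers) + 1L]] <- conv_init(cprev, cout, k = k,
                                             zero_init = TRUE)
  list(layers = layers, cin = cin, cout = cout)
}

subnet_fwd <- function(net, x) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$op == "conv") {
      r <- conv_fwd(l, x); x <- r$y; caches[[i]] <- r$cache
    } else {
      r <- lrelu_fwd(x); x <- r$y; caches[[i]] <- r$cache
    }
  }
  list(y = x, caches = caches)
}

subnet_bwd <- function(net, caches, gy) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$op == "conv") {
      r <- conv_bwd(l, caches[[i]], gy)
      gy <- r$gx
      grads[[i]] <- list(gW = r$gW, gb = r$gb)
    } else {
      gy <- lrelu_bwd(caches[[i]], gy)
      grads[[i]] <- list()
    }
  }
  list(gx = gy, grads = grads)
}

subnet_n_params <- function(net) {
  sum(vapply(net$layers, function(l)
    if (l$op == "conv") length(l$W) + length(l$b) else 0L, numeric(1)))
}
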