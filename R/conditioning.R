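# The conditioning branch: a model-based inversion layer maps the
# measurements into image space, then a feature-extraction network
# produces one feature array per flow scale (plus, for the UNet
# variant, an image-space output used by the conditional loss).

#' Create a model-based inversion layer
#'
#' A classical approximate inverse placed in front of the conditioning
#' network: Moore-Penrose pseudo-inverse, TV-regularized inverse
#' `(A^T A + lambda_tv grad^T grad)^{-1} A^T` (dense operators),
#' filtered back-projection (Radon models), or zero-filled inverse FFT
#' (masked Fourier models; the magnitude image is returned).
#'
#' @param kind one of `"pseudo_inverse"`, `"tv_regularized"`, `"fbp"`,
#'   `"zero_filled_ifft"`.
#' @param fm the `forward_model` the layer inverts.
#' @param lambda_tv TV regularization weight (default 0.02).
#' @param filter,cutoff FBP filter options (see [fbp_reconstruct()]).
#' @return object of class `inversion_layer`.
#' @export
inversion_layer <- function(kind = c("pseudo_inverse", "tv_regularized",
                                     "fbp", "zero_filled_ifft"),
                            fm, lambda_tv = 0.02, filter = "ram-lak",
                            cutoff = 1) {
  kind <- match.arg(kind)
  obj <- list(kind = kind, fm = fm)
  if (kind == "pseudo_inverse") {
    if (fm$kind == "gaussian_cs") {
      obj$P <- MASS::ginv(fm$A)
    } else if (fm$kind != "fourier_masked") {
      stop("pseudo_inverse supports dense and masked-Fourier models; use fbp for Radon",
           call. = FALSE)
    }
  } else if (kind == "tv_regularized") {
    if (fm$kind != "gaussian_cs")
      stop("tv_regularized inversion requires a dense operator", call. = FALSE)
    h <- fm$domain_shape[2L]; w <- fm$domain_shape[3L]
    L <- grad_laplacian(h, w)
    M <- crossprod(fm$A) + lambda_tv * L
    obj$B <- tryCatch(solve(M, t(fm$A)),
                      error = function(e)
                        stop("regularized system is singular: ",
                             conditionMessage(e), call. = FALSE))
    obj$lambda_tv <- lambda_tv
    obj$M <- M
  } else if (kind == "fbp") {
    if (fm$kind != "radon") stop("fbp requires a Radon model", call. = FALSE)
    obj$filter <- filter; obj$cutoff <- cutoff
  } else if (kind == "zero_filled_ifft") {
    if (fm$kind != "fourier_masked")
      stop("zero_filled_ifft requires a masked-Fourier model", call. = FALSE)
  }
  structure(obj, class = "inversion_layer")
}

# grad^T grad for the discrete 2-D forward-difference gradient with
# zero-flux (replicate) boundaries: kron sum of 1-D Neumann Laplacians.
grad_laplacian <- function(h, w) {
  lap1 <- function(k) {
    L <- diag(c(1, rep(2, max(k - 2L, 0L)), 1)[seq_len(k)], k)
    if (k > 1L) {
      idx <- seq_len(k - 1L)
      L[cbind(idx, idx + 1L)] <- -1
      L[cbind(idx + 1L, idx)] <- -1
    }
    L
  }
  diag(w) %x% lap1(h) + lap1(w) %x% diag(h)
}

#' Apply an inversion layer to measurements
#'
#' @param y measurement batch in the forward model's range format.
#' @param layer an [inversion_layer()].
#' @return image batch `(c, h, w, n)`.
#' @export
apply_inversion <- function(y, layer) {
  stopifnot(inherits(layer, "inversion_layer"))
  fm <- layer$fm
  switch(layer$kind,
    pseudo_inverse = {
      if (fm$kind == "gaussian_cs") {
        y <- as.matrix(y)
        array(layer$P %*% y, c(fm$domain_shape, ncol(y)))
      } else {
        forward_adjoint(fm, y)   # orthonormal rows: adjoint = pseudo-inverse
      }
    },
    tv_regularized = {
      y <- as.matrix(y)
      array(layer$B %*% y, c(fm$domain_shape, ncol(y)))
    },
    fbp = fbp_reconstruct(y, fm$geometry, filter = layer$filter,
                          cutoff = layer$cutoff),
    zero_filled_ifft = {
      if (length(dim(y)) == 2L) dim(y) <- c(dim(y), 1L)
      d <- dim(y)
      out <- array(0, c(1L, d[1L], d[2L], d[3L]))
      for (b in seq_len(d[3L])) {
        k <- y[, , b]
        k[, !fm$mask$keep] <- 0
        out[1L, , , b] <- Mod(cifft2(k))
      }
      out
    })
}

# ---------------------------------------------------------------------------
# Conditioning feature networks

cond_widths <- function(width, L) pmin(width * 2^(seq_len(L) - 1L), 256L)

#' Create a conditioning feature network
#'
#' Four variants of increasing capacity produce one feature array per
#' flow scale (spatial sizes halving per scale):
#' * `avg_pool` - one learned convolution, then average pooling per
#'   scale (constant channel width);
#' * `cnn` - a small fully convolutional stack, then average pooling;
#' * `resnet` - residual blocks with strided convolutions replacing the
#'   pooling (channel width doubling per scale, capped at 256);
#' * `unet` - an encoder-decoder whose per-scale activations serve the
#'   invertible UNet's down and up paths and whose head produces an
#'   image-space output for the conditional loss.
#'
#' Parameter counts are strictly ordered
#' `avg_pool < cnn < resnet` by construction.
#'
#' @param kind network variant.
#' @param cin input channels of the reconstruction fed in.
#' @param L number of flow scales.
#' @param width base channel width (default 32).
#' @param seed optional integer seed for initialization.
#' @return object of class `cond_net`.
#' @export
cond_net <- function(kind = c("avg_pool", "cnn", "resnet", "unet"),
                     cin, L, width = 32L, seed = NULL) {
  kind <- match.arg(kind)
  cin <- as.integer(cin); L <- as.integer(L); width <- as.integer(width)
  with_seed(seed, {
    net <- list(kind = kind, cin = cin, L = L, width = width, seed = seed)
    if (kind == "avg_pool") {
      net$conv1 <- conv_init(cin, width)
      net$out_widths <- rep(width, L)
    } else if (kind == "cnn") {
      net$conv1 <- conv_init(cin, width)
      net$conv2 <- conv_init(width, width)
      net$conv3 <- conv_init(width, width)
      net$out_widths <- rep(width, L)
    } else if (kind == "resnet") {
      ws <- cond_widths(width, L)
      net$conv_in <- conv_init(cin, ws[1L])
      net$blocks <- lapply(seq_len(L), function(i) {
        blk <- list(r1 = conv_init(ws[i], ws[i]), r2 = conv_init(ws[i], ws[i]))
        if (i > 1L) blk$down <- conv_init(ws[i - 1L], ws[i], stride = 2L)
        blk
      })
      net$out_widths <- ws
    } else { # unet
      ws <- cond_widths(width, L)
      net$enc <- lapply(seq_len(L), function(i)
        conv_init(if (i == 1L) cin else ws[i - 1L], ws[i]))
      net$bottom <- conv_init(ws[L], ws[L])
      net$dec <- lapply(seq_len(L - 1L), function(i)
        conv_init(ws[i] + ws[i + 1L], ws[i]))
      net$head <- conv_init(ws[1L], cin, zero_init = TRUE)
      net$out_widths <- ws
    }
    structure(net, class = "cond_net")
  })
}

#' @export
print.cond_net <- function(x, ...) {
  cat(sprintf("<cond_net %s: L=%d, widths=%s, %d parameters>\n", x$kind, x$L,
              paste(x$out_widths, collapse = "/"), cond_n_params(x)))
  invisible(x)
}

cond_param_fields <- function(net) {
  switch(net$kind,
    avg_pool = list(list("conv1")),
    cnn = list(list("conv1"), list("conv2"), list("conv3")),
    resnet = c(list(list("conv_in")),
               unlist(lapply(seq_len(net$L), function(i) {
                 f <- list(list("blocks", i, "r1"), list("blocks", i, "r2"))
                 if (i > 1L) f <- c(list(list("blocks", i, "down")), f)
                 f
               }), recursive = FALSE)),
    unet = c(lapply(seq_len(net$L), function(i) list("enc", i)),
             list(list("bottom")),
             lapply(seq_len(net$L - 1L), function(i) list("dec", i)),
             list(list("head"))))
}

cond_get_field <- function(net, path) {
  obj <- net
  for (p in path) obj <- obj[[p]]
  obj
}

cond_assign_field <- function(obj, path, value) {
  if (length(path) == 1L) obj[[path[[1L]]]] <- value
  else obj[[path[[1L]]]] <- cond_assign_field(obj[[path[[1L]]]], path[-1L],
                                              value)
  obj
}

cond_n_params <- function(net) {
  sum(vapply(cond_param_fields(net), function(p) {
    l <- cond_get_field(net, p); length(l$W) + length(l$b)
  }, numeric(1)))
}

# Forward pass; returns pyramid (class conditioning_pyramid) + caches.
cond_fwd <- function(net, x, need_cache = FALSE) {
  L <- net$L
  caches <- list()
  feats <- vector("list", L)
  if (net$kind %in% c("avg_pool", "cnn")) {
    r1 <- conv_fwd(net$conv1, x); a1 <- lrelu_fwd(r1$y)
    h <- a1$y
    caches$c1 <- r1$cache; caches$a1 <- a1$cache
    if (net$kind == "cnn") {
      r2 <- conv_fwd(net$conv2, h); a2 <- lrelu_fwd(r2$y)
      r3 <- conv_fwd(net$conv3, a2$y); a3 <- lrelu_fwd(r3$y)
      h <- a3$y
      caches$c2 <- r2$cache; caches$a2 <- a2$cache
      caches$c3 <- r3$cache; caches$a3 <- a3$cache
    }
    sizes <- list()
    for (i in seq_len(L)) {
      feats[[i]] <- h
      sizes[[i]] <- dim(h)[2:3]
      if (i < L) h <- avgpool_fwd(h)
    }
    caches$sizes <- sizes
  } else if (net$kind == "resnet") {
    r <- conv_fwd(net$conv_in, x); a <- lrelu_fwd(r$y)
    caches$conv_in <- r$cache; caches$a_in <- a$cache
    h <- a$y
    caches$blocks <- vector("list", L)
    for (i in seq_len(L)) {
      bc <- list()
      if (i > 1L) {
        rd <- conv_fwd(net$blocks[[i]]$down, h); ad <- lrelu_fwd(rd$y)
        bc$down <- rd$cache; bc$a_down <- ad$cache
        h <- ad$y
      }
      r1 <- conv_fwd(net$blocks[[i]]$r1, h); a1 <- lrelu_fwd(r1$y)
      r2 <- conv_fwd(net$blocks[[i]]$r2, a1$y)
      bc$r1 <- r1$cache; bc$a1 <- a1$cache; bc$r2 <- r2$cache
      h <- h + r2$y
      feats[[i]] <- h
      caches$blocks[[i]] <- bc
    }
  } else { # unet
    e_acts <- vector("list", L)
    caches$enc <- vector("list", L)
    h <- x
    in_sizes <- vector("list", L)
    for (i in seq_len(L)) {
      in_sizes[[i]] <- dim(h)[2:3]
      r <- conv_fwd(net$enc[[i]], h); a <- lrelu_fwd(r$y)
      caches$enc[[i]] <- list(conv = r$cache, act = a$cache)
      e_acts[[i]] <- a$y
      if (i < L) h <- avgpool_fwd(a$y)
    }
    rb <- conv_fwd(net$bottom, e_acts[[L]]); ab <- lrelu_fwd(rb$y)
    caches$bottom <- list(conv = rb$cache, act = ab$cache)
    d_acts <- vector("list", L)
    d_acts[[L]] <- ab$y
    caches$dec <- vector("list", max(L - 1L, 0L))
    for (i in seq(L - 1L, 1L, length.out = max(L - 1L, 0L))) {
      u <- nnup_fwd(d_acts[[i + 1L]])
      cat_in <- concat_channels(e_acts[[i]], u)
      r <- conv_fwd(net$dec[[i]], cat_in); a <- lrelu_fwd(r$y)
      caches$dec[[i]] <- list(conv = r$cache, act = a$cache,
                              ce = dim(e_acts[[i]])[1L])
      d_acts[[i]] <- a$y
    }
    rh <- conv_fwd(net$head, d_acts[[1L]])
    caches$head <- rh$cache
    caches$in_sizes <- in_sizes
    feats <- d_acts
    pyr <- structure(list(features = d_acts, enc = e_acts, dec = d_acts,
                          head = rh$y, kind = "unet", L = L),
                     class = "conditioning_pyramid")
    return(list(pyramid = pyr, caches = if (need_cache) caches else NULL))
  }
  pyr <- structure(list(features = feats, kind = net$kind, L = L),
                   class = "conditioning_pyramid")
  list(pyramid = pyr, caches = if (need_cache) caches else NULL)
}

# Backward pass. gfeat: list of per-scale gradients (NULL entries ok);
# genc: extra gradients on encoder activations (unet, from the iUNet up
# path); ghead: gradient on the image-space head output.
cond_bwd <- function(net, caches, gfeat, genc = NULL, ghead = NULL) {
  L <- net$L
  grads <- list()
  if (net$kind %in% c("avg_pool", "cnn")) {
    g <- NULL
    for (i in seq(L, 1L)) {
      gi <- gfeat[[i]]
      if (!is.null(g)) {
        sz <- caches$sizes[[i]]
        g <- avgpool_bwd(g, sz[1L], sz[2L])
      }
      g <- if (is.null(gi)) g else if (is.null(g)) gi else g + gi
    }
    if (net$kind == "cnn") {
      g <- lrelu_bwd(caches$a3, g)
      r3 <- conv_bwd(net$conv3, caches$c3, g)
      g <- lrelu_bwd(caches$a2, r3$gx)
      r2 <- conv_bwd(net$conv2, caches$c2, g)
      g <- r2$gx
      grads$conv3 <- list(gW = r3$gW, gb = r3$gb)
      grads$conv2 <- list(gW = r2$gW, gb = r2$gb)
    }
    g <- lrelu_bwd(caches$a1, g)
    r1 <- conv_bwd(net$conv1, caches$c1, g)
    grads$conv1 <- list(gW = r1$gW, gb = r1$gb)
  } else if (net$kind == "resnet") {
    grads$blocks <- vector("list", L)
    g <- NULL
    for (i in seq(L, 1L)) {
      gi <- gfeat[[i]]
      g <- if (is.null(gi)) g else if (is.null(g)) gi else g + gi
      bc <- caches$blocks[[i]]
      bg <- list()
      r2 <- conv_bwd(net$blocks[[i]]$r2, bc$r2, g)
      ga <- lrelu_bwd(bc$a1, r2$gx)
      r1 <- conv_bwd(net$blocks[[i]]$r1, bc$r1, ga)
      g <- g + r1$gx   # residual skip
      bg$r1 <- list(gW = r1$gW, gb = r1$gb)
      bg$r2 <- list(gW = r2$gW, gb = r2$gb)
      if (i > 1L) {
        gd <- lrelu_bwd(bc$a_down, g)
        rd <- conv_bwd(net$blocks[[i]]$down, bc$down, gd)
        g <- rd$gx
        bg$down <- list(gW = rd$gW, gb = rd$gb)
      }
      grads$blocks[[i]] <- bg
    }
    ga <- lrelu_bwd(caches$a_in, g)
    ri <- conv_bwd(net$conv_in, caches$conv_in, ga)
    grads$conv_in <- list(gW = ri$gW, gb = ri$gb)
  } else { # unet
    gd <- vector("list", L)   # gradients on decoder activations
    ge <- vector("list", L)   # gradients on encoder activations
    add <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b
    for (i in seq_len(L)) gd[[i]] <- gfeat[[i]]
    if (!is.null(genc)) for (i in seq_len(L)) ge[[i]] <- genc[[i]]
    grads$dec <- vector("list", max(L - 1L, 0L))
    if (!is.null(ghead)) {
      rh <- conv_bwd(net$head, caches$head, ghead)
      grads$head <- list(gW = rh$gW, gb = rh$gb)
      gd[[1L]] <- add(gd[[1L]], rh$gx)
    } else {
      grads$head <- list(gW = net$head$W * 0, gb = net$head$b * 0)
    }
    for (i in seq_len(max(L - 1L, 0L))) {
      dc <- caches$dec[[i]]
      g <- lrelu_bwd(dc$act, gd[[i]])
      r <- conv_bwd(net$dec[[i]], dc$conv, g)
      grads$dec[[i]] <- list(gW = r$gW, gb = r$gb)
      ce <- dc$ce
      ge[[i]] <- add(ge[[i]], r$gx[seq_len(ce), , , , drop = FALSE])
      gu <- r$gx[ce + seq_len(dim(r$gx)[1L] - ce), , , , drop = FALSE]
      gd[[i + 1L]] <- add(gd[[i + 1L]], nnup_bwd(gu))
    }
    gb <- lrelu_bwd(caches$bottom$act, gd[[L]])
    rb <- conv_bwd(net$bottom, caches$bottom$conv, gb)
    grads$bottom <- list(gW = rb$gW, gb = rb$gb)
    ge[[L]] <- add(ge[[L]], rb$gx)
    grads$enc <- vector("list", L)
    gnext <- NULL
    for (i in seq(L, 1L)) {
      g <- add(ge[[i]], gnext)
      g <- lrelu_bwd(caches$enc[[i]]$act, g)
      r <- conv_bwd(net$enc[[i]], caches$enc[[i]]$conv, g)
      grads$enc[[i]] <- list(gW = r$gW, gb = r$gb)
      if (i > 1L) {
        # the pooling feeding this scale came from e_{i-1}
        gnext <- avgpool_bwd(r$gx, caches$in_sizes[[i - 1L]][1L],
                             caches$in_sizes[[i - 1L]][2L])
      }
    }
  }
  grads
}

#' Build a conditioning pyramid from a reconstruction
#'
#' Runs the conditioning network on the image-space reconstruction
#' produced by the inversion layer and returns one feature array per
#' flow scale (halving spatial sizes).
#'
#' @param recon image batch from [apply_inversion()].
#' @param net a [cond_net()].
#' @return object of class `conditioning_pyramid` with `features`
#'   (list of L arrays); UNet pyramids additionally carry `enc`, `dec`
#'   and the image-space `head`.
#' @export
build_pyramid <- function(recon, net) {
  stopifnot(inherits(net, "cond_net"))
  recon <- as_image_batch(recon)
  if (any(dim(recon)[2:3] %% 2L^(net$L - 1L) != 0L))
    stop("spatial size must be divisible by 2^(L-1)", call. = FALSE)
  cond_fwd(net, recon)$pyramid
}

#' Image-space output of a UNet conditioning pyramid
#'
#' Only the UNet conditioning variant produces an image-space output
#' (used by the conditional reconstruction loss).
#'
#' @param pyramid a `conditioning_pyramid`.
#' @return image batch.
#' @export
conditioning_head <- function(pyramid) {
  if (!identical(pyramid$kind, "unet"))
    stop("conditioning_head requires a unet pyramid", call. = FALSE)
  pyramid$head
}
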