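# Flow architectures assembled from the invertible core. A model is a
# flat list of steps (coupling / mix / down / up / split bookkeeping)
# interpreted by a forward, an inverse and a backward walker, so the
# composed log-determinant is the exact sum over constituent layers.

#' Multi-scale flow configuration
#'
#' The multi-scale architecture applies, per scale,
#' coupling -> downsampling -> coupling -> split: half the channels exit
#' to the latent output at each scale, the rest continue. The final
#' scale is a coupling block whose output is the last latent chunk.
#' Couplings default to affine; a channel-mixing (fixed 1x1 convolution)
#' follows every coupling.
#'
#' @param input_shape image shape `(c, h, w)`; `h`, `w` divisible by
#'   `2^(L-1)`.
#' @param L number of scales (>= 1).
#' @param blocks_per_scale couplings per coupling block (default 2).
#' @param coupling_kind `"affine"` (default) or `"additive"`.
#' @param clamp affine log-scale bound.
#' @param hidden coupling-subnetwork width.
#' @param downsampling `"checkerboard"` or `"haar"`.
#' @param cond_widths integer vector of conditioning channels per scale
#'   (length L), or `NULL` for an unconditional flow.
#' @param mixing `"orthogonal"` or `"permutation"`.
#' @param seed integer seed for all weight initialization.
#' @return config list for [build_flow()].
#' @export
multiscale_config <- function(input_shape, L = 2L, blocks_per_scale = 2L,
                              coupling_kind = "affine", clamp = 2.0,
                              hidden = 64L, downsampling = "checkerboard",
                              cond_widths = NULL, mixing = "orthogonal",
                              seed = 1L) {
  validate_flow_config(input_shape, L, cond_widths)
  list(arch = "multiscale", input_shape = as.integer(input_shape),
       L = as.integer(L), blocks_per_scale = as.integer(blocks_per_scale),
       coupling_kind = coupling_kind, clamp = clamp, hidden = as.integer(hidden),
       downsampling = downsampling, cond_widths = cond_widths,
       mixing = mixing, seed = as.integer(seed))
}

#' Invertible UNet configuration
#'
#' The invertible UNet runs a down path (coupling -> downsampling ->
#' split, with the split-off channels stashed per scale) to the coarsest
#' scale, then an up path that concatenates each stash back, upsamples
#' and applies couplings, so the latent output lives at the input
#' resolution. Couplings default to additive (the stable choice for
#' this architecture); conditioning uses a UNet feature pyramid whose
#' decoder activations feed the down path and encoder activations feed
#' the up path.
#'
#' @inheritParams multiscale_config
#' @param cond_widths_up conditioning channels for the up path (defaults
#'   to `cond_widths`).
#' @return config list for [build_flow()].
#' @export
iunet_config <- function(input_shape, L = 2L, blocks_per_scale = 2L,
                         coupling_kind = "additive", clamp = 2.0,
                         hidden = 64L, downsampling = "checkerboard",
                         cond_widths = NULL, cond_widths_up = NULL,
                         mixing = "orthogonal", seed = 1L) {
  validate_flow_config(input_shape, L, cond_widths)
  list(arch = "iunet", input_shape = as.integer(input_shape),
       L = as.integer(L), blocks_per_scale = as.integer(blocks_per_scale),
       coupling_kind = coupling_kind, clamp = clamp, hidden = as.integer(hidden),
       downsampling = downsampling, cond_widths = cond_widths,
       cond_widths_up = cond_widths_up %||% cond_widths,
       mixing = mixing, seed = as.integer(seed))
}

validate_flow_config <- function(input_shape, L, cond_widths) {
  if (length(input_shape) != 3L) stop("input_shape must be (c, h, w)",
                                      call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (any(input_shape[2:3] %% 2L^(L - 1L) != 0L))
    stop("h and w must be divisible by 2^(L-1)", call. = FALSE)
  if (!is.null(cond_widths) && length(cond_widths) != L)
    stop("cond_widths must have one entry per scale", call. = FALSE)
  invisible(NULL)
}

new_coupling_step <- function(cfg, ch, cond_width, cond_branch, cond_idx,
                              seed) {
  c1 <- as.integer(ceiling(ch / 2))
  conditional <- !is.null(cond_width) && cond_width > 0L
  spec <- coupling_spec(cfg$coupling_kind, c(c1, ch - c1), clamp = cfg$clamp,
                        hidden = cfg$hidden, conditional = conditional,
                        cond_channels = if (conditional) cond_width else 0L,
                        seed = seed)
  list(op = "coupling", spec = spec,
       cond_branch = if (conditional) cond_branch else NA_character_,
       cond_idx = if (conditional) cond_idx else NA_integer_)
}

coupling_block <- function(steps, cfg, ch, cond_width, cond_branch, cond_idx,
                           seed_env) {
  for (b in seq_len(cfg$blocks_per_scale)) {
    seed_env$k <- seed_env$k + 1L
    steps[[length(steps) + 1L]] <-
      new_coupling_step(cfg, ch, cond_width, cond_branch, cond_idx,
                        derive_seed(cfg$seed, seed_env$k))
    seed_env$k <- seed_env$k + 1L
    steps[[length(steps) + 1L]] <-
      list(op = "mix", Q = make_mixing_matrix(ch, cfg$mixing,
                                              derive_seed(cfg$seed, seed_env$k)))
  }
  steps
}

#' Build a flow model from a configuration
#'
#' @param cfg a [multiscale_config()] or [iunet_config()].
#' @return object of class `flow_model` with the step list, the latent
#'   chunk shapes and the total parameter count.
#' @export
build_flow <- function(cfg) {
  steps <- list()
  se <- new.env(); se$k <- 0L
  ch <- cfg$input_shape[1L]
  h <- cfg$input_shape[2L]; w <- cfg$input_shape[3L]
  cw <- cfg$cond_widths
  latent_shapes <- list()
  if (cfg$arch == "multiscale") {
    for (i in seq_len(cfg$L - 1L)) {
      if (ch >= 2L)
        steps <- coupling_block(steps, cfg, ch, cw[i], "features", i, se)
      steps[[length(steps) + 1L]] <- list(op = "down",
                                          method = cfg$downsampling)
      ch <- 4L * ch; h <- h %/% 2L; w <- w %/% 2L
      steps <- coupling_block(steps, cfg, ch, cw[i + 1L], "features",
                              i + 1L, se)
      keep <- ch %/% 2L
      steps[[length(steps) + 1L]] <- list(op = "emit_split", size = keep)
      latent_shapes[[length(latent_shapes) + 1L]] <- c(keep, h, w)
      ch <- ch - keep
    }
    if (ch >= 2L)
      steps <- coupling_block(steps, cfg, ch, cw[cfg$L], "features", cfg$L, se)
    latent_shapes[[length(latent_shapes) + 1L]] <- c(ch, h, w)
  } else { # iunet
    cwu <- cfg$cond_widths_up
    stash_sizes <- integer(0)
    for (i in seq_len(cfg$L - 1L)) {
      if (ch >= 2L)
        steps <- coupling_block(steps, cfg, ch, cw[i], "dec", i, se)
      steps[[length(steps) + 1L]] <- list(op = "down",
                                          method = cfg$downsampling)
      ch <- 4L * ch; h <- h %/% 2L; w <- w %/% 2L
      keep <- ch %/% 2L
      steps[[length(steps) + 1L]] <- list(op = "stash_split", size = keep)
      stash_sizes <- c(stash_sizes, keep)
      ch <- ch - keep
    }
    if (ch >= 2L)
      steps <- coupling_block(steps, cfg, ch, cw[cfg$L], "dec", cfg$L, se)
    for (i in seq(cfg$L - 1L, 1L, length.out = max(cfg$L - 1L, 0L))) {
      steps[[length(steps) + 1L]] <- list(op = "pop_concat",
                                          size = stash_sizes[i])
      ch <- ch + stash_sizes[i]
      steps[[length(steps) + 1L]] <- list(op = "up", method = cfg$downsampling)
      ch <- ch %/% 4L; h <- h * 2L; w <- w * 2L
      if (ch >= 2L)
        steps <- coupling_block(steps, cfg, ch, cwu[i], "enc", i, se)
    }
    latent_shapes[[1L]] <- c(ch, h, w)
  }
  model <- structure(list(arch = cfg$arch, cfg = cfg, steps = steps,
                          latent_shapes = latent_shapes),
                     class = "flow_model")
  model$n_params <- length(flow_params(model))
  model
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("<flow_model %s: L=%d, input=(%s), %d steps, %d parameters>\n",
              x$arch, x$cfg$L, paste(x$cfg$input_shape, collapse = ","),
              length(x$steps), x$n_params))
  invisible(x)
}

get_cond <- function(pyramid, step) {
  if (is.na(step$cond_branch)) return(NULL)
  if (is.null(pyramid)) stop("model is conditional but no pyramid supplied",
                             call. = FALSE)
  br <- pyramid[[step$cond_branch]]
  if (is.null(br) || step$cond_idx > length(br))
    stop("conditioning pyramid scale count does not match the flow",
         call. = FALSE)
  br[[step$cond_idx]]
}

down_fn <- function(method) if (method == "haar") haar_downsample else
  checkerboard_downsample
up_fn <- function(method) if (method == "haar") haar_upsample else
  checkerboard_upsample

# Forward pass x -> latent chunks, with exact composed logdet.
flow_fwd <- function(model, x, pyramid = NULL, need_cache = FALSE) {
  x <- as_image_batch(x)
  if (!all(dim(x)[1:3] == model$cfg$input_shape))
    stop("input shape does not match the model", call. = FALSE)
  nb <- batch_size(x)
  logdet <- numeric(nb)
  z_chunks <- list()
  stash <- list()
  caches <- if (need_cache) vector("list", length(model$steps)) else NULL
  max_scale <- 0
  for (si in seq_along(model$steps)) {
    st <- model$steps[[si]]
    if (st$op == "coupling") {
      cond <- get_cond(pyramid, st)
      r <- coupling_fwd(st$spec, x, cond, cache = need_cache)
      x <- r$y; logdet <- logdet + r$logdet
      if (need_cache) caches[[si]] <- r$cache
      if (!is.null(r$cache$s)) max_scale <- max(max_scale, max(abs(r$cache$s)))
      else if (st$spec$kind == "affine" && !need_cache) max_scale <- NA
    } else if (st$op == "mix") {
      r <- mix_channels(x, st$Q)
      x <- r$output; logdet <- logdet + r$logdet
    } else if (st$op == "down") {
      x <- down_fn(st$method)(x)$output
    } else if (st$op == "up") {
      x <- up_fn(st$method)(x)$output
    } else if (st$op == "emit_split") {
      sp <- split_channels(x, st$size)
      z_chunks[[length(z_chunks) + 1L]] <- sp$kept
      x <- sp$forwarded
    } else if (st$op == "stash_split") {
      sp <- split_channels(x, st$size)
      stash[[length(stash) + 1L]] <- sp$kept
      x <- sp$forwarded
    } else if (st$op == "pop_concat") {
      s <- stash[[length(stash)]]
      stash[[length(stash)]] <- NULL
      x <- concat_channels(x, s)
    }
  }
  z_chunks[[length(z_chunks) + 1L]] <- x
  list(z = z_chunks, logdet = logdet, caches = caches,
       max_log_scale = max_scale)
}

# Inverse pass latent chunks -> x (the sampling direction).
flow_inv <- function(model, z_chunks, pyramid = NULL) {
  expected <- length(model$latent_shapes)
  if (length(z_chunks) != expected)
    stop(sprintf("expected %d latent chunks", expected), call. = FALSE)
  x <- as_image_batch(z_chunks[[expected]])
  zi <- expected - 1L
  stash <- list()
  for (si in rev(seq_along(model$steps))) {
    st <- model$steps[[si]]
    if (st$op == "coupling") {
      x <- coupling_inv(st$spec, x, get_cond(pyramid, st))
    } else if (st$op == "mix") {
      x <- mix_inverse(x, st$Q)
    } else if (st$op == "down") {
      x <- up_fn(st$method)(x)$output
    } else if (st$op == "up") {
      x <- down_fn(st$method)(x)$output
    } else if (st$op == "emit_split") {
      x <- merge_channels(as_image_batch(z_chunks[[zi]]), x)
      zi <- zi - 1L
    } else if (st$op == "stash_split") {
      s <- stash[[length(stash)]]
      stash[[length(stash)]] <- NULL
      x <- merge_channels(s, x)
    } else if (st$op == "pop_concat") {
      cc <- n_channels(x)
      stash[[length(stash) + 1L]] <-
        x[cc - st$size + seq_len(st$size), , , , drop = FALSE]
      x <- x[seq_len(cc - st$size), , , , drop = FALSE]
    }
  }
  x
}

# Backward pass (training direction). gz: list of gradients matching the
# latent chunks; gld: per-sample gradient on logdet. Returns the input
# gradient, parameter gradients per step, and conditioning-feature
# gradients grouped by pyramid branch.
flow_bwd <- function(model, caches, gz, gld) {
  nsteps <- length(model$steps)
  gx <- as_image_batch(gz[[length(gz)]])
  zi <- length(gz) - 1L
  stash <- list()
  gsteps <- vector("list", nsteps)
  gpyr <- list(features = list(), enc = list(), dec = list())
  for (si in rev(seq_len(nsteps))) {
    st <- model$steps[[si]]
    if (st$op == "coupling") {
      r <- coupling_bwd(st$spec, caches[[si]], gx, gld)
      gx <- r$gx
      gsteps[[si]] <- r$gnet
      if (!is.null(r$gcond)) {
        br <- st$cond_branch; idx <- st$cond_idx
        prev <- if (idx <= length(gpyr[[br]])) gpyr[[br]][[idx]] else NULL
        gpyr[[br]][[idx]] <- if (is.null(prev)) r$gcond else prev + r$gcond
      }
    } else if (st$op == "mix") {
      gx <- mix_bwd(gx, st$Q)
    } else if (st$op == "down") {
      gx <- up_fn(st$method)(gx)$output
    } else if (st$op == "up") {
      gx <- down_fn(st$method)(gx)$output
    } else if (st$op == "emit_split") {
      gx <- merge_channels(as_image_batch(gz[[zi]]), gx)
      zi <- zi - 1L
    } else if (st$op == "stash_split") {
      s <- stash[[length(stash)]]
      stash[[length(stash)]] <- NULL
      gx <- merge_channels(s, gx)
    } else if (st$op == "pop_concat") {
      cc <- n_channels(gx)
      stash[[length(stash) + 1L]] <-
        gx[cc - st$size + seq_len(st$size), , , , drop = FALSE]
      gx <- gx[seq_len(cc - st$size), , , , drop = FALSE]
    }
  }
  list(gx = gx, gsteps = gsteps, gpyr = gpyr)
}

# --- parameter flattening -------------------------------------------------

flow_params <- function(model) {
  out <- numeric(0)
  for (st in model$steps) {
    if (st$op == "coupling" && !is.function(st$spec$net)) {
      for (l in st$spec$net$layers)
        if (l$op == "conv") out <- c(out, as.vector(l$W), l$b)
    }
  }
  out
}

flow_set_params <- function(model, theta) {
  pos <- 0L
  for (si in seq_along(model$steps)) {
    st <- model$steps[[si]]
    if (st$op == "coupling" && !is.function(st$spec$net)) {
      for (li in seq_along(st$spec$net$layers)) {
        l <- st$spec$net$layers[[li]]
        if (l$op == "conv") {
          nw <- length(l$W); nb <- length(l$b)
          model$steps[[si]]$spec$net$layers[[li]]$W <-
            matrix(theta[pos + seq_len(nw)], nrow(l$W))
          pos <- pos + nw
          model$steps[[si]]$spec$net$layers[[li]]$b <- theta[pos + seq_len(nb)]
          pos <- pos + nb
        }
      }
    }
  }
  stopifnot(pos == length(theta))
  model
}

flow_grad_vector <- function(model, gsteps) {
  out <- numeric(0)
  for (si in seq_along(model$steps)) {
    st <- model$steps[[si]]
    if (st$op == "coupling" && !is.function(st$spec$net)) {
      g <- gsteps[[si]]
      for (li in seq_along(st$spec$net$layers)) {
        l <- st$spec$net$layers[[li]]
        if (l$op == "conv") {
          gl <- if (is.null(g)) NULL else g[[li]]
          if (is.null(gl)) out <- c(out, numeric(length(l$W) + length(l$b)))
          else out <- c(out, as.vector(gl$gW), gl$gb)
        }
      }
    }
  }
  out
}

cond_params_vec <- function(net) {
  out <- numeric(0)
  for (p in cond_param_fields(net)) {
    l <- cond_get_field(net, p)
    out <- c(out, as.vector(l$W), l$b)
  }
  out
}

cond_set_params <- function(net, theta) {
  pos <- 0L
  for (p in cond_param_fields(net)) {
    l <- cond_get_field(net, p)
    nw <- length(l$W); nb <- length(l$b)
    l$W <- matrix(theta[pos + seq_len(nw)], nrow(l$W)); pos <- pos + nw
    l$b <- theta[pos + seq_len(nb)]; pos <- pos + nb
    net <- cond_assign_field(net, p, l)
  }
  stopifnot(pos == length(theta))
  net
}

cond_grad_vector <- function(net, grads) {
  out <- numeric(0)
  for (p in cond_param_fields(net)) {
    l <- cond_get_field(net, p)
    g <- tryCatch(cond_get_field(grads, p), error = function(e) NULL)
    if (is.null(g)) out <- c(out, numeric(length(l$W) + length(l$b)))
    else out <- c(out, as.vector(g$gW), g$gb)
  }
  out
}

#' Number of trainable parameters
#'
#' @param model a `flow_model`.
#' @param cond optional `cond_net` counted alongside.
#' @return integer parameter count.
#' @export
n_params <- function(model, cond = NULL) {
  length(flow_params(model)) + if (is.null(cond)) 0L else
    length(cond_params_vec(cond))
}

# --- exported architecture surface ----------------------------------------

#' Multi-scale flow: forward, inverse
#'
#' `multiscale_forward` maps an image batch to its latent
#' representation (a list of per-scale chunks) and the exact composed
#' log-determinant; `multiscale_inverse` is the sampling direction.
#' These are thin wrappers over the generic interpreter and also accept
#' invertible-UNet models (see [iunet_forward()]).
#'
#' @param x image batch.
#' @param pyramid a `conditioning_pyramid` (or `NULL` for unconditional
#'   models).
#' @param model a `flow_model` built from [multiscale_config()].
#' @return `multiscale_forward`: list with `z` (latent chunks),
#'   `logdet`, and `max_log_scale` (stability monitor: the largest
#'   absolute clamped log-scale seen; 0 for additive couplings);
#'   `multiscale_inverse`: the image batch.
#' @export
multiscale_forward <- function(x, pyramid = NULL, model) {
  r <- flow_fwd(model, x, pyramid, need_cache = TRUE)
  ms <- r$max_log_scale
  list(z = r$z, logdet = r$logdet, max_log_scale = ms)
}

#' @rdname multiscale_forward
#' @param z latent chunk list as returned by the forward pass.
#' @export
multiscale_inverse <- function(z, pyramid = NULL, model) {
  flow_inv(model, z, pyramid)
}

#' Invertible UNet: forward, inverse
#'
#' Same contract as [multiscale_forward()]; the latent output of an
#' invertible UNet is a single chunk at the input resolution.
#'
#' @inheritParams multiscale_forward
#' @export
iunet_forward <- function(x, pyramid = NULL, model) {
  multiscale_forward(x, pyramid, model)
}

#' @rdname iunet_forward
#' @param z latent chunk list (length 1 for the iUNet).
#' @export
iunet_inverse <- function(z, pyramid = NULL, model) {
  flow_inv(model, z, pyramid)
}

# --- latent flattening ----------------------------------------------------

#' Serialize latent chunks to a samples-by-n matrix (and back)
#'
#' Chunks are laid out in scale order, each chunk in R's native
#' column-major order, so latent codes are reproducible across runs.
#'
#' @param z_chunks list of latent chunk arrays from a flow forward pass.
#' @return `flatten_latent`: a samples-by-n matrix.
#' @export
flatten_latent <- function(z_chunks) {
  nb <- batch_size(as_image_batch(z_chunks[[1L]]))
  mats <- lapply(z_chunks, function(ch) {
    ch <- as_image_batch(ch)
    matrix(ch, prod(dim(ch)[1:3]), nb)
  })
  t(do.call(rbind, mats))
}

#' @rdname flatten_latent
#' @param zmat samples-by-n matrix of latent codes.
#' @param shapes list of chunk shapes (a model's `latent_shapes`).
#' @export
unflatten_latent <- function(zmat, shapes) {
  nb <- nrow(zmat)
  out <- vector("list", length(shapes))
  pos <- 0L
  for (i in seq_along(shapes)) {
    sz <- prod(shapes[[i]])
    blk <- t(zmat[, pos + seq_len(sz), drop = FALSE])
    out[[i]] <- array(blk, c(shapes[[i]], nb))
    pos <- pos + sz
  }
  stopifnot(pos == ncol(zmat))
  out
}

latent_dim <- function(model) sum(vapply(model$latent_shapes, prod, numeric(1)))

# --- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single versioned JSON file holding the flow and
#' conditioning configurations plus all weights at full precision; the
#' model is rebuilt from the stored configuration on load (mixing
#' matrices are reproduced from the stored seeds) and the weights are
#' injected.
#'
#' @param model a `flow_model`.
#' @param path file path.
#' @param cond optional `cond_net` stored alongside.
#' @return `load_checkpoint` returns `list(model, cond)`.
#' @export
save_checkpoint <- function(model, path, cond = NULL) {
  obj <- list(format = "cinnflow-checkpoint", version = 1L,
              cfg = model$cfg, params = flow_params(model))
  if (!is.null(cond)) {
    obj$cond_cfg <- list(kind = cond$kind, cin = cond$cin, L = cond$L,
                         width = cond$width, seed = cond$seed)
    obj$cond_params <- cond_params_vec(cond)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cinnflow-checkpoint"))
    stop("not a cinnflow checkpoint", call. = FALSE)
  cfg <- obj$cfg
  cfg$input_shape <- as.integer(cfg$input_shape)
  if (!is.null(cfg$cond_widths)) cfg$cond_widths <- as.integer(cfg$cond_widths)
  if (!is.null(cfg$cond_widths_up))
    cfg$cond_widths_up <- as.integer(cfg$cond_widths_up)
  model <- build_flow(cfg)
  model <- flow_set_params(model, as.numeric(obj$params))
  cond <- NULL
  if (!is.null(obj$cond_cfg)) {
    cc <- obj$cond_cfg
    cond <- cond_net(cc$kind, cc$cin, cc$L, cc$width,
                     seed = if (is.null(cc$seed)) NULL else cc$seed)
    cond <- cond_set_params(cond, as.numeric(obj$cond_params))
  }
  list(model = model, cond = cond)
}
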