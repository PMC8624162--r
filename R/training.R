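# Maximum-likelihood training. The loss is the negative conditional
# log-likelihood from the change-of-variables formula (full normalized
# base density, nats per sample), optionally plus an image-space MSE on
# the conditioning UNet head. Optimization is Adam with plateau-based
# learning-rate reduction; the returned model is the epoch with minimal
# validation NLL.

#' Negative log-likelihood of latent codes
#'
#' `-(log p_z(z) + logdet)` per sample: the exact negative conditional
#' log-density of the inputs under the flow, in nats. Nothing constant
#' is dropped, so values are comparable across base distributions and
#' models.
#'
#' @param latents latent chunk list (as returned by the flow forward
#'   pass) or a samples-by-n matrix.
#' @param logdet per-sample log-determinant from the same pass.
#' @param base a [base_distribution()] with `n` equal to the latent
#'   dimension.
#' @return one NLL value per sample (nats).
#' @export
nll_loss <- function(latents, logdet, base) {
  zmat <- if (is.list(latents)) flatten_latent(latents) else
    z_as_matrix(latents, base$n)
  if (!all(is.finite(zmat)))
    stop("non-finite latents: training has diverged", call. = FALSE)
  -(log_prob(base, zmat) + logdet)
}

#' Training configuration
#'
#' @param learning_rate initial Adam learning rate (default 1e-4).
#' @param plateau_factor learning-rate multiplier on validation
#'   plateaus (default 0.8, must lie in (0,1)).
#' @param plateau_patience validation rounds without improvement before
#'   the rate is reduced (default 5).
#' @param min_lr floor for the learning rate (default 1e-6).
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training split.
#' @param alpha conditional-loss weight (>= 0; 1.0 is the ablation
#'   default, 0 disables the term).
#' @param train_noise_variance variance of Gaussian noise added to the
#'   training images each epoch (0 disables; 0.005 is the
#'   dequantization-style default for image data).
#' @param val_fraction fraction of the data held out for validation
#'   (split by index before shuffling).
#' @param grad_clip optional gradient-norm clip (NULL disables).
#' @param seed integer seed controlling shuffling and noise.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, plateau_factor = 0.8,
                         plateau_patience = 5L, min_lr = 1e-6,
                         batch_size = 32L, epochs = 10L, alpha = 0,
                         train_noise_variance = 0, val_fraction = 0.1,
                         grad_clip = NULL, seed = 1L, verbose = FALSE) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (plateau_factor <= 0 || plateau_factor >= 1)
    stop("plateau_factor must lie in (0,1)", call. = FALSE)
  if (train_noise_variance < 0)
    stop("train_noise_variance must be >= 0", call. = FALSE)
  list(learning_rate = learning_rate, plateau_factor = plateau_factor,
       plateau_patience = as.integer(plateau_patience), min_lr = min_lr,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       alpha = alpha, train_noise_variance = train_noise_variance,
       val_fraction = val_fraction, grad_clip = grad_clip,
       seed = as.integer(seed), verbose = isTRUE(verbose))
}

take_batch <- function(x, idx) {
  x[, , , idx, drop = FALSE]
}

#' Total training loss on one batch
#'
#' `NLL + alpha * MSE(head, x)`; with `alpha = 0` this is exactly the
#' mean NLL. Used internally by [train_cinn()] and exposed for
#' diagnostics.
#'
#' @param x image batch.
#' @param cond_input image-space conditioning input batch (the output of
#'   [apply_inversion()]), or `NULL` for unconditional models.
#' @param model a `flow_model`.
#' @param cond a `cond_net` (or `NULL`).
#' @param base a [base_distribution()].
#' @param alpha conditional-loss weight.
#' @return list with `loss`, `nll`, `mse` (NA when unused).
#' @export
total_loss <- function(x, cond_input, model, cond, base, alpha = 0) {
  if (alpha > 0 && (is.null(cond) || cond$kind != "unet"))
    stop("alpha > 0 requires a unet conditioning network", call. = FALSE)
  pyr <- NULL
  if (!is.null(cond)) pyr <- cond_fwd(cond, as_image_batch(cond_input))$pyramid
  fw <- flow_fwd(model, x, pyr)
  nll <- mean(nll_loss(fw$z, fw$logdet, base))
  mse <- NA_real_
  loss <- nll
  if (alpha > 0) {
    mse <- mean((conditioning_head(pyr) - x)^2)
    loss <- nll + alpha * mse
  }
  list(loss = loss, nll = nll, mse = mse)
}

# Loss + flat gradient over (flow params, cond params) for one batch.
loss_and_grads <- function(model, cond, base, x, cond_input, alpha = 0) {
  nb <- batch_size(x)
  pyr <- NULL; cond_caches <- NULL
  if (!is.null(cond)) {
    cf <- cond_fwd(cond, cond_input, need_cache = TRUE)
    pyr <- cf$pyramid; cond_caches <- cf$caches
  }
  fw <- flow_fwd(model, x, pyr, need_cache = TRUE)
  zmat <- flatten_latent(fw$z)
  if (!all(is.finite(zmat))) stop("non-finite latents", call. = FALSE)
  nll_vec <- -(log_prob(base, zmat) + fw$logdet)
  nll <- mean(nll_vec)
  gz_mat <- -log_prob_grad(base, zmat) / nb
  gz <- unflatten_latent(gz_mat, model$latent_shapes)
  gld <- rep(-1 / nb, nb)
  bk <- flow_bwd(model, fw$caches, gz, gld)
  gflow <- flow_grad_vector(model, bk$gsteps)
  loss <- nll; mse <- NA_real_
  gcond_vec <- numeric(0)
  if (!is.null(cond)) {
    # unreferenced pyramid scales get zero gradients
    zero_fill <- function(g, ref) {
      out <- vector("list", length(ref))
      for (i in seq_along(ref)) {
        gi <- if (i <= length(g)) g[[i]] else NULL
        out[[i]] <- if (is.null(gi)) array(0, dim(ref[[i]])) else gi
      }
      out
    }
    if (cond$kind == "unet") {
      merge_g <- function(a, b) {
        n <- max(length(a), length(b))
        out <- vector("list", n)
        for (i in seq_len(n)) {
          ai <- if (i <= length(a)) a[[i]] else NULL
          bi <- if (i <= length(b)) b[[i]] else NULL
          out[[i]] <- if (is.null(ai)) bi else if (is.null(bi)) ai else ai + bi
        }
        out
      }
      gfeat <- zero_fill(merge_g(bk$gpyr$features, bk$gpyr$dec), pyr$dec)
      genc <- zero_fill(bk$gpyr$enc, pyr$enc)
      ghead <- NULL
      if (alpha > 0) {
        head <- conditioning_head(pyr)
        mse <- mean((head - x)^2)
        loss <- loss + alpha * mse
        ghead <- 2 * alpha * (head - x) / length(head)
      }
      cg <- cond_bwd(cond, cond_caches, gfeat, genc = genc, ghead = ghead)
    } else {
      cg <- cond_bwd(cond, cond_caches,
                     zero_fill(bk$gpyr$features, pyr$features))
    }
    gcond_vec <- cond_grad_vector(cond, cg)
  }
  list(loss = loss, nll = nll, mse = mse,
       grad = c(gflow, gcond_vec),
       max_log_scale = fw$max_log_scale)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train a conditional (or unconditional) flow model
#'
#' Adam at the configured learning rate with plateau-based reduction
#' (factor `plateau_factor` after `plateau_patience` validation rounds
#' without improvement); the flow and the conditioning network are
#' trained jointly unless `freeze_cond = TRUE`. Per epoch the training
#' images optionally receive fresh Gaussian dequantization noise. The
#' returned model is the checkpoint with minimal validation NLL.
#'
#' @param model a `flow_model` from [build_flow()].
#' @param data list with `x` (image batch array) and optionally
#'   `cond_input` (image-space conditioning input batch, same batch
#'   size). Use [apply_inversion()] to produce `cond_input` from
#'   measurements.
#' @param cfg a [train_config()].
#' @param cond a `cond_net`, or `NULL` for unconditional training.
#' @param base a [base_distribution()]; defaults to the standard normal
#'   of the matching dimension.
#' @param freeze_cond if `TRUE` the conditioning parameters are not
#'   updated (pre-trained conditioning).
#' @return list with `model`, `cond`, and `history` (per-epoch train
#'   NLL, validation NLL, learning-rate trace, `best_epoch`).
#' @export
train_cinn <- function(model, data, cfg = train_config(), cond = NULL,
                       base = NULL, freeze_cond = FALSE) {
  x_all <- as_image_batch(data$x)
  n_all <- batch_size(x_all)
  if (n_all < 2L) stop("dataset too small", call. = FALSE)
  has_cond <- !is.null(cond)
  ci_all <- if (has_cond) as_image_batch(data$cond_input) else NULL
  if (has_cond && batch_size(ci_all) != n_all)
    stop("cond_input batch size must match x", call. = FALSE)
  if (is.null(base)) base <- base_distribution("normal", latent_dim(model))
  if (base$n != latent_dim(model))
    stop("base distribution dimension must equal the latent dimension",
         call. = FALSE)

  n_val <- max(1L, floor(cfg$val_fraction * n_all))
  val_idx <- seq(n_all - n_val + 1L, n_all)   # split by index, pre-shuffle
  tr_idx <- setdiff(seq_len(n_all), val_idx)

  theta <- c(flow_params(model), if (has_cond) cond_params_vec(cond) else
    numeric(0))
  n_flow <- length(flow_params(model))
  opt <- adam_init(length(theta))
  lr <- cfg$learning_rate
  best_val <- Inf; best_theta <- theta; best_epoch <- 0L
  since_improve <- 0L
  hist <- list(train_nll = numeric(0), val_nll = numeric(0), lr = numeric(0))

  val_nll_fn <- function(model, cond) {
    xv <- take_batch(x_all, val_idx)
    pyr <- if (has_cond) cond_fwd(cond, take_batch(ci_all, val_idx))$pyramid
           else NULL
    fw <- flow_fwd(model, xv, pyr)
    mean(nll_loss(fw$z, fw$logdet, base))
  }

  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 1000L + epoch),
                     sample(tr_idx, length(tr_idx)))
    ep_losses <- numeric(0)
    nb <- cfg$batch_size
    starts <- seq(1L, length(ord), by = nb)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + nb - 1L, length(ord))]
      if (length(idx) < 2L) next
      xb <- take_batch(x_all, idx)
      if (cfg$train_noise_variance > 0)
        xb <- add_training_noise(xb, cfg$train_noise_variance,
                                 seed = derive_seed(cfg$seed,
                                                    100000L + epoch * 1000L + bi))
      cb <- if (has_cond) take_batch(ci_all, idx) else NULL
      lg <- tryCatch(
        loss_and_grads(model, cond, base, xb, cb, alpha = cfg$alpha),
        error = function(e) e)
      if (inherits(lg, "error")) {
        warning("aborting training at last good checkpoint: ",
                conditionMessage(lg), call. = FALSE)
        model <- flow_set_params(model, best_theta[seq_len(n_flow)])
        if (has_cond && !freeze_cond)
          cond <- cond_set_params(cond, best_theta[-seq_len(n_flow)])
        hist$best_epoch <- best_epoch
        return(list(model = model, cond = cond, history = hist))
      }
      g <- lg$grad
      if (freeze_cond && has_cond) g[-seq_len(n_flow)] <- 0
      if (!is.null(cfg$grad_clip)) {
        gn <- sqrt(sum(g^2))
        if (gn > cfg$grad_clip) g <- g * (cfg$grad_clip / gn)
      }
      st <- adam_step(opt, theta, g, lr)
      theta <- st$theta; opt <- st$state
      model <- flow_set_params(model, theta[seq_len(n_flow)])
      if (has_cond) cond <- cond_set_params(cond, theta[-seq_len(n_flow)])
      ep_losses <- c(ep_losses, lg$nll)
    }
    vn <- val_nll_fn(model, cond)
    hist$train_nll <- c(hist$train_nll, mean(ep_losses))
    hist$val_nll <- c(hist$val_nll, vn)
    hist$lr <- c(hist$lr, lr)
    if (cfg$verbose)
      message(sprintf("epoch %d: train NLL %.4f, val NLL %.4f, lr %.2e",
                      epoch, mean(ep_losses), vn, lr))
    if (vn < best_val - 1e-12) {
      best_val <- vn; best_theta <- theta; best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$plateau_patience) {
        lr <- max(lr * cfg$plateau_factor, cfg$min_lr)
        since_improve <- 0L
      }
    }
  }
  model <- flow_set_params(model, best_theta[seq_len(n_flow)])
  if (has_cond) cond <- cond_set_params(cond, best_theta[-seq_len(n_flow)])
  hist$best_epoch <- best_epoch
  list(model = model, cond = cond, history = hist)
}
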