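# Self-contained benchmark experiments. These compose the package's
# modules into the three end-to-end studies used for validation:
# density estimation on 2-D Gaussian data, posterior recovery on the
# analytic linear-Gaussian problem, and the conditioning-input ablation
# on synthetic compressed sensing. All randomness is seed-controlled;
# the configurations are the package's fixed study conditions.

#' Density-estimation sanity benchmark
#'
#' Trains an unconditional flow on 2-D standard-normal samples. The
#' analytic optimum of the validation NLL is `log(2*pi) + 1` nats (the
#' differential entropy of the 2-D standard normal), so the gap to that
#' value measures how close maximum-likelihood training gets to the
#' true density.
#'
#' @param seed integer seed.
#' @param n_samples training-set size.
#' @param epochs training epochs.
#' @return list with `val_nll` (best validation NLL), `analytic`
#'   (`log(2*pi) + 1`) and `gap` (their absolute difference).
#' @export
benchmark_density_2d <- function(seed = 1L, n_samples = 20000L, epochs = 8L) {
  cfg <- multiscale_config(c(2L, 1L, 1L), L = 1L, blocks_per_scale = 4L,
                           hidden = 16L, seed = derive_seed(seed, 1L))
  model <- build_flow(cfg)
  x <- with_seed(derive_seed(seed, 2L),
                 array(stats::rnorm(2L * n_samples), c(2L, 1L, 1L, n_samples)))
  tc <- train_config(learning_rate = 3e-3, batch_size = 256L,
                     epochs = epochs, seed = derive_seed(seed, 3L))
  fit <- train_cinn(model, list(x = x), tc)
  val <- min(fit$history$val_nll)
  analytic <- log(2 * pi) + 1
  list(val_nll = val, analytic = analytic, gap = abs(val - analytic),
       history = fit$history)
}

#' Posterior-recovery benchmark on the linear-Gaussian problem
#'
#' Trains a conditional multi-scale flow on pairs from
#' [linear_gaussian_reference()] (4x4 images, 8 Gaussian measurements,
#' known Gaussian prior and noise) and compares the model's conditional
#' mean (100 samples) against the closed-form posterior mean on held-out
#' measurements, plus the rank correlation between the model's pointwise
#' standard deviation and the analytic posterior standard deviation.
#'
#' @param seed integer seed.
#' @param n_train training pairs.
#' @param n_test held-out measurements.
#' @param epochs training epochs.
#' @param N posterior samples per conditional mean.
#' @return list with `rel_l2` (per-test-image relative L2 errors of the
#'   conditional mean), `rel_l2_mean`, `std_rank_cor` (mean Spearman
#'   correlation), and the fitted objects.
#' @export
benchmark_gaussian_posterior <- function(seed = 1L, n_train = 8000L,
                                         n_test = 20L, epochs = 40L,
                                         N = 100L) {
  ref <- linear_gaussian_reference(side = 4L, m = 8L, sigma = 0.05,
                                   seed = derive_seed(seed, 1L))
  tr <- ref$sample_pairs(n_train, seed = derive_seed(seed, 2L))
  inv <- inversion_layer("pseudo_inverse", ref$fm)
  ci <- apply_inversion(tr$measurements, inv)
  cfg <- multiscale_config(c(1L, 4L, 4L), L = 2L, blocks_per_scale = 4L,
                           hidden = 32L, cond_widths = c(16L, 16L),
                           seed = derive_seed(seed, 3L))
  model <- build_flow(cfg)
  cn <- cond_net("cnn", 1L, 2L, width = 16L, seed = derive_seed(seed, 4L))
  tc <- train_config(learning_rate = 1.5e-3, batch_size = 128L,
                     epochs = epochs, plateau_patience = 3L,
                     seed = derive_seed(seed, 5L))
  fit <- train_cinn(model, list(x = tr$images, cond_input = ci), tc,
                    cond = cn)
  te <- ref$sample_pairs(n_test, seed = derive_seed(seed, 6L))
  ci_te <- apply_inversion(te$measurements, inv)
  post_sd <- sqrt(diag(ref$posterior_cov))
  rel <- numeric(n_test); cors <- numeric(n_test)
  for (b in seq_len(n_test)) {
    ps <- posterior_summary(fit$model, fit$cond,
                            ci_te[, , , b, drop = FALSE], N = N,
                            seed = derive_seed(seed, 100L + b))
    mu_true <- ref$posterior_mean(te$measurements[, b])
    rel[b] <- sqrt(sum((as.vector(ps$mean) - mu_true)^2) / sum(mu_true^2))
    cors[b] <- stats::cor(as.vector(ps$std), post_sd, method = "spearman")
  }
  list(rel_l2 = rel, rel_l2_mean = mean(rel), std_rank_cor = mean(cors),
       ref = ref, model = fit$model, cond = fit$cond,
       history = fit$history)
}

# One arm of the conditioning ablation: train with the given inversion
# layer and return the test conditional-mean PSNR.
cs_ablation_arm <- function(fm, inv, train_images, test_images, test_y,
                            seed, epochs, N) {
  ci <- apply_inversion(forward_measure(fm, train_images, seed), inv)
  cfg <- multiscale_config(c(1L, fm$domain_shape[2L], fm$domain_shape[3L]),
                           L = 2L, blocks_per_scale = 2L, hidden = 16L,
                           cond_widths = c(8L, 8L),
                           seed = derive_seed(seed, 31L))
  model <- build_flow(cfg)
  cn <- cond_net("cnn", 1L, 2L, width = 8L, seed = derive_seed(seed, 32L))
  tc <- train_config(learning_rate = 2e-3, batch_size = 32L, epochs = epochs,
                     seed = derive_seed(seed, 33L))
  fit <- train_cinn(model, list(x = train_images, cond_input = ci), tc,
                    cond = cn)
  ci_te <- apply_inversion(test_y, inv)
  ps <- numeric(batch_size(test_images))
  for (b in seq_along(ps)) {
    pm <- posterior_summary(fit$model, fit$cond,
                            ci_te[, , , b, drop = FALSE], N = N,
                            seed = derive_seed(seed, 200L + b))
    ps[b] <- psnr(pm$mean, test_images[, , , b, drop = FALSE], 1)
  }
  mean(ps)
}

forward_measure <- function(fm, images, seed) {
  y <- forward_apply(fm, images)
  add_noise(y, list(kind = "gaussian", level = 0.1),
            seed = derive_seed(seed, 7L))
}

#' Conditioning-input ablation on synthetic compressed sensing
#'
#' Digit-like phantoms are measured with a Gaussian compressed-sensing
#' operator (4x undersampling, 10% relative noise). Two conditional
#' flows with identical architecture and training budget are trained,
#' one conditioned on the TV-regularized inverse (`lambda_tv = 0.02`),
#' one on the Moore-Penrose pseudo-inverse; the test conditional-mean
#' PSNR of each arm is reported per seed.
#'
#' @param seeds integer vector of experiment seeds.
#' @param size image side length (measurements are `size^2 / 4`).
#' @param n_train,n_test training and test set sizes.
#' @param epochs training epochs per arm.
#' @param N posterior samples per conditional mean.
#' @return list with `psnr_tv` and `psnr_pinv` (one mean test PSNR per
#'   seed) and their across-seed means.
#' @export
benchmark_cs_ablation <- function(seeds = 1:3, size = 16L, n_train = 360L,
                                  n_test = 20L, epochs = 20L, N = 100L) {
  n <- size * size
  m <- n %/% 4L
  psnr_tv <- numeric(length(seeds))
  psnr_pinv <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    seed <- seeds[k]
    fm <- make_gaussian_cs(m, n, seed = derive_seed(seed, 1L),
                           image_shape = c(1L, size, size))
    inv_tv <- inversion_layer("tv_regularized", fm, lambda_tv = 0.02)
    inv_pi <- inversion_layer("pseudo_inverse", fm)
    tr_im <- make_phantoms(n_train, size = size, kind = "digits_like",
                           seed = derive_seed(seed, 2L))
    te_im <- make_phantoms(n_test, size = size, kind = "digits_like",
                           seed = derive_seed(seed, 3L))
    te_y <- forward_measure(fm, te_im, seed + 500L)
    psnr_tv[k] <- cs_ablation_arm(fm, inv_tv, tr_im, te_im, te_y, seed,
                                  epochs, N)
    psnr_pinv[k] <- cs_ablation_arm(fm, inv_pi, tr_im, te_im, te_y, seed,
                                    epochs, N)
  }
  list(psnr_tv = psnr_tv, psnr_pinv = psnr_pinv,
       psnr_tv_mean = mean(psnr_tv), psnr_pinv_mean = mean(psnr_pinv))
}
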