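test_that("NLL has the closed form for an identity flow", {
  base <- base_distribution("normal", 16)
  z <- matrix(0, 1, 16)
  expect_equal(nll_loss(z, 0, base), 8 * log(2 * pi))
  # a constant logdet c shifts the loss by exactly -c
  expect_equal(nll_loss(z, 3.7, base), 8 * log(2 * pi) - 3.7)
})

test_that("NLL equals the brute-force change-of-variables density", {
  cfg <- multiscale_config(c(1, 4, 4), L = 2, blocks_per_scale = 1,
                           hidden = 6, seed = 2)
  m <- random_flow(cfg, sd = 0.2)
  base <- base_distribution("normal", 16)
  x <- withr::with_seed(3, array(rnorm(16), c(1, 4, 4, 1)))
  fw <- cinnflow:::flow_fwd(m, x)
  nll <- nll_loss(fw$z, fw$logdet, base)
  f <- function(v) {
    r <- cinnflow:::flow_fwd(m, array(v, c(1, 4, 4, 1)))
    as.vector(flatten_latent(r$z))
  }
  ld <- fd_logdet(f, as.vector(x))
  z <- f(as.vector(x))
  nll_brute <- -(sum(dnorm(z, log = TRUE)) + ld)
  expect_equal(as.numeric(nll), nll_brute, tolerance = 1e-5)
})

test_that("total loss reduces to NLL at alpha 0 and adds the head MSE", {
  icfg <- iunet_config(c(1, 8, 8), L = 2, hidden = 6, cond_widths = c(4, 8),
                       seed = 3)
  m <- random_flow(icfg, sd = 0.1)
  un <- cond_net("unet", 1, 2, width = 4, seed = 4)
  base <- base_distribution("normal", 64)
  x <- withr::with_seed(5, array(rnorm(64 * 2), c(1, 8, 8, 2)))
  ci <- withr::with_seed(6, array(rnorm(64 * 2), c(1, 8, 8, 2)))
  t0 <- total_loss(x, ci, m, un, base, alpha = 0)
  expect_equal(t0$loss, t0$nll)
  t1 <- total_loss(x, ci, m, un, base, alpha = 1)
  expect_equal(t1$loss, t1$nll + t1$mse)
  # alpha > 0 demands a unet head
  cn <- cond_net("cnn", 1, 2, width = 4, seed = 4)
  cfg2 <- multiscale_config(c(1, 8, 8), L = 2, hidden = 6,
                            cond_widths = c(4, 4), seed = 3)
  m2 <- build_flow(cfg2)
  expect_error(total_loss(x, ci, m2, cn, base, alpha = 1), "unet")
})

test_that("analytic gradients match finite differences end to end", {
  cfg <- multiscale_config(c(1, 4, 4), L = 2, blocks_per_scale = 1,
                           hidden = 4, cond_widths = c(2, 2), seed = 5)
  m <- random_flow(cfg, sd = 0.1)
  cn <- cond_net("avg_pool", 1, 2, width = 2, seed = 6)
  base <- base_distribution("radial", 16)
  x <- withr::with_seed(7, array(runif(16 * 2), c(1, 4, 4, 2)))
  ci <- withr::with_seed(8, array(rnorm(16 * 2), c(1, 4, 4, 2)))
  lg <- cinnflow:::loss_and_grads(m, cn, base, x, ci)
  th_f <- cinnflow:::flow_params(m)
  th <- c(th_f, cinnflow:::cond_params_vec(cn))
  idx <- withr::with_seed(9, sample(length(th), 40))
  for (i in idx) {
    ev <- function(v) {
      mm <- cinnflow:::flow_set_params(m, v[seq_along(th_f)])
      cc <- cinnflow:::cond_set_params(cn, v[-seq_along(th_f)])
      total_loss(x, ci, mm, cc, base, 0)$loss
    }
    vp <- th; vm <- th
    vp[i] <- vp[i] + 1e-6; vm[i] <- vm[i] - 1e-6
    num <- (ev(vp) - ev(vm)) / 2e-6
    expect_equal(lg$grad[i], num, tolerance = 1e-4)
  }
})

test_that("training overfits a small fixed batch by at least 1 nat", {
  cfg <- multiscale_config(c(1, 4, 4), L = 2, blocks_per_scale = 2,
                           hidden = 16, seed = 1)
  m <- build_flow(cfg)
  x <- make_phantoms(8, 16, "ellipses", seed = 2)[, 1:4, 1:4, , drop = FALSE]
  base <- base_distribution("normal", 16)
  fw0 <- cinnflow:::flow_fwd(m, x)
  nll0 <- mean(nll_loss(fw0$z, fw0$logdet, base))
  # 200 optimization steps on the same batch (~25 epochs of 8 images
  # with batch size 8 would be 25 steps; use epochs to reach 200)
  tc <- train_config(learning_rate = 5e-3, batch_size = 8, epochs = 220,
                     val_fraction = 0.125, seed = 3)
  fit <- train_cinn(m, list(x = x), tc, base = base)
  fw1 <- cinnflow:::flow_fwd(fit$model, x)
  nll1 <- mean(nll_loss(fw1$z, fw1$logdet, base))
  expect_lt(nll1, nll0 - 1)
})

test_that("training history is seed-deterministic and tracks the best epoch", {
  cfg <- multiscale_config(c(2, 1, 1), L = 1, blocks_per_scale = 2,
                           hidden = 8, seed = 2)
  x <- withr::with_seed(4, array(rnorm(2 * 400), c(2, 1, 1, 400)))
  tc <- train_config(learning_rate = 1e-3, batch_size = 64, epochs = 3,
                     seed = 9)
  f1 <- train_cinn(build_flow(cfg), list(x = x), tc)
  f2 <- train_cinn(build_flow(cfg), list(x = x), tc)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$history$best_epoch, which.min(f1$history$val_nll))
  expect_equal(min(f1$history$val_nll),
               f1$history$val_nll[f1$history$best_epoch])
})

test_that("gradients reach both the flow and the conditioning network", {
  cfg <- multiscale_config(c(1, 4, 4), L = 2, hidden = 4,
                           cond_widths = c(2, 2), seed = 5)
  m <- random_flow(cfg, sd = 0.1)
  cn <- cond_net("avg_pool", 1, 2, width = 2, seed = 6)
  base <- base_distribution("normal", 16)
  x <- withr::with_seed(7, array(runif(32), c(1, 4, 4, 2)))
  ci <- withr::with_seed(8, array(rnorm(32), c(1, 4, 4, 2)))
  lg <- cinnflow:::loss_and_grads(m, cn, base, x, ci)
  nf <- length(cinnflow:::flow_params(m))
  expect_gt(sqrt(sum(lg$grad[seq_len(nf)]^2)), 0)
  expect_gt(sqrt(sum(lg$grad[-seq_len(nf)]^2)), 0)
})

test_that("a high-weight conditional loss drives the head to the images", {
  # single-batch overfit: H(y) approaches the training images in MSE
  icfg <- iunet_config(c(1, 4, 4), L = 2, hidden = 8, cond_widths = c(4, 8),
                       seed = 7)
  m <- build_flow(icfg)
  un <- cond_net("unet", 1, 2, width = 4, seed = 8)
  x <- make_phantoms(8, 16, "ellipses", seed = 9)[, 7:10, 7:10, ,
                                                  drop = FALSE]
  ci <- x + withr::with_seed(10, array(rnorm(length(x), sd = 0.1), dim(x)))
  base <- base_distribution("normal", 16)
  mse0 <- total_loss(x, ci, m, un, base, alpha = 50)$mse
  tc <- train_config(learning_rate = 1e-2, batch_size = 8, epochs = 200,
                     alpha = 50, val_fraction = 0.125, seed = 11)
  fit <- train_cinn(m, list(x = x, cond_input = ci), tc, cond = un,
                    base = base)
  mse1 <- total_loss(x, ci, fit$model, fit$cond, base, alpha = 50)$mse
  expect_lt(mse1, mse0 / 5)
})
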