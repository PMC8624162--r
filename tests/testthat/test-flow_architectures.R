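test_that("identity-initialized multiscale flow is a permutation with zero logdet", {
  cfg <- multiscale_config(c(1, 8, 8), L = 2, hidden = 6,
                           mixing = "permutation", seed = 1)
  m <- build_flow(cfg)
  x <- withr::with_seed(2, array(rnorm(64 * 2), c(1, 8, 8, 2)))
  r <- multiscale_forward(x, NULL, m)
  expect_equal(r$logdet, c(0, 0), tolerance = 1e-12)
  z <- flatten_latent(r$z)
  expect_identical(sort(round(as.vector(z), 10)),
                   sort(round(as.vector(x), 10)))
  expect_equal(multiscale_inverse(r$z, NULL, m), x, tolerance = 1e-12)
})

test_that("latent size equals image size for both architectures", {
  for (L in 1:3) {
    cfg <- multiscale_config(c(1, 8, 8), L = L, hidden = 4, seed = L)
    m <- build_flow(cfg)
    expect_equal(sum(vapply(m$latent_shapes, prod, numeric(1))), 64)
    icfg <- iunet_config(c(1, 8, 8), L = L, hidden = 4, seed = L)
    im <- build_flow(icfg)
    expect_equal(sum(vapply(im$latent_shapes, prod, numeric(1))), 64)
  }
  cfg2 <- multiscale_config(c(2, 8, 8), L = 2, hidden = 4, seed = 1)
  expect_equal(sum(vapply(build_flow(cfg2)$latent_shapes, prod,
                          numeric(1))), 128)
})

test_that("multiscale roundtrip and logdet oracle with random weights", {
  cfg <- multiscale_config(c(1, 8, 8), L = 2, blocks_per_scale = 2,
                           hidden = 8, cond_widths = c(3, 3), seed = 7)
  m <- random_flow(cfg, sd = 0.1)
  cn <- cond_net("avg_pool", 1, 2, width = 3, seed = 3)
  recon <- withr::with_seed(4, array(rnorm(64), c(1, 8, 8, 1)))
  pyr <- build_pyramid(recon, cn)
  x <- withr::with_seed(5, array(rnorm(64), c(1, 8, 8, 1)))
  r <- multiscale_forward(x, pyr, m)
  expect_lt(max(abs(multiscale_inverse(r$z, pyr, m) - x)), 1e-10)
  f <- function(v) {
    rr <- multiscale_forward(array(v, c(1, 8, 8, 1)), pyr, m)
    as.vector(flatten_latent(rr$z))
  }
  ld <- fd_logdet(f, as.vector(x))
  expect_lt(abs(r$logdet - ld) / max(abs(ld), 1e-8), 1e-4)
})

test_that("haar-downsampling multiscale variant also matches the oracle", {
  cfg <- multiscale_config(c(1, 4, 4), L = 2, blocks_per_scale = 1,
                           hidden = 6, downsampling = "haar", seed = 13)
  m <- random_flow(cfg, sd = 0.2)
  x <- withr::with_seed(14, array(rnorm(16), c(1, 4, 4, 1)))
  r <- multiscale_forward(x, NULL, m)
  expect_lt(max(abs(multiscale_inverse(r$z, NULL, m) - x)), 1e-10)
  f <- function(v) {
    rr <- multiscale_forward(array(v, c(1, 4, 4, 1)), NULL, m)
    as.vector(flatten_latent(rr$z))
  }
  ld <- fd_logdet(f, as.vector(x))
  expect_lt(abs(r$logdet - ld) / max(abs(ld), 1e-8), 1e-4)
})

test_that("iUNet with additive couplings: zero logdet, tight roundtrip", {
  icfg <- iunet_config(c(1, 8, 8), L = 2, hidden = 8,
                       cond_widths = c(4, 8), seed = 9)
  im <- random_flow(icfg, sd = 0.3)
  un <- cond_net("unet", 1, 2, width = 4, seed = 5)
  recon <- withr::with_seed(6, array(rnorm(64), c(1, 8, 8, 1)))
  pyr <- build_pyramid(recon, un)
  x <- withr::with_seed(7, array(rnorm(64), c(1, 8, 8, 1)))
  r <- iunet_forward(x, pyr, im)
  expect_length(r$z, 1)
  expect_equal(r$logdet, 0, tolerance = 1e-12)
  expect_equal(r$max_log_scale, 0)
  expect_lt(max(abs(iunet_inverse(r$z, pyr, im) - x)), 1e-10)
})

test_that("affine iUNet logdet matches the full-Jacobian oracle", {
  icfg <- iunet_config(c(1, 8, 8), L = 2, coupling_kind = "affine",
                       blocks_per_scale = 1, hidden = 6,
                       cond_widths = c(4, 8), seed = 11)
  im <- random_flow(icfg, sd = 0.15)
  un <- cond_net("unet", 1, 2, width = 4, seed = 5)
  pyr <- build_pyramid(withr::with_seed(8, array(rnorm(64), c(1, 8, 8, 1))),
                       un)
  x <- withr::with_seed(9, array(rnorm(64), c(1, 8, 8, 1)))
  r <- iunet_forward(x, pyr, im)
  f <- function(v) {
    rr <- iunet_forward(array(v, c(1, 8, 8, 1)), pyr, im)
    as.vector(flatten_latent(rr$z))
  }
  ld <- fd_logdet(f, as.vector(x))
  expect_lt(abs(r$logdet - ld) / max(abs(ld), 1e-8), 1e-4)
})

test_that("sampling from a fixed latent is deterministic and batch-consistent", {
  cfg <- multiscale_config(c(1, 4, 4), L = 2, hidden = 6,
                           cond_widths = c(2, 2), seed = 3)
  m <- random_flow(cfg, sd = 0.2)
  cn <- cond_net("avg_pool", 1, 2, width = 2, seed = 2)
  ci <- withr::with_seed(1, array(rnorm(16), c(1, 4, 4, 1)))
  x1 <- posterior_sample(m, cn, ci, N = 5, seed = 42)
  x2 <- posterior_sample(m, cn, ci, N = 5, seed = 42)
  expect_identical(x1, x2)
  x3 <- posterior_sample(m, cn, ci, N = 5, seed = 43)
  expect_gt(max(abs(x1 - x3)), 0)
})

test_that("config validation rejects bad shapes and mismatched pyramids", {
  expect_error(multiscale_config(c(1, 6, 6), L = 3), "divisible")
  expect_error(multiscale_config(c(1, 8), L = 2), "input_shape")
  cfg <- multiscale_config(c(1, 8, 8), L = 2, hidden = 4,
                           cond_widths = c(2, 2), seed = 1)
  m <- build_flow(cfg)
  x <- array(0, c(1, 8, 8, 1))
  expect_error(multiscale_forward(x, NULL, m), "pyramid")
  cn1 <- cond_net("avg_pool", 1, 1, width = 2, seed = 1)
  pyr1 <- build_pyramid(array(0, c(1, 8, 8, 1)), cn1)
  expect_error(multiscale_forward(x, pyr1, m), "scale count")
  expect_error(multiscale_forward(array(0, c(1, 4, 4, 1)), NULL, m),
               "shape")
})

test_that("checkpoints roundtrip through JSON", {
  cfg <- multiscale_config(c(1, 4, 4), L = 2, hidden = 6,
                           cond_widths = c(2, 2), seed = 5)
  m <- random_flow(cfg, sd = 0.2)
  cn <- cond_net("cnn", 1, 2, width = 2, seed = 6)
  path <- tempfile(fileext = ".json")
  save_checkpoint(m, path, cond = cn)
  lc <- load_checkpoint(path)
  ci <- withr::with_seed(2, array(rnorm(16 * 2), c(1, 4, 4, 2)))
  x <- withr::with_seed(3, array(rnorm(16 * 2), c(1, 4, 4, 2)))
  pyr <- build_pyramid(ci, cn)
  pyr2 <- build_pyramid(ci, lc$cond)
  r1 <- multiscale_forward(x, pyr, m)
  r2 <- multiscale_forward(x, pyr2, lc$model)
  expect_equal(r1$z, r2$z, tolerance = 1e-12)
  expect_equal(r1$logdet, r2$logdet, tolerance = 1e-12)
  unlink(path)
})
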