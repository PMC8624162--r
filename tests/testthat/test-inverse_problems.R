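test_that("gaussian CS operator: shape, variance, determinism", {
  fm <- make_gaussian_cs(196, 784, seed = 5)
  expect_equal(dim(fm$A), c(196, 784))
  # empirical entry variance within 10% of 1/m (m*n > 1e5 entries)
  expect_lt(abs(stats::var(as.vector(fm$A)) - 1 / 196) * 196, 0.1)
  fm2 <- make_gaussian_cs(196, 784, seed = 5)
  expect_identical(fm$A, fm2$A)
  fm3 <- make_gaussian_cs(196, 784, seed = 6)
  expect_gt(max(abs(fm$A - fm3$A)), 0)
  expect_error(make_gaussian_cs(10, 5), "m <= n")
})

test_that("radon transform is linear and zero maps to zero", {
  geom <- radon_geometry(16, n_angles = 10)
  z <- array(0, c(1, 16, 16, 1))
  expect_equal(max(abs(radon_transform(z, geom))), 0)
  a <- make_phantoms(1, 16, "ellipses", seed = 1)
  b <- make_phantoms(1, 16, "ellipses", seed = 2)
  expect_equal(radon_transform(a + 2 * b, geom),
               radon_transform(a, geom) + 2 * radon_transform(b, geom),
               tolerance = 1e-10)
  expect_error(radon_transform(array(0, c(1, 8, 8, 1)), geom), "size")
})

test_that("radon geometry covers the diagonal with increasing angles", {
  geom <- radon_geometry(32, n_angles = 7)
  expect_true(all(diff(geom$angles) > 0))
  expect_gte(geom$n_det, ceiling(32 * sqrt(2)))
  expect_error(radon_geometry(32, n_det = 16), "diagonal")
})

test_that("all forward models pass the adjoint dot-product test", {
  fms <- list(make_gaussian_cs(24, 64, seed = 1, image_shape = c(1, 8, 8)),
              make_radon(16, n_angles = 12),
              make_fourier_masked(16, 16,
                                  make_mri_mask(16, 4, 0.125, seed = 2)))
  for (fm in fms) expect_lt(adjoint_dot_test(fm, seed = 3), 1e-6)
})

test_that("MRI mask keeps the right columns", {
  msk <- make_mri_mask(320, acceleration = 4, center_fraction = 0.08,
                       seed = 9)
  expect_equal(sum(msk$keep), round(320 / 4))
  expect_length(msk$center_cols, round(0.08 * 320))
  expect_true(all(msk$keep[msk$center_cols]))
  # every draw keeps the center
  for (s in 1:5) {
    m2 <- make_mri_mask(64, 4, 0.1, seed = s)
    expect_true(all(m2$keep[m2$center_cols]))
    expect_equal(sum(m2$keep), 16)
  }
  expect_error(make_mri_mask(32, acceleration = 2, center_fraction = 0.6),
               "infeasible")
})

test_that("masked Fourier operator: full-mask inversion and energy bound", {
  x <- make_phantoms(1, 16, "ellipses", seed = 3)
  full <- make_mri_mask(16, 4, 0.125, seed = 1); full$keep[] <- TRUE
  k_full <- fourier_masked_forward(x, full)
  expect_lt(max(Mod(cinnflow:::cifft2(k_full[, , 1]) - x[1, , , 1])), 1e-10)
  msk <- make_mri_mask(16, 4, 0.125, seed = 1)
  k_masked <- fourier_masked_forward(x, msk)
  expect_lte(sum(Mod(k_masked)^2), sum(Mod(k_full)^2))
})

test_that("relative Gaussian noise hits its target level", {
  y <- withr::with_seed(1, matrix(rnorm(196), 196, 1))
  expect_identical(add_noise(y, list(kind = "gaussian", level = 0)), y)
  ratios <- vapply(1:100, function(s) {
    yn <- add_noise(y, list(kind = "gaussian", level = 0.1), seed = s)
    sqrt(sum((yn - y)^2)) / sqrt(sum(y^2))
  }, numeric(1))
  expect_true(all(ratios > 0.08 & ratios < 0.12))
  expect_error(add_noise(y, list(kind = "gaussian", level = -1)), ">= 0")
})

test_that("Poisson noise vanishes at large photon counts", {
  y <- matrix(seq(0.1, 2, length.out = 50), 50, 1)
  yn <- add_noise(y, list(kind = "poisson", n0 = 1e9), seed = 4)
  expect_lt(max(abs(yn - y) / y), 5e-3)
  yn2 <- add_noise(y, list(kind = "poisson", n0 = 100), seed = 4)
  expect_gt(max(abs(yn2 - y)), 0.01)
})

test_that("training noise has the configured variance", {
  x <- array(0.5, c(1, 100, 100, 100))
  expect_identical(add_training_noise(x, 0), x)
  xn <- add_training_noise(x, 0.005, seed = 11)
  expect_lt(abs(stats::var(as.vector(xn - x)) - 0.005) / 0.005, 0.05)
})

test_that("phantoms are bounded, reproducible and non-degenerate", {
  for (kind in c("ellipses", "digits_like")) {
    p1 <- make_phantoms(4, 16, kind, seed = 3)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_identical(p1, make_phantoms(4, 16, kind, seed = 3))
    p2 <- make_phantoms(4, 16, kind, seed = 4)
    expect_gt(max(abs(p1 - p2)), 0)
  }
  expect_error(make_phantoms(1, 8), ">= 16")
})

test_that("synthetic datasets regenerate bit-identically from the seed", {
  fm <- make_gaussian_cs(64, 256, seed = 1, image_shape = c(1, 16, 16))
  d1 <- synthetic_dataset(fm, 5, kind = "digits_like", seed = 42)
  d2 <- synthetic_dataset(fm, 5, kind = "digits_like", seed = 42)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$measurements, d2$measurements)
})

test_that("linear-Gaussian reference posterior matches a direct solve", {
  ref <- linear_gaussian_reference(side = 3, m = 4, sigma = 0.1, seed = 2)
  y <- withr::with_seed(5, rnorm(4))
  mu <- ref$posterior_mean(y)
  # independent route: posterior precision form
  A <- ref$fm$A
  P <- solve(ref$Sigma0) + crossprod(A) / ref$sigma^2
  mu2 <- solve(P, solve(ref$Sigma0, ref$mu0) + crossprod(A, y) / ref$sigma^2)
  expect_equal(mu, as.vector(mu2), tolerance = 1e-8)
  Sig2 <- solve(P)
  expect_equal(ref$posterior_cov, Sig2, tolerance = 1e-8)
  # sampled pairs respect the prior moments roughly
  pp <- ref$sample_pairs(4000, seed = 3)
  xs <- matrix(pp$images, 9, 4000)
  expect_equal(rowMeans(xs), ref$mu0, tolerance = 0.05)
})
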