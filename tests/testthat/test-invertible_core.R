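test_that("affine coupling is the identity at zero subnetwork output", {
  x <- withr::with_seed(1, array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2)))
  # zero-initialized final layer => s = t = 0 at construction
  sp <- coupling_spec("affine", c(1, 1), seed = 3)
  r <- coupling_forward(x, NULL, sp)
  expect_equal(r$output, x)
  expect_equal(r$logdet, c(0, 0))
  # explicit stub: s = 0, t = 0
  sp0 <- coupling_spec("affine", c(1, 1),
                       net = function(z) array(0, c(2, dim(z)[2], dim(z)[3],
                                                    dim(z)[4])))
  r0 <- coupling_forward(x, NULL, sp0)
  expect_equal(r0$output, x)
  expect_equal(coupling_inverse(x, NULL, sp0), x)
})

test_that("additive couplings have exactly zero logdet and exact inverses", {
  for (seed in 1:3) {
    sp <- random_coupling("additive", 2, 2, seed = seed)
    x <- withr::with_seed(seed + 10L, array(rnorm(4 * 4 * 4 * 3),
                                            c(4, 4, 4, 3)))
    r <- coupling_forward(x, NULL, sp)
    expect_identical(r$logdet, c(0, 0, 0))
    expect_equal(coupling_inverse(r$output, NULL, sp), x, tolerance = 1e-12)
  }
})

test_that("affine coupling logdet matches the stub and finite differences", {
  # stub M returning s = ln 2, t = 0 on a (1, 2, 2, 2) input: logdet = 4 ln 2
  # (clamp far above ln 2 so the tanh bound is inactive to ~1e-7)
  sp <- coupling_spec("affine", c(1, 1), clamp = 1000,
                      net = function(z) {
                        d <- dim(z)
                        out <- array(0, c(2, d[2], d[3], d[4]))
                        out[1, , , ] <- log(2)
                        out
                      })
  x <- withr::with_seed(5, array(rnorm(2 * 2 * 2), c(2, 2, 2, 1)))
  r <- coupling_forward(x, NULL, sp)
  expect_equal(r$logdet, 4 * log(2), tolerance = 1e-6)
  f <- function(v) {
    as.vector(coupling_forward(array(v, c(2, 2, 2, 1)), NULL, sp)$output)
  }
  expect_equal(r$logdet, fd_logdet(f, as.vector(x)), tolerance = 1e-6)

  # randomized affine coupling vs finite differences
  spr <- random_coupling("affine", 1, 1, seed = 7)
  rr <- coupling_forward(x, NULL, spr)
  fr <- function(v)
    as.vector(coupling_forward(array(v, c(2, 2, 2, 1)), NULL, spr)$output)
  expect_equal(rr$logdet, fd_logdet(fr, as.vector(x)), tolerance = 1e-4)
})

test_that("coupling roundtrips hold for conditional and clamped cases", {
  for (kind in c("affine", "additive")) {
    sp <- random_coupling(kind, 2, 3, seed = 21, conditional = TRUE,
                          cond_channels = 2, sd = 0.5)
    x <- withr::with_seed(22, array(rnorm(5 * 4 * 4 * 2), c(5, 4, 4, 2)))
    cond <- withr::with_seed(23, array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2)))
    r <- coupling_forward(x, cond, sp)
    expect_lt(max(abs(coupling_inverse(r$output, cond, sp) - x)), 1e-10)
  }
})

test_that("coupling validates shapes and finiteness", {
  sp <- coupling_spec("affine", c(1, 1), seed = 1)
  expect_error(coupling_forward(array(0, c(3, 2, 2, 1)), NULL, sp), "channel")
  bad <- array(0, c(2, 2, 2, 1)); bad[1] <- NaN
  expect_error(coupling_forward(bad, NULL, sp), "non-finite")
  expect_error(coupling_spec("affine", c(1, 0)), "split_sizes")
  spc <- coupling_spec("affine", c(1, 1), conditional = TRUE,
                       cond_channels = 2, seed = 1)
  expect_error(coupling_forward(array(0, c(2, 2, 2, 1)), NULL, spc), "cond")
})

test_that("channel mixing has logdet h*w*log|det Q| and an exact inverse", {
  x <- withr::with_seed(3, array(rnorm(3 * 2 * 2 * 2), c(3, 2, 2, 2)))
  # identity
  r <- mix_channels(x, diag(3))
  expect_equal(r$output, x)
  expect_equal(r$logdet, c(0, 0))
  # orthogonal default: |det Q| = 1
  Q <- make_mixing_matrix(3, "orthogonal", seed = 5)
  expect_equal(abs(det(Q)), 1, tolerance = 1e-12)
  ro <- mix_channels(x, Q)
  expect_equal(ro$logdet, c(0, 0), tolerance = 1e-12)
  expect_equal(cinnflow:::mix_inverse(ro$output, Q), x, tolerance = 1e-12)
  # random invertible Q: logdet = 4 * log|det Q|, cross-checked vs FD
  Qr <- withr::with_seed(6, matrix(rnorm(9), 3) + diag(3))
  rr <- mix_channels(x[, , , 1, drop = FALSE], Qr)
  expect_equal(rr$logdet, 4 * log(abs(det(Qr))), tolerance = 1e-12)
  f <- function(v) as.vector(mix_channels(array(v, c(3, 2, 2, 1)), Qr)$output)
  expect_equal(rr$logdet, fd_logdet(f, as.vector(x[, , , 1])),
               tolerance = 1e-5)
  expect_error(mix_channels(x, matrix(0, 3, 3)), "singular")
  # permutation variant is a valid mixing matrix
  P <- make_mixing_matrix(4, "permutation", seed = 2)
  expect_equal(sort(colSums(P)), rep(1, 4))
})

test_that("checkerboard downsampling is a bit-exact permutation", {
  x <- withr::with_seed(8, array(rnorm(2 * 4 * 6 * 2), c(2, 4, 6, 2)))
  r <- checkerboard_downsample(x)
  expect_equal(dim(r$output), c(8, 2, 3, 2))
  expect_identical(r$logdet, c(0, 0))
  expect_identical(sort(as.vector(r$output)), sort(as.vector(x)))
  expect_identical(checkerboard_upsample(r$output)$output, x)
  expect_error(checkerboard_downsample(array(0, c(1, 3, 4, 1))), "even")
})

test_that("haar downsampling is orthonormal with the explicit 4x4 matrix", {
  v <- 1.7
  r <- haar_downsample(array(v, c(1, 4, 4, 1)))
  expect_equal(r$output[1, , , 1], matrix(2 * v, 2, 2))
  expect_equal(max(abs(r$output[2:4, , , 1])), 0)
  x <- withr::with_seed(9, array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2)))
  rx <- haar_downsample(x)
  expect_equal(sqrt(sum(rx$output^2)), sqrt(sum(x^2)), tolerance = 1e-12)
  expect_equal(haar_upsample(rx$output)$output, x, tolerance = 1e-12)
  # blockwise oracle: output = H4 %*% flattened 2x2 blocks
  H4 <- cinnflow:::haar_block_matrix()
  expect_equal(H4 %*% H4, diag(4), tolerance = 1e-15)
  blk <- c(x[1, 1, 1, 1], x[1, 2, 1, 1], x[1, 1, 2, 1], x[1, 2, 2, 1])
  expect_equal(as.vector(rx$output[c(1, 4, 7, 10), 1, 1, 1]),
               as.vector(H4 %*% blk), tolerance = 1e-12)
})

test_that("split/merge partition channels exactly", {
  x <- withr::with_seed(10, array(rnorm(8 * 2 * 2 * 2), c(8, 2, 2, 2)))
  sp <- split_channels(x)
  expect_equal(dim(sp$kept)[1], 4)
  expect_equal(dim(sp$forwarded)[1], 4)
  expect_identical(merge_channels(sp$kept, sp$forwarded), x)
  expect_equal(length(sp$kept) + length(sp$forwarded), length(x))
  expect_error(split_channels(x, 8), "split size")
  expect_error(split_channels(array(0, c(1, 2, 2, 1))), "at least 2")
})

test_that("inverse(forward(x)) holds across layer types (property)", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2)))
    sp <- random_coupling(if (seed %% 2) "affine" else "additive", 2, 2,
                          seed = seed, sd = 0.5)
    r <- coupling_forward(x, NULL, sp)
    expect_lt(max(abs(coupling_inverse(r$output, NULL, sp) - x)), 1e-10)
    Q <- make_mixing_matrix(4, seed = seed)
    expect_lt(max(abs(cinnflow:::mix_inverse(mix_channels(x, Q)$output, Q) -
                        x)), 1e-12)
    expect_identical(checkerboard_upsample(
      checkerboard_downsample(x)$output)$output, x)
    expect_lt(max(abs(haar_upsample(haar_downsample(x)$output)$output - x)),
              1e-12)
  }
})
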