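test_that("uniform images have identically zero saliency", {
  for (v in c(0, 0.3, 1)) {
    img <- msl_image(array(v, c(16, 16, 3)), "unit")
    expect_equal(max(abs(unclass(ft_saliency(img)))), 0, tolerance = 1e-10)
  }
})

test_that("saliency equals the per-pixel brute-force evaluation", {
  set.seed(41)
  for (cs in c("Lab", "RGB")) {
    bs <- blur_spec(color_space = cs)
    img <- random_unit_image(64, 64)
    ref <- oracle_ft_saliency(unclass(img), bs$kernel1d, cs)
    expect_lt(max(abs(unclass(ft_saliency(img, bs)) - ref)), 1e-6)
  }
})

test_that("a two-color split image has the closed-form saliency ||a-b||/2", {
  a <- c(0.9, 0.1, 0.1); b <- c(0.1, 0.1, 0.9)
  px <- array(0, c(16, 16, 3))
  for (c in 1:3) {
    px[, 1:8, c] <- a[c]
    px[, 9:16, c] <- b[c]
  }
  bs <- blur_spec(kernel1d = NULL, color_space = "RGB")  # blur disabled
  s <- ft_saliency(msl_image(px, "unit"), bs)
  expect_equal(unclass(s)[4, 4], sqrt(sum((a - b)^2)) / 2, tolerance = 1e-12)
  expect_equal(unclass(s)[4, 12], sqrt(sum((a - b)^2)) / 2, tolerance = 1e-12)
})

test_that("saliency is invariant to a global color shift", {
  set.seed(7)
  px <- array(stats::runif(24 * 24 * 3, 0, 0.6), c(24, 24, 3))
  bs <- blur_spec(color_space = "RGB")   # shift invariance is exact in RGB
  s1 <- ft_saliency(msl_image(px, "unit"), bs)
  s2 <- ft_saliency(msl_image(px + 0.3, "unit"), bs)
  expect_lt(max(abs(unclass(s1) - unclass(s2))), 1e-10)
})

test_that("with blur disabled, permuting pixels permutes saliency identically", {
  set.seed(11)
  px <- array(stats::runif(12 * 12 * 3), c(12, 12, 3))
  bs <- blur_spec(kernel1d = NULL, color_space = "RGB")
  s <- unclass(ft_saliency(msl_image(px, "unit"), bs))
  perm <- sample(144)
  pxp <- px
  for (c in 1:3) pxp[, , c] <- matrix(as.vector(px[, , c])[perm], 12, 12)
  sp <- unclass(ft_saliency(msl_image(pxp, "unit"), bs))
  expect_equal(as.vector(sp), as.vector(s)[perm], tolerance = 1e-12)
})

test_that("normalization rescales by the max, preserves ratios and argmax", {
  m <- matrix(c(1, 2, 4, 0), 2, 2)
  n <- normalize_saliency(m)
  expect_equal(max(n), 1)
  expect_equal(unclass(n), m / 4)
  expect_equal(which.max(n), which.max(m))
  z <- normalize_saliency(matrix(0, 3, 3))
  expect_true(all(unclass(z) == 0))
})

test_that("binarization thresholds with ties going to 1", {
  m <- matrix(c(0.1, 0.7, 0.9), 1, 3)
  expect_equal(as.vector(binarize(m, 0.7)), c(0, 1, 1))
  expect_true(all(binarize(m, 0) == 1))
  expect_true(all(binarize(m, 0.95) == c(0, 0, 0)))
  expect_error(binarize(m, 1.2), "\\[0, 1\\]")
  expect_error(binarize(m, -0.1), "\\[0, 1\\]")
})

test_that("blur kernels must be normalized", {
  expect_error(blur_spec(kernel1d = c(1, 1, 1)), "sum to 1")
  expect_silent(blur_spec(kernel1d = c(0.25, 0.5, 0.25)))
})

test_that("Lab conversion gradient matches finite differences", {
  set.seed(3)
  px <- array(stats::runif(8 * 8 * 3, 0.1, 0.9), c(8, 8, 3))
  g_out <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
  ana <- msl:::rgb_to_lab_backward(px, g_out)
  eps <- 1e-6
  for (t in 1:5) {
    i <- sample(8, 1); j <- sample(8, 1); c <- sample(3, 1)
    pp <- px; pp[i, j, c] <- pp[i, j, c] + eps
    pm <- px; pm[i, j, c] <- pm[i, j, c] - eps
    fd <- (sum(msl:::rgb_to_lab(pp) * g_out) -
           sum(msl:::rgb_to_lab(pm) * g_out)) / (2 * eps)
    expect_equal(ana[i, j, c], fd, tolerance = 1e-4)
  }
})

test_that("saliency gradient matches finite differences away from borders", {
  set.seed(5)
  px <- array(stats::runif(12 * 12 * 3, 0.2, 0.8), c(12, 12, 3))
  bs <- blur_spec(color_space = "RGB")
  gs <- matrix(stats::rnorm(144), 12, 12)
  fwd <- msl:::ft_saliency_fwd(px, bs)
  ana <- msl:::ft_saliency_bwd(fwd, gs)
  eps <- 1e-6
  for (t in 1:5) {
    i <- sample(4:9, 1); j <- sample(4:9, 1); c <- sample(3, 1)
    pp <- px; pp[i, j, c] <- pp[i, j, c] + eps
    pm <- px; pm[i, j, c] <- pm[i, j, c] - eps
    fd <- (sum(msl:::ft_saliency_fwd(pp, bs)$s * gs) -
           sum(msl:::ft_saliency_fwd(pm, bs)$s * gs)) / (2 * eps)
    expect_equal(ana[i, j, c], fd, tolerance = 1e-4)
  }
})
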