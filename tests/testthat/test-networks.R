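test_that("bundle builders satisfy the shape contracts on both presets", {
  for (preset in c("tiny", "paper")) {
    size <- 32L
    b <- build_bundle(preset, seed = 4)
    x <- array(stats::runif(size * size * 3, -1, 1), c(size, size, 3))
    g <- msl:::gen_forward(b$G_S2T, x)$out
    expect_equal(dim(g), dim(x))
    expect_true(all(g >= -1 & g <= 1))
    a <- msl:::att_forward(b$A_S, x)$out
    expect_equal(dim(a), c(size, size))
    expect_true(all(a >= 0 & a <= 1))
    d <- msl:::disc_forward(b$D_T, x)$out
    expect_true(is.matrix(d))
    expect_true(all(dim(d) > 1))     # a patch grid, not a scalar score
  }
})

test_that("builders are seed-deterministic", {
  b1 <- build_bundle("tiny", seed = 9)
  b2 <- build_bundle("tiny", seed = 9)
  x <- array(stats::runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  expect_identical(msl:::gen_forward(b1$G_S2T, x)$out,
                   msl:::gen_forward(b2$G_S2T, x)$out)
  expect_identical(msl:::att_forward(b1$A_T, x)$out,
                   msl:::att_forward(b2$A_T, x)$out)
  s1 <- build_segmenter("tiny", seed = 5)
  s2 <- build_segmenter("tiny", seed = 5)
  expect_identical(segment_probs(s1, x), segment_probs(s2, x))
  expect_error(build_bundle("large"), "arg")
})

test_that("attention outputs stay in [0,1] over random inputs", {
  b <- build_bundle("tiny", seed = 2)
  set.seed(31)
  for (k in 1:5) {
    x <- array(stats::runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
    a <- msl:::att_forward(b$A_S, x)$out
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("attended composition obeys its limits bit-exactly", {
  set.seed(32)
  x <- array(stats::runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  g <- array(stats::runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  ones <- matrix(1, 16, 16); zeros <- matrix(0, 16, 16)
  expect_identical(attended_translate(x, ones, g), g)
  expect_identical(attended_translate(x, zeros, g), x)
  # a = 0.5, x = 0, g = 1 -> 0.5 everywhere
  half <- attended_translate(array(0, dim(x)), matrix(0.5, 16, 16),
                             array(1, dim(x)))
  expect_true(all(half == 0.5))
  # pixels with zero attention are untouched even when others change
  a <- matrix(stats::runif(256), 16, 16); a[3, 5] <- 0
  comp <- attended_translate(x, a, g)
  expect_identical(comp[3, 5, ], x[3, 5, ])
  # output stays within the convex hull of x and g
  expect_true(all(comp >= pmin(x, g) - 1e-12 & comp <= pmax(x, g) + 1e-12))
  expect_error(attended_translate(x, a[1:8, ], g), "shape")
})

test_that("segmenter emits per-pixel simplex probabilities and valid labels", {
  FS <- build_segmenter("tiny", seed = 3)
  img <- random_unit_image(16, 16)
  p <- segment_probs(FS, img)
  expect_equal(dim(p), c(16, 16, 4))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-8)
  lab <- segment(FS, img)
  expect_s3_class(lab, "msl_labelmap")
  expect_true(all(unclass(lab) %in% 0:3))
  expect_identical(unclass(segment(FS, img)), unclass(lab))  # eval determinism
})

test_that("argmax ties resolve to the lowest class id", {
  p <- array(0.25, c(8, 8, 4))
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], 4)
  lab <- max.col(pm, ties.method = "first") - 1L
  expect_true(all(lab == 0L))
})

test_that("network gradients agree with finite differences", {
  set.seed(33)
  b <- build_bundle("tiny", seed = 7)
  x <- array(stats::runif(12 * 12 * 3, -0.5, 0.5), c(12, 12, 3))
  # generator: scalar objective sum(out * R)
  R <- array(stats::rnorm(12 * 12 * 3), c(12, 12, 3))
  f <- msl:::gen_forward(b$G_S2T, x)
  msl:::zero_grads(b$G_S2T$net)
  dx <- msl:::gen_backward(b$G_S2T, f$cache, R)
  eps <- 1e-5
  for (t in 1:3) {
    i <- sample(12, 1); j <- sample(12, 1); c <- sample(3, 1)
    xp <- x; xp[i, j, c] <- xp[i, j, c] + eps
    xm <- x; xm[i, j, c] <- xm[i, j, c] - eps
    fd <- (sum(msl:::gen_forward(b$G_S2T, xp)$out * R) -
           sum(msl:::gen_forward(b$G_S2T, xm)$out * R)) / (2 * eps)
    expect_equal(dx[i, j, c], fd, tolerance = 1e-5)
  }
  # attention net input gradient
  Rm <- matrix(stats::rnorm(144), 12, 12)
  fa <- msl:::att_forward(b$A_S, x)
  msl:::zero_grads(b$A_S$net)
  dxa <- msl:::att_backward(b$A_S, fa$cache, Rm)
  for (t in 1:3) {
    i <- sample(12, 1); j <- sample(12, 1); c <- sample(3, 1)
    xp <- x; xp[i, j, c] <- xp[i, j, c] + eps
    xm <- x; xm[i, j, c] <- xm[i, j, c] - eps
    fd <- (sum(msl:::att_forward(b$A_S, xp)$out * Rm) -
           sum(msl:::att_forward(b$A_S, xm)$out * Rm)) / (2 * eps)
    expect_equal(dxa[i, j, c], fd, tolerance = 1e-5)
  }
  # conv weight gradient through the whole generator
  l <- msl:::net_layers(b$G_S2T$net)[[1]]
  f <- msl:::gen_forward(b$G_S2T, x)
  msl:::zero_grads(b$G_S2T$net)
  msl:::gen_backward(b$G_S2T, f$cache, R)
  ana <- l$gW[2, 2, 1, 3]
  l$W[2, 2, 1, 3] <- l$W[2, 2, 1, 3] + eps
  up <- sum(msl:::gen_forward(b$G_S2T, x)$out * R)
  l$W[2, 2, 1, 3] <- l$W[2, 2, 1, 3] - 2 * eps
  dn <- sum(msl:::gen_forward(b$G_S2T, x)$out * R)
  l$W[2, 2, 1, 3] <- l$W[2, 2, 1, 3] + eps
  expect_equal(ana, (up - dn) / (2 * eps), tolerance = 1e-4)
  # segmenter dice-loss gradient w.r.t. the input image
  FS <- build_segmenter("tiny", seed = 7)
  lab <- random_labelmap(12, 12)
  g <- labelmap_onehot(lab)
  fs <- msl:::seg_forward(FS, x)
  for (net in msl:::seg_nets(FS)) msl:::zero_grads(net)
  den <- sum(fs$probs + g)
  dxs <- msl:::seg_backward(FS, fs$cache, fs$probs, -g / den)
  for (t in 1:3) {
    i <- sample(12, 1); j <- sample(12, 1); c <- sample(3, 1)
    xp <- x; xp[i, j, c] <- xp[i, j, c] + eps
    xm <- x; xm[i, j, c] <- xm[i, j, c] - eps
    lp <- with(msl:::seg_forward(FS, xp), 1 - sum(probs * g) / sum(probs + g))
    lm <- with(msl:::seg_forward(FS, xm), 1 - sum(probs * g) / sum(probs + g))
    expect_equal(dxs[i, j, c], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("bundle and segmenter weights survive a save/load round trip", {
  dir <- withr::local_tempdir()
  b <- build_bundle("tiny", seed = 12)
  p <- file.path(dir, "b.rds")
  save_bundle(b, p)
  b2 <- load_bundle(p)
  x <- array(stats::runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  expect_identical(msl:::gen_forward(b$G_T2S, x)$out,
                   msl:::gen_forward(b2$G_T2S, x)$out)
  FS <- build_segmenter("tiny", seed = 12)
  ps <- file.path(dir, "fs.rds")
  save_segmenter(FS, ps)
  expect_identical(segment_probs(load_segmenter(ps), x), segment_probs(FS, x))
})
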