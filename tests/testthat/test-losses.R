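test_that("adversarial losses have the stated closed forms", {
  r1 <- matrix(1, 4, 4); r0 <- matrix(0, 4, 4); rh <- matrix(0.5, 4, 4)
  expect_equal(adversarial_loss_D(r1, r0, "least_squares"), 0)
  expect_equal(adversarial_loss_D(rh, rh, "least_squares"), 0.5)
  expect_equal(adversarial_loss_G(r1, "least_squares"), 0)
  expect_equal(adversarial_loss_G(r0, "least_squares"), 1)
  expect_equal(adversarial_loss_G(rh, "least_squares"), 0.25)
  # log variant: near-perfect scores give a loss ~ 2 eps
  eps <- 1e-4
  expect_equal(adversarial_loss_D(matrix(1 - eps, 4, 4), matrix(eps, 4, 4),
                                  "log"), 2 * eps, tolerance = 1e-3)
  expect_error(adversarial_loss_D(matrix(1.5, 2, 2), rh[1:2, 1:2], "log"),
               "inside")
})

test_that("cycle and attention losses are mean-L1 with metric structure", {
  set.seed(21)
  x <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(cycle_loss(x, x), 0)
  expect_equal(cycle_loss(x, pmin(x + 0.1, 1.1)), 0.1, tolerance = 1e-12)
  y <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(cycle_loss(x, y), oracle_mean_l1(x, y), tolerance = 1e-12)
  # symmetry and triangle inequality
  z <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(cycle_loss(x, y), cycle_loss(y, x))
  expect_lte(cycle_loss(x, z), cycle_loss(x, y) + cycle_loss(y, z) + 1e-12)
  expect_error(cycle_loss(x, y[1:4, , ]), "shape")
})

test_that("source attention consistency sums the two supervised terms", {
  set.seed(22)
  y <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
  expect_equal(attention_consistency_source(y, y, y), 0)
  a2 <- pmin(y + 0.2, 1)
  expect_equal(attention_consistency_source(y, a2, y), mean(abs(a2 - y)),
               tolerance = 1e-12)
  a <- matrix(stats::runif(64), 8, 8); b <- matrix(stats::runif(64), 8, 8)
  expect_equal(attention_consistency_source(a, b, y),
               oracle_mean_l1(a, y) + oracle_mean_l1(b, y), tolerance = 1e-12)
})

test_that("target attention consistency is plain mean-L1", {
  a <- matrix(stats::runif(64), 8, 8)
  expect_equal(attention_consistency_target(a, a), 0)
  expect_equal(attention_consistency_target(a, pmax(a - 0.5, a - 0.5)),
               0.5, tolerance = 1e-12)
  b <- matrix(stats::runif(64), 8, 8)
  expect_equal(attention_consistency_target(a, b), oracle_mean_l1(a, b),
               tolerance = 1e-12)
})

test_that("saliency dice matches the as-printed fixed points", {
  m <- matrix(0, 10, 10); m[2:5, 2:5] <- 1        # 16 ones
  expect_equal(saliency_dice_loss(m, m), 0.5)     # identical masks
  d <- matrix(0, 10, 10); d[7:9, 7:9] <- 1        # disjoint
  expect_equal(saliency_dice_loss(m, d), 1)
  # 100 ones in ref, the same 50 of them in tr -> 1 - 50/150
  ref <- matrix(0, 10, 10); ref[1:10, 1:10] <- 1
  tr <- matrix(0, 10, 10); tr[1:5, 1:10] <- 1
  expect_equal(saliency_dice_loss(ref, tr), 1 - 50 / 150)
  # both empty -> 0 by convention
  expect_equal(saliency_dice_loss(matrix(0, 4, 4), matrix(0, 4, 4)), 0)
  # conventional numerator restores 0 at perfect overlap
  expect_equal(saliency_dice_loss(m, m, conventional = TRUE), 0)
})

test_that("segmentation dice matches the as-printed fixed points", {
  lab <- random_labelmap(8, 8)
  g <- labelmap_onehot(lab)
  expect_equal(segmentation_dice_loss(g, lab), 0.5)       # perfect one-hot
  # completely wrong one-hot
  wrong <- msl_labelmap((unclass(lab) + 1L) %% 4L)
  expect_equal(segmentation_dice_loss(labelmap_onehot(wrong), lab), 1)
  # uniform prediction: sum p*g = N/4, sum(p+g) = 2N
  u <- array(0.25, c(8, 8, 4))
  expect_equal(segmentation_dice_loss(u, lab), 1 - 0.25 / 2)
  expect_equal(segmentation_dice_loss(g, lab, conventional = TRUE), 0)
  bad <- g; bad[1, 1, ] <- c(0.5, 0.5, 0.5, 0.5) * 1.5
  expect_error(segmentation_dice_loss(bad, lab), "simplex")
})

test_that("losses agree with brute-force loops on random inputs", {
  set.seed(100)
  for (case in 1:100) {
    a <- array(stats::runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
    b <- array(stats::runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
    expect_equal(cycle_loss(a, b), oracle_mean_l1(a, b), tolerance = 1e-6)
    m1 <- matrix(stats::runif(256), 16, 16)
    m2 <- matrix(stats::runif(256), 16, 16)
    y <- matrix(sample(0:1, 256, replace = TRUE), 16, 16)
    expect_equal(attention_consistency_source(m1, m2, y),
                 oracle_mean_l1(m1, y) + oracle_mean_l1(m2, y),
                 tolerance = 1e-6)
    expect_equal(attention_consistency_target(m1, m2),
                 oracle_mean_l1(m1, m2), tolerance = 1e-6)
    ref <- matrix(sample(0:1, 256, replace = TRUE), 16, 16)
    expect_equal(saliency_dice_loss(ref, m1), oracle_saliency_dice(ref, m1),
                 tolerance = 1e-6)
    p <- random_probs(16, 16)
    lab <- random_labelmap(16, 16)
    expect_equal(segmentation_dice_loss(p, lab),
                 oracle_seg_dice(p, labelmap_onehot(lab)), tolerance = 1e-6)
    # least-squares adversarial forms
    sc1 <- matrix(stats::runif(64), 8, 8); sc2 <- matrix(stats::runif(64), 8, 8)
    expect_equal(adversarial_loss_D(sc1, sc2, "least_squares"),
                 sum((sc1 - 1)^2) / 64 + sum(sc2^2) / 64, tolerance = 1e-6)
    expect_equal(adversarial_loss_G(sc2, "least_squares"),
                 sum((sc2 - 1)^2) / 64, tolerance = 1e-6)
  }
})

test_that("total loss is the lambda-weighted sum honoring ablations", {
  parts <- list(gan_S2T = 1, gan_T2S = 1, cyc = 1, att_S = 1, att_T = 1,
                sal_S = 1, sal_T = 1)
  w <- default_config()$loss_weights
  rep <- total_loss(parts, w)
  expect_equal(rep$total, 1 + 1 + 5 + 2 + 4 + 1 + 1)
  # ablated cycle contributes nothing regardless of its value
  parts$cyc <- 1e6
  rep2 <- total_loss(parts, w, ablation = list(use_att = TRUE, use_sal = TRUE,
                                               use_cyc = FALSE))
  expect_equal(rep2$total, 1 + 1 + 2 + 4 + 1 + 1)
  expect_false(rep2$active[["cyc"]])
  expect_equal(total_loss(list(), w)$total, 0)
  expect_error(total_loss(list(cyc = NaN), w), "cyc")
})

test_that("total loss is linear in each component with slope lambda", {
  w <- default_config()$loss_weights
  base <- list(gan_S2T = 0.3, gan_T2S = 0.7, cyc = 0.2, att_S = 0.4,
               att_T = 0.1, sal_S = 0.6, sal_T = 0.9)
  lam <- c(gan_S2T = 1, gan_T2S = 1, cyc = w$cyc, att_S = w$att_S,
           att_T = w$att_T, sal_S = w$sal_S, sal_T = w$sal_T)
  for (term in names(base)) {
    bumped <- base
    bumped[[term]] <- base[[term]] + 1
    expect_equal(total_loss(bumped, w)$total - total_loss(base, w)$total,
                 unname(lam[term]), tolerance = 1e-12)
  }
})
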