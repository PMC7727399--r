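test_that("augmentation flips image and label identically and involutively", {
  sc <- make_scene(random_scene_spec(64, "source", seed = 13))
  a1 <- augment(sc$image, sc$label, size = 64, flip = TRUE)
  a2 <- augment(a1$image, a1$label, size = 64, flip = TRUE)
  expect_equal(unclass(a2$image), unclass(sc$image), tolerance = 1e-12)
  expect_identical(unclass(a2$label), unclass(sc$label))
  # pixel-wise correspondence: a marked pixel moves with its label
  ij <- which(unclass(sc$label) == 2L, arr.ind = TRUE)[1, ]
  w <- ncol(unclass(sc$label))
  expect_equal(unclass(a1$label)[ij[1], w + 1L - ij[2]], 2L)
  expect_equal(a1$image[ij[1], w + 1L - ij[2], ],
               unclass(sc$image)[ij[1], ij[2], ])
})

test_that("resizing preserves the class-id set and pairs stay aligned", {
  sc <- make_scene(random_scene_spec(64, "target", seed = 14))
  a <- augment(sc$image, sc$label, size = 32, flip = FALSE)
  expect_equal(dim(unclass(a$image)), c(32, 32, 3))
  expect_equal(dim(unclass(a$label)), c(32, 32))
  expect_true(all(unclass(a$label) %in% 0:3))
  expect_error(augment(sc$image, msl_labelmap(matrix(0L, 16, 16))), "differ")
})

test_that("discriminator inputs follow the stage masking rules", {
  set.seed(15)
  x <- array(stats::runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  expect_identical(discriminator_input(1, x), x)
  ones <- matrix(1, 16, 16)
  expect_identical(discriminator_input(2, x, saliency_bin = ones), x)
  rect <- matrix(0, 16, 16); rect[5:10, 5:10] <- 1
  m3 <- discriminator_input(3, x, attention_bin = rect)
  expect_identical(m3[5:10, 5:10, ], x[5:10, 5:10, ])
  expect_true(all(m3[1:4, , ] == 0))
  expect_error(discriminator_input(2, x), "saliency_bin")
  expect_error(discriminator_input(3, x), "attention_bin")
})

test_that("translation training logs every term and honors ablations", {
  cfg <- tiny_config(seed = 2)
  cfg$schedule <- utils::modifyList(cfg$schedule,
    list(stage1_epochs = 1L, stage2_epochs = 1L, stage3_epochs = 1L,
         decay_epochs = 1L))
  dp <- make_domain_pair(3, size = 64, seed = 2)
  fit <- train_translation(dp$source, dp$target, cfg)
  expect_s3_class(fit, "msl_translation_fit")
  expect_equal(nrow(fit$log), 3)
  expect_equal(fit$log$stage, c(1, 2, 3))
  terms <- c("gan_S2T", "gan_T2S", "cyc", "att_S", "att_T", "sal_S", "sal_T")
  expect_true(all(terms %in% names(fit$log)))
  expect_true(all(is.finite(as.matrix(fit$log[terms]))))
  # saliency terms inactive before stage 3
  expect_equal(fit$log$sal_S[1:2], c(0, 0))
  expect_gt(fit$log$sal_S[3], 0)
  # ablation: attention terms logged as zero and flagged
  cfg$ablation$use_att <- FALSE
  fit2 <- train_translation(dp$source, dp$target, cfg)
  expect_true(all(fit2$log$att_S == 0))
  expect_true(all(fit2$log$att_T == 0))
  expect_setequal(attr(fit2$log, "ablated"), c("att_S", "att_T"))
  expect_error(train_translation(list(), dp$target, cfg), "empty")
})

test_that("fixed seeds reproduce identical first-epoch losses", {
  cfg <- tiny_config(seed = 5)
  cfg$schedule <- utils::modifyList(cfg$schedule,
    list(stage1_epochs = 1L, stage2_epochs = 0L, stage3_epochs = 0L,
         decay_epochs = 1L))
  dp <- make_domain_pair(3, size = 64, seed = 5)
  f1 <- train_translation(dp$source, dp$target, cfg)
  f2 <- train_translation(dp$source, dp$target, cfg)
  expect_identical(f1$log, f2$log)
})

test_that("segmenter training improves on its untrained initialization", {
  cfg <- tiny_config(seed = 3)
  cfg$segmenter$epochs <- 12L
  cfg$segmenter$warmup_epochs <- 8L
  dp <- make_domain_pair(8, size = 64, seed = 3)
  fit <- train_segmenter(dp$source, cfg)
  expect_s3_class(fit, "msl_segmenter_fit")
  expect_equal(nrow(fit$log), 12)
  # held-out split is 80/20
  expect_length(fit$test_idx, 2L)
  untrained <- build_segmenter("tiny", seed = 99)
  gt <- lapply(fit$test_idx, function(i) dp$source[[i]]$label)
  pred_tr <- lapply(fit$test_idx, function(i)
    segment(fit$segmenter, dp$source[[i]]$image))
  pred_un <- lapply(fit$test_idx, function(i)
    segment(untrained, dp$source[[i]]$image))
  miou_tr <- evaluate_segmentation(gt, pred_tr)$mean_iou
  miou_un <- evaluate_segmentation(gt, pred_un)$mean_iou
  expect_gt(miou_tr, miou_un)
  expect_gt(fit$test_metrics$pixel_accuracy, 0.8)
})
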