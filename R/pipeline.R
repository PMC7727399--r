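# ---- end-to-end orchestration ----------------------------------------------

#' Translate target images to source appearance and segment them
#'
#' For each target image: compute the target attention map, generate the
#' source-like image, blend via the attention-guided composition (so
#' unattended disc/cord pixels pass through untouched), then segment with
#' the source-trained model. Images whose size differs from `size` are
#' resized in and the predictions resized back (nearest neighbour), so
#' evaluation stays at native resolution.
#'
#' @param target_images List of [msl_image]s (or a single image).
#' @param bundle Trained `msl_bundle` (uses `A_T` and `G_T2S`).
#' @param FS Trained `msl_segmenter`.
#' @param size Working resolution (the training resolution); default 64 for
#'   the tiny preset, 512 for the paper preset.
#' @param translate If `FALSE`, skip translation (the no-adaptation
#'   baseline).
#' @return List of [msl_labelmap]s in input order.
#' @export
adapt_and_segment <- function(target_images, bundle, FS, size = NULL,
                              translate = TRUE) {
  if (inherits(target_images, "msl_image"))
    target_images <- list(target_images)
  if (is.null(size))
    size <- if (bundle$preset == "tiny") 64L else 512L
  lapply(target_images, function(img) {
    native <- dim(unclass(convert_range(img, "unit")))[1:2]
    work <- augment(img, size = size, flip = FALSE)$image
    x <- unclass(convert_range(work, "signed"))
    if (translate) {
      a_t <- att_forward(bundle$A_T, x)$out
      g <- gen_forward(bundle$G_T2S, x)$out
      x <- attended_translate(x, a_t, g)
    }
    lab <- segment(FS, x)
    if (!identical(dim(unclass(lab)), native))
      lab <- msl_labelmap(resize_nearest(unclass(lab), native[1]))
    lab
  })
}

#' Run the synthetic-domain adaptation experiment for one seed
#'
#' Generates a two-domain synthetic dataset, trains the segmenter on the
#' source domain, trains the translation model, then evaluates target-
#' domain segmentation with and without adaptation.
#'
#' @param config An `msl_config`; `config$seed` drives data, init and
#'   sampling.
#' @param n Scenes per domain.
#' @param verbose Print training progress.
#' @return List: `adapted` and `baseline` `msl_eval` objects, `seg_fit`,
#'   `trans_fit`, `data`.
#' @export
run_adaptation_experiment <- function(config, n = 8L, verbose = FALSE) {
  cfg <- config
  data <- make_domain_pair(n, size = cfg$image_size, seed = cfg$seed)
  seg_fit <- train_segmenter(data$source, cfg, verbose = verbose)
  trans_fit <- train_translation(data$source, data$target, cfg,
                                 verbose = verbose)
  tgt_imgs <- lapply(data$target, `[[`, "image")
  gt <- data$target_labels_eval
  pred_ad <- adapt_and_segment(tgt_imgs, trans_fit$bundle, seg_fit$segmenter,
                               size = cfg$image_size)
  pred_base <- adapt_and_segment(tgt_imgs, trans_fit$bundle,
                                 seg_fit$segmenter, size = cfg$image_size,
                                 translate = FALSE)
  list(adapted = evaluate_segmentation(gt, pred_ad),
       baseline = evaluate_segmentation(gt, pred_base),
       seg_fit = seg_fit, trans_fit = trans_fit, data = data)
}

#' Ablation study over loss-term variants
#'
#' Trains one model per requested variant on shared data and seeds and
#' reports the three evaluation metrics per variant on the held-out
#' synthetic target set.
#'
#' @param config Base `msl_config`.
#' @param variants Subset of `"full"`, `"no_att"`, `"no_sal"`, `"no_cyc"`,
#'   `"no_adaptation"`.
#' @param n Scenes per domain.
#' @param verbose Print training progress.
#' @return Data frame with one row per variant (`pixel_accuracy`,
#'   `mean_class_accuracy`, `mean_iou`), with the per-variant fits in
#'   attribute `"fits"`.
#' @export
run_ablation <- function(config,
                         variants = c("full", "no_att", "no_sal", "no_cyc",
                                      "no_adaptation"),
                         n = 8L, verbose = FALSE) {
  known <- c("full", "no_att", "no_sal", "no_cyc", "no_adaptation")
  bad <- setdiff(variants, known)
  if (length(bad) > 0)
    stop("unknown variant(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- config
  data <- make_domain_pair(n, size = cfg$image_size, seed = cfg$seed)
  seg_fit <- train_segmenter(data$source, cfg)
  tgt_imgs <- lapply(data$target, `[[`, "image")
  gt <- data$target_labels_eval
  fits <- list()
  rows <- lapply(variants, function(v) {
    if (v == "no_adaptation") {
      pred <- lapply(tgt_imgs, function(im) {
        au <- augment(im, size = cfg$image_size, flip = FALSE)
        segment(seg_fit$segmenter, au$image)
      })
    } else {
      vcfg <- cfg
      vcfg$ablation <- list(
        use_att = v != "no_att",
        use_sal = v != "no_sal",
        use_cyc = v != "no_cyc")
      fit <- train_translation(data$source, data$target, vcfg,
                               verbose = verbose)
      fits[[v]] <<- fit
      pred <- adapt_and_segment(tgt_imgs, fit$bundle, seg_fit$segmenter,
                                size = cfg$image_size)
    }
    ev <- evaluate_segmentation(gt, pred)
    data.frame(variant = v, pixel_accuracy = ev$pixel_accuracy,
               mean_class_accuracy = ev$mean_class_accuracy,
               mean_iou = ev$mean_iou)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "seg_fit") <- seg_fit
  out
}
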