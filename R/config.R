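# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' All tunables of the translation-and-segmentation pipeline with their
#' standard values: loss weights lambda_cyc = 5, lambda_att_S = 2,
#' lambda_att_T = 4, lambda_sal_S = lambda_sal_T = 1; discriminator-masking
#' thresholds 0.7 (binarized saliency, stage 2) and 0.2 (binarized attention,
#' stage 3); 512 x 512 working resolution; three-stage schedule of 20 + 5 +
#' 75 epochs with Adam, batch size 1 and a learning rate of 2e-4 decaying
#' linearly to zero over the final `decay_epochs`; segmenter Adam with batch
#' size 5 and learning rate 1e-3.
#'
#' @return A named list of class `msl_config`.
#' @export
default_config <- function() {
  structure(list(
    loss_weights = list(cyc = 5, att_S = 2, att_T = 4, sal_S = 1, sal_T = 1),
    thresholds = list(saliency = 0.7, attention = 0.2, gt_saliency = 0.7),
    schedule = list(stage1_epochs = 20L, stage2_epochs = 5L,
                    stage3_epochs = 75L, lr0 = 2e-4, decay_epochs = 50L,
                    batch_size = 1L),
    segmenter = list(batch_size = 5L, lr = 1e-3, epochs = 30L,
                     warmup_epochs = 10L, train_frac = 0.8),
    image_size = 512L,
    seed = 1L,
    preset = "paper",
    ablation = list(use_att = TRUE, use_sal = TRUE, use_cyc = TRUE),
    adversarial_variant = "least_squares",
    saliency_color_space = "Lab",
    conventional_dice = FALSE,
    use_image_buffer = TRUE,
    d_lr_mult = 1
  ), class = "msl_config")
}

#' Load a run configuration from YAML (or take defaults)
#'
#' Reads a YAML file whose keys override [default_config()]; nested keys are
#' merged field-wise, so a file may set only e.g. `ablation: {use_sal: no}`
#' to run the saliency-ablated model. A missing `path` (or `NULL`) returns
#' the defaults unchanged.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional named list applied on top of the file, same
#'   merge semantics (useful programmatically).
#' @return Validated `msl_config` list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
}

merge_config <- function(base, upd) {
  if (is.null(upd)) return(base)
  for (k in names(upd)) {
    if (is.list(upd[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], upd[[k]])
    else base[[k]] <- upd[[k]]
  }
  base
}

validate_config <- function(cfg) {
  lw <- cfg$loss_weights
  if (any(unlist(lw) < 0))
    stop("loss weights must be nonnegative", call. = FALSE)
  th <- unlist(cfg$thresholds)
  if (any(th < 0 | th > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  sc <- cfg$schedule
  for (f in c("stage1_epochs", "stage2_epochs", "stage3_epochs")) {
    if (sc[[f]] < 0 || sc[[f]] != round(sc[[f]]))
      stop(f, " must be a nonnegative integer", call. = FALSE)
    cfg$schedule[[f]] <- as.integer(sc[[f]])
  }
  if (sc$lr0 <= 0 || cfg$segmenter$lr <= 0)
    stop("learning rates must be positive", call. = FALSE)
  if (!cfg$adversarial_variant %in% c("least_squares", "log"))
    stop("adversarial_variant must be 'least_squares' or 'log'", call. = FALSE)
  if (!cfg$preset %in% c("paper", "tiny"))
    stop("preset must be 'paper' or 'tiny'", call. = FALSE)
  if (!cfg$saliency_color_space %in% c("Lab", "RGB"))
    stop("saliency_color_space must be 'Lab' or 'RGB'", call. = FALSE)
  cfg$image_size <- as.integer(cfg$image_size)
  structure(cfg, class = "msl_config")
}

total_epochs <- function(cfg) {
  with(cfg$schedule, stage1_epochs + stage2_epochs + stage3_epochs)
}

#' Training stage at a given epoch
#'
#' Maps a 0-based epoch index to the curriculum stage: 1 (discriminators see
#' full images), 2 (discriminators see saliency-masked images) or 3
#' (discriminators see attention-masked generated images; saliency loss
#' active).
#'
#' @param epoch 0-based epoch index.
#' @param cfg An `msl_config`.
#' @return Integer 1, 2 or 3.
#' @export
stage_at <- function(epoch, cfg) {
  sc <- cfg$schedule
  if (epoch < 0 || epoch >= total_epochs(cfg))
    stop("epoch out of schedule range", call. = FALSE)
  if (epoch < sc$stage1_epochs) 1L
  else if (epoch < sc$stage1_epochs + sc$stage2_epochs) 2L
  else 3L
}

#' Learning rate at a given epoch
#'
#' Constant at `lr0` until the decay window starts, then linearly decaying
#' to exactly 0 at (one past) the final epoch.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total`.
#' @param schedule The `schedule` component of an `msl_config` (or a list
#'   with `lr0`, `decay_epochs` and the three stage lengths).
#' @return The learning rate.
#' @export
lr_at <- function(epoch, schedule) {
  tot <- schedule$stage1_epochs + schedule$stage2_epochs +
    schedule$stage3_epochs
  if (epoch < 0 || epoch >= tot)
    stop("epoch out of schedule range", call. = FALSE)
  decay_start <- tot - schedule$decay_epochs
  if (epoch < decay_start) return(schedule$lr0)
  # linear from lr0 at decay_start to exactly 0 at the final epoch
  if (tot - 1L == decay_start) return(if (epoch == decay_start) schedule$lr0 else 0)
  schedule$lr0 * (tot - 1 - epoch) / (tot - 1 - decay_start)
}

#' Desk-scale configuration for the synthetic two-domain experiment
#'
#' The configuration used by the scaled-down end-to-end study: tiny network
#' preset at 64 x 64, stage schedule 2 + 1 + 5 epochs with linear decay over
#' the final 4, and learning rates raised by 10x relative to the full-scale
#' defaults (2e-3 translation, 5e-3 segmenter) as appropriate for the far
#' shorter schedule, with a two-timescale discriminator rate (2x the
#' generator rate) for cleaner adversarial gradients over so few
#' iterations. Loss weights, thresholds and all other settings keep their
#' standard values.
#'
#' @param seed Integer seed stored in the config.
#' @return An `msl_config`.
#' @export
tiny_config <- function(seed = 1L) {
  load_config(overrides = list(
    preset = "tiny", image_size = 64L, seed = as.integer(seed),
    schedule = list(stage1_epochs = 2L, stage2_epochs = 1L,
                    stage3_epochs = 5L, lr0 = 2e-3, decay_epochs = 4L),
    segmenter = list(lr = 5e-3, epochs = 30L),
    d_lr_mult = 2))
}
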