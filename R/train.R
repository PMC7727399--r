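# ---- three-stage adversarial training --------------------------------------
#
# Curriculum: (1) discriminators see full images while the attention nets
# are pulled toward the label-derived attended mask; (2) discriminators see
# saliency-masked images (binarized at 0.7) so they concentrate on the most
# salient attended object, the ruler; (3) discriminators see attention-
# masked images (binarized at 0.2) and the saliency-consistency loss joins
# the objective. Generators/attention nets and discriminators alternate
# 1:1 per iteration (Adam, batch size 1).

#' Resize-and-flip data augmentation
#'
#' Resizes the image (bilinear) and, if given, its label map (nearest
#' neighbour, which preserves the class-id set) to `size` x `size`, then
#' flips both horizontally with probability 1/2. The flip decision can be
#' forced for reproducibility.
#'
#' @param image An [msl_image].
#' @param label Optional paired [msl_labelmap] (same H x W).
#' @param size Target side length.
#' @param flip `NULL` (draw from the RNG) or logical.
#' @return List `image`, `label` (label `NULL` if not supplied), `flipped`.
#' @export
augment <- function(image, label = NULL, size = NULL, flip = NULL) {
  px <- unclass(convert_range(image, "unit"))
  if (!is.null(label) && !identical(dim(unclass(label)), dim(px)[1:2]))
    stop("image and label map shapes differ", call. = FALSE)
  if (!is.null(size) && !identical(dim(px)[1:2], c(size, size))) {
    px <- resize_image(px, size, bilinear = TRUE)
    if (!is.null(label))
      label <- msl_labelmap(resize_nearest(unclass(label), size))
  }
  if (is.null(flip)) flip <- stats::runif(1) < 0.5
  if (flip) {
    px <- px[, rev(seq_len(ncol(px))), , drop = FALSE]
    if (!is.null(label))
      label <- msl_labelmap(unclass(label)[, rev(seq_len(ncol(label)))])
  }
  list(image = msl_image(clamp01(px), "unit", attr(image, "domain")),
       label = label, flipped = flip)
}

resize_image <- function(px, size, bilinear = TRUE) {
  out <- array(0, c(size, size, dim(px)[3]))
  filt <- if (bilinear) "bilinear" else "none"
  for (c in seq_len(dim(px)[3]))
    out[, , c] <- EBImage::imageData(
      EBImage::resize(EBImage::Image(px[, , c]), w = size, h = size,
                      filter = filt))
  out
}

resize_nearest <- function(m, size) {
  storage.mode(m) <- "double"
  r <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = size,
                                          h = size, filter = "none"))
  matrix(as.integer(round(r)), size, size)
}

#' Discriminator input for a training stage
#'
#' Stage 1: the full image. Stage 2: image masked by the binarized saliency
#' map. Stage 3: image masked by the binarized attention map.
#'
#' @param stage 1, 2 or 3.
#' @param image H x W x 3 array (or [msl_image]).
#' @param saliency_bin Binary H x W mask (required for stage 2).
#' @param attention_bin Binary H x W mask (required for stage 3).
#' @return Masked array of the image's shape.
#' @export
discriminator_input <- function(stage, image, saliency_bin = NULL,
                                attention_bin = NULL) {
  px <- if (inherits(image, "msl_image")) unclass(image) else image
  m <- switch(as.character(stage),
    "1" = return(px),
    "2" = saliency_bin %||% stop("stage 2 requires saliency_bin", call. = FALSE),
    "3" = attention_bin %||% stop("stage 3 requires attention_bin", call. = FALSE),
    stop("stage must be 1, 2 or 3", call. = FALSE))
  out <- px
  for (c in 1:3) out[, , c] <- px[, , c] * m
  out
}

# binarized, max-normalized FT saliency of a [0,1] array
sal_mask <- function(px_unit, thresh, blur) {
  binarize(normalize_saliency(ft_saliency(px_unit, blur)), thresh)
}

adv_g_grad <- function(scores, variant, n) {
  if (variant == "least_squares") 2 * (scores - 1) / n
  else (1 / (1 + exp(-scores)) - 1) / n   # -log sigmoid(score), logits in
}
adv_d_grads <- function(real, fake, variant, n) {
  if (variant == "least_squares")
    list(real = 2 * (real - 1) / n, fake = 2 * fake / n)
  else list(real = (1 / (1 + exp(-real)) - 1) / n,
            fake = (1 / (1 + exp(-fake))) / n)
}
adv_g_val <- function(scores, variant) {
  if (variant == "least_squares") mean((scores - 1)^2)
  else mean(log1p(exp(-scores)))
}
adv_d_val <- function(real, fake, variant) {
  if (variant == "least_squares") mean((real - 1)^2) + mean(fake^2)
  else mean(log1p(exp(-real))) + mean(log1p(exp(fake)))
}

# dice-on-saliency forward+gradient w.r.t. the translated signed image.
# ref_bin and att_bin are detached masks; returns loss value and gradient.
sal_loss_and_grad <- function(x_signed, ref_bin, att_bin, blur) {
  px_unit <- (x_signed + 1) / 2
  fwd <- ft_saliency_fwd(px_unit, blur)
  mx <- max(fwd$s)
  s_n <- if (mx > 0) fwd$s / mx else fwd$s
  tr <- s_n * att_bin
  ref <- ref_bin * att_bin
  num <- sum(ref * tr); den <- sum(ref) + sum(tr)
  if (den == 0) return(list(value = 0, grad = array(0, dim(x_signed))))
  value <- 1 - num / den
  dtr <- -(ref * den - num) / den^2
  ds <- (dtr * att_bin) / max(mx, 1e-12)
  grad_unit <- ft_saliency_bwd(fwd, ds)
  list(value = value, grad = grad_unit * 0.5)
}

msign <- function(x) sign(x)

#' Train the translation model (attention nets, generators, discriminators)
#'
#' Runs the three-stage curriculum, alternating one minimization step for
#' the generators and attention networks with one maximization step for the
#' discriminators per image pair (Adam, batch size 1, linearly decaying
#' learning rate). The saliency-consistency loss enters at stage 3.
#'
#' @param source_set List of `list(image, label)` (labeled source domain).
#' @param target_set List of `list(image)` (unlabeled target domain).
#' @param config An `msl_config` (see [load_config()]); `config$preset`,
#'   `config$image_size`, schedule, weights and ablation flags are honored.
#' @param bundle Optional pre-built `msl_bundle` to continue training.
#' @param checkpoint_dir Optional directory; weights are saved at each
#'   stage boundary and at the end.
#' @param verbose Print one structured log line per epoch.
#' @return List of class `msl_translation_fit`: `bundle`, `log` (one row
#'   per epoch with every objective term; ablated terms logged as zero and
#'   flagged), `config`.
#' @export
train_translation <- function(source_set, target_set, config = default_config(),
                              bundle = NULL, checkpoint_dir = NULL,
                              verbose = FALSE) {
  if (length(source_set) == 0 || length(target_set) == 0)
    stop("empty dataset", call. = FALSE)
  cfg <- config
  set.seed(cfg$seed)
  if (is.null(bundle)) bundle <- build_bundle(cfg$preset, seed = cfg$seed)
  blur <- blur_spec(color_space = cfg$saliency_color_space)
  variant <- cfg$adversarial_variant
  w <- cfg$loss_weights
  abl <- cfg$ablation
  use_att <- isTRUE(abl$use_att); use_sal <- isTRUE(abl$use_sal)
  use_cyc <- isTRUE(abl$use_cyc)
  opt_G <- adam_state(list(bundle$A_S$net, bundle$A_T$net,
                           bundle$G_S2T$net, bundle$G_T2S$net))
  opt_D <- adam_state(list(bundle$D_S$net, bundle$D_T$net))
  all_nets <- c(opt_G$nets, opt_D$nets)
  pool_S <- list(); pool_T <- list()   # image-history buffers for D updates
  pool_take <- function(pool, img) {
    if (!isTRUE(cfg$use_image_buffer)) return(list(pool = pool, img = img))
    if (length(pool) < 20L) return(list(pool = c(pool, list(img)), img = img))
    if (stats::runif(1) < 0.5) {
      k <- sample.int(length(pool), 1L)
      out <- pool[[k]]; pool[[k]] <- img
      list(pool = pool, img = out)
    } else list(pool = pool, img = img)
  }
  tot <- total_epochs(cfg)
  log_rows <- vector("list", tot)
  term_names <- c("gan_S2T", "gan_T2S", "cyc", "att_S", "att_T",
                  "sal_S", "sal_T")
  for (epoch in seq_len(tot) - 1L) {
    stage <- stage_at(epoch, cfg)
    lr <- lr_at(epoch, cfg$schedule)
    n_iter <- max(length(source_set), length(target_set))
    ord_s <- sample(rep_len(seq_along(source_set), n_iter))
    ord_t <- sample(rep_len(seq_along(target_set), n_iter))
    acc <- stats::setNames(numeric(length(term_names)), term_names)
    acc_d <- 0
    for (it in seq_len(n_iter)) {
      src <- source_set[[ord_s[it]]]
      tgt <- target_set[[ord_t[it]]]
      as_ <- augment(src$image, src$label, size = cfg$image_size)
      at_ <- augment(tgt$image, size = cfg$image_size)
      xs <- unclass(convert_range(as_$image, "signed"))
      xt <- unclass(convert_range(at_$image, "signed"))
      ys_bin <- attended_mask(as_$label)
      xs_unit <- unclass(as_$image); xt_unit <- unclass(at_$image)
      nd <- NULL; npix <- prod(dim(xs)[1:2]); nch <- npix * 3
      # ---------- generator / attention update ----------
      for (net in all_nets) zero_grads(net)
      fa_s <- att_forward(bundle$A_S, xs); a_s <- fa_s$out
      fg_s <- gen_forward(bundle$G_S2T, xs)
      xs2t <- attended_translate(xs, a_s, fg_s$out)
      fa_t <- att_forward(bundle$A_T, xt); a_t <- fa_t$out
      fg_t <- gen_forward(bundle$G_T2S, xt)
      xt2s <- attended_translate(xt, a_t, fg_t$out)
      # stage-dependent discriminator masks (all detached)
      if (stage == 2L) {
        m_fake_T <- sal_mask(xs_unit, cfg$thresholds$saliency, blur)
        m_fake_S <- sal_mask(xt_unit, cfg$thresholds$saliency, blur)
        m_real_T <- m_fake_S; m_real_S <- m_fake_T
      } else if (stage == 3L) {
        m_fake_T <- binarize(a_s, cfg$thresholds$attention)
        m_fake_S <- binarize(a_t, cfg$thresholds$attention)
        m_real_T <- binarize(a_t, cfg$thresholds$attention)
        m_real_S <- binarize(a_s, cfg$thresholds$attention)
      } else m_fake_T <- m_fake_S <- m_real_T <- m_real_S <- NULL
      din_fake_T <- discriminator_input(stage, xs2t, m_fake_T, m_fake_T)
      din_fake_S <- discriminator_input(stage, xt2s, m_fake_S, m_fake_S)
      fd_T <- disc_forward(bundle$D_T, din_fake_T)
      fd_S <- disc_forward(bundle$D_S, din_fake_S)
      nd <- length(fd_T$out)
      gan_S2T <- adv_g_val(fd_T$out, variant)
      gan_T2S <- adv_g_val(fd_S$out, variant)
      dxs2t <- disc_backward(bundle$D_T, fd_T$cache,
                             adv_g_grad(fd_T$out, variant, nd))
      dxt2s <- disc_backward(bundle$D_S, fd_S$cache,
                             adv_g_grad(fd_S$out, variant, nd))
      if (stage > 1L) {
        for (c in 1:3) {
          dxs2t[, , c] <- dxs2t[, , c] * m_fake_T
          dxt2s[, , c] <- dxt2s[, , c] * m_fake_S
        }
      }
      # cycle
      cyc_val <- 0
      if (use_cyc) {
        fc_s <- gen_forward(bundle$G_T2S, xs2t)
        fc_t <- gen_forward(bundle$G_S2T, xt2s)
        cyc_val <- mean(abs(fc_s$out - xs)) + mean(abs(fc_t$out - xt))
        dxs2t <- dxs2t + gen_backward(bundle$G_T2S, fc_s$cache,
                                      w$cyc * msign(fc_s$out - xs) / nch)
        dxt2s <- dxt2s + gen_backward(bundle$G_S2T, fc_t$cache,
                                      w$cyc * msign(fc_t$out - xt) / nch)
      }
      # attention consistency
      att_S_val <- att_T_val <- 0
      da_s <- matrix(0, nrow(a_s), ncol(a_s))
      da_t <- matrix(0, nrow(a_t), ncol(a_t))
      if (use_att) {
        fa_ts <- att_forward(bundle$A_T, xs2t)
        fa_st <- att_forward(bundle$A_S, xt2s)
        att_S_val <- mean(abs(a_s - ys_bin)) + mean(abs(fa_ts$out - ys_bin))
        att_T_val <- mean(abs(a_t - fa_st$out))
        da_s <- da_s + w$att_S * msign(a_s - ys_bin) / npix
        dxs2t <- dxs2t + att_backward(bundle$A_T, fa_ts$cache,
                                      w$att_S * msign(fa_ts$out - ys_bin) / npix)
        da_t <- da_t + w$att_T * msign(a_t - fa_st$out) / npix
        dxt2s <- dxt2s + att_backward(bundle$A_S, fa_st$cache,
                                      -w$att_T * msign(a_t - fa_st$out) / npix)
      }
      # saliency consistency (stage 3 only)
      sal_S_val <- sal_T_val <- 0
      if (use_sal && stage == 3L) {
        att_bin_s <- binarize(a_s, cfg$thresholds$attention)
        att_bin_t <- binarize(a_t, cfg$thresholds$attention)
        ref_s <- sal_mask(xs_unit, cfg$thresholds$gt_saliency, blur)
        ref_t <- sal_mask(xt_unit, cfg$thresholds$gt_saliency, blur)
        sl_s <- sal_loss_and_grad(xs2t, ref_s, att_bin_s, blur)
        sl_t <- sal_loss_and_grad(xt2s, ref_t, att_bin_t, blur)
        sal_S_val <- sl_s$value; sal_T_val <- sl_t$value
        dxs2t <- dxs2t + w$sal_S * sl_s$grad
        dxt2s <- dxt2s + w$sal_T * sl_t$grad
      }
      # through the attended composition into A and G
      bs <- attended_translate_bwd(dxs2t, a_s, fg_s$out, xs)
      bt <- attended_translate_bwd(dxt2s, a_t, fg_t$out, xt)
      att_backward(bundle$A_S, fa_s$cache, da_s + bs$da)
      att_backward(bundle$A_T, fa_t$cache, da_t + bt$da)
      gen_backward(bundle$G_S2T, fg_s$cache, bs$dg)
      gen_backward(bundle$G_T2S, fg_t$cache, bt$dg)
      adam_step(opt_G, lr)
      # ---------- discriminator update ----------
      for (net in all_nets) zero_grads(net)
      pb <- pool_take(pool_T, xs2t); pool_T <- pb$pool; fake_T <- pb$img
      pb <- pool_take(pool_S, xt2s); pool_S <- pb$pool; fake_S <- pb$img
      dreal_T <- discriminator_input(stage, xt, m_real_T, m_real_T)
      dreal_S <- discriminator_input(stage, xs, m_real_S, m_real_S)
      dfake_T <- discriminator_input(stage, fake_T, m_fake_T, m_fake_T)
      dfake_S <- discriminator_input(stage, fake_S, m_fake_S, m_fake_S)
      fr_T <- disc_forward(bundle$D_T, dreal_T)
      ff_T <- disc_forward(bundle$D_T, dfake_T)
      fr_S <- disc_forward(bundle$D_S, dreal_S)
      ff_S <- disc_forward(bundle$D_S, dfake_S)
      gT <- adv_d_grads(fr_T$out, ff_T$out, variant, nd)
      gS <- adv_d_grads(fr_S$out, ff_S$out, variant, nd)
      disc_backward(bundle$D_T, fr_T$cache, gT$real)
      disc_backward(bundle$D_T, ff_T$cache, gT$fake)
      disc_backward(bundle$D_S, fr_S$cache, gS$real)
      disc_backward(bundle$D_S, ff_S$cache, gS$fake)
      adam_step(opt_D, lr * cfg$d_lr_mult)
      acc_d <- acc_d + adv_d_val(fr_T$out, ff_T$out, variant) +
        adv_d_val(fr_S$out, ff_S$out, variant)
      vals <- c(gan_S2T = gan_S2T, gan_T2S = gan_T2S, cyc = cyc_val,
                att_S = att_S_val, att_T = att_T_val,
                sal_S = sal_S_val, sal_T = sal_T_val)
      if (any(!is.finite(vals)))
        stop("non-finite loss term: ",
             paste(names(vals)[!is.finite(vals)], collapse = ", "),
             call. = FALSE)
      acc <- acc + vals
    }
    avg <- acc / n_iter
    rep <- total_loss(as.list(avg), weights = w, ablation = abl)
    row <- data.frame(epoch = epoch, stage = stage, lr = lr,
                      t(avg), total = rep$total, d_loss = acc_d / n_iter)
    log_rows[[epoch + 1L]] <- row
    if (verbose)
      message(sprintf(
        "epoch=%d stage=%d lr=%.2e %s total=%.4f d=%.4f", epoch, stage, lr,
        paste(sprintf("%s=%.4f%s", term_names, avg,
                      ifelse(rep$active[term_names], "", "[ablated]")),
              collapse = " "),
        rep$total, acc_d / n_iter))
    if (!is.null(checkpoint_dir) &&
        (epoch == tot - 1L || stage != stage_at(min(epoch + 1L, tot - 1L), cfg)))
      save_bundle(bundle, file.path(checkpoint_dir,
                                    sprintf("bundle_epoch%03d.rds", epoch)))
  }
  log <- do.call(rbind, log_rows)
  attr(log, "ablated") <- term_names[!total_loss(
    stats::setNames(as.list(numeric(7)), term_names),
    weights = w, ablation = abl)$active[term_names]]
  structure(list(bundle = bundle, log = log, config = cfg),
            class = "msl_translation_fit")
}

#' Train the source-domain segmenter
#'
#' Splits the labeled source set into train/test (default 0.8 : 0.2),
#' minimizes the four-class dice loss with Adam (batch size 5, learning
#' rate 1e-3 by default) under flip augmentation, and reports held-out
#' pixel accuracy and mean IoU. The first `warmup_epochs` epochs use a
#' pixel-wise cross-entropy gradient before switching to the dice
#' objective: with a global dice the softmax gradient of a rare class
#' vanishes with its predicted probability, and at small scale the cord
#' class can otherwise die irrecoverably in the first epochs. The logged
#' loss is the dice value throughout.
#'
#' @param source_set List of `list(image, label)`.
#' @param config An `msl_config`; `config$segmenter` holds the optimizer
#'   settings.
#' @param verbose Print per-epoch loss lines.
#' @return List of class `msl_segmenter_fit`: `segmenter`, `log`,
#'   `test_metrics` (NULL when the test split is empty), `test_idx`.
#' @export
train_segmenter <- function(source_set, config = default_config(),
                            verbose = FALSE) {
  if (length(source_set) == 0) stop("empty dataset", call. = FALSE)
  cfg <- config
  set.seed(cfg$seed + 1L)
  FS <- build_segmenter(cfg$preset, seed = cfg$seed + 1L)
  opt <- adam_state(seg_nets(FS))
  opt$beta1 <- 0.9
  n <- length(source_set)
  n_train <- max(1L, floor(cfg$segmenter$train_frac * n))
  idx <- sample.int(n)
  train_idx <- idx[seq_len(n_train)]
  test_idx <- setdiff(idx, train_idx)
  bs <- cfg$segmenter$batch_size
  log_rows <- vector("list", cfg$segmenter$epochs)
  for (epoch in seq_len(cfg$segmenter$epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = bs)) {
      batch <- ord[start:min(start + bs - 1L, length(ord))]
      for (net in seg_nets(FS)) zero_grads(net)
      bl <- 0
      warm <- epoch <= (cfg$segmenter$warmup_epochs %||% 0L)
      for (i in batch) {
        au <- augment(source_set[[i]]$image, source_set[[i]]$label,
                      size = cfg$image_size)
        x <- unclass(convert_range(au$image, "signed"))
        g <- labelmap_onehot(au$label)
        f <- seg_forward(FS, x)
        den <- sum(f$probs + g)
        fac <- if (isTRUE(cfg$conventional_dice)) 2 else 1
        bl <- bl + 1 - fac * sum(f$probs * g) / den
        dprobs <- if (warm) -g / pmax(f$probs, 1e-8) / (den / 2) / length(batch)
                  else -fac * g / den / length(batch)
        seg_backward(FS, f$cache, f$probs, dprobs)
      }
      adam_step(opt, cfg$segmenter$lr)
      ep_loss <- ep_loss + bl / length(batch); nb <- nb + 1L
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch - 1L,
                                    dice_loss = ep_loss / nb)
    if (verbose) message(sprintf("seg epoch=%d dice=%.4f", epoch - 1L,
                                 ep_loss / nb))
  }
  test_metrics <- NULL
  if (length(test_idx) > 0) {
    gt <- lapply(test_idx, function(i) source_set[[i]]$label)
    pred <- lapply(test_idx, function(i) {
      au <- augment(source_set[[i]]$image, source_set[[i]]$label,
                    size = cfg$image_size, flip = FALSE)
      segment(FS, au$image)
    })
    test_metrics <- evaluate_segmentation(gt, pred)
  }
  structure(list(segmenter = FS, log = do.call(rbind, log_rows),
                 test_metrics = test_metrics, test_idx = test_idx),
            class = "msl_segmenter_fit")
}
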