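# ---- training objectives ---------------------------------------------------
#
# All losses are pure functions of arrays, independent of the network
# implementation. L1 reductions use the mean over all entries so the loss
# weights are resolution-independent. The two dice-style losses follow the
# as-printed convention without the factor 2 in the numerator (perfect
# overlap then scores 0.5, disjoint masks 1.0); `conventional = TRUE`
# restores the standard 2*intersection numerator, which shifts the optimum
# value to 0 without changing its location.

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop(what, " must have identical shape", call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Discriminator adversarial loss
#'
#' Least-squares variant (the LSGAN objective, the default):
#' `mean((real - 1)^2) + mean(fake^2)`. Log variant (the classic cross-
#' entropy game, discriminator ascent written as a minimized loss):
#' `-mean(log real) - mean(log(1 - fake))`.
#'
#' @param real_scores,fake_scores Patch score grids of identical shape.
#' @param variant `"least_squares"` or `"log"`.
#' @return Scalar loss.
#' @export
adversarial_loss_D <- function(real_scores, fake_scores,
                               variant = c("least_squares", "log")) {
  variant <- match.arg(variant)
  check_same_shape(real_scores, fake_scores, "score maps")
  if (variant == "least_squares")
    return(mean((real_scores - 1)^2) + mean(fake_scores^2))
  if (any(real_scores <= 0 | real_scores >= 1) ||
      any(fake_scores <= 0 | fake_scores >= 1))
    stop("log variant requires scores strictly inside (0, 1)", call. = FALSE)
  -mean(log(real_scores)) - mean(log(1 - fake_scores))
}

#' Generator adversarial loss
#'
#' Least-squares: `mean((fake - 1)^2)`; log: `-mean(log fake)` (the
#' non-saturating form).
#'
#' @inheritParams adversarial_loss_D
#' @return Scalar loss.
#' @export
adversarial_loss_G <- function(fake_scores,
                               variant = c("least_squares", "log")) {
  variant <- match.arg(variant)
  if (variant == "least_squares") return(mean((fake_scores - 1)^2))
  if (any(fake_scores <= 0 | fake_scores >= 1))
    stop("log variant requires scores strictly inside (0, 1)", call. = FALSE)
  -mean(log(fake_scores))
}

#' Cycle-consistency loss
#'
#' Mean absolute per-pixel-per-channel difference between an image and its
#' reconstruction after a round trip through both generators.
#'
#' @param x,x_rec Arrays of identical shape and value range.
#' @return Scalar mean-L1 loss.
#' @export
cycle_loss <- function(x, x_rec) {
  check_same_shape(x, x_rec, "image and reconstruction")
  mean(abs(unclass(x) - unclass(x_rec)))
}

#' Source-domain attention-consistency loss
#'
#' The source attention map is supervised directly by the label-derived
#' attended-region mask (ruler + background, see [attended_mask()]), and the
#' target attention network evaluated on the translated source image must
#' agree with the same mask:
#' `mean|A_S(x_s) - y| + mean|A_T(x_{s->t}) - y|`.
#'
#' @param A_S_xs Attention map of the source image under the source
#'   attention network.
#' @param A_T_xs2t Attention map of the translated source image under the
#'   target attention network.
#' @param y_bin Binary attended-region mask from the source label map.
#' @return Scalar loss.
#' @export
attention_consistency_source <- function(A_S_xs, A_T_xs2t, y_bin) {
  check_same_shape(A_S_xs, y_bin, "attention map and mask")
  check_same_shape(A_T_xs2t, y_bin, "attention map and mask")
  mean(abs(A_S_xs - y_bin)) + mean(abs(A_T_xs2t - y_bin))
}

#' Target-domain attention-consistency loss
#'
#' No target labels exist, so consistency is between the two attention
#' networks across the translation: `mean|A_T(x_t) - A_S(x_{t->s})|`.
#'
#' @param A_T_xt,A_S_xt2s Attention maps of identical shape in \[0,1\].
#' @return Scalar loss.
#' @export
attention_consistency_target <- function(A_T_xt, A_S_xt2s) {
  check_same_shape(A_T_xt, A_S_xt2s, "attention maps")
  mean(abs(A_T_xt - A_S_xt2s))
}

#' Saliency-consistency dice loss
#'
#' Dice-style disagreement between the binarized saliency of the original
#' image (the saliency ground truth) and the saliency of its translation,
#' restricted to the attended region. As printed:
#' `1 - sum(ref * tr) / (sum(ref) + sum(tr))`; identical binary masks give
#' exactly 0.5, disjoint masks 1.0. Two all-zero maps give 0 by convention
#' (there is no salient content to preserve).
#'
#' @param S_ref_bin Binary reference saliency mask.
#' @param S_tr Saliency of the translated image (continuous, normalized).
#' @param conventional If `TRUE`, use the standard dice numerator
#'   `2 * intersection` so perfect overlap scores 0.
#' @return Scalar loss.
#' @export
saliency_dice_loss <- function(S_ref_bin, S_tr, conventional = FALSE) {
  check_same_shape(S_ref_bin, S_tr, "saliency maps")
  num <- sum(S_ref_bin * S_tr)
  den <- sum(S_ref_bin) + sum(S_tr)
  if (den == 0) return(0)
  fac <- if (conventional) 2 else 1
  1 - fac * num / den
}

#' Four-class segmentation dice loss
#'
#' As printed: `1 - sum(p * g) / sum(p + g)` over all pixels and classes,
#' with `p` the per-pixel class probabilities and `g` the one-hot ground
#' truth. Because each pixel's probabilities sum to 1, the denominator is
#' the constant `2 * n_pixels`; a perfect one-hot prediction scores exactly
#' 0.5 and a completely wrong one-hot prediction 1.0.
#'
#' @param pred_probs H x W x 4 array, per-pixel probability simplex.
#' @param label An [msl_labelmap] or an H x W x 4 one-hot array.
#' @param conventional If `TRUE`, use the `2 * intersection` numerator.
#' @return Scalar loss.
#' @export
segmentation_dice_loss <- function(pred_probs, label, conventional = FALSE) {
  g <- if (inherits(label, "msl_labelmap")) labelmap_onehot(label) else label
  check_same_shape(pred_probs, g, "probabilities and one-hot labels")
  rowsums <- apply(pred_probs, c(1, 2), sum)
  if (max(abs(rowsums - 1)) > 1e-4)
    stop("pred_probs rows must lie on the probability simplex", call. = FALSE)
  num <- sum(pred_probs * g)
  den <- sum(pred_probs + g)
  fac <- if (conventional) 2 else 1
  1 - fac * num / den
}

#' Combine loss components into the total objective
#'
#' Weighted sum of the two adversarial terms, cycle, the two attention and
#' the two saliency terms. Ablated terms contribute zero and are flagged
#' inactive in the report.
#'
#' @param parts Named list with `gan_S2T`, `gan_T2S`, `cyc`, `att_S`,
#'   `att_T`, `sal_S`, `sal_T` (missing entries treated as 0).
#' @param weights Loss weights list (`cyc`, `att_S`, `att_T`, `sal_S`,
#'   `sal_T`), e.g. `default_config()$loss_weights`.
#' @param ablation List of flags `use_att`, `use_sal`, `use_cyc`.
#' @return List of class `msl_loss_report`: each component's weighted
#'   contribution, `total`, and `active` flags.
#' @export
total_loss <- function(parts, weights = default_config()$loss_weights,
                       ablation = list(use_att = TRUE, use_sal = TRUE,
                                       use_cyc = TRUE)) {
  terms <- c("gan_S2T", "gan_T2S", "cyc", "att_S", "att_T", "sal_S", "sal_T")
  vals <- vapply(terms, function(t) parts[[t]] %||% 0, numeric(1))
  bad <- !is.finite(vals)
  if (any(bad))
    stop("non-finite loss component(s): ", paste(terms[bad], collapse = ", "),
         call. = FALSE)
  active <- c(gan_S2T = TRUE, gan_T2S = TRUE,
              cyc = isTRUE(ablation$use_cyc),
              att_S = isTRUE(ablation$use_att),
              att_T = isTRUE(ablation$use_att),
              sal_S = isTRUE(ablation$use_sal),
              sal_T = isTRUE(ablation$use_sal))
  lam <- c(gan_S2T = 1, gan_T2S = 1, cyc = weights$cyc,
           att_S = weights$att_S, att_T = weights$att_T,
           sal_S = weights$sal_S, sal_T = weights$sal_T)
  contrib <- ifelse(active, lam * vals, 0)
  structure(c(as.list(vals),
              list(total = sum(contrib), active = active,
                   weighted = contrib)),
            class = "msl_loss_report")
}

#' @export
print.msl_loss_report <- function(x, ...) {
  terms <- c("gan_S2T", "gan_T2S", "cyc", "att_S", "att_T", "sal_S", "sal_T")
  for (t in terms)
    cat(sprintf("  %-8s %10.5f %s\n", t, x[[t]],
                if (x$active[[t]]) "" else "(ablated)"))
  cat(sprintf("  %-8s %10.5f\n", "total", x$total))
  invisible(x)
}
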