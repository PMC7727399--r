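# ---- learnable components --------------------------------------------------
#
# Six translation-side networks (two attention nets A_S/A_T, two generators
# G_S2T/G_T2S, two patch discriminators D_S/D_T) plus the source segmenter
# F_S. Two size presets:
#   "paper": 9-residual-block generator, 70x70-receptive-field 4-layer patch
#            discriminator, instance normalization throughout, encoder-
#            decoder attention trunk — the configuration used at 512 x 512.
#   "tiny":  shallow nets without normalization for desk-scale experiments
#            at 64 x 64; the tiny generator is residual (x + f(x), clamped)
#            so it starts near the identity map.

res_block <- function(c, norm = TRUE) {
  parts <- list(layer_conv(c, c, 3L))
  if (norm) parts <- c(parts, list(layer_inorm(c)))
  parts <- c(parts, list(layer_act("relu")), list(layer_conv(c, c, 3L)))
  if (norm) parts <- c(parts, list(layer_inorm(c)))
  nn_res(do.call(nn_chain, parts))
}

build_attention_net <- function(preset) {
  if (preset == "tiny") {
    head <- layer_conv(12L, 1L, init_gain = 1)
    net <- nn_chain(
      layer_conv(3L, 12L), layer_act("relu"),
      layer_conv(12L, 12L), layer_act("relu"),
      head, layer_act("sigmoid"))
  } else {
    head <- layer_conv(32L, 1L, init_gain = 1)
    net <- nn_chain(
      layer_conv(3L, 32L, 7L), layer_inorm(32L), layer_act("relu"),
      layer_conv(32L, 64L, 3L, stride = 2L), layer_inorm(64L), layer_act("relu"),
      res_block(64L),
      layer_upsample2(), layer_conv(64L, 32L), layer_inorm(32L), layer_act("relu"),
      head, layer_act("sigmoid"))
  }
  structure(list(net = net), class = "msl_attention")
}

build_generator <- function(preset) {
  if (preset == "tiny") {
    net <- nn_chain(
      layer_conv(3L, 12L), layer_act("relu"),
      res_block(12L, norm = FALSE),
      layer_conv(12L, 3L, init_gain = 0.02))
    form <- "residual"
  } else {
    up <- function(cin, cout) nn_chain(layer_upsample2(),
                                       layer_conv(cin, cout),
                                       layer_inorm(cout), layer_act("relu"))
    net <- do.call(nn_chain, c(
      list(layer_conv(3L, 64L, 7L), layer_inorm(64L), layer_act("relu"),
           layer_conv(64L, 128L, 3L, stride = 2L), layer_inorm(128L),
           layer_act("relu"),
           layer_conv(128L, 256L, 3L, stride = 2L), layer_inorm(256L),
           layer_act("relu")),
      lapply(1:9, function(i) res_block(256L)),
      list(up(256L, 128L), up(128L, 64L),
           layer_conv(64L, 3L, 7L, init_gain = 1), layer_act("tanh"))))
    form <- "plain"
  }
  structure(list(net = net, form = form), class = "msl_generator")
}

build_discriminator <- function(preset) {
  if (preset == "tiny") {
    net <- nn_chain(
      layer_conv(3L, 12L, stride = 2L), layer_act("lrelu"),
      layer_conv(12L, 24L, stride = 2L), layer_act("lrelu"),
      layer_conv(24L, 1L, init_gain = 1))
  } else {
    net <- nn_chain(
      layer_conv(3L, 64L, 4L, stride = 2L), layer_act("lrelu"),
      layer_conv(64L, 128L, 4L, stride = 2L), layer_inorm(128L), layer_act("lrelu"),
      layer_conv(128L, 256L, 4L, stride = 2L), layer_inorm(256L), layer_act("lrelu"),
      layer_conv(256L, 512L, 4L), layer_inorm(512L), layer_act("lrelu"),
      layer_conv(512L, 1L, 4L, init_gain = 1))
  }
  structure(list(net = net), class = "msl_discriminator")
}

#' Build the six translation-side networks
#'
#' Constructs the two attention networks, two generators and two patch
#' discriminators with seed-deterministic initial weights.
#'
#' @param preset `"paper"` (full-size configuration) or `"tiny"` (shallow
#'   nets for CPU-scale experiments).
#' @param seed Integer seed controlling weight initialization.
#' @return List of class `msl_bundle` with elements `A_S`, `A_T`, `G_S2T`,
#'   `G_T2S`, `D_S`, `D_T` and `preset`.
#' @export
build_bundle <- function(preset = c("tiny", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  with_seed(seed, {
    structure(list(
      A_S = build_attention_net(preset), A_T = build_attention_net(preset),
      G_S2T = build_generator(preset), G_T2S = build_generator(preset),
      D_S = build_discriminator(preset), D_T = build_discriminator(preset),
      preset = preset), class = "msl_bundle")
  })
}

# ---- forward / backward wrappers ------------------------------------------

# Attention: image array -> H x W map in [0,1].
att_forward <- function(A, x) {
  f <- net_forward(A$net, x)
  list(out = f$out[, , 1], cache = f$caches)
}
att_backward <- function(A, cache, dy_map) {
  net_backward(A$net, cache, array(dy_map, c(dim(dy_map), 1L)))
}

# Generator: [-1,1] array -> [-1,1] array.
gen_forward <- function(G, x) {
  f <- net_forward(G$net, x)
  if (G$form == "plain") return(list(out = f$out, cache = list(caches = f$caches)))
  pre <- x + f$out
  out <- pmin(pmax(pre, -1), 1)
  # leaky slope outside the clamp so saturated pixels still receive signal
  list(out = out,
       cache = list(caches = f$caches,
                    mask = ifelse(pre > -1 & pre < 1, 1, 0.1)))
}
gen_backward <- function(G, cache, dy) {
  if (G$form == "plain") return(net_backward(G$net, cache$caches, dy))
  dpre <- dy * cache$mask
  dpre + net_backward(G$net, cache$caches, dpre)
}

disc_forward <- function(D, x) {
  f <- net_forward(D$net, x)
  list(out = f$out[, , 1], cache = f$caches)
}
disc_backward <- function(D, cache, dy_grid) {
  net_backward(D$net, cache, array(dy_grid, c(dim(dy_grid), 1L)))
}

#' Attention-guided translation composition
#'
#' Per-pixel convex blend of the generated and original image weighted by
#' the attention map: `x_att * G(x) + (1 - x_att) * x`. Pixels with zero
#' attention are bit-identical to the input, which is what keeps the
#' foreground (disc and cord) untouched by translation.
#'
#' @param x An [msl_image] in the signed range (or plain array in \[-1,1\]).
#' @param A Either an H x W attention map in \[0,1\] or an attention network
#'   (`msl_attention`), in which case the map is computed from `x`.
#' @param G Either the already-generated image (H x W x 3 array) or a
#'   generator (`msl_generator`) applied to `x`.
#' @return The composed image as an array of the same shape as `x` (an
#'   [msl_image] if `x` was one).
#' @export
attended_translate <- function(x, A, G) {
  px <- if (inherits(x, "msl_image")) unclass(convert_range(x, "signed")) else x
  a <- if (inherits(A, "msl_attention")) att_forward(A, px)$out else A
  g <- if (inherits(G, "msl_generator")) gen_forward(G, px)$out else G
  if (!identical(dim(a), dim(px)[1:2]))
    stop("attention map shape does not match image", call. = FALSE)
  if (!identical(dim(g), dim(px)))
    stop("generated image shape does not match input", call. = FALSE)
  out <- px
  for (c in 1:3) out[, , c] <- a * g[, , c] + (1 - a) * px[, , c]
  if (inherits(x, "msl_image"))
    msl_image(out, range = "signed", domain = attr(x, "domain"))
  else out
}

# Gradient of the composition w.r.t. (a, g, x) given upstream dy.
attended_translate_bwd <- function(dy, a, g, x) {
  da <- dy[, , 1] * (g[, , 1] - x[, , 1]) +
        dy[, , 2] * (g[, , 2] - x[, , 2]) +
        dy[, , 3] * (g[, , 3] - x[, , 3])
  dg <- dy; dx <- dy
  for (c in 1:3) { dg[, , c] <- dy[, , c] * a; dx[, , c] <- dy[, , c] * (1 - a) }
  list(da = da, dg = dg, dx = dx)
}

# ---- segmenter -------------------------------------------------------------

#' Build the source-domain four-class segmenter
#'
#' A symmetric encoder-decoder with additive skip connections and a softmax
#' head over the four classes (background, disc, cord, ruler). The `"tiny"`
#' preset uses one downsampling level and 16 base channels; `"paper"` uses
#' three levels and 32 base channels. Weights are seed-deterministic.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param seed Integer seed.
#' @return Object of class `msl_segmenter`.
#' @export
build_segmenter <- function(preset = c("tiny", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  nf <- if (preset == "tiny") 16L else 32L
  depth <- if (preset == "tiny") 1L else 3L
  with_seed(seed, {
    enc <- nn_chain(layer_conv(3L, nf), layer_act("relu"))
    downs <- lapply(seq_len(depth), function(d)
      nn_chain(layer_conv(nf * 2L^(d - 1L), nf * 2L^d, stride = 2L),
               layer_act("relu")))
    mid <- nn_chain(layer_conv(nf * 2L^depth, nf * 2L^depth), layer_act("relu"))
    ups <- lapply(rev(seq_len(depth)), function(d)
      nn_chain(layer_upsample2(), layer_conv(nf * 2L^d, nf * 2L^(d - 1L)),
               layer_act("relu")))
    head <- layer_conv(nf, 4L, init_gain = 1)
    structure(list(enc = enc, downs = downs, mid = mid, ups = ups,
                   head = head, depth = depth, preset = preset, temp = 1),
              class = "msl_segmenter")
  })
}

softmax_channels <- function(z) {
  zmax <- pmax(z[, , 1], z[, , 2], z[, , 3], z[, , 4])
  e <- z
  for (k in 1:4) e[, , k] <- exp(z[, , k] - zmax)
  s <- e[, , 1] + e[, , 2] + e[, , 3] + e[, , 4]
  for (k in 1:4) e[, , k] <- e[, , k] / s
  e
}

seg_forward <- function(FS, x) {
  d <- dim(x)
  if (d[1] %% 2L^FS$depth != 0L || d[2] %% 2L^FS$depth != 0L)
    stop("image size must be divisible by ", 2L^FS$depth, call. = FALSE)
  fe <- net_forward(FS$enc, x)
  skips <- list(fe$out)
  caches <- list(enc = fe$caches, downs = list(), ups = list())
  h <- fe$out
  for (i in seq_along(FS$downs)) {
    f <- net_forward(FS$downs[[i]], h)
    h <- f$out
    caches$downs[[i]] <- f$caches
    skips[[i + 1L]] <- h
  }
  fm <- net_forward(FS$mid, h)
  caches$mid <- fm$caches
  h <- fm$out
  for (i in seq_along(FS$ups)) {
    f <- net_forward(FS$ups[[i]], h)
    h <- f$out + skips[[FS$depth + 1L - i]]
    caches$ups[[i]] <- f$caches
  }
  fh <- layer_forward(FS$head, h)
  caches$head <- fh$cache
  p <- softmax_channels(fh$out / FS$temp)
  list(probs = p, cache = caches)
}

# dy w.r.t. probabilities; returns gradient w.r.t. the input image.
seg_backward <- function(FS, cache, probs, dprobs) {
  # softmax jacobian per pixel: dz_k = p_k * (dy_k - sum_k dy_k p_k)
  dot <- dprobs[, , 1] * probs[, , 1] + dprobs[, , 2] * probs[, , 2] +
         dprobs[, , 3] * probs[, , 3] + dprobs[, , 4] * probs[, , 4]
  dz <- probs
  for (k in 1:4) dz[, , k] <- probs[, , k] * (dprobs[, , k] - dot) / FS$temp
  dh <- layer_backward(FS$head, cache$head, dz)
  dskips <- vector("list", FS$depth + 1L)
  for (i in rev(seq_along(FS$ups))) {
    lev <- FS$depth + 1L - i
    dskips[[lev]] <- dh
    dh <- net_backward(FS$ups[[i]], cache$ups[[i]], dh)
  }
  dh <- net_backward(FS$mid, cache$mid, dh)
  for (i in rev(seq_along(FS$downs))) {
    if (!is.null(dskips[[i + 1L]])) dh <- dh + dskips[[i + 1L]]
    dh <- net_backward(FS$downs[[i]], cache$downs[[i]], dh)
  }
  if (!is.null(dskips[[1L]])) dh <- dh + dskips[[1L]]
  net_backward(FS$enc, cache$enc, dh)
}

seg_nets <- function(FS) c(list(FS$enc), FS$downs, list(FS$mid), FS$ups,
                           list(FS$head))

#' Per-pixel class probabilities from the segmenter
#'
#' @param FS An `msl_segmenter`.
#' @param img An [msl_image] (any range; converted to signed internally) or
#'   a plain \[-1,1\] array.
#' @return H x W x 4 array of class probabilities.
#' @export
segment_probs <- function(FS, img) {
  px <- if (inherits(img, "msl_image")) unclass(convert_range(img, "signed"))
        else img
  seg_forward(FS, px)$probs
}

#' Segment an image into the four placenta classes
#'
#' Applies the segmenter and takes the per-pixel argmax; probability ties
#' resolve to the lowest class id (deterministic).
#'
#' @inheritParams segment_probs
#' @return An [msl_labelmap].
#' @export
segment <- function(FS, img) {
  p <- segment_probs(FS, img)
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], 4L)
  lab <- max.col(pm, ties.method = "first") - 1L
  msl_labelmap(matrix(lab, d[1], d[2]))
}

# ---- checkpointing ---------------------------------------------------------

bundle_nets <- function(bundle)
  list(A_S = bundle$A_S$net, A_T = bundle$A_T$net,
       G_S2T = bundle$G_S2T$net, G_T2S = bundle$G_T2S$net,
       D_S = bundle$D_S$net, D_T = bundle$D_T$net)

#' Save / load model weights
#'
#' Weights are serialized as an RDS file of plain numeric arrays; the
#' architecture is rebuilt from the preset on load, then populated.
#'
#' @param bundle An `msl_bundle`.
#' @param path Output file.
#' @return `path` invisibly (save); the restored object (load).
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(list(preset = bundle$preset,
               state = lapply(bundle_nets(bundle), net_state)), path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  s <- readRDS(path)
  bundle <- build_bundle(s$preset, seed = 0L)
  nets <- bundle_nets(bundle)
  for (n in names(nets)) net_load_state(nets[[n]], s$state[[n]])
  bundle
}

#' @rdname save_bundle
#' @param FS An `msl_segmenter` (for the segmenter variants).
#' @export
save_segmenter <- function(FS, path) {
  saveRDS(list(preset = FS$preset,
               state = lapply(seg_nets(FS), net_state)), path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_segmenter <- function(path) {
  s <- readRDS(path)
  FS <- build_segmenter(s$preset, seed = 0L)
  nets <- seg_nets(FS)
  for (i in seq_along(nets)) net_load_state(nets[[i]], s$state[[i]])
  FS
}
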