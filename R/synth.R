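# ---- synthetic two-domain placenta-like scenes -----------------------------
#
# Flat 2-D composites that reproduce the *structure* of the cross-hospital
# domain shift, not photographic realism: the disc (ellipse, dark red) and
# cord (tube, pink) share one appearance distribution in both domains, while
# the ruler style and the background cloth differ sharply between domains
# (source: white-tick ruler on green cloth; target: yellow-grid ruler on a
# blue, blood-spotted cloth). Compositing order background -> disc -> cord
# -> ruler; the label map follows the topmost layer.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Specify one synthetic placenta scene
#'
#' Usually produced by [random_scene_spec()]; all geometry is in pixel
#' units of the `size` x `size` canvas.
#'
#' @param size Canvas side length in pixels.
#' @param disc List: `center` (x, y), `axes` (a, b), `angle` (radians),
#'   `color` (RGB in \[0,1\]), `speckle` (noise sd).
#' @param cord List: `points` (n x 2 polyline vertices), `width`, `color`.
#' @param ruler List: `side` ("left"/"right"/"top"/"bottom"), `thickness`,
#'   `period` (stripe spacing, px), `style` ("white_ticks"/"yellow_grid"),
#'   or `NULL` for a scene without a ruler.
#' @param background List: `style` ("green_cloth"/"blue_bloody"), `color`,
#'   `noise` (speckle sd), `blobs` (matrix of x, y, radius, strength for
#'   blood spots; may be NULL).
#' @param seed Integer; makes the speckle noise (and thus the whole scene)
#'   deterministic.
#' @return List of class `msl_scenespec`.
#' @export
scene_spec <- function(size, disc, cord, ruler, background, seed = 1L) {
  spec <- structure(list(size = as.integer(size), disc = disc, cord = cord,
                         ruler = ruler, background = background,
                         seed = as.integer(seed)), class = "msl_scenespec")
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  s <- spec$size
  d <- spec$disc
  if (d$center[1] - d$axes[1] < 1 || d$center[1] + d$axes[1] > s ||
      d$center[2] - d$axes[2] < 1 || d$center[2] + d$axes[2] > s)
    stop("disc ellipse extends outside the canvas", call. = FALSE)
  if (any(spec$cord$points < 1) || any(spec$cord$points > s))
    stop("cord polyline extends outside the canvas", call. = FALSE)
  if (!is.null(spec$ruler) && spec$ruler$thickness >= s / 2)
    stop("ruler thickness exceeds half the canvas", call. = FALSE)
  spec
}

#' Draw a random scene specification for one domain
#'
#' The two domains share the disc and cord appearance distributions and
#' differ only in ruler style and background style — the shift structure of
#' cross-hospital placenta photographs.
#'
#' @param size Canvas side, default 64.
#' @param domain `"source"` or `"target"`.
#' @param seed Integer seed for both the geometry draw and the scene noise.
#' @param with_ruler Include a ruler (default `TRUE`).
#' @return An `msl_scenespec`.
#' @export
random_scene_spec <- function(size = 64L, domain = c("source", "target"),
                              seed = 1L, with_ruler = TRUE) {
  domain <- match.arg(domain)
  with_seed(seed, {
    s <- size
    ruler_side <- sample(c("left", "right", "top", "bottom"), 1)
    thick <- max(6L, round(s * stats::runif(1, 0.12, 0.16)))
    # disc on the opposite half so every class survives compositing
    cx_range <- switch(ruler_side,
      left = c(0.55, 0.72), right = c(0.28, 0.45),
      top = c(0.35, 0.65), bottom = c(0.35, 0.65))
    cy_range <- switch(ruler_side,
      top = c(0.55, 0.72), bottom = c(0.28, 0.45),
      left = c(0.35, 0.65), right = c(0.35, 0.65))
    cx <- s * stats::runif(1, cx_range[1], cx_range[2])
    cy <- s * stats::runif(1, cy_range[1], cy_range[2])
    a <- s * stats::runif(1, 0.18, 0.24)
    b <- a * stats::runif(1, 0.8, 1.0)
    a <- min(a, cx - 1, s - cx); b <- min(b, cy - 1, s - cy)
    disc <- list(center = c(cx, cy), axes = c(a, b),
                 angle = stats::runif(1, 0, pi),
                 color = c(0.52, 0.20, 0.22) + stats::runif(3, -0.04, 0.04),
                 speckle = 0.04)
    # cord: polyline from the disc center toward a canvas corner
    corner <- switch(ruler_side,
      left = c(s, stats::runif(1, 1, s)), right = c(1, stats::runif(1, 1, s)),
      top = c(stats::runif(1, 1, s), s), bottom = c(stats::runif(1, 1, s), 1))
    mid <- (c(cx, cy) + corner) / 2 + stats::runif(2, -0.08 * s, 0.08 * s)
    pts <- rbind(c(cx, cy), mid, corner)
    pts[] <- pmin(pmax(pts, 1), s)
    cord <- list(points = pts, width = max(2.5, s * 0.05),
                 color = c(0.82, 0.60, 0.62) + stats::runif(3, -0.04, 0.04))
    ruler <- if (with_ruler) list(
      side = ruler_side, thickness = thick,
      period = max(3L, round(s / 16)),
      style = if (domain == "source") "white_ticks" else "yellow_grid")
      else NULL
    background <- if (domain == "source") list(
      style = "green_cloth",
      color = c(0.28, 0.48, 0.30) + stats::runif(3, -0.03, 0.03),
      noise = 0.03, blobs = NULL)
    else list(
      style = "blue_bloody",
      color = c(0.28, 0.32, 0.58) + stats::runif(3, -0.03, 0.03),
      noise = 0.05,
      blobs = cbind(stats::runif(3, 1, s), stats::runif(3, 1, s),
                    stats::runif(3, 0.05 * s, 0.12 * s),
                    stats::runif(3, 0.15, 0.35)))
    scene_spec(s, disc, cord, ruler, background,
               seed = sample.int(.Machine$integer.max %/% 2L, 1))
  })
}

dist_to_segment <- function(X, Y, p, q) {
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  len2 <- vx^2 + vy^2
  t <- ((X - p[1]) * vx + (Y - p[2]) * vy) / max(len2, 1e-9)
  t <- pmin(pmax(t, 0), 1)
  sqrt((X - (p[1] + t * vx))^2 + (Y - (p[2] + t * vy))^2)
}

#' Render a synthetic scene and its ground-truth label map
#'
#' Deterministic for a fixed spec (the spec embeds the noise seed).
#'
#' @param spec An `msl_scenespec`.
#' @param domain Optional domain tag attached to the image.
#' @return List with `image` (an [msl_image], unit range) and `label`
#'   (an [msl_labelmap]).
#' @export
make_scene <- function(spec, domain = NULL) {
  stopifnot(inherits(spec, "msl_scenespec"))
  s <- spec$size
  # X = column (j), Y = row (i) in pixel units
  X <- matrix(rep(seq_len(s), each = s), s, s)
  Y <- matrix(rep(seq_len(s), times = s), s, s)
  with_seed(spec$seed, {
    img <- array(0, c(s, s, 3))
    lab <- matrix(0L, s, s)
    bg <- spec$background
    for (c in 1:3)
      img[, , c] <- bg$color[c] + stats::rnorm(s * s, sd = bg$noise)
    if (!is.null(bg$blobs)) {
      for (r in seq_len(nrow(bg$blobs))) {
        bl <- bg$blobs[r, ]
        w <- exp(-((X - bl[1])^2 + (Y - bl[2])^2) / (2 * bl[3]^2)) * bl[4]
        img[, , 1] <- img[, , 1] + w * 0.35
        img[, , 2] <- img[, , 2] - w * 0.15
        img[, , 3] <- img[, , 3] - w * 0.25
      }
    }
    d <- spec$disc
    ca <- cos(d$angle); sa <- sin(d$angle)
    xr <- (X - d$center[1]) * ca + (Y - d$center[2]) * sa
    yr <- -(X - d$center[1]) * sa + (Y - d$center[2]) * ca
    disc_mask <- (xr / d$axes[1])^2 + (yr / d$axes[2])^2 <= 1
    shade <- 1 - 0.25 * ((xr / d$axes[1])^2 + (yr / d$axes[2])^2)
    for (c in 1:3) {
      layer <- d$color[c] * shade + stats::rnorm(s * s, sd = d$speckle)
      img[, , c][disc_mask] <- layer[disc_mask]
    }
    lab[disc_mask] <- 1L
    co <- spec$cord
    dist <- Inf
    for (k in seq_len(nrow(co$points) - 1L))
      dist <- pmin(dist, dist_to_segment(X, Y, co$points[k, ],
                                         co$points[k + 1L, ]))
    cord_mask <- dist <= co$width / 2
    for (c in 1:3) {
      layer <- co$color[c] * (1 - 0.2 * dist / (co$width / 2)) +
        stats::rnorm(s * s, sd = 0.03)
      img[, , c][cord_mask] <- layer[cord_mask]
    }
    lab[cord_mask] <- 2L
    ru <- spec$ruler
    if (!is.null(ru)) {
      rmask <- switch(ru$side,
        left = X <= ru$thickness, right = X > s - ru$thickness,
        top = Y <= ru$thickness, bottom = Y > s - ru$thickness)
      along <- if (ru$side %in% c("left", "right")) Y else X
      across <- if (ru$side %in% c("left", "right")) X else Y
      if (ru$style == "white_ticks") {
        base <- c(0.93, 0.93, 0.90)
        marks <- (along %% ru$period) < 1 &
          (if (ru$side %in% c("left", "top")) across <= ru$thickness * 0.6
           else across > s - ru$thickness * 0.6)
        mark_col <- c(0.15, 0.15, 0.15)
      } else {
        base <- c(0.85, 0.78, 0.25)
        marks <- (along %% ru$period) < 1 | (across %% ru$period) < 1
        mark_col <- c(0.40, 0.35, 0.10)
      }
      for (c in 1:3) {
        layer <- matrix(base[c], s, s) + stats::rnorm(s * s, sd = 0.02)
        layer[marks] <- mark_col[c]
        img[, , c][rmask] <- layer[rmask]
      }
      lab[rmask] <- 3L
    }
    img <- clamp01(img)
    list(image = msl_image(img, range = "unit", domain = domain),
         label = msl_labelmap(lab))
  })
}

#' Generate matched source/target synthetic datasets
#'
#' Produces `n` labeled source scenes and `n` target scenes whose labels are
#' returned separately (`target_labels_eval`) so the training interface only
#' ever sees target images — the unsupervised-adaptation contract.
#'
#' @param n Scenes per domain.
#' @param size Canvas side, default 64.
#' @param seed Integer seed; scene i of each domain derives its own seed
#'   from it.
#' @param source_family,target_family Functions `(size, seed) -> spec`
#'   overriding the default per-domain spec draw (rarely needed).
#' @return List with `source` (list of `image`, `label` lists), `target`
#'   (list of `image`-only lists) and `target_labels_eval` (the withheld
#'   target label maps, evaluation only).
#' @export
make_domain_pair <- function(n, size = 64L, seed = 1L,
                             source_family = NULL, target_family = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  fam <- function(domain, override, sd_) {
    if (!is.null(override)) return(override(size, sd_))
    random_scene_spec(size, domain, seed = sd_)
  }
  src <- lapply(seq_len(n), function(i) {
    sc <- make_scene(fam("source", source_family, seed * 10000L + i),
                     domain = "source")
    list(image = sc$image, label = sc$label)
  })
  tgt_full <- lapply(seq_len(n), function(i)
    make_scene(fam("target", target_family, seed * 10000L + 5000L + i),
               domain = "target"))
  list(source = src,
       target = lapply(tgt_full, function(sc) list(image = sc$image)),
       target_labels_eval = lapply(tgt_full, function(sc) sc$label))
}
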