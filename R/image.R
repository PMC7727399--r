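# ---- core data types -------------------------------------------------------
#
# Images are plain H x W x 3 numeric arrays carrying two attributes:
#   "range"  -- "unit" ([0,1], saliency convention) or "signed" ([-1,1],
#               translation-network convention)
#   "domain" -- optional "source"/"target" tag
# Label maps are H x W integer matrices with values in 0..3.
# Coordinates are row-major, 0-based in formulas (i = row, j = column).

#' Class names for the four-class placenta segmentation problem
#'
#' Fixed class id order: 0 = background, 1 = placenta disc, 2 = umbilical
#' cord, 3 = ruler. The id assignment is a package convention; the class set
#' itself is the standard one for gross placenta photograph analysis.
#'
#' @return Character vector of length 4, names in class-id order.
#' @export
msl_classes <- function() c("background", "disc", "cord", "ruler")

#' Construct a placenta photograph object
#'
#' @param pixels H x W x 3 numeric array.
#' @param range `"unit"` for values in \[0,1\] or `"signed"` for \[-1,1\].
#' @param domain Optional `"source"` or `"target"` tag.
#' @return The pixel array with class `msl_image` and `range`/`domain`
#'   attributes.
#' @export
msl_image <- function(pixels, range = c("unit", "signed"), domain = NULL) {
  range <- match.arg(range)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L)
    stop("image must be at least 8 x 8", call. = FALSE)
  lo <- if (range == "unit") 0 else -1
  rng <- range(pixels)
  if (rng[1] < lo - 1e-8 || rng[2] > 1 + 1e-8)
    stop(sprintf("pixel values [%.4g, %.4g] outside declared '%s' range",
                 rng[1], rng[2], range), call. = FALSE)
  if (!is.null(domain)) domain <- match.arg(domain, c("source", "target"))
  structure(pixels, range = range, domain = domain, class = "msl_image")
}

#' @export
print.msl_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<msl_image %d x %d, range %s%s>\n", d[1], d[2],
              attr(x, "range"),
              if (is.null(attr(x, "domain"))) "" else
                paste0(", domain ", attr(x, "domain"))))
  invisible(x)
}

#' Convert an image between the unit and signed value ranges
#'
#' Translation networks operate on \[-1,1\] pixels (the usual generative-
#' adversarial convention); saliency is computed on \[0,1\] pixels. The map is
#' affine: `signed = 2 * unit - 1`.
#'
#' @param img An [msl_image].
#' @param to Target range, `"unit"` or `"signed"`.
#' @return The converted [msl_image]; a no-op when already in `to`.
#' @export
convert_range <- function(img, to = c("unit", "signed")) {
  to <- match.arg(to)
  stopifnot(inherits(img, "msl_image"))
  from <- attr(img, "range")
  if (from == to) return(img)
  px <- if (to == "signed") unclass(img) * 2 - 1 else (unclass(img) + 1) / 2
  # clamp away round-off outside the target interval
  lo <- if (to == "unit") 0 else -1
  px[px < lo] <- lo
  px[px > 1] <- 1
  msl_image(px, range = to, domain = attr(img, "domain"))
}

#' Construct a segmentation label map
#'
#' @param labels H x W matrix of integer class ids in `0..3`
#'   (see [msl_classes()]).
#' @return Integer matrix with class `msl_labelmap`.
#' @export
msl_labelmap <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  lab <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  bad <- lab < 0L | lab > 3L | is.na(lab)
  if (any(bad))
    stop(sprintf("label map contains invalid class id(s): %s",
                 paste(unique(lab[bad]), collapse = ", ")), call. = FALSE)
  structure(lab, class = "msl_labelmap")
}

#' @export
print.msl_labelmap <- function(x, ...) {
  tab <- tabulate(unclass(x) + 1L, nbins = 4L)
  cat(sprintf("<msl_labelmap %d x %d; px per class: %s>\n",
              nrow(x), ncol(x),
              paste(sprintf("%s=%d", msl_classes(), tab), collapse = " ")))
  invisible(x)
}

#' One-hot encode a label map
#'
#' Produces the indicator tensor `g(i,j,k)` used by the segmentation dice
#' loss: `g[i,j,k] = 1` iff pixel (i,j) is annotated class k.
#'
#' @param lab An [msl_labelmap].
#' @return H x W x 4 numeric 0/1 array.
#' @export
labelmap_onehot <- function(lab) {
  stopifnot(inherits(lab, "msl_labelmap"))
  h <- nrow(lab); w <- ncol(lab)
  g <- array(0, c(h, w, 4L))
  for (k in 0:3) g[, , k + 1L] <- (unclass(lab) == k) * 1
  g
}

#' Binary attended-region mask from a source label map
#'
#' The attended (translated) regions are the domain-discriminative ones:
#' ruler and background, classes {0, 3}. Disc and cord (classes {1, 2}) are
#' the appearance-stable foreground and stay unattended. Used as direct
#' supervision for the source attention network.
#'
#' @param lab An [msl_labelmap].
#' @return H x W numeric 0/1 matrix (1 = attended).
#' @export
attended_mask <- function(lab) {
  stopifnot(inherits(lab, "msl_labelmap"))
  (unclass(lab) == 0L | unclass(lab) == 3L) * 1
}
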