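# ---- frequency-tuned (FT) saliency -----------------------------------------
#
# S(i,j) = || I_blur(i,j) - I_mu ||_2 with I_blur the low-pass filtered pixel
# color vector and I_mu the mean color vector of the *unfiltered* image.
# Color space defaults to CIE Lab (the convention of the FT saliency
# literature); RGB is available for speed or when a differentiable path
# without the Lab nonlinearity is preferred.

#' Blur specification for FT saliency
#'
#' @param kernel1d Separable low-pass kernel weights; default the 5-tap
#'   binomial (1,4,6,4,1)/16, a standard small Gaussian approximation.
#'   `NULL` disables blurring (useful for closed-form checks).
#' @param color_space `"Lab"` (default) or `"RGB"`.
#' @return List of class `msl_blurspec`.
#' @export
blur_spec <- function(kernel1d = c(1, 4, 6, 4, 1) / 16,
                      color_space = c("Lab", "RGB")) {
  color_space <- match.arg(color_space)
  if (!is.null(kernel1d)) {
    if (abs(sum(kernel1d) - 1) > 1e-12)
      stop("blur kernel weights must sum to 1", call. = FALSE)
  }
  structure(list(kernel1d = kernel1d, color_space = color_space),
            class = "msl_blurspec")
}

# Separable 2-D correlation with replicated borders; kernel is symmetric so
# correlation == convolution. x may be a matrix or an H x W x C array.
separable_blur <- function(x, k) {
  if (is.null(k)) return(x)
  blur1 <- function(m, along) {
    r <- (length(k) - 1L) / 2L
    n <- if (along == 1) nrow(m) else ncol(m)
    idx <- function(i) pmin(pmax(i, 1L), n)   # replicate edges
    out <- 0
    for (t in seq_along(k)) {
      off <- t - 1L - r
      sel <- idx(seq_len(n) + off)
      out <- out + k[t] * (if (along == 1) m[sel, , drop = FALSE]
                           else m[, sel, drop = FALSE])
    }
    out
  }
  if (is.matrix(x)) return(blur1(blur1(x, 1), 2))
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- blur1(blur1(x[, , c], 1), 2)
  out
}

# ---- sRGB -> CIE Lab, vectorized, with analytic jacobian -------------------

.lab_M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                   0.2126729, 0.7151522, 0.0721750,
                   0.0193339, 0.1191920, 0.9503041),
                 3, 3, byrow = TRUE)
.lab_white <- c(0.95047, 1.0, 1.08883)   # D65

srgb_linearize <- function(c) ifelse(c <= 0.04045, c / 12.92,
                                     ((c + 0.055) / 1.055)^2.4)
srgb_linearize_d <- function(c) ifelse(c <= 0.04045, 1 / 12.92,
                                       2.4 / 1.055 * ((c + 0.055) / 1.055)^1.4)

.lab_f <- function(t) {
  eps <- (6 / 29)^3
  ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}
.lab_f_d <- function(t) {
  eps <- (6 / 29)^3
  ifelse(t > eps, (1 / 3) * t^(-2 / 3), 1 / (3 * (6 / 29)^2))
}

# img: H x W x 3 in [0,1]. Returns H x W x 3 Lab array (L in [0,100]).
rgb_to_lab <- function(img) {
  d <- dim(img)
  rgb <- matrix(img, ncol = 3L)
  lin <- srgb_linearize(rgb)
  xyz <- lin %*% t(.lab_M)
  xyz <- sweep(xyz, 2, .lab_white, "/")
  fx <- .lab_f(xyz[, 1]); fy <- .lab_f(xyz[, 2]); fz <- .lab_f(xyz[, 3])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  array(lab, d)
}

# Chain rule transpose: given dL/d(lab) (H x W x 3), return dL/d(rgb).
rgb_to_lab_backward <- function(img, grad_lab) {
  d <- dim(img)
  rgb <- matrix(img, ncol = 3L)
  g <- matrix(grad_lab, ncol = 3L)
  lin <- srgb_linearize(rgb)
  xyz <- sweep(lin %*% t(.lab_M), 2, .lab_white, "/")
  fd <- cbind(.lab_f_d(xyz[, 1]), .lab_f_d(xyz[, 2]), .lab_f_d(xyz[, 3]))
  # lab = (116 fy - 16, 500 (fx - fy), 200 (fy - fz))
  dfx <- 500 * g[, 2]
  dfy <- 116 * g[, 1] - 500 * g[, 2] + 200 * g[, 3]
  dfz <- -200 * g[, 3]
  dxyz <- cbind(dfx * fd[, 1], dfy * fd[, 2], dfz * fd[, 3])
  dxyz <- sweep(dxyz, 2, .lab_white, "/")
  dlin <- dxyz %*% .lab_M           # t(t(M)) back through lin %*% t(M)
  drgb <- dlin * srgb_linearize_d(rgb)
  array(drgb, d)
}

#' Frequency-tuned saliency of an image
#'
#' Computes the parameter-free FT saliency statistic: the per-pixel Euclidean
#' distance, in color space, between the low-pass-filtered pixel color and
#' the mean color vector of the whole (unfiltered) image. Bright, uniformly
#' colored regions that differ from the global mean — such as a ruler on a
#' surgical cloth — score high.
#'
#' @param img An [msl_image] in the unit range (or a plain H x W x 3 array
#'   in \[0,1\]).
#' @param blur A [blur_spec()]; defaults to the 5-tap binomial kernel in Lab.
#' @return H x W nonnegative numeric matrix of class `msl_saliency`.
#' @export
ft_saliency <- function(img, blur = blur_spec()) {
  px <- if (inherits(img, "msl_image")) unclass(convert_range(img, "unit"))
        else img
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  cs <- if (blur$color_space == "Lab") rgb_to_lab(px) else px
  mu <- apply(cs, 3, mean)
  cb <- separable_blur(cs, blur$kernel1d)
  v <- sweep(cb, 3, mu)
  s <- sqrt(v[, , 1]^2 + v[, , 2]^2 + v[, , 3]^2)
  structure(s, class = "msl_saliency")
}

# Forward pass retaining intermediates, for the training-time gradient.
ft_saliency_fwd <- function(px, blur) {
  cs <- if (blur$color_space == "Lab") rgb_to_lab(px) else px
  mu <- apply(cs, 3, mean)
  cb <- separable_blur(cs, blur$kernel1d)
  v <- sweep(cb, 3, mu)
  s <- sqrt(v[, , 1]^2 + v[, , 2]^2 + v[, , 3]^2)
  list(s = s, v = v, px = px, blur = blur)
}

# grad_s: dL/dS (H x W). Returns dL/d(px) for px in [0,1].
ft_saliency_bwd <- function(fwd, grad_s) {
  v <- fwd$v
  s <- fwd$s
  safe <- pmax(s, 1e-12)
  g <- array(0, dim(v))
  for (c in 1:3) g[, , c] <- grad_s * v[, , c] / safe
  # through v = blur(cs) - mu(cs): transpose of blur is blur (symmetric,
  # modulo replicated edges) minus the mean path
  gb <- separable_blur(g, fwd$blur$kernel1d)
  n <- prod(dim(s))
  gcs <- gb
  for (c in 1:3) gcs[, , c] <- gb[, , c] - sum(g[, , c]) / n
  if (fwd$blur$color_space == "Lab")
    rgb_to_lab_backward(fwd$px, gcs)
  else gcs
}

#' Max-normalize a saliency map to \[0, 1\]
#'
#' Rescales by the maximum so the fixed binarization thresholds (0.7 for
#' saliency, 0.2 for attention) are scale-free. An all-zero map is returned
#' unchanged.
#'
#' @param s Nonnegative matrix (e.g. from [ft_saliency()]).
#' @return Matrix with maximum 1 (or all zeros), class `msl_saliency`.
#' @export
normalize_saliency <- function(s) {
  m <- max(s)
  out <- if (m > 0) unclass(s) / m else unclass(s)
  structure(out, class = "msl_saliency")
}

#' Binarize a saliency or attention map
#'
#' @param m Matrix with values in \[0,1\] (normalize first if needed).
#' @param thresh Threshold in \[0,1\]; a pixel maps to 1 iff its value is
#'   `>= thresh` (ties go to 1).
#' @return 0/1 numeric matrix.
#' @export
binarize <- function(m, thresh) {
  if (length(thresh) != 1L || is.na(thresh) || thresh < 0 || thresh > 1)
    stop("thresh must be a single value in [0, 1]", call. = FALSE)
  (unclass(m) >= thresh) * 1
}

#' Write a saliency map as an 8-bit grayscale PNG
#'
#' @param s Saliency matrix; max-normalized before encoding.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saliency <- function(s, path) {
  png::writePNG(unclass(normalize_saliency(s)), target = path)
  invisible(path)
}
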