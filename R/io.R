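# ---- readers / writers -----------------------------------------------------

#' Read an RGB photograph
#'
#' Reads a PNG or JPEG file into an [msl_image]. Channel order is RGB; 8-bit
#' (or 16-bit PNG) intensities are rescaled into the requested value range.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @param target_range `"unit"` (\[0,1\]) or `"signed"` (\[-1,1\]).
#' @param domain Optional `"source"`/`"target"` tag attached to the result.
#' @return An [msl_image].
#' @export
read_image <- function(path, target_range = c("unit", "signed"),
                       domain = NULL) {
  target_range <- match.arg(target_range)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' (PNG/JPEG only)",
         call. = FALSE))
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("expected a 3-channel RGB image, got ",
         paste(dim(px), collapse = " x "), call. = FALSE)
  img <- msl_image(px, range = "unit", domain = domain)
  convert_range(img, target_range)
}

#' Write an RGB photograph
#'
#' @param img An [msl_image]; converted to \[0,1\] before encoding.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- convert_range(img, "unit")
  png::writePNG(unclass(img), target = path)
  invisible(path)
}

#' Read a segmentation label map
#'
#' Label maps are stored as single-channel 8-bit grayscale PNG files whose
#' raw pixel value is the class id (0 = background, 1 = disc, 2 = cord,
#' 3 = ruler). This keeps the file lossless and round-trippable bit-exactly.
#'
#' @param path Path to the label PNG.
#' @return An [msl_labelmap].
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    if (!all(abs(px[, , 1] - px[, , 2]) < 1e-9) ||
        !all(abs(px[, , 1] - px[, , 3]) < 1e-9))
      stop("label map PNG has non-identical channels: ", path, call. = FALSE)
    px <- px[, , 1]
  }
  ids <- round(px * 255)
  bad <- ids > 3
  if (any(bad))
    stop(sprintf("label map contains class id(s) >= 4: %s",
                 paste(sort(unique(ids[bad])), collapse = ", ")),
         call. = FALSE)
  msl_labelmap(ids)
}

#' Write a segmentation label map
#'
#' Inverse of [read_label_map()]; the round trip is bit-exact.
#'
#' @param lab An [msl_labelmap].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lab, path) {
  stopifnot(inherits(lab, "msl_labelmap"))
  png::writePNG(unclass(lab) / 255, target = path)
  invisible(path)
}

#' Render a label map as a color overlay image
#'
#' Convenience for visual inspection: background dark, disc red, cord pink,
#' ruler yellow.
#'
#' @param lab An [msl_labelmap].
#' @return An H x W x 3 array in \[0,1\].
#' @export
colorize_label_map <- function(lab) {
  stopifnot(inherits(lab, "msl_labelmap"))
  pal <- rbind(c(0.15, 0.15, 0.15), c(0.8, 0.15, 0.15),
               c(0.95, 0.6, 0.7), c(0.95, 0.9, 0.2))
  h <- nrow(lab); w <- ncol(lab)
  out <- array(0, c(h, w, 3))
  idx <- unclass(lab) + 1L
  for (c in 1:3) out[, , c] <- matrix(pal[idx, c], h, w)
  out
}
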