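# Brute-force oracles: explicit per-pixel / per-class loops, kept deliberately
# naive and independent of the package's vectorized implementations.

oracle_ft_saliency <- function(px_unit, kernel1d, color_space) {
  h <- dim(px_unit)[1]; w <- dim(px_unit)[2]
  cs <- if (color_space == "Lab") msl:::rgb_to_lab(px_unit) else px_unit
  mu <- c(mean(cs[, , 1]), mean(cs[, , 2]), mean(cs[, , 3]))
  blur1px <- function(m, i, j) {
    r <- (length(kernel1d) - 1) / 2
    acc <- 0
    for (a in seq_along(kernel1d)) for (b in seq_along(kernel1d)) {
      ii <- min(max(i + a - 1 - r, 1), h)
      jj <- min(max(j + b - 1 - r, 1), w)
      acc <- acc + kernel1d[a] * kernel1d[b] * m[ii, jj]
    }
    acc
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- numeric(3)
    for (c in 1:3)
      v[c] <- (if (is.null(kernel1d)) cs[i, j, c] else blur1px(cs[, , c], i, j)) - mu[c]
    out[i, j] <- sqrt(sum(v^2))
  }
  out
}

oracle_mean_l1 <- function(a, b) {
  acc <- 0
  for (k in seq_along(a)) acc <- acc + abs(a[k] - b[k])
  acc / length(a)
}

oracle_saliency_dice <- function(ref, tr) {
  num <- 0; den <- 0
  for (k in seq_along(ref)) {
    num <- num + ref[k] * tr[k]
    den <- den + ref[k] + tr[k]
  }
  if (den == 0) 0 else 1 - num / den
}

oracle_seg_dice <- function(p, g) {
  num <- 0; den <- 0
  h <- dim(p)[1]; w <- dim(p)[2]
  for (i in seq_len(h)) for (j in seq_len(w)) for (k in 1:4) {
    num <- num + p[i, j, k] * g[i, j, k]
    den <- den + p[i, j, k] + g[i, j, k]
  }
  1 - num / den
}

oracle_confusion <- function(gt, pred) {
  cm <- matrix(0L, 4, 4)
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt)))
    cm[gt[i, j] + 1L, pred[i, j] + 1L] <- cm[gt[i, j] + 1L, pred[i, j] + 1L] + 1L
  cm
}

random_probs <- function(h, w) {
  z <- array(stats::rexp(h * w * 4), c(h, w, 4))
  s <- z[, , 1] + z[, , 2] + z[, , 3] + z[, , 4]
  for (k in 1:4) z[, , k] <- z[, , k] / s
  z
}

random_labelmap <- function(h, w) {
  msl_labelmap(matrix(sample(0:3, h * w, replace = TRUE), h, w))
}

random_unit_image <- function(h, w, domain = NULL) {
  msl_image(array(stats::runif(h * w * 3), c(h, w, 3)), "unit", domain)
}
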