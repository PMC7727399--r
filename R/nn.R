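# ---- compact CPU conv-net engine -------------------------------------------
#
# Minimal layer library used by the translation and segmentation networks.
# Feature maps are H x W x C numeric arrays. Convolution is evaluated as a
# sum of k*k channel-matrix products (one per kernel offset), which keeps
# everything inside BLAS; backward passes are analytic. Layers are
# environments so parameter gradients and optimizer state mutate in place;
# forward passes return an explicit cache so the same network can appear at
# several points of a computation graph within one training step.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (n in names(fields)) assign(n, fields[[n]], envir = e)
  class(e) <- c(paste0("msl_", type), "msl_layer")
  e
}

he_init <- function(k, cin, cout, gain = 2) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
        c(k, k, cin, cout))
}

layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                       init_gain = 2) {
  new_layer("conv", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), cin = cin, cout = cout,
            W = he_init(k, cin, cout, init_gain), b = numeric(cout),
            gW = NULL, gb = NULL)
}

layer_act <- function(fun = c("relu", "lrelu", "tanh", "sigmoid")) {
  new_layer("act", fun = match.arg(fun))
}

layer_inorm <- function(c) {
  new_layer("inorm", g = rep(1, c), b = numeric(c), gg = NULL, gb = NULL)
}

layer_upsample2 <- function() new_layer("upsample2")

pad_array <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

layer_forward <- function(l, x) {
  switch(l$type,
    conv = {
      if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
      xp <- pad_array(x, l$pad)
      dp <- dim(xp)
      ho <- (dp[1] - l$k) %/% l$stride + 1L
      wo <- (dp[2] - l$k) %/% l$stride + 1L
      n <- ho * wo
      y <- matrix(l$b, n, l$cout, byrow = TRUE)
      for (a in seq_len(l$k)) for (bb in seq_len(l$k)) {
        rows <- seq.int(a, by = l$stride, length.out = ho)
        cols <- seq.int(bb, by = l$stride, length.out = wo)
        xb <- matrix(xp[rows, cols, ], n, l$cin)
        y <- y + xb %*% matrix(l$W[a, bb, , ], l$cin, l$cout)
      }
      list(out = array(y, c(ho, wo, l$cout)), cache = list(xp = xp, ho = ho, wo = wo))
    },
    act = {
      out <- switch(l$fun,
        relu = pmax(x, 0),
        lrelu = ifelse(x > 0, x, 0.2 * x),
        tanh = tanh(x),
        sigmoid = 1 / (1 + exp(-x)))
      list(out = out, cache = list(x = x, out = out))
    },
    inorm = {
      d <- dim(x)
      n <- d[1] * d[2]
      xm <- matrix(x, n, d[3])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      sd_ <- sqrt(colMeans(xc^2) + 1e-5)
      xhat <- sweep(xc, 2, sd_, "/")
      y <- sweep(sweep(xhat, 2, l$g, "*"), 2, l$b, "+")
      list(out = array(y, d), cache = list(xhat = xhat, sd = sd_, d = d))
    },
    upsample2 = {
      d <- dim(x)
      ri <- rep(seq_len(d[1]), each = 2L)
      ci <- rep(seq_len(d[2]), each = 2L)
      list(out = x[ri, ci, , drop = FALSE], cache = list(d = d))
    },
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, cache, dy) {
  switch(l$type,
    conv = {
      xp <- cache$xp
      dp <- dim(xp)
      n <- cache$ho * cache$wo
      dyM <- matrix(dy, n, l$cout)
      if (is.null(l$gW)) { l$gW <- array(0, dim(l$W)); l$gb <- numeric(l$cout) }
      l$gb <- l$gb + colSums(dyM)
      dxp <- array(0, dp)
      for (a in seq_len(l$k)) for (bb in seq_len(l$k)) {
        rows <- seq.int(a, by = l$stride, length.out = cache$ho)
        cols <- seq.int(bb, by = l$stride, length.out = cache$wo)
        xb <- matrix(xp[rows, cols, ], n, l$cin)
        Wb <- matrix(l$W[a, bb, , ], l$cin, l$cout)
        l$gW[a, bb, , ] <- matrix(l$gW[a, bb, , ], l$cin, l$cout) +
          crossprod(xb, dyM)
        dxp[rows, cols, ] <- dxp[rows, cols, ] +
          array(dyM %*% t(Wb), c(cache$ho, cache$wo, l$cin))
      }
      p <- l$pad
      if (p > 0L)
        dxp[p + seq_len(dp[1] - 2L * p), p + seq_len(dp[2] - 2L * p), ,
            drop = FALSE]
      else dxp
    },
    act = {
      x <- cache$x; out <- cache$out
      dy * switch(l$fun,
        relu = (x > 0) * 1,
        lrelu = ifelse(x > 0, 1, 0.2),
        tanh = 1 - out^2,
        sigmoid = out * (1 - out))
    },
    inorm = {
      d <- cache$d
      n <- d[1] * d[2]
      dyM <- matrix(dy, n, d[3])
      if (is.null(l$gg)) { l$gg <- numeric(d[3]); l$gb <- numeric(d[3]) }
      l$gg <- l$gg + colSums(dyM * cache$xhat)
      l$gb <- l$gb + colSums(dyM)
      dxhat <- sweep(dyM, 2, l$g, "*")
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cache$xhat)
      dx <- sweep(sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, "*"),
                  2, cache$sd, "/")
      array(dx, d)
    },
    upsample2 = {
      d <- cache$d
      dx <- array(0, d)
      for (a in 0:1) for (bb in 0:1)
        dx <- dx + dy[seq.int(1L + a, by = 2L, length.out = d[1]),
                      seq.int(1L + bb, by = 2L, length.out = d[2]), ,
                      drop = FALSE]
      dx
    },
    stop("unknown layer type: ", l$type))
}

# ---- network containers ----------------------------------------------------
# A network is a chain of parts; a part is a layer, a residual block, or a
# nested chain. Dispatch is explicit (inherits), not S3.

# Residual block: out = x + inner(x); inner must preserve shape.
nn_res <- function(inner) structure(list(inner = inner), class = "msl_res")

nn_chain <- function(...) structure(list(parts = list(...)), class = "msl_chain")

net_forward <- function(net, x) {
  if (inherits(net, "msl_layer")) {
    f <- layer_forward(net, x)
    return(list(out = f$out, caches = f$cache))
  }
  if (inherits(net, "msl_res")) {
    f <- net_forward(net$inner, x)
    return(list(out = x + f$out, caches = f$caches))
  }
  caches <- vector("list", length(net$parts))
  for (i in seq_along(net$parts)) {
    f <- net_forward(net$parts[[i]], x)
    x <- f$out
    caches[[i]] <- f$caches
  }
  list(out = x, caches = caches)
}

net_backward <- function(net, caches, dy) {
  if (inherits(net, "msl_layer")) return(layer_backward(net, caches, dy))
  if (inherits(net, "msl_res"))
    return(dy + net_backward(net$inner, caches, dy))
  for (i in rev(seq_along(net$parts)))
    dy <- net_backward(net$parts[[i]], caches[[i]], dy)
  dy
}

net_layers <- function(net) {
  if (inherits(net, "msl_layer")) return(list(net))
  if (inherits(net, "msl_res")) return(net_layers(net$inner))
  unlist(lapply(net$parts, net_layers), recursive = FALSE)
}

# ---- optimizer -------------------------------------------------------------

zero_grads <- function(net) {
  for (l in net_layers(net)) {
    if (l$type == "conv") { l$gW <- array(0, dim(l$W)); l$gb <- numeric(l$cout) }
    if (l$type == "inorm") { l$gg <- numeric(length(l$g)); l$gb <- numeric(length(l$b)) }
  }
  invisible(net)
}

adam_state <- function(nets) {
  structure(list(t = 0L, beta1 = 0.5, beta2 = 0.999, eps = 1e-8,
                 nets = nets), class = "msl_adam")
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  upd <- function(l, p, g, m, v) {
    if (is.null(l[[g]])) return()
    if (is.null(l[[m]])) { l[[m]] <- l[[p]] * 0; l[[v]] <- l[[p]] * 0 }
    l[[m]] <- b1 * l[[m]] + (1 - b1) * l[[g]]
    l[[v]] <- b2 * l[[v]] + (1 - b2) * l[[g]]^2
    l[[p]] <- l[[p]] - lr * (l[[m]] / corr1) / (sqrt(l[[v]] / corr2) + opt$eps)
  }
  for (net in opt$nets) for (l in net_layers(net)) {
    if (l$type == "conv") { upd(l, "W", "gW", "mW", "vW"); upd(l, "b", "gb", "mb", "vb") }
    if (l$type == "inorm") { upd(l, "g", "gg", "mg", "vg"); upd(l, "b", "gb", "mb", "vb") }
  }
  invisible(opt)
}

# ---- (de)serialization -----------------------------------------------------

net_state <- function(net) {
  lapply(net_layers(net), function(l) {
    if (l$type == "conv") list(type = "conv", W = l$W, b = l$b)
    else if (l$type == "inorm") list(type = "inorm", g = l$g, b = l$b)
    else list(type = l$type)
  })
}

net_load_state <- function(net, state) {
  ls <- net_layers(net)
  stopifnot(length(ls) == length(state))
  for (i in seq_along(ls)) {
    l <- ls[[i]]; s <- state[[i]]
    stopifnot(identical(l$type, s$type))
    if (l$type == "conv") { l$W <- s$W; l$b <- s$b }
    if (l$type == "inorm") { l$g <- s$g; l$b <- s$b }
  }
  invisible(net)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
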