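# The layer system of the training engine.  A module is a plain list with a
# `type`, a `params` list of weight arrays, and (for composites) a `children`
# list of sub-modules.  `.modFwd()` returns the output plus a cache;
# `.modBwd()` consumes the cache and returns the input gradient and a gradient
# tree mirroring the module tree.  Batch-norm running statistics live in an
# environment so they update in place during forward passes.
#
# All activations travel as (C, H, W, N) arrays until global average pooling
# collapses them to (C, N) matrices.

.mkConv <- function(kh, kw, cin, cout, stride = 1L, groups = 1L, rng = NULL,
                    stage = "") {
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop(sprintf("stage '%s': groups = %d must divide input (%d) and output (%d) channels",
                 stage, groups, cin, cout))
  cinG <- cin %/% groups
  n <- kh * kw * cinG * cout
  W <- if (is.null(rng)) array(0, c(kh, kw, cinG, cout))
  else array(rng$rnorm(n, sd = sqrt(2 / (kh * kw * cinG))), c(kh, kw, cinG, cout))
  list(type = "conv", params = list(W = W),
       stride = as.integer(stride), groups = as.integer(groups))
}

# Batch-norm statistics mode: during a recalibration pass the per-batch
# moments are accumulated into plain sums instead of the exponential moving
# average, so the running statistics can be set to exact training-set moments
# after the last optimisation step.
.bnMode <- new.env(parent = emptyenv())
.bnMode$collect <- FALSE

# act >= 0 fuses a Leaky ReLU with that negative-region slope after the
# affine transform (saves a full pass over the activations); act = -1 is
# plain batch norm.
.mkBN <- function(C, act = -1) {
  st <- new.env(parent = emptyenv())
  st$rmean <- numeric(C)
  st$rvar <- rep(1, C)
  list(type = "bn", params = list(gamma = rep(1, C), beta = numeric(C)),
       state = st, eps = 1e-5, momentum = 0.1, act = act)
}

.mkAct <- function(slope = 0.01) list(type = "act", slope = slope)

.mkPool <- function(z = 3L, stride = 2L)
  list(type = "pool", z = as.integer(z), stride = as.integer(stride))

.mkLRN <- function(t = 2, alpha = 1e-4, beta = 0.75, n = 5L)
  list(type = "lrn", t = t, alpha = alpha, beta = beta, n = as.integer(n))

.mkGAP <- function() list(type = "gap")

.mkDense <- function(cin, k, rng = NULL) {
  W <- if (is.null(rng)) matrix(0, k, cin)
  else matrix(rng$rnorm(k * cin, sd = sqrt(2 / cin)), k, cin)
  list(type = "dense", params = list(W = W, b = numeric(k)))
}

# Bottleneck block: 1x1 reduce -> 3x3 grouped (carries the stride) -> 1x1
# expand, each followed by batch norm; Leaky ReLU after the first two and
# after the residual addition.  Shortcut is the identity when shapes match,
# otherwise a 1x1 projection (+ BN).
.mkBlock <- function(cin, cmid, cout, groups, stride, slope, rng, stage = "") {
  ch <- list(
    c1 = .mkConv(1L, 1L, cin, cmid, 1L, 1L, rng, stage),
    b1 = .mkBN(cmid, act = slope),
    c2 = .mkConv(3L, 3L, cmid, cmid, stride, groups, rng, stage),
    b2 = .mkBN(cmid, act = slope),
    c3 = .mkConv(1L, 1L, cmid, cout, 1L, 1L, rng, stage), b3 = .mkBN(cout))
  if (cin != cout || stride != 1L) {
    ch$sc <- .mkConv(1L, 1L, cin, cout, stride, 1L, rng, stage)
    ch$sbn <- .mkBN(cout)
  }
  list(type = "block", children = ch, slope = slope)
}

.mkSeq <- function(children) list(type = "seq", children = children)

# ---- forward ---------------------------------------------------------------

.modFwd <- function(mod, x, training = FALSE) {
  switch(mod$type,
    conv = {
      y <- .conv2dFwd(x, dim(x), mod$params$W, dim(mod$params$W),
                      mod$stride, mod$groups)
      list(y = y, cache = list(x = x))
    },
    bn = {
      C <- dim(x)[1]
      if (training) {
        stt <- .chanStats(x, C)
        mu <- stt$mean
        v <- pmax(stt$meansq - mu * mu, 0)
        st <- mod$state
        if (.bnMode$collect) {
          m <- length(x) / C              # elements per channel in this batch
          st$cnt <- (if (is.null(st$cnt)) 0 else st$cnt) + m
          st$sumM <- (if (is.null(st$sumM)) 0 else st$sumM) + mu * m
          st$sumM2 <- (if (is.null(st$sumM2)) 0 else st$sumM2) + stt$meansq * m
        } else {
          st$rmean <- (1 - mod$momentum) * st$rmean + mod$momentum * mu
          st$rvar <- (1 - mod$momentum) * st$rvar + mod$momentum * v
        }
      } else {
        mu <- mod$state$rmean
        v <- mod$state$rvar
      }
      invstd <- 1 / sqrt(v + mod$eps)
      r <- .bnFwd(x, C, mod$params$gamma, mod$params$beta, mu, invstd, mod$act)
      list(y = r$y, cache = list(xhat = r$xhat, invstd = invstd))
    },
    act = {
      list(y = .leakyFwd(x, mod$slope), cache = list(x = x))
    },
    pool = {
      r <- .maxpoolFwd(x, dim(x), mod$z, mod$stride)
      list(y = r$y, cache = list(arg = r$arg, xdim = dim(x)))
    },
    lrn = {
      r <- .lrnFwd(x, dim(x)[1], mod$t, mod$alpha, mod$beta, mod$n)
      list(y = r$y, cache = list(x = x, D = r$D))
    },
    gap = {
      d <- dim(x)
      xm <- aperm(x, c(2L, 3L, 1L, 4L))
      list(y = colMeans(xm, dims = 2L), cache = list(xdim = d))
    },
    dense = {
      y <- mod$params$W %*% x + mod$params$b
      list(y = y, cache = list(x = x))
    },
    block = .blockFwd(mod, x, training),
    attention = .attnFwd(mod, x, training),
    seq = {
      caches <- vector("list", length(mod$children))
      for (i in seq_along(mod$children)) {
        r <- .modFwd(mod$children[[i]], x, training)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    stop("unknown module type: ", mod$type))
}

.blockFwd <- function(mod, x, training) {
  ch <- mod$children
  cc <- list()
  r <- .modFwd(ch$c1, x, training); cc$c1 <- r$cache
  r <- .modFwd(ch$b1, r$y, training); cc$b1 <- r$cache
  r <- .modFwd(ch$c2, r$y, training); cc$c2 <- r$cache
  r <- .modFwd(ch$b2, r$y, training); cc$b2 <- r$cache
  r <- .modFwd(ch$c3, r$y, training); cc$c3 <- r$cache
  r <- .modFwd(ch$b3, r$y, training); cc$b3 <- r$cache
  h <- r$y
  if (!is.null(ch$sc)) {
    rs <- .modFwd(ch$sc, x, training); cc$sc <- rs$cache
    rs <- .modFwd(ch$sbn, rs$y, training); cc$sbn <- rs$cache
    sh <- rs$y
  } else sh <- x
  y <- .addActFwd(h, sh, mod$slope)
  cc$y <- y
  list(y = y, cache = cc)
}

# ---- backward --------------------------------------------------------------

.modBwd <- function(mod, cache, dy) {
  switch(mod$type,
    conv = {
      r <- .conv2dBwd(cache$x, dim(cache$x), mod$params$W, dim(mod$params$W),
                      dy, mod$stride, mod$groups)
      list(dx = r$dx, grads = list(params = list(W = r$dw)))
    },
    bn = {
      r <- .bnBwd(cache$xhat, dy, dim(cache$xhat)[1], mod$params$gamma,
                  mod$params$beta, cache$invstd, mod$act)
      list(dx = r$dx,
           grads = list(params = list(gamma = r$dgamma, beta = r$dbeta)))
    },
    act = list(dx = .leakyBwd(cache$x, dy, mod$slope), grads = NULL),
    pool = list(dx = .maxpoolBwd(dy, cache$arg, cache$xdim), grads = NULL),
    lrn = {
      list(dx = .lrnBwd(cache$x, dy, cache$D, dim(cache$x)[1],
                        mod$alpha, mod$beta, mod$n), grads = NULL)
    },
    gap = {
      d <- cache$xdim
      dx <- array(0, d)
      hw <- d[2] * d[3]
      for (n in seq_len(d[4])) dx[, , , n] <- dy[, n] / hw
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = t(mod$params$W) %*% dy,
           grads = list(params = list(W = dy %*% t(cache$x), b = rowSums(dy))))
    },
    block = .blockBwd(mod, cache, dy),
    attention = .attnBwd(mod, cache, dy),
    seq = {
      grads <- vector("list", length(mod$children))
      for (i in rev(seq_along(mod$children))) {
        r <- .modBwd(mod$children[[i]], cache[[i]], dy)
        dy <- r$dx
        grads[i] <- list(r$grads)
      }
      names(grads) <- names(mod$children)
      list(dx = dy, grads = list(children = grads))
    },
    stop("unknown module type: ", mod$type))
}

.blockBwd <- function(mod, cache, dy) {
  ch <- mod$children
  ds <- .addActBwd(cache$y, dy, mod$slope)
  g <- list()
  r <- .modBwd(ch$b3, cache$b3, ds); g$b3 <- r$grads
  r <- .modBwd(ch$c3, cache$c3, r$dx); g$c3 <- r$grads
  r <- .modBwd(ch$b2, cache$b2, r$dx); g$b2 <- r$grads
  r <- .modBwd(ch$c2, cache$c2, r$dx); g$c2 <- r$grads
  r <- .modBwd(ch$b1, cache$b1, r$dx); g$b1 <- r$grads
  r <- .modBwd(ch$c1, cache$c1, r$dx); g$c1 <- r$grads
  dxMain <- r$dx
  if (!is.null(ch$sc)) {
    rs <- .modBwd(ch$sbn, cache$sbn, ds); g$sbn <- rs$grads
    rs <- .modBwd(ch$sc, cache$sc, rs$dx); g$sc <- rs$grads
    dx <- dxMain + rs$dx
  } else dx <- dxMain + ds
  list(dx = dx, grads = list(children = g))
}

# ---- parameter bookkeeping -------------------------------------------------

# Flatten every weight array in a module tree into a named list (path -> array).
.gatherParams <- function(mod, path = "") {
  out <- list()
  if (!is.null(mod$params))
    for (p in names(mod$params)) out[[paste0(path, "/", p)]] <- mod$params[[p]]
  if (!is.null(mod$children))
    for (nm in names(mod$children))
      if (!is.null(mod$children[[nm]]))
        out <- c(out, .gatherParams(mod$children[[nm]], paste0(path, "/", nm)))
  out
}

.setParams <- function(mod, flat, path = "") {
  if (!is.null(mod$params))
    for (p in names(mod$params)) {
      key <- paste0(path, "/", p)
      if (!is.null(flat[[key]])) mod$params[[p]] <- flat[[key]]
    }
  if (!is.null(mod$children))
    for (nm in names(mod$children))
      if (!is.null(mod$children[[nm]]))
        mod$children[[nm]] <- .setParams(mod$children[[nm]], flat, paste0(path, "/", nm))
  mod
}

# Batch-norm running statistics, keyed like .gatherParams().
.gatherBNState <- function(mod, path = "") {
  out <- list()
  if (identical(mod$type, "bn"))
    out[[path]] <- list(rmean = mod$state$rmean, rvar = mod$state$rvar)
  if (!is.null(mod$children))
    for (nm in names(mod$children))
      if (!is.null(mod$children[[nm]]))
        out <- c(out, .gatherBNState(mod$children[[nm]], paste0(path, "/", nm)))
  out
}

.setBNState <- function(mod, flat, path = "") {
  if (identical(mod$type, "bn") && !is.null(flat[[path]])) {
    mod$state$rmean <- flat[[path]]$rmean
    mod$state$rvar <- flat[[path]]$rvar
  }
  if (!is.null(mod$children))
    for (nm in names(mod$children))
      if (!is.null(mod$children[[nm]]))
        mod$children[[nm]] <- .setBNState(mod$children[[nm]], flat, paste0(path, "/", nm))
  mod
}

# Replace the EMA batch-norm running statistics with element-weighted exact
# moments gathered over the full (training) tensor, batch by batch.  Removes
# the train/inference statistics mismatch that an exponential average leaves
# on small datasets.  Large calibration batches keep the pass close to a
# single full-set forward (upstream normalisation inside the pass still uses
# per-batch statistics).
.recalibrateBN <- function(mods, x, batchSize) {
  walk <- function(mod, f) {
    if (identical(mod$type, "bn")) f(mod$state)
    if (!is.null(mod$children)) for (ch in mod$children) if (!is.null(ch)) walk(ch, f)
  }
  root <- list(type = "seq", children = mods)
  walk(root, function(st) { st$cnt <- 0; st$sumM <- 0; st$sumM2 <- 0 })
  .bnMode$collect <- TRUE
  on.exit(.bnMode$collect <- FALSE)
  n <- dim(x)[4]
  bs <- min(n, max(batchSize, 64L))
  for (i0 in seq(1L, n, by = bs)) {
    idx <- i0:min(i0 + bs - 1L, n)
    .netForward(mods, x[, , , idx, drop = FALSE], training = TRUE)
  }
  walk(root, function(st) {
    if (st$cnt > 0) {
      m1 <- st$sumM / st$cnt
      st$rmean <- m1
      st$rvar <- pmax(st$sumM2 / st$cnt - m1 * m1, 0)
    }
    st$cnt <- NULL; st$sumM <- NULL; st$sumM2 <- NULL
  })
  invisible(mods)
}

# ---- optimisers ------------------------------------------------------------

.optimInit <- function() new.env(parent = emptyenv())

.optimStep <- function(mod, grads, st, optimizer, lr, t, path = "") {
  if (!is.null(grads$params) && !is.null(mod$params)) {
    for (p in names(grads$params)) {
      g <- grads$params[[p]]
      key <- paste0(path, "/", p)
      if (optimizer == "adam") {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        m <- st[[paste0(key, ".m")]]; if (is.null(m)) m <- 0
        v <- st[[paste0(key, ".v")]]; if (is.null(v)) v <- 0
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g * g
        st[[paste0(key, ".m")]] <- m
        st[[paste0(key, ".v")]] <- v
        upd <- lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
      } else {                                   # SGD with momentum 0.9
        m <- st[[paste0(key, ".m")]]; if (is.null(m)) m <- 0
        m <- 0.9 * m + g
        st[[paste0(key, ".m")]] <- m
        upd <- lr * m
      }
      mod$params[[p]] <- mod$params[[p]] - upd
    }
  }
  if (!is.null(grads$children) && !is.null(mod$children)) {
    for (nm in names(grads$children)) {
      if (!is.null(grads$children[[nm]]))
        mod$children[[nm]] <- .optimStep(mod$children[[nm]], grads$children[[nm]],
                                         st, optimizer, lr, t, paste0(path, "/", nm))
    }
  }
  mod
}
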