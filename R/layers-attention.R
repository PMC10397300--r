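# Training-time attention block: channel shuffle -> grouped residual attention
# (shared 3x3 conv K over rotated subgroups, Hadamard-modulated by the
# subgroup-0 response) -> per-group channel gates from shared FC layers ->
# spatial gate from the channel-pooled average/max descriptor.  Channel count
# is preserved: groups are reassembled by concatenation after gating, so the
# block can sit on the residual trunk of any stage.

.rot90ccw4 <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(1L, 3L, 2L, 4L))
  y[, rev(seq_len(d[2])), , , drop = FALSE]
}

.rot4 <- function(x, r) {
  for (i in seq_len(r %% 4L)) x <- .rot90ccw4(x)
  x
}

.mkAttention <- function(C, N = 4L, S = 4L, reduction = 16L, rng = NULL,
                         variant = "concat", stage = "") {
  if (C %% (N * S) != 0L)
    stop(sprintf("stage '%s': attention groups N*S = %d must divide %d channels",
                 stage, N * S, C))
  Cg <- C %/% N
  cs <- Cg %/% S
  hidden <- max(1L, as.integer(ceiling(Cg / reduction)))
  scIn <- if (variant == "concat") 2L else 1L
  mk <- function(n, fan) {
    if (is.null(rng)) numeric(n) else rng$rnorm(n, sd = sqrt(2 / fan))
  }
  pos <- .shufflePerm(C, N, S)
  c0 <- 0:(C - 1L)
  sIdx <- (c0 %% Cg) %/% cs
  params <- list(
    K = array(mk(9L * cs * cs, 9 * cs), c(3L, 3L, cs, cs)),
    fc1W = matrix(mk(hidden * Cg, Cg), hidden, Cg), fc1b = numeric(hidden),
    fc2W = matrix(mk(Cg * hidden, hidden), Cg, hidden), fc2b = numeric(Cg),
    spW = array(mk(9L * scIn, 9 * scIn), c(3L, 3L, scIn, 1L)), spb = 0)
  list(type = "attention", params = params,
       C = as.integer(C), N = as.integer(N), S = as.integer(S),
       Cg = as.integer(Cg), cs = as.integer(cs), variant = variant,
       shufFrom = order(pos),                        # xs = x[shufFrom, , , ]
       chS = lapply(0:(S - 1L), function(s) which(sIdx == s)),
       pairIdx = (c0 %/% Cg) * Cg + (c0 %% cs) + 1L)
}

.attnTiledK <- function(mod) {
  NS <- mod$N * mod$S
  cs <- mod$cs
  Kt <- array(0, c(3L, 3L, cs, cs * NS))
  for (g in seq_len(NS)) Kt[, , , (g - 1L) * cs + seq_len(cs)] <- mod$params$K
  Kt
}

.attnFwd <- function(mod, x, training) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; Nb <- d[4]
  if (H != W) stop("attention block requires a square spatial map")
  S <- mod$S; Cg <- mod$Cg

  xs <- x[mod$shufFrom, , , , drop = FALSE]
  xr <- xs
  for (s in seq_len(S - 1L)) {
    ch <- mod$chS[[s + 1L]]
    xr[ch, , , ] <- .rot4(xs[ch, , , , drop = FALSE], s)
  }
  Kt <- .attnTiledK(mod)
  z <- .conv2dFwd(xr, dim(xr), Kt, dim(Kt), 1L, mod$N * S)

  tt <- z * z[mod$pairIdx, , , , drop = FALSE]
  ch0 <- mod$chS[[1L]]
  tt[ch0, , , ] <- z[ch0, , , , drop = FALSE]

  # channel gates: spatial GAP -> shared FC (ReLU) -> shared FC (sigmoid)
  p <- colMeans(aperm(tt, c(2L, 3L, 1L, 4L)), dims = 2L)      # (C, Nb)
  pg <- matrix(p, Cg)                                          # (Cg, N*Nb)
  hr <- pmax(mod$params$fc1W %*% pg + mod$params$fc1b, 0)
  a <- .sigmoid(mod$params$fc2W %*% hr + mod$params$fc2b)      # (Cg, N*Nb)
  aC <- matrix(as.vector(a), C, Nb)
  aexp <- array(0, d)
  for (nb in seq_len(Nb)) aexp[, , , nb] <- aC[, nb]
  u <- tt * aexp

  # spatial gate from channel-pooled average and max maps
  cm <- colMeans(u, dims = 1L)                                 # (H, W, Nb)
  P <- H * W * Nb
  um <- matrix(u, C)
  mi <- max.col(t(um), ties.method = "first")
  mxv <- um[mi + (seq_len(P) - 1L) * C]
  scIn <- if (mod$variant == "concat") 2L else 1L
  sc <- array(0, c(scIn, H, W, Nb))
  if (scIn == 2L) {
    sc[1L, , , ] <- cm
    sc[2L, , , ] <- mxv
  } else sc[1L, , , ] <- cm + mxv
  m <- .conv2dFwd(sc, dim(sc), mod$params$spW, dim(mod$params$spW), 1L, 1L) +
    mod$params$spb
  g <- .sigmoid(m)                                             # (1, H, W, Nb)
  gv <- as.vector(g)
  y <- u * rep(gv, each = C)

  list(y = y,
       cache = list(xr = xr, z = z, tt = tt, pg = pg, hr = hr, a = a,
                    aexp = aexp, u = u, sc = sc, gv = gv, mi = mi, d = d))
}

.attnBwd <- function(mod, cache, dy) {
  d <- cache$d
  C <- d[1]; H <- d[2]; W <- d[3]; Nb <- d[4]
  S <- mod$S; Cg <- mod$Cg
  P <- H * W * Nb
  gv <- cache$gv

  du <- dy * rep(gv, each = C)
  dgate <- colSums(dy * cache$u, dims = 1L)                    # (H, W, Nb)
  dm <- array(as.vector(dgate) * gv * (1 - gv), c(1L, H, W, Nb))
  rs <- .conv2dBwd(cache$sc, dim(cache$sc), mod$params$spW,
                   dim(mod$params$spW), dm, 1L, 1L)
  dspW <- rs$dw
  dspb <- sum(dm)
  if (mod$variant == "concat") {
    davg <- rs$dx[1L, , , , drop = FALSE]
    dmax <- rs$dx[2L, , , , drop = FALSE]
  } else {
    davg <- rs$dx
    dmax <- rs$dx
  }
  du <- du + rep(as.vector(davg) / C, each = C)
  dum <- numeric(C * P)
  dum[cache$mi + (seq_len(P) - 1L) * C] <- as.vector(dmax)
  du <- du + array(dum, d)

  # channel-gate backward
  dt <- du * cache$aexp
  tmp <- du * cache$tt
  dim(tmp) <- c(C, H * W, Nb)
  daC <- matrix(0, C, Nb)
  for (nb in seq_len(Nb)) daC[, nb] <- rowSums(tmp[, , nb, drop = FALSE])
  da <- matrix(as.vector(daC), Cg)
  aS <- cache$a
  dq <- da * aS * (1 - aS)
  dfc2W <- dq %*% t(cache$hr)
  dfc2b <- rowSums(dq)
  dh <- t(mod$params$fc2W) %*% dq
  dh[cache$hr <= 0] <- 0
  dfc1W <- dh %*% t(cache$pg)
  dfc1b <- rowSums(dh)
  dp <- t(mod$params$fc1W) %*% dh                              # (Cg, N*Nb)
  dpC <- matrix(as.vector(dp), C, Nb)
  hw <- H * W
  for (nb in seq_len(Nb)) dt[, , , nb] <- dt[, , , nb] + dpC[, nb] / hw

  # residual-attention backward (product rule through the y0 modulation)
  z <- cache$z
  dz <- dt * z[mod$pairIdx, , , , drop = FALSE]
  ch0 <- mod$chS[[1L]]
  dz[ch0, , , ] <- dt[ch0, , , , drop = FALSE]
  for (s in seq_len(S - 1L)) {
    ch <- mod$chS[[s + 1L]]
    dz[ch0, , , ] <- dz[ch0, , , , drop = FALSE] +
      dt[ch, , , , drop = FALSE] * z[ch, , , , drop = FALSE]
  }
  Kt <- .attnTiledK(mod)
  rk <- .conv2dBwd(cache$xr, dim(cache$xr), Kt, dim(Kt), dz, 1L, mod$N * S)
  dKt <- rk$dw
  dim(dKt) <- c(9L * mod$cs * mod$cs, mod$N * S)
  dK <- array(rowSums(dKt), c(3L, 3L, mod$cs, mod$cs))

  dxs <- rk$dx
  for (s in seq_len(S - 1L)) {
    ch <- mod$chS[[s + 1L]]
    dxs[ch, , , ] <- .rot4(rk$dx[ch, , , , drop = FALSE], (4L - s) %% 4L)
  }
  dx <- array(0, d)
  dx[mod$shufFrom, , , ] <- dxs

  list(dx = dx,
       grads = list(params = list(K = dK, fc1W = dfc1W, fc1b = dfc1b,
                                  fc2W = dfc2W, fc2b = dfc2b,
                                  spW = dspW, spb = dspb)))
}
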