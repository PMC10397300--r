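# Independent brute-force oracles used to verify the package's vectorised /
# compiled implementations.  Everything here is written as plainly as
# possible (explicit loops, direct formulas) and never calls the code paths
# it is used to check.

# Plain convolution of a (C, H, W) tensor with weights (kh, kw, Cin/g, Cout),
# "same" padding with ceil-mode output sizes, zero fill.
oracleConv <- function(x, W, stride = 1L, groups = 1L) {
  d <- dim(x); C <- d[1]; H <- d[2]; Wd <- d[3]
  kh <- dim(W)[1]; kw <- dim(W)[2]; cinG <- dim(W)[3]; cout <- dim(W)[4]
  coutG <- cout %/% groups
  Ho <- ceiling(H / stride); Wo <- ceiling(Wd / stride)
  padT <- max((Ho - 1) * stride + kh - H, 0) %/% 2
  padL <- max((Wo - 1) * stride + kw - Wd, 0) %/% 2
  y <- array(0, c(cout, Ho, Wo))
  for (co in seq_len(cout)) {
    g <- (co - 1) %/% coutG
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
        hi <- (ho - 1) * stride - padT + ki
        wi <- (wo - 1) * stride - padL + kj
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= Wd)
          for (ci in seq_len(cinG))
            acc <- acc + x[g * cinG + ci, hi, wi] * W[ki, kj, ci, co]
      }
      y[co, ho, wo] <- acc
    }
  }
  y
}

# LRN by triple loop, straight from the defining formula.
oracleLRN <- function(a, t, alpha, beta, n) {
  d <- dim(a); C <- d[1]
  h <- n %/% 2
  b <- array(0, d)
  for (i in seq_len(C)) for (u in seq_len(d[2])) for (v in seq_len(d[3])) {
    lo <- max(1, i - h); hi <- min(C, i + h)
    s <- sum(a[lo:hi, u, v]^2)
    b[i, u, v] <- a[i, u, v] / (t + alpha * s)^beta
  }
  b
}

# Channel shuffle by explicit index transposition: channel (n, s, k) moves to
# slot (s, n, k).
oracleShuffle <- function(x, N, S) {
  C <- dim(x)[1]
  blk <- C %/% (N * S)
  y <- x
  for (c0 in 0:(C - 1)) {
    n <- c0 %/% (C %/% N)
    rem <- c0 %% (C %/% N)
    s <- rem %/% blk
    k <- rem %% blk
    y[s * (C %/% S) + n * blk + k + 1, , ] <- x[c0 + 1, , ]
  }
  y
}

# Quarter-turn rotation via the coordinate map (i, j) -> (-j, i), recentred
# onto the 1..H grid, applied r times.
oracleRotate <- function(x, r) {
  d <- dim(x); H <- d[2]
  for (rep in seq_len(r %% 4)) {
    y <- array(0, d)
    for (i in seq_len(H)) for (j in seq_len(H))
      y[, i, j] <- x[, j, H + 1 - i]
    x <- y
  }
  x
}

# Channel attention by explicit mean + two dense layers + sigmoid.
oracleChannelAttention <- function(g, params) {
  C <- dim(g)[1]
  p <- numeric(C)
  for (c0 in seq_len(C)) p[c0] <- mean(g[c0, , ])
  h <- as.vector(params$fc1W %*% p) + params$fc1b
  h[h < 0] <- 0
  q <- as.vector(params$fc2W %*% h) + params$fc2b
  1 / (1 + exp(-q))
}

# Spatial attention by per-position mean/max maps + oracle conv + sigmoid.
oracleSpatialAttention <- function(x, params) {
  d <- dim(x)
  avg <- apply(x, c(2, 3), mean)
  mx <- apply(x, c(2, 3), max)
  if (params$variant == "concat") {
    sc <- array(0, c(2, d[2], d[3]))
    sc[1, , ] <- avg; sc[2, , ] <- mx
  } else sc <- array(avg + mx, c(1, d[2], d[3]))
  m <- oracleConv(sc, params$W, 1, 1)[1, , ] + params$b
  gate <- 1 / (1 + exp(-m))
  y <- x
  for (c0 in seq_len(d[1])) y[c0, , ] <- x[c0, , ] * gate
  y
}

# Eq.-by-eq metric oracle on integer counts; returns percentages computed
# from exact integer numerators/denominators (NA on zero denominators).
oracleMetrics <- function(cm, literal = FALSE) {
  k <- nrow(cm)
  tot <- sum(cm)
  out <- matrix(NA_real_, k, 6,
                dimnames = list(NULL, c("Accuracy", "Precision", "Recall",
                                        "F1", "Sensitivity", "Specificity")))
  rat <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  for (i in seq_len(k)) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- tot - TP - FN - FP
    out[i, "Accuracy"] <- rat(TP + TN, tot)
    out[i, "Precision"] <- rat(TP, TP + FP)
    out[i, "Recall"] <- rat(TP, TP + FN)
    # F1 straight from 2*PRE*RE/(PRE+RE); undefined when PRE or RE is, or
    # when their sum is zero (0/0 in the printed formula)
    pre <- out[i, "Precision"]; re <- out[i, "Recall"]
    out[i, "F1"] <- if (is.na(pre) || is.na(re) || pre + re == 0) NA_real_
    else 2 * pre * re / (pre + re)
    out[i, "Sensitivity"] <- rat(TP, TP + FN)
    out[i, "Specificity"] <- if (literal) rat(TN, TP + TN) else rat(TN, TN + FP)
  }
  out
}

# AUC as the Mann-Whitney rank statistic (ties via midranks).
oracleAUC <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

randTensor <- function(C, H, W, sd = 1) array(rnorm(C * H * W, sd = sd), c(C, H, W))
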