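#' Training hyper-parameters
#'
#' @param lr initial learning rate.
#' @param batchSize mini-batch size.
#' @param epochs number of passes over the training set.
#' @param optimizer `"adam"` or `"sgd"` (momentum 0.9).
#' @param seed RNG seed for batch shuffling.
#' @return a validated list of hyper-parameters.
#' @export
trainingHyperparams <- function(lr = 1e-3, batchSize = 32L, epochs = 100L,
                                optimizer = c("adam", "sgd"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr < 0) stop("lr must be >= 0")
  list(lr = lr, batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       optimizer = optimizer, seed = as.integer(seed))
}

# Stack a BurnImageSet into the internal (3, H, W, N) float tensor in [0, 1].
.setToTensor <- function(set) {
  n <- nImages(set)
  if (n == 0L) stop("empty image set (too few images per class for the split?)")
  d <- dim(set@images[[1L]])
  x <- array(0, c(3L, d[1], d[2], n))
  for (i in seq_len(n)) x[, , , i] <- aperm(set@images[[i]], c(3L, 1L, 2L)) / 255
  x
}

# One-hot encode a factor as a (k, N) matrix.
.oneHot <- function(y, k) {
  Y <- matrix(0, k, length(y))
  Y[cbind(as.integer(y), seq_along(y))] <- 1
  Y
}

# Cross-entropy loss of logits (k, N) against one-hot targets; returns the
# loss and the logit gradient averaged over the batch.
.ceLoss <- function(logits, Y) {
  p <- softmaxProbs(logits)
  n <- ncol(Y)
  loss <- -sum(Y * log(pmax(p, 1e-12))) / n
  list(loss = loss, dlogits = (p - Y) / n, p = p)
}

# Inference over a large tensor in memory-bounded chunks; returns (k, N) probs.
.predictTensor <- function(mods, x, chunk = 32L) {
  n <- dim(x)[4]
  out <- NULL
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    r <- .netForward(mods, x[, , , idx, drop = FALSE], training = FALSE)
    p <- softmaxProbs(r$logits)
    out <- if (is.null(out)) p else cbind(out, p)
  }
  out
}

#' Train a network
#'
#' Mini-batch gradient training of a built network with categorical
#' cross-entropy on the softmax head.  Records per-epoch training loss and
#' accuracy (and validation loss/accuracy when validation data is given) in
#' the model's history; epoch numbering continues across repeated calls so a
#' model can be trained in instalments.
#'
#' @param model a [BurnNet-class].
#' @param data a [BurnImageSet-class] or an internal `(3, H, W, N)` tensor.
#' @param labels factor of training labels (taken from the manifest when
#'   `data` is a `BurnImageSet` and `labels` is `NULL`; mapped through
#'   [toBinaryLabels()] automatically for a 2-class model).
#' @param params hyper-parameters from [trainingHyperparams()].
#' @param valData,valLabels optional held-out validation set, evaluated in
#'   inference mode at the end of every epoch.
#' @param recalibrate after the last step, replace the exponential-moving-
#'   average batch-norm statistics with exact moments over the training set
#'   (one extra forward pass); removes the train/inference statistics
#'   mismatch that the moving average leaves on small datasets.
#' @param verbose print one line per epoch.
#' @return the trained model (weights, batch-norm statistics and history
#'   updated).
#' @export
trainModel <- function(model, data, labels = NULL, params = trainingHyperparams(),
                       valData = NULL, valLabels = NULL, recalibrate = TRUE,
                       verbose = FALSE) {
  prep <- .prepTask(model, data, labels)
  x <- prep$x; y <- prep$y
  k <- model@config@numClasses
  n <- dim(x)[4]
  if (!is.null(valData)) {
    vprep <- .prepTask(model, valData, valLabels)
    vx <- vprep$x; vy <- vprep$y
  }
  Y <- .oneHot(y, k)
  mods <- model@net$modules
  st <- .optimInit()
  rng <- .seededRNG(.deriveSeed(params$seed, "shuffle"))
  t <- 0L
  hist <- list()
  epoch0 <- if (nrow(model@history)) max(model@history$epoch) else 0L

  for (epoch in seq_len(params$epochs)) {
    ord <- rng$sample(n)
    eLoss <- 0; eHit <- 0
    starts <- seq(1L, n, by = params$batchSize)
    for (i0 in starts) {
      idx <- ord[i0:min(i0 + params$batchSize - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      Yb <- Y[, idx, drop = FALSE]
      fw <- .netForward(mods, xb, training = TRUE, keepCaches = TRUE)
      ls <- .ceLoss(fw$logits, Yb)
      t <- t + 1L
      bw <- .netBackward(mods, fw$caches, ls$dlogits)
      mods <- .optimStep(list(type = "seq", children = mods),
                         bw$grads, st, params$optimizer, params$lr, t)$children
      eLoss <- eLoss + ls$loss * length(idx)
      eHit <- eHit + sum(apply(ls$p, 2L, which.max) == as.integer(y[idx]))
    }
    row <- data.frame(epoch = epoch0 + epoch, trainLoss = eLoss / n,
                      trainAcc = eHit / n, valLoss = NA_real_,
                      valAcc = NA_real_, steps = t)
    if (!is.null(valData)) {
      vp <- .predictTensor(mods, vx, params$batchSize)
      vls <- .ceLoss(log(pmax(vp, 1e-12)), .oneHot(vy, k))
      row$valLoss <- vls$loss
      row$valAcc <- mean(apply(vp, 2L, which.max) == as.integer(vy))
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", row$epoch,
                      row$trainLoss, row$trainAcc,
                      if (!is.na(row$valAcc)) sprintf("  val %.3f", row$valAcc) else ""))
  }
  if (recalibrate && params$lr > 0) .recalibrateBN(mods, x, params$batchSize)
  model@net$modules <- mods
  model@history <- rbind(model@history, do.call(rbind, hist))
  model
}

# Resolve data + labels against the model's task arity.
.prepTask <- function(model, data, labels) {
  if (is(data, "BurnImageSet")) {
    if (is.null(labels)) labels <- imageLabels(data)
    data <- .setToTensor(data)
  }
  if (is.null(labels)) stop("labels are required when data is a raw tensor")
  k <- model@config@numClasses
  labels <- if (k == 2L && !all(levels(factor(labels)) %in% graftClasses()))
    toBinaryLabels(labels)
  else factor(labels, levels = model@classLevels)
  if (nlevels(labels) != k || anyNA(labels))
    stop(sprintf("labels do not match the model's %d-class head", k))
  list(x = data, y = labels)
}

#' Predict class probabilities for an image set
#'
#' @param model a trained [BurnNet-class].
#' @param data a [BurnImageSet-class] or `(3, H, W, N)` tensor.
#' @param batchSize chunk size for memory-bounded inference.
#' @return `n x k` probability matrix with class-level column names.
#' @export
predictSet <- function(model, data, batchSize = 32L) {
  if (is(data, "BurnImageSet")) data <- .setToTensor(data)
  p <- t(.predictTensor(model@net$modules, data, batchSize))
  colnames(p) <- model@classLevels
  p
}
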