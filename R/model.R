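#' Construct a stage specification
#'
#' @param name stage label, e.g. `"conv1"`.
#' @param ops list of convolution descriptors; each a list with `k`
#'   (kernel height/width), `out` (output channels), `groups`.
#' @param repeats number of blocks in the stage.
#' @param stride spatial stride of the stage's first block.
#' @param pool optional `list(z = window, stride = s)` trailing max-pool.
#' @return a [StageSpec-class] object.
#' @export
stageSpec <- function(name, ops, repeats = 1L, stride = 1L, pool = NULL) {
  ops <- lapply(ops, function(op) {
    op$k <- as.integer(rep(op$k, length.out = 2L))
    op$out <- as.integer(op$out)
    op$groups <- as.integer(if (is.null(op$groups)) 1L else op$groups)
    op
  })
  new("StageSpec", name = name, ops = ops, repeats = as.integer(repeats),
      stride = as.integer(stride), pool = pool)
}

.defaultAttention <- function() {
  list(groups = 4L, subgroups = 4L, reduction = 16L, variant = "concat",
       stages = c("conv2", "conv3", "conv4", "conv5"))
}

.defaultLRN <- function() {
  list(t = 2, alpha = 1e-4, beta = 0.75, n = 5L, stages = c("conv1", "conv2"))
}

.bottleneckStages <- function(conv1, inner, outer, repeats, cardinality,
                              widthFactor) {
  sc <- function(w) {
    v <- as.integer(round(w * widthFactor))
    if (v < 1L) stop("widthFactor yields a stage with < 1 channel")
    v
  }
  stages <- list(stageSpec("conv1",
                           list(list(k = conv1$k, out = sc(conv1$out), groups = 1L)),
                           repeats = 1L, stride = 2L,
                           pool = list(z = 3L, stride = 2L)))
  nm <- c("conv2", "conv3", "conv4", "conv5")
  strides <- c(1L, 2L, 2L, 2L)
  for (i in seq_along(nm)) {
    stages[[i + 1L]] <- stageSpec(nm[i], list(
      list(k = c(1L, 1L), out = sc(inner[i]), groups = 1L),
      list(k = c(3L, 3L), out = sc(inner[i]), groups = cardinality),
      list(k = c(1L, 1L), out = sc(outer[i]), groups = 1L)),
      repeats = repeats[i], stride = strides[i])
  }
  stages
}

#' Configuration of the slimmed attention network
#'
#' The default arguments reproduce the slimmed ResNeXt-50 burn classifier:
#' a 5 x 5, 256-channel stem convolution (stride 2) followed by a 3 x 3/2
#' max-pool and four bottleneck stages of widths
#' (32,128) x3, (64,256) x4, (256,512) x6, (512,1024) x3 at cardinality 32,
#' Leaky ReLU activations, local response normalisation after the stem and
#' first bottleneck stage, and a residual/channel/spatial attention block on
#' the output of every bottleneck stage.  `widthFactor` scales every width,
#' e.g. `widthFactor = 0.5` with `cardinality = 16` gives the half-width
#' variant used for CPU-scale training.
#'
#' @param numClasses 3 (degree task) or 2 (graft task).
#' @param cardinality number of grouped-convolution paths.
#' @param widthFactor multiplier applied to every channel width.
#' @param inputSize image height and width.
#' @param leakySlope Leaky ReLU negative-region gain.
#' @param attention attention settings list (see [BurnNetConfig-class]),
#'   `TRUE` for the defaults or `NULL`/`FALSE` to disable.
#' @param lrn local-response-normalisation settings list, `TRUE` for the
#'   defaults or `NULL`/`FALSE` to disable.
#' @return a [BurnNetConfig-class] object.
#' @examples
#' cfg <- burnNeXtConfig(numClasses = 3)
#' deriveShapes(cfg)
#' @export
burnNeXtConfig <- function(numClasses = 3L, cardinality = 32L, widthFactor = 1,
                           inputSize = c(100L, 100L), leakySlope = 0.01,
                           attention = TRUE, lrn = TRUE) {
  stages <- .bottleneckStages(list(k = c(5L, 5L), out = 256L),
                              inner = c(32L, 64L, 256L, 512L),
                              outer = c(128L, 256L, 512L, 1024L),
                              repeats = c(3L, 4L, 6L, 3L),
                              cardinality = as.integer(cardinality), widthFactor)
  .finishConfig(stages, numClasses, cardinality, inputSize, leakySlope,
                attention, lrn)
}

#' Configuration of the original ResNeXt-50 topology
#'
#' The unmodified 50-layer grouped-convolution backbone (7 x 7, 64 stem;
#' bottleneck widths (128,256) x3, (256,512) x4, (512,1024) x6, (1024,2048) x3
#' at cardinality 32), used as the reference point for parameter accounting.
#' Attention and LRN are off by default.
#'
#' @inheritParams burnNeXtConfig
#' @return a [BurnNetConfig-class] object.
#' @export
resNeXt50Config <- function(numClasses = 3L, cardinality = 32L, widthFactor = 1,
                            inputSize = c(100L, 100L), leakySlope = 0.01,
                            attention = NULL, lrn = NULL) {
  stages <- .bottleneckStages(list(k = c(7L, 7L), out = 64L),
                              inner = c(128L, 256L, 512L, 1024L),
                              outer = c(256L, 512L, 1024L, 2048L),
                              repeats = c(3L, 4L, 6L, 3L),
                              cardinality = as.integer(cardinality), widthFactor)
  .finishConfig(stages, numClasses, cardinality, inputSize, leakySlope,
                attention, lrn)
}

.finishConfig <- function(stages, numClasses, cardinality, inputSize,
                          leakySlope, attention, lrn) {
  if (isTRUE(attention)) attention <- .defaultAttention()
  if (isFALSE(attention)) attention <- NULL
  if (!is.null(attention))
    attention <- modifyList(.defaultAttention(), attention)
  if (isTRUE(lrn)) lrn <- .defaultLRN()
  if (isFALSE(lrn)) lrn <- NULL
  if (!is.null(lrn)) lrn <- modifyList(.defaultLRN(), lrn)
  new("BurnNetConfig",
      inputShape = as.integer(c(inputSize[1], inputSize[2], 3L)),
      numClasses = as.integer(numClasses),
      cardinality = as.integer(cardinality),
      stages = stages, leakySlope = leakySlope,
      lrn = lrn, attention = attention)
}

#' @describeIn burnNeXtConfig half-width variant for CPU-scale training
#'   (all widths halved, cardinality 16 so each grouped path keeps its
#'   original per-group width).
#' @export
burnNeXtHalfConfig <- function(numClasses = 3L, ...) {
  burnNeXtConfig(numClasses = numClasses, cardinality = 16L,
                 widthFactor = 0.5, ...)
}

# ---- shape derivation ------------------------------------------------------

#' @describeIn deriveShapes audit of the channel/spatial trace of a
#'   configuration under same-padding, ceil-mode stride arithmetic
#'   (`out = ceiling(in / stride)`).  Returns a data.frame with one row per
#'   stage (and pooling step), plus the pooled feature-vector length.
#' @param config a [BurnNetConfig-class].
#' @param ... unused.
#' @export
setMethod("deriveShapes", "BurnNetConfig", function(config, ...) {
  H <- config@inputShape[1]
  W <- config@inputShape[2]
  if (H <= 0L || W <= 0L) stop("deriveShapes: non-positive spatial size")
  rows <- list()
  C <- config@inputShape[3]
  for (st in config@stages) {
    H <- .ceilDiv(H, st@stride)
    W <- .ceilDiv(W, st@stride)
    C <- st@ops[[length(st@ops)]]$out
    rows[[length(rows) + 1L]] <- data.frame(stage = st@name, C = C, H = H, W = W)
    if (!is.null(st@pool)) {
      H <- .ceilDiv(H, st@pool$stride)
      W <- .ceilDiv(W, st@pool$stride)
      rows[[length(rows) + 1L]] <- data.frame(stage = "pool", C = C, H = H, W = W)
    }
    if (H <= 0L || W <= 0L) stop("deriveShapes: non-positive spatial size")
  }
  rows[[length(rows) + 1L]] <- data.frame(stage = "gap", C = C, H = 1L, W = 1L)
  do.call(rbind, rows)
})

# ---- building --------------------------------------------------------------

# Assemble the ordered module list of a configuration.  rng = NULL builds
# zero-weight layers (used for parameter accounting and checkpoint loading).
.buildNet <- function(config, rng = NULL) {
  mods <- list()
  slope <- config@leakySlope
  att <- config@attention
  lrn <- config@lrn
  cin <- config@inputShape[3]
  for (st in config@stages) {
    if (length(st@ops) == 1L) {                       # stem stage
      op <- st@ops[[1L]]
      mods[[st@name]] <- .mkConv(op$k[1], op$k[2], cin, op$out, st@stride,
                                 op$groups, rng, st@name)
      mods[[paste0("bn_", st@name)]] <- .mkBN(op$out, act = slope)
      cin <- op$out
    } else {                                          # bottleneck stage
      blocks <- list()
      for (b in seq_len(st@repeats)) {
        stride <- if (b == 1L) st@stride else 1L
        blocks[[paste0("block", b)]] <-
          .mkBlock(cin, st@ops[[1L]]$out, st@ops[[3L]]$out,
                   st@ops[[2L]]$groups, stride, slope, rng, st@name)
        cin <- st@ops[[3L]]$out
      }
      mods[[st@name]] <- .mkSeq(blocks)
      if (!is.null(att) && st@name %in% att$stages)
        mods[[paste0("att_", st@name)]] <-
          .mkAttention(cin, att$groups, att$subgroups, att$reduction, rng,
                       att$variant, st@name)
    }
    if (!is.null(lrn) && st@name %in% lrn$stages)
      mods[[paste0("lrn_", st@name)]] <- .mkLRN(lrn$t, lrn$alpha, lrn$beta, lrn$n)
    if (!is.null(st@pool))
      mods[[paste0("pool_", st@name)]] <- .mkPool(st@pool$z, st@pool$stride)
  }
  mods[["gap"]] <- .mkGAP()
  mods[["fc"]] <- .mkDense(cin, config@numClasses, rng)
  mods
}

#' Build a network from a configuration
#'
#' Instantiates every layer of the configured topology with He (fan-in scaled)
#' random weights: the stem convolution, the grouped bottleneck stages with
#' identity or 1 x 1 projection shortcuts, the optional LRN and attention
#' blocks, global average pooling and the k-way classifier head.
#'
#' @param config a [BurnNetConfig-class].
#' @param seed RNG seed for weight initialisation.
#' @return a [BurnNet-class] handle.
#' @examples
#' model <- buildModel(burnNeXtConfig(widthFactor = 0.25, cardinality = 8,
#'                                    inputSize = c(32, 32)), seed = 1)
#' @export
buildModel <- function(config, seed = 1L) {
  validObject(config)
  rng <- .seededRNG(.deriveSeed(seed, "init"))
  levels <- if (config@numClasses == 3L) burnClasses() else graftClasses()
  new("BurnNet", config = config, net = list(modules = .buildNet(config, rng)),
      history = data.frame(), classLevels = levels)
}

# ---- forward ---------------------------------------------------------------

# Run the module list on an internal (C, H, W, N) batch.
# Returns logits (k, N), per-module caches, and the stage shape trace.
.netForward <- function(mods, x, training = FALSE, keepCaches = FALSE) {
  caches <- if (keepCaches) vector("list", length(mods)) else NULL
  shapes <- list()
  for (i in seq_along(mods)) {
    r <- .modFwd(mods[[i]], x, training)
    x <- r$y
    if (keepCaches) caches[[i]] <- r$cache
    nm <- names(mods)[i]
    if (grepl("^conv", nm) || grepl("^pool", nm) || nm == "gap")
      shapes[[nm]] <- dim(x)
  }
  if (keepCaches) names(caches) <- names(mods)
  list(logits = x, caches = caches, shapes = shapes)
}

.netBackward <- function(mods, caches, dy) {
  grads <- vector("list", length(mods))
  for (i in rev(seq_along(mods))) {
    r <- .modBwd(mods[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)
  }
  names(grads) <- names(mods)
  list(dx = dy, grads = list(children = grads))
}

# Convert a user-facing batch (n, 3, H, W), a single (3, H, W) image, or an
# internal (C, H, W, N) tensor into the internal layout.
.asBatch <- function(batch, inputShape) {
  d <- dim(batch)
  C <- inputShape[3]; H <- inputShape[1]; W <- inputShape[2]
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("batch must be (n, 3, H, W), (3, H, W) or (3, H, W, n)")
  if (length(d) == 3L) {
    if (!identical(as.integer(d), as.integer(c(C, H, W))))
      stop(sprintf("image shape %s does not match configured %dx%dx%d",
                   paste(d, collapse = "x"), C, H, W))
    return(array(batch, c(d, 1L)))
  }
  if (identical(as.integer(d[2:4]), as.integer(c(C, H, W))))
    return(aperm(batch, c(2L, 3L, 4L, 1L)))          # batch-first layout
  if (identical(as.integer(d[1:3]), as.integer(c(C, H, W))))
    return(batch)                                     # already internal
  stop(sprintf("batch shape %s does not match configured %dx%dx%d",
               paste(d, collapse = "x"), C, H, W))
}

#' Forward inference
#'
#' Runs a batch of images through a built network and returns class
#' probabilities (softmax of the head logits).  Batch-norm layers use their
#' running statistics (inference mode).
#'
#' @param model a [BurnNet-class].
#' @param batch numeric array `(n, 3, H, W)` of images scaled to `[0, 1]`
#'   (a single `(3, H, W)` image is also accepted).
#' @param trace if `TRUE`, attach the per-stage shape trace as attribute
#'   `"shapes"`.
#' @return `n x k` matrix of class probabilities; every row sums to 1.
#' @export
forwardPass <- function(model, batch, trace = FALSE) {
  if (!all(is.finite(batch))) stop("forwardPass: batch must be finite")
  x <- .asBatch(batch, model@config@inputShape)
  r <- .netForward(model@net$modules, x, training = FALSE)
  probs <- t(softmaxProbs(r$logits))
  colnames(probs) <- model@classLevels
  if (trace) attr(probs, "shapes") <- r$shapes
  probs
}

# ---- parameter accounting --------------------------------------------------

# Weight count of one convolution: kh*kw*(Cin/groups)*Cout.
.convWeights <- function(kh, kw, cin, cout, groups) {
  as.numeric(kh) * kw * (cin / groups) * cout
}

#' @describeIn countParameters trainable-parameter accounting under three
#'   explicit conventions.  `"stage_tabulation"` sums only the stage-table
#'   convolution weights (`kh*kw*(Cin/groups)*Cout`; no shortcut projections,
#'   biases, normalisation or attention weights, no classifier head);
#'   `"full_backbone"` additionally counts the 1 x 1 projection shortcut of
#'   each stage's first block; `"all"` counts every trainable scalar in the
#'   built model (batch-norm scale/shift, attention weights and the classifier
#'   head included).
#' @param convention counting convention (see Details).
#' @param ... unused.
#' @examples
#' countParameters(burnNeXtConfig(), "stage_tabulation")   # 4,898,912
#' countParameters(resNeXt50Config(), "full_backbone")     # 22,911,680
#' @export
setMethod("countParameters", "BurnNetConfig",
          function(config, convention = c("stage_tabulation", "full_backbone", "all"), ...) {
  convention <- match.arg(convention)
  if (convention == "all") {
    root <- list(type = "seq", children = .buildNet(config, rng = NULL))
    return(sum(vapply(.gatherParams(root), length, 0L)))
  }
  total <- 0
  cin <- config@inputShape[3]
  for (st in config@stages) {
    if (length(st@ops) == 1L) {
      op <- st@ops[[1L]]
      total <- total + .convWeights(op$k[1], op$k[2], cin, op$out, op$groups)
      cin <- op$out
    } else {
      stageIn <- cin
      for (b in seq_len(st@repeats)) {
        flow <- cin
        for (op in st@ops) {
          total <- total + .convWeights(op$k[1], op$k[2], flow, op$out, op$groups)
          flow <- op$out
        }
        cin <- flow
      }
      if (convention == "full_backbone" && stageIn != cin)
        total <- total + .convWeights(1L, 1L, stageIn, cin, 1L)
    }
  }
  total
})

#' Per-stage parameter breakdown
#'
#' @param config a [BurnNetConfig-class].
#' @param convention counting convention, as in [countParameters()]
#'   (`"all"` is reported per top-level module).
#' @return data.frame with `stage` and `params` columns; the column sum equals
#'   `countParameters(config, convention)`.
#' @export
parameterBreakdown <- function(config,
                               convention = c("stage_tabulation", "full_backbone", "all")) {
  convention <- match.arg(convention)
  if (convention == "all") {
    mods <- .buildNet(config, rng = NULL)
    n <- vapply(mods, function(m) sum(vapply(.gatherParams(m), length, 0L)), 0)
    return(data.frame(stage = names(mods), params = as.numeric(n),
                      row.names = NULL)[n > 0, ])
  }
  rows <- list()
  cin <- config@inputShape[3]
  for (st in config@stages) {
    sub <- 0
    if (length(st@ops) == 1L) {
      op <- st@ops[[1L]]
      sub <- .convWeights(op$k[1], op$k[2], cin, op$out, op$groups)
      cin <- op$out
    } else {
      stageIn <- cin
      for (b in seq_len(st@repeats)) {
        flow <- cin
        for (op in st@ops) {
          sub <- sub + .convWeights(op$k[1], op$k[2], flow, op$out, op$groups)
          flow <- op$out
        }
        cin <- flow
      }
      if (convention == "full_backbone" && stageIn != cin)
        sub <- sub + .convWeights(1L, 1L, stageIn, cin, 1L)
    }
    rows[[st@name]] <- data.frame(stage = st@name, params = sub)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
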