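#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Stage specification of a residual network
#'
#' Describes one stage of the backbone as data: the ordered convolution
#' descriptors of its (repeated) block, the repeat count, the spatial stride
#' applied by the first block, and an optional trailing max-pool.  A
#' convolution descriptor is a list with elements `k` (kernel height/width),
#' `out` (output channels) and `groups`.
#'
#' @slot name stage label (`"conv1"` .. `"conv5"`).
#' @slot ops list of convolution descriptors applied within one block.
#' @slot repeats number of blocks in the stage (>= 1).
#' @slot stride spatial stride of the stage's first block.
#' @slot pool optional pooling descriptor `list(z = window, stride = s)`.
#' @exportClass StageSpec
setClass("StageSpec",
  representation(name = "character", ops = "list", repeats = "integer",
                 stride = "integer", pool = "listOrNULL"))

setValidity("StageSpec", function(object) {
  if (object@repeats < 1L)
    return(sprintf("stage '%s': repeats must be >= 1", object@name))
  for (op in object@ops) {
    if (op$out <= 0L)
      return(sprintf("stage '%s': output channels must be > 0", object@name))
    if (op$out %% op$groups != 0L)
      return(sprintf("stage '%s': groups (%d) must divide output channels (%d)",
                     object@name, op$groups, op$out))
  }
  TRUE
})

#' Declarative network configuration
#'
#' Holds the full topology of the classifier as data: input shape, class
#' count, cardinality, the per-stage convolution table, the Leaky ReLU slope,
#' and the optional local-response-normalisation and attention settings.
#' `burnNeXtConfig()` and `resNeXt50Config()` are the two stock constructors.
#'
#' @slot inputShape integer of length 3: height, width, channels.
#' @slot numClasses number of output classes (2 or 3 for the burn tasks).
#' @slot cardinality number of parallel grouped-convolution paths.
#' @slot stages list of [StageSpec-class] objects.
#' @slot leakySlope negative-region gain of the Leaky ReLU activation.
#' @slot lrn local response normalisation settings
#'   (`list(t, alpha, beta, n, stages)`) or `NULL`.
#' @slot attention attention settings
#'   (`list(groups, subgroups, reduction, variant, stages)`) or `NULL`.
#' @exportClass BurnNetConfig
setClass("BurnNetConfig",
  representation(inputShape = "integer", numClasses = "integer",
                 cardinality = "integer", stages = "list",
                 leakySlope = "numeric", lrn = "listOrNULL",
                 attention = "listOrNULL"))

setValidity("BurnNetConfig", function(object) {
  if (length(object@inputShape) != 3L || any(object@inputShape <= 0L))
    return("inputShape must be three positive integers (H, W, C)")
  if (!(object@numClasses %in% c(2L, 3L)))
    return("numClasses must be 2 (graft task) or 3 (degree task)")
  if (object@cardinality < 1L) return("cardinality must be a positive integer")
  for (st in object@stages) {
    v <- validObject(st, test = TRUE)
    if (is.character(v)) return(v)
  }
  TRUE
})

#' A built (trainable) burn-classification network
#'
#' Opaque handle around the layer tree produced by [buildModel()].  Weights
#' live inside the `net` slot; `history` records per-epoch loss/accuracy once
#' the model has been through [trainModel()].
#'
#' @slot config the [BurnNetConfig-class] the network was built from.
#' @slot net nested list of layers (weights, batch-norm state, topology).
#' @slot history data.frame of per-epoch training/validation loss and accuracy.
#' @slot classLevels character vector naming the output classes.
#' @exportClass BurnNet
setClass("BurnNet",
  representation(config = "BurnNetConfig", net = "list",
                 history = "data.frame", classLevels = "character"))

#' Synthetic burn-image generator settings
#'
#' @slot nPerClass images generated per burn class.
#' @slot imageSize integer height and width of generated images.
#' @slot seed integer seed fixing the whole dataset bit-exactly.
#' @slot noiseSD standard deviation of the additive Gaussian pixel noise
#'   (8-bit pixel units).
#' @slot axesRange range (pixels) of the elliptical lesion semi-axes.
#' @slot centerJitter maximal displacement (pixels) of the lesion centre.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(nPerClass = "integer", imageSize = "integer", seed = "integer",
                 noiseSD = "numeric", axesRange = "numeric",
                 centerJitter = "numeric"))

setValidity("SynthConfig", function(object) {
  if (object@nPerClass < 1L) return("nPerClass must be >= 1")
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    return("imageSize must be two integers >= 8")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (length(object@axesRange) != 2L || any(object@axesRange <= 0))
    return("axesRange must be two positive numbers")
  TRUE
})

#' A labelled set of burn images
#'
#' Container pairing a list of H x W x 3 integer pixel arrays (values in
#' 0..255) with a manifest data.frame (`id`, `label`, `source`, and optional
#' `path`/`split` columns).
#'
#' @slot images list of H x W x 3 integer arrays.
#' @slot manifest data.frame with one row per image.
#' @exportClass BurnImageSet
setClass("BurnImageSet",
  representation(images = "list", manifest = "data.frame"))

setValidity("BurnImageSet", function(object) {
  if (length(object@images) != nrow(object@manifest))
    return("manifest must have one row per image")
  if (!all(c("id", "label") %in% names(object@manifest)))
    return("manifest must have 'id' and 'label' columns")
  for (im in object@images) {
    d <- dim(im)
    if (length(d) != 3L || d[3] != 3L) return("every image must be H x W x 3")
  }
  TRUE
})

#' Classification metric report
#'
#' Per-class one-vs-rest confusion-matrix statistics (accuracy, precision,
#' recall, F1, sensitivity, specificity, all in percent) with their macro
#' average and the overall (trace) accuracy.  Cells whose defining ratio has a
#' zero denominator are `NA` and listed in `flags`.
#'
#' @slot perClass data.frame of per-class metrics (percent).
#' @slot macro named numeric macro-averaged metrics (percent).
#' @slot overallAccuracy percent of items on the confusion-matrix diagonal.
#' @slot mode `"standard"` or `"paper_literal"` specificity definition.
#' @slot flags character vector naming undefined (zero-denominator) cells.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(perClass = "data.frame", macro = "numeric",
                 overallAccuracy = "numeric", mode = "character",
                 flags = "character"))

#' Cross-validation result
#'
#' @slot task `"degree"` or `"graft"`.
#' @slot reports list of per-fold [MetricsReport-class] objects.
#' @slot cms list of per-fold confusion matrices.
#' @slot table data.frame with one row per fold plus the average row
#'   (columns Precision, Recall, F1.score, Sensitivity, Specificity, Accuracy).
#' @slot auc named numeric one-vs-rest AUC per class (pooled folds).
#' @slot log list with seed, configuration hash and run settings.
#' @exportClass CVResult
setClass("CVResult",
  representation(task = "character", reports = "list", cms = "list",
                 table = "data.frame", auc = "numeric", log = "list"))

# ---- generics ---------------------------------------------------------------

#' Derive the stage-by-stage shape trace of a configuration
#'
#' @param config a network configuration.
#' @param ... passed to methods.
#' @return data.frame with columns `stage`, `C`, `H`, `W`.
#' @export
setGeneric("deriveShapes", function(config, ...) standardGeneric("deriveShapes"))

#' Count trainable parameters under an explicit convention
#'
#' @param config a network configuration.
#' @param convention counting convention (see the method Details).
#' @param ... passed to methods.
#' @return total parameter count (numeric).
#' @export
setGeneric("countParameters",
           function(config, convention = c("stage_tabulation", "full_backbone", "all"), ...)
             standardGeneric("countParameters"))

#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @export
setGeneric("imageData", function(x, i) standardGeneric("imageData"))

#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @export
setGeneric("metricsTable", function(x, ...) standardGeneric("metricsTable"))

# ---- accessors / show -------------------------------------------------------

#' @describeIn BurnImageSet number of images in the set.
#' @param x a `BurnImageSet`.
#' @export
setMethod("nImages", "BurnImageSet", function(x) length(x@images))

#' @describeIn BurnImageSet factor of image labels.
#' @export
setMethod("imageLabels", "BurnImageSet",
          function(x) factor(x@manifest$label, levels = burnClasses()))

#' @describeIn BurnImageSet the manifest data.frame.
#' @export
setMethod("manifest", "BurnImageSet", function(x) x@manifest)

#' @describeIn BurnImageSet pixel array of image `i`.
#' @param i image index.
#' @export
setMethod("imageData", "BurnImageSet", function(x, i) x@images[[i]])

#' @describeIn BurnNet configuration the network was built from.
#' @param x a `BurnNet`.
#' @export
setMethod("modelConfig", "BurnNet", function(x) x@config)

#' @describeIn BurnNet per-epoch training history.
#' @export
setMethod("trainingHistory", "BurnNet", function(x) x@history)

setMethod("show", "BurnNetConfig", function(object) {
  cat(sprintf("BurnNetConfig: %dx%dx%d input, %d classes, cardinality %d\n",
              object@inputShape[1], object@inputShape[2], object@inputShape[3],
              object@numClasses, object@cardinality))
  for (st in object@stages) {
    ops <- vapply(st@ops, function(op)
      sprintf("%dx%d,%d%s", op$k[1], op$k[2], op$out,
              if (op$groups > 1L) sprintf(",g=%d", op$groups) else ""), "")
    cat(sprintf("  %-6s [%s] x%d stride %d%s\n", st@name,
                paste(ops, collapse = "; "), st@repeats, st@stride,
                if (!is.null(st@pool))
                  sprintf("  + %dx%d maxpool/%d", st@pool$z, st@pool$z, st@pool$stride)
                else ""))
  }
  cat(sprintf("  attention: %s, LRN: %s\n",
              if (is.null(object@attention)) "off"
              else paste(object@attention$stages, collapse = ","),
              if (is.null(object@lrn)) "off"
              else paste(object@lrn$stages, collapse = ",")))
  invisible(object)
})

setMethod("show", "BurnNet", function(object) {
  cat(sprintf("BurnNet: %d classes (%s), %s trainable parameters\n",
              object@config@numClasses,
              paste(object@classLevels, collapse = "/"),
              format(countParameters(object@config, "all"), big.mark = ",")))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final train acc %.1f%%\n",
                max(object@history$epoch),
                100 * utils::tail(object@history$trainAcc, 1)))
  else cat("  untrained\n")
  invisible(object)
})

setMethod("show", "BurnImageSet", function(object) {
  cat(sprintf("BurnImageSet: %d images\n", nImages(object)))
  print(table(object@manifest$label))
  invisible(object)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s specificity), overall accuracy %.2f%%\n",
              object@mode, object@overallAccuracy))
  print(round(object@perClass, 2))
  cat("macro: "); print(round(object@macro, 2))
  if (length(object@flags))
    cat("undefined cells:", paste(object@flags, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %s task, %d folds\n", object@task, length(object@reports)))
  print(round(object@table, 2))
  invisible(object)
})

#' @describeIn MetricsReport per-class metric table with macro-average row.
#' @param x a `MetricsReport`.
#' @param ... unused.
#' @export
setMethod("metricsTable", "MetricsReport", function(x, ...) {
  rbind(x@perClass, macro = x@macro[colnames(x@perClass)])
})

#' @describeIn CVResult fold-by-fold metric table (plus average row).
#' @export
setMethod("metricsTable", "CVResult", function(x, ...) x@table)
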