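# YAML serialisation of model configurations and single-file checkpoints.

.configToList <- function(config) {
  list(
    input_shape = as.integer(config@inputShape),
    num_classes = config@numClasses,
    cardinality = config@cardinality,
    leaky_slope = config@leakySlope,
    lrn = config@lrn,
    attention = config@attention,
    stages = lapply(config@stages, function(st) list(
      name = st@name,
      ops = lapply(st@ops, function(op)
        list(k = as.integer(op$k), out = op$out, groups = op$groups)),
      repeats = st@repeats, stride = st@stride, pool = st@pool)))
}

.configFromList <- function(lst) {
  stages <- lapply(lst$stages, function(s)
    stageSpec(s$name, s$ops, s$repeats, s$stride, s$pool))
  att <- lst$attention
  if (!is.null(att)) {
    att$stages <- unlist(att$stages)
    att <- modifyList(.defaultAttention(), att)
  }
  lrn <- lst$lrn
  if (!is.null(lrn)) {
    lrn$stages <- unlist(lrn$stages)
    lrn <- modifyList(.defaultLRN(), lrn)
  }
  new("BurnNetConfig",
      inputShape = as.integer(unlist(lst$input_shape)),
      numClasses = as.integer(lst$num_classes),
      cardinality = as.integer(lst$cardinality),
      stages = stages, leakySlope = as.numeric(lst$leaky_slope),
      lrn = lrn, attention = att)
}

#' Write / read a model configuration as YAML
#'
#' @param config a [BurnNetConfig-class].
#' @param path YAML file path.
#' @return `writeModelConfig`: `path`, invisibly; `readModelConfig`: the
#'   configuration.
#' @export
writeModelConfig <- function(config, path) {
  yaml::write_yaml(.configToList(config), path)
  invisible(path)
}

#' @rdname writeModelConfig
#' @export
readModelConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  .configFromList(yaml::read_yaml(path))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding every weight array, the
#' batch-norm running statistics, the training history and the model
#' configuration embedded as YAML text, so a checkpoint is self-describing.
#'
#' @param model a [BurnNet-class].
#' @param path checkpoint file path.
#' @return `saveCheckpoint`: `path`, invisibly; `loadCheckpoint`: the
#'   reconstructed [BurnNet-class].
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(
    configYAML = yaml::as.yaml(.configToList(model@config)),
    params = .gatherParams(list(type = "seq", children = model@net$modules)),
    bn = .gatherBNState(list(type = "seq", children = model@net$modules)),
    history = model@history,
    classLevels = model@classLevels), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  config <- .configFromList(yaml::yaml.load(ck$configYAML))
  root <- list(type = "seq", children = .buildNet(config, rng = NULL))
  root <- .setParams(root, ck$params)
  root <- .setBNState(root, ck$bn)
  new("BurnNet", config = config, net = list(modules = root$children),
      history = ck$history, classLevels = ck$classLevels)
}
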