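#' Map burn-depth labels to the grafting decision
#'
#' Full-thickness and deep dermal burns require skin grafting; superficial
#' burns heal without it.
#'
#' @param labels character or factor of burn-depth labels
#'   (`"superficial"`, `"deep_dermal"`, `"full_thickness"`).
#' @return factor with levels `non_graft`, `graft`.
#' @examples
#' toBinaryLabels(c("superficial", "full_thickness"))
#' @export
toBinaryLabels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), burnClasses())
  if (length(bad))
    stop("unknown burn label(s): ", paste(bad, collapse = ", "))
  factor(ifelse(labels == "superficial", "non_graft", "graft"),
         levels = graftClasses())
}

#' Stratified k-fold split
#'
#' Partitions ids into k folds; each fold's validation set is disjoint from
#' the others and the union of validation sets is the full id set.  When
#' `strata` is given, every class is split 1/k-per-fold separately so no fold
#' loses a class.  Deterministic under `seed`.
#'
#' @param ids vector of item identifiers.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param strata optional factor (same length as `ids`) to stratify on.
#' @return list of k folds, each `list(fold, train, val)`.
#' @export
kfoldSplit <- function(ids, k = 5L, seed = 1L, strata = NULL) {
  n <- length(ids)
  if (n < k) stop("kfoldSplit: need at least k ids")
  rng <- .seededRNG(.deriveSeed(seed, "kfold"))
  fold <- integer(n)
  if (is.null(strata)) {
    fold[rng$sample(n)] <- rep_len(seq_len(k), n)
  } else {
    strata <- as.factor(strata)
    for (lv in levels(strata)) {
      which_lv <- which(strata == lv)
      perm <- if (length(which_lv) == 1L) which_lv else rng$sample(which_lv)
      fold[perm] <- rep_len(seq_len(k), length(which_lv))
    }
  }
  lapply(seq_len(k), function(i)
    list(fold = i, train = ids[fold != i], val = ids[fold == i]))
}

#' Confusion matrix
#'
#' @param yTrue,yPred equal-length vectors of class indices in `0..k-1`, or
#'   factors with identical levels.
#' @param k number of classes (inferred from factor levels when omitted).
#' @return `k x k` integer matrix; rows are true classes, columns predicted.
#' @export
confusionMatrix <- function(yTrue, yPred, k = NULL) {
  if (is.factor(yTrue) || is.factor(yPred)) {
    yTrue <- as.factor(yTrue); yPred <- factor(yPred, levels = levels(yTrue))
    if (is.null(k)) k <- nlevels(yTrue)
    lev <- levels(yTrue)
    yTrue <- as.integer(yTrue) - 1L; yPred <- as.integer(yPred) - 1L
  } else lev <- as.character(0:(k - 1L))
  if (length(yTrue) != length(yPred))
    stop("confusionMatrix: label vectors must have equal length")
  if (anyNA(yTrue) || anyNA(yPred) || any(yTrue < 0L | yTrue >= k) ||
      any(yPred < 0L | yPred >= k))
    stop("confusionMatrix: labels out of range 0..k-1")
  cm <- matrix(0L, k, k, dimnames = list(true = lev, pred = lev))
  for (i in seq_along(yTrue))
    cm[yTrue[i] + 1L, yPred[i] + 1L] <- cm[yTrue[i] + 1L, yPred[i] + 1L] + 1L
  cm
}

#' Metric suite from a confusion matrix
#'
#' One-vs-rest TP/FP/FN/TN statistics per class, reported in percent:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 `2*PRE*RE/(PRE+RE)`, sensitivity (identical to recall by
#' definition), and specificity.  Specificity is the true-negative rate
#' `TN/(TN+FP)` in `"standard"` mode; `"paper_literal"` mode instead computes
#' `TN/(TP+TN)`, preserved for auditability against reports that print that
#' form.  Zero-denominator cells are `NA` and flagged, never silently 0.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @param mode specificity definition (see Details).
#' @return a [MetricsReport-class].
#' @examples
#' cm <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE)
#' metricsFromCM(cm)@perClass
#' @export
metricsFromCM <- function(cm, mode = c("standard", "paper_literal")) {
  mode <- match.arg(mode)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2L)
    stop("metricsFromCM: cm must be a k x k matrix, k >= 2")
  total <- sum(cm)
  if (total == 0) stop("metricsFromCM: all-zero confusion matrix")
  k <- nrow(cm)
  lev <- rownames(cm)
  if (is.null(lev)) lev <- as.character(seq_len(k) - 1L)
  flags <- character()
  ratio <- function(num, den, what, cls) {
    if (den == 0) {
      flags <<- c(flags, paste0(what, ":", cls))
      return(NA_real_)
    }
    100 * num / den
  }
  per <- data.frame(Accuracy = numeric(k), Precision = numeric(k),
                    Recall = numeric(k), F1 = numeric(k),
                    Sensitivity = numeric(k), Specificity = numeric(k),
                    row.names = lev)
  for (i in seq_len(k)) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- total - TP - FN - FP
    per$Accuracy[i] <- ratio(TP + TN, total, "accuracy", lev[i])
    per$Precision[i] <- ratio(TP, TP + FP, "precision", lev[i])
    per$Recall[i] <- ratio(TP, TP + FN, "recall", lev[i])
    pre <- per$Precision[i] / 100; re <- per$Recall[i] / 100
    per$F1[i] <- if (anyNA(c(pre, re))) {
      flags <- c(flags, paste0("f1:", lev[i])); NA_real_
    } else if (pre + re == 0) {
      flags <- c(flags, paste0("f1:", lev[i])); NA_real_
    } else 100 * 2 * pre * re / (pre + re)
    per$Sensitivity[i] <- per$Recall[i]
    per$Specificity[i] <- if (mode == "standard")
      ratio(TN, TN + FP, "specificity", lev[i])
    else ratio(TN, TP + TN, "specificity", lev[i])
  }
  macro <- colMeans(per)
  new("MetricsReport", perClass = per, macro = macro,
      overallAccuracy = 100 * sum(diag(cm)) / total, mode = mode,
      flags = unique(flags))
}

#' ROC curve and AUC
#'
#' One-vs-rest receiver operating characteristic.  With a binary 0/1 (or
#' logical/two-level factor) truth vector and a score vector, returns the ROC
#' points (monotone from (0,0) to (1,1)) and the trapezoid-rule AUC.  With a
#' factor truth vector and an `n x k` score matrix, returns one curve per
#' class.  A truth vector containing a single class yields `auc = NA` with an
#' explanatory flag.
#'
#' @param labels truth labels (see Details).
#' @param scores numeric scores in `[0, 1]`, vector or `n x k` matrix.
#' @return `list(points, auc)`, or a named list of such lists per class.
#' @export
rocCurve <- function(labels, scores) {
  if (is.matrix(scores)) {
    labels <- as.factor(labels)
    lev <- colnames(scores)
    if (is.null(lev)) lev <- levels(labels)
    out <- lapply(seq_along(lev), function(j)
      rocCurve(as.integer(labels == lev[j]), scores[, j]))
    names(out) <- lev
    return(out)
  }
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  if (any(scores < -1e-12 | scores > 1 + 1e-12))
    stop("rocCurve: scores must lie in [0, 1]")
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NA_real_, flag = "single-class truth vector"))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties so the curve moves diagonally through tied scores
  grp <- cumsum(!duplicated(s))
  tpI <- tapply(y, grp, sum)
  fpI <- tapply(1 - y, grp, sum)
  tpr <- c(0, cumsum(tpI) / nPos)
  fpr <- c(0, cumsum(fpI) / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# ---- cross-validated experiment -------------------------------------------

#' Fivefold cross-validated training and evaluation
#'
#' Runs the full experimental protocol on a labelled image set: stratified
#' k-fold split, per-fold weight initialisation and training, validation-fold
#' prediction, confusion matrix and metric suite per fold, plus the across-fold
#' average row and pooled one-vs-rest AUC per class.  Augmentation, when
#' enabled, is applied to training folds only so validation images are never
#' augmented copies of training images.
#'
#' @param dataset a [BurnImageSet-class].
#' @param task `"degree"` (3-class) or `"graft"` (binary, labels mapped
#'   through [toBinaryLabels()]).
#' @param config a [BurnNetConfig-class]; its `numClasses` must match the task.
#' @param params hyper-parameters from [trainingHyperparams()].
#' @param k number of folds.
#' @param seed master seed (fold assignment, per-fold init and shuffling).
#' @param augmentTrain optional [augmentationSet()] applied to training folds.
#' @param metricsMode specificity convention for [metricsFromCM()].
#' @param verbose print per-epoch progress.
#' @return a [CVResult-class].
#' @export
runCVExperiment <- function(dataset, task = c("degree", "graft"), config,
                            params = trainingHyperparams(), k = 5L, seed = 1L,
                            augmentTrain = NULL,
                            metricsMode = c("standard", "paper_literal"),
                            verbose = FALSE) {
  task <- match.arg(task)
  metricsMode <- match.arg(metricsMode)
  labels <- if (task == "degree") imageLabels(dataset)
  else toBinaryLabels(imageLabels(dataset))
  kClasses <- nlevels(labels)
  if (config@numClasses != kClasses)
    stop(sprintf("config has %d classes but task '%s' needs %d",
                 config@numClasses, task, kClasses))
  n <- nImages(dataset)
  folds <- kfoldSplit(seq_len(n), k = k, seed = seed, strata = labels)
  reports <- list(); cms <- list(); rows <- list()
  poolScores <- NULL; poolTruth <- NULL

  for (f in folds) {
    trainSet <- .subsetImages(dataset, f$train)
    if (!is.null(augmentTrain)) trainSet <- augmentDataset(trainSet, augmentTrain)
    model <- buildModel(config, seed = .deriveSeed(seed, paste0("fold", f$fold)))
    p2 <- params
    p2$seed <- .deriveSeed(seed, paste0("shuffle", f$fold))
    model <- trainModel(model, trainSet,
                        labels = if (task == "graft")
                          toBinaryLabels(imageLabels(trainSet)) else NULL,
                        params = p2, verbose = verbose)
    valSet <- .subsetImages(dataset, f$val)
    probs <- predictSet(model, valSet, p2$batchSize)
    truth <- labels[f$val]
    pred <- factor(model@classLevels[apply(probs, 1L, which.max)],
                   levels = levels(truth))
    cm <- confusionMatrix(truth, pred)
    rep <- metricsFromCM(cm, metricsMode)
    reports[[f$fold]] <- rep
    cms[[f$fold]] <- cm
    rows[[f$fold]] <- data.frame(
      Fold = paste0("Fold", f$fold),
      Precision = rep@macro[["Precision"]], Recall = rep@macro[["Recall"]],
      F1.score = rep@macro[["F1"]], Sensitivity = rep@macro[["Sensitivity"]],
      Specificity = rep@macro[["Specificity"]],
      Accuracy = rep@overallAccuracy)
    poolScores <- rbind(poolScores, probs)
    poolTruth <- c(poolTruth, as.character(truth))
  }
  tab <- do.call(rbind, rows)
  avg <- data.frame(Fold = "Average", t(colMeans(tab[, -1])))
  names(avg) <- names(tab)
  tab <- rbind(tab, avg)
  row.names(tab) <- NULL
  roc <- rocCurve(factor(poolTruth, levels = levels(labels)), poolScores)
  auc <- vapply(roc, function(r) r$auc, 0)
  rocPoints <- do.call(rbind, lapply(names(roc), function(cl)
    cbind(class = cl, roc[[cl]]$points)))
  cfgHash <- .strHash(yaml::as.yaml(.configToList(config)))
  new("CVResult", task = task, reports = reports, cms = cms, table = tab,
      auc = auc,
      log = list(seed = seed, configHash = cfgHash, params = params,
                 rocPoints = rocPoints,
                 folds = lapply(folds, function(f) f$val),
                 augmentation = if (is.null(augmentTrain)) "none"
                 else paste(augmentTrain$transforms, collapse = ","),
                 augmentPolicy = "training folds only"))
}

.subsetImages <- function(set, idx) {
  new("BurnImageSet", images = set@images[idx],
      manifest = set@manifest[idx, , drop = FALSE])
}

#' Write cross-validation reports to disk
#'
#' Emits `metrics.csv` (fold-by-fold table with average row), one
#' `confusion_fold<i>.csv` per fold, `roc_auc.csv`, `roc_points.csv` (pooled
#' one-vs-rest curves), and `report.json` with the nested per-class detail
#' and the run log (seed, configuration hash).
#'
#' @param cv a [CVResult-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeCVReport <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "metrics.csv")
  write.csv(cv@table, p, row.names = FALSE)
  paths <- c(paths, p)
  for (i in seq_along(cv@cms)) {
    p <- file.path(dir, sprintf("confusion_fold%d.csv", i))
    write.csv(as.data.frame(cv@cms[[i]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "roc_auc.csv")
  write.csv(data.frame(class = names(cv@auc), auc = cv@auc), p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(cv@log$rocPoints)) {
    p <- file.path(dir, "roc_points.csv")
    write.csv(cv@log$rocPoints, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "report.json")
  logNoPoints <- cv@log
  logNoPoints$rocPoints <- NULL
  detail <- list(task = cv@task, log = logNoPoints,
                 perFold = lapply(cv@reports, function(r)
                   list(perClass = r@perClass, macro = as.list(r@macro),
                        overallAccuracy = r@overallAccuracy, flags = r@flags)))
  writeLines(jsonlite::toJSON(detail, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"), p)
  paths <- c(paths, p)
  invisible(paths)
}
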