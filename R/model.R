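# Gradient-boosted tree sleep stager: pretraining, continued-training
# fine-tuning (append-only), prediction, and the leave-one-subject-out
# protocol.

#' Staging model configuration
#'
#' Hyperparameters of the gradient-boosted 5-class stager. Defaults follow
#' the published configuration: 500 boosting rounds, tree depth capped at 5,
#' up to 90 leaves per tree, 60% of features per tree, and stage weights
#' W=1, N1=2.2, N2=1, N3=1.2, REM=1.4 to counter stage imbalance. The
#' learning rate (0.1) and the number of appended fine-tuning rounds (20)
#' are package defaults, exposed here.
#'
#' @param nEstimators boosting rounds for pretraining.
#' @param maxDepth maximum tree depth.
#' @param numLeaves maximum leaves per tree (leaf-wise growth).
#' @param featureFraction fraction of features sampled per tree, in (0, 1].
#' @param learningRate shrinkage per round.
#' @param classWeights named per-stage sample weights.
#' @param finetuneRounds rounds appended during fine-tuning.
#' @param seed integer seed for training randomness (feature subsampling).
#' @return a validated configuration list of class `stagingConfig`.
#' @export
stagingConfig <- function(nEstimators = 500L, maxDepth = 5L, numLeaves = 90L,
                          featureFraction = 0.60, learningRate = 0.1,
                          classWeights = c(W = 1, N1 = 2.2, N2 = 1,
                                           N3 = 1.2, REM = 1.4),
                          finetuneRounds = 20L, seed = 1L) {
  stopifnot(nEstimators >= 1, maxDepth >= 1,
            featureFraction > 0, featureFraction <= 1,
            learningRate > 0, finetuneRounds >= 0)
  if (!all(stageLevels() %in% names(classWeights)))
    stop("classWeights must name all five stages")
  if (any(classWeights <= 0)) stop("class weights must be positive")
  structure(list(nEstimators = as.integer(nEstimators),
                 maxDepth = as.integer(maxDepth),
                 numLeaves = as.integer(numLeaves),
                 featureFraction = featureFraction,
                 learningRate = learningRate,
                 classWeights = classWeights[stageLevels()],
                 finetuneRounds = as.integer(finetuneRounds),
                 seed = as.integer(seed)),
            class = "stagingConfig")
}

.xgbParams <- function(config) {
  list(objective = "multi:softprob", num_class = 5L,
       tree_method = "hist", grow_policy = "lossguide",
       max_depth = config$maxDepth, max_leaves = config$numLeaves,
       eta = config$learningRate, colsample_bytree = config$featureFraction,
       nthread = 1L, seed = config$seed)
}

# Stack per-subject tables into one design matrix + label/weight vectors.
# Class weights are normalized to mean 1, so a global rescaling of the
# weights cannot change the fitted model.
.assembleTraining <- function(features, hypnograms, config) {
  if (is(features, "FeatureTable")) features <- list(features)
  if (is(hypnograms, "Hypnogram")) hypnograms <- list(hypnograms)
  stopifnot(length(features) == length(hypnograms))
  for (i in seq_along(features)) {
    if (nrow(featureMatrix(features[[i]])) != length(hypnograms[[i]]))
      stop("feature/label length mismatch for table ", i)
  }
  X <- do.call(rbind, lapply(features, featureMatrix))
  y <- unlist(lapply(hypnograms, function(h) stageCodes(h@stages)))
  wRaw <- config$classWeights / mean(config$classWeights)
  w <- wRaw[y + 1L]
  list(X = X, y = y, w = unname(w))
}

.wrapEnsemble <- function(booster, nPre, nApp, manifest, config, frac = NA_real_) {
  new("StagingEnsemble", booster = booster, nPretrainedRounds = as.integer(nPre),
      nAppendedRounds = as.integer(nApp), featureManifest = manifest,
      config = unclass(config), appendedWeightFraction = frac)
}

#' Pretrain the staging ensemble
#'
#' Trains the gradient-boosted 5-class softmax model on pooled per-subject
#' feature tables with per-epoch sample weights `classWeights[stage]`
#' (normalized to mean 1). Training is deterministic given the config seed.
#'
#' @param features list of [FeatureTable-class] (one per subject).
#' @param hypnograms list of [Hypnogram-class], aligned with `features`.
#' @param config a [stagingConfig()].
#' @return a [StagingEnsemble-class] with `nAppendedRounds = 0`.
#' @export
pretrainStager <- function(features, hypnograms, config = stagingConfig()) {
  tr <- .assembleTraining(features, hypnograms, config)
  dtrain <- xgboost::xgb.DMatrix(tr$X, label = tr$y, weight = tr$w)
  booster <- xgboost::xgb.train(.xgbParams(config), dtrain,
                                nrounds = config$nEstimators, verbose = 0)
  .wrapEnsemble(booster, config$nEstimators, 0L, colnames(tr$X), config)
}

#' Fine-tune a pretrained ensemble by continued training
#'
#' Appends `config$finetuneRounds` new boosting rounds fitted to the
#' residuals of the pretrained model on the new data (the `init model`
#' style of continued training). The pretrained trees and the model
#' hyperparameters are left untouched: the serialized pretrained tree
#' section of the result is byte-identical to the original. With 0 rounds
#' the pretrained model is returned unchanged.
#'
#' @param pretrained a [StagingEnsemble-class].
#' @param features,hypnograms fine-tuning data (same layout as in
#'   [pretrainStager()]), which must use the identical feature manifest.
#' @param config a [stagingConfig()]; only `finetuneRounds` and `seed` may
#'   usefully differ from the pretraining config.
#' @return a [StagingEnsemble-class] with `nAppendedRounds =
#'   config$finetuneRounds` and the appended-to-pretrained leaf-weight
#'   fraction recorded.
#' @export
finetuneStager <- function(pretrained, features, hypnograms,
                           config = stagingConfig()) {
  stopifnot(is(pretrained, "StagingEnsemble"))
  tr <- .assembleTraining(features, hypnograms, config)
  miss <- setdiff(pretrained@featureManifest, colnames(tr$X))
  extra <- setdiff(colnames(tr$X), pretrained@featureManifest)
  if (length(miss) || length(extra))
    stop("feature manifest mismatch; missing: [",
         paste(miss, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  if (config$finetuneRounds == 0L) return(pretrained)
  X <- tr$X[, pretrained@featureManifest, drop = FALSE]
  dtrain <- xgboost::xgb.DMatrix(X, label = tr$y, weight = tr$w)
  booster <- xgboost::xgb.train(.xgbParams(config), dtrain,
                                nrounds = config$finetuneRounds,
                                xgb_model = pretrained@booster, verbose = 0)
  nPre <- pretrained@nPretrainedRounds
  tt <- xgboost::xgb.model.dt.tree(model = booster)
  leaf <- tt[tt$Feature == "Leaf", ]
  preTrees <- nPre * 5L
  wPre <- sum(abs(leaf$Gain[leaf$Tree < preTrees]))
  wApp <- sum(abs(leaf$Gain[leaf$Tree >= preTrees]))
  .wrapEnsemble(booster, nPre, config$finetuneRounds,
                pretrained@featureManifest, config, frac = wApp / wPre)
}

#' Predict sleep stages
#'
#' Per-epoch 5-class probabilities and the argmax hypnogram; probability
#' ties break toward the lower stage code.
#'
#' @param model a [StagingEnsemble-class].
#' @param features a [FeatureTable-class] whose columns cover the model's
#'   feature manifest.
#' @return list with `probabilities` (epochs x 5 matrix, rows sum to 1) and
#'   `hypnogram` (a [Hypnogram-class]).
#' @export
predictStages <- function(model, features) {
  stopifnot(is(model, "StagingEnsemble"), is(features, "FeatureTable"))
  X <- featureMatrix(features)
  miss <- setdiff(model@featureManifest, colnames(X))
  if (length(miss))
    stop("features missing from table: ", paste(miss, collapse = ", "))
  X <- X[, model@featureManifest, drop = FALSE]
  p <- stats::predict(model@booster, X)
  p <- matrix(p, ncol = 5L, dimnames = list(NULL, stageLevels()))
  p <- p / rowSums(p)
  pred <- stageLevels()[apply(p, 1, which.max)]
  list(probabilities = p, hypnogram = Hypnogram(pred))
}

#' Leave-one-subject-out evaluation of fine-tuning
#'
#' For each held-out subject, predicts its hypnogram (a) with the pretrained
#' model as-is and (b) with a model fine-tuned on all remaining subjects'
#' data, and scores both against the reference. Subjects with fewer than 10
#' epochs are excluded with a warning.
#'
#' @param features list of per-subject [FeatureTable-class].
#' @param hypnograms list of per-subject [Hypnogram-class].
#' @param pretrained a [StagingEnsemble-class].
#' @param config a [stagingConfig()] controlling the fine-tuning rounds.
#' @return list with `reports` (per subject: `subjectId`, `pre` and `fine`
#'   [EvaluationReport-class]s), `summary` (data.frame of per-subject
#'   accuracy/kappa pairs), and `pairedTest` (the [pairedKappaTest()] on the
#'   kappa pairs).
#' @export
losoEvaluate <- function(features, hypnograms, pretrained,
                         config = stagingConfig()) {
  stopifnot(length(features) == length(hypnograms), length(features) >= 2)
  keep <- vapply(hypnograms, length, integer(1)) >= 10L
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with < 10 epochs excluded")
    features <- features[keep]; hypnograms <- hypnograms[keep]
  }
  n <- length(features)
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    fine <- finetuneStager(pretrained, features[-i], hypnograms[-i], config)
    ref <- hypnograms[[i]]
    predPre <- predictStages(pretrained, features[[i]])$hypnogram
    predFine <- predictStages(fine, features[[i]])$hypnogram
    sid <- features[[i]]@subjectId
    reports[[i]] <- list(
      subjectId = sid,
      pre = confusionAndRates(ref, predPre, subjectId = sid),
      fine = confusionAndRates(ref, predFine, subjectId = sid))
  }
  summary <- data.frame(
    subject = vapply(reports, `[[`, character(1), "subjectId"),
    accuracy_pre = vapply(reports, function(r) accuracy(r$pre), numeric(1)),
    kappa_pre = vapply(reports, function(r) kappaScore(r$pre), numeric(1)),
    accuracy_fine = vapply(reports, function(r) accuracy(r$fine), numeric(1)),
    kappa_fine = vapply(reports, function(r) kappaScore(r$fine), numeric(1)),
    stringsAsFactors = FALSE)
  list(reports = reports, summary = summary,
       pairedTest = pairedKappaTest(summary$kappa_pre, summary$kappa_fine))
}

#' Pooled confusion matrix over a set of LOSO reports
#'
#' Sums per-subject confusion matrices (all epochs across participants) and
#' recomputes the rates, for either the pretrained or fine-tuned arm.
#'
#' @param loso result of [losoEvaluate()].
#' @param which `"pre"` or `"fine"`.
#' @return an [EvaluationReport-class] with `subjectId = "pooled"`.
#' @export
pooledReport <- function(loso, which = c("pre", "fine")) {
  which <- match.arg(which)
  conf <- Reduce(`+`, lapply(loso$reports, function(r) r[[which]]@confusion))
  .reportFromConfusion(conf, subjectId = "pooled")
}

#' Serialize / restore a staging ensemble
#'
#' The booster is written in the native JSON text model format; the
#' pretrained/appended round split, manifest and config travel in a sidecar
#' JSON file (`<path>.meta.json`).
#'
#' @param model a [StagingEnsemble-class].
#' @param path file path for the model JSON.
#' @return `writeStager`: invisibly, `path`; `readStager`: the restored
#'   [StagingEnsemble-class].
#' @export
writeStager <- function(model, path) {
  stopifnot(is(model, "StagingEnsemble"))
  xgboost::xgb.save(model@booster, path)
  cfgOut <- model@config
  cfgOut$classWeights <- as.list(cfgOut$classWeights)  # keep stage names
  meta <- list(nPretrainedRounds = model@nPretrainedRounds,
               nAppendedRounds = model@nAppendedRounds,
               featureManifest = model@featureManifest,
               config = cfgOut,
               appendedWeightFraction = if (is.na(model@appendedWeightFraction))
                 NULL else model@appendedWeightFraction)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeStager
#' @export
readStager <- function(path) {
  booster <- xgboost::xgb.load(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  cw <- unlist(meta$config$classWeights)
  cfg <- stagingConfig(meta$config$nEstimators, meta$config$maxDepth,
                       meta$config$numLeaves, meta$config$featureFraction,
                       meta$config$learningRate, cw,
                       meta$config$finetuneRounds, meta$config$seed)
  .wrapEnsemble(booster, meta$nPretrainedRounds, meta$nAppendedRounds,
                meta$featureManifest, cfg,
                frac = if (is.null(meta$appendedWeightFraction)) NA_real_
                       else as.numeric(meta$appendedWeightFraction))
}

#' Text dump of the ensemble's trees
#'
#' One string per tree node line, as produced by the booster's own dump;
#' used to assert that fine-tuning leaves the pretrained section
#' byte-identical.
#'
#' @param model a [StagingEnsemble-class].
#' @param nRounds dump only the first `nRounds` boosting rounds (5 trees per
#'   round); `NULL` dumps all.
#' @return character vector of dump lines.
#' @export
dumpTrees <- function(model, nRounds = NULL) {
  d <- xgboost::xgb.dump(model@booster)
  if (is.null(nRounds)) return(d)
  starts <- grep("^booster\\[", d)
  nTrees <- nRounds * 5L
  if (nTrees >= length(starts)) return(d)
  d[seq_len(starts[nTrees + 1L] - 1L)]
}
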