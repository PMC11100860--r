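#' @import methods
NULL

#' First-order Markov model of sleep-stage transitions
#'
#' Holds the initial stage distribution and the 5x5 row-stochastic matrix of
#' per-epoch transition probabilities used to generate synthetic hypnograms.
#' Rows and columns are ordered W, N1, N2, N3, REM.
#'
#' @slot initial numeric(5), probability of starting the night in each stage.
#' @slot transition 5x5 numeric matrix; `transition[i, j]` is the probability
#'   of moving from stage i to stage j between consecutive 30-s epochs.
#' @export
setClass("TransitionModel",
  representation(initial = "numeric", transition = "matrix"))

setValidity("TransitionModel", function(object) {
  p <- object@initial; P <- object@transition
  msg <- character()
  if (length(p) != 5L) msg <- c(msg, "initial distribution must have length 5")
  if (!all(dim(P) == c(5L, 5L))) msg <- c(msg, "transition matrix must be 5x5")
  if (any(p < 0) || any(P < 0)) msg <- c(msg, "probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-12) msg <- c(msg, "initial distribution must sum to 1")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12))
    msg <- c(msg, sprintf("transition rows must sum to 1 (worst deviation %.3g)",
                          max(abs(rs - 1))))
  if (length(msg)) msg else TRUE
})

#' Stage-specific spectral recipe for the synthetic EEG generator
#'
#' Describes one sleep stage's signal as a sum of band-limited Gaussian noise
#' components plus stage-typical events. Weights are in units of 10 uV of
#' component standard deviation (weight 1 = 10 uV RMS in that band).
#'
#' @slot bandWeights named numeric(6): weights for sdelta (0.4-1 Hz),
#'   fdelta (1-4 Hz), theta (4-8 Hz), alpha (8-12 Hz), sigma (12-16 Hz),
#'   beta (16-30 Hz).
#' @slot spindleFreq sleep-spindle burst frequency, Hz (N2 only in defaults).
#' @slot spindleDur spindle duration, seconds.
#' @slot spindleRate expected spindle count per 30-s epoch (Poisson rate).
#' @slot spindleAmp spindle peak amplitude, uV.
#' @slot slowWaveScale multiplier applied to the slow-delta component,
#'   modelling high-amplitude slow waves (> 1 in N3).
#' @slot weightJitter s.d. of the per-epoch log-normal jitter multiplying
#'   each band weight independently, emulating within-stage
#'   non-stationarity of band power.
#' @slot noiseFloor standard deviation of the broadband (white) floor, uV.
#' @export
setClass("StageSpectralProfile",
  representation(bandWeights = "numeric", spindleFreq = "numeric",
                 spindleDur = "numeric", spindleRate = "numeric",
                 spindleAmp = "numeric", slowWaveScale = "numeric",
                 weightJitter = "numeric", noiseFloor = "numeric"))

setValidity("StageSpectralProfile", function(object) {
  msg <- character()
  if (length(object@bandWeights) != 6L ||
      !identical(names(object@bandWeights), bandDefinitions()$name))
    msg <- c(msg, "bandWeights must be named after the six canonical bands")
  if (any(object@bandWeights < 0)) msg <- c(msg, "band weights must be >= 0")
  if (object@noiseFloor < 0) msg <- c(msg, "noiseFloor must be >= 0")
  if (object@weightJitter < 0) msg <- c(msg, "weightJitter must be >= 0")
  if (object@spindleRate < 0) msg <- c(msg, "spindleRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Acquisition shift between recording modalities
#'
#' Parameterizes how an ear-canal electrode degrades the signal relative to a
#' central scalp derivation: global amplitude loss, disproportionate loss of
#' delta-band content (the deep sources are further away), extra broadband
#' sensor noise, and between-subject gain variability.
#'
#' @slot amplitudeGain overall multiplicative gain in (0, 1].
#' @slot deltaAttenuation extra multiplicative gain applied to the two delta
#'   components only, in (0, 1].
#' @slot noiseSD standard deviation of additive white noise, uV.
#' @slot subjectJitter relative s.d. of the per-subject log-normal gain.
#' @export
setClass("ModalityShift",
  representation(amplitudeGain = "numeric", deltaAttenuation = "numeric",
                 noiseSD = "numeric", subjectJitter = "numeric"))

setValidity("ModalityShift", function(object) {
  msg <- character()
  if (object@amplitudeGain <= 0 || object@amplitudeGain > 1)
    msg <- c(msg, "amplitudeGain must lie in (0, 1]")
  if (object@deltaAttenuation <= 0 || object@deltaAttenuation > 1)
    msg <- c(msg, "deltaAttenuation must lie in (0, 1]")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@subjectJitter < 0) msg <- c(msg, "subjectJitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Single-channel EEG recording
#'
#' One subject-night of single-channel EEG: the sample vector plus the
#' metadata the pipeline needs (sampling rate, modality, subject id).
#'
#' @slot samples numeric vector, uV-scaled arbitrary units.
#' @slot fs sampling rate, Hz.
#' @slot modality `"scalp"` or `"ear"`.
#' @slot subjectId subject identifier.
#' @slot channelName channel label (e.g. `"C4-M1"`, `"EarL-M1"`).
#' @export
setClass("Recording",
  representation(samples = "numeric", fs = "numeric", modality = "character",
                 subjectId = "character", channelName = "character"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (!object@modality %in% c("scalp", "ear"))
    msg <- c(msg, "modality must be 'scalp' or 'ear'")
  if (length(object@samples) < 1L) msg <- c(msg, "samples must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Hypnogram on a 30-second epoch grid
#'
#' Ordered sleep-stage labels, one per epoch, the shared ground-truth (or
#' predicted) sleep structure of a night.
#'
#' @slot stages factor with levels W, N1, N2, N3, REM; one entry per epoch.
#' @slot epochLength epoch duration in seconds (30 by AASM convention).
#' @export
setClass("Hypnogram",
  representation(stages = "factor", epochLength = "numeric"))

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (!identical(levels(object@stages), stageLevels()))
    msg <- c(msg, "stages must be a factor with levels W, N1, N2, N3, REM")
  if (any(is.na(object@stages))) msg <- c(msg, "stages must not contain NA")
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Epoched recording
#'
#' A preprocessed recording cut into fixed-length non-overlapping epochs,
#' stored as an epochs x samples matrix, with the provenance of the
#' preprocessing that produced it.
#'
#' @slot epochs numeric matrix, one row per 30-s epoch.
#' @slot fs sampling rate of the epoched signal, Hz.
#' @slot epochLength epoch duration, seconds.
#' @slot provenance named list of the resample/filter parameters applied.
#' @slot modality,subjectId,channelName carried over from the [Recording-class].
#' @export
setClass("EpochedRecording",
  representation(epochs = "matrix", fs = "numeric", epochLength = "numeric",
                 provenance = "list", modality = "character",
                 subjectId = "character", channelName = "character"))

setValidity("EpochedRecording", function(object) {
  msg <- character()
  if (nrow(object@epochs) < 1L) msg <- c(msg, "need at least one epoch")
  if (ncol(object@epochs) != object@fs * object@epochLength)
    msg <- c(msg, "epoch width must equal fs * epochLength samples")
  if (length(msg)) msg else TRUE
})

#' Per-epoch feature table
#'
#' Epochs x named-features matrix with recording metadata. After
#' [smoothAndNormalize()] the table holds, for every base feature, the raw
#' column plus a trailing 2-minute rolling-mean variant and a centered
#' 7.5-minute triangular-window variant, both z-scored per recording.
#'
#' @slot values numeric matrix, rows = epochs, columns = named features.
#' @slot subjectId,modality,channelName recording metadata.
#' @export
setClass("FeatureTable",
  representation(values = "matrix", subjectId = "character",
                 modality = "character", channelName = "character"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  cn <- colnames(object@values)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "feature columns must be uniquely named")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "feature values must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Gradient-boosted sleep-staging ensemble
#'
#' A 5-class softmax gradient-boosted tree model together with the record of
#' how many boosting rounds were pretrained versus appended by
#' continued-training fine-tuning, and the feature-name manifest the model
#' was trained on. Fine-tuning never alters pretrained trees: trees for
#' rounds `[0, nPretrainedRounds)` are byte-identical before and after.
#'
#' @slot booster the underlying `xgb.Booster`.
#' @slot nPretrainedRounds boosting rounds in the pretrained section.
#' @slot nAppendedRounds boosting rounds appended by fine-tuning.
#' @slot featureManifest character vector of feature names, in model order.
#' @slot config the [stagingConfig()] list used for training.
#' @slot appendedWeightFraction sum of |leaf values| of appended trees as a
#'   fraction of the pretrained trees' (NA before fine-tuning).
#' @export
setClass("StagingEnsemble",
  representation(booster = "ANY", nPretrainedRounds = "integer",
                 nAppendedRounds = "integer", featureManifest = "character",
                 config = "list", appendedWeightFraction = "numeric"))

#' Per-subject staging evaluation
#'
#' Confusion matrix and the derived agreement metrics for one predicted
#' hypnogram against its reference.
#'
#' @slot confusion 5x5 count matrix; rows = reference stage, cols = predicted.
#' @slot sensitivity,precision named per-stage proportions (NaN where the
#'   stage is absent from the reference / never predicted).
#' @slot accuracy overall proportion of epochs staged correctly.
#' @slot kappa Cohen's kappa in [-1, 1].
#' @slot subjectId subject identifier ("" when pooled).
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", sensitivity = "numeric",
                 precision = "numeric", accuracy = "numeric", kappa = "numeric",
                 subjectId = "character"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (!all(dim(object@confusion) == c(5L, 5L)))
    msg <- c(msg, "confusion matrix must be 5x5")
  if (length(msg)) msg else TRUE
})

#' Shapley attribution matrix
#'
#' Per-epoch, per-feature, per-stage additive contributions to the model's
#' margin (log-odds) output, plus the per-stage base values. Satisfies local
#' accuracy: `baseValues + rowSums(values)` equals the model margin for every
#' epoch and stage head.
#'
#' @slot values 3-d array: epochs x stages x features.
#' @slot baseValues epochs x stages matrix of base (expected-margin) values.
#' @slot modelId short description of the explained model.
#' @export
setClass("ShapMatrix",
  representation(values = "array", baseValues = "matrix", modelId = "character"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: subject %s, %s channel '%s', %.0f Hz, %.1f min\n",
              object@subjectId, object@modality, object@channelName,
              object@fs, length(object@samples) / object@fs / 60))
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(object@stages)
  cat(sprintf("Hypnogram: %d epochs of %gs (%s)\n", length(object@stages),
              object@epochLength,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d epochs x %d features (subject %s, %s)\n",
              nrow(object@values), ncol(object@values),
              object@subjectId, object@modality))
})

setMethod("show", "StagingEnsemble", function(object) {
  cat(sprintf(
    "StagingEnsemble: %d pretrained + %d appended rounds, %d features\n",
    object@nPretrainedRounds, object@nAppendedRounds,
    length(object@featureManifest)))
  if (!is.na(object@appendedWeightFraction))
    cat(sprintf("  appended leaf-weight fraction: %.4f%%\n",
                100 * object@appendedWeightFraction))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport%s: accuracy %.3f, kappa %.3f over %d epochs\n",
              if (nzchar(object@subjectId)) paste0(" [", object@subjectId, "]") else "",
              object@accuracy, object@kappa, sum(object@confusion)))
})

setMethod("show", "TransitionModel", function(object) {
  cat("TransitionModel (rows: from, cols: to)\n")
  print(round(object@transition, 3))
})

# ---- simple accessors -------------------------------------------------------

#' @describeIn Hypnogram-class number of epochs
#' @param x a `Hypnogram`
#' @export
setMethod("length", "Hypnogram", function(x) length(x@stages))

#' Accessors for package classes
#'
#' Small generic accessors used instead of direct slot access: `stages()`
#' (stage factor of a hypnogram), `samples()` (signal of a recording),
#' `featureMatrix()` / `featureNames()` (feature table contents),
#' `confusionMatrix()`, `kappa()`, `accuracy()` (evaluation metrics),
#' `shapArray()` (Shapley contribution array).
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stages", function(object) standardGeneric("stages"))
#' @rdname accessors
#' @export
setMethod("stages", "Hypnogram", function(object) object@stages)

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "Recording", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochedRecording", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureTable", function(object) colnames(object@values))
#' @rdname accessors
#' @export
setMethod("featureNames", "StagingEnsemble", function(object) object@featureManifest)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(object) object@confusion)

#' @rdname accessors
#' @export
setGeneric("kappaScore", function(object) standardGeneric("kappaScore"))
#' @rdname accessors
#' @export
setMethod("kappaScore", "EvaluationReport", function(object) object@kappa)

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setMethod("accuracy", "EvaluationReport", function(object) object@accuracy)

#' @rdname accessors
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setMethod("sensitivity", "EvaluationReport", function(object) object@sensitivity)

#' @rdname accessors
#' @export
setGeneric("precision", function(object) standardGeneric("precision"))
#' @rdname accessors
#' @export
setMethod("precision", "EvaluationReport", function(object) object@precision)

#' @rdname accessors
#' @export
setGeneric("shapArray", function(object) standardGeneric("shapArray"))
#' @rdname accessors
#' @export
setMethod("shapArray", "ShapMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("baseValues", function(object) standardGeneric("baseValues"))
#' @rdname accessors
#' @export
setMethod("baseValues", "ShapMatrix", function(object) object@baseValues)

#' Construct a Hypnogram
#'
#' @param stages character vector or factor of stage labels.
#' @param epochLength epoch duration in seconds.
#' @return a [Hypnogram-class] object.
#' @export
Hypnogram <- function(stages, epochLength = 30) {
  new("Hypnogram", stages = stageFactor(stages), epochLength = epochLength)
}

#' Construct a Recording
#'
#' @param samples numeric signal vector (uV-scaled).
#' @param fs sampling rate in Hz.
#' @param modality `"scalp"` or `"ear"`.
#' @param subjectId subject identifier.
#' @param channelName channel label.
#' @return a [Recording-class] object.
#' @export
Recording <- function(samples, fs, modality = "scalp", subjectId = "s01",
                      channelName = if (modality == "scalp") "C4-M1" else "EarL-M1") {
  new("Recording", samples = as.numeric(samples), fs = fs, modality = modality,
      subjectId = subjectId, channelName = channelName)
}

#' Construct a FeatureTable
#'
#' @param values epochs x features numeric matrix with unique column names.
#' @param subjectId,modality,channelName recording metadata.
#' @return a [FeatureTable-class] object.
#' @export
FeatureTable <- function(values, subjectId = "s01", modality = "scalp",
                         channelName = "") {
  new("FeatureTable", values = as.matrix(values), subjectId = subjectId,
      modality = modality, channelName = channelName)
}
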