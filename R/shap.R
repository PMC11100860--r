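# Shapley-value attribution of staging predictions: exact tree-path
# (path-dependent TreeSHAP) contributions per epoch, feature and stage head,
# plus top-feature rankings per reference stage.

#' Shapley attributions for a staging ensemble
#'
#' Exact TreeSHAP contributions (path-dependent conditioning over the
#' training cover counts stored in the trees) of every feature to every
#' epoch's margin output, per stage head. Satisfies local accuracy: for each
#' epoch and stage, base value + sum of contributions equals the model's
#' margin output.
#'
#' @param model a [StagingEnsemble-class].
#' @param features a [FeatureTable-class] covering the model manifest.
#' @return a [ShapMatrix-class] (epochs x stages x features).
#' @export
shapValues <- function(model, features) {
  stopifnot(is(model, "StagingEnsemble"), is(features, "FeatureTable"))
  X <- featureMatrix(features)
  miss <- setdiff(model@featureManifest, colnames(X))
  if (length(miss))
    stop("features missing from table: ", paste(miss, collapse = ", "))
  X <- X[, model@featureManifest, drop = FALSE]
  pc <- stats::predict(model@booster, X, predcontrib = TRUE)
  # array: epochs x stages x (features, BIAS)
  p <- length(model@featureManifest)
  vals <- pc[, , seq_len(p), drop = FALSE]
  dimnames(vals) <- list(NULL, stageLevels(), model@featureManifest)
  base <- pc[, , p + 1L]
  colnames(base) <- stageLevels()
  new("ShapMatrix", values = vals, baseValues = base,
      modelId = sprintf("%d+%d rounds", model@nPretrainedRounds,
                        model@nAppendedRounds))
}

#' Top features for predicting one stage
#'
#' Ranks features by mean absolute Shapley contribution to the target
#' stage's output head, averaged over the epochs whose *reference* label is
#' that stage (e.g. "which features drive the N3 head during true N3
#' sleep"). Ties are broken by feature name for a stable ordering.
#'
#' @param shap a [ShapMatrix-class].
#' @param reference a [Hypnogram-class] aligned with the SHAP rows.
#' @param stage target stage label.
#' @param k number of top features to return (capped at the feature count).
#' @return data.frame with columns `rank`, `feature`, `mean_abs_shap`;
#'   attribute `stage`.
#' @export
topFeatures <- function(shap, reference, stage, k = 5L) {
  stopifnot(is(shap, "ShapMatrix"))
  ref <- if (is(reference, "Hypnogram")) reference@stages
         else stageFactor(reference)
  if (dim(shap@values)[1] != length(ref))
    stop("SHAP rows and reference hypnogram differ in length")
  stage <- as.character(stage)
  if (!stage %in% stageLevels()) stop("unknown stage: ", stage)
  sel <- which(as.character(ref) == stage)
  if (length(sel) == 0) stop("stage ", stage, " absent from reference")
  m <- abs(shap@values[sel, stage, , drop = FALSE])
  means <- apply(m, 3, mean)
  ord <- order(-means, names(means))
  k <- min(k, length(means))
  out <- data.frame(rank = seq_len(k), feature = names(means)[ord][seq_len(k)],
                    mean_abs_shap = unname(means[ord])[seq_len(k)],
                    stringsAsFactors = FALSE)
  attr(out, "stage") <- stage
  out
}

# ---- independent exhaustive-subset oracle (used by the test suite) ---------

# Parse the booster into a per-tree node list usable for subset-restricted
# prediction.
.treeTable <- function(model) {
  tt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model@booster))
  split(tt, tt$Tree)
}

# f_S(x) for one tree: follow the split when the feature is in S, otherwise
# take the cover-weighted average over both children (path-dependent
# expectation, the same conditioning convention the TreeSHAP attributions
# use).
.treeExpectation <- function(tree, x, inS) {
  rows <- stats::setNames(seq_len(nrow(tree)), tree$ID)
  rec <- function(id) {
    nd <- tree[rows[[id]], ]
    if (nd$Feature == "Leaf") return(nd$Gain)
    if (inS[[nd$Feature]]) {
      nxt <- if (x[[nd$Feature]] < nd$Split) nd$Yes else nd$No
      return(rec(nxt))
    }
    cy <- tree$Cover[rows[[nd$Yes]]]; cn <- tree$Cover[rows[[nd$No]]]
    (cy * rec(nd$Yes) + cn * rec(nd$No)) / (cy + cn)
  }
  rec(tree$ID[tree$Node == 0])
}

#' Brute-force Shapley values over all feature subsets
#'
#' Independent oracle for [shapValues()]: evaluates the subset-restricted
#' prediction `f_S` of every tree by path-dependent expectation and sums the
#' Shapley weights over all `2^|F|` subsets. Exponential in the number of
#' features — intended for models with at most ~10 features.
#'
#' @param model a [StagingEnsemble-class].
#' @param x named numeric vector, one instance.
#' @param stage stage label selecting the output head.
#' @return named numeric of per-feature Shapley values; attribute `base`
#'   holds `f_` of the empty subset.
#' @export
bruteForceShap <- function(model, x, stage = "W") {
  feats <- model@featureManifest
  if (length(feats) > 12) stop("brute force limited to <= 12 features")
  cls <- match(stage, stageLevels()) - 1L
  trees <- .treeTable(model)
  treeIdx <- as.integer(names(trees))
  headTrees <- trees[treeIdx %% 5L == cls]
  fS <- function(S) {
    inS <- stats::setNames(feats %in% S, feats)
    sum(vapply(headTrees, .treeExpectation, numeric(1), x = x, inS = inS))
  }
  nF <- length(feats)
  bits <- 2^(seq_len(nF) - 1)
  # f_S for every subset, indexed by bitmask + 1
  vals <- vapply(0:(2^nF - 1), function(m) fS(feats[bitwAnd(m, bits) > 0]),
                 numeric(1))
  phi <- stats::setNames(numeric(nF), feats)
  for (i in seq_len(nF)) {
    bi <- bits[i]
    for (m in 0:(2^nF - 1)) {
      if (bitwAnd(m, bi) > 0) next
      sz <- sum(bitwAnd(m, bits) > 0)
      wgt <- factorial(sz) * factorial(nF - sz - 1) / factorial(nF)
      phi[i] <- phi[i] + wgt * (vals[m + bi + 1L] - vals[m + 1L])
    }
  }
  attr(phi, "base") <- vals[1L]
  phi
}
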