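# Mutual information between features and sleep stages: plug-in estimate on
# a quantile-binned joint table, in nats.

# equal-frequency binning; ties broken by occurrence order so strictly
# monotone transforms of the feature leave the binning unchanged. A feature
# with at most `bins` distinct values is already discrete and is binned by
# value identity (rank bins would split or merge its levels arbitrarily).
.quantileBin <- function(x, bins = 10L) {
  u <- unique(x)
  if (length(u) <= bins) return(match(x, sort(u)))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

#' Plug-in mutual information of a joint count table
#'
#' `MI = sum p(x,y) log( p(x,y) / (p(x) p(y)) )` in natural-log units, with
#' `0 log 0 = 0`.
#'
#' @param tab two-way contingency table or count matrix.
#' @return MI in nats (>= 0 up to floating point).
#' @export
miFromTable <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  sum(p[idx] * log(p[idx] / (px[idx[, 1]] * py[idx[, 2]])))
}

#' Mutual information between a feature and the sleep stages
#'
#' The continuous feature is discretized into `bins` equal-frequency
#' (quantile) bins, ties broken by rank, and the plug-in MI of the resulting
#' joint table with the stage labels is returned in nats. A constant feature
#' has MI 0. Quantile binning makes the estimate invariant under strictly
#' monotone transforms of the feature and robust to heavy tails.
#'
#' @param featureValues numeric vector, one value per epoch.
#' @param stages a [Hypnogram-class] or stage factor of the same length
#'   (>= 50 epochs).
#' @param bins number of quantile bins.
#' @return MI in nats (scalar).
#' @export
mutualInformation <- function(featureValues, stages, bins = 10L) {
  if (is(stages, "Hypnogram")) stages <- stages@stages
  stages <- stageFactor(stages)
  if (length(featureValues) != length(stages))
    stop("feature and stage vectors must have equal length")
  if (length(stages) < 50) stop("need at least 50 epochs for a stable MI")
  if (stats::sd(featureValues) == 0) return(0)
  b <- .quantileBin(featureValues, bins)
  miFromTable(table(b, stages))
}

#' Compare per-feature mutual information between modalities
#'
#' Computes, for every shared feature column, the MI with the (shared) stage
#' labels from the scalp table and from the ear table, plus the count of
#' features where the scalp MI is strictly higher — the modality-salience
#' summary.
#'
#' @param scalp,ear [FeatureTable-class] objects (or lists of them, pooled
#'   across subjects) sharing the same column set.
#' @param stages a [Hypnogram-class], stage factor, or list matching the
#'   feature-table lists.
#' @param bins number of quantile bins.
#' @return data.frame with columns `feature`, `mi_scalp`, `mi_ear`, and
#'   attributes `nScalpGreater` (strict count) and `nFeatures`.
#' @export
compareModalities <- function(scalp, ear, stages, bins = 10L) {
  pool <- function(x) {
    if (is(x, "FeatureTable")) return(x@values)
    do.call(rbind, lapply(x, featureMatrix))
  }
  xs <- pool(scalp); xe <- pool(ear)
  if (is.list(stages) && !is(stages, "Hypnogram"))
    stages <- unlist(lapply(stages, function(h)
      as.character(if (is(h, "Hypnogram")) h@stages else h)))
  if (is(stages, "Hypnogram")) stages <- stages@stages
  stages <- stageFactor(stages)
  common <- intersect(colnames(xs), colnames(xe))
  extra <- c(setdiff(colnames(xs), colnames(xe)),
             setdiff(colnames(xe), colnames(xs)))
  if (length(extra) > 0)
    stop("feature columns differ between modalities: ",
         paste(extra, collapse = ", "))
  if (length(common) == 0) stop("no shared feature columns")
  if (nrow(xs) != length(stages) || nrow(xe) != length(stages))
    stop("feature tables and stages must cover the same epochs")
  miS <- vapply(common, function(f) mutualInformation(xs[, f], stages, bins),
                numeric(1))
  miE <- vapply(common, function(f) mutualInformation(xe[, f], stages, bins),
                numeric(1))
  out <- data.frame(feature = common, mi_scalp = unname(miS),
                    mi_ear = unname(miE), stringsAsFactors = FALSE)
  attr(out, "nScalpGreater") <- sum(out$mi_scalp > out$mi_ear)
  attr(out, "nFeatures") <- nrow(out)
  out
}
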