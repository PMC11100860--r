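# Scoring predicted against reference hypnograms: confusion matrix,
# per-stage sensitivity/precision, accuracy, Cohen's kappa, and the paired
# comparison of per-subject kappas.

.reportFromConfusion <- function(conf, subjectId = "") {
  sens <- diag(conf) / rowSums(conf)   # NaN where stage absent from reference
  prec <- diag(conf) / colSums(conf)   # NaN where stage never predicted
  names(sens) <- names(prec) <- stageLevels()
  new("EvaluationReport", confusion = conf, sensitivity = sens,
      precision = prec, accuracy = sum(diag(conf)) / sum(conf),
      kappa = .kappaFromConfusion(conf), subjectId = subjectId)
}

.kappaFromConfusion <- function(conf) {
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  if (pe >= 1) {
    if (po >= 1) return(1)
    warning("degenerate marginals (chance agreement 1); kappa set to 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

.asStageFactor <- function(x) {
  if (is(x, "Hypnogram")) x@stages else stageFactor(x)
}

#' Confusion matrix and per-stage rates
#'
#' 5x5 confusion matrix (rows = reference, columns = predicted) with
#' per-stage sensitivity (recall) and precision, overall accuracy, and
#' Cohen's kappa. Stages absent from the reference get sensitivity NaN (not
#' zero); stages never predicted get precision NaN.
#'
#' @param reference,predicted [Hypnogram-class]s (or stage vectors) of equal
#'   length.
#' @param subjectId optional subject identifier carried into the report.
#' @return an [EvaluationReport-class].
#' @export
confusionAndRates <- function(reference, predicted, subjectId = "") {
  ref <- .asStageFactor(reference); pred <- .asStageFactor(predicted)
  if (length(ref) != length(pred))
    stop("reference and predicted hypnograms differ in length")
  conf <- unclass(table(ref, pred))
  dimnames(conf) <- list(reference = stageLevels(), predicted = stageLevels())
  .reportFromConfusion(conf, subjectId = subjectId)
}

#' Cohen's kappa between two hypnograms
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' product of the empirical marginals. Perfect agreement on a single stage
#' (`p_e = 1`, `p_o = 1`) is defined as 1; `p_e = 1` with disagreement is
#' defined as 0 with a warning.
#'
#' @param reference,predicted [Hypnogram-class]s or stage vectors of equal
#'   length >= 2.
#' @return kappa in `[-1, 1]`.
#' @export
cohenKappa <- function(reference, predicted) {
  ref <- .asStageFactor(reference); pred <- .asStageFactor(predicted)
  if (length(ref) != length(pred)) stop("length mismatch")
  if (length(ref) < 2) stop("need at least 2 epochs")
  .kappaFromConfusion(unclass(table(ref, pred)))
}

#' Paired comparison of per-subject kappas
#'
#' Two-sided dependent (paired) t-test on the per-subject kappa differences
#' between the fine-tuned and pretrained models, plus the count of subjects
#' strictly improved. Degenerate inputs: if every difference is exactly
#' zero, t is undefined and p is reported as 1; if the differences are
#' constant but nonzero (zero variance), t is undefined and p is reported as
#' 0 with a warning, since the direction is unambiguous.
#'
#' @param preKappas,fineKappas equal-length numeric vectors (>= 2 subjects).
#' @return list with `meanDifference`, `t`, `p`, `nImproved`, `n`, and the
#'   per-subject `differences`.
#' @export
pairedKappaTest <- function(preKappas, fineKappas) {
  stopifnot(length(preKappas) == length(fineKappas), length(preKappas) >= 2)
  d <- fineKappas - preKappas
  nImp <- sum(d > 0)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(meanDifference = 0, t = NA_real_, p = 1,
                  nImproved = 0L, n = length(d), differences = d))
    }
    warning("constant nonzero kappa differences: t undefined, p set to 0")
    return(list(meanDifference = mean(d), t = NA_real_, p = 0,
                nImproved = nImp, n = length(d), differences = d))
  }
  tt <- stats::t.test(fineKappas, preKappas, paired = TRUE)
  list(meanDifference = unname(tt$estimate), t = unname(tt$statistic),
       p = tt$p.value, nImproved = nImp, n = length(d), differences = d)
}

#' Render a night summary figure
#'
#' Writes a two-panel PNG: a time-frequency spectrogram built from
#' consecutive Welch periodograms of 30-s epochs (log10 power, 0.4-30 Hz)
#' above the hypnogram drawn on the conventional inverted stage axis with
#' REM epochs highlighted.
#'
#' @param rec a [Recording-class].
#' @param hypnogram a non-empty [Hypnogram-class].
#' @param file output PNG path.
#' @param width,height device size in pixels.
#' @return invisibly, `file`.
#' @export
renderSummary <- function(rec, hypnogram, file, width = 900, height = 600) {
  stopifnot(is(rec, "Recording"), is(hypnogram, "Hypnogram"))
  if (length(hypnogram) == 0) stop("empty hypnogram")
  ep <- epochRecording(rec, hypnogram@epochLength)
  nEp <- min(nrow(ep@epochs), length(hypnogram))
  spec <- vapply(seq_len(nEp), function(i) {
    w <- welchPSD(ep@epochs[i, ], rec@fs)
    sel <- w$freq >= 0.4 & w$freq <= 30
    log10(pmax(w$psd[sel], 1e-12))
  }, numeric(sum({w1 <- welchPSD(ep@epochs[1, ], rec@fs); w1$freq >= 0.4 & w1$freq <= 30})))
  freqs <- w1$freq[w1$freq >= 0.4 & w1$freq <= 30]
  hours <- (seq_len(nEp) - 0.5) * hypnogram@epochLength / 3600
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 2, 1))
  graphics::image(hours, freqs, t(spec), col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "", ylab = "Frequency (Hz)",
                  main = sprintf("Spectrogram — subject %s (%s)",
                                 rec@subjectId, rec@modality))
  # hypnogram on the conventional axis: W on top, N3 at the bottom, REM between
  depth <- c(W = 0, REM = -1, N1 = -2, N2 = -3, N3 = -4)
  yy <- depth[as.character(stages(hypnogram)[seq_len(nEp)])]
  graphics::plot(hours, yy, type = "s", yaxt = "n", xlab = "Time (h)",
                 ylab = "Stage", main = "Hypnogram", ylim = c(-4.3, 0.3))
  graphics::axis(2, at = unname(depth), labels = names(depth), las = 1)
  rem <- which(as.character(stages(hypnogram)[seq_len(nEp)]) == "REM")
  if (length(rem))
    graphics::points(hours[rem], yy[rem], col = "red", pch = 15, cex = 0.5)
  invisible(file)
}
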