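# Per-epoch feature set: time-domain moments, non-linear descriptors, Welch
# band powers and ratios, plus smoothed-normalized variants. Base features
# are pure functions of a single epoch; only the smoothing step looks across
# epochs.

#' Canonical EEG frequency bands
#'
#' Six bands tiling 0.4-30 Hz without overlap: slow delta (sdelta, 0.4-1),
#' fast delta (fdelta, 1-4), theta (4-8), alpha (8-12), sigma (12-16,
#' spindle band) and beta (16-30).
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
bandDefinitions <- function() {
  data.frame(name = c("sdelta", "fdelta", "theta", "alpha", "sigma", "beta"),
             low  = c(0.4, 1, 4, 8, 12, 16),
             high = c(1, 4, 8, 12, 16, 30),
             stringsAsFactors = FALSE)
}

#' Time-domain features of one epoch
#'
#' Standard deviation, skewness, interquartile range and excess (Fisher)
#' kurtosis. A constant epoch yields std 0, iqr 0 and — by the degenerate
#' convention — skewness 0 and kurtosis 0.
#'
#' @param epoch numeric vector (length >= 4).
#' @return named numeric: `std`, `skew`, `iqr`, `kurt`.
#' @export
timeDomainFeatures <- function(epoch) {
  stopifnot(length(epoch) >= 4)
  s <- stats::sd(epoch)
  if (s == 0) {
    sk <- 0; ku <- 0
  } else {
    sk <- e1071::skewness(epoch, type = 2)
    ku <- e1071::kurtosis(epoch, type = 2)
  }
  c(std = s, skew = sk, iqr = stats::IQR(epoch), kurt = ku)
}

# zero crossings: sign changes of consecutive samples; exact zeros carry the
# previous sign so a touch without crossing is not counted.
.zeroCrossings <- function(x) {
  s <- sign(x)
  if (s[1] == 0) s[1] <- 1
  for (i in which(s == 0)) s[i] <- s[i - 1]
  sum(diff(s) != 0)
}

# permutation entropy, order 3, delay 1, normalized by log(3!) to [0,1]
.permutationEntropy <- function(x) {
  n <- length(x)
  a <- x[1:(n - 2)]; b <- x[2:(n - 1)]; c <- x[3:n]
  code <- 4L * (a < b) + 2L * (b < c) + (a < c)
  p <- tabulate(code + 1L, nbins = 8L)
  p <- p[p > 0] / length(code)
  h <- -sum(p * log(p))
  min(h / log(6), 1)
}

# Higuchi fractal dimension, kmax = 10: slope of log mean curve length vs
# log(1/k). The k offset sub-series are evaluated together via lagged
# differences grouped by start-offset residue.
.higuchiFD <- function(x, kmax = 10L) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    d <- abs(diff(x, lag = k))
    r <- ((seq_len(n - k) - 1L) %% k) + 1L
    sums <- as.numeric(rowsum(d, r))
    counts <- tabulate(r, nbins = k)
    lk[k] <- mean(sums * (n - 1) / (k * counts * k))
  }
  if (any(lk <= 0)) return(1)
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(kmax))))[[2]]
}

# Petrosian fractal dimension from sign changes of the first difference
.petrosianFD <- function(x) {
  n <- length(x)
  nd <- .zeroCrossings(diff(x))
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' Non-linear features of one epoch
#'
#' Zero-crossing count, Hjorth mobility and complexity, normalized
#' permutation entropy (order 3, delay 1), Higuchi fractal dimension
#' (kmax 10) and Petrosian fractal dimension. Mobility is
#' `sqrt(var(diff(x))/var(x))`; complexity is the mobility of the first
#' difference divided by the mobility of the signal. A zero-variance epoch
#' yields mobility and complexity 0 with a warning.
#'
#' @param epoch numeric vector (length >= 100).
#' @return named numeric: `nzc`, `hmob`, `hcomp`, `perm`, `higuchi`,
#'   `petrosian`.
#' @export
nonlinearFeatures <- function(epoch) {
  stopifnot(length(epoch) >= 100)
  v0 <- stats::var(epoch)
  if (v0 == 0) {
    warning("zero-variance epoch: Hjorth parameters set to 0")
    return(c(nzc = 0, hmob = 0, hcomp = 0, perm = 0, higuchi = 1,
             petrosian = 1))
  }
  d1 <- diff(epoch); d2 <- diff(d1)
  v1 <- stats::var(d1); v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 > 0) sqrt(v2 / v1) / mob else 0
  c(nzc = .zeroCrossings(epoch - mean(epoch)),
    hmob = mob, hcomp = comp,
    perm = .permutationEntropy(epoch),
    higuchi = .higuchiFD(epoch),
    petrosian = .petrosianFD(epoch))
}

#' Welch power spectral density
#'
#' Median-averaged modified periodogram: Hann-windowed segments of
#' `segLength` seconds with 50% overlap. Median averaging (rather than the
#' mean) is robust to occasional high-amplitude segments.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param segLength segment length in seconds (default 5, i.e. 0.2 Hz
#'   resolution at any rate).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welchPSD <- function(x, fs, segLength = 5) {
  nper <- round(segLength * fs)
  if (length(x) < 2 * nper)
    stop("signal shorter than two Welch segments")
  step <- nper %/% 2
  starts <- seq(1, length(x) - nper + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / (nper - 1)))  # Hann
  segs <- vapply(starts, function(s) x[s:(s + nper - 1)] * win,
                 numeric(nper))
  sp <- stats::mvfft(segs)
  nf <- nper %/% 2 + 1
  pxx <- (Mod(sp[seq_len(nf), , drop = FALSE])^2) / (fs * sum(win^2))
  pxx[2:(nf - 1), ] <- 2 * pxx[2:(nf - 1), ]  # one-sided
  # row medians via one joint sort (much cheaper than per-row median())
  k <- ncol(pxx)
  sorted <- matrix(pxx[order(row(pxx), pxx)], nrow = nf, byrow = TRUE)
  med <- if (k %% 2 == 1) sorted[, (k + 1) %/% 2]
         else 0.5 * (sorted[, k %/% 2] + sorted[, k %/% 2 + 1])
  list(freq = (seq_len(nf) - 1) * fs / nper, psd = med)
}

#' Spectral features of one epoch
#'
#' Relative band powers over the six canonical bands (summing to 1), the
#' broadband absolute power (0.4-30 Hz, uV^2), and the four clinical power
#' ratios delta/beta, delta/sigma, delta/theta and alpha/theta, where delta
#' means slow + fast delta combined. An all-zero epoch yields uniform
#' relative powers (with a warning) and zero ratios.
#'
#' @param epoch numeric vector.
#' @param fs sampling rate, Hz.
#' @param bands band table as from [bandDefinitions()].
#' @return named numeric of 11 features.
#' @export
spectralFeatures <- function(epoch, fs, bands = bandDefinitions()) {
  w <- welchPSD(epoch, fs)
  df <- w$freq[2] - w$freq[1]
  absBand <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- w$freq >= bands$low[b] & w$freq < bands$high[b]
    sum(w$psd[sel]) * df
  }, numeric(1))
  names(absBand) <- bands$name
  tot <- sum(absBand)
  if (tot <= 0) {
    warning("all-zero epoch: relative band powers undefined, using uniform")
    rel <- rep(1 / nrow(bands), nrow(bands))
    names(rel) <- bands$name
    return(c(rel, abspow = 0, dbratio = 0, dsratio = 0, dtratio = 0,
             atratio = 0))
  }
  rel <- absBand / tot
  delta <- absBand[["sdelta"]] + absBand[["fdelta"]]
  c(rel, abspow = tot,
    dbratio = delta / absBand[["beta"]],
    dsratio = delta / absBand[["sigma"]],
    dtratio = delta / absBand[["theta"]],
    atratio = absBand[["alpha"]] / absBand[["theta"]])
}

# trailing (causal) rolling mean over `w` epochs, window truncated at the
# start of the night
.rollMeanTrailing <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  lo <- pmax(seq_len(n) - w, 0L)
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

# centered triangular-weighted mean, 2h+1 taps, renormalized at the edges
.triangularCentered <- function(x, taps) {
  h <- (taps - 1L) %/% 2L
  kern <- (h + 1) - abs(seq(-h, h))
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    kk <- kern[j - i + h + 1L]
    out[i] <- sum(x[j] * kk) / sum(kk)
  }
  out
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Append smoothed-normalized feature variants
#'
#' For each base feature, appends a trailing 2-minute rolling-mean variant
#' (4 epochs, causal, truncated at the start) and a centered 7.5-minute
#' triangular-window variant (15 taps, renormalized at the edges). Both are
#' z-scored per recording (mean 0, s.d. 1 across the night); a zero-variance
#' column normalizes to all-zero. Raw columns are retained in their original
#' units.
#'
#' @param table a [FeatureTable-class] of base features.
#' @return a `FeatureTable` with three columns per base feature.
#' @export
smoothAndNormalize <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  x <- table@values
  base <- colnames(x)
  roll <- apply(x, 2, .rollMeanTrailing, w = 4L)
  tri <- apply(x, 2, .triangularCentered, taps = 15L)
  if (nrow(x) == 1L) { roll <- matrix(roll, 1); tri <- matrix(tri, 1) }
  roll <- apply(roll, 2, .zscore); tri <- apply(tri, 2, .zscore)
  if (nrow(x) == 1L) { roll <- matrix(roll, 1); tri <- matrix(tri, 1) }
  colnames(roll) <- paste0(base, "_roll2min_norm")
  colnames(tri) <- paste0(base, "_tri7.5min_norm")
  FeatureTable(cbind(x, roll, tri), subjectId = table@subjectId,
               modality = table@modality, channelName = table@channelName)
}

#' Extract the full per-epoch feature table
#'
#' Composes the time-domain, non-linear and spectral features for every
#' epoch, appends the two smoothed-normalized variants per base feature, and
#' adds two temporal-context columns (`epoch_index`, and `time_norm`, the
#' epoch's position in the night scaled to `[0, 1]`). With the default
#' configuration this yields 21 base features x 3 variants + 2 = 65 columns
#' per channel.
#'
#' @param rec an [EpochedRecording-class] (100 Hz, band-passed).
#' @param smooth logical; append smoothed-normalized variants (default TRUE).
#' @return a [FeatureTable-class].
#' @export
extractFeatures <- function(rec, smooth = TRUE) {
  stopifnot(is(rec, "EpochedRecording"))
  fs <- rec@fs
  nEp <- nrow(rec@epochs)
  feats <- t(vapply(seq_len(nEp), function(i) {
    e <- rec@epochs[i, ]
    c(timeDomainFeatures(e), nonlinearFeatures(e), spectralFeatures(e, fs))
  }, numeric(21)))
  ft <- FeatureTable(feats, subjectId = rec@subjectId, modality = rec@modality,
                     channelName = rec@channelName)
  if (smooth) ft <- smoothAndNormalize(ft)
  ctx <- cbind(epoch_index = seq_len(nEp),
               time_norm = if (nEp > 1) (seq_len(nEp) - 1) / (nEp - 1) else 0)
  FeatureTable(cbind(ft@values, ctx), subjectId = rec@subjectId,
               modality = rec@modality, channelName = rec@channelName)
}
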