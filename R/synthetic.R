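# Synthetic polysomnography generator: Markov hypnograms plus stage-dependent
# band-limited EEG with a configurable scalp-to-ear acquisition shift.

# Amplitude unit for band weights: weight 1 == 10 uV component RMS.
.AMP_UNIT <- 10

#' Default sleep-architecture transition model
#'
#' Strong self-transition (diagonal 0.85-0.90) with physiologically ordered
#' off-diagonal mass (W<->N1, N1->N2, N2<->N3, N2->REM, REM->W/N1/N2) and the
#' night starting awake. The resulting hypnograms show multi-epoch bouts and
#' NREM/REM alternation resembling real sleep without being fitted to any
#' cohort.
#'
#' @return a [TransitionModel-class].
#' @export
defaultTransitionModel <- function() {
  P <- rbind(
    W   = c(0.90, 0.090, 0.010, 0.000, 0.000),
    N1  = c(0.05, 0.850, 0.090, 0.000, 0.010),
    N2  = c(0.01, 0.020, 0.900, 0.045, 0.025),
    N3  = c(0.00, 0.005, 0.095, 0.900, 0.000),
    REM = c(0.02, 0.030, 0.050, 0.000, 0.900))
  colnames(P) <- stageLevels()
  new("TransitionModel", initial = c(1, 0, 0, 0, 0), transition = P)
}

#' Transition model with rare N1
#'
#' Variant of [defaultTransitionModel()] whose stationary N1 prevalence is
#' below 5%, used to study class-weighting of the rare transitional stage.
#'
#' @return a [TransitionModel-class].
#' @export
rareN1TransitionModel <- function() {
  P <- rbind(
    W   = c(0.940, 0.025, 0.035, 0.000, 0.000),
    N1  = c(0.150, 0.600, 0.250, 0.000, 0.000),
    N2  = c(0.010, 0.010, 0.900, 0.050, 0.030),
    N3  = c(0.000, 0.000, 0.100, 0.900, 0.000),
    REM = c(0.030, 0.010, 0.060, 0.000, 0.900))
  colnames(P) <- stageLevels()
  new("TransitionModel", initial = c(1, 0, 0, 0, 0), transition = P)
}

#' Default stage spectral profiles
#'
#' One [StageSpectralProfile-class] per stage encoding textbook stage
#' physiology: W is dominated by alpha and beta, N1 by theta with low
#' amplitude, N2 adds delta and sigma-band spindle bursts, N3 has by far the
#' largest (slow-wave scaled) delta content, and REM is mixed low-amplitude
#' theta. Weights are in 10-uV RMS units per band.
#'
#' @return named list of five `StageSpectralProfile` objects.
#' @export
defaultProfiles <- function() {
  mk <- function(w, spRate = 0, spAmp = 0, sws = 1) {
    names(w) <- bandDefinitions()$name
    new("StageSpectralProfile", bandWeights = w, spindleFreq = 13.5,
        spindleDur = 1.0, spindleRate = spRate, spindleAmp = spAmp,
        slowWaveScale = sws, weightJitter = 0.4, noiseFloor = 5)
  }
  list(
    W   = mk(c(0.3, 0.4, 0.5, 1.5, 0.3, 0.9)),
    N1  = mk(c(0.5, 0.8, 1.2, 0.5, 0.3, 0.4)),
    N2  = mk(c(1.0, 1.5, 1.0, 0.4, 0.8, 0.3), spRate = 3, spAmp = 12),
    N3  = mk(c(3.0, 3.5, 1.0, 0.3, 0.3, 0.2), sws = 1.5),
    REM = mk(c(0.5, 0.9, 1.1, 0.6, 0.3, 0.5)))
}

#' Modality shift presets
#'
#' `scalpShift()` is the identity acquisition (gain 1, no delta attenuation,
#' no added noise). `earShift()` is the default ear-canal degradation:
#' amplitude gain 0.6, delta attenuated to 0.6, additive white noise at 30%
#' of the average scalp signal s.d., 10% per-subject gain jitter. The ear
#' preset is calibrated only to reproduce the direction of the scalp-vs-ear
#' differences (lower feature/stage mutual information, depressed N3
#' sensitivity before fine-tuning), not any cohort-specific magnitude.
#'
#' @param profiles stage profiles used to compute the reference scalp s.d.
#'   for the ear preset's noise level.
#' @return a [ModalityShift-class].
#' @export
scalpShift <- function() {
  new("ModalityShift", amplitudeGain = 1, deltaAttenuation = 1,
      noiseSD = 0, subjectJitter = 0.1)
}

#' @rdname scalpShift
#' @export
earShift <- function(profiles = defaultProfiles()) {
  ref <- mean(vapply(profiles, function(p) {
    sqrt(sum((.AMP_UNIT * p@bandWeights)^2) + p@noiseFloor^2)
  }, numeric(1)))
  new("ModalityShift", amplitudeGain = 0.6, deltaAttenuation = 0.6,
      noiseSD = 0.3 * ref, subjectJitter = 0.1)
}

#' Generate a synthetic hypnogram
#'
#' Draws a stage sequence as a first-order Markov chain from a
#' [TransitionModel-class]. Identical inputs and seed give identical output.
#'
#' @param nEpochs number of 30-s epochs (>= 1).
#' @param model a `TransitionModel`.
#' @param seed integer seed.
#' @return a [Hypnogram-class].
#' @export
generateHypnogram <- function(nEpochs, model = defaultTransitionModel(),
                              seed = 1) {
  stopifnot(nEpochs >= 1)
  validObject(model)
  codes <- integer(nEpochs)
  withSeed(seed, {
    codes[1] <- sample.int(5L, 1L, prob = model@initial)
    if (nEpochs > 1) {
      for (i in 2:nEpochs)
        codes[i] <- sample.int(5L, 1L, prob = model@transition[codes[i - 1], ])
    }
  })
  Hypnogram(stageLevels()[codes])
}

# Weighted sum of band-limited unit-RMS Gaussian noise components for one
# epoch. A single white-noise draw is shaped in the frequency domain; the
# bands are disjoint in frequency, so the components are independent, and
# the weighted sum is a single inverse FFT of the jointly weighted spectrum.
# Each component is scaled by its expected (not realized) s.d., keeping
# natural epoch-to-epoch power variability.
.bandNoiseSum <- function(n, fs, weights) {
  bands <- bandDefinitions()
  z <- stats::fft(stats::rnorm(n))
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # two-sided -> folded frequency
  wv <- numeric(n)
  for (b in seq_len(nrow(bands))) {
    mask <- freqs >= bands$low[b] & freqs < bands$high[b]
    frac <- sum(mask) / n
    if (frac == 0) next
    wv[mask] <- weights[[bands$name[b]]] / sqrt(frac)
  }
  Re(stats::fft(z * wv, inverse = TRUE)) / n
}

#' Generate one 30-s epoch of synthetic EEG
#'
#' The signal is a sum of the six band-limited Gaussian noise components
#' scaled by the stage's band weights (slow delta additionally by its
#' slow-wave scale), plus Hann-windowed spindle bursts for stages with a
#' nonzero spindle rate, plus a white broadband floor. The modality shift is
#' then applied in order: delta components scaled by `deltaAttenuation`, the
#' summed signal by `amplitudeGain`, and finally additive white noise of s.d.
#' `noiseSD`. Calling with the same seed under different shifts reuses the
#' same underlying components, emulating one brain process seen by two
#' sensors.
#'
#' @param stage stage label in W/N1/N2/N3/REM.
#' @param profile a [StageSpectralProfile-class]; if a list of profiles is
#'   given, the entry named after `stage` is used.
#' @param shift a [ModalityShift-class].
#' @param fs sampling rate, Hz (>= 64 so the 30 Hz band is representable).
#' @param seed integer seed.
#' @return numeric vector of `30 * fs` samples.
#' @export
generateEpochSignal <- function(stage, profile = defaultProfiles(),
                                shift = scalpShift(), fs = 256, seed = 1) {
  stage <- as.character(stage)
  if (!stage %in% stageLevels()) stop("unknown stage: ", stage)
  if (is.list(profile)) profile <- profile[[stage]]
  stopifnot(is(profile, "StageSpectralProfile"), is(shift, "ModalityShift"))
  if (fs < 64) stop("fs must be >= 64 Hz to represent the 0.4-30 Hz band")
  n <- round(30 * fs)
  withSeed(seed, {
    w <- profile@bandWeights * .AMP_UNIT
    if (profile@weightJitter > 0)
      w <- w * exp(stats::rnorm(length(w), 0, profile@weightJitter))
    w["sdelta"] <- w["sdelta"] * profile@slowWaveScale
    w[c("sdelta", "fdelta")] <- w[c("sdelta", "fdelta")] * shift@deltaAttenuation
    x <- .bandNoiseSum(n, fs, w)
    if (profile@spindleRate > 0 && profile@spindleAmp > 0) {
      nSp <- stats::rpois(1, profile@spindleRate)
      if (nSp > 0) {
        durN <- round(profile@spindleDur * fs)
        for (k in seq_len(nSp)) {
          t0 <- sample.int(n - durN, 1L)
          tt <- seq_len(durN)
          env <- 0.5 * (1 - cos(2 * pi * (tt - 1) / (durN - 1)))  # Hann
          phase <- stats::runif(1, 0, 2 * pi)
          burst <- profile@spindleAmp * env *
            sin(2 * pi * profile@spindleFreq * tt / fs + phase)
          x[t0 + tt - 1] <- x[t0 + tt - 1] + burst
        }
      }
    }
    if (profile@noiseFloor > 0) x <- x + stats::rnorm(n, sd = profile@noiseFloor)
    x <- x * shift@amplitudeGain
    if (shift@noiseSD > 0) x <- x + stats::rnorm(n, sd = shift@noiseSD)
    x
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' Produces, for each subject, one hypnogram (shared across modalities) and
#' one 256 Hz [Recording-class] per requested modality. Each subject has an
#' independent seed stream and a log-normal per-subject gain (relative s.d.
#' `subjectJitter` from the modality shifts) that multiplies both modalities
#' identically, so between-subject amplitude variability is a subject
#' property, not a sensor property.
#'
#' @param nSubjects number of subjects (>= 2, so leave-one-subject-out is
#'   meaningful).
#' @param epochsPerSubject epochs per night (1200 for a 10-h night).
#' @param modalities subset of `c("scalp", "ear")`.
#' @param seed integer master seed; all per-subject and per-epoch seeds are
#'   derived from it deterministically.
#' @param transition a [TransitionModel-class].
#' @param profiles named list of [StageSpectralProfile-class] per stage.
#' @param shifts named list of [ModalityShift-class] per modality.
#' @param fs native sampling rate, Hz.
#' @return list with one element per subject:
#'   `list(subjectId, hypnogram, recordings)` where `recordings` is a named
#'   list of `Recording` objects.
#' @export
generateCohort <- function(nSubjects, epochsPerSubject,
                           modalities = c("scalp", "ear"), seed = 1,
                           transition = defaultTransitionModel(),
                           profiles = defaultProfiles(),
                           shifts = list(scalp = scalpShift(), ear = earShift(profiles)),
                           fs = 256) {
  stopifnot(nSubjects >= 2, epochsPerSubject >= 1)
  modalities <- match.arg(modalities, c("scalp", "ear"), several.ok = TRUE)
  if (!all(modalities %in% names(shifts)))
    stop("missing shift preset for: ",
         paste(setdiff(modalities, names(shifts)), collapse = ", "))
  lapply(seq_len(nSubjects), function(i) {
    subjSeed <- deriveSeed(seed, 1L, i)
    hyp <- generateHypnogram(epochsPerSubject, transition,
                             seed = deriveSeed(subjSeed, 2L))
    jitterSD <- max(vapply(shifts[modalities], slot, numeric(1), "subjectJitter"))
    gain <- withSeed(deriveSeed(subjSeed, 3L), exp(stats::rnorm(1, 0, jitterSD)))
    nEp <- length(hyp)
    recs <- lapply(modalities, function(m) {
      sh <- shifts[[m]]
      sig <- vapply(seq_len(nEp), function(e) {
        generateEpochSignal(as.character(stages(hyp)[e]), profiles, sh, fs,
                            seed = deriveSeed(subjSeed, 4L, e))
      }, numeric(round(30 * fs)))
      Recording(as.vector(sig) * gain, fs = fs, modality = m,
                subjectId = sprintf("s%02d", i),
                channelName = if (m == "scalp") "C4-M1" else "EarL-M1")
    })
    names(recs) <- modalities
    list(subjectId = sprintf("s%02d", i), hypnogram = hyp, recordings = recs)
  })
}
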