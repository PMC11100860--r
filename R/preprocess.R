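# Preprocessing: bring any recording to the representation the staging model
# expects — 100 Hz, 0.40-30 Hz band, 30-s epochs aligned to the hypnogram.

#' Resample a recording
#'
#' Anti-aliased downsampling by Fourier-domain sinc interpolation: the
#' signal's spectrum is truncated at the new Nyquist frequency (an ideal
#' brick-wall anti-aliasing filter) and inverted at the new length. This is
#' exact band-limited resampling and runs in O(n log n) on whole-night
#' recordings, whose lengths are highly composite. Upsampling is out of
#' scope and rejected.
#'
#' @param rec a [Recording-class].
#' @param targetFs target sampling rate, Hz (<= `rec@fs`).
#' @return a `Recording` at `targetFs` with duration preserved to within one
#'   sample.
#' @export
resampleRecording <- function(rec, targetFs = 100) {
  stopifnot(is(rec, "Recording"))
  if (targetFs > rec@fs) stop("upsampling is not supported")
  if (targetFs == rec@fs) return(rec)
  x <- rec@samples
  n <- length(x)
  nOut <- ceiling(n * targetFs / rec@fs)
  sp <- stats::fft(x)
  z <- complex(nOut)
  kPos <- ceiling(nOut / 2)              # positive-frequency bins incl. DC
  z[seq_len(kPos)] <- sp[seq_len(kPos)]
  kNeg <- nOut - kPos
  if (kNeg > 0) z[(kPos + 1):nOut] <- sp[(n - kNeg + 1):n]
  if (nOut %% 2 == 0) z[kPos + 1] <- Re(z[kPos + 1])  # Nyquist bin real
  y <- Re(stats::fft(z, inverse = TRUE)) / n
  new("Recording", samples = y, fs = targetFs,
      modality = rec@modality, subjectId = rec@subjectId,
      channelName = rec@channelName)
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth filtering, realized as an
#' order-4 high-pass at `low` cascaded with an order-4 low-pass at `high`,
#' each applied with `filtfilt` so no phase delay is introduced at epoch
#' boundaries. The effective magnitude response is the squared one-pass
#' response.
#'
#' @param rec a [Recording-class].
#' @param low,high band edges in Hz; defaults 0.40 and 30.
#' @return the filtered `Recording` (same rate, same length).
#' @export
bandpassRecording <- function(rec, low = 0.40, high = 30) {
  stopifnot(is(rec, "Recording"))
  nyq <- rec@fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("need 0 < low < high < fs/2 (fs/2 = ", nyq, " Hz)")
  hp <- signal::butter(4, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  y <- signal::filtfilt(hp, rec@samples)
  y <- signal::filtfilt(lp, y)
  new("Recording", samples = as.numeric(y), fs = rec@fs,
      modality = rec@modality, subjectId = rec@subjectId,
      channelName = rec@channelName)
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping consecutive 30-s segments; a trailing partial segment is
#' dropped, matching the scoring convention.
#'
#' @param rec a [Recording-class].
#' @param epochLength epoch duration, seconds.
#' @param provenance optional named list recording the preprocessing applied.
#' @return an [EpochedRecording-class].
#' @export
epochRecording <- function(rec, epochLength = 30, provenance = list()) {
  stopifnot(is(rec, "Recording"))
  nPer <- round(epochLength * rec@fs)
  nEp <- floor(length(rec@samples) / nPer)
  if (nEp < 1) stop("recording shorter than one epoch")
  m <- matrix(rec@samples[seq_len(nEp * nPer)], nrow = nEp, ncol = nPer,
              byrow = TRUE)
  new("EpochedRecording", epochs = m, fs = rec@fs, epochLength = epochLength,
      provenance = provenance, modality = rec@modality,
      subjectId = rec@subjectId, channelName = rec@channelName)
}

#' Full preprocessing chain
#'
#' `resample -> bandpass -> epoch`, the fixed pipeline order.
#'
#' @param rec a [Recording-class] (any rate >= 100 Hz).
#' @param targetFs rate after resampling, Hz.
#' @param low,high band edges, Hz.
#' @param epochLength epoch duration, seconds.
#' @return an [EpochedRecording-class] at `targetFs`.
#' @export
preprocessRecording <- function(rec, targetFs = 100, low = 0.40, high = 30,
                                epochLength = 30) {
  rec <- resampleRecording(rec, targetFs)
  rec <- bandpassRecording(rec, low, high)
  epochRecording(rec, epochLength,
                 provenance = list(targetFs = targetFs, low = low, high = high,
                                   filter = "butterworth4-filtfilt",
                                   resampler = "polyphase-fir"))
}
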