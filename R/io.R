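# Readers and writers: EDF (16-bit European Data Format), plain-text
# hypnograms ("epoch_index<TAB>stage_label"), feature CSVs with a JSON
# metadata sidecar, and YAML run configs.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write recordings to an EDF file
#'
#' Minimal EDF writer: one signal per [Recording-class] (all must share the
#' sampling rate and duration), 1-second data records, 16-bit little-endian
#' samples. Physical min/max are taken from the data, so the quantization
#' step is `(max - min) / 65535`.
#'
#' @param recordings a `Recording` or list of them (e.g. scalp + ear).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeEDF <- function(recordings, path) {
  if (is(recordings, "Recording")) recordings <- list(recordings)
  fs <- unique(vapply(recordings, slot, numeric(1), "fs"))
  ns <- unique(vapply(recordings, function(r) length(r@samples), numeric(1)))
  if (length(fs) != 1 || length(ns) != 1)
    stop("all signals must share sampling rate and length")
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  nRec <- floor(ns / fs)   # whole 1-s records; trailing partial second dropped
  nSig <- length(recordings)
  phMin <- vapply(recordings, function(r) min(r@samples), numeric(1))
  phMax <- vapply(recordings, function(r) max(r@samples), numeric(1))
  phMax <- ifelse(phMax > phMin, phMax, phMin + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8),
    .edfPad(paste("X X X", recordings[[1]]@subjectId), 80),
    .edfPad("Startdate X X X X", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(256 * (1 + nSig), 8), .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad("1", 8), .edfPad(nSig, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edfPad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  field(vapply(recordings, function(r)
    paste0("EEG ", r@channelName), character(1)), 16)    # label
  field(rep("", nSig), 80)                               # transducer
  field(rep("uV", nSig), 8)                              # physical dimension
  field(sprintf("%.8g", phMin), 8)
  field(sprintf("%.8g", phMax), 8)
  field(rep("-32768", nSig), 8)
  field(rep("32767", nSig), 8)
  field(rep("", nSig), 80)                               # prefiltering
  field(rep(fs, nSig), 8)                                # samples per record
  field(rep("", nSig), 32)                               # reserved
  scl <- (phMax - phMin) / 65535
  for (r in seq_len(nRec)) {
    for (s in seq_len(nSig)) {
      seg <- recordings[[s]]@samples[((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - phMin[s]) / scl[s]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Counterpart of [writeEDF()]; reads all signals of a 16-bit EDF with
#' integer per-record sample counts.
#'
#' @param path EDF file path.
#' @param modalities optional character vector assigning a modality to each
#'   signal; by default guessed from the channel label (`Ear*` -> ear).
#' @return list of [Recording-class] objects.
#' @export
readEDF <- function(path, modalities = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    x <- readChar(con, w, useBytes = TRUE)
    if (nchar(x, type = "bytes") < w) stop("malformed EDF: truncated header")
    trimws(x)
  }
  rd(8); pid <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nRec <- as.integer(rd(8)); recDur <- as.numeric(rd(8)); nSig <- as.integer(rd(4))
  if (is.na(nSig) || nSig < 1) stop("malformed EDF: bad signal count in header")
  fld <- function(w) vapply(seq_len(nSig), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  phMin <- as.numeric(fld(8)); phMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80); spr <- as.integer(fld(8)); fld(32)
  sig <- lapply(seq_len(nSig), function(i) numeric(nRec * spr[i]))
  for (r in seq_len(nRec)) {
    for (s in seq_len(nSig)) {
      raw <- readBin(con, integer(), n = spr[s], size = 2, endian = "little")
      if (length(raw) < spr[s]) stop("malformed EDF: truncated data record ", r)
      scl <- (phMax[s] - phMin[s]) / (digMax[s] - digMin[s])
      sig[[s]][((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (raw - digMin[s]) * scl + phMin[s]
    }
  }
  subj <- sub("^X X X ", "", pid)
  lapply(seq_len(nSig), function(s) {
    lab <- sub("^EEG ", "", labels[s])
    mod <- if (!is.null(modalities)) modalities[s]
           else if (grepl("^ear", lab, ignore.case = TRUE)) "ear" else "scalp"
    Recording(sig[[s]], fs = spr[s] / recDur, modality = mod,
              subjectId = subj, channelName = lab)
  })
}

#' Write / read a plain-text hypnogram
#'
#' One line per epoch: `epoch_index<TAB>stage_label`, 1-based indices.
#'
#' @param hypnogram a [Hypnogram-class].
#' @param path file path.
#' @return `writeHypnogram`: invisibly `path`; `readHypnogram`: a
#'   [Hypnogram-class].
#' @export
writeHypnogram <- function(hypnogram, path) {
  stopifnot(is(hypnogram, "Hypnogram"))
  writeLines(sprintf("%d\t%s", seq_len(length(hypnogram)),
                     as.character(hypnogram@stages)), path)
  invisible(path)
}

#' @rdname writeHypnogram
#' @export
readHypnogram <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop("malformed hypnogram line ", bad[1], ": '", lines[bad[1]], "'")
  labs <- vapply(parts, `[[`, character(1), 2L)
  unknown <- which(!labs %in% stageLevels())
  if (length(unknown))
    stop("unknown stage label on line ", unknown[1], ": '",
         labs[unknown[1]], "'")
  Hypnogram(labs)
}

#' Write / read a feature table as CSV
#'
#' Values are written with shortest round-trip precision so read-back is
#' exact; recording metadata travels in a JSON sidecar (`<path>.meta.json`).
#'
#' @param table a [FeatureTable-class].
#' @param path CSV file path.
#' @return `writeFeatures`: invisibly `path`; `readFeatures`: a
#'   [FeatureTable-class].
#' @export
writeFeatures <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  m <- table@values
  lines <- c(paste(colnames(m), collapse = ","),
             apply(matrix(sprintf("%.17g", m), nrow(m)), 1, paste,
                   collapse = ","))
  writeLines(lines, path)
  jsonlite::write_json(list(subjectId = table@subjectId,
                            modality = table@modality,
                            channelName = table@channelName),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  metaPath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE)
  else list(subjectId = "unknown", modality = "scalp", channelName = "")
  FeatureTable(as.matrix(df), subjectId = meta$subjectId,
               modality = meta$modality, channelName = meta$channelName)
}

#' Write / read a run configuration
#'
#' YAML serialization of the [runConfig()] list.
#'
#' @param config a run configuration list.
#' @param path YAML file path.
#' @return `writeRunConfig`: invisibly `path`; `readRunConfig`: the list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg)
}
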