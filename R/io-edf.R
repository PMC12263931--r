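# Minimal EDF (European Data Format) writer/reader and a BIDS-style cohort
# layout (one EDF per subject plus a participants.tsv with labels). EDF
# stores 16-bit integers against per-channel physical calibration ranges;
# round-tripping therefore quantizes amplitudes to ~range/65536.

.padStr <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

.fmt8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(x, format = "g", digits = digits, width = 1)
    if (nchar(s) <= 8L) return(s)
  }
  stop("cannot format ", x, " in 8 characters")
}

#' Write a recording to an EDF file
#'
#' Record duration is fixed at one second, so the recording must span a
#' whole number of seconds and the sampling rate must be an integer. Each
#' channel is calibrated to its own symmetric physical range (microvolts).
#' The subject id is stored in the patient-identification field and the
#' class label as \code{label=<AD|HC>} in the recording-identification
#' field, so [readEDF()] can recover both.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@samplingRate
  if (abs(fs - round(fs)) > 1e-8) stop("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  nsamp <- ncol(rec@data)
  if (nsamp %% fs != 0L)
    stop("EDF export needs a whole number of seconds")
  nrec <- nsamp %/% fs
  ns <- nrow(rec@data)

  # quantize against the exact calibration values stored in the header
  # (8-character fields), not their full-precision counterparts
  physMax <- vapply(pmax(apply(abs(rec@data), 1L, max) * 1.001, 1e-6),
                    function(x) as.numeric(.fmt8(x)), 1)
  physMin <- vapply(-physMax, function(x) as.numeric(.fmt8(x)), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    .padStr("0", 8L),
    .padStr(rec@subjectId, 80L),
    .padStr(paste0("label=", rec@label), 80L),
    .padStr("01.01.00", 8L), .padStr("00.00.00", 8L),
    .padStr(as.character(256L * (1L + ns)), 8L),
    .padStr("", 44L),
    .padStr(as.character(nrec), 8L),
    .padStr("1", 8L),
    .padStr(as.character(ns), 4L),
    paste(vapply(rec@channelNames,
                 function(ch) .padStr(paste("EEG", ch), 16L), ""),
          collapse = ""),
    paste(rep(.padStr("", 80L), ns), collapse = ""),
    paste(rep(.padStr("uV", 8L), ns), collapse = ""),
    paste(vapply(physMin, function(x) .padStr(.fmt8(x), 8L), ""),
          collapse = ""),
    paste(vapply(physMax, function(x) .padStr(.fmt8(x), 8L), ""),
          collapse = ""),
    paste(rep(.padStr("-32768", 8L), ns), collapse = ""),
    paste(rep(.padStr("32767", 8L), ns), collapse = ""),
    paste(rep(.padStr("", 80L), ns), collapse = ""),
    paste(rep(.padStr(as.character(fs), 8L), ns), collapse = ""),
    paste(rep(.padStr("", 32L), ns), collapse = "")),
    con, eos = NULL)

  gain <- (physMax - physMin) / 65535
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round((rec@data[, cols, drop = FALSE] - physMin) / gain) - 32768
    block <- pmin(pmax(block, -32768), 32767)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' Reads the subset of EDF written by [writeEDF()] and standard
#' whole-second EDF exports with uniform per-signal sampling rates.
#'
#' @param path EDF file path.
#' @param subjectId override for the subject id (default: the EDF patient
#'   field).
#' @param label override for the class label (default: parsed from a
#'   \code{label=} token in the recording field, else \code{NA}).
#' @param channelMap optional named character vector renaming stored
#'   channel labels (e.g. \code{c(T7 = "T3")}); disabled by default.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, subjectId = NULL, label = NULL,
                    channelMap = character(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8L)
  patient <- rd(80L)
  recording <- rd(80L)
  rd(8L); rd(8L); rd(8L); rd(44L)
  nrec <- as.integer(rd(8L))
  recDur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), "")
  vapply(seq_len(ns), function(i) rd(80L), "")
  vapply(seq_len(ns), function(i) rd(8L), "")
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  vapply(seq_len(ns), function(i) rd(80L), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), ""))
  vapply(seq_len(ns), function(i) rd(32L), "")
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1L] / recDur

  data <- matrix(0, ns, nrec * spr[1L])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1L], ncol = ns)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    data[, cols] <- t(block)
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  data <- data * gain + (physMin - digMin * gain)

  chn <- sub("^EEG ", "", labels)
  if (length(channelMap)) {
    hit <- chn %in% names(channelMap)
    chn[hit] <- channelMap[chn[hit]]
  }
  if (is.null(label)) {
    m <- regmatches(recording, regexpr("label=(AD|HC)", recording))
    label <- if (length(m)) sub("label=", "", m) else NA_character_
  }
  new("EEGRecording",
      subjectId = if (is.null(subjectId)) patient else subjectId,
      label = label, channelNames = chn, samplingRate = fs, data = data)
}

#' Persist a cohort as a minimal BIDS-style EEG layout
#'
#' Writes \code{participants.tsv} (participant_id, label) and one EDF per
#' subject under \code{<dir>/<id>/eeg/<id>_task-rest_eeg.edf}.
#'
#' @param cohort list of \linkS4class{EEGRecording} objects.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohortBIDS <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    participant_id = vapply(cohort, subjectId, ""),
    label = vapply(cohort, classLabel, ""),
    stringsAsFactors = FALSE)
  write.table(tab, file.path(dir, "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (rec in cohort) {
    sub <- file.path(dir, rec@subjectId, "eeg")
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    writeEDF(rec, file.path(sub, paste0(rec@subjectId, "_task-rest_eeg.edf")))
  }
  invisible(dir)
}

#' Read a BIDS-style cohort written by [writeCohortBIDS()]
#'
#' @param dir cohort directory containing \code{participants.tsv}.
#' @param channelMap passed to [readEDF()].
#' @return list of \linkS4class{EEGRecording} objects with labels from the
#'   participants table.
#' @export
readCohortBIDS <- function(dir, channelMap = character(0)) {
  tab <- read.delim(file.path(dir, "participants.tsv"),
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$participant_id[i]
    files <- list.files(file.path(dir, id, "eeg"), pattern = "\\.edf$",
                        full.names = TRUE)
    if (!length(files)) stop("no EDF file for subject ", id)
    readEDF(files[1L], subjectId = id, label = tab$label[i],
            channelMap = channelMap)
  })
}
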