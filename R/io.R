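# Minimal readers/writers for the ECG container formats used by BrainAmp
# style recordings. Only what single-lead continuous ECG needs is covered:
# EDF (one signal, 16-bit), WFDB format 16 (.hea/.dat) and the BrainVision
# triplet (read-only, INT_16 or IEEE_FLOAT_32, multiplexed), plus two-column
# CSV. Values are microvolts on both sides of every round trip.

padField <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

writeEdf <- function(rec, path) {
  fs <- rec@samplingRate
  stopIfNot(abs(fs - round(fs)) < 1e-9,
            "EDF export requires an integer sampling rate")
  fs <- round(fs)
  x <- rec@samples
  n <- length(x)
  nrec <- ceiling(n / fs)
  physMin <- min(x); physMax <- max(x)
  if (physMax <= physMin) physMax <- physMin + 1
  dmin <- -32768; dmax <- 32767
  scale <- (dmax - dmin) / (physMax - physMin)
  dig <- as.integer(pmin(pmax(
    round((c(x, numeric(nrec * fs - n)) - physMin) * scale) + dmin,
    dmin), dmax))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8), padField("X X X X", 80),
    padField(paste0("Startdate X X X X len=", n), 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 + 256, 8), padField("", 44), padField(nrec, 8),
    padField("1", 8), padField("1", 4),
    padField("ECG", 16), padField("synthetic", 80), padField("uV", 8),
    padField(sprintf("%.8g", physMin), 8), padField(sprintf("%.8g", physMax), 8),
    padField(dmin, 8), padField(dmax, 8), padField("", 80),
    padField(fs, 8), padField("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

readEdf <- function(path, meta = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                       # version
  readChar(con, 80, useBytes = TRUE)                      # patient
  recField <- readChar(con, 80, useBytes = TRUE)
  readChar(con, 16, useBytes = TRUE)                      # date+time
  as.integer(readChar(con, 8, useBytes = TRUE))           # header bytes
  readChar(con, 44, useBytes = TRUE)
  nrec <- as.integer(readChar(con, 8, useBytes = TRUE))
  recDur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  stopIfNot(ns == 1L, "only single-signal EDF files are supported")
  readChar(con, 16, useBytes = TRUE); readChar(con, 80, useBytes = TRUE)
  readChar(con, 8, useBytes = TRUE)
  physMin <- as.numeric(readChar(con, 8, useBytes = TRUE))
  physMax <- as.numeric(readChar(con, 8, useBytes = TRUE))
  dmin <- as.numeric(readChar(con, 8, useBytes = TRUE))
  dmax <- as.numeric(readChar(con, 8, useBytes = TRUE))
  readChar(con, 80, useBytes = TRUE)
  spr <- as.integer(readChar(con, 8, useBytes = TRUE))
  readChar(con, 32, useBytes = TRUE)
  dig <- readBin(con, "integer", n = nrec * spr, size = 2L, signed = TRUE,
                 endian = "little")
  x <- physMin + (dig - dmin) * (physMax - physMin) / (dmax - dmin)
  nTrue <- regmatches(recField, regexpr("len=[0-9]+", recField))
  if (length(nTrue)) x <- x[seq_len(as.integer(sub("len=", "", nTrue)))]
  fs <- spr / recDur
  EcgRecording(x, fs, meta = meta)
}

writeWfdb <- function(rec, path) {
  base <- sub("\\.hea$", "", path)
  recName <- basename(base)
  x <- rec@samples
  maxAbs <- max(abs(x), 1e-6)
  gain <- 32000 / maxAbs
  adu <- as.integer(pmin(pmax(round(x * gain), -32768), 32767))
  chk <- sum(as.numeric(adu)) %% 65536
  if (chk > 32767) chk <- chk - 65536
  hea <- c(sprintf("%s 1 %.10g %d", recName, rec@samplingRate, length(x)),
           sprintf("%s.dat 16 %.10g(0)/uV 16 0 %d %d 0 ECG",
                   recName, gain, adu[1], as.integer(chk)))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adu, con, size = 2L, endian = "little")
  invisible(paste0(base, ".hea"))
}

readWfdb <- function(path, meta = list()) {
  base <- sub("\\.hea$", "", path)
  hea <- readLines(paste0(base, ".hea"))
  hea <- hea[!grepl("^#", hea)]
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  n <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- strsplit(trimws(hea[2]), "\\s+")[[1]]
  stopIfNot(sig[2] == "16", "only WFDB format 16 is supported")
  gainField <- sig[3]
  baseline <- 0
  if (grepl("\\(", gainField)) {
    baseline <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gainField))
  }
  gain <- as.numeric(sub("[(/].*$", "", gainField))
  if (!is.finite(gain) || gain == 0) gain <- 200
  datFile <- file.path(dirname(base), strsplit(sig[1], "\\s+")[[1]][1])
  sz <- file.info(datFile)$size
  con <- file(datFile, "rb")
  on.exit(close(con))
  adu <- readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
                 endian = "little")
  if (!is.na(n)) adu <- adu[seq_len(n)]
  EcgRecording((adu - baseline) / gain, fs, meta = meta)
}

readBrainVision <- function(path, meta = list()) {
  hdrLines <- readLines(path, warn = FALSE)
  getVal <- function(key) {
    ln <- grep(paste0("^", key, "="), hdrLines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^", key, "="), "", ln[1])
  }
  stopIfNot(identical(toupper(getVal("DataFormat")), "BINARY"),
            "only binary BrainVision data are supported")
  orientation <- toupper(getVal("DataOrientation"))
  nChan <- as.integer(getVal("NumberOfChannels"))
  sampInt <- as.numeric(getVal("SamplingInterval"))  # microseconds
  binFmt <- toupper(getVal("BinaryFormat"))
  dataFile <- file.path(dirname(path), getVal("DataFile"))
  ch1 <- strsplit(getVal("Ch1"), ",")[[1]]
  resolution <- if (length(ch1) >= 3 && nzchar(ch1[3])) as.numeric(ch1[3]) else 1
  sz <- file.info(dataFile)$size
  con <- file(dataFile, "rb")
  on.exit(close(con))
  if (binFmt == "INT_16") {
    raw <- readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
                   endian = "little")
  } else if (binFmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, "numeric", n = sz / 4, size = 4L, endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", binFmt, call. = FALSE)
  }
  x <- if (nChan > 1L) {
    stopIfNot(orientation == "MULTIPLEXED",
              "multi-channel data must be MULTIPLEXED")
    raw[seq(1L, length(raw), by = nChan)]   # first channel
  } else raw
  EcgRecording(x * resolution, 1e6 / sampInt, meta = meta)
}

writeCsvEcg <- function(rec, path) {
  tt <- rec@t0 + (seq_along(rec@samples) - 1L) / rec@samplingRate
  write.csv(data.frame(time_s = tt, ecg_uv = rec@samples), path,
            row.names = FALSE)
  invisible(path)
}

readCsvEcg <- function(path, meta = list()) {
  d <- read.csv(path)
  stopIfNot(all(c("time_s", "ecg_uv") %in% names(d)),
            "CSV must have columns time_s and ecg_uv")
  dts <- diff(d$time_s)
  if (any(dts <= 0)) stop("non-monotonic time column", call. = FALSE)
  stopIfNot(max(dts) - min(dts) < 0.01 * median(dts),
            "CSV time column is not uniformly sampled")
  EcgRecording(d$ecg_uv, 1 / median(dts), t0 = d$time_s[1], meta = meta)
}

#' Read an ECG recording
#'
#' Dispatches on `format` (or the file extension): `"edf"`, `"wfdb"`
#' (`.hea` + `.dat`, format 16), `"brainvision"` (`.vhdr` triplet) or
#' `"csv"` (columns `time_s`, `ecg_uv`). Samples are returned in µV.
#'
#' @param path file path (for WFDB, the `.hea` file; for BrainVision, the
#'   `.vhdr` file).
#' @param format one of `"edf"`, `"wfdb"`, `"brainvision"`, `"csv"`;
#'   guessed from the extension when missing.
#' @param meta named list merged into the recording metadata (use this to
#'   attach manifest labels such as subject/condition/side/phase).
#' @return an [EcgRecording].
#' @export
readEcg <- function(path, format = NULL, meta = list()) {
  stopIfNot(file.exists(path), paste("file not found:", path))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", hea = "wfdb", vhdr = "brainvision",
                     csv = "csv",
                     stop("cannot guess format from extension: ", path,
                          call. = FALSE))
  }
  format <- match.arg(tolower(format), c("edf", "wfdb", "brainvision", "csv"))
  switch(format,
         edf = readEdf(path, meta),
         wfdb = readWfdb(path, meta),
         brainvision = readBrainVision(path, meta),
         csv = readCsvEcg(path, meta))
}

#' Write an ECG recording
#'
#' @param rec an [EcgRecording].
#' @param path output path (for WFDB give the `.hea` path; the `.dat` is
#'   written alongside).
#' @param format `"edf"`, `"wfdb"` or `"csv"`.
#' @return the path, invisibly.
#' @export
writeEcg <- function(rec, path, format = c("wfdb", "edf", "csv")) {
  stopIfNot(is(rec, "EcgRecording"), "rec must be an EcgRecording")
  format <- match.arg(format)
  switch(format,
         edf = writeEdf(rec, path),
         wfdb = writeWfdb(rec, path),
         csv = writeCsvEcg(rec, path))
}
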