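# Binary codec for chunked multimodal recordings, plus CSV/WAV export and
# missing-sample accounting.
#
# File dialect (little-endian throughout):
#   header : magic "LBK1" (4 B), format version uint8 (1 = v1 firmware,
#            2 = v2), device-id length uint8 + raw bytes
#   chunk  : modality tag uint8 (1 ecg, 2 imu, 3 audio),
#            start/end UTC ms as uint64 (stored as two uint32, lo then hi),
#            sample count uint32,
#            payload (ecg uint16 ADC; imu int16 x 9 fixed-point;
#                     audio int32 holding a 24-bit sample),
#            mask appendix: uint32 run count, then (start uint32, len uint32)
#            per run of padded samples (0-based starts).
# Padded samples are stored as literal zeros AND in the run-length mask, so
# true zeros and padding stay distinguishable downstream.

.MAGIC <- charToRaw("LBK1")
.MOD_TAG <- c(ecg = 1L, imu = 2L, audio = 3L)

.writeU32 <- function(con, v) {
  v <- as.numeric(v)
  writeBin(as.integer(ifelse(v >= 2^31, v - 2^32, v)), con,
           size = 4, endian = "little")
}

.readU32 <- function(con, n = 1) {
  v <- readBin(con, "integer", n = n, size = 4, endian = "little")
  if (length(v) < n) return(NULL)
  v + (v < 0) * 2^32
}

.writeU64 <- function(con, v) {
  v <- as.numeric(v)
  .writeU32(con, v %% 2^32)
  .writeU32(con, v %/% 2^32)
}

.readU64 <- function(con) {
  lo <- .readU32(con); hi <- .readU32(con)
  if (is.null(lo) || is.null(hi)) return(NULL)
  lo + hi * 2^32
}

.writeU16 <- function(con, v) {
  v <- as.numeric(v)
  writeBin(as.integer(ifelse(v >= 2^15, v - 2^16, v)), con,
           size = 2, endian = "little")
}

.maskRuns <- function(mask) {
  # 0-based (start, length) runs of TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], r$lengths[r$values])
}

#' Write a recording to the chunked binary format
#'
#' @param recording A valid [Recording-class].
#' @param path Output file path.
#' @return Number of bytes written, invisibly.
#' @seealso [readRecording()] for the inverse; round-trips are bit-exact.
#' @export
writeRecording <- function(recording, path) {
  methods::validObject(recording)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.MAGIC, con)
  writeBin(as.integer(match(recording@firmwareVersion, c("v1", "v2"))),
           con, size = 1)
  id <- charToRaw(recording@deviceId)
  if (length(id) > 255) stop("device id longer than 255 bytes")
  writeBin(as.integer(length(id)), con, size = 1)
  if (length(id)) writeBin(id, con)
  for (ch in recording@chunks) {
    writeBin(.MOD_TAG[[ch@modality]], con, size = 1)
    .writeU64(con, ch@startUTC)
    .writeU64(con, ch@endUTC)
    n <- chunkLength(ch)
    .writeU32(con, n)
    if (ch@modality == "ecg") {
      .writeU16(con, ch@samples)
    } else if (ch@modality == "audio") {
      writeBin(as.integer(round(ch@samples * .AUDIO_SCALE)), con,
               size = 4, endian = "little")
    } else {
      raw <- t(ch@samples) * .IMU_SCALES  # column-recycling over channels
      writeBin(as.integer(round(as.vector(raw))), con,
               size = 2, endian = "little")
    }
    runs <- .maskRuns(ch@missingMask)
    .writeU32(con, nrow(runs))
    if (nrow(runs)) .writeU32(con, as.vector(t(runs)))
  }
  invisible(file.size(path))
}

.readChunk <- function(con) {
  tag <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
  if (length(tag) == 0) return(NULL)
  modality <- names(.MOD_TAG)[match(tag, .MOD_TAG)]
  if (is.na(modality)) stop("unknown modality tag: ", tag)
  s <- .readU64(con); e <- .readU64(con); n <- .readU32(con)
  if (is.null(s) || is.null(e) || is.null(n)) return(FALSE)
  if (modality == "ecg") {
    v <- readBin(con, "integer", n = n, size = 2, endian = "little",
                 signed = FALSE)
    if (length(v) < n) return(FALSE)
    samples <- as.numeric(v)
  } else if (modality == "audio") {
    v <- readBin(con, "integer", n = n, size = 4, endian = "little")
    if (length(v) < n) return(FALSE)
    samples <- v / .AUDIO_SCALE
  } else {
    v <- readBin(con, "integer", n = n * 9, size = 2, endian = "little")
    if (length(v) < n * 9) return(FALSE)
    samples <- t(matrix(v / .IMU_SCALES, nrow = 9))
    colnames(samples) <- IMU_CHANNELS
  }
  nRuns <- .readU32(con)
  if (is.null(nRuns)) return(FALSE)
  mask <- rep(FALSE, n)
  if (nRuns > 0) {
    rv <- .readU32(con, nRuns * 2)
    if (is.null(rv) || length(rv) < nRuns * 2) return(FALSE)
    runs <- matrix(rv, ncol = 2, byrow = TRUE)
    for (i in seq_len(nRuns))
      mask[seq.int(runs[i, 1] + 1, length.out = runs[i, 2])] <- TRUE
  }
  SensorChunk(modality, s, e, samples, mask)
}

#' Read a recording from the chunked binary format
#'
#' A file truncated mid-chunk is read up to the last complete chunk, with a
#' warning. A bad magic number or unknown format version is an error.
#'
#' @param path Input file path.
#' @return A [Recording-class].
#' @export
readRecording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4 || !identical(magic, .MAGIC))
    stop("not a chunked recording file (bad magic)")
  ver <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
  if (!(ver %in% 1:2)) stop("unsupported format version: ", ver)
  idLen <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
  deviceId <- rawToChar(readBin(con, "raw", n = idLen))
  chunks <- list()
  repeat {
    ch <- .readChunk(con)
    if (is.null(ch)) break
    if (isFALSE(ch)) {
      warning("file truncated mid-chunk; trailing chunk dropped")
      break
    }
    chunks[[length(chunks) + 1L]] <- ch
  }
  Recording(chunks, firmwareVersion = c("v1", "v2")[ver], deviceId = deviceId)
}

.sampleUTC <- function(ch) {
  ch@startUTC + (seq_len(chunkLength(ch)) - 1) * 1000 / ch@nominalRate
}

#' Export a recording to CSV (ecg, imu) and WAV (audio)
#'
#' ECG chunks are pooled into `ecg.csv` (columns `utc_ms, adc, padded`),
#' IMU into `imu.csv` (`utc_ms, ax..mz, padded`), audio into `audio.wav`
#' (16-bit PCM mono, 22050 Hz). Modalities with no chunks emit no file.
#'
#' @param recording A valid [Recording-class].
#' @param outDir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
exportRecording <- function(recording, outDir) {
  methods::validObject(recording)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  ecg <- chunks(recording, "ecg")
  if (length(ecg)) {
    df <- do.call(rbind, lapply(ecg, function(ch)
      data.frame(utc_ms = .sampleUTC(ch), adc = ch@samples,
                 padded = as.integer(ch@missingMask))))
    f <- file.path(outDir, "ecg.csv")
    utils::write.csv(df, f, row.names = FALSE)
    out["ecg"] <- f
  }
  imu <- chunks(recording, "imu")
  if (length(imu)) {
    df <- do.call(rbind, lapply(imu, function(ch) {
      d <- as.data.frame(ch@samples)
      names(d) <- IMU_CHANNELS
      cbind(data.frame(utc_ms = .sampleUTC(ch)), d,
            data.frame(padded = as.integer(ch@missingMask)))
    }))
    f <- file.path(outDir, "imu.csv")
    utils::write.csv(df, f, row.names = FALSE)
    out["imu"] <- f
  }
  aud <- chunks(recording, "audio")
  if (length(aud)) {
    wave <- unlist(lapply(aud, function(ch) ch@samples))
    f <- file.path(outDir, "audio.wav")
    writeWav(wave, f, rate = 22050)
    out["audio"] <- f
  }
  invisible(out)
}

#' Proportion of missing samples across chunks
#'
#' Computed against the sample count expected from each chunk's UTC span and
#' nominal rate: `1 - observed_non_padded / expected`. Invariant under chunk
#' reordering.
#'
#' @param chunks A list of [SensorChunk-class] objects (or a single chunk).
#' @return Proportion in `[0, 1]`.
#' @export
missingFraction <- function(chunks) {
  if (methods::is(chunks, "SensorChunk")) chunks <- list(chunks)
  if (!length(chunks)) stop("missingFraction needs at least one chunk")
  expected <- sum(vapply(chunks, function(ch)
    round((ch@endUTC - ch@startUTC) / 1000 * ch@nominalRate), numeric(1)))
  if (expected <= 0) stop("zero expected samples")
  observed <- sum(vapply(chunks, function(ch)
    sum(!ch@missingMask), numeric(1)))
  max(0, 1 - observed / expected)
}

# --- minimal mono PCM WAV I/O -------------------------------------------
# 16-bit RIFF/WAVE; written by hand since the processing chain only needs
# plain PCM and exact frame counts.

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`.
#' @param path Output path.
#' @param rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
writeWav <- function(samples, path, rate) {
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataLen <- 2 * length(pcm)
  writeBin(charToRaw("RIFF"), con)
  .writeU32(con, 36 + dataLen)
  writeBin(charToRaw("WAVEfmt "), con)
  .writeU32(con, 16)
  .writeU16(con, c(1, 1))            # PCM, mono
  .writeU32(con, c(rate, rate * 2))  # sample rate, byte rate
  .writeU16(con, c(2, 16))           # block align, bits per sample
  writeBin(charToRaw("data"), con)
  .writeU32(con, dataLen)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path Input path.
#' @return List with `samples` (numeric in `[-1, 1]`) and `rate`.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readBin(con, "raw", 4), charToRaw("RIFF")))
    stop("not a RIFF file")
  .readU32(con)
  if (!identical(readBin(con, "raw", 4), charToRaw("WAVE")))
    stop("not a WAVE file")
  rate <- NULL
  repeat {
    id <- rawToChar(readBin(con, "raw", 4))
    if (nchar(id) < 4) stop("no data chunk found")
    len <- .readU32(con)
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1) stop("only mono PCM supported")
      rate <- .readU32(con)
      readBin(con, "raw", len - 8)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", len / 2, size = 2, endian = "little")
      return(list(samples = pcm / 32767, rate = rate))
    } else readBin(con, "raw", len)
  }
}
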