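# Central S4 containers. All timestamps are UTC milliseconds (numeric, since
# the values exceed .Machine$integer.max). Samples are stored at codec
# precision (see quantizeSamples) so that write/read round-trips are
# bit-exact by construction.

MODALITIES <- c("ecg", "imu", "audio")

#' Nominal sampling rate of a modality
#'
#' The platform samples ECG at 2426 Hz, 9-axis inertial data at a nominal
#' 70 Hz, and audio at 22050 Hz.
#'
#' @param modality One of `"ecg"`, `"imu"`, `"audio"`.
#' @return Sampling rate in samples per second.
#' @export
nominalRateOf <- function(modality) {
  switch(match.arg(modality, MODALITIES),
         ecg = 2426, imu = 70, audio = 22050)
}

#' Nominal chunk period of a modality
#'
#' Audio is written to storage every 10 s; ECG and IMU every 30 s.
#'
#' @param modality One of `"ecg"`, `"imu"`, `"audio"`.
#' @return Chunk period in seconds.
#' @export
chunkPeriodOf <- function(modality) {
  switch(match.arg(modality, MODALITIES), ecg = 30, imu = 30, audio = 10)
}

# Storage scale factors: value = stored integer / scale.
# ECG is raw ADC counts (uint16), audio is 24-bit full scale, IMU channels
# are int16 with fixed-point scales (accel m/s^2, gyro deg/s, mag a.u.).
.IMU_SCALES <- c(1000, 1000, 1000, 100, 100, 100, 1000, 1000, 1000)
.AUDIO_SCALE <- 8388607  # 2^23 - 1

IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' Snap sample values to codec precision
#'
#' ECG samples are rounded to integer ADC counts and clamped to the uint16
#' range; IMU channels are rounded to their fixed-point grids; audio is
#' clamped to \[-1, 1\] and rounded to the 24-bit grid. Applying this is what
#' makes binary round-trips exact.
#'
#' @param modality Modality string.
#' @param samples Numeric vector (ecg, audio) or n x 9 matrix (imu).
#' @return Samples on the storage grid, same shape as the input.
#' @export
quantizeSamples <- function(modality, samples) {
  modality <- match.arg(modality, MODALITIES)
  if (modality == "ecg") {
    pmin(pmax(round(samples), 0), 65535)
  } else if (modality == "audio") {
    round(pmin(pmax(samples, -1), 1) * .AUDIO_SCALE) / .AUDIO_SCALE
  } else {
    m <- as.matrix(samples)
    for (j in seq_len(ncol(m))) {
      s <- .IMU_SCALES[j]
      m[, j] <- pmin(pmax(round(m[, j] * s), -32768), 32767) / s
    }
    m
  }
}

#' SensorChunk: one timestamped block of samples for one modality
#'
#' A chunk holds the samples written in one storage flush (10 s of audio or
#' 30 s of ECG/IMU), the chunk's start/end UTC timestamps, and a logical
#' missing-sample mask. Mask entries that are `TRUE` mark zero-padding
#' inserted in place of samples the device failed to write; padded samples
#' are exactly zero. A chunk may also hold fewer samples than its UTC span
#' implies (samples dropped at acquisition time and never padded); both
#' situations are counted by [missingFraction()].
#'
#' @slot modality `"ecg"`, `"imu"`, or `"audio"`.
#' @slot startUTC,endUTC Chunk start/end, UTC milliseconds (numeric).
#' @slot nominalRate Samples per second.
#' @slot samples Numeric vector (ecg ADC counts; audio in \[-1,1\]) or an
#'   n x 9 matrix for IMU (accel m/s^2, gyro deg/s, magnetometer a.u.).
#' @slot missingMask Logical, one entry per sample (row).
#' @export
setClass("SensorChunk", representation(
  modality = "character",
  startUTC = "numeric",
  endUTC = "numeric",
  nominalRate = "numeric",
  samples = "ANY",
  missingMask = "logical"
))

setValidity("SensorChunk", function(object) {
  msg <- character()
  if (!(object@modality %in% MODALITIES))
    msg <- c(msg, "modality must be one of ecg/imu/audio")
  if (length(object@startUTC) != 1 || length(object@endUTC) != 1)
    msg <- c(msg, "startUTC and endUTC must be scalars")
  if (object@endUTC <= object@startUTC)
    msg <- c(msg, "endUTC must be after startUTC")
  n <- chunkLength(object)
  if (length(object@missingMask) != n)
    msg <- c(msg, "missingMask length must equal the number of samples")
  if (object@modality %in% MODALITIES) {
    period <- (object@endUTC - object@startUTC) / 1000
    nomP <- chunkPeriodOf(object@modality)
    if (abs(period - nomP) > 1)
      msg <- c(msg, sprintf("chunk period %.2f s outside %g +/- 1 s", period, nomP))
    if (object@modality == "imu") {
      if (!is.matrix(object@samples) || ncol(object@samples) != 9)
        msg <- c(msg, "imu samples must be an n x 9 matrix")
    } else if (!is.numeric(object@samples) || !is.null(dim(object@samples))) {
      msg <- c(msg, "ecg/audio samples must be a plain numeric vector")
    }
  }
  if (any(object@missingMask)) {
    padded <- if (is.matrix(object@samples))
      object@samples[object@missingMask, , drop = FALSE]
    else object@samples[object@missingMask]
    if (any(padded != 0)) msg <- c(msg, "padded samples must be exactly zero")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SensorChunk
#'
#' Samples are snapped to codec precision and padded positions are zeroed.
#'
#' @param modality `"ecg"`, `"imu"`, or `"audio"`.
#' @param startUTC,endUTC UTC milliseconds.
#' @param samples Numeric vector, or n x 9 matrix for IMU.
#' @param missingMask Logical per-sample padding mask; default all `FALSE`.
#' @param nominalRate Sampling rate; defaults to the modality's nominal rate.
#' @return A [SensorChunk-class] object.
#' @examples
#' ch <- SensorChunk("ecg", 0, 30000, rep(2048, 72780))
#' chunkLength(ch)
#' @export
SensorChunk <- function(modality, startUTC, endUTC, samples,
                        missingMask = NULL, nominalRate = nominalRateOf(modality)) {
  modality <- match.arg(modality, MODALITIES)
  samples <- quantizeSamples(modality, samples)
  n <- if (is.matrix(samples)) nrow(samples) else length(samples)
  if (is.null(missingMask)) missingMask <- rep(FALSE, n)
  if (any(missingMask)) {
    if (is.matrix(samples)) samples[missingMask, ] <- 0
    else samples[missingMask] <- 0
  }
  methods::new("SensorChunk", modality = modality,
               startUTC = as.numeric(startUTC), endUTC = as.numeric(endUTC),
               nominalRate = nominalRate, samples = samples,
               missingMask = missingMask)
}

#' Recording: a set of chunks from one device
#'
#' @slot chunks List of [SensorChunk-class] objects; within each modality
#'   chunks must be time-ordered and non-overlapping.
#' @slot firmwareVersion `"v1"` (FAT32-era firmware, substantial sample
#'   loss) or `"v2"` (exFAT firmware, little to no loss).
#' @slot deviceId Free-form device identifier.
#' @export
setClass("Recording", representation(
  chunks = "list",
  firmwareVersion = "character",
  deviceId = "character"
))

setValidity("Recording", function(object) {
  msg <- character()
  if (!(object@firmwareVersion %in% c("v1", "v2")))
    msg <- c(msg, "firmwareVersion must be 'v1' or 'v2'")
  if (!all(vapply(object@chunks, methods::is, logical(1), "SensorChunk")))
    msg <- c(msg, "chunks must all be SensorChunk objects")
  else {
    for (m in MODALITIES) {
      ch <- Filter(function(x) x@modality == m, object@chunks)
      if (length(ch) > 1) {
        starts <- vapply(ch, function(x) x@startUTC, numeric(1))
        ends <- vapply(ch, function(x) x@endUTC, numeric(1))
        o <- order(starts)
        if (any(ends[o][-length(o)] > starts[o][-1] + 1e-9))
          msg <- c(msg, sprintf("%s chunks overlap", m))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param chunks List of [SensorChunk-class] objects.
#' @param firmwareVersion `"v1"` or `"v2"`.
#' @param deviceId Device identifier string.
#' @return A [Recording-class] object with chunks sorted by modality start.
#' @export
Recording <- function(chunks = list(), firmwareVersion = "v1",
                      deviceId = "dev0") {
  if (length(chunks)) {
    key <- order(vapply(chunks, function(x) match(x@modality, MODALITIES), 1L),
                 vapply(chunks, function(x) x@startUTC, numeric(1)))
    chunks <- chunks[key]
  }
  methods::new("Recording", chunks = chunks,
               firmwareVersion = firmwareVersion, deviceId = deviceId)
}

#' IBISeries: beat times and interbeat intervals with edit flags
#'
#' Interval `i` spans `beatTimes[i]` to `beatTimes[i+1]`; `ibiMs[i]` is its
#' duration in milliseconds, quantized to the 4 ms grid of the 250 Hz IBI
#' clock. Flags record the editing history of each interval.
#'
#' @slot beatTimes Beat times in seconds from recording start
#'   (length `length(ibiMs) + 1`).
#' @slot ibiMs Interval durations, ms, each a multiple of 4.
#' @slot flags One of `ok`, `edited_divide`, `edited_combine`,
#'   `edited_interpolate`, `missing_overlap` per interval.
#' @slot session Session label per interval (`""` when unsegmented).
#' @slot unusable `TRUE` when the edited fraction exceeded the usability
#'   threshold in [correctMissingArtifacts()].
#' @slot editedFraction Fraction of intervals that required editing.
#' @export
setClass("IBISeries", representation(
  beatTimes = "numeric",
  ibiMs = "numeric",
  flags = "character",
  session = "character",
  unusable = "logical",
  editedFraction = "numeric"
))

IBI_FLAGS <- c("ok", "edited_divide", "edited_combine",
               "edited_interpolate", "missing_overlap")

setValidity("IBISeries", function(object) {
  msg <- character()
  n <- length(object@ibiMs)
  if (length(object@beatTimes) != n + 1L && !(n == 0 && length(object@beatTimes) <= 1))
    msg <- c(msg, "beatTimes must have one more element than ibiMs")
  if (length(object@flags) != n) msg <- c(msg, "flags length mismatch")
  if (length(object@session) != n) msg <- c(msg, "session length mismatch")
  if (n) {
    if (!all(object@flags %in% IBI_FLAGS)) msg <- c(msg, "invalid flag value")
    d <- diff(object@beatTimes) * 1000
    if (max(abs(d - object@ibiMs)) > 0.5)
      msg <- c(msg, "ibiMs must equal diff(beatTimes) in ms")
    if (max(abs(object@ibiMs / 4 - round(object@ibiMs / 4))) > 1e-6)
      msg <- c(msg, "ibiMs must be multiples of 4 ms")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IBISeries
#'
#' @param beatTimes Beat times in seconds (will be snapped to the 4 ms grid).
#' @param flags Optional per-interval flags (default `"ok"`).
#' @param session Optional per-interval session labels (default `""`).
#' @return An [IBISeries-class] object.
#' @export
IBISeries <- function(beatTimes, flags = NULL, session = NULL) {
  beatTimes <- round(beatTimes / 0.004) * 0.004
  n <- max(length(beatTimes) - 1L, 0L)
  ibi <- round(diff(beatTimes) * 250) * 4
  if (is.null(flags)) flags <- rep("ok", n)
  if (is.null(session)) session <- rep("", n)
  methods::new("IBISeries", beatTimes = beatTimes, ibiMs = as.numeric(ibi),
               flags = flags, session = session, unusable = FALSE,
               editedFraction = 0)
}

#' RSAResult: per-epoch RSA values and their task-level mean
#'
#' RSA is the natural log of band-limited heart-period variance (ln ms^2),
#' computed in 30 s epochs and averaged over epochs.
#'
#' @slot epochValues ln(ms^2) per epoch; `NA` for undefined (zero-variance)
#'   epochs, which are excluded from the mean.
#' @slot taskMean Mean of the defined epoch values.
#' @slot nEpochs Number of defined epochs.
#' @slot band The (low, high) Hz band used.
#' @export
setClass("RSAResult", representation(
  epochValues = "numeric",
  taskMean = "numeric",
  nEpochs = "integer",
  band = "numeric"
))

setValidity("RSAResult", function(object) {
  if (object@nEpochs >= 1 &&
      abs(object@taskMean - mean(object@epochValues, na.rm = TRUE)) > 1e-8)
    "taskMean must be the mean of the defined epoch values"
  else TRUE
})
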