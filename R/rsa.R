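# Respiratory sinus arrhythmia by the Porges-Bohrer moving-polynomial
# method: step-interpolated heart period, local cubic detrending, zero-phase
# FIR band-pass in the respiration band, ln variance in 30 s epochs.

#' Band configuration for RSA estimation
#'
#' Adults use the 0.12-0.40 Hz respiration band on a 0.5 s heart-period
#' grid; infants use 0.3-1.3 Hz on a 0.25 s grid (so the band's upper edge
#' stays below the Nyquist frequency of the grid). The detrend is a
#' 21-point moving cubic polynomial and epochs are 30 s.
#'
#' @param subjectClass `"adult"` or `"infant"`.
#' @param band Optional (low, high) Hz override.
#' @param resampleStep Optional grid step override, seconds.
#' @param epochS Epoch length, seconds.
#' @param detrendWindow Detrend window, points (odd).
#' @param detrendOrder Detrend polynomial order.
#' @param firTaps FIR band-pass length (odd).
#' @return List of class `bandConfig`.
#' @export
bandConfig <- function(subjectClass = c("adult", "infant"), band = NULL,
                       resampleStep = NULL, epochS = 30,
                       detrendWindow = 21, detrendOrder = 3,
                       firTaps = 127) {
  subjectClass <- match.arg(subjectClass)
  if (is.null(band))
    band <- if (subjectClass == "adult") c(0.12, 0.40) else c(0.30, 1.30)
  if (is.null(resampleStep))
    resampleStep <- if (subjectClass == "adult") 0.5 else 0.25
  if (band[2] >= 1 / (2 * resampleStep))
    stop("band upper edge must be below the Nyquist of the resampled grid")
  structure(list(subjectClass = subjectClass, band = band,
                 resampleStep = resampleStep, epochS = epochS,
                 detrendWindow = detrendWindow,
                 detrendOrder = detrendOrder, firTaps = firTaps),
            class = "bandConfig")
}

#' Compute RSA from an IBI series
#'
#' Pipeline: (1) step-interpolate heart period (ms) onto the uniform grid of
#' `cfg$resampleStep`; (2) detrend by subtracting a centred moving
#' cubic-polynomial (Savitzky-Golay) fit of `cfg$detrendWindow` points;
#' (3) zero-phase Hamming-window FIR band-pass within `cfg$band`;
#' (4) take the natural log of the variance of the filtered series in
#' non-overlapping 30 s epochs anchored at session start (trailing partial
#' epoch dropped); (5) average epochs. A zero-variance epoch is undefined
#' (`NA`) and excluded from the mean with a warning.
#'
#' @param ibi An [IBISeries-class] (or numeric vector of beat times, s).
#' @param cfg A [bandConfig()].
#' @return An [RSAResult-class].
#' @export
computeRSA <- function(ibi, cfg = bandConfig("adult")) {
  bt <- if (methods::is(ibi, "IBISeries")) ibi@beatTimes else ibi
  if (length(bt) < 3) stop("too few beats for RSA")
  hp <- diff(bt) * 1000
  span <- bt[length(bt)] - bt[1]
  if (span < cfg$epochS) stop("session shorter than one epoch")
  grid <- seq(bt[1], bt[length(bt)], by = cfg$resampleStep)
  # heart period as a step function of time (value = current interval)
  hpGrid <- stats::approx(bt[-length(bt)], hp, grid, method = "constant",
                          rule = 2)$y
  trend <- signal::sgolayfilt(hpGrid, p = cfg$detrendOrder,
                              n = cfg$detrendWindow)
  detr <- hpGrid - trend
  fs <- 1 / cfg$resampleStep
  fir <- as.numeric(signal::fir1(cfg$firTaps - 1, cfg$band / (fs / 2),
                                 type = "pass"))
  filt <- signal::filtfilt(fir, 1, detr)
  epochLen <- round(cfg$epochS / cfg$resampleStep)
  nEp <- floor(length(filt) / epochLen)
  if (nEp < 1) stop("session shorter than one epoch after resampling")
  vals <- vapply(seq_len(nEp), function(k) {
    seg <- filt[((k - 1) * epochLen + 1):(k * epochLen)]
    v <- stats::var(seg)
    if (v <= .Machine$double.eps) NA_real_ else log(v)
  }, numeric(1))
  if (anyNA(vals))
    warning(sprintf("%d epoch(s) had zero variance and were excluded",
                    sum(is.na(vals))))
  defined <- sum(!is.na(vals))
  if (!defined) stop("all epochs undefined (constant heart period)")
  methods::new("RSAResult", epochValues = vals,
               taskMean = mean(vals, na.rm = TRUE),
               nEpochs = as.integer(defined), band = cfg$band)
}

#' Task-transition contrasts of RSA with one-tailed paired tests
#'
#' Given per-subject task means in task order, reports the change across
#' each adjacent task pair, a one-tailed paired t-test in the direction of
#' the expected sign, and whether the observed mean change agrees with it.
#'
#' @param taskMeans Numeric matrix, subjects x tasks (ordered), of RSA task
#'   means; or a list (per subject) of equal-length named vectors.
#' @param expectedPattern Signs (+1/-1) of the expected task-to-task change
#'   (`next - previous`), length `ncol - 1`.
#' @return Data frame with one row per transition: `from`, `to`,
#'   `meanDelta`, `t`, `df`, `pOneTailed`, `signAgrees`.
#' @export
rsaContrast <- function(taskMeans, expectedPattern) {
  if (is.list(taskMeans) && !is.data.frame(taskMeans)) {
    nm <- names(taskMeans[[1]])
    if (!all(vapply(taskMeans, function(x) identical(names(x), nm),
                    logical(1))))
      stop("mismatched task sets across subjects")
    taskMeans <- do.call(rbind, taskMeans)
  }
  taskMeans <- as.matrix(taskMeans)
  nT <- ncol(taskMeans)
  if (nT < 2) stop("need at least two tasks")
  if (length(expectedPattern) != nT - 1)
    stop("expectedPattern must have one sign per transition")
  labs <- colnames(taskMeans)
  if (is.null(labs)) labs <- paste0("task", seq_len(nT))
  out <- lapply(seq_len(nT - 1), function(j) {
    d <- taskMeans[, j + 1] - taskMeans[, j]
    sgn <- sign(expectedPattern[j])
    if (nrow(taskMeans) >= 2 && stats::sd(d) > 0) {
      tt <- pairedT(d * sgn, tail = "one")
      t <- tt$t * sgn; df <- tt$df; p <- tt$p
    } else {
      t <- if (all(d == 0)) 0 else NA_real_
      df <- nrow(taskMeans) - 1L
      p <- if (all(d == 0)) 0.5 else NA_real_
    }
    data.frame(from = labs[j], to = labs[j + 1], meanDelta = mean(d),
               t = t, df = df, pOneTailed = p,
               signAgrees = sign(mean(d)) == sgn ||
                 (mean(d) == 0 && sgn == 0))
  })
  do.call(rbind, out)
}
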