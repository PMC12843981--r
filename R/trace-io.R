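# On-disk trace formats:
#  (a) delimited text with header columns time_s, voltage_v
#  (b) raw little-endian float binary (.f64 default, .f32 optional) plus a
#      JSON sidecar {"sampling_rate_hz", "laser_power_mw", "lsb_v", "label",
#      "dtype"}

sidecarPath <- function(path) paste0(path, ".json")

#' Read a voltage time trace from disk
#'
#' Supports two formats: delimited text with header columns `time_s` and
#' `voltage_v` (the sampling rate is inferred from the median time step,
#' which must be uniform), or raw little-endian float binary accompanied by
#' a JSON sidecar carrying the sampling rate and metadata. A one-column
#' `voltage_v` text file is accepted only with a sidecar, since it carries
#' no sampling rate itself.
#'
#' @param path file to read.
#' @param sidecar path to the JSON sidecar; defaults to `<path>.json` when
#'   that file exists.
#' @return A [TimeTrace-class].
#' @seealso [writeTrace()]
#' @export
readTrace <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sidecar) && file.exists(sidecarPath(path)))
    sidecar <- sidecarPath(path)
  meta <- if (!is.null(sidecar)) {
    if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else NULL

  isBinary <- grepl("\\.(f32|f64)$", path)
  if (isBinary) {
    if (is.null(meta)) stop("binary trace requires a JSON sidecar")
    dtype <- if (!is.null(meta$dtype)) meta$dtype
             else if (grepl("\\.f32$", path)) "f32" else "f64"
    size <- if (dtype == "f32") 4L else 8L
    n <- file.size(path) / size
    if (n != floor(n)) stop("binary file size is not a multiple of ", size)
    x <- readBin(path, "numeric", n = n, size = size, endian = "little")
    fs <- meta$sampling_rate_hz
    if (is.null(fs)) stop("sampling rate unavailable")
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "",
                             check.names = FALSE)
    if (all(c("time_s", "voltage_v") %in% names(tab))) {
      tt <- tab$time_s
      dt <- diff(tt)
      if (any(dt <= 0)) stop("time must be strictly increasing")
      if (max(dt) - min(dt) > 1e-9)
        stop("non-uniform sampling (time steps differ by > 1e-9 s)")
      fs <- 1 / stats::median(dt)
      x <- tab$voltage_v
    } else if ("voltage_v" %in% names(tab)) {
      if (is.null(meta) || is.null(meta$sampling_rate_hz))
        stop("sampling rate unavailable")
      fs <- meta$sampling_rate_hz
      x <- tab$voltage_v
    } else {
      stop("unrecognised trace format: need time_s/voltage_v columns")
    }
  }
  if (any(!is.finite(x))) stop("trace contains NaN/Inf samples")
  TimeTrace(
    samples = x, samplingRate = fs,
    laserPower = if (!is.null(meta$laser_power_mw)) meta$laser_power_mw
                 else NA_real_,
    lsb = if (!is.null(meta$lsb_v)) meta$lsb_v else 0.002441,
    label = if (!is.null(meta$label)) as.list(meta$label) else list()
  )
}

#' Write a voltage time trace to disk
#'
#' The default format is raw little-endian float64 binary plus a JSON
#' sidecar, which round-trips samples and metadata bit-exactly. A float32
#' binary (half the size; samples rounded to float32 precision, still far
#' below the acquisition LSB) and a two-column `time_s`/`voltage_v` text
#' format are available.
#'
#' @param trace a [TimeTrace-class].
#' @param path output path; for binary formats the extension `.f64`/`.f32`
#'   is appended if absent and a `<path>.json` sidecar is written.
#' @param format `"f64"` (default), `"f32"`, or `"csv"`.
#' @return The path written, invisibly.
#' @export
writeTrace <- function(trace, path, format = c("f64", "f32", "csv")) {
  stopifnot(is(trace, "TimeTrace"))
  validObject(trace)
  format <- match.arg(format)
  if (format == "csv") {
    tt <- (seq_along(trace@samples) - 1) / trace@samplingRate
    utils::write.table(
      data.frame(time_s = tt, voltage_v = trace@samples),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  ext <- paste0(".", format)
  if (!endsWith(path, ext)) path <- paste0(path, ext)
  size <- if (format == "f32") 4L else 8L
  writeBin(trace@samples, path, size = size, endian = "little")
  meta <- list(sampling_rate_hz = trace@samplingRate,
               lsb_v = trace@lsb, dtype = format)
  if (!is.na(trace@laserPower)) meta$laser_power_mw <- trace@laserPower
  if (length(trace@label)) meta$label <- trace@label
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Locate the trapping event in a raw trace
#'
#' A trapping event appears as a jump in the transmitted laser intensity
#' together with an increase in the noise coming from the thermal motion of
#' the trapped protein. The onset is the first sample where the 10 Hz
#' low-pass signal exceeds `baseline mean + jumpSigma * baseline sd` and
#' stays above it for at least `sustain` seconds (brief dips are tolerated:
#' at least 95% of the sustain window must remain above threshold, since
#' the trapped signal itself fluctuates). The event is accepted only if the
#' high-frequency residual rms after onset exceeds the pre-onset residual
#' rms by at least `noiseFactor`, both measured away from the
#' filter-smeared transition edge. The analysed trapped segment starts
#' `guard` seconds after onset so the transition edge does not contaminate
#' spectral or density statistics.
#'
#' @param trace a [TimeTrace-class] with at least `baselineDuration +
#'   sustain` seconds of data and an untrapped baseline at the start.
#' @param jumpSigma jump threshold in baseline standard deviations.
#' @param sustain minimum time above threshold (s).
#' @param baselineDuration initial span used to estimate the untrapped
#'   level (s).
#' @param guard settling time excluded after onset (s).
#' @param cutoff low-pass cutoff used to track the slow intensity level (Hz).
#' @param noiseFactor required ratio of post-onset to pre-onset
#'   high-frequency residual rms; thermal motion of a trapped protein
#'   raises the noise far beyond this margin.
#' @return A [TrappingEvent-class].
#' @export
detectTrappingEvent <- function(trace, jumpSigma = 5, sustain = 0.5,
                                baselineDuration = 1, guard = 0.1,
                                cutoff = 10, noiseFactor = 1.05) {
  stopifnot(is(trace, "TimeTrace"))
  fs <- trace@samplingRate
  x <- trace@samples
  n <- length(x)
  nb <- round(baselineDuration * fs)
  ns <- round(sustain * fs)
  ng <- round(guard * fs)
  if (n < nb + ns)
    stop("trace shorter than baseline + sustain")
  lp <- butterLowpass(x, fs, cutoff)
  bm <- mean(lp[seq_len(nb)])
  bs <- stats::sd(x[seq_len(nb)])
  above <- lp > bm + jumpSigma * bs
  # fraction of the sustain window above threshold, per starting sample
  if (n - ns + 1L < nb + 1L) stop("no trapping event found")
  cs <- cumsum(c(0, above))
  frac <- (cs[(1L + ns):(n + 1L)] - cs[1:(n - ns + 1L)]) / ns
  cand <- which(above[1:(n - ns + 1L)] & frac >= 0.95)
  cand <- cand[cand > nb]
  if (!length(cand)) stop("no trapping event found")
  onset <- cand[1L]
  resid <- x - lp
  preEnd <- max(onset - ng, 2L)
  postStart <- min(onset + ng, n)
  preRms <- sqrt(mean(resid[seq_len(preEnd - 1L)]^2))
  postRms <- sqrt(mean(resid[postStart:n]^2))
  if (postRms <= noiseFactor * preRms)
    stop("no trapping event found (no noise increase)")
  start <- min(onset + ng, n)
  new("TrappingEvent",
      trace = trace, onsetIndex = as.integer(onset),
      trappedStart = as.integer(start), trappedEnd = as.integer(n),
      baselineMean = mean(x[seq_len(onset - 1L)]),
      baselineStd = stats::sd(x[seq_len(onset - 1L)]))
}

# zero-phase 4th-order Butterworth low-pass; odd-reflection padding
# suppresses the startup transient that zero initial conditions would
# otherwise smear into both ends of the signal
butterLowpass <- function(x, fs, cutoff, order = 4L) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(x)
  mu <- mean(x)
  x <- x - mu
  npad <- min(n - 1L, ceiling(10 * fs / cutoff))
  head <- 2 * x[1L] - x[(npad + 1L):2L]
  tail <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filtfilt(bf, c(head, x, tail))
  as.numeric(y[(npad + 1L):(npad + n)]) + mu
}
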