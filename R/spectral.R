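# Corner-frequency spectroscopy: detrend -> Welch PSD -> Lorentzian fit.
# The corner frequency is where the Lorentzian is reduced by 3 dB from its
# low-frequency plateau: S(fc) - noiseFloor = s0 / 2.

#' Remove linear drift and DC offset from a voltage segment
#'
#' Subtracts the least-squares straight line, leaving a segment with zero
#' mean and zero least-squares slope.
#'
#' @param x numeric vector (length >= 2).
#' @return The detrended vector.
#' @export
detrendVoltage <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to detrend")
  t <- seq_len(n) - (n + 1) / 2          # centred time index, mean 0
  slope <- sum(t * x) / sum(t * t)
  x - mean(x) - slope * t
}

#' Welch-averaged one-sided power spectral density
#'
#' Splits the segment into tapered, overlapping sub-segments, averages
#' their one-sided periodograms, and drops the DC bin. Each sub-segment
#' has its mean removed before tapering. The density is scaled so that its
#' integral over frequency equals the signal variance (Parseval).
#'
#' @param x voltage segment (already detrended for drift, or not: each
#'   sub-segment is demeaned).
#' @param samplingRate sampling frequency (Hz).
#' @param subLength sub-segment length (s); default 1 s, giving 1 Hz
#'   resolution.
#' @param overlap fraction of overlap between consecutive sub-segments.
#' @param taper `"hann"` (default) or `"rectangular"`.
#' @return A [PSDEstimate-class].
#' @export
estimatePSD <- function(x, samplingRate, subLength = 1, overlap = 0.5,
                        taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  nseg <- round(subLength * samplingRate)
  if (length(x) < nseg)
    stop("segment shorter than one sub-segment")
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  } else rep(1, nseg)
  U <- sum(w^2)
  nf <- nseg %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    P <- Mod(X[1:(nf + 1L)])^2 / (samplingRate * U)
    acc <- acc + P
  }
  acc <- acc / length(starts)
  # one-sided: double interior bins (not DC; not Nyquist when nseg even)
  dbl <- 2:(nf + if (nseg %% 2L == 0L) 0L else 1L)
  acc[dbl] <- 2 * acc[dbl]
  freq <- (0:nf) * samplingRate / nseg
  new("PSDEstimate", frequency = freq[-1L], density = acc[-1L],
      settings = list(segment_length_s = length(x) / samplingRate,
                      sub_length_s = subLength, overlap = overlap,
                      taper = taper, n_sub = length(starts),
                      sampling_rate_hz = samplingRate))
}

#' Fit a Lorentzian to a power spectral density
#'
#' Fits `S(f) = s0 / (1 + (f/fc)^2) + noiseFloor` by least squares on
#' `log10(S)` after averaging the PSD into logarithmically spaced
#' frequency bins, so every decade carries comparable weight (raw
#' periodogram ordinates are exponentially distributed and crowd the high
#' frequencies). Parameters are optimised on a log scale, keeping `s0`,
#' `fc` and the noise floor positive. The deterministic starting point is
#' `s0` = mean density of the lowest decade and `fc` = the first frequency
#' where the binned density falls below `s0 / 2`.
#'
#' @param psd a [PSDEstimate-class].
#' @param band fitted frequency interval in Hz (default 5 Hz to 5 kHz);
#'   must contain at least 10 PSD points.
#' @param nLogBins number of logarithmic bins used for the fit.
#' @param fitNoiseFloor if `FALSE` the additive white floor is fixed to 0.
#' @return A [LorentzianFit-class].
#' @export
fitLorentzian <- function(psd, band = c(5, 5000), nLogBins = 50,
                          fitNoiseFloor = TRUE) {
  stopifnot(is(psd, "PSDEstimate"), length(band) == 2, band[1] < band[2])
  sel <- psd@frequency >= band[1] & psd@frequency <= band[2]
  if (sum(sel) < 10L)
    stop("band contains fewer than 10 PSD points")
  f <- psd@frequency[sel]
  d <- psd@density[sel]

  edges <- 10^seq(log10(min(f)), log10(max(f)), length.out = nLogBins + 1L)
  idx <- findInterval(f, edges, rightmost.closed = TRUE)
  binN <- as.numeric(rowsum(rep(1, length(f)), idx))
  fb <- as.numeric(rowsum(f, idx)) / binN
  db <- as.numeric(rowsum(d, idx)) / binN
  pos <- is.finite(db) & db > 0
  if (sum(pos) < 4L) stop("too few positive PSD bins in band")

  lowDecade <- pos & fb <= min(fb[pos]) * 10
  s0Init <- mean(db[lowDecade])
  below <- which(pos & db < s0Init / 2)
  fcInit <- if (length(below)) fb[below[1L]]
            else sqrt(min(fb[pos]) * max(fb[pos]))
  floorInit <- max(min(db[pos]) / 10, s0Init * 1e-9)

  logd <- log10(db[pos])
  residFun <- function(p) {
    s0 <- exp(p[1]); fc <- exp(p[2])
    nfl <- if (fitNoiseFloor) exp(p[3]) else 0
    # bin the model exactly as the data so decimation cancels in the fit
    mb <- as.numeric(rowsum(s0 / (1 + (f / fc)^2) + nfl, idx)) / binN
    log10(mb[pos]) - logd
  }
  p0 <- c(log(s0Init), log(fcInit),
          if (fitNoiseFloor) log(floorInit) else NULL)
  fit <- minpack.lm::nls.lm(p0, fn = residFun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  res <- residFun(p)
  new("LorentzianFit",
      s0 = exp(p[1]), fc = exp(p[2]),
      noiseFloor = if (fitNoiseFloor) exp(p[3]) else 0,
      rss = sum(res^2), band = as.numeric(band),
      diagnostics = list(n_points = sum(pos), n_log_bins = nLogBins,
                         converged = fit$info %in% 1:4,
                         info = fit$info, message = fit$message,
                         fit_noise_floor = fitNoiseFloor))
}

#' Evaluate a fitted Lorentzian model
#'
#' @param fit a [LorentzianFit-class].
#' @param f frequencies (Hz).
#' @return Model density `s0 / (1 + (f/fc)^2) + noiseFloor` in V^2/Hz.
#' @export
lorentzianModel <- function(fit, f) {
  fit@s0 / (1 + (f / fit@fc)^2) + fit@noiseFloor
}

#' Corner frequency of a trapping event
#'
#' Convenience composition: detrend the trapped segment, estimate its
#' Welch PSD, and fit a Lorentzian. Identical, by construction, to calling
#' [detrendVoltage()], [estimatePSD()] and [fitLorentzian()] stepwise with
#' the same settings.
#'
#' @param event a [TrappingEvent-class] whose trapped segment is at least
#'   `window` seconds long.
#' @param window analysis window (s); the first `window` seconds of the
#'   trapped segment are used (default 10 s).
#' @param subLength,overlap,taper passed to [estimatePSD()].
#' @param band,nLogBins,fitNoiseFloor passed to [fitLorentzian()].
#' @param full if `TRUE` return the [LorentzianFit-class]; otherwise the
#'   corner frequency in Hz.
#' @export
cornerFrequency <- function(event, window = 10, subLength = 1,
                            overlap = 0.5, taper = "hann",
                            band = c(5, 5000), nLogBins = 50,
                            fitNoiseFloor = TRUE, full = FALSE) {
  stopifnot(is(event, "TrappingEvent"))
  fs <- samplingRate(event)
  seg <- trappedSamples(event)
  nw <- round(window * fs)
  if (length(seg) < nw)
    stop("trapped segment shorter than the analysis window")
  seg <- detrendVoltage(seg[seq_len(nw)])
  psd <- estimatePSD(seg, fs, subLength = subLength, overlap = overlap,
                     taper = taper)
  fit <- fitLorentzian(psd, band = band, nLogBins = nLogBins,
                       fitNoiseFloor = fitNoiseFloor)
  if (full) fit else fit@fc
}
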