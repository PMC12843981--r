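# Two-state recognition: transitions are selected on the first derivative
# of the 10 Hz low-pass signal (threshold: 3x the overall standard
# deviation of the absolute derivative) and genuine steps are distinguished
# from transient noise by the local level change versus the local standard
# deviation within 0.1 s windows.

#' Zero-phase low-pass filter a trace
#'
#' Applies a 4th-order Butterworth low-pass forward and backward
#' (zero phase, unit DC gain).
#'
#' @param trace a [TimeTrace-class] or numeric vector.
#' @param cutoff cutoff frequency (Hz), below Nyquist; default 10 Hz.
#' @param samplingRate required when `trace` is a bare numeric vector.
#' @return A [FilteredTrace-class].
#' @export
lowpassTrace <- function(trace, cutoff = 10, samplingRate = NULL) {
  if (is(trace, "TimeTrace")) {
    x <- trace@samples
    fs <- trace@samplingRate
  } else {
    if (is.null(samplingRate)) stop("samplingRate required for a vector")
    x <- as.numeric(trace)
    fs <- samplingRate
  }
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, Nyquist)")
  new("FilteredTrace", samples = butterLowpass(x, fs, cutoff), raw = x,
      samplingRate = fs, cutoff = cutoff, filterOrder = 4L,
      zeroPhase = TRUE)
}

#' Detect and validate discrete transitions in a filtered signal
#'
#' Candidate transitions are samples of the low-pass signal whose absolute
#' first difference exceeds `kSigma` times the standard deviation of the
#' absolute first difference over the whole segment; near-contiguous runs
#' of candidates (one physical step smeared by the low-pass filter)
#' collapse to the extremal-derivative sample. A candidate is validated as
#' a genuine step only if the level change between the `window`-long
#' stretches before and after it (excluding a `guard` neighbourhood around
#' the candidate) exceeds `levelFactor` times the larger of the two local
#' standard deviations. Local statistics are measured on the raw signal,
#' whose local standard deviation is the thermal fluctuation amplitude a
#' genuine conformational step must beat; short transients fail because
#' both windows straddle the same level. Candidates too close to the
#' segment edges to host both windows are discarded.
#'
#' @param filtered a [FilteredTrace-class] (see [lowpassTrace()]).
#' @param kSigma derivative threshold factor (default 3).
#' @param window local-statistics window (s, default 0.1).
#' @param levelFactor required step height in local standard deviations
#'   (default 2); 0 disables validation.
#' @param guard half-width of the neighbourhood excluded around each
#'   candidate (s, default 0.005).
#' @param refineThreshold if `TRUE` (default) the derivative scale is
#'   re-estimated once with the first-pass candidate runs excluded, so
#'   that the steps themselves do not inflate the threshold; `FALSE`
#'   keeps the single-pass scale.
#' @return An unlabelled [StateSequence-class]: validated transition
#'   indices, per-segment mean levels and dwell times; run
#'   [assignStates()] to obtain two-state labels and occupancies.
#' @export
detectTransitions <- function(filtered, kSigma = 3, window = 0.1,
                              levelFactor = 2, guard = 0.005,
                              refineThreshold = TRUE) {
  stopifnot(is(filtered, "FilteredTrace"), kSigma > 0)
  x <- filtered@samples
  fs <- filtered@samplingRate
  n <- length(x)
  nw <- round(window * fs)
  ng <- round(guard * fs)
  if (n < 3L * nw) stop("segment shorter than 3 windows")

  d <- diff(x)
  thr <- kSigma * stats::sd(abs(d))
  cand <- which(abs(d) > thr)
  if (refineThreshold && length(cand)) {
    # steps inflate sd(|d|); re-estimate it on the step-free derivative
    drop <- unique(pmin(pmax(rep(cand, each = 2 * ng + 1L) +
                               (-ng):ng, 1L), n - 1L))
    if (length(drop) < n - 2L) {
      thr <- kSigma * stats::sd(abs(d[-drop]))
      cand <- which(abs(d) > thr)
    }
  }

  xv <- if (length(filtered@raw) == n) filtered@raw else x
  validated <- integer()
  if (length(cand) && thr > 0) {
    # collapse candidate runs (allowing guard-sized gaps inside a smeared
    # step) to the extremal derivative
    runId <- cumsum(c(1L, diff(cand) > max(1L, ng)))
    peaks <- vapply(split(cand, runId), function(ii)
      ii[which.max(abs(d[ii]))], integer(1))
    for (i in peaks) {
      loA <- i - ng - nw; hiA <- i - ng - 1L
      loB <- i + 1L + ng; hiB <- i + ng + nw
      if (loA < 1L || hiB > n) next
      before <- xv[loA:hiA]
      after <- xv[loB:hiB]
      stepOk <- levelFactor <= 0 ||
        abs(mean(after) - mean(before)) >
          levelFactor * max(stats::sd(before), stats::sd(after))
      if (stepOk) validated <- c(validated, i + 1L)  # first sample of new segment
    }
  }
  validated <- sort(unique(validated))

  segStart <- c(1L, validated)
  segEnd <- c(validated - 1L, n)
  levels <- vapply(seq_along(segStart), function(j)
    mean(xv[segStart[j]:segEnd[j]]), numeric(1))
  dwell <- (segEnd - segStart + 1L) / fs

  new("StateSequence",
      transitions = as.integer(validated), segmentLevels = levels,
      labels = rep(NA_integer_, length(levels)),
      occupancy = numeric(), dwellTimes = dwell,
      samplingRate = fs, nSamples = as.integer(n))
}

#' Assign two-state labels to a transition sequence
#'
#' Clusters segment mean levels into two centers by one-dimensional
#' two-means with deterministic initialisation at the extreme levels
#' (no RNG). Label 0 is the lower-voltage state, label 1 the
#' higher-voltage state; occupancy is the time fraction spent in each
#' label. A single segment (or indistinguishable levels) yields one state
#' with occupancy 1.
#'
#' @param seq a [StateSequence-class] from [detectTransitions()].
#' @return The labelled [StateSequence-class].
#' @export
assignStates <- function(seq) {
  stopifnot(is(seq, "StateSequence"))
  levels <- seq@segmentLevels
  if (length(levels) == 0L) stop("empty state sequence")
  total <- sum(seq@dwellTimes)
  if (length(levels) == 1L || diff(range(levels)) < .Machine$double.eps^0.5) {
    seq@labels <- rep(0L, length(levels))
    seq@occupancy <- c("0" = 1)
    return(seq)
  }
  km <- stats::kmeans(levels, centers = matrix(range(levels), ncol = 1))
  lower <- which.min(km$centers)
  lab <- ifelse(km$cluster == lower, 0L, 1L)
  occ <- vapply(c(0L, 1L), function(k)
    sum(seq@dwellTimes[lab == k]) / total, numeric(1))
  names(occ) <- c("0", "1")
  seq@labels <- lab
  seq@occupancy <- occ
  seq
}

#' Tabulate state-0 occupancy against temperature
#'
#' Collects the occupancy of the lower-voltage state (label 0) across
#' measurements at different local temperatures, averaging duplicate
#' temperatures (flagged via `nEntries`), and reports the dominant state
#' per temperature (`"tie"` at exactly 0.5).
#'
#' @param seqs list of labelled [StateSequence-class] objects.
#' @param temperatures local temperature per sequence (degrees C).
#' @return A data.frame sorted by temperature with columns `temperature`,
#'   `occupancy0`, `dominant`, `nEntries`.
#' @export
occupancyVsTemperature <- function(seqs, temperatures) {
  stopifnot(length(seqs) == length(temperatures), length(seqs) >= 1,
            all(is.finite(temperatures)))
  occ0 <- vapply(seqs, function(s) {
    stopifnot(is(s, "StateSequence"))
    if (!length(s@occupancy)) stop("sequence is unlabelled; run assignStates")
    if ("0" %in% names(s@occupancy)) unname(s@occupancy["0"]) else 0
  }, numeric(1))
  agg <- stats::aggregate(occ0, by = list(temperature = temperatures), mean)
  cnt <- stats::aggregate(occ0, by = list(temperature = temperatures), length)
  out <- data.frame(temperature = agg$temperature, occupancy0 = agg$x,
                    nEntries = cnt$x)
  out$dominant <- ifelse(out$occupancy0 > 0.5, "0",
                         ifelse(out$occupancy0 < 0.5, "1", "tie"))
  out <- out[order(out$temperature),
             c("temperature", "occupancy0", "dominant", "nEntries")]
  rownames(out) <- NULL
  out
}
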