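# End-to-end orchestration: trace -> trapping event -> corner frequency ->
# zero-power fit per sample group; trace -> state sequence -> energy
# landscape -> stability curve; optional event classification. Every
# setting is carried in one AnalysisConfig and stamped into the report, so
# a report reproduces exactly from its own provenance.

#' Aggregate configuration for the full analysis
#'
#' Collects the settings of every stage with the study defaults: 10 s PSD
#' window with 1 s Hann sub-segments, 5 Hz-5 kHz Lorentzian band, 10 Hz
#' low-pass state detection with a 3x derivative threshold and 0.1 s
#' validation window, LSB 0.002441 V, 51 Richardson-Lucy iterations, 6%
#' PSF fallback, and a 0.58 K/mW thermal model.
#'
#' @param spectral list of [cornerFrequency()] settings.
#' @param detection list of [detectTrappingEvent()] settings.
#' @param states list of [detectTransitions()] settings plus `cutoff`.
#' @param landscape a [landscapeConfig()].
#' @param thermal a [thermalModel()] or `NULL` (landscapes then require an
#'   explicit temperature).
#' @param classification a [classificationRule()].
#' @param seed global seed recorded in provenance; the landscape dither is
#'   the only stochastic stage and consumes `landscape$seed`.
#' @return A list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(spectral = list(window = 10, subLength = 1,
                                           overlap = 0.5, taper = "hann",
                                           band = c(5, 5000), nLogBins = 50,
                                           fitNoiseFloor = TRUE),
                           detection = list(jumpSigma = 5, sustain = 0.5,
                                            baselineDuration = 1,
                                            guard = 0.1, cutoff = 10),
                           states = list(cutoff = 10, kSigma = 3,
                                         window = 0.1, levelFactor = 2),
                           landscape = landscapeConfig(),
                           thermal = NULL,
                           classification = classificationRule(),
                           seed = 1) {
  structure(list(spectral = spectral, detection = detection,
                 states = states, landscape = landscape, thermal = thermal,
                 classification = classification, seed = as.integer(seed)),
            class = "AnalysisConfig")
}

#' Run the full NOT analysis over a set of traces
#'
#' For every trace: locate the trapping event, fit the corner frequency,
#' detect and label two-state transitions, and (when a temperature is
#' available) reconstruct the free-energy landscape. Traces sharing a
#' `group` label are pooled into a zero-power fit of corner frequency
#' versus mean APD voltage; landscapes with finite deltaG feed a quadratic
#' stability fit. Per-trace failures are recorded in the report, not
#' fatal.
#'
#' @param traces list of [TimeTrace-class] objects and/or file paths
#'   readable by [readTrace()].
#' @param config an [analysisConfig()].
#' @param classify if `TRUE`, classify events with the config's rule.
#' @return A list of class `AnalysisReport`: `events` (per-trace results),
#'   `zeroPower` (per group), `stability`, `classification`, `errors`, and
#'   `provenance` (config echo + hash, seed, package version). Serialise
#'   with [reportToJson()]; re-running with the same inputs and config
#'   reproduces the JSON byte-for-byte.
#' @export
runFullAnalysis <- function(traces, config = analysisConfig(),
                            classify = FALSE) {
  stopifnot(inherits(config, "AnalysisConfig"))
  if (length(traces) == 0L) stop("no traces supplied")
  sp <- config$spectral
  st <- config$states
  dt <- config$detection

  events <- list()
  errors <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    id <- if (is.character(tr)) basename(tr) else
      if (!is.null(tr@label$id)) tr@label$id else paste0("trace", i)
    res <- tryCatch({
      if (is.character(tr)) tr <- readTrace(tr)
      ev <- detectTrappingEvent(tr, jumpSigma = dt$jumpSigma,
                                sustain = dt$sustain,
                                baselineDuration = dt$baselineDuration,
                                guard = dt$guard, cutoff = dt$cutoff)
      fit <- cornerFrequency(ev, window = sp$window,
                             subLength = sp$subLength,
                             overlap = sp$overlap, taper = sp$taper,
                             band = sp$band, nLogBins = sp$nLogBins,
                             fitNoiseFloor = sp$fitNoiseFloor, full = TRUE)
      seg <- trappedSamples(ev)
      fs <- samplingRate(ev)
      lp <- lowpassTrace(seg, cutoff = st$cutoff, samplingRate = fs)
      seq <- assignStates(detectTransitions(lp, kSigma = st$kSigma,
                                            window = st$window,
                                            levelFactor = st$levelFactor))
      land <- tryCatch(
        withCallingHandlers(
          landscapePipeline(ev, seq, thermal = config$thermal,
                            config = config$landscape),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      r <- detrendVoltage(seg)
      occ0 <- if ("0" %in% names(occupancy(seq)))
        unname(occupancy(seq)["0"]) else 0
      list(id = id,
           group = if (!is.null(tr@label$group)) tr@label$group else "all",
           onset_s = (onsetIndex(ev) - 1) / fs,
           abscissa_v = mean(seg),
           laser_power_mw = laserPower(tr),
           fc_hz = cornerFreq(fit), s0 = plateau(fit),
           noise_floor = noiseFloor(fit),
           amplitude_v = sqrt(mean(r^2)),
           n_transitions = length(transitions(seq)),
           occupancy0 = occ0,
           delta_g_kbt = if (is.null(land)) NA else deltaG(land),
           temperature_c = if (is.null(land)) NA
                           else land@temperature - 273.15)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        list(id = id, message = conditionMessage(res))
    } else {
      events[[length(events) + 1L]] <- res
    }
  }

  groups <- vapply(events, `[[`, character(1), "group")
  zeroPower <- list()
  for (g in unique(groups)) {
    ee <- events[groups == g]
    ab <- vapply(ee, `[[`, numeric(1), "abscissa_v")
    fc <- vapply(ee, `[[`, numeric(1), "fc_hz")
    if (length(ab) >= 2L && length(unique(ab)) >= 2L) {
      zf <- fitZeroPower(ab, fc, label = g)
      zeroPower[[g]] <- list(group = g, intercept_hz = zf@intercept,
                             slope = zf@slope,
                             stderr_intercept = zf@stderrIntercept,
                             r_squared = zf@rSquared, n = zf@nPoints)
    }
  }

  dg <- vapply(events, function(e) as.numeric(e$delta_g_kbt), numeric(1))
  tc <- vapply(events, function(e) as.numeric(e$temperature_c), numeric(1))
  ok <- is.finite(dg) & is.finite(tc)
  stability <- if (sum(ok) >= 3L && length(unique(tc[ok])) >= 3L) {
    sc <- fitStabilityCurve(tc[ok], dg[ok])
    list(coefficients = as.list(sc@coefficients),
         vertex_temperature_c = sc@vertexTemperature,
         is_maximum = sc@isMaximum, n = sum(ok))
  } else NULL

  classification <- if (classify && length(events)) {
    feats <- data.frame(
      eventId = vapply(events, `[[`, character(1), "id"),
      fcHz = vapply(events, `[[`, numeric(1), "fc_hz"),
      amplitudeV = vapply(events, `[[`, numeric(1), "amplitude_v"),
      laserPowerMw = vapply(events, function(e)
        as.numeric(e$laser_power_mw), numeric(1)))
    cl <- classifyEvents(feats, config$classification)
    list(labels = as.character(cl$labels),
         counts = as.list(as.integer(cl$counts)) |>
           stats::setNames(names(cl$counts)))
  } else NULL

  cfgJson <- configToJson(config)
  structure(list(events = events, zeroPower = zeroPower,
                 stability = stability, classification = classification,
                 errors = errors,
                 provenance = list(
                   config = jsonlite::fromJSON(cfgJson,
                                               simplifyVector = FALSE),
                   config_hash = fnv1aHash(cfgJson),
                   seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("nanotrap")))),
            class = "AnalysisReport")
}

configToJson <- function(config) {
  declass <- function(x) {
    if (is.list(x)) lapply(unclass(x), declass) else x
  }
  as.character(jsonlite::toJSON(declass(config), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

# cheap deterministic content hash (polynomial rolling, mod 2^31-1) for
# provenance stamping; not cryptographic
fnv1aHash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Serialise an analysis report to JSON
#'
#' @param report an `AnalysisReport` from [runFullAnalysis()].
#' @return A JSON string; deterministic for identical inputs and config.
#' @export
reportToJson <- function(report) {
  stopifnot(inherits(report, "AnalysisReport"))
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA, null = "null", na = "null"))
}
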