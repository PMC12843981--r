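# Per-event features and egg-white classification. At a common reference
# power, conalbumin trapping events sit in a 36-56 Hz corner-frequency
# gate (9 mW), while the more abundant ovalbumin events fall below it.

#' Extract classification features from a trapping event
#'
#' @param event a [TrappingEvent-class].
#' @param eventId identifier carried into the feature table.
#' @param ... spectral settings passed to [cornerFrequency()].
#' @return One-row data.frame: `eventId`, `fcHz` (corner frequency),
#'   `amplitudeV` (rms of the detrended trapped segment), `laserPowerMw`.
#' @export
extractFeatures <- function(event, eventId = "event", ...) {
  stopifnot(is(event, "TrappingEvent"))
  fc <- cornerFrequency(event, ...)
  r <- detrendVoltage(trappedSamples(event))
  data.frame(eventId = eventId, fcHz = fc,
             amplitudeV = sqrt(mean(r^2)),
             laserPowerMw = laserPower(event))
}

#' Classification rule for egg-white trapping events
#'
#' @param mode `"gate"` (corner-frequency interval at a reference power;
#'   the literal published rule) or `"two_means"` (unsupervised two-means
#'   on standardised corner frequency and fluctuation amplitude).
#' @param gate corner-frequency interval in Hz, valid at `referencePower`.
#' @param referencePower laser power at which the gate applies (mW).
#' @param inGateLabel,outGateLabel labels assigned inside/outside the gate.
#' @return A list of class `ClassificationRule`.
#' @export
classificationRule <- function(mode = c("gate", "two_means"),
                               gate = c(36, 56), referencePower = 9,
                               inGateLabel = "conalbumin",
                               outGateLabel = "ovalbumin-like") {
  mode <- match.arg(mode)
  stopifnot(length(gate) == 2, gate[1] < gate[2], referencePower > 0)
  structure(list(mode = mode, gate = gate,
                 referencePower = referencePower,
                 inGateLabel = inGateLabel, outGateLabel = outGateLabel),
            class = "ClassificationRule")
}

#' Classify trapping events into protein species
#'
#' Gate mode labels an event by whether its corner frequency falls inside
#' the rule's interval; because the corner frequency scales with laser
#' power, every event must sit within 10% of the rule's reference power.
#' Two-means mode clusters the standardised (corner frequency, fluctuation
#' amplitude) pairs into two groups, initialised deterministically at the
#' two points extreme in corner frequency; the higher-frequency cluster
#' receives the in-gate label.
#'
#' @param features data.frame as returned by [extractFeatures()] (columns
#'   `eventId`, `fcHz`, `amplitudeV`, `laserPowerMw`).
#' @param rule a [classificationRule()].
#' @return A list with `labels` (per event, in input order), `counts`
#'   (table per label), and, in two-means mode, `centers` on the original
#'   feature scale.
#' @export
classifyEvents <- function(features, rule = classificationRule()) {
  stopifnot(inherits(rule, "ClassificationRule"),
            all(c("fcHz", "amplitudeV") %in% names(features)))
  fc <- features$fcHz
  if (rule$mode == "gate") {
    pw <- features$laserPowerMw
    if (any(is.na(pw)) ||
        any(abs(pw - rule$referencePower) > 0.1 * rule$referencePower))
      stop("gate mode requires all events within 10% of the reference power")
    labels <- ifelse(fc >= rule$gate[1] & fc <= rule$gate[2],
                     rule$inGateLabel, rule$outGateLabel)
    return(list(labels = labels, counts = table(labels)))
  }
  if (nrow(features) < 2L) stop("two_means mode needs at least 2 events")
  std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
                     else v - mean(v)
  Z <- cbind(std(fc), std(features$amplitudeV))
  init <- Z[c(which.min(fc), which.max(fc)), , drop = FALSE]
  km <- stats::kmeans(Z, centers = init)
  hi <- which.max(tapply(fc, km$cluster, mean))
  labels <- ifelse(km$cluster == hi, rule$inGateLabel, rule$outGateLabel)
  centers <- data.frame(
    label = ifelse(seq_len(2) == hi, rule$inGateLabel, rule$outGateLabel),
    fcHz = tapply(fc, km$cluster, mean),
    amplitudeV = tapply(features$amplitudeV, km$cluster, mean))
  rownames(centers) <- NULL
  list(labels = labels, counts = table(labels), centers = centers)
}
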