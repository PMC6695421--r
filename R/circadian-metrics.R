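# Unwrap daily onset clock times across midnight: whenever the day-to-day
# jump exceeds 12 h in magnitude, shift by 24 h so drifting onsets form a
# continuous line for the regression.
.unwrapOnsets <- function(onset) {
  out <- onset
  for (i in seq_along(out)[-1]) {
    if (is.na(out[i]) || is.na(out[i - 1])) next
    d <- out[i] - out[i - 1]
    out[i] <- out[i] - 24 * round(d / 24)
  }
  out
}

#' Onset error: dispersion of onsets about their linear trend
#'
#' Standard deviation of the residuals from the least-squares line of daily
#' onset time against day index.  Detrending makes the measure invariant to
#' a constant shift and to linear drift (a non-24 h period); onsets are
#' unwrapped across midnight first.
#'
#' @param onsets daily onset clock times (h); NAs allowed.
#' @param days matching day indices (default 1..n).
#' @return residual SD (h); NA with a warning if < 3 valid onsets.
#' @export
onsetError <- function(onsets, days = seq_along(onsets)) {
  ok <- !is.na(onsets)
  if (sum(ok) < 3) {
    warning("fewer than 3 valid onsets: onset error undefined")
    return(NA_real_)
  }
  y <- .unwrapOnsets(onsets[ok])
  d <- days[ok]
  fit <- lm(y ~ d)
  sd(residuals(fit))
}

#' Circadian metrics of an actogram condition window
#'
#' Quantifies the final `windowDays` days of one light condition: total
#' activity (mean daily counts), alpha (mean onset-to-offset length, mod
#' 24 h, over valid days), onset error (residual SD about the linear onset
#' trend) and tau (chi-square periodogram peak over the window).
#'
#' @param acto an [Actogram-class].
#' @param condition condition label to quantify (one of
#'   `unique(acto@condition)`).
#' @param windowDays analysis window at the end of the condition block.
#' @param thresholdFrac onset-detection threshold fraction.
#' @return one-row data.frame: animal, sex, condition, nightLux, tau,
#'   totalActivity, alpha, onsetError, nValidDays.
#' @export
circadianMetrics <- function(acto, condition, windowDays = 10,
                             thresholdFrac = 0.2) {
  nb <- as.integer(1440 / acto@binMinutes)
  condByDay <- acto@condition[seq(1, length(acto@counts), by = nb)]
  luxByDay <- acto@nightLux[seq(1, length(acto@counts), by = nb)]
  days <- which(condByDay == condition)
  if (!length(days)) stop("condition not present in actogram")
  if (length(days) < windowDays)
    stop("condition block shorter than the analysis window")
  days <- tail(days, windowDays)

  phase <- dailyPhaseTable(acto, days, thresholdFrac = thresholdFrac)
  valid <- phase$valid
  alpha <- if (any(valid))
    mean((phase$offset[valid] - phase$onset[valid]) %% 24) else NA_real_
  # onsets remain usable on days whose offset was truncated by record end
  oe <- onsetError(phase$onset, days)

  winIdx <- ((days[1] - 1) * nb + 1):(days[length(days)] * nb)
  total <- sum(acto@counts[winIdx]) / windowDays
  tau <- if (windowDays * 24 >= 7 * 24) {
    pg <- chiSquarePeriodogram(acto@counts[winIdx],
                               binMinutes = acto@binMinutes)
    pg@tau
  } else NA_real_

  data.frame(animal = acto@animal, sex = acto@sex, condition = condition,
             nightLux = luxByDay[days[1]], tau = tau,
             totalActivity = total, alpha = alpha, onsetError = oe,
             nValidDays = sum(valid))
}

#' Metrics table for a cohort of actograms
#'
#' @param actos list of [Actogram-class] objects.
#' @param conditions condition labels (default: all present, in order of
#'   first appearance).
#' @inheritParams circadianMetrics
#' @return data.frame, one row per animal x condition.
#' @export
circadianMetricsTable <- function(actos, conditions = NULL,
                                  windowDays = 10, thresholdFrac = 0.2) {
  if (is.null(conditions))
    conditions <- unique(actos[[1]]@condition)
  rows <- list()
  for (a in actos) for (cond in conditions) {
    rows[[length(rows) + 1L]] <-
      circadianMetrics(a, cond, windowDays, thresholdFrac)
  }
  do.call(rbind, rows)
}
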