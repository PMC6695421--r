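#' Detect daily activity onset and offset
#'
#' Template-free rule: the day's onset is the start of the first run of at
#' least `runMinutes` of bins at or above the activity threshold that is
#' preceded by at least `quietHours` below threshold (the quiet span may
#' extend into the previous day); the offset is the end of the last such
#' qualifying run of the active phase — runs separated by gaps shorter than
#' the quiet span are chained, and the chain may extend past midnight into
#' the next day.  The threshold defaults to 20% of the day's mean nonzero
#' bin count.
#'
#' @param acto an [Actogram-class].
#' @param day day index (1-based, midnight-to-midnight).
#' @param thresholdFrac threshold as a fraction of the day's mean nonzero
#'   bin count.
#' @param runMinutes minimum qualifying run length (min).
#' @param quietHours required preceding quiet span (h).
#' @return one-row data.frame: day, onset (h, clock), offset (h, clock),
#'   valid.
#' @examples
#' cfg <- simConfig(studyDays = 3, conditionLux = c(d = 0.005))
#' a <- simActogram(cfg, noise = "none", jitterSD = 0, alpha = 12)
#' detectOnsetOffset(a, 2)
#' @export
detectOnsetOffset <- function(acto, day, thresholdFrac = 0.2,
                              runMinutes = 30, quietHours = 3) {
  nb <- as.integer(1440 / acto@binMinutes)
  nDays <- length(acto@counts) %/% nb
  if (day < 1 || day > nDays) stop("day out of range")
  binH <- acto@binMinutes / 60
  getDay <- function(d) {
    if (d < 1 || d > nDays) return(rep(0, nb))
    as.numeric(acto@counts[((d - 1) * nb + 1):(d * nb)])
  }
  x <- getDay(day)
  nz <- x[x > 0]
  invalid <- data.frame(day = day, onset = NA_real_, offset = NA_real_,
                        valid = FALSE)
  if (!length(nz)) return(invalid)
  thr <- thresholdFrac * mean(nz)
  runBins <- max(1L, ceiling(runMinutes / acto@binMinutes))
  quietBins <- max(1L, ceiling(quietHours * 60 / acto@binMinutes))

  # context window: previous day | day | next day (absent days are padded
  # with zeros, but onsets/offsets that rely on padded spans are rejected)
  series <- c(getDay(day - 1), x, getDay(day + 1))
  act <- series >= thr
  runStarts <- which(act & !c(FALSE, act[-length(act)]))
  runEnds <- which(act & !c(act[-1], FALSE))
  if (!length(runStarts)) return(invalid)
  runLen <- runEnds - runStarts + 1
  realLo <- if (day > 1) 1L else nb + 1L           # first real series index
  realHi <- if (day < nDays) 3L * nb else 2L * nb  # last real series index

  qualifies <- runLen >= runBins
  precededQuiet <- vapply(seq_along(runStarts), function(ri) {
    lo <- runStarts[ri] - quietBins
    # the quiet span must exist within recorded data, not in padding
    lo >= realLo && all(!act[lo:(runStarts[ri] - 1)])
  }, logical(1))
  cand <- which(qualifies & precededQuiet &
                runStarts > nb & runStarts <= 2 * nb)
  if (!length(cand)) return(invalid)
  oi <- cand[1]
  onset <- (runStarts[oi] - nb - 1) * binH

  # chain runs separated by sub-quiet gaps; offset = end of the last
  # qualifying-length run in the chain
  last <- oi
  ri <- oi
  while (ri < length(runStarts) &&
         runStarts[ri + 1] - runEnds[ri] - 1 < quietBins) {
    ri <- ri + 1
    if (qualifies[ri]) last <- ri
  }
  # offset truncated by the end of recorded data: cannot be confirmed
  if (runEnds[last] >= realHi)
    return(data.frame(day = day, onset = onset, offset = NA_real_,
                      valid = FALSE))
  offset <- ((runEnds[last] - nb) * binH) %% 24
  data.frame(day = day, onset = onset, offset = offset, valid = TRUE)
}

#' Onset/offset table for all days of an actogram
#'
#' @inheritParams detectOnsetOffset
#' @param days day indices (default all complete days).
#' @return data.frame with one row per day.
#' @export
dailyPhaseTable <- function(acto, days = NULL, thresholdFrac = 0.2,
                            runMinutes = 30, quietHours = 3) {
  nb <- as.integer(1440 / acto@binMinutes)
  if (is.null(days)) days <- seq_len(length(acto@counts) %/% nb)
  do.call(rbind, lapply(days, function(d)
    detectOnsetOffset(acto, d, thresholdFrac, runMinutes, quietHours)))
}
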