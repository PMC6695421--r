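#' Time-since-dusk phase of timestamps
#'
#' Maps each timestamp to an angle on \[0, 2 pi): the elapsed fraction of the
#' current dusk-to-dusk span, rotated so the anchor instant (civil dusk +
#' `anchorOffset` hours) maps to pi.  Civil dusk (sun altitude -6 degrees)
#' is computed from the NOAA solar equations at the given coordinates.
#'
#' @param time POSIXct vector (UTC).
#' @param lat,lon geographic coordinates (degrees).
#' @param anchorOffset hours relative to solar dusk that should map to pi
#'   (one of -2..+2 in the model grid; any value accepted).
#' @return list with `theta` (radians in \[0, 2 pi)), `hoursSinceDusk`, and
#'   `duskPrev` (POSIXct of the previous civil dusk).
#' @examples
#' d <- duskTime(as.Date("2012-06-01"), 41.88, 0)
#' computePhase(d, 41.88, 0, anchorOffset = 0)$theta  # pi
#' @export
computePhase <- function(time, lat, lon = 0, anchorOffset = 0) {
  if (!inherits(time, "POSIXct")) stop("time must be POSIXct")
  dates <- as.Date(time, tz = "UTC")
  span <- range(dates)
  allDates <- seq(span[1] - 1, span[2] + 1, by = "day")
  dusk <- duskTime(allDates, lat, lon)
  # index of the dusk preceding (or equal to) each timestamp
  idx <- findInterval(as.numeric(time), as.numeric(dusk))
  if (any(idx < 1 | idx >= length(dusk)))
    stop("timestamp outside the computable dusk table")
  duskPrev <- dusk[idx]
  duskNext <- dusk[idx + 1]
  spanH <- as.numeric(difftime(duskNext, duskPrev, units = "hours"))
  hsd <- as.numeric(difftime(time, duskPrev, units = "hours"))
  thetaRaw <- 2 * pi * hsd / spanH
  thetaAnchor <- 2 * pi * anchorOffset / spanH
  theta <- (thetaRaw - thetaAnchor + pi) %% (2 * pi)
  list(theta = theta, hoursSinceDusk = hsd, duskPrev = duskPrev)
}
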