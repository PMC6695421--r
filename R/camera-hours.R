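# meteorological season (quarter) of POSIXct timestamps
.seasonOf <- function(time) {
  mo <- as.POSIXlt(time, tz = "UTC")$mon + 1
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "fall", "fall", "fall", "winter")[mo]
}

#' Build the camera-hour presence table for one model specification
#'
#' One record per active camera-hour (half-open hours \[h, h+1)); presence
#' is 1 iff at least one detection of any species in the group fell in that
#' hour.  Attaches the time-since-dusk phase at the hour midpoint (rotated
#' by the spec's anchor offset), the light indicator at the spec's (cutoff,
#' buffer), the mean-humans-per-(hour x season) control, day length and its
#' square, moon fraction, and the per-camera land-use/position covariates.
#' Cameras lacking complete covariates are excluded with a message.
#'
#' @param detections data.frame camera, species, timestamp (POSIXct).
#' @param activeHours data.frame camera, hourStart (POSIXct).
#' @param humans data.frame camera, hourStart, count.
#' @param covariates per-camera covariate data.frame (NA rows incomplete).
#' @param siteLux buffer table from [bufferIlluminationTable()] (camera,
#'   radius, meanLux).
#' @param spec list: `species` (group species vector), `cutoff` (lux),
#'   `buffer` (m), `anchorOffset` (h), `order` (harmonic order, carried
#'   along for the fit).
#' @param lat,lon coordinates for solar computations.
#' @return data.frame of camera-hour records with design covariates.
#' @export
buildCameraHourTable <- function(detections, activeHours, humans,
                                 covariates, siteLux, spec,
                                 lat = 41.88, lon = 0) {
  complete <- covariates$camera[complete.cases(covariates)]
  dropped <- setdiff(unique(activeHours$camera), complete)
  if (length(dropped))
    message(length(dropped), " cameras excluded for incomplete covariates")
  rec <- activeHours[activeHours$camera %in% complete, , drop = FALSE]

  # presence: any group detection within the record's hour
  det <- detections[detections$species %in% spec$species &
                    detections$camera %in% complete, , drop = FALSE]
  hourKey <- function(cam, hr)
    paste0(cam, "#", floor(as.numeric(hr) / 3600))
  presKeys <- unique(hourKey(det$camera, det$timestamp))
  rec$presence <- as.integer(hourKey(rec$camera, rec$hourStart) %in% presKeys)

  mid <- rec$hourStart + 1800
  ph <- computePhase(mid, lat, lon, anchorOffset = spec$anchorOffset)
  rec$theta <- ph$theta
  rec$hoursSinceDusk <- ph$hoursSinceDusk

  lx <- siteLux[siteLux$radius == spec$buffer, , drop = FALSE]
  rec$bufferLux <- lx$meanLux[match(rec$camera, lx$camera)]
  if (any(is.na(rec$bufferLux)))
    stop("siteLux table lacks entries at the requested buffer")
  rec$light <- as.integer(rec$bufferLux > spec$cutoff)

  # human-activity control: mean count per (camera, hour-of-day, season)
  hod <- as.POSIXlt(humans$hourStart, tz = "UTC")$hour
  hKey <- paste0(humans$camera, "#", hod, "#", .seasonOf(humans$hourStart))
  hMean <- tapply(humans$count, hKey, mean)
  rKey <- paste0(rec$camera, "#", as.POSIXlt(rec$hourStart, tz = "UTC")$hour,
                 "#", .seasonOf(rec$hourStart))
  rec$humans <- as.numeric(hMean[rKey])
  rec$humans[is.na(rec$humans)] <- 0

  dts <- as.Date(rec$hourStart, tz = "UTC")
  uD <- sort(unique(dts))
  dl <- dayLength(uD, lat)
  rec$dayLength <- dl[match(dts, uD)]
  rec$dayLength2 <- rec$dayLength^2
  rec$moon <- moonFraction(mid)

  rec <- merge(rec, covariates, by = "camera", sort = FALSE)
  rec <- rec[order(rec$camera, rec$hourStart), ]
  rownames(rec) <- NULL
  attr(rec, "spec") <- spec
  rec
}
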