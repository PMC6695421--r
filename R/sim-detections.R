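# von Mises density (numerically stable for large kappa)
.vmDensity <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# mean of the true lux surface within `radius` m of (x, y)
.bufferTrueLux <- function(truth, x, y, radius) {
  cc <- cellCenters(truth)
  v <- as.vector(t(gridValues(truth)))   # row-major to match cellCenters
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    sel <- (cc$x - x[i])^2 + (cc$y - y[i])^2 <= radius^2
    out[i] <- mean(v[sel])
  }
  out
}

#' Generate synthetic camera-trap detections and covariates
#'
#' Cameras are placed uniformly over the domain; each camera's generating
#' light class is defined by the mean of the *true* lux surface within the
#' configured buffer (default 1 km, cutoff 6 lux).  Detections arrive as a
#' thinned Poisson process per active camera-hour with rate
#' abundance x group circular activity density at the hour's time-since-dusk
#' phase; at light sites the density's concentration and peak phase shift
#' per the group spec.  Human observations and per-camera land-use/land-cover
#' covariates are emitted alongside; a configurable fraction of cameras has
#' incomplete covariates.
#'
#' @param config a [simConfig()] list.
#' @param lightscape output of [simLightscape()] (for the true lux surface).
#' @return list with `detections` (camera, species, timestamp),
#'   `cameras` (locations, true buffer lux, light class, abundance),
#'   `activeHours` (camera, hourStart), `humans` (camera, hourStart, count)
#'   and `covariates` (one row per camera; NA rows are incomplete).
#' @export
simDetections <- function(config, lightscape) {
  validateSimConfig(config)
  if (length(config$speciesGroups) == 0) stop("species groups must be configured")
  if (config$nCameras < 1) stop("at least one camera must be configured")
  set.seed(substreamSeed(config$seed, "detections"))

  m <- config$cameraMargin
  cams <- data.frame(
    camera = sprintf("C%03d", seq_len(config$nCameras)),
    x = runif(config$nCameras, m, config$domainWidth - m),
    y = runif(config$nCameras, m, config$domainHeight - m))
  cams$bufferLuxTrue <- .bufferTrueLux(lightscape$truth, cams$x, cams$y,
                                       config$bufferTrue)
  cams$lightTrue <- cams$bufferLuxTrue > config$lightCutoffTrue
  cams$abundance <- rlnorm(config$nCameras, config$abundanceMeanLog,
                           config$abundanceSdLog)

  # deployment schedule: quarterly, `deploymentDays` days each
  starts <- as.POSIXct(character(0), tz = "UTC")
  for (yr in seq_len(config$studyYears)) {
    for (q in seq_len(config$deploymentsPerYear)) {
      mo <- c("01-05", "04-05", "07-05", "10-05")[((q - 1) %% 4) + 1]
      starts <- c(starts, as.POSIXct(
        sprintf("%d-%s 00:00:00", 2011 + yr, mo), tz = "UTC"))
    }
  }
  hourOffsets <- unlist(lapply(starts, function(s)
    as.numeric(s) + 3600 * (seq_len(config$deploymentDays * 24) - 1)))
  hours <- as.POSIXct(hourOffsets, origin = "1970-01-01", tz = "UTC")

  active <- expand.grid(camera = cams$camera, hourStart = hours,
                        stringsAsFactors = FALSE)
  if (config$dutyCycle < 1)
    active <- active[runif(nrow(active)) < config$dutyCycle, ]
  active <- active[order(active$camera, active$hourStart), ]
  rownames(active) <- NULL

  # phase at each hour midpoint (anchor 0: dusk itself maps to pi)
  uh <- sort(unique(active$hourStart))
  midTheta <- computePhase(uh + 1800, config$lat, config$lon,
                           anchorOffset = 0)$theta
  theta <- midTheta[match(as.numeric(active$hourStart), as.numeric(uh))]

  camIdx <- match(active$camera, cams$camera)
  det <- vector("list", length(config$speciesGroups))
  for (gi in seq_along(config$speciesGroups)) {
    g <- config$speciesGroups[[gi]]
    mu <- ifelse(cams$lightTrue[camIdx], g$mu + g$phaseShiftLight, g$mu)
    kap <- ifelse(cams$lightTrue[camIdx], g$kappaLight, g$kappaDark)
    dens <- .vmDensity(theta, mu, kap)
    rate <- cams$abundance[camIdx] * g$abundanceMult * dens * 2 * pi / 24
    nDet <- rpois(length(rate), rate)
    tot <- sum(nDet)
    if (tot == 0) next
    rows <- rep(seq_along(nDet), nDet)
    det[[gi]] <- data.frame(
      camera = active$camera[rows],
      species = sample(g$species, tot, replace = TRUE),
      timestamp = active$hourStart[rows] + runif(tot, 0, 3600))
  }
  detections <- do.call(rbind, det)
  if (is.null(detections))
    detections <- data.frame(camera = character(0), species = character(0),
                             timestamp = as.POSIXct(character(0), tz = "UTC"))
  detections <- detections[order(detections$camera, detections$timestamp), ]
  rownames(detections) <- NULL

  # human observations: diurnal profile scaled by local illumination
  hourOfDay <- as.POSIXlt(active$hourStart, tz = "UTC")$hour
  humanProfile <- .vmDensity(2 * pi * (hourOfDay + 0.5) / 24, mu = pi, 2)
  humanRate <- exp(0.2 + 0.35 * log1p(cams$bufferLuxTrue[camIdx])) *
    humanProfile * 2 * pi / 24 * 12
  humans <- data.frame(camera = active$camera, hourStart = active$hourStart,
                       count = rpois(length(humanRate), humanRate))

  # per-camera covariates (km^2 extents within 1 km, plus position terms)
  areaTot <- pi * 1^2
  luxz <- scale(log1p(cams$bufferLuxTrue))[, 1]
  prop <- function(base, slope) {
    p <- exp(base + slope * luxz + rnorm(config$nCameras, 0, 0.3))
    p / (1 + p)
  }
  covars <- data.frame(
    camera = cams$camera,
    residential = areaTot * prop(-0.8, 0.3),
    denseResidential = areaTot * prop(-2, 0.8),
    commercial = areaTot * prop(-2.2, 0.9),
    industrial = areaTot * prop(-2.5, 0.4),
    treeCover = areaTot * prop(-0.9, -0.6),
    grassCover = areaTot * prop(-1.2, -0.4),
    pavedCover = areaTot * prop(-1.1, 0.8),
    lnDistCenter = log(sqrt((cams$x - config$domainWidth / 2)^2 +
                            (cams$y - config$domainHeight / 2)^2) + 50))
  nIncomplete <- round(config$incompleteCovariateFraction * config$nCameras)
  if (nIncomplete > 0) {
    drop <- sample(config$nCameras, nIncomplete)
    covars$residential[drop] <- NA_real_
  }

  list(detections = detections, cameras = cams, activeHours = active,
       humans = humans, covariates = covars)
}
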