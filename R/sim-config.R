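#' Configuration for the synthetic urban-lightscape study
#'
#' Collects every tunable of the synthetic data generators in one validated
#' list.  Defaults reproduce the study conditions the pipeline is designed
#' around: a mid-latitude city block of a few kilometers, 998 ground control
#' points, 83 cameras deployed 4 times a year for 28 days, a 12:12
#' light/dark laboratory schedule with 6-min activity bins, and nocturnal /
#' diurnal species groups whose circular activity shifts at illuminated
#' sites.
#'
#' @param seed integer master seed; every generator derives its own
#'   substream from it, so outputs are reproducible module by module.
#' @param domainWidth,domainHeight extent of the study domain (m).
#' @param fineCell resolution (m) of the ground-truth lux surface.
#' @param imageCell resolution (m) of the synthetic nighttime image bands.
#' @param rasterCell resolution (m) of the estimated illumination raster.
#' @param landCell resolution (m) of the land-cover raster.
#' @param nControlPoints ground illumination control points.
#' @param nSources number of point light sources.
#' @param sourceD0 decay half-distance d0 (m): lux = I / (1 + (d/d0)^2).
#' @param sourceIntensityMeanLog,sourceIntensitySdLog log-normal parameters
#'   of source intensities (lux at the source).
#' @param cbdBoost,cbdScale intensity multiplier 1 + cbdBoost *
#'   exp(-d/cbdScale) toward a bright central-business-district corner at
#'   (3/4 width, 3/4 height); cbdScale defaults to domainWidth / 4.  Gives
#'   the lightscape the km-scale bright-core / dark-periphery structure of
#'   a city, so 1-km buffer means genuinely separate light and dark sites.
#' @param ambientLux ambient illuminance away from all sources.
#' @param controlNoiseSdLog multiplicative (log-normal) measurement noise of
#'   the lux meter.
#' @param luxFloor instrument floor (lux).
#' @param psfSigma point-spread blur (m) applied to the image bands.
#' @param bandNoiseSd additive digital-number noise per band.
#' @param bandGains,bandOffsets per-band gain/offset of the log-like
#'   DN = gain * ln(1 + lux) + offset transform.
#' @param nCameras camera traps.
#' @param cameraMargin minimum distance (m) from camera to domain edge.
#' @param deploymentsPerYear,deploymentDays,dutyCycle camera schedule.
#' @param studyYears years of camera data.
#' @param lat,lon geographic anchor of the domain (solar computations).
#' @param lightCutoffTrue lux threshold defining the generating light/dark
#'   site classes (true 1-km buffer mean of the lux surface).
#' @param bufferTrue radius (m) of that generating buffer.
#' @param speciesGroups list of group specs; see Details.
#' @param abundanceMeanLog,abundanceSdLog log-normal per-camera abundance
#'   (expected group detections per day; each group spec can scale it via
#'   its `abundanceMult`).
#' @param incompleteCovariateFraction fraction of cameras with missing
#'   land-use covariates (excluded from occurrence modeling downstream).
#' @param studyDays days of actogram recording per light condition.
#' @param actogramBinMinutes actogram bin width (min).
#' @param nAnimalsM,nAnimalsF male/female animals.
#' @param conditionLux nighttime lux of the successive 4-week conditions.
#' @param dayLux daytime illuminance of the LD cycle (lux).
#' @param lightsOffHour clock hour at which the dark phase starts.
#' @param meanCountsPerBin expected wheel counts per active bin in darkness.
#' @param basePeriod endogenous/entrained period (h).
#' @param alphaDark active-phase length (h) under dark nights.
#' @param alphaFloor asymptotic active-phase length (h) under bright nights.
#' @param alphaLuxScale e-folding lux of the alpha compression.
#' @param jitterDark,jitterBright onset jitter SD (h) at 0 lux and at the
#'   brightest condition (linear in lux in between).
#' @param suppressionPerLux total-activity suppression s: counts scale by
#'   exp(-s * lux).
#' @param greenFraction target greenspace fraction of the landscape.
#' @param nBuildings building footprints.
#' @param nNeighborhoodsX,nNeighborhoodsY neighborhood partition grid.
#'
#' @details A species group spec is a list with elements `name`, `species`
#' (character vector), `mu` (peak phase, radians since dusk), `kappaDark`,
#' `kappaLight` (von Mises concentration at dark/light sites) and
#' `phaseShiftLight` (radians added to `mu` at light sites).  The defaults
#' give nocturnal animals a sharper, slightly delayed activity peak at
#' illuminated sites (about 20% lower activity level) and diurnal animals
#' the opposite, milder response.
#'
#' @return a validated list of class "simConfig".
#' @export
simConfig <- function(seed = 1L,
                      domainWidth = 3000, domainHeight = 3000,
                      fineCell = 5, imageCell = 15, rasterCell = 30,
                      landCell = 3,
                      nControlPoints = 998,
                      nSources = 45, sourceD0 = 30,
                      sourceIntensityMeanLog = log(7),
                      sourceIntensitySdLog = 1.1,
                      cbdBoost = 18, cbdScale = NULL,
                      ambientLux = 0.1,
                      controlNoiseSdLog = 0.15, luxFloor = 0.01,
                      psfSigma = 20, bandNoiseSd = 0.05,
                      bandGains = c(1, 0.8), bandOffsets = c(0, 0.1),
                      nCameras = 83, cameraMargin = 150,
                      deploymentsPerYear = 4, deploymentDays = 28,
                      dutyCycle = 1,
                      studyYears = 1,
                      lat = 41.88, lon = 0,
                      lightCutoffTrue = 6, bufferTrue = 1000,
                      speciesGroups = defaultSpeciesGroups(),
                      abundanceMeanLog = log(4), abundanceSdLog = 0.6,
                      incompleteCovariateFraction = 21 / 83,
                      studyDays = 28, actogramBinMinutes = 6,
                      nAnimalsM = 8, nAnimalsF = 7,
                      conditionLux = c(dark1 = 0.005, lux6 = 6, lux20 = 20,
                                       lux32 = 32, dark2 = 0.005),
                      dayLux = 1800, lightsOffHour = 18,
                      meanCountsPerBin = 20,
                      basePeriod = 24, alphaDark = 12.24,
                      alphaFloor = 9.1, alphaLuxScale = 1.5,
                      jitterDark = 0.22, jitterBright = 0.72,
                      suppressionPerLux = 0.012,
                      greenFraction = 0.4, nBuildings = 350,
                      nNeighborhoodsX = 5, nNeighborhoodsY = 5) {
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

#' Default nocturnal and diurnal species groups
#'
#' Species pooling follows the camera-trap analysis conventions for urban
#' mid-western mammals: nocturnal = cat, coyote, opossum, raccoon, rat,
#' skunk; diurnal = dog, fox squirrel, gray squirrel.
#'
#' @return list of two group specs.
#' @export
defaultSpeciesGroups <- function() {
  list(
    nocturnal = list(
      name = "nocturnal",
      species = c("cat", "coyote", "opossum", "raccoon", "rat", "skunk"),
      mu = pi, kappaDark = 1.2, kappaLight = 1.62,
      phaseShiftLight = 2 * pi / 24, abundanceMult = 1),
    diurnal = list(
      name = "diurnal",
      species = c("dog", "fox_squirrel", "gray_squirrel"),
      mu = 0.25 * pi + pi, kappaDark = 1.32, kappaLight = 1.2,
      phaseShiftLight = 0, abundanceMult = 3))
}

#' @rdname simConfig
#' @param cfg a simConfig list.
#' @export
validateSimConfig <- function(cfg) {
  stopifnot(
    is.numeric(cfg$seed), length(cfg$seed) == 1, cfg$seed == round(cfg$seed),
    cfg$domainWidth > 0, cfg$domainHeight > 0,
    cfg$fineCell > 0, cfg$imageCell > 0, cfg$rasterCell > 0, cfg$landCell > 0,
    cfg$domainWidth %% cfg$rasterCell == 0,
    cfg$domainHeight %% cfg$rasterCell == 0,
    cfg$imageCell %% cfg$fineCell == 0,
    cfg$nControlPoints >= 0, cfg$nCameras >= 0,
    cfg$ambientLux >= 0, cfg$luxFloor > 0,
    1440 %% cfg$actogramBinMinutes == 0,
    cfg$alphaDark < cfg$basePeriod, cfg$alphaDark > 0,
    cfg$greenFraction > 0, cfg$greenFraction < 1,
    length(cfg$bandGains) == length(cfg$bandOffsets),
    length(cfg$bandGains) >= 1)
  invisible(TRUE)
}

#' Deterministic per-generator substream seed
#'
#' Splits the master seed into independent, reproducible substreams, one per
#' generator, so regenerating one module never perturbs another.
#'
#' @param seed master integer seed.
#' @param id generator name.
#' @return integer seed < 2^31.
#' @export
substreamSeed <- function(seed, id) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)) * 131)
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}
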