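#' True lux at points of a synthetic lightscape
#'
#' Evaluates the generating illuminance field: ambient plus, for every point
#' source, I / (1 + (d / d0)^2) — bounded at the source, inverse-square in
#' the far field.
#'
#' @param sources data.frame with columns x, y, intensity, d0.
#' @param ambient ambient lux.
#' @param x,y point coordinates (m).
#' @return vector of true illuminance (lux).
#' @export
trueLuxAt <- function(sources, ambient, x, y) {
  lux <- rep(ambient, length(x))
  for (k in seq_len(nrow(sources))) {
    d2 <- (x - sources$x[k])^2 + (y - sources$y[k])^2
    lux <- lux + sources$intensity[k] / (1 + d2 / sources$d0[k]^2)
  }
  lux
}

#' Generate a synthetic urban lightscape
#'
#' Produces a ground-truth illuminance surface, blurred and noisy nighttime
#' image bands (a monotone log-like transform of the surface, convolved with
#' a Gaussian point-spread kernel, resampled to the image resolution), and
#' ground control points that sample the true surface with multiplicative
#' measurement noise clipped to the instrument floor.
#'
#' @param config a [simConfig()] list.
#' @return list with elements `truth` (fine [GridLayer-class] of lux),
#'   `bands` (list of GridLayer digital-number bands), `controlPoints`
#'   (data.frame x, y, lux, luxTrue), `sources` and `ambient`.
#' @examples
#' ls <- simLightscape(simConfig(seed = 7, domainWidth = 600,
#'   domainHeight = 600, nControlPoints = 50, nSources = 5))
#' head(ls$controlPoints)
#' @export
simLightscape <- function(config) {
  validateSimConfig(config)
  if (config$nControlPoints < 1)
    stop("at least one control point must be requested")
  if (length(config$bandGains) < 1) stop("at least one band must be configured")
  set.seed(substreamSeed(config$seed, "lightscape"))

  sources <- data.frame(
    x = runif(config$nSources, 0, config$domainWidth),
    y = runif(config$nSources, 0, config$domainHeight),
    intensity = rlnorm(config$nSources, config$sourceIntensityMeanLog,
                       config$sourceIntensitySdLog),
    d0 = rep(config$sourceD0, config$nSources))
  # bright-core gradient toward the CBD corner
  cbdScale <- if (is.null(config$cbdScale)) config$domainWidth / 4
              else config$cbdScale
  cbd <- c(0.75 * config$domainWidth, 0.75 * config$domainHeight)
  dCbd <- sqrt((sources$x - cbd[1])^2 + (sources$y - cbd[2])^2)
  sources$intensity <- sources$intensity *
    (1 + config$cbdBoost * exp(-dCbd / cbdScale))

  nx <- config$domainWidth / config$fineCell
  ny <- config$domainHeight / config$fineCell
  xs <- (seq_len(nx) - 0.5) * config$fineCell
  ys <- (ny - seq_len(ny) + 0.5) * config$fineCell   # row 1 = north
  luxMat <- matrix(config$ambientLux, ny, nx)
  for (k in seq_len(nrow(sources))) {
    dx2 <- (xs - sources$x[k])^2
    dy2 <- (ys - sources$y[k])^2
    luxMat <- luxMat + sources$intensity[k] /
      (1 + outer(dy2, dx2, `+`) / sources$d0[k]^2)
  }
  truth <- gridLayer(luxMat, 0, 0, config$fineCell)

  fac <- config$imageCell / config$fineCell
  sigmaCells <- config$psfSigma / config$fineCell
  bands <- vector("list", length(config$bandGains))
  for (b in seq_along(bands)) {
    dn <- config$bandGains[b] * log1p(luxMat) + config$bandOffsets[b]
    dn <- .gaussBlur(dn, sigmaCells)
    coarse <- aggregateGrid(gridLayer(dn, 0, 0, config$fineCell), fac)
    v <- gridValues(coarse)
    v <- v + matrix(rnorm(length(v), 0, config$bandNoiseSd), nrow(v), ncol(v))
    bands[[b]] <- gridLayer(v, 0, 0, config$imageCell)
  }
  names(bands) <- paste0("band", seq_along(bands))

  margin <- 25  # keep 20-m feature discs inside the image extent
  cp <- data.frame(
    x = runif(config$nControlPoints, margin, config$domainWidth - margin),
    y = runif(config$nControlPoints, margin, config$domainHeight - margin))
  cp$luxTrue <- trueLuxAt(sources, config$ambientLux, cp$x, cp$y)
  cp$lux <- pmax(cp$luxTrue *
                   exp(rnorm(nrow(cp), 0, config$controlNoiseSdLog)),
                 config$luxFloor)

  list(truth = truth, bands = bands, controlPoints = cp,
       sources = sources, ambient = config$ambientLux)
}
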