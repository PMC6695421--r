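#' @import methods
#' @importFrom stats approx coef dchisq glm lm logLik median optimize pchisq
#'   predict qchisq quantile rbinom rlnorm rnorm rpois runif sd var anova
#'   as.formula binomial ks.test setNames aggregate complete.cases BIC
#'   residuals vcov relevel qnorm na.omit model.matrix
#' @importFrom utils head read.csv write.csv tail write.table read.table
#' @rawNamespace exportMethods(show, dim)
NULL

#' GridLayer: a georeferenced regular grid
#'
#' A minimal north-up raster container: a numeric (or integer/logical) matrix
#' with an affine placement in a projected coordinate system measured in
#' meters.  Row 1 is the northern-most row; column 1 the western-most column.
#' Cell (i, j) covers the half-open square
#' \eqn{[xmin + (j-1)c, xmin + jc) \times [ymin + (n_{row}-i)c, ymin + (n_{row}-i+1)c)}
#' where c is the cell size.
#'
#' @slot values matrix of cell values (NA = masked / no data).
#' @slot xmin x coordinate (m) of the western edge.
#' @slot ymin y coordinate (m) of the southern edge.
#' @slot cellsize cell edge length in meters (> 0).
#' @exportClass GridLayer
setClass("GridLayer",
  representation(values = "matrix", xmin = "numeric", ymin = "numeric",
                 cellsize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
        object@cellsize <= 0)
      msg <- c(msg, "cellsize must be a single positive finite number")
    if (length(object@xmin) != 1L || !is.finite(object@xmin))
      msg <- c(msg, "xmin must be a single finite number")
    if (length(object@ymin) != 1L || !is.finite(object@ymin))
      msg <- c(msg, "ymin must be a single finite number")
    if (length(msg)) msg else TRUE
  })

#' Actogram: binned wheel-running activity for one animal
#'
#' Counts of wheel revolutions in contiguous fixed-width time bins, together
#' with the nighttime illuminance (lux) of the light condition each bin
#' belongs to and a condition label per bin.  The recording starts at local
#' midnight of day 1; the light schedule is 12 h light / 12 h dark.
#'
#' @slot animal animal identifier.
#' @slot sex "M", "F" or NA.
#' @slot binMinutes bin width in minutes; must divide 1440.
#' @slot counts non-negative integer counts per bin.
#' @slot nightLux nighttime illuminance (lux) of the condition of each bin.
#' @slot condition condition label per bin (e.g. "dark1", "lux6").
#' @slot lightsOffHour local clock hour at which the dark phase begins.
#' @exportClass Actogram
setClass("Actogram",
  representation(animal = "character", sex = "character",
                 binMinutes = "numeric", counts = "integer",
                 nightLux = "numeric", condition = "character",
                 lightsOffHour = "numeric"),
  validity = function(object) {
    msg <- character()
    if (1440 %% object@binMinutes != 0)
      msg <- c(msg, "binMinutes must divide 1440")
    if (any(object@counts < 0L, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
    n <- length(object@counts)
    if (length(object@nightLux) != n || length(object@condition) != n)
      msg <- c(msg, "counts, nightLux and condition must have equal length")
    if (length(msg)) msg else TRUE
  })

#' IlluminationMixture: univariate Gaussian mixture over illuminance
#'
#' The result of EM fitting over a range of component counts K with BIC
#' model selection, optionally on log-transformed lux (ln(lux + 0.01)).
#'
#' @slot K number of components of the selected model.
#' @slot weights mixing weights (sum to 1).
#' @slot means component means on the fitting scale.
#' @slot variances component variances on the fitting scale (> 0).
#' @slot logLik maximized log-likelihood.
#' @slot BIC -2 logLik + p ln(n) of the selected model.
#' @slot responsibilities n x K posterior membership matrix (rows sum to 1).
#' @slot transform "log" or "identity": scale the mixture was fitted on.
#' @slot equalVariance TRUE if the selected model ties variances.
#' @slot data the raw lux values the model was fitted to.
#' @slot bicTable BIC per candidate (K, family) examined.
#' @exportClass IlluminationMixture
setClass("IlluminationMixture",
  representation(K = "integer", weights = "numeric", means = "numeric",
                 variances = "numeric", logLik = "numeric", BIC = "numeric",
                 responsibilities = "matrix", transform = "character",
                 equalVariance = "logical", data = "numeric",
                 bicTable = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1")
    if (any(object@variances <= 0))
      msg <- c(msg, "variances must be positive")
    if (nrow(object@responsibilities) > 0) {
      rs <- rowSums(object@responsibilities)
      if (max(abs(rs - 1)) > 1e-6)
        msg <- c(msg, "responsibility rows must sum to 1")
    }
    if (length(msg)) msg else TRUE
  })

#' PeriodogramResult: chi-square periodogram of an actogram
#'
#' @slot periods candidate periods (h).
#' @slot Qp periodogram statistic per candidate period.
#' @slot df degrees of freedom (bins per period - 1) per candidate.
#' @slot threshold chi-square 0.99 quantile per candidate.
#' @slot tau peak significant period (h); NA if none significant.
#' @slot significant TRUE if any candidate exceeds its threshold.
#' @exportClass PeriodogramResult
setClass("PeriodogramResult",
  representation(periods = "numeric", Qp = "numeric", df = "numeric",
                 threshold = "numeric", tau = "numeric",
                 significant = "logical"),
  validity = function(object) {
    msg <- character()
    if (any(object@Qp < 0, na.rm = TRUE)) msg <- c(msg, "Qp must be >= 0")
    if (!is.na(object@tau) &&
        (object@tau < min(object@periods) || object@tau > max(object@periods)))
      msg <- c(msg, "tau must lie in the scanned period range")
    if (length(msg)) msg else TRUE
  })

#' CircularDensity: von Mises kernel density on the 24 h circle
#'
#' @slot grid evaluation angles in [0, 2*pi).
#' @slot density estimated density at the grid angles (integrates to 1).
#' @slot kappa kernel concentration used.
#' @slot n number of observations the density was fitted to.
#' @slot times the observation angles (radians).
#' @exportClass CircularDensity
setClass("CircularDensity",
  representation(grid = "numeric", density = "numeric", kappa = "numeric",
                 n = "integer", times = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
    if (length(object@grid) != length(object@density))
      msg <- c(msg, "grid and density lengths differ")
    if (length(object@grid) > 8) {
      integral <- mean(object@density) * 2 * pi
      if (abs(integral - 1) > 1e-6)
        msg <- c(msg, "density must integrate to 1 over the circle")
    }
    if (length(msg)) msg else TRUE
  })

#' ActivityLevel: proportion of time active, from a circular density
#'
#' act = 1 / (2 * pi * max density); 1 for uniform (always active), smaller
#' for concentrated activity.
#'
#' @slot act point estimate in (0, 1] (up to numerical tolerance).
#' @slot se bootstrap standard error.
#' @slot n sample size.
#' @slot boot bootstrap replicate estimates.
#' @exportClass ActivityLevel
setClass("ActivityLevel",
  representation(act = "numeric", se = "numeric", n = "integer",
                 boot = "numeric"),
  validity = function(object) {
    if (object@act <= 0 || object@act > 1 + 1e-6)
      "act must lie in (0, 1]" else TRUE
  })

#' PatchSet: labeled connected components of a binary raster
#'
#' @slot labels integer matrix; 0 = background, k = patch k.
#' @slot cellsize cell edge length (m).
#' @slot connectivity 4 or 8.
#' @slot cells cells per patch (patch k at index k).
#' @exportClass PatchSet
setClass("PatchSet",
  representation(labels = "matrix", cellsize = "numeric",
                 connectivity = "numeric", cells = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@connectivity %in% c(4, 8))
      msg <- c(msg, "connectivity must be 4 or 8")
    if (length(object@cells) &&
        sum(object@cells) != sum(object@labels > 0))
      msg <- c(msg, "patch cell counts must sum to the labeled area")
    if (length(msg)) msg else TRUE
  })
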