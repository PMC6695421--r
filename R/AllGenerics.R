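#' @describeIn GridLayer cell values as a matrix
#' @param x a GridLayer (or other object with values)
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @describeIn GridLayer cell edge length in meters
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @describeIn GridLayer extent as c(xmin, xmax, ymin, ymax)
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' Number of mixture components
#' @param x a fitted model object
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Estimated circadian period (hours)
#' @param x a PeriodogramResult
#' @export
setGeneric("tauHat", function(x) standardGeneric("tauHat"))

#' Activity-level point estimate
#' @param x an ActivityLevel
#' @export
setGeneric("activityEstimate", function(x) standardGeneric("activityEstimate"))

#' Number of patches
#' @param x a PatchSet
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' Per-patch areas in square meters
#' @param x a PatchSet
#' @export
setGeneric("patchAreas", function(x) standardGeneric("patchAreas"))
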