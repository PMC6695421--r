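#' Mean illuminance of control points within a radius of each control point
#'
#' The regression outcome is the natural log of the mean measured
#' illuminance within 20 m of each control point, plus 1; with sparse
#' transect data the 20-m mean usually reduces to the point's own reading.
#'
#' @param controlPoints data.frame with x, y, lux.
#' @param radius neighborhood radius (m).
#' @return vector of neighborhood-mean lux per control point.
#' @export
neighborhoodMeanLux <- function(controlPoints, radius = 20) {
  x <- controlPoints$x; y <- controlPoints$y; lux <- controlPoints$lux
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    sel <- (x - x[i])^2 + (y - y[i])^2 <= radius^2
    out[i] <- mean(lux[sel])
  }
  out
}

#' Fit the imagery-to-illuminance ensemble regression
#'
#' Random forest regression of ln(mean lux within 20 m + 1) on the
#' area-weighted image-band features of each control point.  The feature
#' subset size (mtry) is tuned by out-of-bag error on the training split
#' only; a held-out subset provides the cross-validation report: variance
#' explained on held-out points and, for each lux cutoff, the above/below
#' classification accuracy of the back-transformed predictions.
#'
#' @param features feature matrix from [extractImageFeatures()].
#' @param lux measured control-point illuminance (lux).
#' @param holdout number of control points kept for cross-validation
#'   (must be < number of points).
#' @param controlPoints optional data.frame (x, y, lux) from which the 20-m
#'   neighborhood-mean outcome is computed; if NULL, `lux` itself is used.
#' @param cutoffs lux cutoffs for the classification accuracies.
#' @param nTrees random forest size.
#' @param seed seed controlling the holdout split and forest.
#' @return list of class "illuminationModel": `forest`, `cvReport` (list
#'   with varianceExplained and cutoffAccuracy), `holdoutIdx`, `outcome`.
#' @export
fitIlluminationModel <- function(features, lux, holdout = 200,
                                 controlPoints = NULL,
                                 cutoffs = c(1, 3, 6), nTrees = 500,
                                 seed = 1) {
  n <- nrow(features)
  if (holdout >= n) stop("holdout must be smaller than the number of points")
  meanLux <- if (is.null(controlPoints)) lux
             else neighborhoodMeanLux(controlPoints)
  yAll <- log(meanLux + 1)
  set.seed(seed)
  testIdx <- sample(n, holdout)
  trainIdx <- setdiff(seq_len(n), testIdx)
  xTrain <- features[trainIdx, , drop = FALSE]
  yTrain <- yAll[trainIdx]

  constantOutcome <- var(yTrain) < 1e-12
  if (constantOutcome) {
    forest <- NULL
    predTest <- rep(mean(yTrain), length(testIdx))
  } else {
    mtry <- tryCatch({
      tuned <- NULL
      utils::capture.output(
        tuned <- randomForest::tuneRF(xTrain, yTrain, ntreeTry = 100,
                                      stepFactor = 1.5, improve = 0.01,
                                      trace = FALSE, plot = FALSE))
      tuned[which.min(tuned[, 2]), 1]
    }, error = function(e) max(1, floor(ncol(features) / 3)))
    forest <- randomForest::randomForest(xTrain, yTrain, ntree = nTrees,
                                         mtry = mtry)
    predTest <- predict(forest, features[testIdx, , drop = FALSE])
  }

  yTest <- yAll[testIdx]
  sse <- sum((yTest - predTest)^2)
  sst <- sum((yTest - mean(yTest))^2)
  # <= 0 by convention when the outcome is (near-)constant or fit is worse
  varExpl <- if (sst < 1e-12) 0 else 1 - sse / sst
  luxPred <- pmax(exp(predTest) - 1, 0)
  luxObs <- meanLux[testIdx]
  acc <- vapply(cutoffs, function(cut)
    mean((luxPred > cut) == (luxObs > cut)), numeric(1))
  names(acc) <- paste0("lux", cutoffs)

  structure(list(forest = forest, constant = constantOutcome,
                 constantValue = if (constantOutcome) mean(yTrain) else NULL,
                 cvReport = list(varianceExplained = varExpl,
                                 cutoffAccuracy = acc,
                                 nTrain = length(trainIdx),
                                 nHoldout = holdout),
                 holdoutIdx = testIdx, outcome = yAll),
            class = "illuminationModel")
}

#' @export
print.illuminationModel <- function(x, ...) {
  cat(sprintf("illuminationModel: %d train / %d holdout\n",
              x$cvReport$nTrain, x$cvReport$nHoldout))
  cat(sprintf("  held-out variance explained: %.3f\n",
              x$cvReport$varianceExplained))
  cat("  cutoff accuracy:",
      paste(sprintf("%s %.2f", names(x$cvReport$cutoffAccuracy),
                    x$cvReport$cutoffAccuracy), collapse = ", "), "\n")
  invisible(x)
}

#' Predict illuminance at points with a fitted imagery model
#'
#' @param model an "illuminationModel".
#' @param features feature matrix matching the fitted feature definition.
#' @return predicted illuminance (lux), back-transformed as exp(yhat) - 1
#'   and floored at 0.
#' @export
predictIlluminationPoints <- function(model, features) {
  yhat <- if (model$constant) rep(model$constantValue, nrow(features))
          else predict(model$forest, features)
  pmax(exp(yhat) - 1, 0)
}

#' Rasterize model predictions to an illumination grid
#'
#' Predicts illuminance at a dense cloud of points (uniform random points
#' plus an even grid, mirroring dense point-wise prediction followed by
#' cell averaging) and averages the back-transformed predictions within
#' each raster cell (half-open cell intervals, point-in-cell by floor
#' division).  Cells containing no points are masked (NA).
#'
#' @param model an "illuminationModel".
#' @param bands list of [GridLayer-class] image bands.
#' @param nRandom number of uniform random prediction points.
#' @param gridSpacing spacing (m) of the even prediction grid.
#' @param cell output cell size (m), default 30.
#' @param margin inset (m) keeping feature discs inside the band extent.
#' @param radii feature radii matching the fitted model.
#' @param seed seed for the random points.
#' @return an [IlluminationRaster][GridLayer-class] (GridLayer of lux).
#' @export
predictIlluminationRaster <- function(model, bands, nRandom = 100000,
                                      gridSpacing = 25, cell = 30,
                                      margin = 25, radii = c(0, 5, 10, 20),
                                      seed = 1) {
  ext <- gridExtent(bands[[1]])
  set.seed(seed)
  px <- runif(nRandom, ext["xmin"] + margin, ext["xmax"] - margin)
  py <- runif(nRandom, ext["ymin"] + margin, ext["ymax"] - margin)
  gx <- seq(ext["xmin"] + margin, ext["xmax"] - margin, by = gridSpacing)
  gy <- seq(ext["ymin"] + margin, ext["ymax"] - margin, by = gridSpacing)
  px <- c(px, rep(gx, times = length(gy)))
  py <- c(py, rep(gy, each = length(gx)))

  feats <- extractImageFeatures(bands, px, py, radii = radii)
  lux <- predictIlluminationPoints(model, feats)

  nx <- ceiling((ext["xmax"] - ext["xmin"]) / cell)
  ny <- ceiling((ext["ymax"] - ext["ymin"]) / cell)
  jj <- floor((px - ext["xmin"]) / cell) + 1
  ii <- ny - floor((py - ext["ymin"]) / cell)
  ok <- jj >= 1 & jj <= nx & ii >= 1 & ii <= ny
  cellId <- (jj[ok] - 1) * ny + ii[ok]
  sums <- rowsum(lux[ok], cellId)
  counts <- rowsum(rep(1, sum(ok)), cellId)
  m <- matrix(NA_real_, ny, nx)
  m[as.integer(rownames(sums))] <- sums / counts
  gridLayer(m, ext[["xmin"]], ext[["ymin"]], cell)
}
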