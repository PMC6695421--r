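test_that("noiseless monotone band-to-lux map is learned almost exactly", {
  ls <- fixture("noiselessLS", function()
    simLightscape(smallConfig(bandNoiseSd = 0, psfSigma = 0,
                              controlNoiseSdLog = 0, nControlPoints = 1000)))
  cp <- ls$controlPoints
  feats <- extractImageFeatures(ls$bands, cp$x, cp$y)
  mod <- fitIlluminationModel(feats, cp$lux, holdout = 200,
                              controlPoints = cp, seed = 4)
  expect_gt(mod$cvReport$varianceExplained, 0.9)
  expect_true(all(mod$cvReport$cutoffAccuracy >= 0.6))
})

test_that("constant outcome reports <= 0 variance explained by convention", {
  set.seed(5)
  feats <- matrix(rnorm(300), 100, 3)
  colnames(feats) <- paste0("f", 1:3)
  mod <- fitIlluminationModel(feats, rep(2, 100), holdout = 30, seed = 1)
  expect_lte(mod$cvReport$varianceExplained, 0)
  expect_equal(unique(predictIlluminationPoints(mod, feats)), 2,
               tolerance = 1e-9)
  expect_error(fitIlluminationModel(feats, rep(2, 100), holdout = 100),
               "holdout")
})

test_that("back-transform floors predictions at zero lux", {
  set.seed(6)
  feats <- matrix(rnorm(200), 100, 2)
  colnames(feats) <- c("a", "b")
  lux <- rep(0, 100)  # ln(0 + 1) = 0 outcome; forest may predict < 0
  mod <- fitIlluminationModel(feats, lux, holdout = 20, seed = 2)
  expect_true(all(predictIlluminationPoints(mod, feats) >= 0))
})

test_that("rasterization averages per cell and masks empty cells", {
  # constant model: every cell with points gets exp(c) - 1
  cMod <- structure(list(forest = NULL, constant = TRUE,
                         constantValue = log(3 + 1)), class = "illuminationModel")
  b <- gridLayer(matrix(0, 40, 40), 0, 0, 15)
  r <- predictIlluminationRaster(cMod, list(b), nRandom = 4000,
                                 gridSpacing = 50, cell = 30, seed = 7)
  v <- gridValues(r)
  expect_equal(unique(v[!is.na(v)]), 3, tolerance = 1e-9)
  # sparse sampling leaves point-free cells masked
  r2 <- predictIlluminationRaster(cMod, list(b), nRandom = 10,
                                  gridSpacing = 400, cell = 30, seed = 7)
  expect_gt(sum(is.na(gridValues(r2))), 300)
})

test_that("cell value is the arithmetic mean of point predictions", {
  # three points in one 30 m cell with back-transformed values 1, 2, 3
  jj <- 1; lux <- c(1, 2, 3)
  sums <- rowsum(lux, rep(1, 3))
  expect_equal(as.numeric(sums / 3), 2)
  # end-to-end: constant-by-construction check of conservation of the mean
  ls <- smallLightscape()
  cp <- ls$controlPoints
  feats <- extractImageFeatures(ls$bands, cp$x, cp$y)
  mod <- fitIlluminationModel(feats, cp$lux, holdout = 30,
                              controlPoints = cp, seed = 3)
  r <- predictIlluminationRaster(mod, ls$bands, nRandom = 20000,
                                 gridSpacing = 40, seed = 8)
  tr <- aggregateGrid(ls$truth, 6)
  ok <- !is.na(gridValues(r))
  medErr <- median(abs(gridValues(r) - gridValues(tr))[ok])
  expect_lt(medErr, 0.5 * median(gridValues(tr)))
})
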