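test_that("generators are pure functions of config and seed", {
  cfg <- smallConfig()
  a <- simLightscape(cfg); b <- simLightscape(cfg)
  expect_identical(a$controlPoints, b$controlPoints)
  expect_identical(gridValues(a$truth), gridValues(b$truth))
  l1 <- simLandscape(cfg); l2 <- simLandscape(cfg)
  expect_identical(gridValues(l1$landCover), gridValues(l2$landCover))
  act1 <- simActogram(cfg, animal = "x")
  act2 <- simActogram(cfg, animal = "x")
  expect_identical(act1@counts, act2@counts)
})

test_that("noiseless square-wave actogram has identical daily onsets", {
  cfg <- smallConfig(studyDays = 10, conditionLux = c(dark = 0.005))
  a <- simActogram(cfg, noise = "none", jitterSD = 0, suppression = 0,
                   period = 24, alpha = 12)
  nb <- 1440 / cfg$actogramBinMinutes
  days <- matrix(a@counts, nrow = nb)
  for (d in 2:10) expect_identical(days[, d], days[, 1])
  expect_error(simActogram(cfg, alpha = 25, period = 24), "alpha")
})

test_that("daily totals follow the Poisson count model of the generator", {
  cfg <- smallConfig(studyDays = 10, conditionLux = c(dark = 0.005),
                     actogramBinMinutes = 6)
  a <- simActogram(cfg, alpha = 9, meanCounts = 20, jitterSD = 0,
                   suppression = 0)
  # alpha = 9 h of 6-min bins: 90 active bins/day at mean 20 -> 1800/day
  nDays <- 10
  total <- sum(a@counts)
  mu <- 20 * 90 * nDays
  expect_lt(abs(total - mu), 3 * sqrt(mu))
})

test_that("raising night lux with positive suppression lowers total counts", {
  cfg <- smallConfig(studyDays = 10)
  dark <- simActogram(cfg, conditionLux = c(dark = 0.005), alpha = 10,
                      suppression = 0.01, jitterSD = 0, seed = 77)
  bright <- simActogram(cfg, conditionLux = c(bright = 32), alpha = 10,
                        suppression = 0.01, jitterSD = 0, seed = 77)
  expect_lt(sum(bright@counts), sum(dark@counts))
})

test_that("one point source follows the configured decay law exactly", {
  src <- data.frame(x = 0, y = 0, intensity = 50, d0 = 30)
  d <- c(0, 10, 30, 100, 500)
  expect_equal(trueLuxAt(src, 0.2, d, rep(0, 5)),
               0.2 + 50 / (1 + (d / 30)^2), tolerance = 1e-12)
})

test_that("control points read ambient (noise only) when no sources exist", {
  cfg <- smallConfig(nSources = 0, ambientLux = 0.3, controlNoiseSdLog = 0.05)
  ls <- simLightscape(cfg)
  expect_equal(ls$controlPoints$luxTrue, rep(0.3, nrow(ls$controlPoints)))
  expect_equal(median(ls$controlPoints$lux), 0.3, tolerance = 0.05)
  expect_true(all(ls$controlPoints$lux >= cfg$luxFloor))
})

test_that("zero abundance yields no detections for a camera", {
  cfg <- smallConfig(abundanceMeanLog = -30)
  ls <- smallLightscape()
  dets <- simDetections(cfg, ls)
  expect_equal(nrow(dets$detections), 0)
})

test_that("detection times follow the configured circular density", {
  # single nocturnal group, no light effect, high abundance
  grp <- list(nocturnal = list(name = "nocturnal", species = "raccoon",
                               mu = pi, kappaDark = 1.5, kappaLight = 1.5,
                               phaseShiftLight = 0, abundanceMult = 1))
  cfg <- smallConfig(speciesGroups = grp, abundanceMeanLog = log(30),
                     abundanceSdLog = 0, deploymentDays = 20)
  ls <- smallLightscape()
  dets <- simDetections(cfg, ls)
  th <- computePhase(dets$detections$timestamp, cfg$lat, cfg$lon, 0)$theta
  # chi-square goodness of fit against the generating von Mises density
  brk <- seq(0, 2 * pi, length.out = 13)
  obs <- table(cut(th, brk))
  dens <- function(t) exp(1.5 * cos(t - pi)) / (2 * pi * besselI(1.5, 0))
  pExp <- vapply(seq_len(12), function(i)
    integrate(dens, brk[i], brk[i + 1])$value, numeric(1))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pExp / sum(pExp)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("a configured light-site phase delay moves the circular mean", {
  grp <- list(nocturnal = list(name = "nocturnal", species = "raccoon",
                               mu = pi, kappaDark = 2, kappaLight = 2,
                               phaseShiftLight = 2 * pi / 24,  # +1 h
                               abundanceMult = 1))
  cfg <- smallConfig(speciesGroups = grp, abundanceMeanLog = log(30),
                     abundanceSdLog = 0, deploymentDays = 20,
                     bufferTrue = 300, lightCutoffTrue = 6)
  ls <- smallLightscape()
  dets <- simDetections(cfg, ls)
  expect_true(any(dets$cameras$lightTrue) && any(!dets$cameras$lightTrue))
  th <- computePhase(dets$detections$timestamp, cfg$lat, cfg$lon, 0)$theta
  isLight <- dets$detections$camera %in%
    dets$cameras$camera[dets$cameras$lightTrue]
  cmean <- function(t) atan2(mean(sin(t)), mean(cos(t)))
  dMean <- (cmean(th[isLight]) - cmean(th[!isLight])) %% (2 * pi)
  dMeanH <- dMean * 24 / (2 * pi)
  expect_equal(dMeanH, 1, tolerance = 0.35)
})

test_that("landscape hits the greenspace target and partitions the domain", {
  cfg <- smallConfig()
  land <- simLandscape(cfg)
  gv <- gridValues(land$landCover)
  green <- mean(gv %in% landCoverClasses()[c("treeCanopy", "grassShrub",
                                             "bareEarth")])
  expect_lt(abs(green - cfg$greenFraction), 0.05)
  expect_setequal(sort(unique(as.vector(gv))), 1:7)
  # neighborhoods tile the domain: every cell center in exactly one polygon
  cc <- cellCenters(aggregateGrid(land$landCover, 20, "mean"))
  counts <- rowSums(vapply(land$neighborhoods, function(p)
    pointInPolygon(cc$x, cc$y, p), logical(nrow(cc))))
  expect_true(all(counts == 1))
  # building polygons coincide with building-class cells
  idx <- cellIndex(land$landCover,
                   (land$buildings$xmin + land$buildings$xmax) / 2,
                   (land$buildings$ymin + land$buildings$ymax) / 2)
  vals <- gridValues(land$landCover)[cbind(idx$row, idx$col)]
  expect_true(all(vals == landCoverClasses()["building"]))
})
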