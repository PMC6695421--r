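test_that("majority resampling follows the strict > 50% rule", {
  cls <- landCoverClasses()
  # 2x2 blocks of 2 source cells green -> exactly half -> FALSE
  src <- matrix(cls["paved"], 4, 4)
  src[1:2, 1] <- cls["treeCanopy"]        # half of the top-left 2x2 block
  src[3:4, 3:4] <- cls["grassShrub"]      # all of the bottom-right block
  lc <- gridLayer(src, 0, 0, 15)
  gs <- resampleGreenspace(lc, 30)
  expect_identical(gridValues(gs),
                   matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
  expect_error(resampleGreenspace(lc, 40), "alignment")
})

test_that("random resampling equals a brute-force counting oracle", {
  set.seed(91)
  src <- matrix(sample(1:7, 30 * 30, replace = TRUE), 30, 30)
  lc <- gridLayer(src, 0, 0, 10)
  gs <- resampleGreenspace(lc, 30)
  for (i in 1:10) for (j in 1:10) {
    block <- src[((i - 1) * 3 + 1):(i * 3), ((j - 1) * 3 + 1):(j * 3)]
    expect_identical(gridValues(gs)[i, j], mean(block %in% 1:3) > 0.5)
  }
})

test_that("illuminated mask respects cutoff extremes and checker patterns", {
  gs <- gridLayer(matrix(TRUE, 4, 4), 0, 0, 30)
  checker <- matrix(ifelse((outer(1:4, 1:4, `+`)) %% 2 == 0, 7, 5), 4, 4)
  lx <- gridLayer(checker, 0, 0, 30)
  hi <- illuminatedMask(gs, lx, cutoff = 100)
  expect_true(!any(gridValues(hi)))
  lo <- illuminatedMask(gs, lx, cutoff = -1)
  expect_identical(gridValues(lo), gridValues(gs))
  six <- illuminatedMask(gs, lx, cutoff = 6)
  expect_identical(gridValues(six), checker == 7)
  # masked illumination counts as not exceeding, and is reported
  lx2 <- lx; lx2@values[1, 1] <- NA
  expect_message(m2 <- illuminatedMask(gs, lx2, cutoff = 6), "masked")
  expect_false(gridValues(m2)[1, 1])
  expect_error(illuminatedMask(gs, gridLayer(matrix(1, 2, 2), 0, 0, 30)),
               "aligned")
})

test_that("patch labeling matches adjacency semantics on a checkerboard", {
  m <- outer(1:6, 1:6, `+`) %% 2 == 0
  p4 <- labelPatches(gridLayer(m, 0, 0, 30), connectivity = 4)
  expect_equal(nPatches(p4), sum(m))
  p8 <- labelPatches(gridLayer(m, 0, 0, 30), connectivity = 8)
  expect_equal(nPatches(p8), 1L)
  full <- labelPatches(gridLayer(matrix(TRUE, 10, 10), 0, 0, 30))
  expect_equal(nPatches(full), 1L)
  expect_equal(patchAreas(full), 90000)
})

test_that("labeling equals an independent flood-fill oracle", {
  set.seed(92)
  for (rep in 1:6) {
    m <- matrix(runif(20 * 20) < 0.45, 20, 20)
    for (conn in c(4, 8)) {
      got <- labelPatches(gridLayer(m, 0, 0, 30), connectivity = conn)
      oracle <- floodFillLabels(m, conn)
      expect_true(sameLabeling(got@labels, oracle))
      expect_equal(sum(got@cells), sum(m))
    }
  }
})

test_that("single 2x2 patch metrics follow perimeter arithmetic", {
  m <- matrix(FALSE, 6, 6); m[3:4, 3:4] <- TRUE
  p <- labelPatches(gridLayer(m, 0, 0, 30))
  met <- landscapeMetrics(p, landscapeArea = 36 * 900)
  expect_equal(met$nPatches, 1)
  expect_equal(met$meanPatchArea, 3600)
  expect_equal(met$totalEdge, 240)
  expect_true(is.na(met$meanNearestNeighbor))
  expect_equal(met$percentLandscape, 4 / 36 * 100)
})

test_that("two cells separated by one empty cell are 30 m apart", {
  m <- matrix(FALSE, 3, 5)
  m[2, 2] <- TRUE; m[2, 4] <- TRUE
  p <- labelPatches(gridLayer(m, 0, 0, 30), connectivity = 4)
  expect_equal(nPatches(p), 2L)
  enn <- nightlux:::.nearestNeighborDistances(p)
  expect_equal(enn, c(30, 30))
})

test_that("metrics equal brute-force recomputation on random masks", {
  set.seed(93)
  for (rep in 1:4) {
    m <- matrix(runif(15 * 15) < 0.4, 15, 15)
    p <- labelPatches(gridLayer(m, 0, 0, 30))
    met <- landscapeMetrics(p, landscapeArea = 225 * 900)
    # brute-force total edge: count exposed faces cell by cell
    edge <- 0
    for (i in 1:15) for (j in 1:15) {
      if (!m[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > 15 || jj < 1 || jj > 15 || !m[ii, jj])
          edge <- edge + 30
      }
    }
    expect_equal(met$totalEdge, edge)
    # brute-force ENN over all cell pairs of different patches
    if (met$nPatches >= 2) {
      idx <- which(m, arr.ind = TRUE)
      lab <- p@labels[p@labels > 0]
      labs <- p@labels[idx]
      mins <- rep(Inf, met$nPatches)
      for (a in seq_len(nrow(idx))) for (b in seq_len(nrow(idx))) {
        if (labs[a] == labs[b]) next
        d <- sqrt(max(abs(idx[a, 1] - idx[b, 1]) - 1, 0)^2 +
                  max(abs(idx[a, 2] - idx[b, 2]) - 1, 0)^2) * 30
        mins[labs[a]] <- min(mins[labs[a]], d)
      }
      expect_equal(met$meanNearestNeighbor, mean(mins[is.finite(mins)]))
    }
    expect_equal(sum(patchAreas(p)), sum(m) * 900)
  }
})

test_that("illuminated greenspace is monotone in cutoff with exact limit", {
  ls <- smallLightscape()
  cfg <- smallConfig()
  land <- fixture("smallLand", function() simLandscape(smallConfig()))
  gs <- resampleGreenspace(land$landCover, 30)
  illum <- aggregateGrid(ls$truth, 6)
  prev <- Inf
  for (cut in c(1, 3, 6, 12, 50)) {
    lit <- suppressMessages(illuminatedMask(gs, illum, cut))
    area <- sum(gridValues(lit))
    expect_lte(area, prev)
    prev <- area
  }
  # cutoff beyond the raster maximum reproduces whole-greenspace metrics
  litInf <- suppressMessages(illuminatedMask(gs, illum,
                                             max(gridValues(illum)) + 1))
  expect_equal(sum(gridValues(litInf)), 0)
  rep <- fragmentationReport(gs, illum, cutoff = max(gridValues(illum)) + 1)
  expect_equal(rep$dark, landscapeMetrics(labelPatches(gs, 8),
                                          prod(dim(gs)) * 900))
})

test_that("neighborhood shares recover a constructed two-polygon split", {
  gs <- gridLayer(matrix(TRUE, 4, 8), 0, 0, 30)
  lit <- matrix(FALSE, 4, 8); lit[, 1:4][1, ] <- TRUE   # 4 lit cells left
  lit[, 5:8] <- TRUE                                     # all lit right
  litG <- gridLayer(lit, 0, 0, 30)
  polys <- list(west = cbind(x = c(0, 120, 120, 0, 0),
                             y = c(0, 0, 120, 120, 0)),
                east = cbind(x = c(120, 240, 240, 120, 120),
                             y = c(0, 0, 120, 120, 0)))
  st <- neighborhoodPhotopollution(gs, litG, polys)
  expect_equal(st$percentPhotopolluted[st$neighborhood == "west"], 25)
  expect_equal(st$percentPhotopolluted[st$neighborhood == "east"], 100)
  # one polygon containing everything reproduces the global share
  all1 <- neighborhoodPhotopollution(gs, litG,
    list(all = cbind(x = c(0, 240, 240, 0, 0), y = c(0, 0, 120, 120, 0))))
  expect_equal(all1$percentPhotopolluted, 100 * sum(lit) / 32)
  # polygon with no greenspace is flagged
  gs0 <- gridLayer(matrix(FALSE, 4, 8), 0, 0, 30)
  st0 <- neighborhoodPhotopollution(gs0, litG, polys)
  expect_true(all(st0$flagged))
  expect_true(all(is.na(st0$percentPhotopolluted)))
})
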