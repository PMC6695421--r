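#' Land-cover class codes used by the synthetic landscape
#'
#' Seven classes mirroring a high-resolution urban land-cover inventory.
#' @return named integer vector.
#' @export
landCoverClasses <- function() {
  c(treeCanopy = 1L, grassShrub = 2L, bareEarth = 3L, water = 4L,
    building = 5L, road = 6L, paved = 7L)
}

#' Generate a synthetic urban landscape
#'
#' A seven-class land-cover raster (tree canopy, grass/shrub, bare earth,
#' water, buildings, roads, other paved), rectangular building footprints
#' that coincide exactly with the building-class cells, and a rectangular
#' neighborhood partition of the domain.  Greenspace (tree + grass + bare)
#' is carved from a smoothed random field by quantile thresholding, so the
#' realized greenspace fraction matches the target closely; roads form a
#' regular grid; buildings are stamped rectangles.
#'
#' @param config a [simConfig()] list.
#' @return list with `landCover` (integer [GridLayer-class]), `buildings`
#'   (data.frame xmin, xmax, ymin, ymax) and `neighborhoods` (list of closed
#'   polygon matrices tiling the domain).
#' @export
simLandscape <- function(config) {
  validateSimConfig(config)
  stopifnot(config$greenFraction > 0, config$greenFraction < 1)
  set.seed(substreamSeed(config$seed, "landscape"))
  cls <- landCoverClasses()
  cell <- config$landCell
  nx <- as.integer(config$domainWidth / cell)
  ny <- as.integer(config$domainHeight / cell)

  lc <- matrix(NA_integer_, ny, nx)

  # building rectangles snapped to the land-cover grid
  nB <- config$nBuildings
  bw <- round(runif(nB, 9, 45) / cell)  # 9-45 m footprints
  bh <- round(runif(nB, 9, 45) / cell)
  bx <- floor(runif(nB, 0, nx - bw))
  by <- floor(runif(nB, 0, ny - bh))
  for (k in seq_len(nB)) {
    rows <- (ny - by[k] - bh[k] + 1):(ny - by[k])
    cols <- (bx[k] + 1):(bx[k] + bw[k])
    lc[rows, cols] <- cls["building"]
  }
  buildings <- data.frame(
    xmin = bx * cell, xmax = (bx + bw) * cell,
    ymin = by * cell, ymax = (by + bh) * cell)

  # road grid every 300 m, 9 m wide
  roadEvery <- max(1L, round(300 / cell))
  roadHalf <- max(0L, round(4.5 / cell))
  roadLines <- seq(roadEvery, max(nx, ny), by = roadEvery)
  for (r in roadLines) {
    if (r <= nx) {
      cs <- max(1, r - roadHalf):min(nx, r + roadHalf)
      block <- lc[, cs, drop = FALSE]
      block[is.na(block)] <- cls["road"]
      lc[, cs] <- block
    }
    if (r <= ny) {
      rs <- max(1, r - roadHalf):min(ny, r + roadHalf)
      block <- lc[rs, , drop = FALSE]
      block[is.na(block)] <- cls["road"]
      lc[rs, ] <- block
    }
  }

  # smoothed random field drives the remaining classes
  field <- .gaussBlur(matrix(rnorm(ny * nx), ny, nx), 30 / cell)
  open <- is.na(lc)
  # greenspace fraction is a share of the WHOLE domain; inflate the share of
  # open cells accordingly
  targetOpenShare <- min(config$greenFraction * ny * nx / sum(open), 0.97)
  thr <- quantile(field[open], 1 - targetOpenShare)
  green <- open & field >= thr
  sub <- .gaussBlur(matrix(rnorm(ny * nx), ny, nx), 15 / cell)
  gq <- quantile(sub[green], c(0.55, 0.85))
  lc[green & sub < gq[1]] <- cls["treeCanopy"]
  lc[green & sub >= gq[1] & sub < gq[2]] <- cls["grassShrub"]
  lc[green & sub >= gq[2]] <- cls["bareEarth"]
  rest <- is.na(lc)
  rq <- quantile(field[rest], 0.05)
  lc[rest & field < rq] <- cls["water"]
  lc[is.na(lc)] <- cls["paved"]

  # neighborhoods: rectangular partition (no overlap, no gap)
  nbx <- config$nNeighborhoodsX; nby <- config$nNeighborhoodsY
  wX <- config$domainWidth / nbx; wY <- config$domainHeight / nby
  neighborhoods <- list()
  for (i in seq_len(nbx)) for (j in seq_len(nby)) {
    x0 <- (i - 1) * wX; y0 <- (j - 1) * wY
    neighborhoods[[sprintf("N%02d", length(neighborhoods) + 1L)]] <-
      cbind(x = c(x0, x0 + wX, x0 + wX, x0, x0),
            y = c(y0, y0, y0 + wY, y0 + wY, y0))
  }

  list(landCover = gridLayer(lc, 0, 0, cell), buildings = buildings,
       neighborhoods = neighborhoods)
}
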