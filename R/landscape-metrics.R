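#' Total edge of a binary raster
#'
#' Sum of cell-face lengths between a TRUE cell and a FALSE cell, by
#' default also counting faces on the landscape boundary (FRAGSTATS-style
#' total edge with the boundary included); `boundary = FALSE` excludes
#' faces on the raster edge.
#'
#' @param mask logical matrix or [GridLayer-class].
#' @param cellsize cell edge length (m) when `mask` is a matrix.
#' @param boundary count faces on the landscape boundary.
#' @return total edge length (m).
#' @export
totalEdge <- function(mask, cellsize = 30, boundary = TRUE) {
  if (is(mask, "GridLayer")) { cellsize <- cellSize(mask)
                               mask <- gridValues(mask) }
  m <- !is.na(mask) & mask
  nr <- nrow(m); nc <- ncol(m)
  faces <- 0L
  if (nc > 1) faces <- faces + sum(m[, -nc] != m[, -1])
  if (nr > 1) faces <- faces + sum(m[-nr, ] != m[-1, ])
  if (boundary) faces <- faces + sum(m[1, ]) + sum(m[nr, ]) +
    sum(m[, 1]) + sum(m[, nc])
  faces * cellsize
}

# min edge-to-edge distance between cell squares of two patches:
# sqrt(max(|di|-1,0)^2 + max(|dj|-1,0)^2) * cellsize over all cell pairs
.nearestNeighborDistances <- function(patches) {
  K <- nPatches(patches)
  if (K < 2) return(rep(NA_real_, K))
  lab <- patches@labels
  # only patch-boundary cells can attain the minimum edge-to-edge distance
  m <- lab > 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(mm) rbind(FALSE, cbind(FALSE, mm, FALSE), FALSE)
  pm <- pad(m)
  interior <- pm[1:nr, 2:(nc + 1)] & pm[3:(nr + 2), 2:(nc + 1)] &
    pm[2:(nr + 1), 1:nc] & pm[2:(nr + 1), 3:(nc + 2)] & m
  keep <- m & !interior
  idx <- which(keep, arr.ind = TRUE)
  pid <- lab[keep]
  out <- rep(Inf, K)
  for (k in seq_len(K)) {
    own <- pid == k
    if (!any(!own)) next
    di <- abs(outer(idx[own, 1], idx[!own, 1], `-`)) - 1
    dj <- abs(outer(idx[own, 2], idx[!own, 2], `-`)) - 1
    d2 <- pmax(di, 0)^2 + pmax(dj, 0)^2
    out[k] <- sqrt(min(d2)) * patches@cellsize
  }
  out
}

#' Landscape fragmentation metrics of a patch set
#'
#' Number of patches, mean and SD of patch area, total edge, mean
#' nearest-neighbor distance (edge-to-edge between cell squares; undefined
#' when fewer than two patches), and percent of landscape.
#'
#' @param patches a [PatchSet-class].
#' @param landscapeArea total landscape area (m^2) for the percentage.
#' @param boundary count boundary faces in total edge.
#' @return one-row data.frame: nPatches, meanPatchArea, sdPatchArea,
#'   totalEdge, meanNearestNeighbor, percentLandscape.
#' @export
landscapeMetrics <- function(patches, landscapeArea, boundary = TRUE) {
  areas <- patchAreas(patches)
  K <- length(areas)
  enn <- .nearestNeighborDistances(patches)
  data.frame(
    nPatches = K,
    meanPatchArea = if (K) mean(areas) else 0,
    sdPatchArea = if (K > 1) sd(areas) else 0,
    totalEdge = totalEdge(patches@labels > 0, patches@cellsize, boundary),
    meanNearestNeighbor = if (K >= 2) mean(enn[is.finite(enn)]) else NA_real_,
    percentLandscape = sum(areas) / landscapeArea * 100)
}

#' Photopollution share of greenspace per neighborhood polygon
#'
#' Assigns greenspace cells to the polygon containing their center (first
#' containing polygon wins, with a warning if polygons overlap) and
#' reports, per polygon, greenspace cells, illuminated greenspace cells and
#' the percent photopolluted.  Polygons without greenspace are flagged.
#'
#' @param gs logical greenspace [GridLayer-class].
#' @param illuminated logical illuminated-greenspace GridLayer (aligned).
#' @param polygons named list of polygon matrices (columns x, y).
#' @return data.frame neighborhood, greenCells, litCells,
#'   percentPhotopolluted, flagged.
#' @export
neighborhoodPhotopollution <- function(gs, illuminated, polygons) {
  if (!all(dim(gs) == dim(illuminated)))
    stop("masks are not aligned")
  cc <- cellCenters(gs)
  g <- as.vector(t(gridValues(gs)))           # row-major like cellCenters
  lit <- as.vector(t(gridValues(illuminated)))
  assigned <- rep(NA_integer_, nrow(cc))
  overlap <- FALSE
  for (p in seq_along(polygons)) {
    inside <- pointInPolygon(cc$x, cc$y, polygons[[p]])
    overlap <- overlap || any(inside & !is.na(assigned))
    assigned[inside & is.na(assigned)] <- p
  }
  if (overlap)
    warning("overlapping polygons: first-containing polygon wins")
  nms <- if (!is.null(names(polygons))) names(polygons)
         else paste0("poly", seq_along(polygons))
  out <- data.frame(neighborhood = nms,
                    greenCells = NA_integer_, litCells = NA_integer_,
                    percentPhotopolluted = NA_real_, flagged = FALSE)
  for (p in seq_along(polygons)) {
    sel <- !is.na(assigned) & assigned == p
    gc <- sum(g[sel], na.rm = TRUE)
    lc <- sum(lit[sel], na.rm = TRUE)
    out$greenCells[p] <- gc
    out$litCells[p] <- lc
    if (gc == 0) out$flagged[p] <- TRUE
    else out$percentPhotopolluted[p] <- lc / gc * 100
  }
  out
}

#' Fragmentation comparison: whole greenspace vs illuminated-excluded
#'
#' Computes patch metrics for the entire greenspace and for the greenspace
#' remaining at or below the lux cutoff (the dark remainder), plus percent
#' change per metric — the standard summary of how photopollution
#' fragments habitat.
#'
#' @param gs logical greenspace [GridLayer-class].
#' @param illum illumination [GridLayer-class] (lux).
#' @param cutoff lux threshold.
#' @param connectivity patch adjacency (8 or 4).
#' @return list: `whole`, `dark` (metric rows), `percentChange`,
#'   `percentGreenspaceLit`.
#' @export
fragmentationReport <- function(gs, illum, cutoff = 6, connectivity = 8) {
  area <- prod(dim(gs)) * cellSize(gs)^2
  lit <- suppressMessages(illuminatedMask(gs, illum, cutoff))
  darkMask <- gridLayer(gridValues(gs) & !gridValues(lit),
                        gs@xmin, gs@ymin, cellSize(gs))
  whole <- landscapeMetrics(labelPatches(gs, connectivity), area)
  dark <- landscapeMetrics(labelPatches(darkMask, connectivity), area)
  pc <- 100 * (dark - whole) / whole
  litShare <- 100 * sum(gridValues(lit)) / max(sum(gridValues(gs)), 1)
  list(whole = whole, dark = dark, percentChange = pc,
       percentGreenspaceLit = litShare)
}
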