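#' Resample land cover to a greenspace mask
#'
#' A target cell is greenspace iff a strict majority (> 50%) of its source
#' land-cover cells belong to the greenspace classes (tree canopy,
#' grass/shrub, bare earth by default).
#'
#' @param lc land-cover [GridLayer-class] of integer class codes.
#' @param targetCell target resolution (m); must be an integer multiple of
#'   the source cell.
#' @param greenClasses class codes counted as greenspace.
#' @return logical [GridLayer-class] at the target resolution.
#' @export
resampleGreenspace <- function(lc, targetCell = 30,
                               greenClasses = landCoverClasses()[c(
                                 "treeCanopy", "grassShrub", "bareEarth")]) {
  src <- cellSize(lc)
  fac <- targetCell / src
  if (abs(fac - round(fac)) > 1e-9)
    stop("alignment error: target cell must be an integer multiple of the ",
         "source cell")
  fac <- as.integer(round(fac))
  isGreen <- matrix(as.numeric(gridValues(lc) %in% greenClasses),
                    nrow(gridValues(lc)), ncol(gridValues(lc)))
  frac <- aggregateGrid(gridLayer(isGreen, lc@xmin, lc@ymin, src), fac)
  gridLayer(gridValues(frac) > 0.5, lc@xmin, lc@ymin, targetCell)
}

#' Photopolluted-greenspace mask
#'
#' TRUE where a cell is greenspace and its estimated illuminance exceeds
#' the cutoff.  Masked (NA) illumination cells are treated as
#' not-exceeding; their count is attached as an attribute and reported via
#' a message.
#'
#' @param gs logical greenspace [GridLayer-class].
#' @param illum illumination [GridLayer-class] (lux), cell-aligned with gs.
#' @param cutoff lux threshold (default 6).
#' @return logical GridLayer of illuminated greenspace, with attribute
#'   `nMaskedGreen`.
#' @export
illuminatedMask <- function(gs, illum, cutoff = 6) {
  if (!all(dim(gs) == dim(illum)) ||
      !isTRUE(all.equal(cellSize(gs), cellSize(illum))))
    stop("greenspace and illumination rasters are not aligned")
  g <- gridValues(gs)
  lx <- gridValues(illum)
  masked <- is.na(lx) & g
  if (any(masked))
    message(sum(masked), " greenspace cells had masked illumination ",
            "(treated as not exceeding the cutoff)")
  out <- g & !is.na(lx) & lx > cutoff
  res <- gridLayer(out, gs@xmin, gs@ymin, cellSize(gs))
  attr(res, "nMaskedGreen") <- sum(masked)
  res
}

#' Label connected greenspace patches
#'
#' Two-pass connected-component labeling with union-find, under
#' 8-neighborhood (default) or 4-neighborhood adjacency.
#'
#' @param mask logical [GridLayer-class] or matrix.
#' @param connectivity 8 (default) or 4.
#' @return a [PatchSet-class].
#' @examples
#' m <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
#' nPatches(labelPatches(gridLayer(m, 0, 0, 30), connectivity = 8))
#' @export
labelPatches <- function(mask, connectivity = 8) {
  if (is(mask, "GridLayer")) {
    m <- gridValues(mask); cs <- cellSize(mask)
  } else { m <- mask; cs <- 30 }
  m <- !is.na(m) & m
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nextLab <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    nbr <- integer(0)
    if (i > 1 && m[i - 1, j]) nbr <- c(nbr, labels[i - 1, j])
    if (j > 1 && m[i, j - 1]) nbr <- c(nbr, labels[i, j - 1])
    if (connectivity == 8) {
      if (i > 1 && j > 1 && m[i - 1, j - 1]) nbr <- c(nbr, labels[i - 1, j - 1])
      if (i > 1 && j < nc && m[i - 1, j + 1]) nbr <- c(nbr, labels[i - 1, j + 1])
    }
    if (!length(nbr)) {
      nextLab <- nextLab + 1L
      parent[nextLab] <- nextLab
      labels[i, j] <- nextLab
    } else {
      roots <- vapply(nbr, findRoot, integer(1))
      r <- min(roots)
      labels[i, j] <- r
      for (rr in roots) parent[rr] <- r
    }
  }
  # flatten and relabel 1..K in raster order of first appearance
  if (nextLab > 0) {
    roots <- vapply(seq_len(nextLab), findRoot, integer(1))
    pos <- which(t(labels) > 0)   # row-major first appearance
    lab <- t(labels)[pos]
    firstRoot <- unique(roots[lab])
    remap <- integer(nextLab)
    remap[firstRoot] <- seq_along(firstRoot)
    labels[labels > 0] <- remap[roots[labels[labels > 0]]]
    K <- length(firstRoot)
  } else K <- 0L
  cells <- if (K > 0) as.numeric(tabulate(labels[labels > 0], nbins = K))
           else numeric(0)
  new("PatchSet", labels = labels, cellsize = cs,
      connectivity = connectivity, cells = cells)
}

#' @rdname labelPatches
#' @param x a PatchSet
#' @export
setMethod("nPatches", "PatchSet", function(x) length(x@cells))

#' @rdname labelPatches
#' @export
setMethod("patchAreas", "PatchSet", function(x) x@cells * x@cellsize^2)

setMethod("show", "PatchSet", function(object) {
  cat(sprintf(
    "PatchSet: %d patches (%d-connectivity), %d cells of %g m\n",
    length(object@cells), as.integer(object@connectivity),
    sum(object@cells), object@cellsize))
  invisible(NULL)
})
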