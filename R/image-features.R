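#' Area-weighted image features around points
#'
#' For each point and each image band: the value of the containing pixel
#' (radius 0) and, for each positive radius, the mean pixel value over the
#' disc of that radius, weighted by the exact fraction of the disc's area
#' falling in each pixel (weights sum to 1 by construction; the disc/pixel
#' intersection areas are computed in closed form).  All bands must share
#' one affine transform.  Vectorized over points: for each radius the fixed
#' neighborhood of pixel offsets around the containing pixel is swept once.
#'
#' @param bands list of [GridLayer-class] image bands.
#' @param x,y point coordinates (m); every disc must lie inside the band
#'   extent.
#' @param radii disc radii in meters; 0 means the containing pixel.
#' @return matrix of features, one row per point, columns named
#'   band<b>_r<radius>.
#' @examples
#' b <- gridLayer(matrix(1, 4, 4), 0, 0, 10)
#' extractImageFeatures(list(b), 20, 20)
#' @export
extractImageFeatures <- function(bands, x, y, radii = c(0, 5, 10, 20)) {
  stopifnot(length(bands) >= 1)
  cs <- cellSize(bands[[1]])
  ext <- gridExtent(bands[[1]])
  for (b in bands) {
    if (!isTRUE(all.equal(gridExtent(b), ext)) ||
        !isTRUE(all.equal(cellSize(b), cs)))
      stop("all bands must share one transform")
  }
  rmax <- max(radii)
  if (any(x - rmax < ext["xmin"] | x + rmax > ext["xmax"] |
          y - rmax < ext["ymin"] | y + rmax > ext["ymax"]))
    stop("point (with its largest disc) outside the band extent")

  nP <- length(x)
  nr <- nrow(gridValues(bands[[1]]))
  nc <- ncol(gridValues(bands[[1]]))
  j0 <- floor((x - ext["xmin"]) / cs) + 1        # containing pixel
  i0 <- nr - floor((y - ext["ymin"]) / cs)

  out <- matrix(NA_real_, nP, length(bands) * length(radii))
  colnames(out) <- as.vector(outer(
    seq_along(radii), seq_along(bands),
    function(ri, bi) sprintf("band%d_r%g", bi, radii[ri])))

  for (bi in seq_along(bands)) {
    v <- gridValues(bands[[bi]])
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      colIdx <- (bi - 1) * length(radii) + ri
      if (r == 0) {
        out[, colIdx] <- v[cbind(i0, j0)]
        next
      }
      span <- ceiling(r / cs)
      acc <- numeric(nP)
      wsum <- numeric(nP)
      for (di in -span:span) for (dj in -span:span) {
        jj <- j0 + dj; ii <- i0 + di
        x1 <- ext["xmin"] + (jj - 1) * cs
        y1 <- ext["ymin"] + (nr - ii) * cs
        a <- discRectArea(x, y, r, x1, x1 + cs, y1, y1 + cs)
        nz <- a > 0 & ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
        if (!any(nz)) next
        acc[nz] <- acc[nz] + a[nz] * v[cbind(ii[nz], jj[nz])]
        wsum[nz] <- wsum[nz] + a[nz]
      }
      out[, colIdx] <- acc / wsum
    }
  }
  out
}
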