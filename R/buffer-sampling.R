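#' Mean estimated illuminance in a buffer around a camera
#'
#' Samples points uniformly on the disc of the given radius (rejection
#' against building footprints and masked raster cells) and returns the
#' mean raster illuminance over accepted points.  Deterministic given the
#' seed.
#'
#' @param raster an illumination [GridLayer-class] (lux).
#' @param x,y buffer center (m).
#' @param radius buffer radius (m); the analysis grid uses 300, 500, 1000.
#' @param buildings building footprints: data.frame (xmin, xmax, ymin,
#'   ymax) or list of polygon matrices; NULL for none.
#' @param n number of sample points (the returned n may be smaller if
#'   valid area is scarce).
#' @param seed RNG seed.
#' @param maxTries rejection-sampling budget as a multiple of n.
#' @return list: camera buffer summary with `meanLux`, `n`, `radius`.
#' @export
sampleBufferIllumination <- function(raster, x, y, radius, buildings = NULL,
                                     n = 1000, seed = 1, maxTries = 200) {
  set.seed(seed)
  accepted <- 0L
  luxSum <- 0
  luxVals <- numeric(0)
  tries <- 0L
  batch <- max(n, 1000L)
  while (accepted < n && tries < maxTries) {
    r <- radius * sqrt(runif(batch))
    a <- runif(batch, 0, 2 * pi)
    px <- x + r * cos(a)
    py <- y + r * sin(a)
    inBldg <- if (is.null(buildings)) rep(FALSE, batch)
      else if (is.data.frame(buildings)) pointInRects(px, py, buildings)
      else Reduce(`|`, lapply(buildings, function(p)
        pointInPolygon(px, py, p)), rep(FALSE, batch))
    v <- extractAt(raster, px, py)
    ok <- !inBldg & !is.na(v)
    keep <- which(ok)[seq_len(min(sum(ok), n - accepted))]
    luxVals <- c(luxVals, v[keep])
    accepted <- accepted + length(keep)
    tries <- tries + 1L
  }
  if (accepted == 0L)
    stop("no valid sampling area: buffer fully masked or inside buildings")
  list(meanLux = mean(luxVals), n = accepted, radius = radius)
}

#' Buffer illumination table for a camera set
#'
#' @param raster illumination [GridLayer-class].
#' @param cameras data.frame with camera, x, y.
#' @param radii buffer radii (m).
#' @param buildings see [sampleBufferIllumination()].
#' @param n points per buffer.
#' @param seed base seed; each (camera, radius) gets its own substream.
#' @return data.frame camera, radius, meanLux, n.
#' @export
bufferIlluminationTable <- function(raster, cameras, radii = c(300, 500,
                                    1000), buildings = NULL, n = 1000,
                                    seed = 1) {
  rows <- list()
  for (i in seq_len(nrow(cameras))) for (r in radii) {
    s <- substreamSeed(seed, sprintf("buffer:%s:%g", cameras$camera[i], r))
    bld <- buildings
    if (is.data.frame(bld) && nrow(bld))   # keep only footprints near buffer
      bld <- bld[bld$xmax >= cameras$x[i] - r & bld$xmin <= cameras$x[i] + r &
                 bld$ymax >= cameras$y[i] - r & bld$ymin <= cameras$y[i] + r, ]
    b <- sampleBufferIllumination(raster, cameras$x[i], cameras$y[i], r,
                                  buildings = bld, n = n, seed = s)
    rows[[length(rows) + 1L]] <- data.frame(
      camera = cameras$camera[i], radius = r, meanLux = b$meanLux, n = b$n)
  }
  do.call(rbind, rows)
}
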