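#' Create a GridLayer
#'
#' @param values matrix of cell values; row 1 is the northern-most row.
#' @param xmin,ymin coordinates (m) of the south-west corner of the grid.
#' @param cellsize cell edge length in meters.
#' @return a [GridLayer-class] object.
#' @examples
#' g <- gridLayer(matrix(1:6, 2, 3), 0, 0, 30)
#' gridExtent(g)
#' @export
gridLayer <- function(values, xmin = 0, ymin = 0, cellsize = 30) {
  new("GridLayer", values = as.matrix(values), xmin = xmin, ymin = ymin,
      cellsize = cellsize)
}

#' @rdname gridLayer
#' @param x a GridLayer
#' @export
setMethod("gridValues", "GridLayer", function(x) x@values)

#' @rdname gridLayer
#' @export
setMethod("cellSize", "GridLayer", function(x) x@cellsize)

#' @rdname gridLayer
#' @export
setMethod("gridExtent", "GridLayer", function(x) {
  c(xmin = x@xmin, xmax = x@xmin + ncol(x@values) * x@cellsize,
    ymin = x@ymin, ymax = x@ymin + nrow(x@values) * x@cellsize)
})

setMethod("dim", "GridLayer", function(x) dim(x@values))

setMethod("show", "GridLayer", function(object) {
  e <- gridExtent(object)
  cat(sprintf("GridLayer: %d x %d cells of %g m\n", nrow(object@values),
              ncol(object@values), object@cellsize))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]\n", e[1], e[2], e[3], e[4]))
  v <- object@values[is.finite(object@values)]
  if (length(v))
    cat(sprintf("  values: min %.4g  median %.4g  max %.4g  (%d NA)\n",
                min(v), median(v), max(v), sum(!is.finite(object@values))))
  invisible(NULL)
})

#' Locate points on a grid
#'
#' Maps projected coordinates to (row, col) indices using half-open cell
#' intervals \[edge, edge + cellsize) and floor division, so a point on the
#' shared edge of two cells belongs to the cell to its north-east side in x
#' and to the cell above it in y only at the grid's own origin convention.
#'
#' @param layer a GridLayer.
#' @param x,y coordinate vectors (m).
#' @return data.frame with columns row, col (NA when outside the grid).
#' @export
cellIndex <- function(layer, x, y) {
  nr <- nrow(layer@values)
  col <- floor((x - layer@xmin) / layer@cellsize) + 1
  row <- nr - floor((y - layer@ymin) / layer@cellsize)
  bad <- col < 1 | col > ncol(layer@values) | row < 1 | row > nr |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Read grid values at point locations
#'
#' @inheritParams cellIndex
#' @return vector of cell values; NA outside the grid.
#' @export
extractAt <- function(layer, x, y) {
  idx <- cellIndex(layer, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- layer@values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Coordinates of all cell centers
#'
#' @param layer a GridLayer.
#' @return data.frame x, y in row-major (northern row first) order.
#' @export
cellCenters <- function(layer) {
  nr <- nrow(layer@values); nc <- ncol(layer@values); cs <- layer@cellsize
  xs <- layer@xmin + (seq_len(nc) - 0.5) * cs
  ys <- layer@ymin + (nr - seq_len(nr) + 0.5) * cs
  data.frame(row = rep(seq_len(nr), each = nc), col = rep(seq_len(nc), nr),
             x = rep(xs, nr), y = rep(ys, each = nc))
}

#' Block-aggregate a grid to a coarser resolution
#'
#' @param layer a GridLayer.
#' @param factor integer aggregation factor (new cell = factor x factor block).
#' @param fun summary applied per block ("mean" or a function).
#' @return a coarser GridLayer.
#' @export
aggregateGrid <- function(layer, factor, fun = "mean") {
  stopifnot(factor >= 1, factor == round(factor))
  v <- layer@values
  nr <- nrow(v); nc <- ncol(v)
  stopifnot(nr %% factor == 0, nc %% factor == 0)
  if (identical(fun, "mean")) {
    # exact block means via two matrix products
    rFac <- diag(nr %/% factor)[rep(seq_len(nr %/% factor), each = factor), ,
                                drop = FALSE]
    cFac <- diag(nc %/% factor)[rep(seq_len(nc %/% factor), each = factor), ,
                                drop = FALSE]
    out <- t(rFac) %*% v %*% cFac / factor^2
  } else {
    f <- match.fun(fun)
    out <- matrix(NA_real_, nr %/% factor, nc %/% factor)
    for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
      out[i, j] <- f(v[((i - 1) * factor + 1):(i * factor),
                       ((j - 1) * factor + 1):(j * factor)])
    }
  }
  gridLayer(out, layer@xmin, layer@ymin, layer@cellsize * factor)
}
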