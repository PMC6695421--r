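# Exact circle/rectangle geometry used by area-weighted pixel features and
# the analytic oracles in the test-suite.

# antiderivative of sqrt(r^2 - x^2), x clamped to [-r, r]
.hInt <- function(x, r) {
  x <- pmin(pmax(x, -r), r)
  (x * sqrt(pmax(r^2 - x^2, 0)) + r^2 * asin(x / r)) / 2
}

# area of {x^2 + y^2 <= r^2, x >= a, y >= b} for scalar-compatible vectors,
# assuming b >= 0 (general b handled by .cornerArea)
.cornerAreaNN <- function(a, b, r) {
  out <- numeric(length(a))
  feasible <- b < r
  if (!any(feasible)) return(out)
  cc <- sqrt(pmax(r^2 - b^2, 0))
  lo <- pmax(a, -cc)
  hi <- cc
  pos <- feasible & lo < hi
  out[pos] <- (.hInt(hi[pos], r) - .hInt(lo[pos], r)) -
    b[pos] * (hi[pos] - lo[pos])
  out
}

# area of {x^2 + y^2 <= r^2, x >= a, y >= b}, any a, b (vectorized)
.cornerArea <- function(a, b, r) {
  a <- rep_len(a, max(length(a), length(b)))
  b <- rep_len(b, length(a))
  out <- numeric(length(a))
  neg <- b < 0
  if (any(!neg)) out[!neg] <- .cornerAreaNN(a[!neg], b[!neg], r)
  if (any(neg)) {
    # reflect the part below the x-axis: K(a,b) = 2 K(a,0) - K(a,-b)
    out[neg] <- 2 * .cornerAreaNN(a[neg], rep(0, sum(neg)), r) -
      .cornerAreaNN(a[neg], -b[neg], r)
  }
  out
}

# area of the disc of radius r at the origin with x <= a (vectorized)
.discHalfArea <- function(a, r) {
  a <- pmin(pmax(a, -r), r)
  pi * r^2 - (r^2 * acos(a / r) - a * sqrt(pmax(r^2 - a^2, 0)))
}

#' Exact area of intersection between a disc and axis-aligned rectangles
#'
#' Computes, for each rectangle, the area of its intersection with the disc
#' of radius `r` centered at (`cx`, `cy`).  Used to form area-proportional
#' pixel weights for disc-buffered image features; exact closed form, no
#' sampling.
#'
#' @param cx,cy disc center (m).
#' @param r disc radius (m).
#' @param x1,x2,y1,y2 rectangle edges (vectors, x1 < x2, y1 < y2).
#' @return vector of intersection areas.
#' @examples
#' discRectArea(0, 0, 1, -2, 2, -2, 2)  # pi
#' @export
discRectArea <- function(cx, cy, r, x1, x2, y1, y2) {
  # translate to disc-centered coordinates
  g <- function(a, b) {
    # area of disc with x <= a, y <= b:
    # S(a) + S(b) - pi r^2 + K(a, b)
    .discHalfArea(a, r) + .discHalfArea(b, r) - pi * r^2 +
      .cornerArea(a, b, r)
  }
  a1 <- x1 - cx; a2 <- x2 - cx; b1 <- y1 - cy; b2 <- y2 - cy
  pmax(g(a2, b2) - g(a1, b2) - g(a2, b1) + g(a1, b1), 0)
}

#' Test whether points fall inside a polygon
#'
#' Ray-casting (even-odd) rule; points exactly on an edge are classified by
#' the crossing parity and should not be relied upon.
#'
#' @param px,py point coordinates.
#' @param poly two-column matrix (x, y) of polygon vertices, closed or open.
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ]) && nrow(poly) > 3)
    poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test whether points fall inside any rectangle of a footprint table
#'
#' @param px,py point coordinates.
#' @param rects data.frame with columns xmin, xmax, ymin, ymax.
#' @return logical vector.
#' @export
pointInRects <- function(px, py, rects) {
  inside <- rep(FALSE, length(px))
  if (is.null(rects) || nrow(rects) == 0) return(inside)
  for (k in seq_len(nrow(rects))) {
    inside <- inside |
      (px >= rects$xmin[k] & px < rects$xmax[k] &
       py >= rects$ymin[k] & py < rects$ymax[k])
  }
  inside
}

# separable Gaussian blur of a matrix (reflecting edges); sigma in cells
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(v, r) c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
  conv1 <- function(v) {
    vp <- pad(v, rad)
    out <- stats::filter(vp, k, sides = 2)
    out[(rad + 1):(rad + length(v))]
  }
  m1 <- apply(m, 2, conv1)
  t(apply(t(m1), 2, conv1))
}
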