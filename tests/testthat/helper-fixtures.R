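# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

smallConfig <- function(...) {
  defaults <- list(seed = 11, domainWidth = 1200, domainHeight = 1200,
                   nControlPoints = 120, nSources = 12, nCameras = 10,
                   cameraMargin = 100, deploymentDays = 10, studyYears = 1,
                   nBuildings = 60, nNeighborhoodsX = 2, nNeighborhoodsY = 2)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

smallLightscape <- function() fixture("smallLS", function()
  simLightscape(smallConfig()))

# direct sampler of von Mises angles (rejection; Best-Fisher not needed at
# test scale)
rvonmises <- function(n, mu, kappa) {
  out <- numeric(0)
  fmax <- exp(kappa) / (2 * pi * besselI(kappa, 0))
  while (length(out) < n) {
    cand <- runif(2 * n, 0, 2 * pi)
    u <- runif(2 * n, 0, fmax)
    f <- exp(kappa * cos(cand - mu)) / (2 * pi * besselI(kappa, 0))
    out <- c(out, cand[u < f])
  }
  out[seq_len(n)]
}

# independent flood-fill labeling oracle (recursive stack, any connectivity)
floodFillLabels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb4 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nb8 <- rbind(nb4, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  nb <- if (connectivity == 8) nb8 else nb4
  k <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (!mask[si, sj] || lab[si, sj] != 0L) next
    k <- k + 1L
    stack <- list(c(si, sj))
    lab[si, sj] <- k
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in seq_len(nrow(nb))) {
        i <- cur[1] + nb[d, 1]; j <- cur[2] + nb[d, 2]
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- k
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# partition-equality of two labelings up to label permutation
sameLabeling <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  pairs <- unique(cbind(a[a > 0], b[a > 0]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}
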