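#' Enumerate the occurrence-model grid
#'
#' The full factorial of lux cutoffs x buffer radii x dusk anchor offsets x
#' harmonic orders, for each species group: 3 x 3 x 5 x 3 x 2 = 270 models
#' at the defaults.
#'
#' @param cutoffs lux cutoffs dividing light from dark cameras.
#' @param buffers buffer radii (m).
#' @param anchors anchor offsets (h) relative to solar dusk mapped to pi.
#' @param orders harmonic orders of the circadian functional form.
#' @param groups named list: group name -> species vector.
#' @return data.frame, one row per model spec.
#' @export
modelGrid <- function(cutoffs = c(1, 3, 6), buffers = c(300, 500, 1000),
                      anchors = -2:2, orders = 1:3,
                      groups = list(
                        nocturnal = defaultSpeciesGroups()$nocturnal$species,
                        diurnal = defaultSpeciesGroups()$diurnal$species)) {
  g <- expand.grid(group = names(groups), cutoff = cutoffs,
                   buffer = buffers, anchorOffset = anchors, order = orders,
                   stringsAsFactors = FALSE)
  attr(g, "groups") <- groups
  g
}

#' Fit the model grid and select the minimum-BIC spec per group
#'
#' Every spec is fitted on its own camera-hour table (the phase anchor and
#' the light classification change the design).  Per group the minimum-BIC
#' spec is returned; ties break toward fewer parameters, then lower cutoff.
#' Specs whose table cannot be fitted (e.g. all-present or all-absent) are
#' recorded as missing and selection runs over the rest.
#'
#' @param detections,activeHours,humans,covariates,siteLux see
#'   [buildCameraHourTable()].
#' @param grid spec grid from [modelGrid()] (needs its `groups` attribute).
#' @param lat,lon solar coordinates.
#' @param controls include control covariates.
#' @param verbose print progress.
#' @return list of class "gridSelection": `best` (named list of
#'   "occurrenceFit" per group), `bicTable` (grid + BIC + logLik + n),
#'   `missing` (failed spec rows).
#' @export
selectModelGrid <- function(detections, activeHours, humans, covariates,
                            siteLux, grid = modelGrid(), lat = 41.88,
                            lon = 0, controls = TRUE, verbose = FALSE) {
  if (nrow(grid) == 0) stop("model grid is empty")
  groups <- attr(grid, "groups")
  if (is.null(groups)) stop("grid lacks its groups attribute")

  # tables depend only on (group, buffer, anchor): the cutoff merely flips
  # the light indicator, and the harmonic order only enters the formula.
  # Specs are processed grouped by table so only one camera-hour table and
  # the per-group running best fit are ever held in memory.
  keys <- paste(grid$group, grid$buffer, grid$anchorOffset, sep = "|")
  ordIdx <- order(keys)
  bic <- rep(NA_real_, nrow(grid)); ll <- rep(NA_real_, nrow(grid))
  np <- rep(NA_integer_, nrow(grid)); nn <- rep(NA_integer_, nrow(grid))
  ok <- logical(nrow(grid))
  best <- list()
  rec <- NULL; curKey <- ""
  done <- 0L
  for (i in ordIdx) {
    row <- grid[i, ]
    if (keys[i] != curKey) {
      spec <- list(species = groups[[row$group]], cutoff = row$cutoff,
                   buffer = row$buffer, anchorOffset = row$anchorOffset,
                   order = row$order, group = row$group)
      rec <- suppressMessages(
        buildCameraHourTable(detections, activeHours, humans, covariates,
                             siteLux, spec, lat, lon))
      curKey <- keys[i]
    }
    spec <- attr(rec, "spec")
    spec$order <- row$order
    spec$group <- row$group
    spec$cutoff <- row$cutoff
    rec$light <- as.integer(rec$bufferLux > row$cutoff)
    fit <- tryCatch(
      suppressWarnings(fitOccurrenceModel(rec, spec, controls)),
      error = function(e) NULL)
    done <- done + 1L
    if (verbose && done %% 25 == 0)
      message(sprintf("fitted %d / %d specs", done, nrow(grid)))
    if (is.null(fit)) next
    ok[i] <- TRUE
    bic[i] <- fit$BIC; ll[i] <- fit$logLik
    np[i] <- fit$nPar; nn[i] <- fit$n
    g <- row$group
    incumbent <- best[[g]]
    better <- is.null(incumbent) || fit$BIC < incumbent$BIC - 1e-9 ||
      (abs(fit$BIC - incumbent$BIC) <= 1e-9 &&
       (fit$nPar < incumbent$nPar ||
        (fit$nPar == incumbent$nPar && spec$cutoff < incumbent$spec$cutoff)))
    if (better) best[[g]] <- fit
  }

  bicTable <- cbind(grid, BIC = bic, logLik = ll, nPar = np, n = nn)
  structure(list(best = best[names(groups)[names(groups) %in% names(best)]],
                 bicTable = bicTable,
                 missing = grid[!ok, , drop = FALSE]),
            class = "gridSelection")
}

#' @export
print.gridSelection <- function(x, ...) {
  cat(sprintf("gridSelection: %d specs fitted, %d missing\n",
              sum(!is.na(x$bicTable$BIC)), nrow(x$missing)))
  for (g in names(x$best)) {
    s <- x$best[[g]]$spec
    cat(sprintf(
      "  %s: cutoff %g lux, buffer %g m, anchor %+g h, order %d (BIC %.1f)\n",
      g, s$cutoff, s$buffer, s$anchorOffset, s$order, x$best[[g]]$BIC))
  }
  invisible(x)
}
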