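#' Read and write control-point tables
#'
#' Plain CSV with columns x, y, lux (projected meters / lux).
#'
#' @param path file path.
#' @return data.frame with x, y, lux.
#' @export
readControlPoints <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("x", "y", "lux") %in% names(d)))
  if (any(!is.finite(d$x) | !is.finite(d$y))) stop("non-finite coordinates")
  if (any(d$lux < 0)) stop("negative illuminance")
  d
}

#' @rdname readControlPoints
#' @param controlPoints data.frame with x, y, lux.
#' @export
writeControlPoints <- function(controlPoints, path) {
  write.csv(controlPoints[, c("x", "y", "lux")], path, row.names = FALSE)
}

#' Write / read an actogram as CSV
#'
#' Columns: animal_id, bin_start_iso, counts, night_lux, condition.
#'
#' @param acto an [Actogram-class].
#' @param path file path.
#' @param startDate date of the first bin.
#' @export
writeActogramCSV <- function(acto, path, startDate = "2017-01-01") {
  t0 <- as.POSIXct(paste(startDate, "00:00:00"), tz = "UTC")
  bins <- t0 + (seq_along(acto@counts) - 1) * acto@binMinutes * 60
  write.csv(data.frame(
    animal_id = acto@animal,
    bin_start_iso = format(bins, "%Y-%m-%dT%H:%M:%SZ"),
    counts = acto@counts, night_lux = acto@nightLux,
    condition = acto@condition), path, row.names = FALSE)
}

#' @rdname writeActogramCSV
#' @param lightsOffHour clock hour of dark onset (not stored in the CSV).
#' @return [readActogramCSV()] returns an [Actogram-class].
#' @export
readActogramCSV <- function(path, lightsOffHour = 18) {
  d <- read.csv(path)
  t <- as.POSIXct(d$bin_start_iso, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  binMin <- as.numeric(difftime(t[2], t[1], units = "mins"))
  new("Actogram", animal = as.character(d$animal_id[1]),
      sex = NA_character_, binMinutes = binMin,
      counts = as.integer(d$counts), nightLux = d$night_lux,
      condition = as.character(d$condition), lightsOffHour = lightsOffHour)
}

#' Write / read detection records
#'
#' Columns: camera_id, species, timestamp_iso.
#'
#' @param detections data.frame camera, species, timestamp.
#' @param path file path.
#' @export
writeDetectionsCSV <- function(detections, path) {
  write.csv(data.frame(
    camera_id = detections$camera, species = detections$species,
    timestamp_iso = format(detections$timestamp, "%Y-%m-%dT%H:%M:%SZ")),
    path, row.names = FALSE)
}

#' @rdname writeDetectionsCSV
#' @export
readDetectionsCSV <- function(path) {
  d <- read.csv(path)
  data.frame(camera = as.character(d$camera_id),
             species = as.character(d$species),
             timestamp = as.POSIXct(d$timestamp_iso,
                                    format = "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC"))
}

#' Write / read a GridLayer as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#'
#' @param layer a [GridLayer-class].
#' @param path file path (conventionally .asc).
#' @export
writeAsciiGrid <- function(layer, path) {
  v <- gridValues(layer)
  storage <- ifelse(is.na(v), -9999, v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.6f", layer@xmin),
               sprintf("yllcorner %.6f", layer@ymin),
               sprintf("cellsize %.6f", layer@cellsize),
               "NODATA_value -9999"), con)
  write.table(format(storage, trim = TRUE, digits = 10), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' @rdname writeAsciiGrid
#' @return [readAsciiGrid()] returns a [GridLayer-class].
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6)
  val <- function(i) as.numeric(strsplit(hdr[i], "\\s+")[[1]][2])
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == val(6)] <- NA
  gridLayer(m, val(3), val(4), val(5))
}

#' Write / read polygon sets as GeoJSON
#'
#' Each polygon is a closed ring in projected meters; properties carry the
#' polygon name.
#'
#' @param polygons named list of polygon matrices (columns x, y).
#' @param path file path.
#' @export
writeGeoJSONPolygons <- function(polygons, path) {
  features <- lapply(seq_along(polygons), function(i) {
    p <- as.matrix(polygons[[i]])
    if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
    ring <- lapply(seq_len(nrow(p)), function(r) c(p[r, 1], p[r, 2]))
    list(type = "Feature",
         properties = list(name = if (!is.null(names(polygons)))
           names(polygons)[i] else paste0("poly", i)),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
}

#' @rdname writeGeoJSONPolygons
#' @return [readGeoJSONPolygons()] returns a named list of polygon
#'   matrices.
#' @export
readGeoJSONPolygons <- function(path) {
  j <- jsonlite::read_json(path)
  out <- list()
  for (f in j$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt)
      c(x = pt[[1]], y = pt[[2]])))
    out[[f$properties$name]] <- m
  }
  out
}

#' Write rectangle footprints as GeoJSON polygons
#'
#' @param rects data.frame xmin, xmax, ymin, ymax.
#' @param path file path.
#' @export
writeGeoJSONRects <- function(rects, path) {
  polys <- lapply(seq_len(nrow(rects)), function(i)
    cbind(x = c(rects$xmin[i], rects$xmax[i], rects$xmax[i], rects$xmin[i],
                rects$xmin[i]),
          y = c(rects$ymin[i], rects$ymin[i], rects$ymax[i], rects$ymax[i],
                rects$ymin[i])))
  names(polys) <- paste0("building", seq_len(nrow(rects)))
  writeGeoJSONPolygons(polys, path)
}
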