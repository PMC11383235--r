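#' Construct a detection set
#'
#' A detection set holds all nucleus detections of one scan replicate within
#' one rectangular region of interest (ROI), together with the ROI bounds and
#' the pixel size the image was analysed at. Coordinates are continuous
#' micron coordinates in the slide frame with the image convention (y grows
#' downward); ROI bounds are inclusive on all edges, so a centroid exactly on
#' a boundary is inside.
#'
#' @param records data frame with columns `id`, `x_um`, `y_um`, `area_um2`,
#'   `hema_median`, `eosin_median` (one row per detected nucleus; `id` unique).
#'   Stain columns may be `NA` when the export lacks them.
#' @param roi_bounds numeric of length 4, `c(x_min, y_min, x_max, y_max)` in
#'   microns.
#' @param pixel_size_um pixel size of the analysed image in micron per pixel.
#' @param scan_id,roi_id labels identifying the scan replicate and the ROI.
#' @return an object of class `detection_set`.
#' @examples
#' rec <- data.frame(id = c("n1", "n2"), x_um = c(10, 50), y_um = c(20, 60),
#'                   area_um2 = c(12, 18), hema_median = c(0.5, 0.6),
#'                   eosin_median = c(0.2, 0.25))
#' detection_set(rec, roi_bounds = c(0, 0, 220, 220), pixel_size_um = 0.11)
#' @export
detection_set <- function(records, roi_bounds, pixel_size_um,
                          scan_id = "scan", roi_id = "roi") {
  cols <- c("id", "x_um", "y_um", "area_um2", "hema_median", "eosin_median")
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    records <- data.frame(id = character(), x_um = numeric(), y_um = numeric(),
                          area_um2 = numeric(), hema_median = numeric(),
                          eosin_median = numeric())
  }
  records <- as.data.frame(records)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop_format("records lack column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[cols]
  records$id <- as.character(records$id)
  rownames(records) <- NULL

  if (!is.numeric(roi_bounds) || length(roi_bounds) != 4L)
    stop_domain("roi_bounds must be numeric c(x_min, y_min, x_max, y_max)")
  roi_bounds <- as.double(roi_bounds)
  names(roi_bounds) <- c("x_min", "y_min", "x_max", "y_max")
  if (roi_bounds["x_max"] <= roi_bounds["x_min"] ||
      roi_bounds["y_max"] <= roi_bounds["y_min"])
    stop_domain("ROI width and height must be positive")
  if (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0)
    stop_domain("pixel_size_um must be a positive scalar")

  if (nrow(records)) {
    if (anyDuplicated(records$id))
      stop_domain("nucleus ids must be unique within a detection set")
    if (!all(is.finite(records$x_um)) || !all(is.finite(records$y_um)))
      stop_domain("centroid coordinates must be finite")
    if (!all(is.finite(records$area_um2)) || any(records$area_um2 <= 0))
      stop_domain("nucleus areas must be finite and > 0")
    inside <- records$x_um >= roi_bounds["x_min"] &
      records$x_um <= roi_bounds["x_max"] &
      records$y_um >= roi_bounds["y_min"] &
      records$y_um <= roi_bounds["y_max"]
    if (!all(inside))
      stop_domain(sum(!inside), " record(s) fall outside roi_bounds")
  }

  structure(list(scan_id = as.character(scan_id), roi_id = as.character(roi_id),
                 records = records, roi_bounds = roi_bounds,
                 pixel_size_um = as.double(pixel_size_um)),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  b <- x$roi_bounds
  cat(sprintf("Detection set '%s' (ROI '%s'): %d nuclei\n",
              x$scan_id, x$roi_id, nrow(x$records)))
  cat(sprintf("  ROI [%g, %g] x [%g, %g] um, pixel size %g um/px\n",
              b["x_min"], b["x_max"], b["y_min"], b["y_max"], x$pixel_size_um))
  if (nrow(x$records))
    cat(sprintf("  area: median %.2f um^2, range %.2f-%.2f\n",
                stats::median(x$records$area_um2),
                min(x$records$area_um2), max(x$records$area_um2)))
  invisible(x)
}

#' Table dialect for detection exports
#'
#' Describes how a delimited per-nucleus measurement table maps onto the
#' fields of a detection set. The default mimics a QuPath-style measurement
#' export: tab-delimited, centroid columns in microns, one area and two
#' per-nucleus median stain columns. Every element can be remapped for other
#' tools.
#'
#' @param delim field delimiter (`"\t"` or `","`).
#' @param units units of the centroid columns, `"um"` or `"px"`. Pixel
#'   coordinates are converted to microns on read using the set's pixel size.
#' @param id name of an id column, or `NA` to number rows sequentially.
#' @param x,y,area,hema,eosin column names for the centroid coordinates, the
#'   nucleus area, and the median stain values. `hema`/`eosin` may be `NA`
#'   when absent from the export.
#' @return a `nucleus_dialect` list.
#' @export
nucleus_dialect <- function(delim = "\t", units = c("um", "px"),
                            id = NA_character_,
                            x = "Centroid X µm", y = "Centroid Y µm",
                            area = "Nucleus: Area",
                            hema = "Nucleus: Hematoxylin OD median",
                            eosin = "Nucleus: Eosin OD median") {
  units <- match.arg(units)
  structure(list(delim = delim, units = units, id = id,
                 x = x, y = y, area = area, hema = hema, eosin = eosin),
            class = "nucleus_dialect")
}

# Internal plain dialect used by write_detections()/read round trips.
plain_dialect <- function(delim = "\t") {
  nucleus_dialect(delim = delim, units = "um", id = "id",
                  x = "x_um", y = "y_um", area = "area_um2",
                  hema = "hema_median", eosin = "eosin_median")
}

#' Read a per-nucleus detection table
#'
#' Reads a delimited text export of a nucleus segmentation run and returns a
#' [detection_set()] with coordinates normalised to microns. Row order is
#' preserved; ids come from the dialect's id column or are generated
#' sequentially (`"n1"`, `"n2"`, ...). An empty file yields an empty
#' detection set.
#'
#' @param path path of the delimited text file.
#' @param roi_bounds,pixel_size_um,scan_id,roi_id metadata passed to
#'   [detection_set()] (usually from a scan config, see [read_roi_config()]).
#' @param dialect a [nucleus_dialect()] mapping columns to fields.
#' @return a `detection_set`.
#' @export
read_detections <- function(path, roi_bounds, pixel_size_um,
                            scan_id = "scan", roi_id = "roi",
                            dialect = nucleus_dialect()) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  if (file.size(path) == 0L)
    return(detection_set(NULL, roi_bounds, pixel_size_um, scan_id, roi_id))
  tab <- utils::read.table(path, header = TRUE, sep = dialect$delim,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  needed <- c(x = dialect$x, y = dialect$y, area = dialect$area)
  for (f in names(needed)) {
    if (!needed[[f]] %in% names(tab))
      stop_format("column '", needed[[f]], "' (", f, ") missing from ", path)
  }
  n <- nrow(tab)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (what != "stain" && anyNA(v))
      stop_format("non-numeric ", what, " in column '", col, "' at row ",
                  which(is.na(v))[1L])
    v
  }
  if (n == 0L)
    return(detection_set(NULL, roi_bounds, pixel_size_um, scan_id, roi_id))
  x <- num(dialect$x, "coordinate")
  y <- num(dialect$y, "coordinate")
  area <- num(dialect$area, "area")
  if (identical(dialect$units, "px")) {
    x <- px_to_um(x, pixel_size_um)
    y <- px_to_um(y, pixel_size_um)
    area <- area * pixel_size_um^2
  }
  hema <- if (!is.na(dialect$hema) && dialect$hema %in% names(tab))
    num(dialect$hema, "stain") else rep(NA_real_, n)
  eosin <- if (!is.na(dialect$eosin) && dialect$eosin %in% names(tab))
    num(dialect$eosin, "stain") else rep(NA_real_, n)
  ids <- if (!is.na(dialect$id) && dialect$id %in% names(tab))
    as.character(tab[[dialect$id]]) else paste0("n", seq_len(n))
  rec <- data.frame(id = ids, x_um = x, y_um = y, area_um2 = area,
                    hema_median = hema, eosin_median = eosin)
  detection_set(rec, roi_bounds, pixel_size_um, scan_id, roi_id)
}

#' Write a detection set as delimited text
#'
#' Writes micron-unit columns `id, x_um, y_um, area_um2, hema_median,
#' eosin_median` with a header line, re-readable losslessly by
#' [read_detections()] with the matching plain dialect (field values agree to
#' better than 1e-9 after a round trip).
#'
#' @param ds a `detection_set`.
#' @param path output path.
#' @param delim field delimiter.
#' @return invisibly, `path`.
#' @export
write_detections <- function(ds, path, delim = "\t") {
  stopifnot(inherits(ds, "detection_set"))
  rec <- ds$records
  out <- data.frame(id = rec$id,
                    x_um = format(rec$x_um, digits = 17, trim = TRUE),
                    y_um = format(rec$y_um, digits = 17, trim = TRUE),
                    area_um2 = format(rec$area_um2, digits = 17, trim = TRUE),
                    hema_median = format(rec$hema_median, digits = 17, trim = TRUE),
                    eosin_median = format(rec$eosin_median, digits = 17, trim = TRUE))
  ok <- tryCatch({
    suppressWarnings(utils::write.table(out, path, sep = delim, quote = FALSE,
                                        row.names = FALSE, col.names = TRUE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_format("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Convert a pixel length to microns
#'
#' At the native analysis resolution an ROI of 2,000 pixels corresponds to
#' 220 microns (0.11 micron per pixel); this is the linear conversion behind
#' that equivalence.
#'
#' @param length_px length in pixels (vectorised).
#' @param pixel_size_um pixel size in micron per pixel, > 0.
#' @return `length_px * pixel_size_um`.
#' @examples
#' px_to_um(2000, 0.11)  # 220
#' @export
px_to_um <- function(length_px, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || any(!is.finite(pixel_size_um)) ||
      any(pixel_size_um <= 0))
    stop_domain("pixel_size_um must be positive and finite")
  if (!is.numeric(length_px) || any(!is.finite(length_px)))
    stop_domain("length_px must be finite")
  length_px * pixel_size_um
}

#' Read detections from a GeoJSON FeatureCollection
#'
#' Convenience reader for object exports in GeoJSON interchange format: takes
#' each feature's centroid (mean of the outer-ring vertices for polygons,
#' the point itself for points) and looks up measurement properties.
#'
#' @inheritParams read_detections
#' @param area_prop,hema_prop,eosin_prop property names holding the nucleus
#'   area and median stain values.
#' @return a `detection_set`.
#' @export
read_detections_geojson <- function(path, roi_bounds, pixel_size_um,
                                    scan_id = "scan", roi_id = "roi",
                                    area_prop = "area_um2",
                                    hema_prop = "hema_median",
                                    eosin_prop = "eosin_median") {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  n <- length(feats)
  if (n == 0L)
    return(detection_set(NULL, roi_bounds, pixel_size_um, scan_id, roi_id))
  x <- y <- area <- hema <- eosin <- rep(NA_real_, n)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (identical(geom$type, "Point")) {
      x[i] <- as.numeric(geom$coordinates[[1]])
      y[i] <- as.numeric(geom$coordinates[[2]])
    } else if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
      ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
      x[i] <- mean(xs); y[i] <- mean(ys)
    } else {
      stop_format("unsupported geometry type '", geom$type, "' at feature ", i)
    }
    pr <- f$properties %||% list()
    area[i] <- as.numeric(pr[[area_prop]] %||% NA_real_)
    hema[i] <- as.numeric(pr[[hema_prop]] %||% NA_real_)
    eosin[i] <- as.numeric(pr[[eosin_prop]] %||% NA_real_)
    ids[i] <- as.character(pr$id %||% f$id %||% paste0("n", i))
  }
  rec <- data.frame(id = ids, x_um = x, y_um = y, area_um2 = area,
                    hema_median = hema, eosin_median = eosin)
  detection_set(rec, roi_bounds, pixel_size_um, scan_id, roi_id)
}

#' Read scan/ROI metadata from a YAML config
#'
#' Expects keys `scan_id`, `roi_id`, `pixel_size_um` and `roi_bounds`
#' (list or vector of x_min, y_min, x_max, y_max).
#'
#' @param path YAML file path.
#' @return a named list with the four keys, bounds as a numeric vector.
#' @export
read_roi_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("scan_id", "roi_id", "pixel_size_um", "roi_bounds"))
    if (is.null(cfg[[k]])) stop_format("config key '", k, "' missing in ", path)
  cfg$roi_bounds <- as.numeric(unlist(cfg$roi_bounds))
  cfg$pixel_size_um <- as.numeric(cfg$pixel_size_um)
  cfg[c("scan_id", "roi_id", "pixel_size_um", "roi_bounds")]
}
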