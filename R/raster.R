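#' Georeferenced raster grid
#'
#' The package's universal raster currency: one or more bands of numeric
#' values on a regular north-up grid, a logical validity mask, and a simple
#' affine georeference (lower-left corner plus square pixel size, as in the
#' ESRI ASCII grid header). Row 1 is the northernmost row.
#'
#' @param values numeric matrix (single band) or 3-d array
#'   `[row, col, band]`.
#' @param pixel_size pixel edge length in metres (> 0).
#' @param xll,yll x/y coordinate of the lower-left corner of the grid.
#' @param mask logical matrix of valid pixels; defaults to `!is.na` of the
#'   first band intersected over all bands.
#' @param band_names character vector, one per band.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, pixel_size, xll = 0, yll = 0,
                        mask = NULL, band_names = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  nb <- dim(values)[3L]
  if (is.null(band_names)) band_names <- paste0("band", seq_len(nb))
  if (length(band_names) != nb) stop("band_names length must equal band count")
  if (is.null(mask)) {
    mask <- !apply(is.na(values), c(1L, 2L), any)
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(values)[1:2]))
    stop("mask must be a logical matrix matching the grid shape")
  structure(
    list(values = values, mask = mask, pixel_size = pixel_size,
         xll = xll, yll = yll, band_names = band_names),
    class = "raster_grid")
}

#' Binary habitat label raster
#'
#' A single-band `raster_grid` whose valid values are 0 (Non-PO) or 1 (PO).
#'
#' @param labels integer/numeric matrix of 0/1 (NA allowed where invalid).
#' @inheritParams raster_grid
#' @return An object of class `c("label_raster", "raster_grid")`.
#' @export
label_raster <- function(labels, pixel_size, xll = 0, yll = 0, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(labels)
  vals <- labels + 0.0  # canonical double storage
  ok <- vals[mask]
  if (length(ok) && !all(ok %in% c(0, 1)))
    stop("labels must be 0 or 1 wherever valid")
  g <- raster_grid(vals, pixel_size, xll, yll, mask, band_names = "class")
  class(g) <- c("label_raster", class(g))
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d px, %d band(s) [%s], pixel %g m, %.1f%% valid\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              paste(x$band_names, collapse = ", "),
              x$pixel_size, 100 * mean(x$mask)))
  invisible(x)
}

n_bands <- function(g) dim(g$values)[3L]

grid_dim <- function(g) dim(g$values)[1:2]

#' Extract one band of a raster as a matrix (NA where invalid)
#' @param g a `raster_grid`
#' @param band band index or name
#' @keywords internal
band_matrix <- function(g, band = 1L) {
  if (is.character(band)) band <- match(band, g$band_names)
  m <- g$values[, , band, drop = TRUE]
  if (!is.matrix(m)) m <- matrix(m, grid_dim(g)[1L], grid_dim(g)[2L])
  m[!g$mask] <- NA_real_
  m
}

# x/y coordinates of pixel centres, row 1 = north
pixel_centres <- function(g) {
  d <- grid_dim(g)
  list(x = g$xll + (seq_len(d[2L]) - 0.5) * g$pixel_size,
       y = g$yll + (d[1L] - seq_len(d[1L]) + 0.5) * g$pixel_size)
}

#' Check that two rasters live on the same grid
#' @keywords internal
stop_unless_aligned <- function(a, b, what = "rasters") {
  ok <- identical(grid_dim(a), grid_dim(b)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
  if (!ok) stop(sprintf("alignment error: %s are not on the same grid", what))
  invisible(TRUE)
}

NODATA <- -9999

#' Write a raster to disk
#'
#' Single-band grids are written as one ESRI ASCII grid (`.asc`): a
#' plain-text, GDAL-readable format carrying the georeference in its header
#' and invalid pixels as the NODATA value. Multi-band grids are written as
#' one `.asc` per band plus a small JSON manifest (`path` itself) recording
#' band order and names.
#'
#' @param g a `raster_grid` or `label_raster`.
#' @param path output path: `.asc` for single-band, `.json` manifest for
#'   multi-band.
#' @return `path`, invisibly.
#' @export
write_raster <- function(g, path) {
  stopifnot(inherits(g, "raster_grid"))
  if (n_bands(g) == 1L) {
    write_asc_band(band_matrix(g, 1L), g, path)
  } else {
    stem <- sub("\\.json$", "", path)
    files <- sprintf("%s_b%d.asc", basename(stem), seq_len(n_bands(g)))
    for (b in seq_len(n_bands(g)))
      write_asc_band(band_matrix(g, b), g, file.path(dirname(path), files[b]))
    man <- list(format = "posimap-raster", version = 1L,
                band_files = files, band_names = g$band_names,
                label_raster = inherits(g, "label_raster"))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

write_asc_band <- function(m, g, path) {
  d <- dim(m)
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\ncellsize %.17g\nNODATA_value %d",
    d[2L], d[1L], g$xll, g$yll, g$pixel_size, NODATA)
  m[is.na(m)] <- NODATA
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path an `.asc` file or a multi-band `.json` manifest.
#' @return a `raster_grid` (or `label_raster` if the manifest says so).
#' @export
read_raster <- function(path) {
  if (grepl("\\.json$", path)) {
    man <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) stop("format error: unreadable raster manifest: ",
                                             conditionMessage(e)))
    if (!identical(man$format, "posimap-raster"))
      stop("format error: not a posimap raster manifest")
    bands <- lapply(file.path(dirname(path), man$band_files), read_asc_band)
    if (length(unique(lapply(bands, function(b) dim(b$m)))) != 1L)
      stop("format error: band shapes disagree with manifest")
    if (length(man$band_names) != length(bands))
      stop("format error: band count does not match manifest metadata")
    h <- bands[[1L]]
    vals <- array(unlist(lapply(bands, `[[`, "m")),
                  c(dim(h$m), length(bands)))
    mask <- !apply(is.na(vals), c(1L, 2L), any)
    g <- raster_grid(vals, h$cellsize, h$xll, h$yll, mask, man$band_names)
    if (isTRUE(man$label_raster))
      g <- label_raster(band_matrix(g, 1L), h$cellsize, h$xll, h$yll, mask)
    g
  } else {
    h <- read_asc_band(path)
    raster_grid(h$m, h$cellsize, h$xll, h$yll)
  }
}

read_asc_band <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 7L) stop("format error: truncated ASCII grid: ", path)
  kv <- strsplit(trimws(ln[1:6]), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!identical(keys, need) || anyNA(vals))
    stop("format error: missing georeference header in ", path)
  nc <- as.integer(vals[1L]); nr <- as.integer(vals[2L])
  body <- scan(text = ln[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc)
    stop("format error: cell count mismatch in ", path)
  m <- matrix(body, nr, nc, byrow = TRUE)
  m[m == vals[6L]] <- NA_real_
  list(m = m, xll = vals[3L], yll = vals[4L], cellsize = vals[5L])
}

#' Read a binary label map from an `.asc` file
#' @inheritParams read_raster
#' @return a `label_raster`
#' @export
read_label_raster <- function(path) {
  g <- read_raster(path)
  if (inherits(g, "label_raster")) return(g)
  label_raster(band_matrix(g, 1L), g$pixel_size, g$xll, g$yll, g$mask)
}

#' Ordered multi-date collection of scenes on one grid
#'
#' @param scenes list of multi-band `raster_grid`s sharing grid, pixel size
#'   and band order.
#' @param dates character identifiers, one per scene.
#' @return An object of class `scene_stack`.
#' @export
scene_stack <- function(scenes, dates = NULL) {
  if (length(scenes) < 1L) stop("a scene stack needs at least one scene")
  if (is.null(dates)) dates <- sprintf("date%02d", seq_along(scenes))
  stopifnot(length(dates) == length(scenes))
  for (s in scenes[-1L]) {
    stop_unless_aligned(scenes[[1L]], s, "scenes in a stack")
    if (!identical(scenes[[1L]]$band_names, s$band_names))
      stop("alignment error: band order differs across dates")
  }
  structure(list(scenes = scenes, dates = as.character(dates)),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack> %d date(s): %s\n", length(x$scenes),
              paste(x$dates, collapse = ", ")))
  print(x$scenes[[1L]])
  invisible(x)
}
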