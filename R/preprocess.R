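#' Screen a per-year archive for unusable dates
#'
#' Automated stand-in for visual quality control: a date is kept when its
#' no-data (cloud) fraction is at most `max_masked_fraction` and each of its
#' per-band spatial means lies within `band_anomaly_z` robust z-scores
#' (median / 1.4826*MAD across dates) of the archive-wide median of date
#' means. Every rejection is reported with its reason.
#'
#' @param stack a `scene_stack`.
#' @param max_masked_fraction maximum tolerated invalid-pixel fraction.
#' @param band_anomaly_z robust z-score cut for per-band date means.
#' @return the retained `scene_stack` (subset of dates, original order).
#' @export
screen_images <- function(stack, max_masked_fraction = 0.3,
                          band_anomaly_z = 3.0) {
  stopifnot(inherits(stack, "scene_stack"))
  nd <- length(stack$scenes)
  masked <- vapply(stack$scenes, function(s) mean(!s$mask), 0)
  nb <- n_bands(stack$scenes[[1L]])
  means <- t(vapply(stack$scenes, function(s)
    vapply(seq_len(nb), function(b) mean(band_matrix(s, b), na.rm = TRUE), 0),
    numeric(nb)))
  med <- apply(means, 2L, stats::median)
  mad <- apply(means, 2L, stats::mad)  # 1.4826 * median abs deviation
  dev <- abs(sweep(means, 2L, med))
  z <- sweep(dev, 2L, mad, `/`)  # mad = 0, dev > 0 -> Inf (always anomalous)
  z[dev == 0] <- 0
  keep <- rep(TRUE, nd)
  for (i in seq_len(nd)) {
    if (masked[i] > max_masked_fraction) {
      keep[i] <- FALSE
      message(sprintf("screen: dropping %s (masked fraction %.2f > %.2f)",
                      stack$dates[i], masked[i], max_masked_fraction))
    } else if (any(z[i, ] > band_anomaly_z)) {
      keep[i] <- FALSE
      message(sprintf("screen: dropping %s (band-mean robust z %.1f > %.1f)",
                      stack$dates[i], max(z[i, ]), band_anomaly_z))
    }
  }
  if (!any(keep))
    stop(sprintf(paste0("empty archive: all %d dates rejected at ",
                        "max_masked_fraction=%.2f, band_anomaly_z=%.1f"),
                 nd, max_masked_fraction, band_anomaly_z))
  scene_stack(stack$scenes[keep], stack$dates[keep])
}

#' Median-stack a multi-date archive into a yearly composite
#'
#' Per pixel and band, the median over the dates where the pixel is valid;
#' an even count of observations takes the midpoint of the two central
#' values. Pixels observed fewer than `min_valid` times become invalid.
#' Median compositing suppresses transient artifacts — boats, swell, residual
#' glint — that survive per-date masking.
#'
#' @param stack a `scene_stack`.
#' @param min_valid minimum number of valid observations per pixel
#'   (default 3, the usual minimum archive depth per year).
#' @return multi-band composite `raster_grid`.
#' @export
median_stack <- function(stack, min_valid = 3L) {
  stopifnot(inherits(stack, "scene_stack"), min_valid >= 1L)
  scenes <- stack$scenes
  d <- grid_dim(scenes[[1L]])
  nb <- n_bands(scenes[[1L]])
  nvalid <- Reduce(`+`, lapply(scenes, function(s) s$mask + 0L))
  mask <- nvalid >= min_valid
  vals <- array(NA_real_, c(d, nb))
  for (b in seq_len(nb)) {
    obs <- vapply(scenes, function(s) band_matrix(s, b), matrix(0, d[1L], d[2L]))
    obs <- matrix(obs, nrow = prod(d))        # pixels x dates
    med <- apply(obs, 1L, stats::median, na.rm = TRUE)
    med[!mask] <- NA_real_
    vals[, , b] <- med
  }
  g <- scenes[[1L]]
  raster_grid(vals, g$pixel_size, g$xll, g$yll, mask, g$band_names)
}

#' Resample coarse bathymetry onto the analysis grid
#'
#' Bilinear interpolation of the four nearest coarse-cell centres (via
#' [pracma::interp2()]) at each fine pixel centre; fine pixels outside the
#' coarse centre extent, or touching invalid coarse cells, become invalid.
#'
#' @param bathy coarse single-band depth `raster_grid`.
#' @param target `raster_grid` defining the output grid.
#' @return depth `raster_grid` on the target grid.
#' @export
resample_bathymetry <- function(bathy, target) {
  cc <- pixel_centres(bathy)
  tc <- pixel_centres(target)
  if (max(tc$x) < min(cc$x) || min(tc$x) > max(cc$x) ||
      max(tc$y) < min(cc$y) || min(tc$y) > max(cc$y))
    stop("coverage error: bathymetry extent is disjoint from the target grid")
  # interp2 wants ascending axes; our y runs north->south
  Z <- band_matrix(bathy, 1L)
  yc <- rev(cc$y)
  Z <- Z[nrow(Z):1, , drop = FALSE]
  d <- grid_dim(target)
  xp <- rep(tc$x, each = d[1L])
  yp <- rep(tc$y, d[2L])
  inx <- xp >= min(cc$x) & xp <= max(cc$x) & yp >= min(yc) & yp <= max(yc)
  out <- rep(NA_real_, length(xp))
  if (any(inx))
    out[inx] <- pracma::interp2(cc$x, yc, Z, xp[inx], yp[inx], method = "linear")
  m <- matrix(out, d[1L], d[2L])
  raster_grid(m, target$pixel_size, target$xll, target$yll,
              band_names = "depth_m")
}

#' Crop a raster beyond the seagrass depth limit
#'
#' Marks invalid every pixel whose depth exceeds `max_depth` (exactly
#' `max_depth` is retained) or whose depth is unknown; open- and deep-ocean
#' pixels are spectrally confusable with seagrass and are removed before
#' classification.
#'
#' @param grid raster to crop (any `raster_grid` or `label_raster`).
#' @param bathy depth `raster_grid` on the same grid (positive-down metres).
#' @param max_depth depth limit in metres (default 40).
#' @return `grid` with the deep pixels invalidated.
#' @export
apply_depth_mask <- function(grid, bathy, max_depth = 40) {
  stop_unless_aligned(grid, bathy, "grid and bathymetry")
  depth <- band_matrix(bathy, 1L)
  keep <- !is.na(depth) & depth <= max_depth
  mask <- grid$mask & keep
  vals <- grid$values
  for (b in seq_len(n_bands(grid))) {
    m <- vals[, , b]; m[!mask] <- NA_real_; vals[, , b] <- m
  }
  out <- grid
  out$values <- vals
  out$mask <- mask
  out
}

#' Read habitat polygons from a GeoJSON file
#'
#' Supports Feature/FeatureCollection of Polygon and MultiPolygon
#' geometries; the habitat class is read from `property`.
#'
#' @param path `.geojson`/`.json` file.
#' @param property name of the class property (default "habitat").
#' @return list of `list(class=, rings=)`, rings being x/y matrices.
#' @export
read_habitat_geojson <- function(path, property = "habitat") {
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("format error: unreadable GeoJSON: ",
                                          conditionMessage(e)))
  feats <- switch(gj$type %||% "",
                  FeatureCollection = gj$features,
                  Feature = list(gj),
                  stop("format error: not a GeoJSON Feature/FeatureCollection"))
  lapply(feats, function(f) {
    cls <- f$properties[[property]]
    if (is.null(cls)) stop("classification-schema error: feature without a '",
                           property, "' property")
    geom <- f$geometry
    rings <- switch(geom$type,
                    Polygon = geom$coordinates,
                    MultiPolygon = do.call(c, geom$coordinates),
                    stop("format error: unsupported geometry type ", geom$type))
    rings <- lapply(rings, function(r)
      matrix(unlist(r), ncol = 2L, byrow = TRUE))
    list(class = as.character(cls), rings = rings)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# even-odd ray-casting containment of points in one polygon (all rings,
# so interior rings act as holes); boundary treatment follows the parity rule
points_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    x <- r[, 1L]; y <- r[, 2L]
    n <- length(x)
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

#' Rasterize habitat polygons into binary training labels
#'
#' A pixel takes the class of the polygon containing its centre; classes
#' are mapped to 1 (PO) / 0 (Non-PO) through `class_map`. When overlapping
#' polygons claim one centre, the last-listed polygon wins (warned). Pixel
#' centres covered by no polygon are invalid — unknown ground, excluded from
#' training and accuracy but still predicted.
#'
#' @param polygons list from [read_habitat_geojson()] (or built in code).
#' @param target `raster_grid` defining the output grid.
#' @param class_map named numeric vector mapping habitat strings to 1/0,
#'   e.g. `c("PO" = 1, "sand" = 0)`. A class absent from the map is an
#'   error naming it.
#' @return a `label_raster`.
#' @export
rasterize_habitat <- function(polygons, target,
                              class_map = c("PO" = 1, "Non-PO" = 0)) {
  d <- grid_dim(target)
  tc <- pixel_centres(target)
  px <- rep(tc$x, each = d[1L])
  py <- rep(tc$y, d[2L])
  lab <- rep(NA_real_, length(px))
  overlaps <- 0L
  for (pg in polygons) {
    if (!pg$class %in% names(class_map))
      stop("classification-schema error: unmapped habitat class '",
           pg$class, "'")
    hit <- points_in_polygon(px, py, pg$rings)
    overlaps <- overlaps + sum(hit & !is.na(lab) &
                                 lab != class_map[[pg$class]])
    lab[hit] <- class_map[[pg$class]]
  }
  if (overlaps > 0L)
    warning(sprintf("rasterize: %d pixel(s) claimed by conflicting polygons; last listed wins",
                    overlaps))
  label_raster(matrix(lab, d[1L], d[2L]), target$pixel_size,
               target$xll, target$yll)
}

#' Build the per-pixel feature table
#'
#' One row per pixel valid in the composite AND the bathymetry (AND the
#' labels, when given): features blue, green, red reflectance and depth,
#' plus the (row, col) pixel index for map reconstruction. Per-feature mean
#' and standard deviation over the table are stored as the `scaling`
#' attribute, for z-score standardization at training time.
#'
#' @param composite multi-band `raster_grid` (first three bands are taken as
#'   blue, green, red).
#' @param bathy depth `raster_grid` on the same grid.
#' @param labels optional `label_raster`; adds a `label` column and
#'   restricts rows to labelled pixels.
#' @return a `data.frame` of class `feature_table` with columns
#'   `blue, green, red, depth[, label], row, col`.
#' @export
build_feature_table <- function(composite, bathy, labels = NULL) {
  stop_unless_aligned(composite, bathy, "composite and bathymetry")
  if (n_bands(composite) < 3L) stop("composite needs at least 3 bands")
  mask <- composite$mask & bathy$mask
  if (!is.null(labels)) {
    stop_unless_aligned(composite, labels, "composite and labels")
    mask <- mask & labels$mask
  }
  if (!any(mask)) stop("empty-table error: no co-valid pixels")
  idx <- which(mask, arr.ind = TRUE)
  tab <- data.frame(blue = band_matrix(composite, 1L)[mask],
                    green = band_matrix(composite, 2L)[mask],
                    red = band_matrix(composite, 3L)[mask],
                    depth = band_matrix(bathy, 1L)[mask])
  if (!is.null(labels)) tab$label <- as.integer(band_matrix(labels, 1L)[mask])
  tab$row <- idx[, 1L]
  tab$col <- idx[, 2L]
  feats <- c("blue", "green", "red", "depth")
  attr(tab, "scaling") <- list(
    mean = vapply(tab[feats], mean, 0),
    sd = vapply(tab[feats], function(v) {
      s <- stats::sd(v); if (is.na(s) || s == 0) 1 else s
    }, 0))
  class(tab) <- c("feature_table", class(tab))
  tab
}
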