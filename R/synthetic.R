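#' Optical parameters of the synthetic shallow-water scene
#'
#' Per-band (blue, green, red) parameters of the two-flow exponential
#' reflectance model used by [simulate_reflectance()]. The defaults are
#' synthetic choices — dark green-brown seagrass canopy over a bright
#' sand/rock background, clear oligotrophic Mediterranean-like attenuation —
#' not calibrated constants.
#'
#' @param bottom_albedo_po per-band bottom reflectance of a *P. oceanica*
#'   canopy, unitless in \[0, 1\].
#' @param bottom_albedo_other per-band bottom reflectance of sand/rock.
#' @param deep_water_reflectance per-band asymptotic reflectance over
#'   optically deep water.
#' @param attenuation per-band effective diffuse attenuation coefficient
#'   (1/m), strictly positive.
#' @param noise_sd per-band additive Gaussian noise standard deviation.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(bottom_albedo_po = c(0.030, 0.060, 0.030),
                          bottom_albedo_other = c(0.200, 0.250, 0.220),
                          deep_water_reflectance = c(0.020, 0.010, 0.005),
                          attenuation = c(0.040, 0.060, 0.300),
                          noise_sd = c(0.005, 0.005, 0.005)) {
  p <- list(bottom_albedo_po = bottom_albedo_po,
            bottom_albedo_other = bottom_albedo_other,
            deep_water_reflectance = deep_water_reflectance,
            attenuation = attenuation,
            noise_sd = rep_len(noise_sd, length(attenuation)))
  refl <- c(p$bottom_albedo_po, p$bottom_albedo_other, p$deep_water_reflectance)
  if (any(refl < 0 | refl > 1)) stop("reflectances must lie in [0, 1]")
  if (any(p$attenuation <= 0)) stop("attenuation must be strictly positive")
  if (any(p$noise_sd < 0)) stop("noise_sd must be non-negative")
  if (all(p$bottom_albedo_po == p$bottom_albedo_other))
    stop("PO and non-PO albedo must differ in at least one band")
  nb <- lengths(p)
  if (length(unique(nb)) != 1L) stop("all optics fields need one value per band")
  structure(p, class = "optics_params")
}

#' Transient-artifact model for the synthetic image archive
#'
#' @param boat_rate expected fraction of pixels per date struck by a bright
#'   single-pixel transient (a boat).
#' @param swell_amplitude amplitude of additive sinusoidal stripe noise
#'   applied to a random subset of dates.
#' @param cloud_fraction expected no-data fraction per date (rectangular
#'   cloud patches).
#' @param seasonal_amplitude amplitude of the date-level additive spectral
#'   offset mimicking seasonal algal variation.
#' @param seed integer RNG seed for the artifact draws.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(boat_rate = 0.002, swell_amplitude = 0.01,
                          cloud_fraction = 0.10, seasonal_amplitude = 0.01,
                          seed = 1L) {
  rates <- c(boat_rate, cloud_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates/fractions must lie in [0, 1]")
  if (swell_amplitude < 0 || seasonal_amplitude < 0)
    stop("amplitudes must be non-negative")
  structure(list(boat_rate = boat_rate, swell_amplitude = swell_amplitude,
                 cloud_fraction = cloud_fraction,
                 seasonal_amplitude = seasonal_amplitude,
                 seed = as.integer(seed)),
            class = "artifact_spec")
}

# smooth low-frequency random field: sum of a few random plane sinusoids,
# unit-ish amplitude; wavelength controlled by `scale` (pixels)
smooth_field <- function(nr, nc, scale, n_waves = 6L) {
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), nc), nr, nc)
  f <- matrix(0, nr, nc)
  for (k in seq_len(n_waves)) {
    theta <- stats::runif(1L, 0, 2 * pi)
    wl <- scale * stats::runif(1L, 0.7, 1.6)
    phase <- stats::runif(1L, 0, 2 * pi)
    f <- f + stats::rnorm(1L, 0, 1) *
      sin(2 * pi * (x * cos(theta) + y * sin(theta)) / wl + phase)
  }
  f / sqrt(n_waves)
}

#' Generate a synthetic bathymetry grid
#'
#' A smooth shore-to-deep depth gradient (shore on the western, column-1
#' edge) plus a low-frequency random perturbation. Depth is positive-down in
#' metres, in (0, `max_depth`].
#'
#' @param width,height grid size in pixels (>= 8).
#' @param max_depth maximum depth in metres (> 0).
#' @param pixel_size pixel edge length in metres.
#' @param seed integer seed; equal seeds give bit-identical grids.
#' @return single-band `raster_grid` of depths.
#' @export
generate_bathymetry <- function(width, height, max_depth = 50, pixel_size = 10,
                                seed = 1L) {
  if (width < 8 || height < 8) stop("width and height must be at least 8 pixels")
  if (max_depth <= 0) stop("max_depth must be positive")
  withr::with_seed(as.integer(seed), {
    ramp <- 0.02 + 0.98 * (seq_len(width) - 0.5) / width
    base <- matrix(rep(ramp, each = height), height, width) * max_depth
    pert <- smooth_field(height, width, scale = max(width, height) / 2) *
      0.04 * max_depth
    depth <- pmin(pmax(base + pert, 1e-3), max_depth)
    raster_grid(depth, pixel_size, band_names = "depth_m")
  })
}

#' Generate a synthetic binary habitat-truth map
#'
#' Thresholds a smooth random field so that contiguous blob-shaped seagrass
#' patches cover approximately `cover_fraction` of the zone shallower than
#' `depth_limit`; no seagrass is ever placed deeper than `depth_limit`.
#'
#' @param bathymetry depth `raster_grid` from [generate_bathymetry()].
#' @param cover_fraction target PO fraction of the shallow zone, in (0, 1).
#' @param patch_scale characteristic patch size in pixels.
#' @param depth_limit deepest depth (m) at which seagrass may occur.
#' @param seed integer seed.
#' @return a `label_raster` (1 = PO, 0 = Non-PO).
#' @export
generate_habitat_map <- function(bathymetry, cover_fraction = 0.35,
                                 patch_scale = 24, depth_limit = 40,
                                 seed = 1L) {
  if (cover_fraction <= 0 || cover_fraction >= 1)
    stop("cover_fraction must lie strictly inside (0, 1)")
  d <- grid_dim(bathymetry)
  depth <- band_matrix(bathymetry, 1L)
  withr::with_seed(as.integer(seed), {
    f <- smooth_field(d[1L], d[2L], scale = patch_scale)
    shallow <- !is.na(depth) & depth <= depth_limit
    # quantile threshold inside the shallow zone pins the realized fraction
    thr <- stats::quantile(f[shallow], 1 - cover_fraction, names = FALSE)
    lab <- matrix(0, d[1L], d[2L])
    lab[shallow & f > thr] <- 1
    lab[is.na(depth)] <- NA
    label_raster(lab, bathymetry$pixel_size, bathymetry$xll, bathymetry$yll)
  })
}

#' Simulate surface reflectance over a mapped bottom
#'
#' Two-flow exponential shallow-water model: per band with bottom albedo A,
#' deep-water reflectance R_inf, attenuation K and depth z,
#' `R = R_inf + (A - R_inf) * exp(-2 K z) + noise`, clipped to \[0, 1\].
#'
#' @param habitat `label_raster` of bottom type (1 = PO albedo, 0 = other).
#' @param bathymetry depth `raster_grid` on the same grid.
#' @param optics an [optics_params()] object.
#' @param seed integer seed for the noise draw.
#' @return 3-band `raster_grid` (blue, green, red).
#' @export
simulate_reflectance <- function(habitat, bathymetry, optics = optics_params(),
                                 seed = 1L) {
  stop_unless_aligned(habitat, bathymetry, "habitat and bathymetry")
  d <- grid_dim(habitat)
  z <- band_matrix(bathymetry, 1L)
  lab <- band_matrix(habitat, 1L)
  nb <- length(optics$attenuation)
  vals <- array(NA_real_, c(d, nb))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(nb)) {
      A <- ifelse(lab == 1, optics$bottom_albedo_po[b],
                  optics$bottom_albedo_other[b])
      r <- optics$deep_water_reflectance[b] +
        (A - optics$deep_water_reflectance[b]) *
        exp(-2 * optics$attenuation[b] * z)
      if (optics$noise_sd[b] > 0)
        r <- r + matrix(stats::rnorm(prod(d), 0, optics$noise_sd[b]), d[1L], d[2L])
      vals[, , b] <- pmin(pmax(r, 0), 1)
    }
  })
  mask <- habitat$mask & bathymetry$mask
  for (b in seq_len(nb)) {
    m <- vals[, , b]; m[!mask] <- NA_real_; vals[, , b] <- m
  }
  raster_grid(vals, habitat$pixel_size, habitat$xll, habitat$yll, mask,
              band_names = c("blue", "green", "red")[seq_len(nb)])
}

#' Simulate a multi-date image archive with transient artifacts
#'
#' Each date is a [simulate_reflectance()] draw plus, per the artifact spec:
#' independently placed single-pixel bright outliers (boats), optional
#' additive sinusoidal swell stripes at a random angle on a random subset of
#' dates, a date-level additive spectral offset (seasonality), and
#' rectangular cloud patches recorded as no-data in the validity mask.
#' Bit-reproducible given `artifacts$seed`.
#'
#' @inheritParams simulate_reflectance
#' @param artifacts an [artifact_spec()].
#' @param n_dates number of acquisition dates (1–50).
#' @return a `scene_stack`.
#' @export
simulate_time_series <- function(habitat, bathymetry, optics = optics_params(),
                                 artifacts = artifact_spec(), n_dates = 6L) {
  if (n_dates < 1 || n_dates > 50) stop("n_dates must lie in [1, 50]")
  stop_unless_aligned(habitat, bathymetry, "habitat and bathymetry")
  d <- grid_dim(habitat)
  npx <- prod(d)
  scenes <- withr::with_seed(artifacts$seed, {
    lapply(seq_len(n_dates), function(t) {
      sc <- simulate_reflectance(habitat, bathymetry, optics,
                                 seed = sample.int(.Machine$integer.max, 1L))
      vals <- sc$values
      mask <- sc$mask
      # seasonal per-band offset, uniform in +-amplitude
      if (artifacts$seasonal_amplitude > 0) {
        off <- stats::runif(n_bands(sc), -artifacts$seasonal_amplitude,
                            artifacts$seasonal_amplitude)
        for (b in seq_len(n_bands(sc))) vals[, , b] <- vals[, , b] + off[b]
      }
      # swell stripes on roughly half the dates
      if (artifacts$swell_amplitude > 0 && stats::runif(1L) < 0.5) {
        theta <- stats::runif(1L, 0, pi)
        wl <- stats::runif(1L, 8, 24)
        x <- matrix(rep(seq_len(d[2L]), each = d[1L]), d[1L], d[2L])
        y <- matrix(rep(seq_len(d[1L]), d[2L]), d[1L], d[2L])
        stripe <- artifacts$swell_amplitude *
          sin(2 * pi * (x * cos(theta) + y * sin(theta)) / wl)
        for (b in seq_len(n_bands(sc))) vals[, , b] <- vals[, , b] + stripe
      }
      # boats: isolated bright outliers
      if (artifacts$boat_rate > 0) {
        n_boat <- stats::rbinom(1L, npx, artifacts$boat_rate)
        if (n_boat > 0) {
          idx <- sample.int(npx, n_boat)
          for (b in seq_len(n_bands(sc))) {
            m <- vals[, , b]; m[idx] <- 0.9; vals[, , b] <- m
          }
        }
      }
      # clouds: one rectangular no-data patch of ~cloud_fraction area
      if (artifacts$cloud_fraction > 0) {
        target <- artifacts$cloud_fraction * npx
        h <- min(d[1L], max(2L, round(sqrt(target * stats::runif(1L, 0.6, 1.6)))))
        w <- min(d[2L], max(2L, round(target / h)))
        r0 <- sample.int(max(1L, d[1L] - h + 1L), 1L)
        c0 <- sample.int(max(1L, d[2L] - w + 1L), 1L)
        mask[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- FALSE
      }
      for (b in seq_len(n_bands(sc))) {
        m <- pmin(pmax(vals[, , b], 0), 1)
        m[!mask] <- NA_real_
        vals[, , b] <- m
      }
      raster_grid(vals, sc$pixel_size, sc$xll, sc$yll, mask, sc$band_names)
    })
  })
  scene_stack(scenes)
}

#' Write a habitat label raster as GeoJSON polygons
#'
#' Exports the PO class as rectangular run-length polygons (one per maximal
#' horizontal run of PO pixels), each carrying a `habitat` property. Meant
#' to exercise the polygon rasterizer round-trip; not a cartographic product.
#'
#' @param habitat a `label_raster`.
#' @param path output `.geojson` path.
#' @param po_class,nonpo_class habitat strings written for PO runs and for
#'   the background rectangle.
#' @return `path`, invisibly.
#' @export
write_habitat_geojson <- function(habitat, path, po_class = "PO",
                                  nonpo_class = "Non-PO") {
  d <- grid_dim(habitat)
  px <- habitat$pixel_size
  lab <- band_matrix(habitat, 1L)
  feats <- list()
  # background rectangle first: overlapping PO runs are listed later and win
  xmax <- habitat$xll + d[2L] * px
  ymax <- habitat$yll + d[1L] * px
  feats[[1L]] <- geojson_rect(habitat$xll, habitat$yll, xmax, ymax, nonpo_class)
  for (r in seq_len(d[1L])) {
    v <- lab[r, ]
    v[is.na(v)] <- 0
    runs <- rle(v)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values == 1)) {
      x0 <- habitat$xll + (starts[k] - 1L) * px
      x1 <- habitat$xll + ends[k] * px
      y1 <- habitat$yll + (d[1L] - r + 1L) * px
      y0 <- y1 - px
      feats[[length(feats) + 1L]] <- geojson_rect(x0, y0, x1, y1, po_class)
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

geojson_rect <- function(x0, y0, x1, y1, cls) {
  ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
  list(type = "Feature",
       properties = list(habitat = cls),
       geometry = list(type = "Polygon", coordinates = list(ring)))
}
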