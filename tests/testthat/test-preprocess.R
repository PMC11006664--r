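make_scene <- function(vals3, px = 10, mask = NULL) {
  raster_grid(vals3, px, mask = mask, band_names = c("blue", "green", "red"))
}

const_stack <- function(n, value = 0.1, nr = 6, nc = 6) {
  scene_stack(replicate(n, make_scene(array(value, c(nr, nc, 3))),
                        simplify = FALSE))
}

test_that("screening keeps clean dates and drops cloudy or anomalous ones", {
  expect_length(screen_images(const_stack(5), 0.3, 3.0)$scenes, 5L)
  # one date half-masked
  scenes <- const_stack(5)$scenes
  m <- matrix(TRUE, 6, 6); m[1:3, ] <- FALSE
  v <- array(0.1, c(6, 6, 3)); v[rep(!m, 3)] <- NA
  scenes[[3]] <- make_scene(v, mask = m)
  expect_message(kept <- screen_images(scene_stack(scenes), 0.3, 3.0),
                 "masked fraction")
  expect_length(kept$scenes, 4L)
  # one date with a wildly bright band mean
  scenes2 <- const_stack(7)$scenes
  scenes2[[2]] <- make_scene(array(c(0.9, 0.1, 0.1)[rep(1:3, each = 36)],
                                   c(6, 6, 3)))
  expect_message(kept2 <- screen_images(scene_stack(scenes2), 0.3, 3.0),
                 "robust z")
  expect_length(kept2$scenes, 6L)
  # singleton archive passes through
  expect_length(screen_images(const_stack(1), 0.3, 3.0)$scenes, 1L)
  # everything rejected is a loud error
  all_mask <- matrix(FALSE, 6, 6)
  bad <- make_scene(array(NA_real_, c(6, 6, 3)), mask = all_mask)
  expect_error(screen_images(scene_stack(list(bad)), 0.3, 3.0),
               "empty archive")
})

test_that("median stacking takes per-pixel medians, midpoints, and min_valid", {
  expect_equal(median_stack(const_stack(5, 0.1), 3)$values[2, 2, 1], 0.1)
  # boat outlier in one of five dates is ignored by the median
  vals <- c(0.10, 0.11, 0.12, 0.11, 0.90)
  scenes <- lapply(vals, function(v) make_scene(array(v, c(4, 4, 3))))
  expect_equal(median_stack(scene_stack(scenes), 3)$values[1, 1, 1], 0.11)
  # even count -> midpoint of the two central values
  scenes2 <- lapply(c(0.10, 0.20), function(v) make_scene(array(v, c(4, 4, 3))))
  comp2 <- median_stack(scene_stack(scenes2), 2)
  expect_equal(comp2$values[3, 3, 2], 0.15)
  # pixels with fewer than min_valid observations become invalid
  m <- matrix(TRUE, 4, 4); m[1, 1] <- FALSE
  v <- array(0.2, c(4, 4, 3)); v[1, 1, ] <- NA
  holey <- make_scene(v, mask = m)
  comp3 <- median_stack(scene_stack(list(holey, holey, holey,
                                         make_scene(array(0.2, c(4, 4, 3))))),
                        min_valid = 2)
  expect_false(comp3$mask[1, 1])
  expect_true(comp3$mask[2, 2])
})

test_that("median stacking resists corruption of any strict minority of dates", {
  withr::with_seed(31, {
    base <- matrix(runif(64, 0, 0.3), 8, 8)
    clean <- scene_stack(replicate(5, make_scene(array(base, c(8, 8, 3))),
                                   simplify = FALSE))
    dirty_scenes <- clean$scenes
    for (k in 1:2) {  # corrupt 2 of 5 dates with arbitrary junk
      v <- array(base, c(8, 8, 3))
      hit <- sample(64, 20)
      for (b in 1:3) {
        mb <- v[, , b]; mb[hit] <- runif(20, 0.5, 1); v[, , b] <- mb
      }
      dirty_scenes[[k]] <- make_scene(v)
    }
    expect_identical(median_stack(scene_stack(dirty_scenes), 3)$values,
                     median_stack(clean, 3)$values)
  })
})

test_that("bilinear bathymetry resampling matches hand-evaluated cases", {
  fine <- raster_grid(matrix(0, 10, 10), 10)          # 100 m x 100 m extent
  coarse_const <- raster_grid(matrix(20, 3, 3), 50)   # 150 m coarse cells
  r <- resample_bathymetry(coarse_const, fine)
  expect_true(all(abs(r$values[r$mask] - 20) < 1e-12))
  # coarse 2x2, 25 m cells: west column 10 m deep, east column 30 m deep;
  # coarse centres sit at x = 12.5, 37.5 and y = 12.5, 37.5
  coarse <- raster_grid(matrix(c(10, 10, 30, 30), 2, 2), 25)
  fine_node <- raster_grid(matrix(0, 10, 10), 5)
  rn <- resample_bathymetry(coarse, fine_node)
  # fine pixel (8, 3) is centred exactly on the coarse node (12.5, 12.5)
  expect_equal(rn$values[8, 3, 1], 10, tolerance = 1e-12)
  expect_equal(rn$values[8, 8, 1], 30, tolerance = 1e-12)
  # fine pixel centred midway between the 10 m and 30 m centres along x
  fine_mid <- raster_grid(matrix(0, 5, 5), 10)
  rm <- resample_bathymetry(coarse, fine_mid)
  expect_equal(rm$values[3, 3, 1], 20, tolerance = 1e-12)
  # out-of-extent fine pixels are invalid
  expect_false(all(rn$mask))
  expect_true(rn$mask[8, 3])
  expect_error(resample_bathymetry(raster_grid(matrix(1, 2, 2), 50,
                                               xll = 1e6, yll = 1e6), fine),
               "coverage error")
})

test_that("depth crop is inclusive at the limit, idempotent, and total", {
  depth <- matrix(c(45, 40, 39.9, 20, NA, 5), 2, 3)
  bathy <- raster_grid(depth, 10, band_names = "depth_m")
  g <- make_scene(array(0.1, c(2, 3, 3)))
  out <- apply_depth_mask(g, bathy, 40)
  expect_false(out$mask[1, 1])      # 45 m: beyond the limit
  expect_true(out$mask[2, 1])       # 40 m exactly: retained
  expect_false(out$mask[1, 3])      # unknown depth: removed
  expect_identical(apply_depth_mask(out, bathy, 40)$values, out$values)
  # uniform shallow field is untouched
  shallow <- flat_bathy(2, 3, 20)
  expect_identical(apply_depth_mask(g, shallow, 40)$values, g$values)
  expect_error(apply_depth_mask(g, flat_bathy(5, 5, 20), 40), "alignment")
})

test_that("rasterization burns polygons by pixel-centre containment", {
  target <- raster_grid(matrix(0, 8, 8), 10)  # 80 m x 80 m, centres at 5,15,..
  sq <- list(class = "PO",
             rings = list(matrix(c(20, 20, 50, 20, 50, 50, 20, 50, 20, 20),
                                 ncol = 2, byrow = TRUE)))
  lab <- rasterize_habitat(list(sq), target)
  # 3x3 block of pixel centres inside [20,50]^2; everything else unknown
  expect_identical(sum(lab$values == 1, na.rm = TRUE), 9L)
  expect_identical(sum(lab$mask), 9L)
  # overlap: last-listed polygon wins, with a warning
  sq0 <- list(class = "Non-PO", rings = sq$rings)
  expect_warning(lab2 <- rasterize_habitat(list(sq, sq0), target),
                 "conflicting")
  expect_identical(sum(lab2$values == 1, na.rm = TRUE), 0L)
  expect_identical(sum(lab2$values == 0, na.rm = TRUE), 9L)
  expect_error(rasterize_habitat(list(list(class = "kelp", rings = sq$rings)),
                                 target),
               "kelp")
})

test_that("circle rasterization equals the exhaustive pixel-centre oracle", {
  target <- raster_grid(matrix(0, 12, 12), 10)
  theta <- seq(0, 2 * pi, length.out = 100)
  cx <- 60; cy <- 60; radius <- 25
  ring <- cbind(cx + radius * cos(theta), cy + radius * sin(theta))
  circ <- list(class = "PO", rings = list(ring))
  lab <- rasterize_habitat(list(circ), target)
  centres <- expand.grid(x = seq(5, 115, 10), y = seq(5, 115, 10))
  inside <- (centres$x - cx)^2 + (centres$y - cy)^2 <= radius^2
  expect_identical(sum(lab$values == 1, na.rm = TRUE), sum(inside))
})

test_that("feature tables intersect masks and round-trip pixel indices", {
  comp <- make_scene(array(runif(4 * 4 * 3), c(4, 4, 3)))
  bathy <- flat_bathy(4, 4, 20)
  tab <- build_feature_table(comp, bathy)
  expect_identical(nrow(tab), 16L)
  expect_named(attr(tab, "scaling")$mean, c("blue", "green", "red", "depth"))
  # 3 depth-invalid pixels drop 3 rows
  d <- matrix(20, 4, 4); d[1, 1] <- NA; d[2, 2] <- NA; d[4, 4] <- NA
  tab2 <- build_feature_table(comp, raster_grid(d, 10, band_names = "depth_m"))
  expect_identical(nrow(tab2), 13L)
  # labels: rebuild the raster from (index, label) and compare
  lab <- random_label(4, 4, seed = 8)
  tab3 <- build_feature_table(comp, bathy, lab)
  rebuilt <- matrix(NA_real_, 4, 4)
  rebuilt[cbind(tab3$row, tab3$col)] <- tab3$label
  expect_identical(rebuilt, lab$values[, , 1])
  empty <- raster_grid(matrix(NA_real_, 4, 4), 10)
  expect_error(build_feature_table(comp, empty), "empty-table")
})
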