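#' Integer codes of the change-map categories
#' @export
CHANGE_CODES <- c(unknown = 0L, no_change = 1L, gain = 2L, loss = 3L)

#' Meadow change between two yearly maps
#'
#' Compares an earlier and a later binary map pixel by pixel: gain where
#' Non-PO became PO, loss where PO became Non-PO, no-change where the
#' classes agree, unknown where either year is invalid. Areas are pixel
#' counts times `pixel_size^2 / 1e6` km².
#'
#' @param map_a earlier-year `label_raster`.
#' @param map_b later-year `label_raster` on the same grid.
#' @return list with `change_map` (categorical raster coded as
#'   [CHANGE_CODES]), counts, and `gained_area`, `lost_area`, `net_area`
#'   in km².
#' @export
pairwise_change <- function(map_a, map_b) {
  stop_unless_aligned(map_a, map_b, "the two yearly maps")
  a <- band_matrix(map_a, 1L)
  b <- band_matrix(map_b, 1L)
  d <- dim(a)
  code <- matrix(CHANGE_CODES[["unknown"]], d[1L], d[2L])
  ok <- !is.na(a) & !is.na(b)
  code[ok & a == b] <- CHANGE_CODES[["no_change"]]
  code[ok & a == 0 & b == 1] <- CHANGE_CODES[["gain"]]
  code[ok & a == 1 & b == 0] <- CHANGE_CODES[["loss"]]
  # area = count * px^2 / 1e6 in this order: integer-valued doubles divide
  # exactly, so constructed counts give exact km2
  area_km2 <- function(count) count * map_a$pixel_size^2 / 1e6
  n_gain <- sum(code == CHANGE_CODES[["gain"]])
  n_loss <- sum(code == CHANGE_CODES[["loss"]])
  list(change_map = raster_grid(code, map_a$pixel_size, map_a$xll, map_a$yll,
                                mask = matrix(TRUE, d[1L], d[2L]),
                                band_names = "change"),
       n_gain = n_gain, n_loss = n_loss,
       n_no_change = sum(code == CHANGE_CODES[["no_change"]]),
       n_unknown = sum(code == CHANGE_CODES[["unknown"]]),
       gained_area = area_km2(n_gain),
       lost_area = area_km2(n_loss),
       net_area = area_km2(n_gain - n_loss))
}

#' Per-pixel transition counts over a multi-year map series
#'
#' Counts, at each pixel, how many consecutive-year pairs change class.
#' Pairs with an invalid year are skipped and flagged in a quality raster.
#' A count of 0 covers both always-PO and always-Non-PO pixels; the
#' always-PO subset is returned separately since stable meadow is the
#' quantity of conservation interest. The display raster bins counts as
#' 0, 1, 2, >=3 (code 3).
#'
#' @param series list of >= 2 `label_raster`s in chronological order.
#' @return list with `counts` (integer raster), `binned` (codes 0/1/2/3,
#'   3 meaning >= 3), `always_po` (binary raster flagging pixels PO in
#'   every valid year, with at least one valid year), and `gap_flag`
#'   (binary raster: some consecutive pair was skipped for invalidity).
#' @export
transition_count <- function(series) {
  if (length(series) < 2L)
    stop("transition counting needs at least 2 maps")
  for (m in series[-1L]) stop_unless_aligned(series[[1L]], m, "series maps")
  d <- grid_dim(series[[1L]])
  mats <- lapply(series, band_matrix, band = 1L)
  counts <- matrix(0L, d[1L], d[2L])
  gaps <- matrix(FALSE, d[1L], d[2L])
  for (i in seq_len(length(mats) - 1L)) {
    a <- mats[[i]]; b <- mats[[i + 1L]]
    ok <- !is.na(a) & !is.na(b)
    counts <- counts + (ok & a != b)
    gaps <- gaps | !ok
  }
  any_valid <- Reduce(`|`, lapply(mats, function(m) !is.na(m)))
  counts_m <- counts
  counts_m[!any_valid] <- NA_integer_
  binned <- pmin(counts_m, 3L)
  always_po <- Reduce(`&`, lapply(mats, function(m) is.na(m) | m == 1)) &
    any_valid
  g <- series[[1L]]
  mk <- function(v, name) raster_grid(v + 0, g$pixel_size, g$xll, g$yll,
                                      band_names = name)
  list(counts = mk(counts_m, "transitions"),
       binned = mk(binned, "transitions_binned"),
       always_po = mk(ifelse(any_valid, always_po + 0, NA_real_), "always_po"),
       gap_flag = mk(gaps + 0, "pair_skipped"))
}
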