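#' Per-pixel confusion counts between a predicted and a reference map
#'
#' Cross-tabulates prediction against ground truth over the pixels valid in
#' both rasters. Positives are the PO class (1).
#'
#' @param pred,truth `label_raster`s on one grid.
#' @return named list `tp, tn, fp, fn`.
#' @export
confusion_counts <- function(pred, truth) {
  stop_unless_aligned(pred, truth, "prediction and truth")
  p <- band_matrix(pred, 1L)
  t <- band_matrix(truth, 1L)
  ok <- !is.na(p) & !is.na(t)
  if (!any(ok)) stop("empty-assessment error: no co-valid pixels")
  list(tp = sum(p[ok] == 1 & t[ok] == 1),
       tn = sum(p[ok] == 0 & t[ok] == 0),
       fp = sum(p[ok] == 1 & t[ok] == 0),
       fn = sum(p[ok] == 0 & t[ok] == 1))
}

#' The three thematic-map accuracy statistics
#'
#' Overall accuracy `(TP+TN)/n`, producer's accuracy `TP/(TP+FN)` (how
#' often true PO is detected; omission-error complement) and user's
#' accuracy `TP/(TP+FP)` (how often mapped PO is truly PO;
#' commission-error complement). A statistic with an empty denominator is
#' reported as `NA` (not applicable).
#'
#' @param tp,tn,fp,fn non-negative confusion counts (or a list with these
#'   names as `tp`).
#' @return named list `overall, producers, users` plus the counts and `n`.
#' @export
accuracy_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    cc <- tp; tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty-assessment error: all confusion counts are zero")
  list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
       overall = (tp + tn) / n,
       producers = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       users = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Depth-stratified accuracy report
#'
#' Computes the three accuracy statistics overall and within depth strata;
#' a stratum `(low, high]` uses pixels with `low < depth <= high` (a bin
#' starting at 0 also includes depth exactly 0). Deeper water attenuates
#' the bottom signal, so accuracy is expected to fall with depth; the
#' default bins are the conventional 0–25 m / 25–40 m split.
#'
#' @param pred,truth `label_raster`s on one grid.
#' @param bathy depth `raster_grid` on the same grid.
#' @param bins list of `c(low, high)` depth bounds in metres,
#'   non-overlapping.
#' @return An `accuracy_report`: overall metrics plus `strata`, a list of
#'   per-bin sub-reports with their bounds.
#' @export
stratified_accuracy <- function(pred, truth, bathy,
                                bins = list(c(0, 25), c(25, 40))) {
  stop_unless_aligned(pred, bathy, "prediction and bathymetry")
  for (i in seq_along(bins)) for (j in seq_along(bins)) {
    if (i < j && bins[[i]][2L] > bins[[j]][1L] && bins[[j]][2L] > bins[[i]][1L])
      stop("invalid bins: depth strata overlap")
  }
  overall <- accuracy_metrics(confusion_counts(pred, truth))
  depth <- band_matrix(bathy, 1L)
  strata <- lapply(bins, function(b) {
    sel <- !is.na(depth) & depth > b[1L] & depth <= b[2L]
    if (b[1L] <= 0) sel <- sel | (!is.na(depth) & depth == 0)
    sub_pred <- pred; sub_pred$mask <- pred$mask & sel
    cc <- tryCatch(confusion_counts(sub_pred, truth), error = function(e) NULL)
    if (is.null(cc))
      return(list(depth_low = b[1L], depth_high = b[2L], n = 0L))
    c(list(depth_low = b[1L], depth_high = b[2L]), accuracy_metrics(cc))
  })
  structure(c(overall, list(strata = strata)), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> n=%d  overall %.3f  producer's %.3f  user's %.3f\n",
              x$n, x$overall, x$producers, x$users))
  for (s in x$strata) {
    if (is.null(s$n) || s$n == 0) next
    cat(sprintf("  %g-%g m: n=%d overall %.3f producer's %.3f user's %.3f\n",
                s$depth_low, s$depth_high, s$n, s$overall, s$producers, s$users))
  }
  invisible(x)
}

#' Integer codes of the per-pixel performance categories
#' @export
PERFORMANCE_CODES <- c(unknown = 0L, TP = 1L, TN = 2L, FP = 3L, FN = 4L)

#' Per-pixel model-performance map
#'
#' Categorical raster classifying every pixel as TP, TN, FP, FN or unknown
#' (truth or prediction invalid), with the integer coding of
#' [PERFORMANCE_CODES]. Category counts equal [confusion_counts()].
#'
#' @param pred,truth `label_raster`s on one grid.
#' @return single-band `raster_grid` of category codes (band
#'   `performance`), valid everywhere.
#' @export
performance_map <- function(pred, truth) {
  stop_unless_aligned(pred, truth, "prediction and truth")
  p <- band_matrix(pred, 1L)
  t <- band_matrix(truth, 1L)
  code <- matrix(PERFORMANCE_CODES[["unknown"]], nrow(p), ncol(p))
  ok <- !is.na(p) & !is.na(t)
  code[ok & p == 1 & t == 1] <- PERFORMANCE_CODES[["TP"]]
  code[ok & p == 0 & t == 0] <- PERFORMANCE_CODES[["TN"]]
  code[ok & p == 1 & t == 0] <- PERFORMANCE_CODES[["FP"]]
  code[ok & p == 0 & t == 1] <- PERFORMANCE_CODES[["FN"]]
  raster_grid(code, pred$pixel_size, pred$xll, pred$yll,
              mask = matrix(TRUE, nrow(p), ncol(p)),
              band_names = "performance")
}
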