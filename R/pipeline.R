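#' Run the full differencing pipeline on an image pair
#'
#' End-to-end convenience wrapper: (optional) tie-point registration of T1
#' onto T2's grid, PC1 absolute differencing on the clipped common extent,
#' spectral thresholding (manual value or the truth-based percentile rule),
#' unsmoothed polygonization, the area filter, and — when truth is supplied —
#' matching and accuracy metrics.
#'
#' @param t1,t2 [multiband_image()] acquisitions.
#' @param truth optional [truth_set()]; required when `threshold` is `NULL`.
#' @param tie_pts optional [tie_points()] linking T1 to T2; when given, T1 is
#'   affine-registered and resampled onto T2's grid first.
#' @param threshold a [spectral_threshold()], or `NULL` to derive one with
#'   [suggest_threshold()].
#' @param percentile percentile for [suggest_threshold()] (default 0.05).
#' @param spatial a [spatial_threshold()] (default 0.99–10 m2).
#' @param connectivity polygon connectivity, 8 (default) or 4.
#' @param r_match,match_on matching parameters, see [match_detections()].
#' @return object of class `animal_count`: `diff`, `threshold`, `mask`,
#'   `polygons` (area-filtered), `n_candidates` (pre-filter), `count`
#'   (= number of retained polygons), and when truth was given `match`
#'   ([match_detections()]) and `evaluation` ([compute_metrics()]).
#' @export
enumerate_animals <- function(t1, t2, truth = NULL, tie_pts = NULL,
                              threshold = NULL, percentile = 0.05,
                              spatial = spatial_threshold(),
                              connectivity = 8, r_match = 1.0,
                              match_on = "both") {
  if (!is.null(tie_pts)) {
    fit <- fit_affine(tie_pts, pixel_size = t2$transform$pixel_size)
    t1 <- warp_image(t1, fit, t2$transform, dim(t2))
  } else {
    fit <- NULL
  }
  diff <- difference_pc1(t1, t2)
  if (is.null(threshold)) {
    if (is.null(truth))
      stop_id("no_threshold", "supply a spectral threshold or a truth set")
    threshold <- suggest_threshold(diff, truth, percentile)
  }
  mask <- threshold_mask(diff, threshold)
  cand <- extract_polygons(mask, diff$transform, connectivity, rings = FALSE)
  polys <- lapply(filter_by_area(cand, spatial), function(p) {
    p$rings <- polygon_rings(p)
    p
  })
  res <- list(diff = diff, threshold = threshold, mask = mask,
              registration = fit,
              polygons = polys, n_candidates = length(cand),
              count = length(polys))
  if (!is.null(truth)) {
    res$match <- match_detections(polys, truth, r_match, match_on)
    res$evaluation <- compute_metrics(res$match)
  }
  structure(res, class = "animal_count")
}

#' @export
print.animal_count <- function(x, ...) {
  cat(sprintf(
    "<animal_count> %d candidate polygons, %d retained by the area filter\n",
    x$n_candidates, x$count))
  cat(sprintf("  spectral threshold [%.4g, %g]\n",
              x$threshold$t_low, x$threshold$t_high))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
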