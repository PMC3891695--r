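#' Tie-point set for image-to-image registration
#'
#' Pairs of map coordinates for features identified in both acquisitions:
#' `(x1, y1)` in the source (T1) frame, `(x2, y2)` in the target (T2) frame.
#'
#' @param x data.frame with columns `x1`, `y1`, `x2`, `y2` (meters).
#' @return an object of class `tie_points`.
#' @export
tie_points <- function(x) {
  x <- as.data.frame(x)
  need <- c("x1", "y1", "x2", "y2")
  if (!all(need %in% names(x)))
    stop_id("tie_columns", "tie points need columns %s", paste(need, collapse = ", "))
  if (nrow(x) < 3) stop_id("tie_count", "need >= 3 tie points, got %d", nrow(x))
  structure(x[need], class = c("tie_points", "data.frame"))
}

#' Read tie points from CSV
#'
#' @param path CSV with columns `x1,y1,x2,y2` in map meters.
#' @return a [tie_points()] object.
#' @export
read_tie_points <- function(path) {
  if (!file.exists(path)) stop_id("missing_file", "file not found: %s", path)
  tie_points(utils::read.csv(path))
}

#' Fit a first-order (affine) registration from tie points
#'
#' Least-squares fit of `x' = a x + b y + c`, `y' = d x + e y + f` linking the
#' source frame to the target frame, minimizing the summed squared
#' map-coordinate residuals. The residual root-mean-square is reported in
#' pixels (the conventional registration unit at a stated ground sample
#' distance).
#'
#' @param tp a [tie_points()] object or data.frame with `x1,y1,x2,y2`.
#' @param pixel_size meters per pixel used to express the RMSE (default 0.25).
#' @return an object of class `affine_fit`: `coefficients` (named a..f),
#'   `residuals` (per-point dx, dy meters, predicted minus observed),
#'   `rmse_m`, `rmse_pixels`, `pixel_size`, `n`.
#' @export
fit_affine <- function(tp, pixel_size = 0.25) {
  tp <- if (inherits(tp, "tie_points")) tp else tie_points(tp)
  X <- cbind(tp$x1, tp$y1, 1)
  qx <- qr(X)
  if (qx$rank < 3)
    stop_id("degenerate_ties", "tie points are collinear or duplicated")
  bx <- qr.coef(qx, tp$x2)
  by <- qr.coef(qx, tp$y2)
  pred <- cbind(X %*% bx, X %*% by)
  res <- pred - cbind(tp$x2, tp$y2)
  colnames(res) <- c("dx", "dy")
  rmse_m <- sqrt(mean(res[, 1]^2 + res[, 2]^2))
  structure(list(
    coefficients = c(a = bx[1], b = bx[2], c = bx[3],
                     d = by[1], e = by[2], f = by[3]),
    residuals = res, rmse_m = rmse_m,
    rmse_pixels = rmse_m / pixel_size,
    pixel_size = pixel_size, n = nrow(tp)
  ), class = "affine_fit")
}

#' @export
print.affine_fit <- function(x, ...) {
  cat(sprintf("<affine_fit> %d tie points, RMSE %.3f px (%.3f m)\n",
              x$n, x$rmse_pixels, x$rmse_m))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Apply an affine fit to map coordinates
#'
#' @param object an [fit_affine()] result.
#' @param xy two-column matrix of map coordinates.
#' @param ... unused.
#' @return two-column matrix of transformed coordinates.
#' @export
predict.affine_fit <- function(object, xy, ...) {
  co <- object$coefficients
  xy <- rbind(xy)  # accept a bare length-2 vector
  cbind(x = co["a"] * xy[, 1] + co["b"] * xy[, 2] + co["c"],
        y = co["d"] * xy[, 1] + co["e"] * xy[, 2] + co["f"],
        deparse.level = 0)
}

invert_affine <- function(fit) {
  co <- fit$coefficients
  m <- matrix(co[c("a", "d", "b", "e")], 2)
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(det) < 1e-14) stop_id("singular_affine", "affine transform is singular")
  mi <- matrix(c(m[2, 2], -m[2, 1], -m[1, 2], m[1, 1]), 2) / det
  tr <- -mi %*% c(co["c"], co["f"])
  c(a = mi[1, 1], b = mi[1, 2], c = tr[1], d = mi[2, 1], e = mi[2, 2], f = tr[2])
}

identity_fit <- function(pixel_size = 0.25) {
  structure(list(coefficients = c(a = 1, b = 0, c = 0, d = 0, e = 1, f = 0),
                 residuals = matrix(0, 0, 2), rmse_m = 0, rmse_pixels = 0,
                 pixel_size = pixel_size, n = 0L),
            class = "affine_fit")
}

# bilinear sampling of one band matrix at fractional 0-based pixel coords;
# coords within snap_tol of an integer collapse to the exact cell so identity
# and whole-pixel shifts are exact and do not bleed nodata
bilinear_sample <- function(mat, fr, fc, snap_tol = 1e-7) {
  nr <- nrow(mat); nc <- ncol(mat)
  fr[abs(fr - round(fr)) < snap_tol] <- round(fr[abs(fr - round(fr)) < snap_tol])
  fc[abs(fc - round(fc)) < snap_tol] <- round(fc[abs(fc - round(fc)) < snap_tol])
  r0 <- floor(fr); c0 <- floor(fc)
  wr <- fr - r0; wc <- fc - c0
  out <- rep(NA_real_, length(fr))
  val_at <- function(r, c) {
    ok <- r >= 0 & r < nr & c >= 0 & c < nc
    v <- rep(NA_real_, length(r))
    v[ok] <- mat[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  acc <- rep(0, length(fr)); bad <- rep(FALSE, length(fr))
  for (dr in 0:1) for (dc in 0:1) {
    w <- (if (dr == 0) 1 - wr else wr) * (if (dc == 0) 1 - wc else wc)
    use <- w > 0
    if (!any(use)) next
    v <- val_at(r0 + dr, c0 + dc)
    bad <- bad | (use & is.na(v))
    v[!use | is.na(v)] <- 0
    acc <- acc + w * v
  }
  out[!bad] <- acc[!bad]
  out
}

#' Resample an image through an affine fit onto a target grid
#'
#' Bilinear resampling of each band onto the target lattice. The fit maps
#' source-frame coordinates to target-frame coordinates (as produced by
#' [fit_affine()] from source-to-target tie points); it is inverted internally
#' to look up source values. Any output pixel whose bilinear 4-neighborhood
#' touches nodata (or falls outside the source grid) is nodata.
#'
#' @param img source [multiband_image()].
#' @param fit an [fit_affine()] result (or `NULL` for the identity).
#' @param target_transform [geo_transform()] of the output grid.
#' @param target_dim integer `c(n_rows, n_cols)` of the output grid.
#' @return a [multiband_image()] on the target grid.
#' @export
warp_image <- function(img, fit, target_transform, target_dim) {
  if (is.null(fit)) fit <- identity_fit(target_transform$pixel_size)
  nr <- target_dim[1]; nc <- target_dim[2]
  idx <- expand.grid(row = 0:(nr - 1), col = 0:(nc - 1))
  ctr <- pixel_to_map(idx$row, idx$col, target_transform)
  inv <- invert_affine(fit)
  sx <- inv["a"] * ctr[, 1] + inv["b"] * ctr[, 2] + inv["c"]
  sy <- inv["d"] * ctr[, 1] + inv["e"] * ctr[, 2] + inv["f"]
  st <- img$transform
  fr <- (st$origin_y - sy) / st$pixel_size - 0.5
  fc <- (sx - st$origin_x) / st$pixel_size - 0.5
  nb <- dim(img$bands)[3]
  out <- array(NA_real_, dim = c(nr, nc, nb))
  for (b in seq_len(nb)) {
    plane <- img$bands[, , b]
    out[, , b] <- matrix(bilinear_sample(plane, fr, fc), nr, nc)
  }
  multiband_image(out, target_transform, img$band_names)
}

#' Assess residual mis-registration from paired check features
#'
#' Given the map coordinates of the same `k` ground features measured in the
#' T1 and the T2 image (features independent of the registration tie points),
#' reports per-axis *absolute* offsets with their mean and sample standard
#' deviation — the residual misalignment that image differencing will see,
#' compared against animal body length when judging commission risk.
#'
#' @param points_t1,points_t2 two-column matrices (x, y meters), equal length.
#' @return object of class `misreg_report`: per-point `offsets` data.frame
#'   (`dx`, `dy`, absolute meters) and `mean_x`, `std_x`, `mean_y`, `std_y`.
#' @export
assess_misregistration <- function(points_t1, points_t2) {
  p1 <- rbind(points_t1); p2 <- rbind(points_t2)
  if (nrow(p1) != nrow(p2))
    stop_id("length_mismatch", "point lists differ in length (%d vs %d)",
            nrow(p1), nrow(p2))
  if (nrow(p1) < 1) stop_id("empty_points", "need at least one check feature")
  dx <- abs(p2[, 1] - p1[, 1]); dy <- abs(p2[, 2] - p1[, 2])
  structure(list(
    offsets = data.frame(dx = dx, dy = dy),
    mean_x = mean(dx), std_x = if (length(dx) > 1) stats::sd(dx) else NA_real_,
    mean_y = mean(dy), std_y = if (length(dy) > 1) stats::sd(dy) else NA_real_,
    k = length(dx)
  ), class = "misreg_report")
}

#' @export
print.misreg_report <- function(x, ...) {
  cat(sprintf("<misreg_report> %d check features\n", x$k))
  cat(sprintf("  mean |dx| %.3f m (sd %.3f), mean |dy| %.3f m (sd %.3f)\n",
              x$mean_x, x$std_x, x$mean_y, x$std_y))
  invisible(x)
}

#' Write a mis-registration report as CSV
#'
#' One row per pasture-style report: Mean X, STD X, Mean Y, STD Y. Units are
#' meters by default; `units = "cm"` multiplies by 100 for centimeter tables.
#'
#' @param reports a `misreg_report` or list of them.
#' @param path output CSV path.
#' @param units `"m"` (default) or `"cm"`.
#' @param labels optional row labels.
#' @return the data.frame written, invisibly.
#' @export
write_misregistration_csv <- function(reports, path, units = c("m", "cm"),
                                      labels = NULL) {
  units <- match.arg(units)
  if (inherits(reports, "misreg_report")) reports <- list(reports)
  f <- if (units == "cm") 100 else 1
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(mean_x = r$mean_x * f, std_x = r$std_x * f,
               mean_y = r$mean_y * f, std_y = r$std_y * f, k = r$k)
  }))
  df <- cbind(label = labels %||% seq_len(nrow(df)), df, units = units)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
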