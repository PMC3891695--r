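#' Principal component analysis of a 3-band image
#'
#' Eigen-decomposition of the 3x3 *covariance* matrix of band values over the
#' valid pixels (covariance, not correlation: the bands share one physical
#' unit, and covariance is the remote-sensing default for same-unit bands).
#' PC1 — the band combination carrying the largest share of the correlated
#' inter-band variance — is returned as a grid on the source transform with
#' the source mask.
#'
#' Eigenvector sign is arbitrary in any decomposition; an uncontrolled flip
#' between two acquisitions would turn "no change" into maximal change. Each
#' loading vector's sign is fixed so the sum of its loadings is positive
#' (tie: first nonzero loading positive), making PC1 of two near-identical
#' images near-identical.
#'
#' @param img a [multiband_image()] with >= 4 valid pixels and nonzero
#'   variance in at least one band.
#' @return object of class `pca_result`: `eigenvalues` (descending),
#'   `loadings` (3x3, columns = components), `variance_fraction`, `center`
#'   (band means), `pc1` (matrix, `NA` at masked cells), `transform`.
#' @export
compute_pca <- function(img) {
  stopifnot(inherits(img, "multiband_image"))
  nb <- dim(img$bands)[3]
  v <- matrix(img$bands, ncol = nb)
  v <- v[!img$mask, , drop = FALSE]
  if (nrow(v) < 4) stop_id("too_few_pixels", "need >= 4 valid pixels for PCA")
  cv <- stats::cov(v)
  if (all(abs(cv) < 1e-24))
    stop_id("constant_image", "all bands are constant; covariance is zero")
  e <- eigen(cv, symmetric = TRUE)   # eigenvalues already descending
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    s <- sum(load[, j])
    if (abs(s) < 1e-12) s <- load[which(abs(load[, j]) > 1e-12)[1], j]
    if (s < 0) load[, j] <- -load[, j]
  }
  ev <- pmax(e$values, 0)
  ctr <- colMeans(v)
  centered <- sweep(matrix(img$bands, ncol = nb), 2, ctr)
  pc1 <- matrix(centered %*% load[, 1], dim(img$bands)[1], dim(img$bands)[2])
  pc1[img$mask] <- NA_real_
  structure(list(eigenvalues = ev, loadings = load,
                 variance_fraction = ev / sum(ev), center = ctr,
                 pc1 = pc1, transform = img$transform,
                 band_names = img$band_names),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n  variance fractions:",
      paste(sprintf("%.4f", x$variance_fraction), collapse = " "), "\n")
  cat("  PC1 loadings:",
      paste(sprintf("%+.4f", x$loadings[, 1]), collapse = " "),
      sprintf("(%s)\n", paste(x$band_names, collapse = "/")))
  invisible(x)
}

#' Log a PCA result as JSON
#'
#' @param pca a [compute_pca()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pca_json <- function(pca, path) {
  jsonlite::write_json(list(
    eigenvalues = pca$eigenvalues,
    loadings = pca$loadings,
    variance_fraction = pca$variance_fraction,
    center = pca$center,
    band_names = pca$band_names
  ), path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
  invisible(path)
}

#' Absolute PC1 difference of two acquisitions
#'
#' Clips the pair to its common extent, runs [compute_pca()] on each *clipped*
#' image independently (so both decompositions see the same spatial support),
#' and returns the absolute pixel-to-pixel PC1 difference with the union of
#' the two masks. Low values reflect inherent acquisition differences
#' (sensor/atmosphere); high values flag features that moved — candidate
#' animals.
#'
#' @param t1,t2 [multiband_image()] acquisitions on a common lattice.
#' @return object of class `difference_image`: `values` (matrix, `NA` at
#'   masked cells, all unmasked values >= 0), `transform`, and the two
#'   `pca_result`s.
#' @export
difference_pc1 <- function(t1, t2) {
  cl <- clip_to_common_extent(t1, t2)
  p1 <- compute_pca(cl$a)
  p2 <- compute_pca(cl$b)
  d <- abs(p2$pc1 - p1$pc1)
  structure(list(values = d, transform = cl$a$transform,
                 pca_t1 = p1, pca_t2 = p2),
            class = "difference_image")
}

#' @export
print.difference_image <- function(x, ...) {
  cat(sprintf("<difference_image> %d x %d px, max |dPC1| %.4g, %d nodata px\n",
              nrow(x$values), ncol(x$values),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Write a difference image as single-band float32 GeoTIFF
#'
#' @param diff a [difference_pc1()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_difference_geotiff <- function(diff, path) {
  img <- multiband_image(array(diff$values, dim = c(dim(diff$values), 1)),
                         diff$transform, band_names = "pc1_absdiff")
  write_geotiff(img, path)
}

#' Read a single-band difference GeoTIFF
#'
#' @param path file written by [write_difference_geotiff()].
#' @return a `difference_image` (without the PCA logs).
#' @export
read_difference_geotiff <- function(path) {
  raw <- read_tiff_raw(path)
  if (is.null(raw$transform))
    stop_id("no_georef", "file carries no geotransform tags: %s", path)
  structure(list(values = raw$values[, , 1], transform = raw$transform,
                 pca_t1 = NULL, pca_t2 = NULL),
            class = "difference_image")
}
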