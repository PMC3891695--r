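#' Geotransform for a north-up raster grid
#'
#' Planar map coordinates in meters, square pixels. `origin_x`/`origin_y` is
#' the map position of the *corner* of pixel (0, 0) (top-left). Row index
#' increases as map y decreases (north-up convention).
#'
#' @param origin_x,origin_y map coordinates (m) of the top-left corner.
#' @param pixel_size pixel edge length in meters (> 0); 0.25 for the 25 cm
#'   imagery this pipeline targets.
#' @return an object of class `geo_transform`.
#' @export
geo_transform <- function(origin_x, origin_y, pixel_size = 0.25) {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y), is.numeric(pixel_size))
  if (pixel_size <= 0) stop_id("bad_transform", "pixel_size must be > 0")
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 pixel_size = as.numeric(pixel_size)),
            class = "geo_transform")
}

#' @export
print.geo_transform <- function(x, ...) {
  cat(sprintf("<geo_transform> origin (%.6g, %.6g), pixel %.6g m, north-up\n",
              x$origin_x, x$origin_y, x$pixel_size))
  invisible(x)
}

#' Pixel index to map coordinates (pixel centers)
#'
#' Returns the map coordinates of the *center* of each pixel. Indices are
#' 0-based; out-of-grid indices are allowed (extrapolated on the same lattice).
#'
#' @param row,col 0-based pixel indices (vectorized).
#' @param transform a [geo_transform()].
#' @return two-column matrix with columns `x`, `y` (meters).
#' @export
pixel_to_map <- function(row, col, transform) {
  s <- transform$pixel_size
  cbind(x = transform$origin_x + (col + 0.5) * s,
        y = transform$origin_y - (row + 0.5) * s)
}

#' Map coordinates to pixel index
#'
#' Pixel footprints are half-open: `[x, x + s)` in x and `(y - s, y]` in y, so
#' a point exactly on a shared edge belongs to the higher column / lower row
#' index. Inverse of [pixel_to_map()] on pixel centers.
#'
#' @param x,y map coordinates in meters (vectorized).
#' @param transform a [geo_transform()].
#' @return two-column integer matrix with columns `row`, `col` (0-based).
#' @export
map_to_pixel <- function(x, y, transform) {
  s <- transform$pixel_size
  # snap tolerance absorbs float error so exact-edge points follow the
  # half-open rule instead of falling one ulp short
  eps <- 1e-9
  cbind(row = as.integer(floor((transform$origin_y - y) / s + eps)),
        col = as.integer(floor((x - transform$origin_x) / s + eps)))
}

#' Three-band reflectance image
#'
#' The core raster container: three co-registered single-band grids
#' (green/red/NIR by default) sharing one geotransform and one validity mask.
#' Invalid (nodata) cells are stored as `NA` in every band.
#'
#' @param bands numeric array `n_rows x n_cols x 3` (or a list of 3 matrices).
#'   `NA` cells are treated as nodata.
#' @param transform a [geo_transform()].
#' @param band_names character vector of band labels.
#' @return an object of class `multiband_image` with fields `bands`,
#'   `transform`, `mask` (`TRUE` = invalid), `band_names`.
#' @export
multiband_image <- function(bands, transform,
                            band_names = c("green", "red", "nir")) {
  if (is.list(bands)) bands <- array(unlist(bands),
                                     dim = c(dim(bands[[1]]), length(bands)))
  stopifnot(is.array(bands), length(dim(bands)) == 3)
  nb <- dim(bands)[3]
  if (nb != length(band_names))
    stop_id("band_count", "expected %d band names for %d bands",
            nb, length(band_names))
  mask <- apply(is.na(bands), c(1, 2), any)
  for (b in seq_len(nb)) {
    plane <- bands[, , b]
    plane[mask] <- NA_real_
    bands[, , b] <- plane
  }
  if (all(mask)) stop_id("empty_image", "image has no valid pixel")
  dimnames(bands) <- list(NULL, NULL, band_names)
  structure(list(bands = bands, transform = transform, mask = mask,
                 band_names = band_names),
            class = "multiband_image")
}

#' @export
print.multiband_image <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf(
    "<multiband_image> %d x %d px, bands %s, pixel %.6g m, %d nodata px\n",
    d[1], d[2], paste(x$band_names, collapse = "/"),
    x$transform$pixel_size, sum(x$mask)))
  invisible(x)
}

#' @export
dim.multiband_image <- function(x) dim(x$bands)[1:2]

# integer lattice offset of b relative to a; error if not on a common lattice
lattice_offset <- function(a, b, tol_m = 1e-6) {
  s <- a$pixel_size
  if (abs(s - b$pixel_size) > 1e-9)
    stop_id("pixel_size", "pixel sizes differ (%g vs %g)", s, b$pixel_size)
  kc <- (b$origin_x - a$origin_x) / s
  kr <- (a$origin_y - b$origin_y) / s
  if (abs(kc - round(kc)) * s > tol_m || abs(kr - round(kr)) * s > tol_m)
    stop_id("misaligned", "grids are not on a common pixel lattice")
  c(row = as.integer(round(kr)), col = as.integer(round(kc)))
}

#' Clip two images to their common extent
#'
#' Both images must share the pixel size and sit on a common lattice (origins
#' differing by integer pixel multiples within 1e-6 m). Output images share an
#' identical geotransform and shape equal to the footprint intersection.
#' Differenced images are clipped to the minimum extent of the two
#' acquisitions to avoid edge effects.
#'
#' @param a,b [multiband_image()] objects.
#' @return list of the two clipped images (`a`, `b`).
#' @export
clip_to_common_extent <- function(a, b) {
  k <- lattice_offset(a$transform, b$transform)
  da <- dim(a); db <- dim(b)
  # global pixel indices on a's lattice: a rows [0, da1), b rows [kr, kr+db1)
  r0 <- max(0L, k["row"]); r1 <- min(da[1], k["row"] + db[1])
  c0 <- max(0L, k["col"]); c1 <- min(da[2], k["col"] + db[2])
  if (r1 <= r0 || c1 <= c0) stop_id("no_overlap", "image extents do not overlap")
  sub <- function(img, rows, cols) {
    tr <- img$transform
    s <- tr$pixel_size
    t2 <- geo_transform(tr$origin_x + (cols[1] - 1) * s,
                        tr$origin_y - (rows[1] - 1) * s, s)
    multiband_image(img$bands[rows, cols, , drop = FALSE], t2, img$band_names)
  }
  list(a = sub(a, (r0 + 1):r1, (c0 + 1):c1),
       b = sub(b, (r0 - k["row"] + 1):(r1 - k["row"]),
               (c0 - k["col"] + 1):(c1 - k["col"])))
}
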