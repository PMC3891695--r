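# Minimal GeoTIFF codec for float reflectance rasters.
#
# Writer emits a deterministic little-endian baseline TIFF: uncompressed,
# float32, pixel-interleaved, one strip, with ModelPixelScale, ModelTiepoint,
# a minimal GeoKey directory (projected model, pixel-is-area, linear meters)
# and a GDAL-style ASCII nodata tag. Reader handles that layout plus the
# common variants (big-endian, multiple strips, planar band-sequential,
# float64 samples).

NODATA_SENTINEL <- -9999

.tif_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L,
                RATIONAL = 5L, DOUBLE = 12L)
.tif_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L, `12` = 8L)

#' Write a 3-band image as GeoTIFF
#'
#' Uncompressed float32 GeoTIFF with the geotransform stored as
#' ModelPixelScale + ModelTiepoint tags and nodata as the GDAL ASCII tag
#' (sentinel -9999). Output bytes are a pure function of the image, so two
#' writes of the same image are identical.
#'
#' @param img a [multiband_image()] (any band count >= 1).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(img, path) {
  stopifnot(inherits(img, "multiband_image"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_id("unwritable", "cannot open '%s' for writing", path))
  on.exit(close(con))
  bands <- img$bands
  nr <- dim(bands)[1]; nc <- dim(bands)[2]; nb <- dim(bands)[3]
  tr <- img$transform

  vals <- aperm(bands, c(3, 2, 1))            # sample fastest, then col, row
  vals[is.na(vals)] <- NODATA_SENTINEL
  data_len <- nr * nc * nb * 4

  nodata_str <- c(charToRaw(format(NODATA_SENTINEL)), as.raw(0))
  if (length(nodata_str) %% 2 == 1) nodata_str <- c(nodata_str, as.raw(0))
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 1,      # model type: projected
                          1025, 0, 1, 1,      # raster type: pixel is area
                          3076, 0, 1, 9001))  # linear unit: meter

  # layout: header(8) | strip data | IFD | external tag payloads
  ifd_off <- 8 + data_len
  ntags <- 15L
  ext_off <- ifd_off + 2 + ntags * 12 + 4
  ext <- list()
  put_ext <- function(raw_bytes) {
    off <- ext_off + sum(vapply(ext, length, 0L))
    ext[[length(ext) + 1L]] <<- raw_bytes
    off
  }
  raw_of <- function(v, type) {
    if (type == .tif_types[["SHORT"]]) writeBin(as.integer(v), raw(), size = 2, endian = "little")
    else if (type == .tif_types[["LONG"]]) writeBin(as.integer(v), raw(), size = 4, endian = "little")
    else if (type == .tif_types[["DOUBLE"]]) writeBin(as.numeric(v), raw(), size = 8, endian = "little")
    else if (type == .tif_types[["ASCII"]]) as.raw(v)
    else stop("unsupported type")
  }
  entry <- function(tag, type, values) {
    n <- length(values)
    payload <- raw_of(values, type)
    if (length(payload) <= 4) {
      val <- c(payload, raw(4 - length(payload)))
    } else {
      val <- raw_of(put_ext(payload), .tif_types[["LONG"]])
    }
    c(raw_of(tag, .tif_types[["SHORT"]]), raw_of(type, .tif_types[["SHORT"]]),
      raw_of(n, .tif_types[["LONG"]]), val)
  }
  tt <- .tif_types
  entries <- list(
    entry(256, tt[["LONG"]], nc),
    entry(257, tt[["LONG"]], nr),
    entry(258, tt[["SHORT"]], rep(32L, nb)),
    entry(259, tt[["SHORT"]], 1L),
    entry(262, tt[["SHORT"]], 1L),
    entry(273, tt[["LONG"]], 8L),
    entry(277, tt[["SHORT"]], nb),
    entry(278, tt[["LONG"]], nr),
    entry(279, tt[["LONG"]], data_len),
    entry(284, tt[["SHORT"]], 1L),
    entry(339, tt[["SHORT"]], rep(3L, nb)),
    entry(33550, tt[["DOUBLE"]], c(tr$pixel_size, tr$pixel_size, 0)),
    entry(33922, tt[["DOUBLE"]], c(0, 0, 0, tr$origin_x, tr$origin_y, 0)),
    entry(34735, tt[["SHORT"]], geokeys),
    entry(42113, tt[["ASCII"]], nodata_str)
  )
  stopifnot(length(entries) == ntags)

  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  writeBin(as.integer(ntags), con, size = 2, endian = "little")
  for (e in entries) writeBin(e, con)
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  for (x in ext) writeBin(x, con)
  invisible(path)
}

read_tiff_ifd <- function(con, endian) {
  n <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
  tags <- vector("list", n)
  for (i in seq_len(n)) {
    tag <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", size = 4, endian = endian)
    val_raw <- readBin(con, "raw", n = 4)
    tags[[i]] <- list(tag = tag, type = type, count = count, raw = val_raw)
  }
  tags
}

read_tag_values <- function(con, t, endian) {
  size <- .tif_type_size[[as.character(t$type)]]
  total <- size * t$count
  decode <- function(r) {
    rc <- rawConnection(r)
    on.exit(close(rc))
    switch(as.character(t$type),
      `1` = as.integer(readBin(rc, "raw", n = t$count)),
      `2` = rawToChar(r[r != as.raw(0)]),
      `3` = readBin(rc, "integer", n = t$count, size = 2, signed = FALSE, endian = endian),
      `4` = readBin(rc, "integer", n = t$count, size = 4, endian = endian),
      `12` = readBin(rc, "numeric", n = t$count, size = 8, endian = endian),
      stop_id("tiff_type", "unsupported TIFF tag type %d", t$type))
  }
  if (total <= 4) {
    decode(t$raw[seq_len(total)])
  } else {
    rc0 <- rawConnection(t$raw)
    off <- readBin(rc0, "integer", size = 4, endian = endian)
    close(rc0)
    seek(con, off)
    decode(readBin(con, "raw", n = total))
  }
}

# low-level reader: returns list(values = nr x nc x nb array with NA nodata,
# transform, nbands)
read_tiff_raw <- function(path) {
  if (!file.exists(path)) stop_id("missing_file", "file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2)
  endian <- if (rawToChar(magic) == "II") "little"
            else if (rawToChar(magic) == "MM") "big"
            else stop_id("not_tiff", "not a TIFF file: %s", path)
  fortytwo <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
  if (fortytwo != 42) stop_id("not_tiff", "not a TIFF file: %s", path)
  ifd_off <- readBin(con, "integer", size = 4, endian = endian)
  seek(con, ifd_off)
  tags <- read_tiff_ifd(con, endian)
  get <- function(code, default = NULL) {
    for (t in tags) if (t$tag == code) return(read_tag_values(con, t, endian))
    default
  }
  nc <- get(256); nr <- get(257)
  bits <- get(258, 1L)
  compression <- get(259, 1L)
  strip_off <- get(273); spp <- get(277, 1L)
  rps <- get(278, nr); strip_cnt <- get(279)
  planar <- get(284, 1L)
  fmt <- get(339, rep(1L, spp))
  scale <- get(33550); tiepoint <- get(33922)
  nodata <- suppressWarnings(as.numeric(get(42113, NA_character_)))
  if (compression != 1) stop_id("tiff_layout", "only uncompressed TIFF supported")
  if (!all(fmt == 3)) stop_id("tiff_layout", "only IEEE float samples supported")
  if (!all(bits %in% c(32L, 64L)) || length(unique(bits)) != 1)
    stop_id("tiff_layout", "unsupported bit depth")
  ssize <- bits[1] / 8

  read_strip <- function(i) {
    seek(con, strip_off[i])
    readBin(con, "numeric", n = strip_cnt[i] / ssize, size = ssize, endian = endian)
  }
  arr <- array(NA_real_, dim = c(nr, nc, spp))
  if (planar == 1) {
    vals <- unlist(lapply(seq_along(strip_off), read_strip))
    arr <- aperm(array(vals, dim = c(spp, nc, nr)), c(3, 2, 1))
  } else {
    strips_per_band <- length(strip_off) / spp
    for (b in seq_len(spp)) {
      idx <- ((b - 1) * strips_per_band + 1):(b * strips_per_band)
      vals <- unlist(lapply(idx, read_strip))
      arr[, , b] <- t(array(vals, dim = c(nc, nr)))
    }
  }
  if (!is.na(nodata)) arr[arr == nodata] <- NA_real_
  transform <- NULL
  if (!is.null(scale) && !is.null(tiepoint)) {
    if (abs(scale[1] - scale[2]) > 1e-9)
      stop_id("nonsquare_pixels", "pixels are not square (%g x %g)", scale[1], scale[2])
    # tiepoint maps raster (i,j,k) -> model (x,y,z); we require the corner form
    ox <- tiepoint[4] - tiepoint[1] * scale[1]
    oy <- tiepoint[5] + tiepoint[2] * scale[2]
    transform <- geo_transform(ox, oy, scale[1])
  }
  list(values = arr, transform = transform, nbands = spp)
}

#' Read a 3-band GeoTIFF
#'
#' Reads an uncompressed float GeoTIFF into a [multiband_image()]. The file
#' must carry at least three bands and square pixels; nodata values (GDAL
#' ASCII tag) are folded into the validity mask.
#'
#' @param path file path.
#' @param bands named integer vector mapping band labels to file band indices
#'   (declared order green/red/nir by default).
#' @return a [multiband_image()].
#' @export
read_geotiff <- function(path, bands = c(green = 1, red = 2, nir = 3)) {
  raw <- read_tiff_raw(path)
  if (raw$nbands < 3)
    stop_id("band_count", "expected >= 3 bands, found %d in %s", raw$nbands, path)
  if (is.null(raw$transform))
    stop_id("no_georef", "file carries no geotransform tags: %s", path)
  if (max(bands) > raw$nbands)
    stop_id("band_count", "band mapping requests band %d of %d", max(bands), raw$nbands)
  multiband_image(raw$values[, , bands, drop = FALSE], raw$transform,
                  band_names = names(bands))
}
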