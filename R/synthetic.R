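# Synthetic paired pasture scenes with known truth: the statistical structure
# single-day differencing assumes (static textured grassland, compact animal
# blobs that move, attached shadows, sub-pixel to multi-pixel mis-registration,
# additive sensor noise), so every pipeline stage is testable without flight
# imagery.

#' Configuration for a synthetic pasture scene pair
#'
#' Defaults describe a late-autumn senescent grassland pasture imaged at
#' 25 cm ground sample distance, with dark livestock (cattle/horses) whose
#' per-animal coat brightness varies.
#'
#' @param extent pasture edge length in meters (square; default 250 m,
#'   i.e. 6.2 ha — the mean pasture size of the validation study design).
#' @param pixel_size meters per pixel (default 0.25).
#' @param n_animals number of animals (default 15).
#' @param animal_area_range body footprint area interval in m2 (default
#'   1.2–3.0, adult cow/horse seen from above).
#' @param animal_reflectance signed per-band reflectance offsets of an animal
#'   versus its background (default dark in all bands).
#' @param animal_contrast_range per-animal multiplier on the offsets,
#'   sampled uniformly (coat variation; default 0.5–1).
#' @param aspect_range body length-to-width ratio interval (default 1.5–2.5).
#' @param movement min/max distance in meters an animal moves between
#'   acquisitions (uniform; direction uniform; default 2–20 m).
#' @param min_separation minimum distance (m) enforced between the positions
#'   of *different* animals, pooled over both acquisitions (default 0: herds
#'   may bunch, producing merged and dual polygons). Set above one body
#'   length to emulate fully separable individuals.
#' @param background list: `mean` per-band reflectance, `correlation_length`
#'   (m) of the texture field, `texture_cv` (relative sd of the
#'   multiplicative texture).
#' @param shadow list: `enabled`, `offset_t1`/`offset_t2` (meters, shadow
#'   displacement from the animal at each acquisition; defaults approximate a
#'   ~1.5 m tall animal under a low autumn sun, whose azimuth moves between
#'   acquisitions), `intensity` (multiplier < 1 on shadowed background).
#' @param misregistration `c(dx, dy)` meters applied to the T2 image by
#'   resampling (residual registration error; default none).
#' @param noise_sd per-band additive Gaussian sensor noise sd (reflectance
#'   units, default 0.01), independent between acquisitions.
#' @param psf_sigma camera point-spread blur sd in pixels applied to the
#'   rendered scene before noise (default 0.5; 0 disables).
#' @param seed integer RNG seed; scenes are bit-reproducible from it.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(extent = 250, pixel_size = 0.25, n_animals = 15,
                         animal_area_range = c(1.2, 3.0),
                         animal_reflectance = c(green = -0.06, red = -0.07, nir = -0.18),
                         animal_contrast_range = c(0.5, 1.0),
                         aspect_range = c(1.5, 2.5),
                         movement = c(2, 20), min_separation = 0,
                         background = list(mean = c(green = 0.13, red = 0.14, nir = 0.30),
                                           correlation_length = 1.0,
                                           texture_cv = 0.15),
                         shadow = list(enabled = FALSE,
                                       offset_t1 = c(0.9, 2.5),
                                       offset_t2 = c(1.7, 2.0),
                                       intensity = 0.55),
                         misregistration = c(0, 0),
                         noise_sd = 0.01, psf_sigma = 0.5, seed = 1L) {
  cfg <- list(extent = extent, pixel_size = pixel_size, n_animals = n_animals,
              animal_area_range = animal_area_range,
              animal_reflectance = animal_reflectance,
              animal_contrast_range = animal_contrast_range,
              aspect_range = aspect_range, movement = movement,
              min_separation = min_separation,
              background = background, shadow = shadow,
              misregistration = misregistration,
              noise_sd = noise_sd, psf_sigma = psf_sigma,
              seed = as.integer(seed))
  stopifnot(cfg$n_animals >= 0, cfg$noise_sd >= 0, cfg$psf_sigma >= 0,
            cfg$extent > 0, cfg$pixel_size > 0,
            cfg$animal_area_range[1] >= cfg$pixel_size^2,
            cfg$animal_area_range[2] <= cfg$extent^2)
  structure(cfg, class = "scene_config")
}

# periodic Gaussian-smoothed white-noise field, normalized to sd 1
gaussian_field <- function(nr, nc, sigma_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma_px <= 0) return(z)
  fr <- c(0:(floor(nr / 2)), -(ceiling(nr / 2) - 1):-1) / nr
  fc <- c(0:(floor(nc / 2)), -(ceiling(nc / 2) - 1):-1) / nc
  gk <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, `+`))
  sm <- Re(stats::fft(stats::fft(z) * gk, inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  fr <- c(0:(floor(nr / 2)), -(ceiling(nr / 2) - 1):-1) / nr
  fc <- c(0:(floor(nc / 2)), -(ceiling(nc / 2) - 1):-1) / nc
  gk <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(m) * gk, inverse = TRUE)) / (nr * nc)
}

# logical matrix of pixel centers inside a rotated ellipse (map coords);
# evaluated only on the ellipse's bounding box for speed
ellipse_mask <- function(nr, nc, transform, cx, cy, a, b, theta) {
  out <- matrix(FALSE, nr, nc)
  px <- map_to_pixel(c(cx - a, cx + a), c(cy + a, cy - a), transform)
  rows <- max(0L, px[1, "row"]):min(nr - 1L, px[2, "row"])
  cols <- max(0L, px[1, "col"]):min(nc - 1L, px[2, "col"])
  if (px[1, "row"] > nr - 1L || px[2, "row"] < 0L ||
      px[1, "col"] > nc - 1L || px[2, "col"] < 0L) return(out)
  rr <- rep(rows, length(cols)); cc <- rep(cols, each = length(rows))
  ctr <- pixel_to_map(rr, cc, transform)
  dx <- ctr[, 1] - cx; dy <- ctr[, 2] - cy
  u <- dx * cos(theta) + dy * sin(theta)
  w <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (w / b)^2 <= 1
  out[cbind(rr[inside] + 1L, cc[inside] + 1L)] <- TRUE
  out
}

#' Generate a synthetic T1/T2 pasture scene pair with known truth
#'
#' The background is a spatially correlated multiplicative texture field,
#' identical in T1 and T2 before noise (grass does not move). Each animal is
#' a filled rotated ellipse of the sampled footprint area, rendered at its T1
#' position in T1 and at `pos_t1 + displacement` in T2 (displacement
#' direction uniform, length from the movement interval, redrawn — up to
#' 1000 attempts — if it would leave the pasture). Optional attached shadows
#' are equally sized ellipses at an acquisition-specific offset, darkening
#' the background. The rendered scenes get a point-spread blur, independent
#' per-acquisition sensor noise, and (optionally) a residual mis-registration
#' applied to T2 by bilinear resampling (border pixels that sample outside
#' the scene become nodata). Fully reproducible from `config$seed`.
#'
#' @param config a [scene_config()].
#' @return object of class `synthetic_scene`: `t1`, `t2`
#'   ([multiband_image()]s), `truth` ([truth_set()]), `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  s <- config$pixel_size
  n <- as.integer(round(config$extent / s))
  tr <- geo_transform(0, config$extent, s)
  bg <- config$background
  g <- gaussian_field(n, n, bg$correlation_length / s)
  base <- lapply(bg$mean, function(mu) mu * (1 + bg$texture_cv * g))

  # animal placement and movement
  margin <- 2.5  # keep bodies and attached shadows inside the pasture
  k <- config$n_animals
  if (k > 0) {
    x1 <- y1 <- x2 <- y2 <- numeric(k)
    sep <- config$min_separation
    placed_x <- placed_y <- numeric(0)
    clear_of_others <- function(x, y)
      sep <= 0 || !length(placed_x) ||
        all((placed_x - x)^2 + (placed_y - y)^2 >= sep^2)
    for (i in seq_len(k)) {
      ok <- FALSE
      for (att in seq_len(1000)) {
        xx <- stats::runif(1, margin, config$extent - margin)
        yy <- stats::runif(1, margin, config$extent - margin)
        if (clear_of_others(xx, yy)) {
          x1[i] <- xx; y1[i] <- yy; ok <- TRUE; break
        }
      }
      if (!ok) stop_id("placement", "could not place animal %d", i)
      ok <- FALSE
      for (att in seq_len(1000)) {
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, config$movement[1], config$movement[2])
        xx <- x1[i] + len * cos(ang); yy <- y1[i] + len * sin(ang)
        if (xx > margin && xx < config$extent - margin &&
            yy > margin && yy < config$extent - margin &&
            clear_of_others(xx, yy)) {
          x2[i] <- xx; y2[i] <- yy; ok <- TRUE; break
        }
      }
      if (!ok) stop_id("placement", "could not place displacement for animal %d", i)
      placed_x <- c(placed_x, x1[i], x2[i])
      placed_y <- c(placed_y, y1[i], y2[i])
    }
    area <- stats::runif(k, config$animal_area_range[1], config$animal_area_range[2])
    aspect <- stats::runif(k, config$aspect_range[1], config$aspect_range[2])
    theta <- stats::runif(k, 0, pi)
    contrast <- stats::runif(k, config$animal_contrast_range[1],
                             config$animal_contrast_range[2])
    bsemi <- sqrt(area / (pi * aspect)); asemi <- aspect * bsemi
  }

  render <- function(phase) {
    bands <- base
    if (k > 0) {
      xs <- if (phase == "t1") x1 else x2
      ys <- if (phase == "t1") y1 else y2
      off <- if (phase == "t1") config$shadow$offset_t1 else config$shadow$offset_t2
      if (isTRUE(config$shadow$enabled)) {
        for (i in seq_len(k)) {
          sm <- ellipse_mask(n, n, tr, xs[i] + off[1], ys[i] + off[2],
                             asemi[i], bsemi[i], theta[i])
          for (b in seq_along(bands)) bands[[b]][sm] <-
              bands[[b]][sm] * config$shadow$intensity
        }
      }
      for (i in seq_len(k)) {
        am <- ellipse_mask(n, n, tr, xs[i], ys[i], asemi[i], bsemi[i], theta[i])
        for (b in seq_along(bands)) bands[[b]][am] <-
            base[[b]][am] + config$animal_reflectance[b] * contrast[i]
      }
    }
    if (config$psf_sigma > 0)
      bands <- lapply(bands, gaussian_blur, sigma_px = config$psf_sigma)
    bands <- lapply(bands, function(m) m + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n))
    multiband_image(array(unlist(bands), dim = c(n, n, 3)), tr,
                    band_names = names(bg$mean))
  }

  t1 <- render("t1")
  t2 <- render("t2")
  mis <- config$misregistration
  if (any(mis != 0)) {
    # displace T2 content by (dx, dy): the value seen at a pixel center p is
    # the true scene at p - (dx, dy)
    shift_fit <- identity_fit(s)
    shift_fit$coefficients[c("c", "f")] <- c(mis[1], mis[2])
    t2 <- warp_image(t2, shift_fit, tr, c(n, n))
  }
  truth <- if (k > 0) {
    truth_set(data.frame(id = seq_len(k), x_t1 = x1, y_t1 = y1,
                         x_t2 = x2, y_t2 = y2))
  } else {
    structure(list(animals = data.frame(id = integer(), x_t1 = numeric(),
                                        y_t1 = numeric(), x_t2 = numeric(),
                                        y_t2 = numeric()),
                   known_count = 0L), class = "truth_set")
  }
  structure(list(t1 = t1, t2 = t2, truth = truth, config = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %g m pasture, %d animals, seed %d\n",
              x$config$extent, x$config$n_animals, x$config$seed))
  invisible(x)
}

#' Generate a suite of independent pasture scenes
#'
#' Mirrors a multi-pasture survey design: independent scenes whose seeds are
#' derived from the base seed (`base seed + pasture index`), with optional
#' per-pasture config overrides (e.g. herd sizes varying 3–38 across
#' pastures).
#'
#' @param n_pastures number of scenes (>= 1).
#' @param base_cfg a [scene_config()] shared by all pastures.
#' @param overrides optional list (length `n_pastures`) of per-pasture
#'   config field overrides, e.g. `list(list(n_animals = 18), ...)`.
#' @return list of [generate_scene()] results.
#' @export
generate_pasture_suite <- function(n_pastures, base_cfg = scene_config(),
                                   overrides = NULL) {
  if (n_pastures < 1) stop_id("bad_suite", "n_pastures must be >= 1")
  lapply(seq_len(n_pastures), function(i) {
    cfg <- unclass(base_cfg)
    if (!is.null(overrides) && length(overrides) >= i && !is.null(overrides[[i]]))
      cfg <- utils::modifyList(cfg, overrides[[i]])
    cfg$seed <- base_cfg$seed + i
    generate_scene(do.call(scene_config, cfg))
  })
}

#' Write a scene to disk (paired GeoTIFFs, truth, config)
#'
#' Materializes `t1.tif`, `t2.tif`, `truth.csv`, `truth.geojson` and
#' `config.yaml` under a directory.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_geotiff(scene$t1, file.path(dir, "t1.tif"))
  write_geotiff(scene$t2, file.path(dir, "t2.tif"))
  write_truth(scene$truth, file.path(dir, "truth.csv"))
  write_truth(scene$truth, file.path(dir, "truth.geojson"))
  cfg <- unclass(scene$config)
  cfg$background$mean <- as.list(cfg$background$mean)
  cfg$animal_reflectance <- as.list(cfg$animal_reflectance)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
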