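#' Spectral threshold on the difference image
#'
#' The interval of absolute PC1 difference classed as change. Both bounds are
#' inclusive; the upper bound defaults to `Inf` (a pure lower cut).
#'
#' @param t_low minimum absolute difference classed as change (>= 0).
#' @param t_high upper bound, default `Inf`.
#' @return object of class `spectral_threshold`.
#' @export
spectral_threshold <- function(t_low, t_high = Inf) {
  if (!(t_low >= 0 && t_low < t_high))
    stop_id("bad_threshold", "need 0 <= t_low < t_high")
  structure(list(t_low = as.numeric(t_low), t_high = as.numeric(t_high)),
            class = "spectral_threshold")
}

#' Admissible polygon area interval
#'
#' Candidate animal polygons outside this area window are discarded: larger
#' features are too large to be animals (the upper limit accommodates two
#' animals close enough to merge into one polygon) and smaller ones are too
#' small. Bounds are inclusive — the removal rules are strict inequalities.
#'
#' @param min_area,max_area area bounds in m2 (defaults 0.99 and 10).
#' @return object of class `spatial_threshold`.
#' @export
spatial_threshold <- function(min_area = 0.99, max_area = 10) {
  if (!(min_area > 0 && min_area < max_area))
    stop_id("bad_threshold", "need 0 < min_area < max_area")
  structure(list(min_area = as.numeric(min_area),
                 max_area = as.numeric(max_area)),
            class = "spatial_threshold")
}

#' Binary change mask from a difference image
#'
#' Cell is `TRUE` iff unmasked and `t_low <= value <= t_high` (inclusive both
#' ends); pixels outside the spectral threshold are removed from the analysis.
#'
#' @param diff a [difference_pc1()] result.
#' @param st a [spectral_threshold()].
#' @return logical matrix.
#' @export
threshold_mask <- function(diff, st) {
  stopifnot(inherits(st, "spectral_threshold"))
  v <- diff$values
  m <- !is.na(v) & v >= st$t_low & v <= st$t_high
  m[is.na(m)] <- FALSE
  m
}

#' Suggest a spectral threshold from known animal locations
#'
#' Formalizes the heuristic threshold choice as a reproducible rule: sample
#' the difference values in a 3x3-pixel window around each known animal's T1
#' and T2 positions and take a low percentile (order statistic, default 5%)
#' of that sample as `t_low`. The percentile is an explicit, overridable
#' parameter, keeping the step semi-automated: the rule is reproducible but a
#' manual threshold can always be supplied instead.
#'
#' @param diff a [difference_pc1()] result.
#' @param truth a [truth_set()].
#' @param percentile fraction in `[0, 1]` (default 0.05).
#' @return a [spectral_threshold()] with `t_high = Inf`.
#' @export
suggest_threshold <- function(diff, truth, percentile = 0.05) {
  stopifnot(inherits(truth, "truth_set"), percentile >= 0, percentile <= 1)
  v <- diff$values
  nr <- nrow(v); nc <- ncol(v)
  samp <- numeric(0)
  pos <- rbind(as.matrix(truth$animals[c("x_t1", "y_t1")]),
               as.matrix(truth$animals[c("x_t2", "y_t2")]))
  px <- map_to_pixel(pos[, 1], pos[, 2], diff$transform)
  for (i in seq_len(nrow(px))) {
    rows <- (px[i, "row"] - 1):(px[i, "row"] + 1)
    cols <- (px[i, "col"] - 1):(px[i, "col"] + 1)
    rows <- rows[rows >= 0 & rows < nr]
    cols <- cols[cols >= 0 & cols < nc]
    if (length(rows) && length(cols))
      samp <- c(samp, as.vector(v[rows + 1, cols + 1]))
  }
  samp <- samp[!is.na(samp)]
  if (!length(samp))
    stop_id("no_sample", "no unmasked difference values around truth positions")
  spectral_threshold(quantile_type1(samp, percentile))
}

# union-find labeling of TRUE cells (C++ core); connectivity 4 or 8; returns
# a list of 0-based pixel-index matrices, one per component, ordered by the
# component's (min row, min col)
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  storage.mode(mask) <- "logical"
  lab <- .label_cc(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) return(list())
  cells <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[cells]
  ord <- order(lv, cells[, 1], cells[, 2])
  cells <- cells[ord, , drop = FALSE]; lv <- lv[ord]
  groups <- split(seq_len(nrow(cells)), lv)
  key_r <- vapply(groups, function(g) min(cells[g, 1]), 0L)
  key_c <- vapply(groups, function(g) min(cells[g, 2]), 0L)
  groups <- groups[order(key_r, key_c)]
  lapply(groups, function(g) {
    m <- cells[g, , drop = FALSE] - 1L   # 0-based
    colnames(m) <- c("row", "col")
    m
  })
}

# trace exact pixel-edge boundary rings of one component.
# pixels: 0-based (row, col) matrix. Returns list of closed rings in map
# coordinates; edge-cancellation + left-turn-priority walking, so diagonal
# pinch corners stay on one ring.
trace_rings <- function(pixels, transform) {
  r <- pixels[, 1]; c <- pixels[, 2]
  rmin <- min(r); cmin <- min(c)
  h <- max(r) - rmin + 1L; w <- max(c) - cmin + 1L
  L <- matrix(FALSE, h, w)
  L[cbind(r - rmin + 1L, c - cmin + 1L)] <- TRUE
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- L
  up    <- pad[1:h, 2:(w + 1)]
  down  <- pad[3:(h + 2), 2:(w + 1)]
  left  <- pad[2:(h + 1), 1:w]
  right <- pad[2:(h + 1), 3:(w + 2)]
  # directed edges, interior kept on the right of travel; corners in local
  # 0-based corner coords (corner (i,j) = top-left of local pixel (i,j));
  # dir codes 0=E,1=S,2=W,3=N
  es <- list()
  add <- function(which_cells, f_r, f_c, t_r, t_c, dir) {
    idx <- which(which_cells, arr.ind = TRUE)
    if (nrow(idx) == 0) return()
    i <- idx[, 1] - 1L; j <- idx[, 2] - 1L
    es[[length(es) + 1L]] <<- cbind(fr = i + f_r, fc = j + f_c,
                                    tr = i + t_r, tc = j + t_c, dir = dir)
  }
  add(L & !up,    0L, 0L, 0L, 1L, 0L)  # top edge, eastward
  add(L & !right, 0L, 1L, 1L, 1L, 1L)  # right edge, southward
  add(L & !down,  1L, 1L, 1L, 0L, 2L)  # bottom edge, westward
  add(L & !left,  1L, 0L, 0L, 0L, 3L)  # left edge, northward
  ed <- do.call(rbind, es)
  ne <- nrow(ed)
  from_key <- ed[, "fr"] * (w + 2L) + ed[, "fc"]
  to_key <- ed[, "tr"] * (w + 2L) + ed[, "tc"]
  # each corner has at most two outgoing boundary edges; build O(1) successor
  # lookup (out1/out2 indexed by position in the sorted unique-key table)
  ukeys <- sort(unique(from_key))
  pos_from <- match(from_key, ukeys)
  out1 <- out2 <- rep(NA_integer_, length(ukeys))
  for (i in seq_len(ne)) {
    p <- pos_from[i]
    if (is.na(out1[p])) out1[p] <- i else out2[p] <- i
  }
  pos_to <- match(to_key, ukeys)
  used <- rep(FALSE, ne)
  rings <- list()
  ord <- order(ed[, "fr"], ed[, "fc"], ed[, "dir"])
  for (start in ord) {
    if (used[start]) next
    path <- integer(64); len <- 0L
    cur <- start
    repeat {
      used[cur] <- TRUE
      len <- len + 1L
      if (len > length(path)) path <- c(path, integer(length(path)))
      path[len] <- cur
      if (to_key[cur] == from_key[start]) break
      p <- pos_to[cur]
      c1 <- out1[p]; c2 <- out2[p]
      if (!is.na(c1) && used[c1]) c1 <- NA_integer_
      if (!is.na(c2) && used[c2]) c2 <- NA_integer_
      if (is.na(c1) && is.na(c2)) break  # defensive; edge sets always close
      if (!is.na(c1) && !is.na(c2)) {
        # prefer the left turn, then straight, then right (relative to travel)
        pr1 <- match((ed[c1, "dir"] - ed[cur, "dir"]) %% 4, c(3, 0, 1, 2))
        pr2 <- match((ed[c2, "dir"] - ed[cur, "dir"]) %% 4, c(3, 0, 1, 2))
        cur <- if (pr1 <= pr2) c1 else c2
      } else {
        cur <- if (is.na(c1)) c2 else c1
      }
    }
    e <- path[seq_len(len)]
    rings[[length(rings) + 1L]] <- rbind(ed[e, c("fr", "fc"), drop = FALSE],
                                         ed[e[len], c("tr", "tc")])
  }
  s <- transform$pixel_size
  lapply(rings, function(m) {
    cbind(x = transform$origin_x + (cmin + m[, 2]) * s,
          y = transform$origin_y - (rmin + m[, 1]) * s,
          deparse.level = 0)
  })
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Extract change polygons from a binary mask
#'
#' One polygon per connected component of `TRUE` cells (8-connectivity by
#' default: compact animal blobs with point-spread halos produce diagonal
#' pixel chains that 4-connectivity would split). Boundaries trace the exact
#' pixel edges — no smoothing or simplification — so size and shape are
#' preserved; area is pixel count times pixel area. Output is sorted by
#' (min row, min col) of each component for deterministic, diffable results.
#'
#' @param mask logical matrix (from [threshold_mask()]).
#' @param transform the [geo_transform()] of the mask grid.
#' @param connectivity 8 (default) or 4.
#' @param rings trace boundary rings now (default). With `FALSE` the `rings`
#'   field is left `NULL` and can be filled later with [polygon_rings()] —
#'   useful when most candidates will be dropped by the area filter.
#' @return list of `detection_polygon` objects, each with `pixels` (0-based
#'   row/col matrix), `pixel_count`, `area_m2`, `centroid` (map coords, mean
#'   of member pixel centers), and `rings` (closed map-coordinate rings;
#'   exterior counter-clockwise, holes clockwise).
#' @export
extract_polygons <- function(mask, transform, connectivity = 8, rings = TRUE) {
  comps <- label_components(mask, connectivity)
  s <- transform$pixel_size
  out <- lapply(comps, function(px) {
    ctr <- pixel_to_map(px[, 1], px[, 2], transform)
    p <- structure(list(pixels = px, pixel_count = nrow(px),
                        area_m2 = nrow(px) * s^2,
                        centroid = c(x = mean(ctr[, 1]), y = mean(ctr[, 2])),
                        rings = NULL, transform = transform),
                   class = "detection_polygon")
    if (rings) p$rings <- polygon_rings(p)
    p
  })
  names(out) <- NULL
  out
}

#' Boundary rings of a detection polygon
#'
#' Returns the polygon's exact pixel-edge boundary rings in map coordinates
#' (exterior first, counter-clockwise; holes clockwise), tracing them if the
#' polygon was extracted with `rings = FALSE`.
#'
#' @param poly a `detection_polygon`.
#' @return list of closed two-column coordinate matrices.
#' @export
polygon_rings <- function(poly) {
  if (!is.null(poly$rings)) return(poly$rings)
  rings <- trace_rings(poly$pixels, poly$transform)
  areas <- vapply(rings, ring_signed_area, 0)
  ext <- which.max(abs(areas))
  rings <- lapply(seq_along(rings), function(i) {
    pos_wanted <- (i == ext)   # exterior CCW (positive), holes CW
    if ((areas[i] > 0) != pos_wanted)
      rings[[i]][rev(seq_len(nrow(rings[[i]]))), , drop = FALSE]
    else rings[[i]]
  })
  rings[c(ext, setdiff(seq_along(rings), ext))]
}

#' @export
print.detection_polygon <- function(x, ...) {
  cat(sprintf("<detection_polygon> %d px, %.4f m2, centroid (%.2f, %.2f)\n",
              x$pixel_count, x$area_m2, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Filter polygons by the spatial (area) threshold
#'
#' Keeps exactly the polygons with `min_area <= area_m2 <= max_area`
#' (inclusive bounds; the removal rules are strictly-greater / strictly-
#' smaller). Order is preserved; the filter is idempotent.
#'
#' @param polys list of polygons from [extract_polygons()].
#' @param st a [spatial_threshold()].
#' @return filtered list.
#' @export
filter_by_area <- function(polys, st = spatial_threshold()) {
  stopifnot(inherits(st, "spatial_threshold"))
  keep <- vapply(polys, function(p) p$area_m2 >= st$min_area &&
                                    p$area_m2 <= st$max_area, TRUE)
  polys[keep]
}

# distance from a map point to a polygon (0 if inside); min over member
# pixel footprints of the point-to-rectangle distance
polygon_point_distance <- function(poly, x, y) {
  s <- poly$transform$pixel_size
  lx <- poly$transform$origin_x + poly$pixels[, 2] * s
  hy <- poly$transform$origin_y - poly$pixels[, 1] * s
  ddx <- pmax(0, lx - x, x - (lx + s))
  ddy <- pmax(0, (hy - s) - y, y - hy)
  min(sqrt(ddx^2 + ddy^2))
}

#' Write detection polygons as GeoJSON
#'
#' FeatureCollection of Polygon features in map coordinates with properties
#' `area_m2`, `pixel_count`, `centroid_x`, `centroid_y`.
#'
#' @param polys list of polygons from [extract_polygons()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path) {
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    p$rings <- polygon_rings(p)
    list(type = "Feature",
         properties = list(id = i, area_m2 = p$area_m2,
                           pixel_count = p$pixel_count,
                           centroid_x = unname(p$centroid[1]),
                           centroid_y = unname(p$centroid[2])),
         geometry = list(type = "Polygon",
                         coordinates = lapply(p$rings, function(r)
                           lapply(seq_len(nrow(r)), function(k) unname(r[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a binary change mask as single-band GeoTIFF (0/1)
#'
#' @param mask logical matrix.
#' @param transform the mask's [geo_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_geotiff <- function(mask, transform, path) {
  img <- multiband_image(array(as.numeric(mask), dim = c(dim(mask), 1)),
                         transform, band_names = "change")
  write_geotiff(img, path)
}
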