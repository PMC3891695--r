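# shared fixtures: tiny images, random masks, and the independent
# connected-component oracle (igraph on the pixel-adjacency graph — a
# different algorithm and library from the package's union-find labeling)

make_image <- function(nrow = 10, ncol = 10, seed = 1, origin = c(0, nrow * 0.25),
                       pixel_size = 0.25, fill = NULL) {
  set.seed(seed)
  arr <- if (is.null(fill)) array(runif(nrow * ncol * 3), dim = c(nrow, ncol, 3))
         else array(fill, dim = c(nrow, ncol, 3))
  multiband_image(arr, geo_transform(origin[1], origin[2], pixel_size))
}

# ramp image: band b value = a_x * x + a_y * y + offset_b at pixel centers
make_ramp <- function(nrow, ncol, a_x = 2, a_y = 3, pixel_size = 0.25,
                      origin = c(0, nrow * pixel_size)) {
  gt <- geo_transform(origin[1], origin[2], pixel_size)
  ctr <- pixel_to_map(rep(0:(nrow - 1), ncol), rep(0:(ncol - 1), each = nrow), gt)
  plane <- matrix(a_x * ctr[, 1] + a_y * ctr[, 2], nrow, ncol)
  multiband_image(array(c(plane, plane + 1, plane + 2),
                        dim = c(nrow, ncol, 3)), gt)
}

random_mask <- function(nrow, ncol, density) {
  matrix(stats::runif(nrow * ncol) < density, nrow, ncol)
}

# oracle: component membership of TRUE cells via igraph
oracle_labels <- function(mask, connectivity = 8) {
  cells <- which(mask, arr.ind = TRUE)
  n <- nrow(cells)
  if (n == 0) return(list(n_components = 0L, membership = integer(0), cells = cells))
  K <- ncol(mask) + 2L
  keys <- cells[, 1] * K + cells[, 2]
  offs <- if (connectivity == 4) list(c(0, 1), c(1, 0))
          else list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  edges <- NULL
  for (o in offs) {
    nb <- match((cells[, 1] + o[1]) * K + (cells[, 2] + o[2]), keys)
    hit <- which(!is.na(nb))
    if (length(hit)) edges <- rbind(edges, cbind(hit, nb[hit]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  list(n_components = comp$no, membership = comp$membership, cells = cells)
}

# independent shoelace signed area of a closed ring
ring_area_for_test <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# translation-only affine fit (src -> dst displaced by dx, dy meters)
identity_fit_for_test <- function(dx = 0, dy = 0, pixel_size = 0.25) {
  fit_affine(data.frame(x1 = c(0, 10, 0), y1 = c(0, 0, 10),
                        x2 = c(0, 10, 0) + dx, y2 = c(0, 0, 10) + dy),
             pixel_size = pixel_size)
}

clean_cfg <- function(seed, extent = 100, n_animals = 6, ...) {
  scene_config(extent = extent, n_animals = n_animals, seed = seed,
               animal_reflectance = c(green = -0.08, red = -0.08, nir = -0.30),
               animal_contrast_range = c(1, 1), movement = c(4, 16),
               psf_sigma = 0, ...)
}
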