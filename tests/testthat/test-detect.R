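fake_diff <- function(values, pixel_size = 0.25) {
  structure(list(values = values,
                 transform = geo_transform(0, nrow(values) * pixel_size,
                                           pixel_size)),
            class = "difference_image")
}

test_that("spectral thresholding is inclusive at both bounds", {
  d <- fake_diff(matrix(c(0.1, 0.5, 0.9, NA), 2, 2))
  expect_equal(sum(threshold_mask(d, spectral_threshold(0))), 3)     # NA never true
  expect_equal(sum(threshold_mask(d, spectral_threshold(1.5))), 0)
  m <- threshold_mask(d, spectral_threshold(0.5))
  expect_equal(sort(d$values[m]), c(0.5, 0.9))
  m <- threshold_mask(d, spectral_threshold(0.1, 0.5))
  expect_equal(sort(d$values[m]), c(0.1, 0.5))
  expect_error(spectral_threshold(-1), "t_low")
  # raising t_low never increases the true-cell count
  set.seed(5)
  dd <- fake_diff(matrix(runif(900), 30, 30))
  counts <- sapply(seq(0, 1, 0.1), function(t)
    sum(threshold_mask(dd, spectral_threshold(t))))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold suggestion takes the percentile of truth-window samples", {
  # all sampled values equal c -> t_low = c
  d <- fake_diff(matrix(0.42, 10, 10))
  tr <- truth_set(data.frame(id = 1, x_t1 = 1.2, y_t1 = 1.2,
                             x_t2 = 2.0, y_t2 = 2.0))
  expect_equal(suggest_threshold(d, tr)$t_low, 0.42)

  # values 1..81 sampled in full: 5th percentile = sort-based order statistic
  set.seed(8)
  vals <- matrix(sample(1:81), 9, 9)
  d <- fake_diff(vals)
  # tile the whole 9x9 grid with 3x3 windows: truth positions every 3 px
  ctr <- expand.grid(x = c(0.375, 1.125, 1.875), y = c(0.375, 1.125, 1.875))
  tr <- truth_set(data.frame(id = seq_len(nrow(ctr)),
                             x_t1 = ctr$x, y_t1 = ctr$y,
                             x_t2 = ctr$x, y_t2 = ctr$y))
  got <- suggest_threshold(d, tr, percentile = 0.05)$t_low
  expect_equal(got, unname(quantile(vals[], 0.05, type = 1)))

  # truth point in a fully masked region is an error
  d <- fake_diff(matrix(NA_real_, 10, 10))
  tr1 <- truth_set(data.frame(id = 1, x_t1 = 1.2, y_t1 = 1.2,
                              x_t2 = 1.2, y_t2 = 1.2))
  expect_error(suggest_threshold(d, tr1), "no unmasked")
})

test_that("polygon extraction follows the connectivity rule", {
  gt <- geo_transform(0, 2.5, 0.25)
  m <- matrix(FALSE, 10, 10)
  m[3, 3] <- TRUE
  p <- extract_polygons(m, gt)
  expect_length(p, 1)
  expect_equal(p[[1]]$area_m2, 0.0625)
  expect_equal(p[[1]]$pixel_count, 1)
  ring <- p[[1]]$rings[[1]]
  expect_equal(nrow(ring), 5)                       # closed square
  expect_equal(abs(ring_area_for_test(ring)), 0.0625)

  # diagonal touch: one polygon under 8-connectivity, two under 4
  m <- matrix(FALSE, 10, 10); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_length(extract_polygons(m, gt, connectivity = 8), 1)
  expect_length(extract_polygons(m, gt, connectivity = 4), 2)
  # empty mask: empty list
  expect_length(extract_polygons(matrix(FALSE, 5, 5), gt), 0)
})

test_that("boundaries trace exact pixel edges (shoelace area = pixel count)", {
  set.seed(31)
  gt <- geo_transform(0, 10, 0.25)
  for (trial in 1:25) {
    m <- random_mask(40, 40, runif(1, 0.2, 0.7))
    polys <- extract_polygons(m, gt)
    # partition property: polygons cover every true cell exactly once
    expect_equal(sum(vapply(polys, `[[`, 0, "pixel_count")), sum(m))
    # enclosed (shoelace) area of the rings equals the pixel area, polygon-wise
    shoelace <- vapply(polys, function(p)
      sum(vapply(p$rings, ring_area_for_test, 0)), 0)
    expect_equal(shoelace, vapply(polys, `[[`, 0, "area_m2"), tolerance = 1e-10)
  }
})

test_that("component labeling agrees with the independent graph oracle", {
  set.seed(13)
  for (conn in c(4, 8)) {
    ok_counts <- ok_partition <- logical(200)
    for (trial in 1:200) {
      m <- random_mask(30, 30, runif(1, 0.1, 0.9))
      polys <- extract_polygons(m, geo_transform(0, 7.5), conn, rings = FALSE)
      orc <- oracle_labels(m, conn)
      ok_counts[trial] <- length(polys) == orc$n_components
      # each of our components must sit inside exactly one oracle component
      K <- ncol(m) + 2L
      okeys <- orc$cells[, 1] * K + orc$cells[, 2]
      ok_partition[trial] <- all(vapply(polys, function(p) {
        pk <- (p$pixels[, 1] + 1) * K + (p$pixels[, 2] + 1)
        length(unique(orc$membership[match(pk, okeys)])) == 1L
      }, TRUE))
    }
    expect_true(all(ok_counts))
    expect_true(all(ok_partition))
  }
})

test_that("polygon output is deterministic and ordered by first pixel", {
  set.seed(3)
  m <- random_mask(25, 25, 0.3)
  gt <- geo_transform(0, 25 * 0.25)
  a <- extract_polygons(m, gt)
  b <- extract_polygons(m, gt)
  expect_identical(a, b)
  firsts <- t(vapply(a, function(p) p$pixels[1, ], c(row = 0L, col = 0L)))
  keymin <- t(vapply(a, function(p) c(min(p$pixels[, 1]), min(p$pixels[, 2])), c(0L, 0L)))
  expect_false(is.unsorted(order(keymin[, 1], keymin[, 2])))
  expect_equal(order(keymin[, 1], keymin[, 2]), seq_along(a))
})

test_that("the area filter keeps exactly the 0.99-10 m2 window, inclusively", {
  gt <- geo_transform(0, 30, 0.25)
  # one component of npx pixels, laid out in rows of 40
  poly_of_n <- function(npx) {
    m <- matrix(FALSE, 60, 60)
    m[cbind(10 + (seq_len(npx) - 1) %/% 40, 5 + (seq_len(npx) - 1) %% 40)] <- TRUE
    p <- extract_polygons(m, gt)
    expect_length(p, 1)
    p[[1]]
  }
  st <- spatial_threshold()                  # 0.99 .. 10 m2
  expect_equal(poly_of_n(15)$area_m2, 0.9375)
  expect_length(filter_by_area(list(poly_of_n(15)), st), 0)   # too small
  expect_equal(poly_of_n(16)$area_m2, 1.0)
  expect_length(filter_by_area(list(poly_of_n(16)), st), 1)   # kept
  expect_equal(poly_of_n(160)$area_m2, 10.0)
  expect_length(filter_by_area(list(poly_of_n(160)), st), 1)  # kept
  expect_equal(poly_of_n(161)$area_m2, 10.0625)
  expect_length(filter_by_area(list(poly_of_n(161)), st), 0)  # too large

  # idempotent and monotone: shrinking the window never adds polygons
  polys <- lapply(c(10, 16, 50, 100, 160, 200), poly_of_n)
  kept <- filter_by_area(polys, st)
  expect_identical(filter_by_area(kept, st), kept)
  narrower <- filter_by_area(polys, spatial_threshold(2, 8))
  expect_true(all(vapply(narrower, `[[`, 0, "area_m2") %in%
                  vapply(kept, `[[`, 0, "area_m2")))
})
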