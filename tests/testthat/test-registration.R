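true_affine <- c(a = 1.001, b = -0.002, c = 3.2, d = 0.0015, e = 0.999, f = -1.7)
apply_affine <- function(co, xy) {
  cbind(co["a"] * xy[, 1] + co["b"] * xy[, 2] + co["c"],
        co["d"] * xy[, 1] + co["e"] * xy[, 2] + co["f"])
}

test_that("a known affine is recovered exactly from noiseless tie points", {
  set.seed(1)
  src <- cbind(runif(12, 0, 200), runif(12, 0, 200))
  dst <- apply_affine(true_affine, src)
  fit <- fit_affine(data.frame(x1 = src[, 1], y1 = src[, 2],
                               x2 = dst[, 1], y2 = dst[, 2]))
  expect_equal(unname(fit$coefficients), unname(true_affine), tolerance = 1e-9)
  expect_lt(fit$rmse_pixels, 1e-9)
  # three non-collinear points: 6 equations, 6 unknowns, exact fit
  fit3 <- fit_affine(data.frame(x1 = c(0, 10, 0), y1 = c(0, 0, 10),
                                x2 = c(1, 11.2, 0.7), y2 = c(2, 2.4, 12.5)))
  expect_lt(fit3$rmse_pixels, 1e-9)
  expect_error(fit_affine(data.frame(x1 = c(0, 1, 2), y1 = c(0, 1, 2),
                                     x2 = c(0, 1, 2), y2 = c(0, 1, 2))),
               "collinear")
})

test_that("RMSE under noise matches a brute-force residual recomputation", {
  set.seed(23)
  src <- cbind(runif(37, 0, 300), runif(37, 0, 300))
  dst <- apply_affine(true_affine, src) + matrix(rnorm(74, 0, 0.4), ncol = 2)
  tp <- data.frame(x1 = src[, 1], y1 = src[, 2], x2 = dst[, 1], y2 = dst[, 2])
  fit <- fit_affine(tp, pixel_size = 0.25)
  pred <- apply_affine(fit$coefficients, src)
  rmse_brute <- sqrt(mean((pred[, 1] - dst[, 1])^2 + (pred[, 2] - dst[, 2])^2)) / 0.25
  expect_equal(fit$rmse_pixels, rmse_brute, tolerance = 1e-9)
  # projection idempotence: refitting on the fitted predictions is exact
  fit2 <- fit_affine(data.frame(x1 = src[, 1], y1 = src[, 2],
                                x2 = pred[, 1], y2 = pred[, 2]))
  expect_equal(unname(fit2$coefficients), unname(fit$coefficients),
               tolerance = 1e-9)
  expect_lt(fit2$rmse_pixels, 1e-8)
})

test_that("warping is exact for identity and whole-pixel translations", {
  img <- make_image(12, 12, seed = 4)
  out <- warp_image(img, NULL, img$transform, dim(img))
  expect_equal(out$bands, img$bands)

  shift <- identity_fit_for_test(dx = 0.25, dy = 0)  # one pixel east
  out <- warp_image(img, shift, img$transform, dim(img))
  expect_equal(out$bands[, 2:12, ], img$bands[, 1:11, ])
  expect_true(all(is.na(out$bands[, 1, ])))  # no source data west of the grid
})

test_that("fractional warps reproduce a linear ramp and compose additively", {
  img <- make_ramp(20, 20)
  half <- identity_fit_for_test(dx = 0.125, dy = 0)  # half a pixel
  out <- warp_image(img, half, img$transform, dim(img))
  # interior of a ramp: bilinear interpolation is exact, shifted by dx
  expect_equal(out$bands[5:15, 5:15, 1], img$bands[5:15, 5:15, 1] - 2 * 0.125,
               tolerance = 1e-10)
  # composing two translations equals translating once by the sum
  a <- warp_image(warp_image(img, identity_fit_for_test(0.1, 0.05),
                             img$transform, dim(img)),
                  identity_fit_for_test(0.07, -0.12), img$transform, dim(img))
  b <- warp_image(img, identity_fit_for_test(0.17, -0.07),
                  img$transform, dim(img))
  expect_equal(a$bands[5:15, 5:15, ], b$bands[5:15, 5:15, ], tolerance = 1e-9)
})

test_that("mis-registration reports absolute per-axis offsets with mean and SD", {
  p <- cbind(runif(4, 0, 50), runif(4, 0, 50))
  r <- assess_misregistration(p, p)
  expect_equal(r$mean_x, 0); expect_equal(r$mean_y, 0)

  r <- assess_misregistration(p, cbind(p[, 1] + 0.26, p[, 2] - 1.28))
  expect_equal(r$mean_x, 0.26); expect_equal(r$mean_y, 1.28)
  expect_equal(r$std_x, 0); expect_equal(r$std_y, 0)

  p1 <- cbind(rep(0, 5), rep(0, 5))
  p2 <- cbind(c(0.2, 0.4, 0.6, 0.8, 1.0), c(0.4, 0.8, 1.2, 1.6, 2.0))
  r <- assess_misregistration(p1, p2)
  expect_equal(r$mean_x, 0.6); expect_equal(r$mean_y, 1.2)
  expect_equal(r$std_x, sd(c(0.2, 0.4, 0.6, 0.8, 1.0)))
  expect_error(assess_misregistration(p1, p2[1:3, ]), "length")

  f <- withr::local_tempfile(fileext = ".csv")
  df <- write_misregistration_csv(r, f, units = "cm")
  expect_equal(df$mean_x, 60); expect_equal(df$mean_y, 120)
  expect_equal(read.csv(f)$mean_y, 120)
})
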