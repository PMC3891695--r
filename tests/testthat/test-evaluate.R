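# polygon fixture: a square block of pixels around a map position
block_poly <- function(cx, cy, gt, half = 2) {
  px <- map_to_pixel(cx, cy, gt)
  m <- matrix(FALSE, 80, 80)
  m[(px[1] - half):(px[1] + half) + 1, (px[2] - half):(px[2] + half) + 1] <- TRUE
  extract_polygons(m, gt)[[1]]
}

gt20 <- geo_transform(0, 20, 0.25)

test_that("matching credits containment, flags distant polygons, allows duals", {
  tr <- truth_set(data.frame(id = 1, x_t1 = 5, y_t1 = 5, x_t2 = 9, y_t2 = 9))
  p_on <- block_poly(9, 9, gt20)
  mr <- match_detections(list(p_on), tr)
  expect_equal(mr$correct_polygons, 1)
  expect_equal(mr$missed, 0)
  expect_equal(mr$incorrect, 0)

  # a polygon farther than r_match from every truth position is incorrect
  p_far <- block_poly(15, 15, gt20)
  mr <- match_detections(list(p_on, p_far), tr)
  expect_equal(mr$incorrect, 1)
  expect_equal(mr$polygons$label, c("correct", "incorrect"))

  # one polygon containing two animals' positions: a dual
  tr2 <- truth_set(data.frame(id = 1:2, x_t1 = c(4.9, 5.1), y_t1 = c(5, 5.1),
                              x_t2 = c(14, 2), y_t2 = c(14, 2)))
  p_both <- block_poly(5, 5, gt20, half = 3)
  mr <- match_detections(list(p_both), tr2, match_on = "t1")
  expect_equal(mr$correct_polygons, 1)
  expect_equal(mr$dual_polygons, 1)
  expect_equal(mr$missed, 0)

  # proximity within r_match counts; beyond it does not
  p_near <- block_poly(9, 9, gt20)       # edge ~0.6 m from (10.2, 9)
  tr3 <- truth_set(data.frame(id = 1, x_t1 = 10.2, y_t1 = 9,
                              x_t2 = 10.2, y_t2 = 9))
  expect_equal(match_detections(list(p_near), tr3, r_match = 1)$missed, 0)
  expect_equal(match_detections(list(p_near), tr3, r_match = 0.3)$missed, 1)

  # deterministic under repetition
  mr1 <- match_detections(list(p_on, p_far, p_both), tr2)
  mr2 <- match_detections(list(p_on, p_far, p_both), tr2)
  expect_identical(mr1, mr2)
})

test_that("each animal is credited at most once: duplicate footprints become commission", {
  tr <- truth_set(data.frame(id = 1, x_t1 = 5, y_t1 = 5, x_t2 = 9, y_t2 = 9))
  both_footprints <- list(block_poly(5, 5, gt20), block_poly(9, 9, gt20))
  mr <- match_detections(both_footprints, tr)
  expect_equal(mr$correct_polygons, 1)
  expect_equal(mr$incorrect, 1)
  expect_equal(mr$missed, 0)
  ev <- compute_metrics(mr)
  expect_equal(ev$p_correct, 100)
  expect_equal(ev$p_commiss, 50)
})

test_that("accuracy metrics reproduce every published pasture row exactly", {
  counts <- eight_pasture_counts()
  expected <- rbind(
    c(50, 50, 40), c(66, 34, 15), c(75, 25, 70), c(79, 21, 33),
    c(92, 8, 83), c(93, 7, 90), c(97, 3, 0), c(100, 0, 95))
  for (i in 1:8) {
    ev <- compute_metrics(counts[i, ])
    expect_equal(ev$p_correct_rounded, expected[i, 1])
    expect_equal(ev$p_omiss_rounded, expected[i, 2])
    expect_equal(ev$p_commiss_rounded, expected[i, 3])
    # partition identities
    expect_equal(ev$mapped, ev$correct_polygons + ev$incorrect)
    expect_equal(ev$known, ev$correct_polygons + ev$dual_polygons + ev$missed)
    # correct and omission are complementary before rounding
    expect_equal(ev$p_correct + ev$p_omiss, 100)
  }
})

test_that("metrics handle degenerate inputs and reject inconsistent counts", {
  perfect <- compute_metrics(list(known = 10, mapped = 10, correct_polygons = 10,
                                  dual_polygons = 0, missed = 0, incorrect = 0))
  expect_equal(c(perfect$p_correct, perfect$p_omiss, perfect$p_commiss),
               c(100, 0, 0))
  none <- compute_metrics(list(known = 5, mapped = 0, correct_polygons = 0,
                               dual_polygons = 0, missed = 5, incorrect = 0))
  expect_equal(none$p_commiss, 0)
  expect_error(compute_metrics(list(known = 5, mapped = 3, correct_polygons = 2,
                                    dual_polygons = 0, missed = 2, incorrect = 2)),
               "mapped")
  # commission is monotone in incorrect count at fixed correct count
  pc <- sapply(0:10, function(k)
    compute_metrics(list(known = 8, mapped = 5 + k, correct_polygons = 5,
                         dual_polygons = 0, missed = 3, incorrect = k))$p_commiss)
  expect_true(all(diff(pc) >= 0))
})

test_that("the cross-pasture summary reproduces the published aggregates", {
  counts <- eight_pasture_counts()
  results <- lapply(1:8, function(i) compute_metrics(counts[i, ]))
  sm <- summarize_evaluations(results)
  expect_equal(unname(sm$means_rounded[c("p_correct", "p_omiss", "p_commiss")]),
               c(82, 18, 53))
  expect_equal(unname(sm$sums[c("known", "mapped", "incorrect",
                                "correct_polygons", "dual_polygons", "missed")]),
               c(158, 385, 265, 120, 6, 32))
  # published dispersion: SD 17/17/36 on the percentage columns
  expect_equal(unname(round_half_up(sm$sds[c("p_correct", "p_omiss", "p_commiss")])),
               c(17, 17, 36))
  # a single result: mean equals the result, SD absent
  one <- summarize_evaluations(results[7])
  expect_equal(unname(one$means["p_commiss"]), 0)
  expect_true(is.na(one$sds["p_correct"]))
})

test_that("count correction implements the detection-probability rule", {
  expect_equal(detection_probability(10, 20), 0.5)
  expect_equal(adjust_count(40, 0.50), 80)
  expect_equal(adjust_count(37, 1), 37)
  expect_error(adjust_count(40, 0), "detection_prob")
  expect_error(adjust_count(40, 1.2), "detection_prob")
  expect_error(detection_probability(25, 20), "observed")
})

test_that("truth sets round-trip through CSV and GeoJSON", {
  tr <- truth_set(data.frame(id = 1:3, x_t1 = c(1, 2, 3), y_t1 = c(4, 5, 6),
                             x_t2 = c(7, 8, 9), y_t2 = c(10, 11, 12)))
  fc <- withr::local_tempfile(fileext = ".csv")
  fg <- withr::local_tempfile(fileext = ".geojson")
  write_truth(tr, fc); write_truth(tr, fg)
  expect_equal(read_truth(fc)$animals, tr$animals)
  got <- read_truth(fg)$animals
  expect_equal(got[order(got$id), ], tr$animals, ignore_attr = TRUE)
  expect_error(truth_set(data.frame(id = c(1, 1), x_t1 = 1:2, y_t1 = 1:2,
                                    x_t2 = 1:2, y_t2 = 1:2)), "unique")
})
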