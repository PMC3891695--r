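#' Evaluation counts from the original eight-pasture census
#'
#' Per-pasture match counts from the eight fenced cattle/horse pastures used
#' to validate single-day image differencing: known animals (ground counts),
#' mapped change polygons, correctly mapped polygons, polygons representing
#' two animals, missed animals, and incorrectly mapped polygons. Feeding a
#' row to [compute_metrics()] reproduces the published accuracy percentages;
#' [summarize_evaluations()] over all rows reproduces the across-pasture
#' means (82% correct, 18% omission, 53% commission).
#'
#' @return data.frame with columns `pasture`, `known`, `mapped`,
#'   `correct_polygons`, `dual_polygons`, `missed`, `incorrect`.
#' @export
eight_pasture_counts <- function() {
  data.frame(
    pasture          = 1:8,
    known            = c(18, 38,  4, 29, 13,  15, 38,  3),
    mapped           = c(15, 26, 10, 33, 71, 136, 35, 59),
    correct_polygons = c( 9, 22,  3, 22, 12,  14, 35,  3),
    dual_polygons    = c( 0,  3,  0,  1,  0,   0,  2,  0),
    missed           = c( 9, 13,  1,  6,  1,   1,  1,  0),
    incorrect        = c( 6,  4,  7, 11, 59, 122,  0, 56)
  )
}
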