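#' Known animal locations for an image pair
#'
#' Ground-count surrogate: per-animal map positions at the two acquisition
#' times. Used to choose spectral thresholds and to score detections.
#'
#' @param animals data.frame with columns `id`, `x_t1`, `y_t1`, `x_t2`,
#'   `y_t2` (map meters). `id`s must be unique.
#' @return object of class `truth_set` with fields `animals` and
#'   `known_count`.
#' @export
truth_set <- function(animals) {
  animals <- as.data.frame(animals)
  need <- c("id", "x_t1", "y_t1", "x_t2", "y_t2")
  if (!all(need %in% names(animals)))
    stop_id("truth_columns", "truth needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(animals$id)) stop_id("truth_ids", "animal ids must be unique")
  structure(list(animals = animals[need], known_count = nrow(animals)),
            class = "truth_set")
}

#' Read a truth set from CSV or GeoJSON
#'
#' CSV: columns `id, x_t1, y_t1, x_t2, y_t2`. GeoJSON: Point features with
#' properties `id` and `phase` (`"t1"` or `"t2"`), one point per animal per
#' phase.
#'
#' @param path file path (`.csv` or `.geojson`/`.json`).
#' @return a [truth_set()].
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_id("missing_file", "file not found: %s", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    rows <- lapply(gj$features, function(f)
      data.frame(id = f$properties$id, phase = f$properties$phase,
                 x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]))
    long <- do.call(rbind, rows)
    t1 <- long[long$phase == "t1", ]; t2 <- long[long$phase == "t2", ]
    m <- merge(t1[c("id", "x", "y")], t2[c("id", "x", "y")],
               by = "id", suffixes = c("_t1", "_t2"))
    truth_set(m)
  } else {
    truth_set(utils::read.csv(path))
  }
}

#' Write a truth set (CSV and/or GeoJSON)
#'
#' @param truth a [truth_set()].
#' @param path output path; format chosen by extension as in [read_truth()].
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  a <- truth$animals
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- list()
    for (i in seq_len(nrow(a))) for (ph in c("t1", "t2")) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(id = a$id[i], phase = ph),
        geometry = list(type = "Point",
                        coordinates = c(a[[paste0("x_", ph)]][i],
                                        a[[paste0("y_", ph)]][i])))
    }
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(a, path, row.names = FALSE)
  }
  invisible(path)
}

#' Match detection polygons to known animal locations
#'
#' A polygon is eligible for an animal if it contains, or lies within
#' `r_match` of, the animal's T1 or T2 position (configurable via
#' `match_on`). Assignment is greedy in order of increasing polygon-animal
#' distance (distance to the nearer of the animal's considered positions;
#' ties broken by animal order then polygon order), each animal credited to
#' at most one polygon and each polygon credited at most two animals (two
#' animals close enough to merge produce one "dual" polygon). Polygons left
#' without credit are incorrectly mapped; animals left without credit are
#' missed. Deterministic: identical inputs give identical assignments.
#'
#' The default `r_match` of 1 m is roughly half an adult cow body length.
#'
#' @param polys list of polygons (after [filter_by_area()]).
#' @param truth a [truth_set()].
#' @param r_match coincidence radius in meters (> 0), default 1.
#' @param match_on which truth positions count: `"both"` (default), `"t1"`,
#'   `"t2"`.
#' @return object of class `match_result`: `polygons` data.frame (label,
#'   credited ids), `animals` data.frame (status, polygon index), and the
#'   counts `mapped`, `correct_polygons`, `dual_polygons`, `incorrect`,
#'   `missed`, `known`.
#' @export
match_detections <- function(polys, truth, r_match = 1.0,
                             match_on = c("both", "t1", "t2")) {
  match_on <- match.arg(match_on)
  stopifnot(inherits(truth, "truth_set"))
  if (r_match <= 0) stop_id("bad_r_match", "r_match must be > 0")
  np <- length(polys); na <- truth$known_count
  a <- truth$animals
  dmat <- matrix(Inf, np, na)
  for (p in seq_len(np)) for (k in seq_len(na)) {
    d <- Inf
    if (match_on %in% c("both", "t1"))
      d <- min(d, polygon_point_distance(polys[[p]], a$x_t1[k], a$y_t1[k]))
    if (match_on %in% c("both", "t2"))
      d <- min(d, polygon_point_distance(polys[[p]], a$x_t2[k], a$y_t2[k]))
    dmat[p, k] <- d
  }
  elig <- which(dmat <= r_match + 1e-9, arr.ind = TRUE)
  credited <- rep(NA_integer_, na)       # polygon index per animal
  n_credit <- rep(0L, np)
  if (nrow(elig)) {
    ord <- order(dmat[elig], elig[, 2], elig[, 1])
    for (i in ord) {
      p <- elig[i, 1]; k <- elig[i, 2]
      if (is.na(credited[k]) && n_credit[p] < 2L) {
        credited[k] <- p
        n_credit[p] <- n_credit[p] + 1L
      }
    }
  }
  poly_df <- data.frame(
    polygon = seq_len(np),
    n_animals = n_credit,
    label = ifelse(n_credit > 0L, "correct", "incorrect"))
  animal_df <- data.frame(
    id = a$id, polygon = credited,
    status = ifelse(is.na(credited), "missed", "detected"))
  structure(list(
    polygons = poly_df, animals = animal_df,
    mapped = np,
    correct_polygons = sum(n_credit > 0L),
    dual_polygons = sum(n_credit == 2L),
    incorrect = sum(n_credit == 0L),
    missed = sum(is.na(credited)),
    known = na
  ), class = "match_result")
}

#' Accuracy metrics for one pasture
#'
#' Computes the per-pasture accuracy row from match counts:
#' `p_correct = 100 * (correct_polygons + dual_polygons) / known` (animals
#' credited: a dual polygon counts its two animals),
#' `p_omiss = 100 * missed / known`, and
#' `p_commiss = 100 * incorrect / mapped` (0 when nothing was mapped).
#' The polygon-count variant `p_correct_polygon = 100 * correct_polygons /
#' known` is also reported for transparency. Percentages are kept unrounded
#' and additionally rounded to the nearest integer (half away from zero).
#'
#' The partition identities `mapped = correct_polygons + incorrect` and
#' `known = correct_polygons + dual_polygons + missed` are asserted.
#'
#' @param mr a [match_detections()] result, or a list/one-row data.frame of
#'   counts with fields `mapped`, `correct_polygons`, `dual_polygons`,
#'   `missed`, `incorrect` (so published count tables can be scored
#'   directly).
#' @param known known number of animals (defaults to `mr$known`).
#' @return object of class `evaluation_result`.
#' @export
compute_metrics <- function(mr, known = NULL) {
  g <- function(f) {
    v <- mr[[f]]
    if (is.null(v) || is.na(v)) stop_id("bad_counts", "missing count '%s'", f)
    as.numeric(v)
  }
  known <- as.numeric(known %||% mr[["known"]])
  if (is.null(known) || is.na(known) || known < 0)
    stop_id("bad_counts", "known must be a count >= 0")
  mapped <- g("mapped"); correct <- g("correct_polygons")
  dual <- g("dual_polygons"); missed <- g("missed"); incorrect <- g("incorrect")
  if (mapped != correct + incorrect)
    stop_id("inconsistent_counts", "mapped != correct_polygons + incorrect")
  if (known != correct + dual + missed)
    stop_id("inconsistent_counts",
            "known != correct_polygons + dual_polygons + missed")
  if (known == 0 && (correct + dual) > 0)
    stop_id("inconsistent_counts", "credited animals with known = 0")
  p_correct <- if (known > 0) 100 * (correct + dual) / known else NA_real_
  p_correct_polygon <- if (known > 0) 100 * correct / known else NA_real_
  p_omiss <- if (known > 0) 100 * missed / known else NA_real_
  p_commiss <- if (mapped > 0) 100 * incorrect / mapped else 0
  structure(list(
    known = known, mapped = mapped, correct_polygons = correct,
    dual_polygons = dual, missed = missed, incorrect = incorrect,
    p_correct = p_correct, p_omiss = p_omiss, p_commiss = p_commiss,
    p_correct_polygon = p_correct_polygon,
    p_correct_rounded = round_half_up(p_correct),
    p_omiss_rounded = round_half_up(p_omiss),
    p_commiss_rounded = round_half_up(p_commiss)
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> known %d, mapped %d (correct %d, dual %d, incorrect %d), missed %d\n",
    x$known, x$mapped, x$correct_polygons, x$dual_polygons, x$incorrect, x$missed))
  cat(sprintf("  P_correct %g%%  P_omiss %g%%  P_commiss %g%%\n",
              x$p_correct_rounded, x$p_omiss_rounded, x$p_commiss_rounded))
  invisible(x)
}

#' Summarize accuracy across pastures
#'
#' Column sums of the count fields plus the arithmetic mean and sample
#' standard deviation (n - 1) of the count fields and of the *unrounded*
#' percentage fields; rounded display values are derived afterwards. With a
#' single result the SDs are reported as `NA`.
#'
#' @param results list of [compute_metrics()] results.
#' @return object of class `evaluation_summary` with `sums`, `means`, `sds`,
#'   `means_rounded`, and the per-pasture `table`.
#' @export
summarize_evaluations <- function(results) {
  if (!length(results)) stop_id("empty_results", "need at least one result")
  stopifnot(all(vapply(results, inherits, TRUE, "evaluation_result")))
  counts <- c("known", "mapped", "correct_polygons", "dual_polygons",
              "missed", "incorrect")
  pcts <- c("p_correct", "p_omiss", "p_commiss")
  tab <- do.call(rbind, lapply(results, function(r)
    as.data.frame(r[c(counts, pcts,
                      paste0(pcts, "_rounded"), "p_correct_polygon")])))
  sds <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  structure(list(
    table = tab,
    sums = colSums(tab[counts]),
    means = colMeans(tab[c(counts, pcts)]),
    sds = vapply(tab[c(counts, pcts)], sds, 0),
    means_rounded = round_half_up(colMeans(tab[c(counts, pcts)])),
    n = nrow(tab)
  ), class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("<evaluation_summary> %d pastures\n", x$n))
  cat(sprintf("  mean P_correct %g%%, P_omiss %g%%, P_commiss %g%%\n",
              x$means_rounded["p_correct"], x$means_rounded["p_omiss"],
              x$means_rounded["p_commiss"]))
  cat(sprintf("  totals: known %d, mapped %d, incorrect %d, dual %d\n",
              x$sums["known"], x$sums["mapped"], x$sums["incorrect"],
              x$sums["dual_polygons"]))
  invisible(x)
}

#' Write evaluation results as CSV
#'
#' Per-pasture rows (counts, rounded and unrounded percentages) plus,
#' optionally, Sum / Mean / STD rows matching the conventional accuracy
#' table layout.
#'
#' @param results list of [compute_metrics()] results.
#' @param path output CSV path.
#' @param summary append Sum/Mean/STD rows (default `TRUE`).
#' @return the data.frame written, invisibly.
#' @export
write_evaluation_csv <- function(results, path, summary = TRUE) {
  sm <- summarize_evaluations(results)
  tab <- cbind(pasture = as.character(seq_len(nrow(sm$table))), sm$table)
  if (summary && nrow(tab) > 1) {
    counts <- c("known", "mapped", "correct_polygons", "dual_polygons",
                "missed", "incorrect")
    pcts <- c("p_correct", "p_omiss", "p_commiss")
    blank <- tab[1, ]; blank[, -1] <- NA
    mk <- function(label, vals) {
      r <- blank; r$pasture <- label
      for (nm in names(vals)) if (nm %in% names(r)) r[[nm]] <- vals[[nm]]
      r
    }
    tab <- rbind(tab,
                 mk("Sum", as.list(sm$sums)),
                 mk("Mean", as.list(round_half_up(sm$means))),
                 mk("STD", as.list(round_half_up(sm$sds))))
  }
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(tab)
}

#' Detection probability from a mark-resight check
#'
#' Ratio of marked animals observed during a survey to marked animals
#' available: 10 of 20 collared animals seen gives 0.50.
#'
#' @param observed marked animals seen during the survey.
#' @param marked marked animals available (> 0, >= observed).
#' @return detection probability in (0, 1].
#' @export
detection_probability <- function(observed, marked) {
  if (marked <= 0 || observed < 0 || observed > marked)
    stop_id("bad_resight", "need 0 <= observed <= marked, marked > 0")
  observed / marked
}

#' Correct a survey count by the detection probability
#'
#' Standard sightability correction: the raw count is divided by the
#' probability of detection (40 animals counted at p = 0.50 gives an
#' adjusted estimate of 80).
#'
#' @param count raw survey count (>= 0).
#' @param detection_prob detection probability in (0, 1].
#' @return adjusted population estimate.
#' @export
adjust_count <- function(count, detection_prob) {
  if (!(detection_prob > 0 && detection_prob <= 1))
    stop_id("bad_probability", "detection_prob must be in (0, 1]")
  if (count < 0) stop_id("bad_count", "count must be >= 0")
  count / detection_prob
}
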