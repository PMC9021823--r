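#' Outstanding-performance threshold
#'
#' The cohort-level cut for calling a performance "outstanding": the mean of
#' the pooled recalled performance scores plus one standard deviation. The
#' study design reports this rounded to the nearest integer (scores are
#' judge-panel aggregates on a 1--100 scale); full precision is available
#' with `round = "none"`.
#'
#' @param scores numeric vector of pooled performance scores (>= 2 values).
#' @param round `"nearest"` (default), `"floor"`, or `"none"`.
#' @param sd_method `"sample"` (default; pooled scores are a descriptive
#'   sample) or `"population"`.
#' @return single numeric threshold.
#' @examples
#' # a pooled set with mean 80 and SD 5 gives 85
#' outstanding_threshold(c(75, 85, 75, 85, 80), round = "none",
#'                       sd_method = "population")
#' @export
outstanding_threshold <- function(scores, round = c("nearest", "floor", "none"),
                                  sd_method = c("sample", "population")) {
  round <- match.arg(round)
  sd_method <- match.arg(sd_method)
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2)
    stop_izof("need at least 2 scores to set an outstanding threshold",
              class = "izof_estimability_error")
  thr <- mean(scores) + sd_by(scores, sd_method)
  switch(round, nearest = round(thr), floor = floor(thr), none = thr)
}

#' In-zone versus out-of-zone performance difference (D statistic)
#'
#' For each participant and subscale, D is the mean performance score over
#' recalled occasions whose subscale intensity falls inside the participant's
#' zone minus the mean score over occasions falling outside. D is undefined
#' (`NA`) when either side is empty; undefined values are excluded from, not
#' zero-filled into, cohort averages.
#'
#' @param cohort an `izof_cohort`; recalled occasions are used.
#' @param zones an `izof_zones` table from [estimate_zones()].
#' @return data frame with one row per participant and subscale:
#'   `participant_id`, `subscale`, `n_in`, `n_out`, `d_value`.
#' @export
d_statistics <- function(cohort, zones) {
  rec <- cohort[cohort$phase == "recalled", , drop = FALSE]
  out <- lapply(split(rec, rec$participant_id), function(d) {
    rows <- lapply(SUBSCALES, function(s) {
      z <- zones[zones$participant_id == d$participant_id[1] &
                   zones$subscale == s, ]
      if (nrow(z) != 1)
        stop_izof("no zone for participant ", d$participant_id[1],
                  " subscale ", s, class = "izof_estimability_error")
      inz <- classify_zone(d[[s]], z$lower, z$upper) == "in"
      data.frame(participant_id = d$participant_id[1], subscale = s,
                 n_in = sum(inz), n_out = sum(!inz),
                 d_value = if (any(inz) && any(!inz))
                   mean(d$score[inz]) - mean(d$score[!inz]) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correct-classification percentage of a zone
#'
#' The retrospective validity measure: the percentage of a participant's
#' recalled occasions that are concordant with the zone, i.e. outstanding
#' (score at or above `threshold`) *and* in-zone, or less-than-outstanding
#' *and* out-of-zone. The comparison uses `>=` so a score exactly at the
#' integer threshold counts as outstanding.
#'
#' @inheritParams d_statistics
#' @param threshold the outstanding-performance cut
#'   (see [outstanding_threshold()]).
#' @return data frame with one row per participant and subscale:
#'   `participant_id`, `subscale`, `n`, `pct` (0--100).
#' @export
correct_classification <- function(cohort, zones, threshold) {
  rec <- cohort[cohort$phase == "recalled", , drop = FALSE]
  if (nrow(rec) == 0)
    stop_izof("no recalled occasions", class = "izof_estimability_error")
  out <- lapply(split(rec, rec$participant_id), function(d) {
    rows <- lapply(SUBSCALES, function(s) {
      z <- zones[zones$participant_id == d$participant_id[1] &
                   zones$subscale == s, ]
      inz <- classify_zone(d[[s]], z$lower, z$upper) == "in"
      outstanding <- d$score >= threshold
      conc <- (outstanding & inz) | (!outstanding & !inz)
      data.frame(participant_id = d$participant_id[1], subscale = s,
                 n = nrow(d), pct = 100 * mean(conc),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cohort descriptive tables
#'
#' Builds the two cohort-level summaries of the retrospective phase:
#' `table1` describes, across participants, the personal-best performance
#' score `S` and each subscale's zone parameters (`M`, the zone center, and
#' `half_sd`, the zone half-width); `table2` is the classification report,
#' summarising per-participant correct-classification percentages per
#' subscale. Each participant carries equal weight in the averages.
#'
#' @inheritParams correct_classification
#' @return list with data frames `table1` (rows: mean, sd, median, min, max)
#'   and `table2` (one row per subscale: mean, sd, min, max of percentages).
#' @export
build_cohort_tables <- function(cohort, zones, threshold) {
  rec <- cohort[cohort$phase == "recalled", , drop = FALSE]
  best <- vapply(split(rec$score, rec$participant_id), max, numeric(1))
  ids <- names(best)

  cols <- list(S = describe(as.numeric(best)))
  for (s in SUBSCALES) {
    z <- zones[zones$subscale == s, ]
    z <- z[match(ids, z$participant_id), ]
    cols[[paste0(s, "_M")]] <- describe(z$center)
    cols[[paste0(s, "_half_sd")]] <- describe(z$half_width)
  }
  table1 <- data.frame(statistic = c("mean", "sd", "median", "min", "max"),
                       cols, stringsAsFactors = FALSE)

  cc <- correct_classification(cohort, zones, threshold)
  table2 <- do.call(rbind, lapply(SUBSCALES, function(s) {
    p <- cc$pct[cc$subscale == s]
    data.frame(subscale = s, mean = mean(p),
               sd = if (length(p) > 1) stats::sd(p) else 0,
               min = min(p), max = max(p), stringsAsFactors = FALSE)
  }))
  list(table1 = table1, table2 = table2)
}
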