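#' Estimate per-participant optimal zones
#'
#' For each participant, the optimal zone of a subscale is `M` plus or minus
#' half the within-person standard deviation: `M` is the mean subscale
#' intensity over the occasion(s) attaining that participant's maximum
#' recalled performance score (by default all occasions tied for the best are
#' included), and the SD is taken over *all* of the participant's recalled
#' occasions. The population (divide-by-n) SD is the default since the
#' recalled occasions form a fixed design rather than a sample.
#'
#' @param cohort an `izof_cohort` (or coercible data frame); only
#'   `phase == "recalled"` rows are used.
#' @param best_rule how "personal best" occasions are selected for `M`:
#'   `"all-tied-best"` (default; every occasion tied for the maximum score),
#'   `"top1"` (first occasion attaining the maximum, in row order),
#'   `"topk"` (the `k` highest-scoring occasions, ties broken by row order),
#'   or `"quantile"` (occasions with score at or above the `q` quantile).
#' @param sd_method `"population"` (divide by n, default) or `"sample"`
#'   (divide by n-1).
#' @param k,q parameters for `best_rule = "topk"` / `"quantile"`.
#' @return A data frame of class `izof_zones` with one row per participant
#'   and subscale: `participant_id`, `subscale`, `n_occasions_used`, `n_best`,
#'   `center`, `half_width`, `lower`, `upper`. Bounds are carried at full
#'   precision; round only for display.
#' @examples
#' occ <- data.frame(participant_id = 14, occasion_id = 1:4, phase = "recalled",
#'                   ca = c(22, 30, 30, 22), sa = 20, sc = 15,
#'                   score = c(95, 90, 95, 90))
#' estimate_zones(occ)  # CA zone [24, 28]: M = 26 over the two best, SD = 4
#' @export
estimate_zones <- function(cohort, best_rule = c("all-tied-best", "top1",
                                                 "topk", "quantile"),
                           sd_method = c("population", "sample"),
                           k = 2, q = 0.75) {
  best_rule <- match.arg(best_rule)
  sd_method <- match.arg(sd_method)
  if (!inherits(cohort, "izof_cohort")) cohort <- as_cohort(cohort)
  rec <- cohort[cohort$phase == "recalled", , drop = FALSE]
  if (nrow(rec) == 0)
    stop_izof("no recalled occasions to estimate zones from",
              class = "izof_estimability_error")
  out <- lapply(split(rec, rec$participant_id), function(d) {
    if (nrow(d) < 2)
      stop_izof("participant ", d$participant_id[1], " has fewer than 2 ",
                "recalled occasions", class = "izof_estimability_error")
    best <- switch(best_rule,
      "all-tied-best" = which(d$score == max(d$score)),
      "top1"          = which.max(d$score),
      "topk"          = order(-d$score)[seq_len(min(k, nrow(d)))],
      "quantile"      = which(d$score >= stats::quantile(d$score, q)))
    rows <- lapply(SUBSCALES, function(s) {
      m <- mean(d[[s]][best])
      hw <- sd_by(d[[s]], sd_method) / 2
      data.frame(participant_id = d$participant_id[1], subscale = s,
                 n_occasions_used = nrow(d), n_best = length(best),
                 center = m, half_width = hw,
                 lower = m - hw, upper = m + hw,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("izof_zones", "data.frame")
  out
}

#' Classify an anxiety intensity against a zone
#'
#' Membership is trichotomous: `below` when the intensity is under the lower
#' bound, `in` when it lies within the zone (both bounds inclusive), `above`
#' when it exceeds the upper bound. Inclusive bounds make membership and
#' [zone_distance()] consistent: `classify_zone(x, lo, up) == "in"` exactly
#' when `zone_distance(x, lo, up) == 0`.
#'
#' @param x numeric vector of intensities.
#' @param lower,upper zone bounds (recycled against `x`).
#' @return factor with levels `below`, `in`, `above`.
#' @examples
#' classify_zone(19, 19.68, 28)   # below
#' classify_zone(19.68, 19.68, 28) # in (inclusive bound)
#' @export
classify_zone <- function(x, lower, upper) {
  stopifnot(all(lower <= upper))
  factor(ifelse(x < lower, "below", ifelse(x > upper, "above", "in")),
         levels = c("below", "in", "above"))
}

#' Distance from an intensity to the closest zone border
#'
#' Zero for any in-zone intensity; otherwise the absolute distance to the
#' nearer of the two bounds. Continuous in `x` and weakly increasing as `x`
#' moves away from the zone on either side.
#'
#' @inheritParams classify_zone
#' @return numeric vector of nonnegative distances.
#' @examples
#' zone_distance(19, 19.68, 28)  # 0.68
#' zone_distance(30, 24, 28)     # 2
#' @export
zone_distance <- function(x, lower, upper) {
  stopifnot(all(lower <= upper))
  pmax(lower - x, x - upper, 0)
}

# Wide layout of a zone table: one row per participant, columns
# <subscale>_lower/<subscale>_upper/<subscale>_center. Internal convenience
# for membership and distance computations.
zones_wide <- function(zones) {
  ids <- unique(zones$participant_id)
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (s in SUBSCALES) {
    z <- zones[zones$subscale == s, ]
    m <- match(ids, z$participant_id)
    out[[paste0(s, "_center")]] <- z$center[m]
    out[[paste0(s, "_lower")]] <- z$lower[m]
    out[[paste0(s, "_upper")]] <- z$upper[m]
  }
  out
}
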