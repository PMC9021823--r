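# Fixed row order of the eight membership combinations, (SA, CA, SC),
# from all-in to none-in.
COMBINATION_PATTERNS <- matrix(c(
  "In",  "In",  "In",
  "In",  "In",  "Out",
  "In",  "Out", "In",
  "Out", "In",  "In",
  "In",  "Out", "Out",
  "Out", "In",  "Out",
  "Out", "Out", "In",
  "Out", "Out", "Out"), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("sa", "ca", "sc")))

#' Membership-combination table for predicted performances
#'
#' Assigns every predicted occasion to one of the eight In/Out patterns over
#' (SA, CA, SC) -- `below` and `above` both collapse to `Out` -- and
#' summarises the actual jury scores within each pattern. Rows are in the
#' fixed all-in to none-in order; counts partition the predicted cohort.
#'
#' @param cohort an `izof_cohort`; `phase == "predicted"` rows are used.
#' @param zones an `izof_zones` table covering every predicted participant.
#' @return data frame of class `izof_combinations` with columns
#'   `combination`, `sa`, `ca`, `sc`, `n`, `pct`, `mean`, `sd`, `median`,
#'   `min`, `max` (score statistics `NA` where undefined). The
#'   per-occasion assignments (with membership trichotomy and score) are
#'   attached as `attr(, "assignments")`.
#' @export
combination_table <- function(cohort, zones) {
  pred <- cohort[cohort$phase == "predicted", , drop = FALSE]
  assign <- membership_of(pred, zones)
  pat_key <- apply(COMBINATION_PATTERNS, 1, paste, collapse = "/")
  got_key <- paste(assign$sa_in, assign$ca_in, assign$sc_in, sep = "/")
  idx <- match(got_key, pat_key)
  total <- nrow(assign)

  rows <- lapply(seq_len(8), function(i) {
    sc <- assign$score[idx == i]
    n <- length(sc)
    data.frame(combination = i,
               sa = COMBINATION_PATTERNS[i, "sa"],
               ca = COMBINATION_PATTERNS[i, "ca"],
               sc = COMBINATION_PATTERNS[i, "sc"],
               n = n,
               pct = if (total > 0) 100 * n / total else NA_real_,
               mean = if (n > 0) mean(sc) else NA_real_,
               sd = if (n > 1) stats::sd(sc) else NA_real_,
               median = if (n > 0) stats::median(sc) else NA_real_,
               min = if (n > 0) min(sc) else NA_real_,
               max = if (n > 0) max(sc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "assignments") <- assign
  class(out) <- c("izof_combinations", "data.frame")
  out
}

# Per-predicted-occasion membership: trichotomy per subscale, In/Out collapse,
# number of in-zone subscales, and the actual score.
membership_of <- function(pred, zones) {
  zw <- zones_wide(zones)
  m <- match(pred$participant_id, zw$participant_id)
  if (nrow(pred) > 0 && anyNA(m))
    stop_izof("predicted occasions without estimated zones: participant(s) ",
              paste(unique(pred$participant_id[is.na(m)]), collapse = ", "),
              class = "izof_estimability_error")
  out <- data.frame(participant_id = pred$participant_id,
                    occasion_id = pred$occasion_id,
                    score = pred$score, stringsAsFactors = FALSE)
  for (s in SUBSCALES) {
    memb <- classify_zone(pred[[s]], zw[[paste0(s, "_lower")]][m],
                          zw[[paste0(s, "_upper")]][m])
    out[[paste0(s, "_membership")]] <- memb
    out[[paste0(s, "_in")]] <- ifelse(memb == "in", "In", "Out")
    out[[paste0(s, "_distance")]] <- zone_distance(
      pred[[s]], zw[[paste0(s, "_lower")]][m], zw[[paste0(s, "_upper")]][m])
  }
  out$n_in <- rowSums(out[paste0(SUBSCALES, "_in")] == "In")
  out
}

#' Percentage of the cohort with at least k subscales in-zone
#'
#' The prospective headline statistic: the percentage of predicted
#' performances whose membership pattern has at least `k` of the three
#' subscales inside the zone and whose actual score meets `score_floor`.
#'
#' @param combinations an `izof_combinations` table from
#'   [combination_table()].
#' @param k minimum number of in-zone subscales, 0--3.
#' @param score_floor minimum actual score (default `-Inf`: membership only).
#' @return single percentage in 0--100.
#' @export
at_least_k_in <- function(combinations, k, score_floor = -Inf) {
  stopifnot(is_count(k), k <= 3)
  assign <- attr(combinations, "assignments")
  if (is.null(assign)) {
    if (is.finite(score_floor))
      stop_izof("score_floor needs per-occasion assignments; build the table ",
                "with combination_table()", class = "izof_config_error")
    n_in <- rowSums(combinations[c("sa", "ca", "sc")] == "In")
    return(100 * sum(combinations$n[n_in >= k]) / sum(combinations$n))
  }
  if (nrow(assign) == 0) return(NA_real_)
  100 * mean(assign$n_in >= k & assign$score >= score_floor)
}

#' Trichotomous membership tally per subscale
#'
#' Counts, per subscale, how many predicted performances fall below, in, or
#' above the zone -- the full trichotomy that the binary In/Out combination
#' table collapses.
#'
#' @inheritParams combination_table
#' @return data frame with one row per subscale and membership status:
#'   `subscale`, `membership`, `n`, `pct`.
#' @export
membership_tally <- function(cohort, zones) {
  pred <- cohort[cohort$phase == "predicted", , drop = FALSE]
  assign <- membership_of(pred, zones)
  out <- do.call(rbind, lapply(SUBSCALES, function(s) {
    tab <- table(assign[[paste0(s, "_membership")]])
    data.frame(subscale = s, membership = names(tab),
               n = as.integer(tab),
               pct = if (nrow(assign) > 0) 100 * as.integer(tab) / nrow(assign)
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Zone-distance versus performance dataset
#'
#' One (distance, score) pair per predicted occasion per subscale: the
#' distance from the pre-performance anxiety intensity to the closest border
#' of the participant's zone (0 inside the zone) against the actual jury
#' score. This is the input to the rank-correlation analysis and the
#' scatterplot export.
#'
#' @inheritParams combination_table
#' @return data frame with columns `participant_id`, `occasion_id`,
#'   `subscale`, `distance`, `score`.
#' @export
distance_score_dataset <- function(cohort, zones) {
  pred <- cohort[cohort$phase == "predicted", , drop = FALSE]
  assign <- membership_of(pred, zones)
  out <- do.call(rbind, lapply(SUBSCALES, function(s) {
    data.frame(participant_id = assign$participant_id,
               occasion_id = assign$occasion_id,
               subscale = rep(s, nrow(assign)),
               distance = assign[[paste0(s, "_distance")]],
               score = assign$score, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tie-aware Spearman rank correlation
#'
#' Spearman's rho computed as the Pearson correlation of average-assigned
#' (mid)ranks, with a two-sided p-value from the t approximation on n - 2
#' degrees of freedom, or from exact enumeration of all permutations for
#' small samples. Ties -- ubiquitous in zone distances, which are exactly 0
#' inside the zone -- are handled by midranks in both modes.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param method `"t-approximation"` (default) or `"exact"` (full
#'   permutation enumeration; limited to n <= 8).
#' @return list of class `izof_cor`: `rho`, `p_value`, `n`, `method`. A
#'   constant input vector yields `rho = NA` (undefined) with `p_value = NA`.
#' @examples
#' spearman_cor(c(1, 2, 3), c(3, 2, 1))  # rho = -1
#' spearman_cor(c(1, 2, 3), c(1, 3, 2))  # rho = 0.5
#' @export
spearman_cor <- function(x, y, method = c("t-approximation", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y))
    stop_izof("x and y must have equal length", class = "izof_validation_error")
  n <- length(x)
  if (n < 3)
    stop_izof("need n >= 3 for a rank correlation p-value",
              class = "izof_validation_error")
  if (anyNA(x) || anyNA(y))
    stop_izof("missing values are not supported", class = "izof_validation_error")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    res <- list(rho = NA_real_, p_value = NA_real_, n = n, method = method)
    class(res) <- "izof_cor"
    return(res)
  }
  rho <- stats::cor(rx, ry)
  p <- if (method == "t-approximation") {
    if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8)
      stop_izof("exact permutation enumeration supported for n <= 8",
                class = "izof_config_error")
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    # |cov(rx, permuted ry)| is a monotone statistic for |rho| at fixed
    # marginal ranks, so compare the permuted cross-products directly
    stat <- abs(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc)
    mean(stat >= abs(sum(rxc * ryc)) - 1e-12)
  }
  res <- list(rho = rho, p_value = p, n = n, method = method)
  class(res) <- "izof_cor"
  res
}

#' @export
print.izof_cor <- function(x, ...) {
  cat("Spearman rank correlation (", x$method, ")\n", sep = "")
  cat("  rho =", formatC(x$rho, digits = 4, format = "f"),
      " p =", format.pval(x$p_value, digits = 3), " n =", x$n, "\n")
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows); n is kept small by callers.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Per-subscale rank correlations between zone distance and score.
phase2_correlations <- function(dist_scores, method = "t-approximation") {
  do.call(rbind, lapply(SUBSCALES, function(s) {
    d <- dist_scores[dist_scores$subscale == s, ]
    if (nrow(d) < 3) {
      return(data.frame(subscale = s, rho = NA_real_, p_value = NA_real_,
                        n = nrow(d), stringsAsFactors = FALSE))
    }
    r <- spearman_cor(d$distance, d$score, method = method)
    data.frame(subscale = s, rho = r$rho, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  }))
}
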