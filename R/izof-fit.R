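#' Fit individual zones of optimal functioning to a cohort
#'
#' The central entry point. From the recalled (retrospective) occasions it
#' estimates each participant's per-subscale optimal zone -- the mean
#' intensity at the personal-best performance(s) plus or minus half the
#' within-person SD -- and the retrospective validity statistics: the
#' cohort outstanding-performance threshold (pooled mean + 1 SD), the
#' in-zone/out-of-zone performance difference (D), per-participant correct
#' classification rates, and the cohort descriptive tables. If the cohort
#' contains predicted occasions (pre-jury anxiety plus the actual jury
#' score), the prospective stage is added: membership-combination table,
#' trichotomous membership tally, and tie-aware Spearman correlations
#' between zone distance and performance.
#'
#' @param data an `izof_cohort`, a data frame in the cohort schema, or a
#'   path to a cohort CSV (see [as_cohort()]).
#' @inheritParams estimate_zones
#' @param threshold_round rounding applied to the reported
#'   outstanding-performance threshold: `"nearest"` (default), `"floor"`,
#'   `"none"`.
#' @param item_key optional item key when `data` carries item columns.
#' @return An object of class `izof`: a list with components `zones`,
#'   `threshold` (list: `value` as used, `full` unrounded), `d_stats`,
#'   `classification`, `table1`, `table2`, `phase2` (list with
#'   `combinations`, `tally`, `distance_scores`, `correlations`, or `NULL`
#'   when the cohort has no predicted occasions), `cohort`, `settings`,
#'   `call`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 12), seed = 42)
#' fit <- izof(sim$cohort)
#' fit
#' coef(fit)[1:2, ]
#' summary(fit)
#' @seealso [estimate_zones()], [combination_table()], [run_pipeline()]
#' @export
izof <- function(data, best_rule = c("all-tied-best", "top1", "topk",
                                     "quantile"),
                 sd_method = c("population", "sample"),
                 threshold_round = c("nearest", "floor", "none"),
                 k = 2, q = 0.75, item_key = NULL) {
  best_rule <- match.arg(best_rule)
  sd_method <- match.arg(sd_method)
  threshold_round <- match.arg(threshold_round)
  cohort <- if (is.character(data) && length(data) == 1) {
    read_cohort(data, item_key = item_key)
  } else if (inherits(data, "izof_cohort")) data else {
    as_cohort(data, item_key = item_key)
  }

  zones <- estimate_zones(cohort, best_rule = best_rule,
                          sd_method = sd_method, k = k, q = q)
  rec <- cohort[cohort$phase == "recalled", ]
  thr_full <- outstanding_threshold(rec$score, round = "none")
  thr <- switch(threshold_round, nearest = round(thr_full),
                floor = floor(thr_full), none = thr_full)
  d_stats <- d_statistics(cohort, zones)
  classification <- correct_classification(cohort, zones, thr)
  tables <- build_cohort_tables(cohort, zones, thr)

  phase2 <- NULL
  if (any(cohort$phase == "predicted")) {
    ds <- distance_score_dataset(cohort, zones)
    phase2 <- list(combinations = combination_table(cohort, zones),
                   tally = membership_tally(cohort, zones),
                   distance_scores = ds,
                   correlations = phase2_correlations(ds))
  }

  structure(list(zones = zones,
                 threshold = list(value = thr, full = thr_full),
                 d_stats = d_stats, classification = classification,
                 table1 = tables$table1, table2 = tables$table2,
                 phase2 = phase2, cohort = cohort,
                 settings = list(best_rule = best_rule, sd_method = sd_method,
                                 threshold_round = threshold_round,
                                 k = k, q = q),
                 call = match.call()),
            class = "izof")
}

#' @export
print.izof <- function(x, ...) {
  n_part <- length(unique(x$cohort$participant_id))
  n_rec <- sum(x$cohort$phase == "recalled")
  n_pred <- sum(x$cohort$phase == "predicted")
  cat("Individual zones of optimal functioning\n\n")
  cat("  Participants:", n_part, "  recalled occasions:", n_rec,
      "  predicted occasions:", n_pred, "\n")
  cat("  Zone rule: M (", x$settings$best_rule, ") +/- SD/2 (",
      x$settings$sd_method, " SD)\n", sep = "")
  cat("  Outstanding threshold:", x$threshold$value,
      sprintf("(mean + 1 SD = %.2f)", x$threshold$full), "\n")
  if (!is.null(x$phase2)) {
    cat("  All three subscales in-zone:",
        sprintf("%.1f%%", x$phase2$combinations$pct[1]), "\n")
  }
  invisible(x)
}

#' @describeIn izof zone parameters as a matrix, one row per participant,
#'   columns `<subscale>_center`, `<subscale>_lower`, `<subscale>_upper`.
#' @param object,x an `izof` fit.
#' @param ... unused.
#' @export
coef.izof <- function(object, ...) {
  zw <- zones_wide(object$zones)
  m <- as.matrix(zw[-1])
  rownames(m) <- zw$participant_id
  m
}

#' @export
summary.izof <- function(object, ...) {
  d_summary <- do.call(rbind, lapply(SUBSCALES, function(s) {
    d <- object$d_stats$d_value[object$d_stats$subscale == s]
    d <- d[!is.na(d)]
    data.frame(subscale = s, n_defined = length(d),
               mean_d = if (length(d)) mean(d) else NA_real_,
               sd_d = if (length(d) > 1) stats::sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(table1 = object$table1, table2 = object$table2,
              d_summary = d_summary, threshold = object$threshold,
              phase2 = object$phase2)
  class(out) <- "summary.izof"
  out
}

#' @export
print.summary.izof <- function(x, digits = 3, ...) {
  cat("Cohort descriptives (best score S; zone center M and half-width):\n")
  print(format(x$table1, digits = digits), row.names = FALSE)
  cat("\nOutstanding threshold:", x$threshold$value,
      sprintf("(unrounded %.2f)", x$threshold$full), "\n")
  cat("\nCorrect classification (% across participants):\n")
  print(format(x$table2, digits = digits), row.names = FALSE)
  cat("\nIn-zone minus out-of-zone score difference (D):\n")
  print(format(x$d_summary, digits = digits), row.names = FALSE)
  if (!is.null(x$phase2)) {
    cat("\nPredicted-phase membership combinations (SA/CA/SC):\n")
    print(format(as.data.frame(x$phase2$combinations), digits = digits),
          row.names = FALSE)
    cat("\nZone distance vs performance (Spearman):\n")
    print(format(x$phase2$correlations, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Predict zone membership for new anxiety measurements
#'
#' Classifies new pre-performance CSAI-2 triplets against the fitted zones:
#' per-subscale membership (below/in/above), distance to the closest zone
#' border, the binary In/Out pattern, and the number of in-zone subscales.
#'
#' @param object an `izof` fit.
#' @param newdata data frame with `participant_id`, `ca`, `sa`, `sc`; by
#'   default the predicted-phase occasions of the training cohort.
#' @param ... unused.
#' @return data frame with one row per input row: memberships, distances,
#'   `n_in`, and `pattern` (e.g. `"In/Out/In"` in SA/CA/SC order).
#' @export
predict.izof <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- object$cohort[object$cohort$phase == "predicted", , drop = FALSE]
    if (nrow(newdata) == 0)
      stop_izof("no predicted occasions in the training cohort; supply newdata",
                class = "izof_validation_error")
  }
  if (!"occasion_id" %in% names(newdata)) newdata$occasion_id <- seq_len(nrow(newdata))
  if (!"score" %in% names(newdata)) newdata$score <- NA_real_
  a <- membership_of(newdata, object$zones)
  a$pattern <- paste(a$sa_in, a$ca_in, a$sc_in, sep = "/")
  a
}

#' Plot zone distance against performance score
#'
#' Scatterplots, one panel per subscale, of the distance from the
#' pre-performance anxiety intensity to the closest zone border against the
#' actual performance score, annotated with the Spearman correlation.
#'
#' @param x an `izof` fit with predicted occasions.
#' @param ... passed to [graphics::plot()].
#' @export
plot.izof <- function(x, ...) {
  if (is.null(x$phase2))
    stop_izof("no predicted occasions to plot", class = "izof_validation_error")
  ds <- x$phase2$distance_scores
  rho <- x$phase2$correlations
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  labs <- c(ca = "Cognitive anxiety", sa = "Somatic anxiety",
            sc = "Self-confidence")
  for (s in SUBSCALES) {
    d <- ds[ds$subscale == s, ]
    r <- rho$rho[rho$subscale == s]
    graphics::plot(d$distance, d$score, xlab = "Distance from zone border",
                   ylab = "Performance score",
                   main = sprintf("%s (rho = %.2f)", labs[[s]], r), ...)
  }
  invisible(x)
}

#' Simulate cohorts from a fitted zone model
#'
#' Parametric simulation: new cohorts are generated with each participant's
#' latent optimal triplet fixed at the fitted zone centers and latent
#' half-widths at the fitted half-widths, with occasion, performance and
#' judge noise taken from `config`.
#'
#' @param object an `izof` fit.
#' @param nsim number of cohorts.
#' @param seed integer seed (cohort `i` uses `seed + i - 1`).
#' @param config an `izof_sim_config` providing the noise parameters.
#' @param ... unused.
#' @return list of `nsim` cohorts (`izof_cohort` data frames).
#' @export
simulate.izof <- function(object, nsim = 1, seed = NULL,
                          config = cohort_config(), ...) {
  zw <- zones_wide(object$zones)
  mu <- as.matrix(zw[paste0(SUBSCALES, "_center")])
  colnames(mu) <- SUBSCALES
  z <- object$zones
  hw <- sapply(SUBSCALES, function(s)
    z$half_width[z$subscale == s][match(zw$participant_id,
                                        z$participant_id[z$subscale == s])])
  hw <- matrix(hw, nrow(mu), 3, dimnames = list(NULL, SUBSCALES))
  lapply(seq_len(nsim), function(i) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    sim <- generate_from_latents(mu, config, halfwidth = hw, seed = s)
    sim$cohort
  })
}
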