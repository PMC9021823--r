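#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the parameters of the data-generating model used by
#' [simulate_cohort()]. Defaults emulate the study design the analysis
#' assumes: 30 pianists, 4 recalled occasions plus 1 predicted jury, latent
#' optimal anxiety levels whose cohort distribution matches the reported
#' descriptives (CA 18.0 +/- 4.9, SA 17.3 +/- 4.8, SC 20.9 +/- 5.5 on the
#' 9--36 instrument scale), occasion-to-occasion state fluctuation, a
#' performance penalty proportional to distance from the latent zone, and a
#' seven-judge panel with independent judge noise.
#'
#' @param n_participants number of simulated pianists.
#' @param n_recalled,n_predicted occasions per participant in each phase.
#' @param center_mean,center_sd named numeric vectors (`ca`, `sa`, `sc`):
#'   cohort distribution of the latent optimal level per subscale,
#'   instrument units.
#' @param state_sd within-person SD of occasion-to-occasion anxiety
#'   fluctuation around the latent optimum, instrument units.
#' @param true_zone_halfwidth half-width of the latent optimal zone,
#'   instrument units; the default 1.3 equals half the default `state_sd`,
#'   which makes the estimated M +/- SD/2 band a consistent estimator of
#'   the latent zone.
#' @param base_score performance score at zero zone distance (1--100 scale).
#' @param penalty_beta score-units of penalty per unit of mean zone distance.
#' @param score_noise_sd SD of residual performance noise, score units.
#' @param n_judges panel size (>= 3).
#' @param judge_noise_sd SD of independent per-judge scoring noise.
#' @param subscale_correlation 3x3 correlation matrix for the state
#'   fluctuations across subscales (identity by default).
#' @param seed optional integer seed used by [simulate_cohort()].
#' @return list of class `izof_sim_config`.
#' @export
cohort_config <- function(n_participants = 30, n_recalled = 4, n_predicted = 1,
                          center_mean = c(ca = 18.0, sa = 17.3, sc = 20.9),
                          center_sd = c(ca = 4.9, sa = 4.8, sc = 5.5),
                          state_sd = 2.6,
                          true_zone_halfwidth = 1.3,
                          base_score = 93, penalty_beta = 2.0,
                          score_noise_sd = 1.0, n_judges = 7,
                          judge_noise_sd = 2.0,
                          subscale_correlation = diag(3), seed = NULL) {
  cfg <- list(n_participants = n_participants, n_recalled = n_recalled,
              n_predicted = n_predicted, center_mean = center_mean,
              center_sd = center_sd, state_sd = state_sd,
              true_zone_halfwidth = true_zone_halfwidth,
              base_score = base_score, penalty_beta = penalty_beta,
              score_noise_sd = score_noise_sd, n_judges = n_judges,
              judge_noise_sd = judge_noise_sd,
              subscale_correlation = subscale_correlation, seed = seed)
  for (f in c("n_participants", "n_recalled", "n_predicted", "n_judges"))
    if (!is_count(cfg[[f]]))
      stop_izof("config field '", f, "' must be a nonnegative integer",
                class = "izof_config_error")
  if (cfg$n_judges < 3)
    stop_izof("config field 'n_judges' must be >= 3", class = "izof_config_error")
  for (f in c("state_sd", "true_zone_halfwidth", "score_noise_sd",
              "judge_noise_sd"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0)
      stop_izof("config field '", f, "' must be a single nonnegative number",
                class = "izof_config_error")
  for (f in c("center_mean", "center_sd")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 3 || !all(SUBSCALES %in% names(v)))
      stop_izof("config field '", f, "' must be numeric with names ca, sa, sc",
                class = "izof_config_error")
    cfg[[f]] <- v[SUBSCALES]
  }
  if (any(cfg$center_sd < 0))
    stop_izof("config field 'center_sd' must be nonnegative",
              class = "izof_config_error")
  R <- cfg$subscale_correlation
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) ||
      !isSymmetric(unname(R)) || any(abs(diag(R) - 1) > 1e-12))
    stop_izof("config field 'subscale_correlation' must be a symmetric 3x3 ",
              "correlation matrix", class = "izof_config_error")
  class(cfg) <- "izof_sim_config"
  cfg
}

#' Simulate a cohort with known latent optimal zones
#'
#' Generates a complete cohort under the model the analysis assumes. Per
#' participant, a latent optimal triplet `mu` is drawn from the cohort
#' distribution and clipped to the 9--36 instrument range; the latent zone is
#' `mu` +/- `true_zone_halfwidth`. Each occasion's observed triplet is
#' `round(clip(mu + state noise))` (the instrument is integer-valued).
#' Occasion performance is `base_score - penalty_beta * mean(zone distance
#' over the three subscales) + noise`, clipped to 1--100; each judge reports
#' that performance plus independent noise, rounded and clipped, and the
#' occasion score is the trimmed panel aggregate ([aggregate_judges()]).
#'
#' The same `seed` and config give a bit-identical cohort. The caller's RNG
#' state is preserved.
#'
#' @param config an `izof_sim_config` from [cohort_config()].
#' @param seed integer seed; overrides `config$seed`.
#' @return list with `cohort` (an `izof_cohort` with judge columns) and
#'   `latents` (one row per participant and subscale: `participant_id`,
#'   `subscale`, `mu`, `true_lower`, `true_upper`).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 5), seed = 1)
#' head(sim$cohort)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  if (!inherits(config, "izof_sim_config"))
    stop_izof("config must come from cohort_config()",
              class = "izof_config_error")
  mu <- draw_latent_centers(config, seed = seed)
  generate_from_latents(mu, config,
                        seed = if (is.null(seed)) NULL else seed + 1L)
}

draw_latent_centers <- function(config, seed = NULL) {
  n <- config$n_participants
  if (n == 0)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, SUBSCALES)))
  with_seed(seed, {
    mu <- vapply(SUBSCALES, function(s)
      pmin(pmax(stats::rnorm(n, config$center_mean[[s]],
                             config$center_sd[[s]]), 9), 36), numeric(n))
    matrix(mu, nrow = n, dimnames = list(NULL, SUBSCALES))
  })
}

# Generate occasions, scores and judge panels around fixed latent centers.
# `mu` is an n x 3 matrix (columns ca, sa, sc); half-widths may be a single
# number or an n x 3 matrix for per-participant zones.
generate_from_latents <- function(mu, config, halfwidth = NULL, seed = NULL) {
  n <- nrow(mu)
  hw <- if (is.null(halfwidth)) config$true_zone_halfwidth else halfwidth
  if (length(hw) == 1) hw <- matrix(hw, n, 3, dimnames = list(NULL, SUBSCALES))
  n_occ <- config$n_recalled + config$n_predicted
  ids <- sprintf("P%03d", seq_len(n))

  latents <- data.frame(
    participant_id = rep(ids, each = 3),
    subscale = rep(SUBSCALES, times = n),
    mu = as.vector(t(mu)),
    true_lower = as.vector(t(mu - hw)),
    true_upper = as.vector(t(mu + hw)),
    stringsAsFactors = FALSE)

  empty <- data.frame(participant_id = character(0), occasion_id = character(0),
                      phase = character(0), ca = numeric(0), sa = numeric(0),
                      sc = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0 || n_occ == 0) {
    cohort <- empty
    class(cohort) <- c("izof_cohort", "data.frame")
    return(list(cohort = cohort, latents = latents))
  }

  L <- chol(config$subscale_correlation)
  rows <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      z <- matrix(stats::rnorm(n_occ * 3), n_occ, 3) %*% L
      intensity <- round(pmin(pmax(
        matrix(mu[i, ], n_occ, 3, byrow = TRUE) + config$state_sd * z, 9), 36))
      colnames(intensity) <- SUBSCALES
      dist <- sapply(SUBSCALES, function(s)
        zone_distance(intensity[, s], mu[i, s] - hw[i, s], mu[i, s] + hw[i, s]))
      dist <- matrix(dist, n_occ, 3)
      perf <- pmin(pmax(config$base_score -
                          config$penalty_beta * rowMeans(dist) +
                          stats::rnorm(n_occ, 0, config$score_noise_sd), 1), 100)
      judges <- round(pmin(pmax(
        matrix(perf, n_occ, config$n_judges) +
          matrix(stats::rnorm(n_occ * config$n_judges, 0,
                              config$judge_noise_sd), n_occ), 1), 100))
      score <- apply(judges, 1, aggregate_judges)
      phase <- rep(c("recalled", "predicted"),
                   c(config$n_recalled, config$n_predicted))
      occ <- c(if (config$n_recalled > 0) paste0("r", seq_len(config$n_recalled)),
               if (config$n_predicted > 0) paste0("p", seq_len(config$n_predicted)))
      d <- data.frame(participant_id = ids[i], occasion_id = occ, phase = phase,
                      ca = intensity[, "ca"], sa = intensity[, "sa"],
                      sc = intensity[, "sc"], score = score,
                      stringsAsFactors = FALSE)
      d[paste0("judge_", seq_len(config$n_judges))] <- judges
      d
    })
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort <- as_cohort(cohort)
  list(cohort = cohort, latents = latents)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Zone-center recovery error against known latents
#'
#' Mean absolute error, per subscale, between estimated zone centers and the
#' latent optimal levels of a simulated cohort -- the parameter-recovery
#' check that the M +/- SD/2 estimator is measuring what the generator
#' planted.
#'
#' @param zones an `izof_zones` table estimated on a simulated cohort.
#' @param latents the `latents` component returned by [simulate_cohort()].
#' @return named numeric vector `c(ca=, sa=, sc=)` of MAEs, instrument units.
#' @export
recovery_error <- function(zones, latents) {
  key_z <- paste(zones$participant_id, zones$subscale)
  key_l <- paste(latents$participant_id, latents$subscale)
  m <- match(key_z, key_l)
  if (anyNA(m) || length(key_z) != length(key_l))
    stop_izof("zones and latents cover different participant/subscale sets",
              class = "izof_alignment_error")
  err <- abs(zones$center - latents$mu[m])
  vapply(SUBSCALES, function(s) mean(err[zones$subscale == s]), numeric(1))
}
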