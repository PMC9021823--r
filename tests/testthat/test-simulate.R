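test_that("generator config validates its fields by name", {
  expect_s3_class(cohort_config(), "izof_sim_config")
  expect_error(cohort_config(n_participants = -1), "n_participants",
               class = "izof_config_error")
  expect_error(cohort_config(state_sd = -0.1), "state_sd",
               class = "izof_config_error")
  expect_error(cohort_config(n_judges = 2), "n_judges",
               class = "izof_config_error")
  expect_error(cohort_config(center_mean = c(ca = 18, sa = 17)),
               "center_mean", class = "izof_config_error")
  expect_error(cohort_config(subscale_correlation = matrix(1, 2, 2)),
               "subscale_correlation", class = "izof_config_error")
})

test_that("same seed and config give a bit-identical cohort", {
  a <- simulate_cohort(cohort_config(n_participants = 6), seed = 123)
  b <- simulate_cohort(cohort_config(n_participants = 6), seed = 123)
  expect_identical(a, b)
  c <- simulate_cohort(cohort_config(n_participants = 6), seed = 124)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("simulation preserves the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_cohort(cohort_config(n_participants = 3), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("an empty cohort request yields an empty, valid cohort", {
  sim <- simulate_cohort(cohort_config(n_participants = 0), seed = 1)
  expect_s3_class(sim$cohort, "izof_cohort")
  expect_equal(nrow(sim$cohort), 0)
  expect_equal(nrow(sim$latents), 0)
})

test_that("the noise-free limit degenerates to the base score inside the zone", {
  cfg <- cohort_config(n_participants = 10, state_sd = 0, score_noise_sd = 0,
                       judge_noise_sd = 0)
  sim <- simulate_cohort(cfg, seed = 2)
  lat <- sim$latents
  for (s in c("ca", "sa", "sc")) {
    l <- lat[lat$subscale == s, ]
    m <- match(sim$cohort$participant_id, l$participant_id)
    expect_equal(sim$cohort[[s]], round(pmin(pmax(l$mu[m], 9), 36)))
    expect_equal(zone_distance(sim$cohort[[s]], l$true_lower[m],
                               l$true_upper[m]),
                 rep(0, nrow(sim$cohort)))
  }
  expect_equal(sim$cohort$score, rep(93, nrow(sim$cohort)))
})

test_that("generated values always respect instrument and score bounds", {
  set.seed(71)
  for (i in 1:10) {
    cfg <- cohort_config(n_participants = sample(1:8, 1),
                         n_recalled = sample(2:5, 1),
                         state_sd = runif(1, 0, 8),
                         true_zone_halfwidth = runif(1, 0, 4),
                         base_score = runif(1, 40, 99),
                         penalty_beta = runif(1, 0, 10),
                         score_noise_sd = runif(1, 0, 10),
                         judge_noise_sd = runif(1, 0, 10))
    sim <- simulate_cohort(cfg, seed = i)
    coh <- sim$cohort
    for (s in c("ca", "sa", "sc")) {
      expect_true(all(coh[[s]] >= 9 & coh[[s]] <= 36))
      expect_true(all(coh[[s]] == floor(coh[[s]])))
    }
    expect_true(all(coh$score >= 1 & coh$score <= 100))
    judges <- as.matrix(coh[grep("^judge_", names(coh))])
    expect_true(all(judges >= 1 & judges <= 100))
    # occasion scores are the trimmed panel aggregate of their judges
    expect_equal(coh$score, apply(judges, 1, oracle_trim))
  }
})

test_that("the correlation hook induces cross-subscale state dependence", {
  R <- matrix(0.9, 3, 3); diag(R) <- 1
  cfg <- cohort_config(n_participants = 1, n_recalled = 400, n_predicted = 0,
                       subscale_correlation = R, state_sd = 3)
  sim <- simulate_cohort(cfg, seed = 8)
  expect_gt(cor(sim$cohort$ca, sim$cohort$sa), 0.6)
  cfg0 <- cohort_config(n_participants = 1, n_recalled = 400, n_predicted = 0,
                        state_sd = 3)
  sim0 <- simulate_cohort(cfg0, seed = 8)
  expect_lt(abs(cor(sim0$cohort$ca, sim0$cohort$sa)), 0.25)
})

test_that("recovery error is near zero without noise and relabel-invariant", {
  cfg <- cohort_config(n_participants = 12, state_sd = 0, score_noise_sd = 0,
                       judge_noise_sd = 0)
  sim <- simulate_cohort(cfg, seed = 4)
  z <- estimate_zones(sim$cohort)
  mae <- recovery_error(z, sim$latents)
  expect_true(all(mae <= 0.5))  # only the integer rounding of intensities

  shuf <- sim$latents[sample(nrow(sim$latents)), ]
  expect_equal(recovery_error(z, shuf), mae)
  expect_error(recovery_error(z, sim$latents[-1, ]),
               class = "izof_alignment_error")
})

test_that("zone-distance penalties produce negative rank correlations", {
  sim <- simulate_cohort(cohort_config(n_participants = 60, penalty_beta = 4,
                                       judge_noise_sd = 0.5), seed = 10)
  fit <- izof(sim$cohort)
  expect_true(all(fit$phase2$correlations$rho < 0))
})
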