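test_that("combination table counts patterns in the fixed SA/CA/SC order", {
  pats <- expand_counts(c(2, 0, 0, 0, 0, 0, 0, 1))
  coh <- make_pattern_cohort(pats, pred_scores = c(93, 95, 86))
  comb <- combination_table(coh, estimate_zones(coh))
  expect_equal(comb$n, c(2, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(comb$pct[1], 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(comb$pct[8], 100 * 1 / 3, tolerance = 1e-12)
  expect_equal(comb$mean[1], 94)
  expect_equal(comb$sd[1], sd(c(93, 95)))
  expect_true(is.na(comb$mean[2]))
  expect_equal(unname(unlist(comb[1, c("sa", "ca", "sc")])),
               c("In", "In", "In"))
})

test_that("combination table with no predicted occasions is empty but shaped", {
  d <- as_cohort(make_recalled("p", ca = c(18, 22, 20, 20), sa = rep(20, 4),
                               sc = rep(20, 4), score = c(95, 90, 91, 92)))
  comb <- combination_table(d, estimate_zones(d))
  expect_equal(nrow(comb), 8)
  expect_equal(comb$n, rep(0, 8))
  expect_true(all(is.na(comb$mean)))

  # predicted occasion without zones is an estimability error
  pred_only <- d[1, ]
  pred_only$phase <- "predicted"
  expect_error(combination_table(pred_only, make_zones("other")),
               class = "izof_estimability_error")
})

test_that("combination counts partition any simulated predicted cohort", {
  for (s in 1:5) {
    sim <- simulate_cohort(cohort_config(n_participants = 15), seed = s)
    fit <- izof(sim$cohort)
    comb <- fit$phase2$combinations
    expect_equal(sum(comb$n), 15)
    expect_equal(sum(comb$pct), 100, tolerance = 1e-9)
  }
})

test_that("at-least-k-in percentages follow the combination counts", {
  counts <- c(14, 1, 2, 1, 1, 0, 1, 10)
  coh <- make_pattern_cohort(expand_counts(counts))
  comb <- combination_table(coh, estimate_zones(coh))
  expect_equal(comb$n, counts)
  expect_equal(at_least_k_in(comb, 0), 100)
  expect_equal(at_least_k_in(comb, 2), 60, tolerance = 1e-12)
  expect_equal(at_least_k_in(comb, 3), 100 * 14 / 30, tolerance = 1e-12)

  # count-only path (a bare table without per-occasion assignments)
  bare <- as.data.frame(comb)
  attr(bare, "assignments") <- NULL
  expect_equal(at_least_k_in(bare, 2), 60, tolerance = 1e-12)
  expect_error(at_least_k_in(bare, 2, score_floor = 90),
               class = "izof_config_error")

  # a score floor filters individuals, not groups
  scores <- c(rep(95, 18), rep(85, 12))
  coh2 <- make_pattern_cohort(expand_counts(counts), pred_scores = scores)
  comb2 <- combination_table(coh2, estimate_zones(coh2))
  expect_equal(at_least_k_in(comb2, 2, score_floor = 90), 60)
  expect_equal(at_least_k_in(comb2, 0, score_floor = 90), 60)
})

test_that("membership tally keeps the below/in/above trichotomy", {
  pats <- expand_counts(c(1, 0, 0, 0, 0, 0, 0, 1))
  coh <- make_pattern_cohort(pats)
  tal <- membership_tally(coh, estimate_zones(coh))
  ca <- tal[tal$subscale == "ca", ]
  # the "Out" participant sits above the zone (value 25 vs zone [19, 21])
  expect_equal(ca$n[ca$membership == "in"], 1)
  expect_equal(ca$n[ca$membership == "above"], 1)
  expect_equal(sum(tal$n[tal$subscale == "sa"]), 2)
})

test_that("distance-score dataset has one pair per participant and subscale", {
  sim <- simulate_cohort(cohort_config(n_participants = 10), seed = 3)
  fit <- izof(sim$cohort)
  ds <- fit$phase2$distance_scores
  expect_equal(nrow(ds), 10 * 3)
  expect_true(all(ds$distance >= 0))

  # all-in predicted cohort: every distance is zero
  coh <- make_pattern_cohort(expand_counts(c(3, 0, 0, 0, 0, 0, 0, 0)))
  ds0 <- distance_score_dataset(coh, estimate_zones(coh))
  expect_equal(ds0$distance, rep(0, 9))
})

test_that("spearman matches hand computations and handles ties by midranks", {
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3), c(1, 3, 2))$rho, 0.5)

  x <- c(0, 0, 1, 2)  # midranks (1.5, 1.5, 3, 4)
  y <- c(5, 7, 6, 9)
  expect_equal(spearman_cor(x, y)$rho,
               oracle_pearson(c(1.5, 1.5, 3, 4), oracle_midrank(y)),
               tolerance = 1e-12)

  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
  expect_error(spearman_cor(1:2, 1:2), class = "izof_validation_error")
  expect_error(spearman_cor(1:4, 1:5), class = "izof_validation_error")
})

test_that("spearman agrees with the base-R cross-check and is rank-invariant", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- rnorm(n)
    r <- spearman_cor(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
    # invariant under strictly monotone transforms of either argument
    expect_equal(spearman_cor(exp(x), y^3 + 2 * y)$rho, r$rho,
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p-values match brute-force enumeration", {
  set.seed(62)
  x <- c(2, 0, 1, 1, 3)
  y <- c(10, 8, 9, 11, 14)
  r <- spearman_cor(x, y, method = "exact")
  # brute force: all 120 permutations of y against x
  perms <- izofr:::all_permutations(5)
  rhos <- apply(perms, 1, function(p) oracle_spearman(x, y[p]))
  expect_equal(r$p_value, mean(abs(rhos) >= abs(r$rho) - 1e-12),
               tolerance = 1e-12)
  expect_error(spearman_cor(1:9, 9:1, method = "exact"),
               class = "izof_config_error")
})

test_that("rank correlations approach -1 as generator noise vanishes", {
  # performance responds to the mean zone distance over subscales, so the
  # per-subscale limit needs the subscale states driven in lockstep
  R <- matrix(0.999, 3, 3); diag(R) <- 1
  cfg <- cohort_config(n_participants = 40, state_sd = 3,
                       true_zone_halfwidth = 0.4, penalty_beta = 4,
                       score_noise_sd = 0.01, judge_noise_sd = 0,
                       subscale_correlation = R)
  sim <- simulate_cohort(cfg, seed = 9)
  pred <- sim$cohort[sim$cohort$phase == "predicted", ]
  lat <- sim$latents
  dists <- sapply(c("ca", "sa", "sc"), function(s) {
    l <- lat[lat$subscale == s, ]
    m <- match(pred$participant_id, l$participant_id)
    zone_distance(pred[[s]], l$true_lower[m], l$true_upper[m])
  })
  # integer rounding of the intensities keeps the per-subscale correlations
  # just short of the pooled limit
  for (j in 1:3)
    expect_lt(spearman_cor(dists[, j], pred$score)$rho, -0.8)
  expect_lt(spearman_cor(rowMeans(dists), pred$score)$rho, -0.99)
})
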