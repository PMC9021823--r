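# Independent brute-force oracles, written against the definitions rather
# than the package implementation.

# Midranks computed by counting, not via rank().
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

# Pearson correlation from the explicit sum formula.
oracle_pearson <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

oracle_spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

# Zone estimation: explicit mean over argmax-score occasions and explicit
# root-mean-square deviation.
oracle_zone <- function(values, scores, sd_method = "population") {
  best <- values[scores == max(scores)]
  m <- sum(best) / length(best)
  n <- length(values)
  ss <- sum((values - sum(values) / n)^2)
  s <- if (sd_method == "population") sqrt(ss / n) else sqrt(ss / (n - 1))
  c(center = m, half_width = s / 2, lower = m - s / 2, upper = m + s / 2)
}

# Trimmed panel aggregate: sort, drop one from each end, average.
oracle_trim <- function(panel) {
  s <- sort(panel)
  mean(s[2:(length(s) - 1)])
}

# Correct classification by explicit occasion-by-occasion counting.
oracle_cc <- function(values, scores, lower, upper, threshold) {
  hits <- 0
  for (i in seq_along(values)) {
    inz <- values[i] >= lower && values[i] <= upper
    outst <- scores[i] >= threshold
    if ((outst && inz) || (!outst && !inz)) hits <- hits + 1
  }
  100 * hits / length(values)
}

# One-participant recalled block in the cohort schema.
make_recalled <- function(id, ca, sa, sc, score) {
  data.frame(participant_id = id, occasion_id = seq_along(score),
             phase = "recalled", ca = ca, sa = sa, sc = sc, score = score,
             stringsAsFactors = FALSE)
}

# A hand-built zone table row set for one participant.
make_zones <- function(id, ca = c(19, 21), sa = c(19, 21), sc = c(19, 21)) {
  do.call(rbind, Map(function(s, b) {
    data.frame(participant_id = id, subscale = s, n_occasions_used = 4,
               n_best = 1, center = mean(b), half_width = diff(b) / 2,
               lower = b[1], upper = b[2], stringsAsFactors = FALSE)
  }, c("ca", "sa", "sc"), list(ca, sa, sc)))
}

# Cohort whose per-participant zones are [19, 21] on every subscale:
# recalled values (18, 22, 22, 18) with scores (95, 95, 90, 90) give
# M = 20 and population SD = 2. Predicted triplets are then placed in or
# out of zone per the requested (SA, CA, SC) In/Out pattern.
make_pattern_cohort <- function(patterns, pred_scores = NULL) {
  n <- nrow(patterns)
  if (is.null(pred_scores)) pred_scores <- rep(90, n)
  rows <- lapply(seq_len(n), function(i) {
    id <- sprintf("S%02d", i)
    rec <- make_recalled(id, ca = c(18, 22, 22, 18), sa = c(18, 22, 22, 18),
                         sc = c(18, 22, 22, 18), score = c(95, 95, 90, 90))
    val <- function(m) if (m == "In") 20 else 25
    pred <- data.frame(participant_id = id, occasion_id = "jury",
                       phase = "predicted",
                       ca = val(patterns[i, "ca"]), sa = val(patterns[i, "sa"]),
                       sc = val(patterns[i, "sc"]), score = pred_scores[i],
                       stringsAsFactors = FALSE)
    rbind(rec, pred)
  })
  as_cohort(do.call(rbind, rows))
}

# Expand Table-style combination counts (SA/CA/SC order, all-in first) into
# one pattern row per participant.
expand_counts <- function(counts) {
  pats <- matrix(c("In", "In", "In",
                   "In", "In", "Out",
                   "In", "Out", "In",
                   "Out", "In", "In",
                   "In", "Out", "Out",
                   "Out", "In", "Out",
                   "Out", "Out", "In",
                   "Out", "Out", "Out"), ncol = 3, byrow = TRUE,
                 dimnames = list(NULL, c("sa", "ca", "sc")))
  pats[rep(seq_len(8), counts), , drop = FALSE]
}
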