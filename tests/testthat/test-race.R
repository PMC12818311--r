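# Two-accumulator race: analytic choice probability, simulation,
# mutual inhibition, bias, priority index, CP-by-SRT.

unit <- function(m, svm = 1 / 6, t0 = 80) {
  later_params(mu = 1 / m, sigma = svm / m, t0_ms = t0)
}

test_that("race probability matches its closed form at anchor points", {
  u <- unit(150)
  expect_equal(race_probability(race_spec(u, u)), 0.5)
  # rate difference of one pooled SD: Phi(1)
  s <- sqrt(2) * u$sigma
  u2 <- later_params(u$mu - s, u$sigma, 80)
  expect_equal(race_probability(race_spec(u, u2)), 0.8413447,
               tolerance = 1e-6)
  # deterministic race
  d1 <- later_params(1 / 100, 0, 80)
  d2 <- later_params(1 / 200, 0, 80)
  expect_equal(race_probability(race_spec(d1, d2)), 1)
  expect_error(race_probability(race_spec(d1, d1)), "tie")
})

test_that("simulation converges to the analytic race probability", {
  spec <- race_spec(unit(140), unit(180), beta = 0.9)
  p <- race_probability(spec)
  tr <- simulate_race(spec, 1e5, seed = 3)
  expect_lt(abs(mean(tr$winner == "ratio1") - p), 0.005)
})

test_that("an uninhibited race shows statistical facilitation", {
  u1 <- unit(150)
  u2 <- unit(160)
  race <- simulate_race(race_spec(u1, u2, beta = 1), 2e4, seed = 9)
  single <- sample_srt(u1, 2e4, seed = 10)
  expect_lte(median(race$srt_ms), median(single))
})

test_that("inhibition can be solved to produce a target two-choice slowing", {
  # construct beta so the analytic race median exceeds the single-unit
  # median by 37 ms, then confirm by simulation
  u1 <- unit(210)
  u2 <- unit(218)
  single_med <- 80 + 210
  beta_hat <- uniroot(function(b) {
    spec <- race_spec(u1, u2, beta = b)
    race_srt_quantiles(spec, 0.5) - single_med - 37
  }, c(0.55, 0.999), tol = 1e-9)$root
  expect_lt(beta_hat, 1)
  tr <- simulate_race(race_spec(u1, u2, beta = beta_hat), 2e5, seed = 4)
  expect_equal(median(tr$srt_ms) - single_med, 37, tolerance = 0.06)
})

test_that("mutual inhibition is recovered from two-choice quantiles", {
  u1 <- unit(140)
  u2 <- unit(230)
  spec <- race_spec(u1, u2, beta = 0.85)
  srts <- simulate_race(spec, 960, seed = 15)$srt_ms
  fit <- fit_mutual_inhibition(srts, list(ratio1 = u1, comp = u2))
  expect_equal(fit$beta, 0.85, tolerance = 0.03 / 0.85)
  expect_false(fit$boundary)
})

test_that("an uninhibited generator drives beta to the boundary with a warning", {
  u1 <- unit(140)
  u2 <- unit(150)
  srts <- simulate_race(race_spec(u1, u2, beta = 1), 960, seed = 16)$srt_ms
  expect_warning(
    fit <- fit_mutual_inhibition(srts, list(ratio1 = u1, comp = u2)),
    "boundary"
  )
  expect_gt(fit$beta, 0.97)
})

test_that("small samples still return a usable inhibition estimate", {
  u1 <- unit(140)
  u2 <- unit(230)
  srts <- simulate_race(race_spec(u1, u2, beta = 0.85), 120,
                        seed = 17)$srt_ms
  fit <- suppressWarnings(
    fit_mutual_inhibition(srts, list(ratio1 = u1, comp = u2))
  )
  expect_true(fit$beta >= 0.5 && fit$beta <= 1)
})

test_that("CP1 prediction handles equal rates, dominance and bias cancellation", {
  u1 <- unit(150)
  expect_equal(predict_cp1(u1, u1), 0.5)
  # a much slower competitor (low ratio): CP1 well above chance
  expect_gt(predict_cp1(u1, unit(320), beta = 0.85), 0.95)
  # side-averaged bias cancels to first order
  bias <- 0.2 * u1$sigma
  u2 <- unit(165)
  spec <- race_spec(u1, u2, bias = bias)
  side_gap <- race_probability(spec, "right") - race_probability(spec, "left")
  expect_gt(side_gap, 0.01)
  expect_equal(predict_cp1(u1, u2, bias = bias), predict_cp1(u1, u2),
               tolerance = 0.005)
})

test_that("the priority index interpolates between its anchors", {
  expect_equal(priority_index(0.75, 0.75, 0), 1)
  expect_equal(priority_index(0, 0.75, 0), 0)
  # the worked case: observed 76% against a 75% race prediction
  expect_equal(priority_index(0.76, 0.75, 0), 1.0133, tolerance = 1e-4)
  # affine invariance
  f <- function(p) 0.2 + 0.6 * p
  expect_equal(priority_index(f(0.7), f(0.8), f(1)),
               priority_index(0.7, 0.8, 1))
  expect_error(priority_index(0.7, 1, 1), "undefined")
  expect_error(priority_index(0.7, 0.8, 1.3), "cp_salience")
})

test_that("directional bias estimation finds planted preferences", {
  set.seed(31)
  sym <- tibble::tibble(
    participant_id = "P1",
    chosen_side = sample(c("left", "right"), 400, replace = TRUE)
  )
  est <- estimate_directional_bias(sym)
  expect_gt(est$p_value, 0.05)

  biased <- tibble::tibble(
    participant_id = "P2",
    chosen_side = sample(c("left", "right"), 600, replace = TRUE,
                         prob = c(0.4, 0.6))
  )
  est <- estimate_directional_bias(biased, sigma_ref = 0.001)
  expect_lt(est$p_value, 0.05)
  lo_true <- log(0.6 / 0.4)
  se <- sqrt(1 / (est$n_right) + 1 / (est$n_trials - est$n_right))
  expect_lt(abs(est$log_odds_right - lo_true), 2 * se)
  expect_gt(est$bias_rate, 0)

  one_sided <- tibble::tibble(participant_id = "P3",
                              chosen_side = rep("right", 50))
  expect_error(estimate_directional_bias(one_sided), "single-sided")
})

test_that("bias pooling is invariant to condition labels", {
  set.seed(33)
  trials <- tibble::tibble(
    participant_id = "P1",
    condition = rep(c("a", "b"), each = 200),
    chosen_side = sample(c("left", "right"), 400, replace = TRUE,
                         prob = c(0.45, 0.55))
  )
  shuffled <- trials
  shuffled$condition <- sample(shuffled$condition)
  expect_equal(estimate_directional_bias(trials)$log_odds_right,
               estimate_directional_bias(shuffled)$log_odds_right)
})

test_that("choice probability by SRT bin behaves under null and mixture", {
  spec <- race_spec(unit(150), unit(200), beta = 0.9)
  tr <- simulate_race(spec, 6000, seed = 41)
  trials <- tibble::tibble(srt_ms = tr$srt_ms,
                           chose_ratio1 = tr$winner == "ratio1")
  # single bin equals the overall CP
  one <- cp_by_srt(trials, breaks = c(0, 1e4))
  expect_equal(one$cp, mean(trials$chose_ratio1))
  # under the null of SRT-independent choice the CP profile is flat:
  # per-bin CPs cover the generating probability
  set.seed(43)
  null_trials <- tibble::tibble(
    srt_ms = sample_srt(later_params(1 / 150, 1 / 900, 80), 5000),
    chose_ratio1 = runif(5000) < 0.7
  )
  bins <- cp_by_srt(null_trials,
                    breaks = quantile(null_trials$srt_ms, seq(0, 1, 0.2)))
  covered <- mean(bins$ci_lo <= 0.7 & 0.7 <= bins$ci_hi)
  expect_gte(covered, 0.8)
  # mixture: slow trials choose at random, so CP decays toward 0.5
  set.seed(42)
  slow <- tibble::tibble(
    srt_ms = runif(3000, 350, 500),
    chose_ratio1 = sample(c(TRUE, FALSE), 3000, replace = TRUE)
  )
  fast <- trials[trials$srt_ms < 300, ]
  mix <- dplyr::bind_rows(fast, slow)
  res <- cp_by_srt(mix, breaks = c(0, 300, 600))
  expect_gt(res$cp[1], res$cp[2])
  expect_equal(res$cp[2], 0.5, tolerance = 0.05)
  expect_false(any(res$sparse))
  expect_s3_class(attr(res, "srt_cdf"), "tbl_df")
})
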