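# Payoff-time computation, SRT prediction, and model fitting.

foveolar_params <- function(k = 4, u = 0, direction = "right",
                            extension = "power") {
  payoff_params(
    scaling_constant = k, urgency = u,
    resolution = resolution_function(
      if (direction == "right") "cone_temporal" else "cone_nasal"
    ),
    duration = main_sequence(direction, extension = extension)
  )
}

test_that("payoff time is cost over benefit with the right guards", {
  expect_equal(payoff_time(20, 0.5), 40)
  # distal limit: payoff-time reduces toward the bare movement cost
  expect_equal(payoff_time(20, 0), 20)
  expect_error(payoff_time(20, 1), "never pays off")
  expect_error(payoff_time(0, 0.5), "duration_ms")
  # cost floor: payoff-time is never below the saccade duration
  d <- runif(50, 10, 60)
  r <- runif(50, 0, 0.99)
  expect_true(all(payoff_time(d, r) >= d))
})

test_that("predicted SRT reproduces the hand-chained closed form", {
  # chained by hand from the printed constants, independently of the
  # package internals: duration 10^1.21, ratio 1/sqrt(1 + 3.19)
  dur <- 10^1.21
  r_ratio <- 1 / sqrt(1 + 3.19)
  by_hand <- 80 + 4 * dur / (1 - r_ratio)
  expect_equal(by_hand, 206.836, tolerance = 1e-4)
  expect_equal(predict_median_srt(1, 0, foveolar_params()), by_hand,
               tolerance = 1e-9)
})

test_that("the urgency solution matches its zero-urgency limit", {
  p0 <- foveolar_params(u = 0)
  p_eps <- foveolar_params(u = 1e-12)
  for (e in c(0.3, 1, 3)) {
    expect_equal(predict_median_srt(e, 0, p_eps),
                 predict_median_srt(e, 0, p0), tolerance = 1e-9)
  }
})

test_that("urgency strictly shortens stage-2 medians, more at longer payoffs", {
  p_flat <- foveolar_params(u = 0)
  p_urg <- foveolar_params(u = 0.005)
  e <- c(0.2, 0.5, 1, 3)
  flat <- vapply(e, predict_median_srt, numeric(1), diameter_deg = 0,
                 params = p_flat)
  urg <- vapply(e, predict_median_srt, numeric(1), diameter_deg = 0,
                params = p_urg)
  shortening <- flat - urg
  expect_true(all(shortening > 0))
  # absolute shortening grows with the flat-model stage-2 median
  expect_true(all(diff(shortening[order(flat)]) > 0))
})

test_that("the foveolar model predicts the central SRT peak on both meridians", {
  e_grid <- seq(0.1, 0.7, by = 0.05)
  for (dir in c("right", "left")) {
    p <- foveolar_params(direction = dir)
    srt <- vapply(e_grid, predict_median_srt, numeric(1),
                  diameter_deg = 0, params = p)
    expect_true(all(diff(srt) < 0), info = dir)
  }
})

test_that("predicted SRT rises again in the periphery (bowl shape)", {
  p <- foveolar_params(extension = "linear")
  e_grid <- c(seq(0.1, 8.5, by = 0.1), 9)
  srt <- vapply(e_grid, predict_median_srt, numeric(1),
                diameter_deg = 0, params = p)
  expect_gt(srt[length(srt)], min(srt))
  # discrete slope is negative in the foveola, positive near 9 degrees
  expect_lt(srt[2] - srt[1], 0)
  expect_gt(srt[length(srt)] - srt[length(srt) - 1], 0)
})

test_that("at fixed eccentricity predicted SRT is non-decreasing in diameter", {
  p <- payoff_params(duration = main_sequence("right", extension = "linear"))
  for (e in c(4, 6, 9)) {
    srt <- vapply(c(0, 2, 4, 8), function(d) predict_median_srt(e, d, p),
                  numeric(1))
    expect_true(all(diff(srt) >= 0), info = paste("e =", e))
  }
})

test_that("curves for different diameters collapse against the ratio", {
  p <- payoff_params(duration = main_sequence("right", extension = "linear"))
  grid <- tidyr::expand_grid(
    diameter_deg = c(2, 4, 8),
    ratio = c(0.125, 0.25, 0.375, 0.5, 0.75, 1, 1.5, 2, 3)
  )
  grid$eccentricity_deg <- grid$diameter_deg * grid$ratio
  curve <- predict_srt_curve(grid, p)
  spread <- curve |>
    dplyr::group_by(ratio) |>
    dplyr::summarise(spread = max(predicted_median_srt_ms) -
                       min(predicted_median_srt_ms))
  drop <- curve |>
    dplyr::group_by(diameter_deg) |>
    dplyr::summarise(
      drop = predicted_median_srt_ms[ratio == 0.125] -
        predicted_median_srt_ms[ratio == 1]
    )
  expect_lt(max(spread$spread), min(drop$drop))
  # the 12-degree-eccentricity departures: SRT rises again at e = 12
  # for the 8-degree ring relative to its ratio-1 point
  d8 <- curve[curve$diameter_deg == 8, ]
  expect_gt(d8$predicted_median_srt_ms[d8$eccentricity_deg == 12],
            d8$predicted_median_srt_ms[d8$eccentricity_deg == 8])
})

test_that("predict_srt_curve on one condition equals predict_median_srt", {
  p <- foveolar_params()
  curve <- predict_srt_curve(
    data.frame(eccentricity_deg = 1, diameter_deg = 0), p
  )
  expect_equal(curve$predicted_median_srt_ms, predict_median_srt(1, 0, p))
})

test_that("payoff fitting recovers a noiseless scaling constant exactly", {
  p <- foveolar_params(k = 4)
  e <- c(0.2, 0.3, 0.5, 0.8, 1, 2)
  med <- vapply(e, predict_median_srt, numeric(1), diameter_deg = 0,
                params = p)
  fit <- fit_payoff_model(
    data.frame(eccentricity_deg = e, diameter_deg = 0, median_srt_ms = med),
    foveolar_params(k = 1), free = "k"
  )
  expect_equal(fit$params$scaling_constant, 4, tolerance = 1e-4)
  expect_gt(fit$adj_r_squared, 0.9999)
  expect_equal(tidy(fit)$estimate[1], fit$params$scaling_constant)
  expect_equal(glance(fit)$nobs, 6)
})

test_that("two-parameter fitting recovers k and u from noisy medians", {
  p <- foveolar_params(k = 3.6, u = 0.002, direction = "left")
  e <- seq(0.15, 2.25, length.out = 15)
  truth <- vapply(e, predict_median_srt, numeric(1), diameter_deg = 0,
                  params = p)
  set.seed(77)
  obs <- truth + rnorm(15, 0, 5)
  fit <- fit_payoff_model(
    data.frame(eccentricity_deg = e, diameter_deg = 0,
               median_srt_ms = obs),
    foveolar_params(direction = "left"), free = "ku"
  )
  expect_equal(fit$params$scaling_constant, 3.6, tolerance = 0.1)
  expect_equal(fit$params$urgency, 0.002, tolerance = 0.1)
})

test_that("fitting refuses under-determined problems", {
  expect_error(
    fit_payoff_model(
      data.frame(eccentricity_deg = 1, diameter_deg = 0,
                 median_srt_ms = 200),
      free = "k"
    ),
    "at least"
  )
})
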