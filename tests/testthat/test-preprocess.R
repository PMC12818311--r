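# Velocity estimation, saccade detection, validity filters.

flat_trace <- function(n = 200, dt = 2, x = 0) {
  tibble::tibble(t_ms = seq(0, by = dt, length.out = n),
                 x_deg = x, y_deg = 0)
}

# one planted saccade via the same logistic profile the generator uses
planted_trace <- function(amp = 4, onset = 300, dur = 25, dt = 2,
                          total = 800, noise = 0) {
  t <- seq(0, total, by = dt)
  slope <- 2 * log(199) / dur
  x <- amp / (1 + exp(-slope * (t - onset - dur / 2)))
  tibble::tibble(
    t_ms = t,
    x_deg = x + rnorm(length(t), 0, noise),
    y_deg = rnorm(length(t), 0, noise)
  )
}

test_that("central-difference speed is exact for constant and linear motion", {
  v <- compute_velocity(flat_trace())
  expect_true(all(v$speed_deg_s[2:199] == 0))
  expect_true(is.na(v$speed_deg_s[1]) && is.na(v$speed_deg_s[200]))

  ramp <- flat_trace()
  ramp$x_deg <- 0.02 * ramp$t_ms # 20 deg/s in x
  v <- compute_velocity(ramp)
  expect_equal(v$speed_deg_s[2:199], rep(20, 198), tolerance = 1e-9)

  bad <- flat_trace()
  bad$t_ms[5] <- bad$t_ms[5] + 0.5
  expect_error(compute_velocity(bad), "non-uniform")
})

test_that("peak speed of a smooth profile matches the analytic peak", {
  # a long, well-resolved profile so the finite-difference stencil does
  # not materially attenuate the peak
  dur <- 60
  amp <- 8
  tr <- planted_trace(amp = amp, dur = dur)
  v <- compute_velocity(tr)
  analytic_peak <- amp * (2 * log(199) / dur) / 4 * 1000 # deg/s
  expect_equal(max(v$speed_deg_s, na.rm = TRUE), analytic_peak,
               tolerance = 0.02)
})

test_that("blink-adjacent samples have undefined speed", {
  tr <- flat_trace()
  tr$blink <- FALSE
  tr$blink[100:105] <- TRUE
  tr$x_deg[100:105] <- NA
  v <- compute_velocity(tr)
  expect_true(all(is.na(v$speed_deg_s[99:106])))
  expect_false(is.na(v$speed_deg_s[97]))
})

test_that("detection needs a sustained supra-threshold excursion", {
  v <- compute_velocity(flat_trace())
  expect_equal(nrow(detect_saccades(v)), 0)
  # one isolated sample at 20 deg/s fails the two-consecutive rule
  tr <- flat_trace()
  tr$x_deg[100] <- tr$x_deg[100] + 0.08 # single-sample spike
  v <- compute_velocity(tr)
  expect_true(any(v$speed_deg_s > 15, na.rm = TRUE))
  expect_equal(nrow(detect_saccades(v)), 0)
})

test_that("planted saccades are detected at the right time with the right size", {
  tr <- planted_trace(amp = 4, onset = 300, dur = 25)
  ev <- detect_saccades(compute_velocity(tr))
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$onset_ms - 300), 2) # within one sample at 500 Hz
  expect_equal(ev$amplitude_deg, 4, tolerance = 0.02)
  expect_equal(ev$direction, "right")
})

test_that("detection is translation invariant and amplitude covariant", {
  tr <- planted_trace(amp = 3, onset = 300)
  ev <- detect_saccades(compute_velocity(tr))
  shifted <- tr
  shifted$t_ms <- shifted$t_ms + 500
  ev_shift <- detect_saccades(compute_velocity(shifted))
  expect_equal(ev_shift$onset_ms, ev$onset_ms + 500)
  scaled <- tr
  scaled$x_deg <- 2 * scaled$x_deg
  ev_scaled <- detect_saccades(compute_velocity(scaled))
  # the marked start/end samples can move by one sample when speeds
  # scale, so covariance holds to within the boundary-sample tails
  expect_equal(ev_scaled$amplitude_deg, 2 * ev$amplitude_deg,
               tolerance = 0.02)
  expect_lte(abs(ev_scaled$onset_ms - ev$onset_ms), 2)
})

test_that("noisy traces still localize onsets of 1-degree saccades", {
  set.seed(55)
  errs <- vapply(1:25, function(i) {
    amp <- runif(1, 1, 8)
    tr <- planted_trace(amp = amp, onset = 400,
                        dur = 10^1.21 * amp^0.25, noise = 0.01)
    ev <- detect_saccades(compute_velocity(tr), first_only = TRUE)
    abs(ev$onset_ms[1] - 400)
  }, numeric(1))
  expect_true(all(errs <= 2))
})

test_that("an all-blink trace yields an empty flagged result", {
  tr <- flat_trace()
  tr$blink <- TRUE
  tr$x_deg <- NA
  ev <- detect_saccades(compute_velocity(tr))
  expect_equal(nrow(ev), 0)
  expect_true(attr(ev, "all_blink"))
})

test_that("validity bounds are strict on the stated side", {
  trials <- tibble::tibble(
    direction = "right",
    srt_ms = c(79, 80, 600, 601, 300),
    comp_eccentricity_deg = NA_real_
  )
  res <- filter_trials(trials)
  expect_equal(res$trials$exclusion_reason,
               c("anticipatory", "none", "none", "too_slow", "none"))
  expect_equal(sum(res$report$n), 5)
})

test_that("direction and blink rules apply, and the report adds up", {
  trials <- tibble::tibble(
    direction = c("right", "right", "left", "left"),
    saccade_direction = c("right", "left", "left", "left"),
    blink = c(FALSE, FALSE, TRUE, FALSE),
    srt_ms = c(300, 300, 300, 300),
    comp_eccentricity_deg = NA_real_
  )
  res <- filter_trials(trials)
  expect_equal(res$trials$exclusion_reason,
               c("none", "wrong_direction", "blink", "none"))
  expect_equal(sum(res$report$n), nrow(trials))
  expect_equal(attr(res$report, "inclusion_fraction"), 0.5)
  expect_error(filter_trials(tibble::tibble(direction = "l",
                                            srt_ms = NA_real_)),
               "cannot be filtered")
})

test_that("either direction is legitimate on choice trials", {
  trials <- tibble::tibble(
    direction = c("right", "right"),
    saccade_direction = c("left", "left"),
    comp_eccentricity_deg = c(NA_real_, 0.5),
    srt_ms = 300
  )
  res <- filter_trials(trials)
  expect_equal(res$trials$exclusion_reason,
               c("wrong_direction", "none"))
})

test_that("planted violation batches report the exact inclusion fraction", {
  cfg <- synthetic_config("exp2", n_participants = 2,
                          trials_per_condition = 10, seed = 404)
  gen <- generate_experiment(cfg)
  res <- filter_trials(gen$trials)
  # 600 trials, 7% planted invalid: inclusion is exactly 93%
  expect_equal(nrow(gen$trials), 600)
  expect_equal(attr(res$report, "inclusion_fraction"), 0.93)
  expect_equal(sum(res$report$n), 600)
})
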