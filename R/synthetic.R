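# Seeded synthetic-data generator reproducing the statistical structure
# of the three experimental designs: condition grids, foreperiod
# schedules, recinormal stage-2 latencies whose medians follow the
# payoff-time model, two-accumulator races for free choice, planted
# invalid trials, and gaze traces with main-sequence-consistent
# saccades.

#' Condition grids of the three experimental designs
#'
#' Returns the exact published grids:
#' \describe{
#'   \item{exp1}{single ring steps; 27 combinations of ring diameter
#'     (4, 8, 12 deg) and eccentricity producing 15 distinct
#'     eccentricity/diameter ratios between 0.125 and 3 (all rings at
#'     1.5, 2, 3, 4, 6, 8, 9, 12 deg, plus the 4 and 8 deg rings at
#'     1 deg and the 12 deg ring at 4.5 deg).}
#'   \item{exp2}{foveolar point-target steps; 15 eccentricities (0.1 to
#'     0.8 in 0.1 steps, 1, 2, plus 0.13, 1.5, 3, 6, 9 deg) crossed
#'     with 2 directions, diameter 0.}
#'   \item{exp3_single}{single rings covering 5 ratios in 11 conditions
#'     (2 deg ring stepping 0.5, 2, 9, 18; 4 deg ring 0.5, 1, 4, 18;
#'     8 deg ring 1, 2, 8 deg).}
#'   \item{exp3_choice}{two-ring free choice; 8 pairs, each with one
#'     ring at ratio 1 and a competing ring of the same diameter at
#'     ratio 0.125, 0.25, 4.5 or 9.}
#' }
#'
#' @param template One of `"exp1"`, `"exp2"`, `"exp3_single"`,
#'   `"exp3_choice"`.
#' @return A tibble of conditions with `diameter_deg`,
#'   `eccentricity_deg`, `ratio`, and for the choice grid
#'   `comp_eccentricity_deg`/`comp_ratio`; the exp2 grid also carries
#'   `direction`.
#' @export
generate_conditions <- function(template = c("exp1", "exp2",
                                             "exp3_single",
                                             "exp3_choice")) {
  template <- match.arg(template)
  grid <- switch(template,
    exp1 = {
      shared <- tidyr::expand_grid(
        diameter_deg = c(4, 8, 12),
        eccentricity_deg = c(1.5, 2, 3, 4, 6, 8, 9, 12)
      )
      extra <- tibble::tibble(
        diameter_deg = c(4, 8, 12),
        eccentricity_deg = c(1, 1, 4.5)
      )
      dplyr::bind_rows(shared, extra)
    },
    exp2 = tidyr::expand_grid(
      diameter_deg = 0,
      eccentricity_deg = c(seq(0.1, 0.8, by = 0.1), 1, 2,
                           0.13, 1.5, 3, 6, 9),
      direction = c("left", "right")
    ),
    exp3_single = tibble::tibble(
      diameter_deg = c(2, 2, 2, 2, 4, 4, 4, 4, 8, 8, 8),
      eccentricity_deg = c(0.5, 2, 9, 18, 0.5, 1, 4, 18, 1, 2, 8)
    ),
    exp3_choice = tibble::tibble(
      diameter_deg = c(2, 2, 2, 4, 4, 4, 8, 8),
      eccentricity_deg = c(2, 2, 2, 4, 4, 4, 8, 8),
      comp_eccentricity_deg = c(0.5, 9, 18, 0.5, 1, 18, 1, 2)
    )
  )
  grid$ratio <- ifelse(grid$diameter_deg > 0,
                       grid$eccentricity_deg / grid$diameter_deg, Inf)
  if (template == "exp3_choice") {
    grid$comp_diameter_deg <- grid$diameter_deg
    grid$comp_ratio <- grid$comp_eccentricity_deg / grid$comp_diameter_deg
  }
  grid
}

# truncated-exponential rate giving a target mean on [lo, hi]
non_ageing_rate <- function(lo = 620, hi = 1510, target_mean = 1000) {
  w <- hi - lo
  trunc_mean <- function(rate) {
    lo + 1 / rate - w * exp(-rate * w) / (1 - exp(-rate * w))
  }
  stats::uniroot(function(r) trunc_mean(r) - target_mean,
                 lower = 1e-6, upper = 0.1, tol = 1e-12)$root
}

#' Sample fixation foreperiods
#'
#' `"non_ageing"` draws from an exponential distribution truncated to
#' 620--1510 ms whose rate is solved numerically so the truncated mean
#' is 1000 ms: the constant hazard keeps the expectation of the target
#' step flat across the fixation period. `"uniform"` draws from
#' Uniform(800, 1300) ms, the conventional schedule.
#'
#' @param n Number of foreperiods.
#' @param mode `"non_ageing"` or `"uniform"`.
#' @param seed Optional integer seed.
#' @return Durations in ms.
#' @export
generate_foreperiods <- function(n, mode = c("non_ageing", "uniform"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "uniform") {
    return(stats::runif(n, 800, 1300))
  }
  lo <- 620
  hi <- 1510
  rate <- non_ageing_rate(lo, hi, 1000)
  u <- stats::runif(n)
  lo - log(1 - u * (1 - exp(-rate * (hi - lo)))) / rate
}

#' Configuration of a synthetic experiment
#'
#' Bundles the experiment template with the ground-truth model
#' parameters the generator embodies. Defaults reproduce the published
#' designs: trial counts per condition of 24 (exp1), 52 (exp2, the
#' per-participant session total of 1560 trials spread over 30
#' conditions), 44/120 (exp3 single/choice); non-ageing foreperiods for
#' exp1 and uniform 800--1300 ms for exp2/exp3; rate variability
#' `sigma/mu = 1/6`; 10% lognormal between-participant jitter on the
#' scaling constant; mutual inhibition `beta = 0.85`; and a 7% planted
#' invalid-trial rate. The ring templates default to `k = 4` with
#' urgency `u = 0.1` (which keeps predicted medians within the 80--600
#' ms validity window across all ratios); exp2 uses the foveolar model
#' with the printed constants (`k` 4 temporal / 3.6 nasal, no urgency,
#' cone resolution).
#'
#' @param template `"exp1"`, `"exp2"` or `"exp3"`.
#' @param n_participants Number of simulated participants.
#' @param trials_per_condition Repetitions of each grid condition (for
#'   exp3, length 2: single, choice).
#' @param payoff A [payoff_params()] ground truth (ring templates).
#' @param sigma_over_mu Rate SD as a fraction of mean rate.
#' @param beta Mutual inhibition factor (exp3 races).
#' @param bias_logodds_sd SD of the per-participant rightward-bias
#'   log-odds (0 = unbiased population).
#' @param foreperiod_mode Passed to [generate_foreperiods()].
#' @param invalid_rate Fraction of trials planted invalid (split evenly
#'   across anticipatory, too-slow, wrong-direction and blink).
#' @param k_jitter_cv Lognormal coefficient of variation of the
#'   per-participant scaling constant.
#' @param seed Master seed (mandatory; all sub-seeds derive from it).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(template = c("exp1", "exp2", "exp3"),
                             n_participants = NULL,
                             trials_per_condition = NULL,
                             payoff = NULL,
                             sigma_over_mu = 1 / 6,
                             beta = 0.85,
                             bias_logodds_sd = 0,
                             foreperiod_mode = NULL,
                             invalid_rate = 0.07,
                             k_jitter_cv = 0.1,
                             seed) {
  template <- match.arg(template)
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  n_participants <- n_participants %||%
    switch(template, exp1 = 6, exp2 = 3, exp3 = 12)
  trials_per_condition <- trials_per_condition %||%
    switch(template, exp1 = 24, exp2 = 52, exp3 = c(44, 120))
  payoff <- payoff %||% if (template == "exp2") {
    payoff_params(
      scaling_constant = 4, urgency = 0,
      resolution = resolution_function("cone_temporal"),
      duration = main_sequence("right", extension = "linear")
    )
  } else {
    payoff_params(
      scaling_constant = 4, urgency = 0.1,
      resolution = resolution_function("peripheral_normalized"),
      duration = main_sequence("right", extension = "linear")
    )
  }
  foreperiod_mode <- foreperiod_mode %||%
    switch(template, exp1 = "non_ageing", exp2 = "uniform",
           exp3 = "uniform")
  stopifnot(
    n_participants >= 1, all(trials_per_condition >= 1),
    sigma_over_mu > 0, beta > 0, beta <= 1, invalid_rate >= 0,
    invalid_rate < 1, k_jitter_cv >= 0
  )
  structure(
    list(
      template = template,
      n_participants = n_participants,
      trials_per_condition = trials_per_condition,
      payoff = payoff,
      sigma_over_mu = sigma_over_mu,
      beta = beta,
      bias_logodds_sd = bias_logodds_sd,
      foreperiod_mode = foreperiod_mode,
      invalid_rate = invalid_rate,
      k_jitter_cv = k_jitter_cv,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# per-direction payoff params for the foveolar experiment: the printed
# constants (temporal 4, nasal 3.6) unless the config overrides them
exp2_direction_params <- function(payoff, direction) {
  if (direction == "right") {
    payoff$resolution <- resolution_function("cone_temporal")
    payoff$duration <- main_sequence("right",
                                     extension = payoff$duration$extension)
    payoff
  } else {
    payoff$resolution <- resolution_function("cone_nasal")
    payoff$duration <- main_sequence("left",
                                     extension = payoff$duration$extension)
    payoff$scaling_constant <- payoff$scaling_constant * 3.6 / 4
    payoff
  }
}

# stage-2 median for a condition under (possibly jittered) k
condition_stage2_median <- function(payoff, k, e, d) {
  pt <- condition_payoff_time(payoff, e, d)
  stage2_median(k * pt, payoff$urgency)
}

# sample n stage-2 latencies with median m, resampling rates until the
# total latency stays within the validity window (truncation is rare at
# the default parameters and keeps planted-validity bookkeeping exact)
sample_valid_srt <- function(n, m, sigma_over_mu, t0, max_srt = 600) {
  mu <- 1 / m
  sigma <- sigma_over_mu * mu
  r <- sample_positive_rates(n, mu, sigma)
  bad <- which(t0 + 1 / r > max_srt)
  while (length(bad) > 0) {
    r[bad] <- sample_positive_rates(length(bad), mu, sigma)
    bad <- bad[t0 + 1 / r[bad] > max_srt]
  }
  t0 + 1 / r
}

#' Generate a complete synthetic experiment
#'
#' Builds a full trial table from a [synthetic_config()]: for every
#' participant and grid condition, foreperiods are sampled, stage-2
#' latencies are drawn from a recinormal whose median equals the
#' payoff-time model prediction under that participant's jittered
#' scaling constant, free-choice trials are decided by a
#' mutually-inhibited two-accumulator race with the participant's
#' directional bias, and a fixed fraction of trials is planted invalid
#' (anticipatory, too-slow, wrong-direction, blink in rotation). The
#' ground truth of every stochastic ingredient is returned alongside
#' the trials for parameter-recovery testing.
#'
#' @param config A [synthetic_config()].
#' @return A list: `trials` (tibble in the [read_trials()] schema) and
#'   `truth` (list of the generating parameters: per-participant `k`,
#'   bias, per-condition stage-2 medians, `beta`, planted invalid
#'   counts).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  t0 <- config$payoff$sensory_window_ms
  seeds <- derive_subseeds(config$seed, config$n_participants + 1L)
  participants <- sprintf("P%02d", seq_len(config$n_participants))

  single_grid <- switch(config$template,
    exp1 = generate_conditions("exp1"),
    exp2 = generate_conditions("exp2"),
    exp3 = generate_conditions("exp3_single")
  )
  choice_grid <- if (config$template == "exp3") {
    generate_conditions("exp3_choice")
  } else {
    NULL
  }
  n_single_reps <- config$trials_per_condition[1]
  n_choice_reps <- if (length(config$trials_per_condition) > 1) {
    config$trials_per_condition[2]
  } else {
    0L
  }

  all_trials <- vector("list", config$n_participants)
  truth_participants <- vector("list", config$n_participants)

  for (pi in seq_len(config$n_participants)) {
    set.seed(seeds[pi])
    k_base <- config$payoff$scaling_constant
    k_i <- if (config$k_jitter_cv > 0) {
      sdlog <- sqrt(log(1 + config$k_jitter_cv^2))
      k_base * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    } else {
      k_base
    }
    bias_logodds <- if (config$bias_logodds_sd > 0) {
      stats::rnorm(1, 0, config$bias_logodds_sd)
    } else {
      0
    }

    # --- single-target trials -------------------------------------------
    single <- tidyr::uncount(single_grid, n_single_reps)
    if (!"direction" %in% names(single)) {
      single$direction <- sample(c("left", "right"), nrow(single),
                                 replace = TRUE)
    }
    pay_for <- function(direction) {
      p <- if (config$template == "exp2") {
        exp2_direction_params(config$payoff, direction)
      } else {
        config$payoff
      }
      p$scaling_constant <- p$scaling_constant * k_i / k_base
      p
    }
    med_cache <- new.env(parent = emptyenv())
    stage2_for <- function(e, d, direction) {
      key <- paste(e, d, direction)
      if (is.null(med_cache[[key]])) {
        p <- pay_for(direction)
        med_cache[[key]] <- condition_stage2_median(
          p, p$scaling_constant, e, d
        )
      }
      med_cache[[key]]
    }
    single$stage2_median <- purrr::pmap_dbl(
      list(single$eccentricity_deg, single$diameter_deg,
           single$direction),
      stage2_for
    )
    single$srt_ms <- unlist(lapply(seq_len(nrow(single)), function(i) {
      sample_valid_srt(1, single$stage2_median[i], config$sigma_over_mu,
                       t0)
    }))
    single$chosen_side <- "none"
    single$comp_diameter_deg <- NA_real_
    single$comp_eccentricity_deg <- NA_real_
    single$experiment_id <- switch(config$template,
      exp1 = "exp1", exp2 = "exp2", exp3 = "exp3_single"
    )

    # --- free-choice trials ---------------------------------------------
    choice <- NULL
    if (!is.null(choice_grid) && n_choice_reps > 0) {
      choice <- tidyr::uncount(choice_grid, n_choice_reps)
      # counterbalanced side of the ratio-1 target
      choice$direction <- rep_len(c("left", "right"), nrow(choice))
      mu_of <- function(e, d) {
        1 / stage2_for(e, d, "right")
      }
      sigma_ref <- config$sigma_over_mu *
        mu_of(choice_grid$eccentricity_deg[1],
              choice_grid$diameter_deg[1])
      bias_rate <- if (bias_logodds != 0) {
        stats::qnorm(stats::plogis(bias_logodds)) * sqrt(2) * sigma_ref
      } else {
        0
      }
      res <- purrr::pmap(
        list(choice$eccentricity_deg, choice$diameter_deg,
             choice$comp_eccentricity_deg, choice$direction),
        function(e1, d, e2, side1) {
          u1 <- later_params(mu_of(e1, d),
                             config$sigma_over_mu * mu_of(e1, d), t0)
          u2 <- later_params(mu_of(e2, d),
                             config$sigma_over_mu * mu_of(e2, d), t0)
          spec <- race_spec(u1, u2, beta = config$beta, bias = bias_rate)
          tr <- simulate_race(spec, 1, side_of_ratio1 = side1)
          while (tr$srt_ms > 600) {
            tr <- simulate_race(spec, 1, side_of_ratio1 = side1)
          }
          tr
        }
      )
      choice$chosen_side <- purrr::map_chr(res, "chosen_side")
      choice$srt_ms <- purrr::map_dbl(res, "srt_ms")
      choice$stage2_median <- NA_real_
      choice$experiment_id <- "exp3_choice"
      choice$comp_ratio <- NULL
      truth_bias <- bias_rate
    } else {
      truth_bias <- 0
    }

    trials <- dplyr::bind_rows(single, choice)
    trials$participant_id <- participants[pi]
    trials$foreperiod_ms <- generate_foreperiods(
      nrow(trials), config$foreperiod_mode
    )
    trials$amplitude_deg <- trials$eccentricity_deg
    trials$duration_ms <- saccade_duration(
      main_sequence("right", extension = "linear"),
      trials$amplitude_deg
    )
    trials$saccade_direction <- ifelse(
      trials$chosen_side == "none", trials$direction, trials$chosen_side
    )
    trials$blink <- FALSE

    # --- planted invalid trials -----------------------------------------
    n_tr <- nrow(trials)
    n_invalid <- round(config$invalid_rate * n_tr)
    planted <- integer(0)
    if (n_invalid > 0) {
      planted <- sample.int(n_tr, n_invalid)
      reasons <- rep_len(c("anticipatory", "too_slow", "wrong_direction",
                           "blink"), n_invalid)
      # a choice trial has no wrong direction; plant a blink instead
      choice_planted <- !is.na(trials$comp_eccentricity_deg[planted])
      reasons[reasons == "wrong_direction" & choice_planted] <- "blink"
      for (j in seq_along(planted)) {
        i <- planted[j]
        switch(reasons[j],
          anticipatory = {
            trials$srt_ms[i] <- stats::runif(1, 20, 79)
          },
          too_slow = {
            trials$srt_ms[i] <- stats::runif(1, 601, 900)
          },
          wrong_direction = {
            trials$saccade_direction[i] <-
              if (trials$direction[i] == "left") "right" else "left"
          },
          blink = {
            trials$blink[i] <- TRUE
          }
        )
      }
      trials$.planted_reason <- "none"
      trials$.planted_reason[planted] <- reasons
    } else {
      trials$.planted_reason <- "none"
    }
    trials$exclusion_reason <- trials$.planted_reason
    trials$valid <- trials$exclusion_reason == "none"
    trials$.planted_reason <- NULL

    all_trials[[pi]] <- trials
    truth_participants[[pi]] <- list(
      participant_id = participants[pi],
      k = k_i,
      bias_logodds = bias_logodds,
      bias_rate = truth_bias,
      n_planted_invalid = n_invalid
    )
  }

  trials <- dplyr::bind_rows(all_trials)
  medians <- trials |>
    dplyr::filter(!is.na(.data$stage2_median)) |>
    dplyr::distinct(
      .data$participant_id, .data$diameter_deg, .data$eccentricity_deg,
      .data$direction, .data$stage2_median
    )
  trials$stage2_median <- NULL
  cols <- c(
    "participant_id", "experiment_id", "diameter_deg",
    "eccentricity_deg", "direction", "comp_diameter_deg",
    "comp_eccentricity_deg", "foreperiod_ms", "srt_ms", "amplitude_deg",
    "duration_ms", "saccade_direction", "blink", "chosen_side", "valid",
    "exclusion_reason"
  )
  trials <- trials[, c(cols, setdiff(names(trials), cols))]
  list(
    trials = tibble::as_tibble(trials),
    truth = list(
      config = config,
      participants = truth_participants,
      stage2_medians = medians,
      beta = config$beta,
      sigma_over_mu = config$sigma_over_mu,
      t0_ms = t0
    )
  )
}

#' Generate gaze traces for a set of trials
#'
#' Produces a 500 Hz (by default) position trace per trial: stationary
#' fixation, then at `foreperiod + srt` a horizontal saccade whose
#' position follows a scaled logistic rising from 0.5% to 99.5% of the
#' trial's amplitude over its main-sequence duration, plus additive
#' Gaussian position noise. Trials flagged `blink` get a gap of
#' blink-masked samples during fixation.
#'
#' @param trials A trial tibble with `foreperiod_ms`, `srt_ms`,
#'   `amplitude_deg`, `duration_ms`, `saccade_direction` and `blink`.
#' @param sample_rate_hz Sampling rate.
#' @param noise_sd Position noise SD in degrees.
#' @param tail_ms Trace continuation after saccade offset.
#' @param seed Optional integer seed.
#' @return A tibble with columns `trial_id`, `t_ms`, `x_deg`, `y_deg`,
#'   `blink`; the planted saccade onset per trial is attached as
#'   attribute `"planted_onset_ms"`.
#' @export
generate_eye_traces <- function(trials, sample_rate_hz = 500,
                                noise_sd = 0.01, tail_ms = 80,
                                seed = NULL) {
  stopifnot(all(c("foreperiod_ms", "srt_ms", "amplitude_deg",
                  "duration_ms", "saccade_direction") %in% names(trials)))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1000 / sample_rate_hz
  blink_col <- if ("blink" %in% names(trials)) trials$blink else
    rep(FALSE, nrow(trials))
  onset_truth <- numeric(nrow(trials))
  traces <- lapply(seq_len(nrow(trials)), function(i) {
    fp <- trials$foreperiod_ms[i]
    onset <- fp + trials$srt_ms[i]
    dur <- trials$duration_ms[i]
    amp <- trials$amplitude_deg[i] *
      (if (trials$saccade_direction[i] == "left") -1 else 1)
    total <- onset + dur + tail_ms
    t <- seq(0, total, by = dt)
    # logistic from 0.5% to 99.5% of amplitude across the duration
    slope <- 2 * log(199) / dur
    x <- amp / (1 + exp(-slope * (t - onset - dur / 2)))
    x <- x + stats::rnorm(length(t), 0, noise_sd)
    y <- stats::rnorm(length(t), 0, noise_sd)
    blink <- rep(FALSE, length(t))
    if (blink_col[i]) {
      b0 <- which.min(abs(t - fp / 2))
      blink[b0:min(length(t), b0 + round(100 / dt))] <- TRUE
      x[blink] <- NA_real_
      y[blink] <- NA_real_
    }
    onset_truth[i] <<- onset
    tibble::tibble(trial_id = i, t_ms = t, x_deg = x, y_deg = y,
                   blink = blink)
  })
  out <- dplyr::bind_rows(traces)
  attr(out, "planted_onset_ms") <- onset_truth
  out
}
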