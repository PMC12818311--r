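# Two-accumulator race model of free choice between simultaneous targets.
# Each target drives an independent LATER unit; with equal thresholds the
# unit drawing the larger rate wins. A multiplicative mutual-inhibition
# factor beta slows both mean rates in two-choice trials, and a signed
# rate offset models directional (rightward) bias.

#' Specification of a two-unit race
#'
#' @param unit_ratio1 [later_params()] of the reference (ratio = 1)
#'   target's accumulator, inferred from single-target trials.
#' @param unit_comp [later_params()] of the competing target's
#'   accumulator.
#' @param beta Mutual-inhibition factor in `(0, 1]` multiplying both
#'   mean rates (1 = no inhibition). Rate SDs are left unscaled, so
#'   inhibition produces a parallel reciprobit shift.
#' @param bias Signed rate offset (1/ms) added to whichever unit's
#'   target is on the right; positive = rightward preference.
#' @return An object of class `race_spec`.
#' @export
race_spec <- function(unit_ratio1, unit_comp, beta = 1, bias = 0) {
  stopifnot(
    inherits(unit_ratio1, "later_params"),
    inherits(unit_comp, "later_params"),
    beta > 0, beta <= 1
  )
  structure(
    list(unit_ratio1 = unit_ratio1, unit_comp = unit_comp,
         beta = beta, bias = bias),
    class = "race_spec"
  )
}

#' @export
print.race_spec <- function(x, ...) {
  cat(sprintf(
    "<race_spec> mu = (%.4g, %.4g) /ms, beta = %.3g, bias = %.3g\n",
    x$unit_ratio1$mu, x$unit_comp$mu, x$beta, x$bias
  ))
  invisible(x)
}

# effective (inhibition-scaled, bias-adjusted) mean rates
race_effective_mu <- function(spec, side_of_ratio1) {
  mu1 <- spec$beta * spec$unit_ratio1$mu
  mu2 <- spec$beta * spec$unit_comp$mu
  if (side_of_ratio1 == "right") {
    mu1 <- mu1 + spec$bias
  } else {
    mu2 <- mu2 + spec$bias
  }
  c(mu1, mu2)
}

#' Analytic probability that the reference target wins the race
#'
#' With equal thresholds and rates drawn once per trial, the unit with
#' the larger sampled rate finishes first, so
#' \eqn{P = \Phi\left((\mu_1' - \mu_2') / \sqrt{\sigma_1^2 +
#' \sigma_2^2}\right)} where \eqn{\mu'} are the inhibition-scaled,
#' bias-adjusted mean rates.
#'
#' @param spec A [race_spec()].
#' @param side_of_ratio1 `"left"` or `"right"`: where the reference
#'   target appears (the directional bias favours the right side).
#' @return Probability of choosing the ratio-1 target.
#' @export
race_probability <- function(spec, side_of_ratio1 = c("left", "right")) {
  stopifnot(inherits(spec, "race_spec"))
  side_of_ratio1 <- match.arg(side_of_ratio1)
  mu <- race_effective_mu(spec, side_of_ratio1)
  s2 <- spec$unit_ratio1$sigma^2 + spec$unit_comp$sigma^2
  if (s2 == 0) {
    if (mu[1] == mu[2]) {
      stop("degenerate tie: both rate SDs are zero and rates are equal",
           call. = FALSE)
    }
    return(as.numeric(mu[1] > mu[2]))
  }
  stats::pnorm((mu[1] - mu[2]) / sqrt(s2))
}

#' Simulate two-choice race trials
#'
#' Samples both units' rates (truncated positive), declares the larger
#' rate the winner, and records the winner's finishing time
#' `t0 + 1/max(rate)`; the shared onset delay is taken from the
#' reference unit.
#'
#' @inheritParams race_probability
#' @param n Number of trials.
#' @param seed Optional integer seed.
#' @return A tibble with columns `winner` (`"ratio1"`/`"comp"`),
#'   `chosen_side`, and `srt_ms`.
#' @export
simulate_race <- function(spec, n, seed = NULL,
                          side_of_ratio1 = c("left", "right")) {
  stopifnot(inherits(spec, "race_spec"), n >= 1)
  side_of_ratio1 <- match.arg(side_of_ratio1)
  if (!is.null(seed)) set.seed(seed)
  mu <- race_effective_mu(spec, side_of_ratio1)
  r1 <- sample_positive_rates(n, mu[1], spec$unit_ratio1$sigma)
  r2 <- sample_positive_rates(n, mu[2], spec$unit_comp$sigma)
  win1 <- r1 > r2
  other_side <- if (side_of_ratio1 == "left") "right" else "left"
  tibble::tibble(
    winner = ifelse(win1, "ratio1", "comp"),
    chosen_side = ifelse(win1, side_of_ratio1, other_side),
    srt_ms = spec$unit_ratio1$t0_ms + 1 / pmax(r1, r2)
  )
}

# analytic race-latency quantiles: P(SRT <= t) = P(max rate >= 1/(t - t0))
# = 1 - Phi((x - mu1)/s1) * Phi((x - mu2)/s2) at x = 1/(t - t0)
race_srt_quantiles <- function(spec, probs,
                               side_of_ratio1 = "left") {
  mu <- race_effective_mu(spec, side_of_ratio1)
  s1 <- spec$unit_ratio1$sigma
  s2 <- spec$unit_comp$sigma
  cdf_max <- function(x) {
    stats::pnorm(x, mu[1], s1) * stats::pnorm(x, mu[2], s2)
  }
  vapply(probs, function(q) {
    lo <- min(mu) - 8 * max(s1, s2, 1e-12)
    hi <- max(mu) + 8 * max(s1, s2, 1e-12)
    x <- stats::uniroot(function(v) cdf_max(v) - (1 - q),
                        lower = lo, upper = hi, tol = 1e-12)$root
    spec$unit_ratio1$t0_ms + 1 / x
  }, numeric(1))
}

#' Fit the mutual-inhibition factor from two-choice latencies
#'
#' Finds the single `beta` that best explains why two-choice latencies
#' are slower than the single-target accumulators predict: minimises the
#' summed squared distance between observed two-choice SRT deciles and
#' the analytic race-model deciles, across all supplied choice
#' conditions. Nelder--Mead from the fixed start `beta = 0.9`, so the
#' fit is deterministic.
#'
#' @param choice_srts A numeric vector (one condition) or a list of
#'   numeric vectors (one per condition) of two-choice latencies in ms.
#' @param unit_pairs A list `list(ratio1 = , comp = )` of
#'   [later_params()] for one condition, or a list of such pairs
#'   matching `choice_srts`.
#' @param probs Quantiles to match (default deciles).
#' @return A list of class `beta_fit` with `beta`, `objective` and
#'   `boundary` (TRUE with a warning when the estimate lies at the
#'   `[0.5, 1]` search bounds).
#' @export
fit_mutual_inhibition <- function(choice_srts, unit_pairs,
                                  probs = seq(0.1, 0.9, by = 0.1)) {
  if (is.numeric(choice_srts)) choice_srts <- list(choice_srts)
  if (inherits(unit_pairs[[1]], "later_params")) {
    unit_pairs <- list(unit_pairs)
  }
  stopifnot(length(choice_srts) == length(unit_pairs))
  obs_q <- lapply(choice_srts, stats::quantile, probs = probs,
                  names = FALSE, type = 7)
  objective <- function(beta) {
    if (beta < 0.5 || beta > 1) {
      return(1e12 * (1 + abs(beta - 0.75)))
    }
    total <- 0
    for (i in seq_along(unit_pairs)) {
      spec <- race_spec(unit_pairs[[i]]$ratio1, unit_pairs[[i]]$comp,
                        beta = beta)
      pred <- race_srt_quantiles(spec, probs)
      total <- total + sum((obs_q[[i]] - pred)^2)
    }
    total
  }
  opt <- suppressWarnings(
    stats::optim(0.9, objective, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
  )
  beta_hat <- opt$par
  boundary <- beta_hat <= 0.502 || beta_hat >= 0.9995
  if (boundary) {
    warning("mutual-inhibition estimate at search boundary (beta = ",
            signif(beta_hat, 4), ")", call. = FALSE)
  }
  structure(
    list(beta = min(beta_hat, 1), objective = opt$value,
         boundary = boundary),
    class = "beta_fit"
  )
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("<beta_fit> beta = %.4g%s\n", x$beta,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Predicted probability of choosing the reference target
#'
#' Race-model CP1 for one choice condition, built from the single-target
#' accumulators plus the mutual-inhibition factor and directional bias,
#' averaged over the two counterbalanced placements of the reference
#' target (left/right), under which a side bias cancels to first order.
#'
#' @param unit_ratio1,unit_comp [later_params()] inferred from
#'   single-target trials for the reference and competing conditions.
#' @param beta Mutual-inhibition factor.
#' @param bias Rightward rate offset (1/ms).
#' @return Predicted CP1 in `[0, 1]`.
#' @export
predict_cp1 <- function(unit_ratio1, unit_comp, beta = 1, bias = 0) {
  spec <- race_spec(unit_ratio1, unit_comp, beta = beta, bias = bias)
  (race_probability(spec, "left") + race_probability(spec, "right")) / 2
}

#' Priority index of an observed choice probability
#'
#' Locates the observed choice probability between the
#' salience-by-proximity benchmark (`cp_salience`, 0 or 1: always choose
#' the nearer target) and the race-model prediction (`cp_model`):
#' `index = (cp_obs - cp_salience) / (cp_model - cp_salience)`. An index
#' of 1 means choices are fully explained by racing accumulators given
#' the measured SRT variability; 0 means pure salience-by-proximity;
#' values above 1 mean the higher-payoff target is chosen even more
#' often than the race model predicts.
#'
#' @param cp_obs Observed choice probability of the reference target.
#' @param cp_model Race-model prediction (see [predict_cp1()]).
#' @param cp_salience Salience-by-proximity benchmark, 0 when the
#'   competing target is nearer and 1 when the reference target is
#'   nearer (any probability in `[0, 1]` is accepted so the index is
#'   invariant under a common affine rescaling of all three
#'   probabilities).
#' @return The index, vectorised.
#' @examples
#' priority_index(0.76, 0.75, 0) # ~ 1.013
#' @export
priority_index <- function(cp_obs, cp_model, cp_salience) {
  if (any(cp_salience < 0 | cp_salience > 1)) {
    stop("cp_salience must lie in [0, 1]", call. = FALSE)
  }
  if (any(cp_model == cp_salience)) {
    stop("priority index undefined: cp_model equals cp_salience",
         call. = FALSE)
  }
  (cp_obs - cp_salience) / (cp_model - cp_salience)
}

#' Estimate directional choice bias from counterbalanced choice trials
#'
#' Pools rightward-choice counts across conditions (the bias is assumed
#' independent of the competing ratio), tests them against 0.5 with an
#' exact binomial test, and converts the preference into a rightward
#' rate offset by numerically inverting [race_probability()] for a
#' symmetric reference race.
#'
#' @param choice_trials A data frame with columns `participant_id` and
#'   `chosen_side` (`"left"`/`"right"`); requires both sides to occur in
#'   the design.
#' @param sigma_ref Reference rate SD (1/ms) used for the rate-offset
#'   conversion; when `NULL` the offset column is omitted.
#' @return A tibble per participant: `n_trials`, `n_right`, `p_right`,
#'   `log_odds_right`, `p_value`, and (given `sigma_ref`) `bias_rate`.
#' @export
estimate_directional_bias <- function(choice_trials, sigma_ref = NULL) {
  stopifnot(all(c("participant_id", "chosen_side") %in%
                  names(choice_trials)))
  sides <- unique(choice_trials$chosen_side)
  if (!all(c("left", "right") %in% sides)) {
    stop("bias is not identifiable from a single-sided design",
         call. = FALSE)
  }
  out <- choice_trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_right = sum(.data$chosen_side == "right"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_right = .data$n_right / .data$n_trials,
      log_odds_right = log(.data$p_right / (1 - .data$p_right)),
      p_value = purrr::map2_dbl(
        .data$n_right, .data$n_trials,
        function(x, n) stats::binom.test(x, n, p = 0.5)$p.value
      )
    )
  if (!is.null(sigma_ref)) {
    out$bias_rate <- vapply(out$p_right, function(p) {
      if (p <= 0 || p >= 1) {
        return(sign(p - 0.5) * Inf)
      }
      ref <- later_params(mu = 3 * sigma_ref, sigma = sigma_ref)
      stats::uniroot(
        function(b) {
          race_probability(race_spec(ref, ref, bias = b), "right") - p
        },
        lower = -20 * sigma_ref, upper = 20 * sigma_ref, tol = 1e-12
      )$root
    }, numeric(1))
  }
  out
}

#' Choice probability as a function of reaction time
#'
#' Bins choice trials by SRT and reports the per-bin probability of
#' choosing the reference (priority) target with exact binomial
#' confidence intervals, plus the overall SRT cumulative distribution
#' for overlay. Bins with fewer than `min_n` trials are flagged; empty
#' bins are omitted.
#'
#' @param choice_trials Data frame with columns `srt_ms` and
#'   `chose_ratio1` (logical).
#' @param breaks Bin edges in ms.
#' @param min_n Flag threshold for sparse bins.
#' @param conf_level Confidence level of the binomial intervals.
#' @return A tibble per bin: `bin_lo`, `bin_hi`, `n`, `cp`, `ci_lo`,
#'   `ci_hi`, `sparse`; the SRT empirical CDF is attached as attribute
#'   `"srt_cdf"`.
#' @export
cp_by_srt <- function(choice_trials, breaks, min_n = 5,
                      conf_level = 0.95) {
  stopifnot(all(c("srt_ms", "chose_ratio1") %in% names(choice_trials)),
            length(breaks) >= 2)
  bin <- cut(choice_trials$srt_ms, breaks = breaks, right = FALSE)
  keep <- !is.na(bin)
  df <- tibble::tibble(
    bin = bin[keep],
    chose = choice_trials$chose_ratio1[keep]
  )
  out <- df |>
    dplyr::group_by(.data$bin, .drop = TRUE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_chose = sum(.data$chose),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_lo = breaks[as.integer(.data$bin)],
      bin_hi = breaks[as.integer(.data$bin) + 1L],
      cp = .data$n_chose / .data$n,
      ci = purrr::map2(.data$n_chose, .data$n, binom_ci,
                       conf_level = conf_level),
      ci_lo = purrr::map_dbl(.data$ci, 1),
      ci_hi = purrr::map_dbl(.data$ci, 2),
      sparse = .data$n < min_n
    ) |>
    dplyr::select("bin_lo", "bin_hi", "n", "cp", "ci_lo", "ci_hi",
                  "sparse")
  srt <- sort(choice_trials$srt_ms)
  attr(out, "srt_cdf") <- tibble::tibble(
    srt_ms = srt,
    cdf = seq_along(srt) / length(srt)
  )
  out
}
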