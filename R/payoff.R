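# The payoff-time model: movement cost / foveation benefit translated
# into the accumulation rate of a rise-to-threshold decision unit.

#' Parameters of the payoff-time latency model
#'
#' The dual-stage model splits a saccade latency into a fixed sensory
#' detection/selection window `sensory_window_ms` (stage 1, default 80 ms
#' for suprathreshold targets) and a motor-preparation accumulator
#' (stage 2) whose threshold-normalized mean rate is inversely
#' proportional to the payoff-time of the candidate saccade:
#' \eqn{\mu = 1 / (k \cdot PT)}, so the stage-2 median equals
#' \eqn{k \cdot PT} exactly. The scaling constant `k` absorbs the
#' unobservable threshold and baseline urgency of a given setup; only the
#' product of rate constant and threshold is identifiable.
#'
#' An optional urgency (deadline) term grows the rate linearly with time
#' since target onset, \eqn{rate(t) = \mu (1 + u t)}; the accumulated
#' signal reaches threshold when \eqn{\mu (t + u t^2 / 2) = 1}, giving
#' the closed-form stage-2 median
#' \eqn{t = (\sqrt{1 + 2 u k PT} - 1)/u}, which reduces to
#' \eqn{k \cdot PT} as \eqn{u \to 0}.
#'
#' @param scaling_constant `k`, unitless, `> 0`. Typical fitted values:
#'   4 (temporal) and 3.6 (nasal) for foveolar point targets.
#' @param sensory_window_ms Stage-1 duration `T_s` in ms, `> 0`.
#' @param urgency `u`, per-ms fractional rate growth, `>= 0`; 0 disables
#'   the deadline process.
#' @param resolution A [resolution_function()]; benefit curve.
#' @param duration A [main_sequence()]; cost curve.
#' @param averaging Extended-target averaging region passed to
#'   [foveation_benefit()].
#' @return An object of class `payoff_params`.
#' @export
payoff_params <- function(scaling_constant = 4,
                          sensory_window_ms = 80,
                          urgency = 0,
                          resolution = resolution_function("peripheral_normalized"),
                          duration = main_sequence("right"),
                          averaging = c("disc", "ring", "chord")) {
  averaging <- match.arg(averaging)
  stopifnot(
    scaling_constant > 0, sensory_window_ms > 0, urgency >= 0,
    inherits(resolution, "resolution_function"),
    inherits(duration, "main_sequence")
  )
  structure(
    list(
      scaling_constant = scaling_constant,
      sensory_window_ms = sensory_window_ms,
      urgency = urgency,
      resolution = resolution,
      duration = duration,
      averaging = averaging
    ),
    class = "payoff_params"
  )
}

#' @export
print.payoff_params <- function(x, ...) {
  cat(sprintf(
    "<payoff_params> k = %.4g, T_s = %g ms, u = %g, %s resolution, %s averaging\n",
    x$scaling_constant, x$sensory_window_ms, x$urgency,
    x$resolution$family, x$averaging
  ))
  invisible(x)
}

#' Payoff-time of a saccade
#'
#' The post-saccadic time at which the information gained by foveating a
#' target overtakes what continued peripheral preview would have
#' delivered: `payoff_time = duration / (1 - r_e/r_0)`. The numerator is
#' the movement cost (the saccade's duration, during which vision is
#' suppressed), the denominator the normalized resolution benefit of
#' foveating. It is always at least the saccade duration, and diverges as
#' the benefit vanishes.
#'
#' @param duration_ms Saccade duration (movement cost), ms, `> 0`.
#' @param r_ratio Peripheral-to-foveal resolution ratio `r_e/r_0` in
#'   `[0, 1)`.
#' @return Payoff-time in ms. Vectorised over both arguments.
#' @examples
#' payoff_time(20, 0.5) # 40 ms
#' @export
payoff_time <- function(duration_ms, r_ratio) {
  if (any(duration_ms <= 0)) stop("duration_ms must be > 0", call. = FALSE)
  if (any(r_ratio < 0)) stop("r_ratio must be >= 0", call. = FALSE)
  if (any(r_ratio >= 1)) {
    stop(
      "infinite payoff-time: r_ratio >= 1 means no foveation benefit, ",
      "the saccade never pays off",
      call. = FALSE
    )
  }
  duration_ms / (1 - r_ratio)
}

# stage-2 median latency for a given k * PT product and urgency u;
# written as 2*k_pt / (sqrt(1 + 2*u*k_pt) + 1), the cancellation-free
# form of (sqrt(1 + 2*u*k_pt) - 1)/u, exact in the u -> 0 limit
stage2_median <- function(k_pt, urgency) {
  2 * k_pt / (sqrt(1 + 2 * urgency * k_pt) + 1)
}

# payoff-time of one condition under a payoff_params object
condition_payoff_time <- function(params, eccentricity_deg, diameter_deg) {
  b <- foveation_benefit(
    params$resolution, eccentricity_deg, diameter_deg,
    mode = params$averaging
  )
  dur <- saccade_duration(params$duration, eccentricity_deg)
  payoff_time(dur, 1 - b)
}

#' Predicted median saccade reaction time for one condition
#'
#' Chains the model: foveation benefit at the condition's eccentricity
#' and diameter, saccade duration at amplitude equal to the target-center
#' eccentricity, payoff-time, stage-2 median `k * PT` (urgency-adjusted
#' when `u > 0`), plus the fixed sensory window.
#'
#' @param eccentricity_deg Target-center step size, degrees, `> 0`.
#' @param diameter_deg Target diameter, degrees (`0` = point target).
#' @param params A [payoff_params()].
#' @return Predicted median SRT in ms.
#' @examples
#' p <- payoff_params(
#'   scaling_constant = 4,
#'   resolution = resolution_function("cone_temporal"),
#'   duration = main_sequence("right")
#' )
#' predict_median_srt(1, 0, p) # ~ 206.8 ms
#' @export
predict_median_srt <- function(eccentricity_deg, diameter_deg = 0, params) {
  stopifnot(inherits(params, "payoff_params"))
  pt <- condition_payoff_time(params, eccentricity_deg, diameter_deg)
  params$sensory_window_ms +
    stage2_median(params$scaling_constant * pt, params$urgency)
}

#' Predicted SRT curve over a grid of conditions
#'
#' Vectorised [predict_median_srt()] over a condition table.
#'
#' @param conditions A data frame with columns `eccentricity_deg` and
#'   `diameter_deg` (extra columns are carried through).
#' @param params A [payoff_params()].
#' @return A tibble sorted by `ratio`, with columns `eccentricity_deg`,
#'   `diameter_deg`, `ratio` (`e/D`, `Inf` for point targets),
#'   `payoff_time_ms` and `predicted_median_srt_ms`.
#' @export
predict_srt_curve <- function(conditions, params) {
  stopifnot(
    is.data.frame(conditions),
    all(c("eccentricity_deg", "diameter_deg") %in% names(conditions))
  )
  out <- tibble::as_tibble(conditions)
  out$payoff_time_ms <- purrr::map2_dbl(
    out$eccentricity_deg, out$diameter_deg,
    function(e, d) condition_payoff_time(params, e, d)
  )
  out$predicted_median_srt_ms <- params$sensory_window_ms +
    vapply(
      params$scaling_constant * out$payoff_time_ms,
      stage2_median,
      numeric(1),
      urgency = params$urgency
    )
  out$ratio <- ifelse(
    out$diameter_deg > 0,
    out$eccentricity_deg / out$diameter_deg,
    Inf
  )
  dplyr::arrange(out, .data$ratio, .data$diameter_deg)
}

#' Fit the payoff-time model to observed median SRTs
#'
#' Derivative-free Nelder--Mead minimisation of the squared error between
#' observed per-condition median SRTs and the model prediction, with the
#' scaling constant `k` free (`free = "k"`) or both `k` and the urgency
#' term `u` free (`free = "ku"`). Starting values are fixed
#' (`k0 = 4`, `u0 = 0.001`) so the fit is deterministic.
#'
#' @param summaries A data frame with columns `eccentricity_deg`,
#'   `diameter_deg` and `median_srt_ms` (one row per condition).
#' @param params A [payoff_params()] template providing the fixed pieces
#'   (sensory window, resolution and duration functions, averaging mode).
#' @param free `"k"` or `"ku"`.
#' @return An object of class `payoff_fit`: the fitted [payoff_params()]
#'   plus `sse`, `r_squared`, `adj_r_squared`, `n_conditions`,
#'   `convergence` and the observed/predicted table. Has [tidy()] and
#'   [glance()] methods.
#' @export
fit_payoff_model <- function(summaries, params = payoff_params(),
                             free = c("k", "ku")) {
  free <- match.arg(free)
  stopifnot(
    is.data.frame(summaries),
    all(c("eccentricity_deg", "diameter_deg", "median_srt_ms") %in%
          names(summaries))
  )
  n <- nrow(summaries)
  n_free <- if (free == "k") 1L else 2L
  if (n < n_free + 1L) {
    stop("need at least ", n_free + 1L, " conditions to fit ", n_free,
         " free parameter(s)", call. = FALSE)
  }
  # payoff-times depend only on the fixed pieces; precompute once
  pt <- purrr::map2_dbl(
    summaries$eccentricity_deg, summaries$diameter_deg,
    function(e, d) condition_payoff_time(params, e, d)
  )
  obs <- summaries$median_srt_ms
  predict_for <- function(k, u) {
    params$sensory_window_ms +
      vapply(k * pt, stage2_median, numeric(1), urgency = u)
  }
  objective <- function(par) {
    k <- exp(par[1])
    u <- if (n_free == 2L) exp(par[2]) else params$urgency
    sum((obs - predict_for(k, u))^2)
  }
  start <- if (n_free == 1L) log(4) else c(log(4), log(0.001))
  opt <- suppressWarnings(
    stats::optim(start, objective, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  )
  if (opt$convergence != 0) {
    stop("payoff model fit did not converge (optim code ", opt$convergence,
         "); last value ", signif(opt$value, 6), call. = FALSE)
  }
  k_hat <- exp(opt$par[1])
  u_hat <- if (n_free == 2L) exp(opt$par[2]) else params$urgency
  fitted_params <- params
  fitted_params$scaling_constant <- k_hat
  fitted_params$urgency <- u_hat
  pred <- predict_for(k_hat, u_hat)
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - n_free - 1)
  structure(
    list(
      params = fitted_params,
      free = free,
      sse = sse,
      r_squared = r2,
      adj_r_squared = adj_r2,
      n_conditions = n,
      convergence = opt$convergence,
      fitted = tibble::tibble(
        eccentricity_deg = summaries$eccentricity_deg,
        diameter_deg = summaries$diameter_deg,
        payoff_time_ms = pt,
        observed_median_srt_ms = obs,
        predicted_median_srt_ms = pred
      )
    ),
    class = "payoff_fit"
  )
}

#' @export
print.payoff_fit <- function(x, ...) {
  cat(sprintf(
    "<payoff_fit> k = %.4g%s over %d conditions; SSE = %.4g, adj R^2 = %.3f\n",
    x$params$scaling_constant,
    if (x$free == "ku") sprintf(", u = %.4g", x$params$urgency) else "",
    x$n_conditions, x$sse, x$adj_r_squared
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_payoff_model
#' @param x A `payoff_fit` object.
#' @param ... Unused.
#' @export
tidy.payoff_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = "scaling_constant",
    estimate = x$params$scaling_constant
  )
  if (x$free == "ku") {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(term = "urgency", estimate = x$params$urgency)
    )
  }
  out
}

#' @rdname fit_payoff_model
#' @export
glance.payoff_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse,
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    nobs = x$n_conditions
  )
}
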