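# Visual resolution vs eccentricity, and the saccadic main sequence.
# These are the benefit and cost curves feeding the payoff-time model.

#' Parametric visual-resolution functions of eccentricity
#'
#' Constructs one of three resolution-vs-eccentricity curves used by the
#' payoff-time model. The two cone families describe foveolar resolution
#' derived from reciprocal cone spacing (one-to-one cone-to-midget-ganglion
#' mapping) along the temporal and nasal horizontal meridians; the
#' peripheral family is the direction-averaged cortical-magnification
#' estimate, normalized so its foveal value is 1, appropriate beyond the
#' foveola and for spatially extended targets.
#'
#' The functional forms are
#' \itemize{
#'   \item cone families: \eqn{r(e) = c_0 / \sqrt{1 + c_1 e}}
#'   \item peripheral:    \eqn{r(e) = 1 / (1 + c_1 e)}
#' }
#' with defaults \eqn{c_0 = 151.7, c_1 = 3.19} (temporal),
#' \eqn{c_0 = 148.7, c_1 = 3.27} (nasal) and \eqn{c_1 = 0.365}
#' (peripheral, \eqn{c_0 = 1}). All are strictly decreasing in
#' eccentricity \eqn{e \ge 0} (degrees).
#'
#' @param family One of `"cone_temporal"`, `"cone_nasal"`,
#'   `"peripheral_normalized"`.
#' @param c0,c1 Optional overrides for the coefficients; defaults are the
#'   standard constants for the chosen family.
#' @return An object of class `resolution_function`.
#' @examples
#' fn <- resolution_function("cone_temporal")
#' resolution_at(fn, 1) # 151.7 / sqrt(4.19)
#' @export
resolution_function <- function(family = c(
                                  "cone_temporal", "cone_nasal",
                                  "peripheral_normalized"
                                ),
                                c0 = NULL, c1 = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    cone_temporal = c(c0 = 151.7, c1 = 3.19),
    cone_nasal = c(c0 = 148.7, c1 = 3.27),
    peripheral_normalized = c(c0 = 1, c1 = 0.365)
  )
  c0 <- c0 %||% unname(defaults["c0"])
  c1 <- c1 %||% unname(defaults["c1"])
  stopifnot(c0 > 0, c1 > 0)
  structure(
    list(family = family, c0 = c0, c1 = c1),
    class = "resolution_function"
  )
}

#' @export
print.resolution_function <- function(x, ...) {
  form <- if (x$family == "peripheral_normalized") {
    sprintf("%g / (1 + %g * e)", x$c0, x$c1)
  } else {
    sprintf("%g / sqrt(1 + %g * e)", x$c0, x$c1)
  }
  cat("<resolution_function> ", x$family, ": r(e) = ", form, "\n", sep = "")
  invisible(x)
}

#' Evaluate a resolution function at given eccentricities
#'
#' @param fn A [resolution_function()].
#' @param e Eccentricity in degrees, vectorised, must be `>= 0`.
#' @return Resolution in the function's relative units.
#' @export
resolution_at <- function(fn, e) {
  stopifnot(inherits(fn, "resolution_function"))
  if (any(e < 0)) {
    stop("eccentricity must be >= 0 (got ", min(e), ")", call. = FALSE)
  }
  if (fn$family == "peripheral_normalized") {
    fn$c0 / (1 + fn$c1 * e)
  } else {
    fn$c0 / sqrt(1 + fn$c1 * e)
  }
}

#' Average resolution over an extended target
#'
#' For a ring or disc of diameter `D` centered at eccentricity `center_e`,
#' averages the resolution function over the target by deterministic
#' midpoint quadrature. Three averaging regions are available:
#' `"ring"` averages over the ring locus (points at distance
#' \eqn{\sqrt{e^2 + R^2 + 2 e R \cos\varphi}} with \eqn{R = D/2} and
#' \eqn{\varphi} uniform on the circle), `"disc"` averages over the
#' enclosed disc area, `"chord"` over the horizontal diameter. `D = 0`
#' degenerates to [resolution_at()] at `center_e`.
#'
#' `ring_average_resolution()` is the ring-locus case.
#'
#' @param fn A [resolution_function()].
#' @param center_e Eccentricity of the target center, degrees, `>= 0`.
#' @param diameter_d Target diameter in degrees, `>= 0`.
#' @param n_quadrature Number of angular quadrature nodes (`>= 8`;
#'   default 256, at which doubling the node count moves results by
#'   less than 1e-6).
#' @param mode Averaging region, one of `"disc"`, `"ring"`, `"chord"`.
#' @return Average resolution (scalar).
#' @export
target_average_resolution <- function(fn, center_e, diameter_d,
                                      n_quadrature = 256,
                                      mode = c("disc", "ring", "chord")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fn, "resolution_function"), length(center_e) == 1L,
            length(diameter_d) == 1L, diameter_d >= 0)
  if (center_e < 0) stop("center_e must be >= 0", call. = FALSE)
  if (n_quadrature < 8) {
    stop("n_quadrature must be >= 8 for acceptable accuracy", call. = FALSE)
  }
  if (diameter_d == 0) {
    return(resolution_at(fn, center_e))
  }
  R <- diameter_d / 2
  phi <- (seq_len(n_quadrature) - 0.5) / n_quadrature * 2 * pi
  switch(mode,
    ring = {
      d <- sqrt(center_e^2 + R^2 + 2 * center_e * R * cos(phi))
      mean(resolution_at(fn, d))
    },
    disc = {
      # polar midpoint rule, radial weight rho
      n_r <- max(32L, ceiling(n_quadrature / 4))
      rho <- (seq_len(n_r) - 0.5) / n_r * R
      d <- sqrt(outer(rho^2, rep(1, n_quadrature)) + center_e^2 +
                  2 * center_e * outer(rho, cos(phi)))
      vals <- resolution_at(fn, as.vector(d))
      w <- rep(rho, times = n_quadrature)
      sum(vals * w) / sum(w)
    },
    chord = {
      x <- center_e + (2 * (seq_len(n_quadrature) - 0.5) / n_quadrature - 1) * R
      mean(resolution_at(fn, abs(x)))
    }
  )
}

#' @rdname target_average_resolution
#' @export
ring_average_resolution <- function(fn, center_e, diameter_d,
                                    n_quadrature = 256) {
  target_average_resolution(fn, center_e, diameter_d, n_quadrature,
                            mode = "ring")
}

#' Normalized foveation benefit of a saccade
#'
#' The benefit of foveating a target is the fractional resolution gain
#' \eqn{b = 1 - r_e / r_0}, where \eqn{r_e} is the average resolution of
#' the target viewed peripherally at its current eccentricity and
#' \eqn{r_0} the average resolution of the same target once foveated
#' (centered at eccentricity 0, the peak resolution for that target
#' size). `b` lies in `[0, 1)`: 0 means a saccade gains nothing, values
#' near 1 mean peripheral preview is almost worthless relative to
#' foveation.
#'
#' @inheritParams target_average_resolution
#' @param center_e Current target-center eccentricity, degrees, `> 0`.
#' @return The benefit `b` in `[0, 1)`.
#' @export
foveation_benefit <- function(fn, center_e, diameter_d = 0,
                              n_quadrature = 256,
                              mode = c("disc", "ring", "chord")) {
  mode <- match.arg(mode)
  if (center_e <= 0) stop("center_e must be > 0", call. = FALSE)
  r_e <- target_average_resolution(fn, center_e, diameter_d, n_quadrature, mode)
  r_0 <- target_average_resolution(fn, 0, diameter_d, n_quadrature, mode)
  b <- 1 - r_e / r_0
  if (b <= 0) {
    stop(
      "degenerate foveation benefit (r_e >= r_0): no resolution gain from ",
      "foveating a target of diameter ", diameter_d, " deg at ", center_e,
      " deg with '", mode, "' averaging",
      call. = FALSE
    )
  }
  b
}

#' Main-sequence saccade duration fits
#'
#' Saccade duration T grows with amplitude A along the stereotyped
#' "main sequence". For small amplitudes (`A < range_max`, default 4
#' degrees) it is well described by a power law
#' \eqn{T = 10^{c} A^{x}} (T in ms, A in degrees); beyond that it is
#' quasi-linear. `main_sequence()` holds the coefficients; defaults are
#' the monocular-recording fits for rightward (temporal retina,
#' `c = 1.21, x = 0.25`) and leftward (nasal, `c = 1.22, x = 0.33`)
#' saccades.
#'
#' Above `range_max`, `extension = "power"` simply continues the power
#' law, while `extension = "linear"` switches to
#' `T(range_max) + linear_slope * (A - range_max)`, continuous at the
#' break; the default slope of 2.2 ms/deg is the classic large-amplitude
#' main-sequence slope.
#'
#' @param direction `"right"` (temporal) or `"left"` (nasal); selects the
#'   default coefficients.
#' @param log10_intercept,exponent Power-law coefficients `c` and `x`.
#' @param range_max Upper amplitude bound of the power-law regime (deg).
#' @param extension Large-amplitude behaviour, `"power"` or `"linear"`.
#' @param linear_slope Slope (ms/deg) of the linear extension.
#' @return An object of class `main_sequence`.
#' @examples
#' ms <- main_sequence("right")
#' saccade_duration(ms, 1) # 10^1.21 ~= 16.2 ms
#' @export
main_sequence <- function(direction = c("right", "left"),
                          log10_intercept = NULL, exponent = NULL,
                          range_max = 4,
                          extension = c("power", "linear"),
                          linear_slope = 2.2) {
  direction <- match.arg(direction)
  extension <- match.arg(extension)
  defaults <- switch(direction,
    right = c(c = 1.21, x = 0.25),
    left = c(c = 1.22, x = 0.33)
  )
  log10_intercept <- log10_intercept %||% unname(defaults["c"])
  exponent <- exponent %||% unname(defaults["x"])
  stopifnot(exponent > 0, range_max > 0, linear_slope > 0)
  structure(
    list(
      direction = direction,
      log10_intercept = log10_intercept,
      exponent = exponent,
      range_max = range_max,
      extension = extension,
      linear_slope = linear_slope
    ),
    class = "main_sequence"
  )
}

#' @export
print.main_sequence <- function(x, ...) {
  cat(sprintf(
    "<main_sequence> %s: T = 10^%.3g * A^%.3g (A < %g deg), %s extension\n",
    x$direction, x$log10_intercept, x$exponent, x$range_max, x$extension
  ))
  invisible(x)
}

#' Saccade duration from a main-sequence fit
#'
#' @param fit A [main_sequence()] object.
#' @param amplitude Saccade amplitude in degrees, vectorised, `> 0`.
#' @return Duration in ms.
#' @export
saccade_duration <- function(fit, amplitude) {
  stopifnot(inherits(fit, "main_sequence"))
  if (any(amplitude <= 0)) {
    stop("amplitude must be > 0", call. = FALSE)
  }
  pow <- 10^fit$log10_intercept * amplitude^fit$exponent
  if (fit$extension == "power") {
    return(pow)
  }
  t_break <- 10^fit$log10_intercept * fit$range_max^fit$exponent
  ifelse(
    amplitude < fit$range_max,
    pow,
    t_break + fit$linear_slope * (amplitude - fit$range_max)
  )
}

#' Fit a main-sequence power law to amplitude/duration pairs
#'
#' Ordinary least squares on `(log10 A, log10 T)`, optionally restricted
#' to an amplitude range.
#'
#' @param amplitudes,durations Positive numeric vectors of equal length.
#' @param range Length-2 amplitude window (deg) to fit within; default
#'   covers all points.
#' @param direction Direction label carried into the fit.
#' @return A [main_sequence()] object with extra fields `r_squared` and
#'   `n_points`.
#' @export
fit_main_sequence <- function(amplitudes, durations,
                              range = c(0, Inf), direction = "right") {
  stopifnot(length(amplitudes) == length(durations))
  if (any(amplitudes <= 0) || any(durations <= 0)) {
    stop("amplitudes and durations must all be > 0", call. = FALSE)
  }
  keep <- amplitudes >= range[1] & amplitudes <= range[2]
  a <- amplitudes[keep]
  t <- durations[keep]
  if (length(a) < 3) stop("need >= 3 points within range", call. = FALSE)
  if (length(unique(a)) < 2) {
    stop("degenerate fit: a single distinct amplitude", call. = FALSE)
  }
  m <- stats::lm(log10(t) ~ log10(a))
  r2 <- 1 - sum(stats::resid(m)^2) /
    sum((log10(t) - mean(log10(t)))^2)
  fit <- main_sequence(
    direction = if (direction %in% c("left", "right")) direction else "right",
    log10_intercept = unname(stats::coef(m)[1]),
    exponent = unname(stats::coef(m)[2]),
    range_max = max(a)
  )
  fit$r_squared <- r2
  fit$n_points <- length(a)
  fit
}
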