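# Descriptive analyses: power-law SRT vs eccentricity/diameter ratio,
# ROC separation between ratio conditions, and the spatial-scale effect.

#' Fit a power law of SRT against eccentricity/diameter ratio
#'
#' Ordinary least squares on `(log10 ratio, log10 SRT)` restricted to
#' the SRT-changing region `ratio <= max_ratio` (default 1; above that
#' SRT plateaus). Back-transformed, the fit is
#' \eqn{SRT = a \cdot ratio^{b}} with `a` in ms (the predicted SRT at
#' ratio 1) and `b` the (typically negative) exponent. The fit is
#' scale-equivariant: multiplying all SRTs by `c` multiplies `a` by `c`
#' and leaves `b` unchanged.
#'
#' @param ratios Positive eccentricity/diameter ratios.
#' @param srts Positive latencies (ms), per-condition medians or raw
#'   per-trial values.
#' @param max_ratio Upper ratio bound of the fitted region.
#' @return A `power_law_fit`: `a_ms`, `b`, `r_squared` (on the log
#'   scale), `n_points`, `max_ratio`. Has [tidy()]/[glance()] methods.
#' @export
fit_power_law <- function(ratios, srts, max_ratio = 1) {
  stopifnot(length(ratios) == length(srts))
  if (any(ratios <= 0) || any(srts <= 0)) {
    stop("ratios and srts must all be > 0", call. = FALSE)
  }
  keep <- ratios <= max_ratio
  if (!any(keep)) {
    stop("no points at or below max_ratio = ", max_ratio, call. = FALSE)
  }
  r <- ratios[keep]
  s <- srts[keep]
  if (length(unique(r)) < 3) {
    stop("need >= 3 distinct ratios at or below max_ratio", call. = FALSE)
  }
  m <- stats::lm(log10(s) ~ log10(r))
  structure(
    list(
      a_ms = 10^unname(stats::coef(m)[1]),
      b = unname(stats::coef(m)[2]),
      r_squared = 1 - sum(stats::resid(m)^2) /
        sum((log10(s) - mean(log10(s)))^2),
      n_points = length(r),
      max_ratio = max_ratio
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> SRT = %.4g * ratio^%.3g (n = %d, R^2 = %.3f)\n",
    x$a_ms, x$b, x$n_points, x$r_squared
  ))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x A `power_law_fit` object.
#' @param ... Unused.
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a_ms", "b"),
    estimate = c(x$a_ms, x$b)
  )
}

#' @rdname fit_power_law
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    nobs = x$n_points,
    max_ratio = x$max_ratio
  )
}

#' ROC area between two latency samples
#'
#' Area under the ROC curve traced by plotting one empirical CDF against
#' the other; equals the Mann--Whitney probability that a random draw
#' from `srts_a` exceeds one from `srts_b`, with ties counted half
#' (midranks). `auc_separation(a, b) + auc_separation(b, a) = 1`
#' exactly.
#'
#' @param srts_a,srts_b Latency samples, each with at least 10 values.
#' @return AUC in `[0, 1]`.
#' @export
auc_separation <- function(srts_a, srts_b) {
  n_a <- length(srts_a)
  n_b <- length(srts_b)
  if (n_a < 10 || n_b < 10) {
    stop("need at least 10 latencies in each sample", call. = FALSE)
  }
  r <- rank(c(srts_a, srts_b), ties.method = "average")
  (sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2) / (n_a * n_b)
}

#' Magnitude of the spatial-scale effect
#'
#' The SRT difference between the lowest (most overlapping) ratio
#' condition and ratio = 1. `method = "pooled"` takes the difference of
#' medians pooled across participants (and ring sizes) at the two
#' ratios; `method = "fitted"` evaluates a fitted power law at both
#' ratios instead.
#'
#' @param data A data frame with columns `ratio` and `srt_ms` (raw
#'   trials or condition medians).
#' @param low_ratio,ref_ratio The two ratio conditions compared.
#' @param method `"pooled"` or `"fitted"`.
#' @param tol Matching tolerance on the ratio values.
#' @return The difference `SRT(low_ratio) - SRT(ref_ratio)` in ms.
#' @export
scale_effect_magnitude <- function(data, low_ratio = 0.125,
                                   ref_ratio = 1,
                                   method = c("pooled", "fitted"),
                                   tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(all(c("ratio", "srt_ms") %in% names(data)))
  if (method == "fitted") {
    fit <- fit_power_law(data$ratio, data$srt_ms, max_ratio = ref_ratio)
    return(fit$a_ms * (low_ratio^fit$b - ref_ratio^fit$b))
  }
  lo <- data$srt_ms[abs(data$ratio - low_ratio) < tol]
  hi <- data$srt_ms[abs(data$ratio - ref_ratio) < tol]
  if (length(lo) == 0 || length(hi) == 0) {
    stop("both ratio conditions must be present (", low_ratio, " and ",
         ref_ratio, ")", call. = FALSE)
  }
  stats::median(lo) - stats::median(hi)
}
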