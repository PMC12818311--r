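# Gaze-trace preprocessing: central-difference velocity, threshold
# saccade detection, and the offline trial-validity filters.

#' Central-difference eye speed
#'
#' Estimates per-sample speed from gaze position by a central difference:
#' speed at sample i uses positions at i +/- `separation` over
#' `2 * separation * dt`. Endpoint samples and samples within
#' `separation` of a blink have undefined speed (`NA`). Larger
#' separations trade temporal resolution for instrument-noise
#' suppression; 1 is the default and the knob is exposed for noisier
#' trackers.
#'
#' @param trace A data frame with columns `t_ms` (strictly increasing,
#'   uniform spacing), `x_deg`, `y_deg`, and optionally `blink`
#'   (logical).
#' @param separation Half-width of the difference stencil, in samples.
#' @return The trace tibble with an added `speed_deg_s` column.
#' @export
compute_velocity <- function(trace, separation = 1) {
  stopifnot(all(c("t_ms", "x_deg", "y_deg") %in% names(trace)),
            separation >= 1)
  n <- nrow(trace)
  if (n < 2 * separation + 1) stop("trace too short", call. = FALSE)
  dt <- diff(trace$t_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("non-uniform sampling: t_ms must increase in constant steps",
         call. = FALSE)
  }
  dt <- dt[1]
  s <- separation
  idx <- (s + 1):(n - s)
  speed <- rep(NA_real_, n)
  dx <- trace$x_deg[idx + s] - trace$x_deg[idx - s]
  dy <- trace$y_deg[idx + s] - trace$y_deg[idx - s]
  speed[idx] <- sqrt(dx^2 + dy^2) / (2 * s * dt) * 1000 # deg/ms -> deg/s
  if ("blink" %in% names(trace)) {
    bl <- which(trace$blink)
    if (length(bl) > 0) {
      near <- unique(as.vector(outer(bl, -s:s, `+`)))
      near <- near[near >= 1 & near <= n]
      speed[near] <- NA_real_
    }
  }
  out <- tibble::as_tibble(trace)
  out$speed_deg_s <- speed
  out
}

#' Detect saccades by velocity thresholds
#'
#' A saccade is identified when speed exceeds `onset_threshold` for at
#' least `min_consecutive` consecutive samples; its start and end are
#' then marked where speed falls below `offset_threshold` on either side
#' of that excursion. Events overlapping blink samples are discarded.
#'
#' @param trace A trace with a `speed_deg_s` column (see
#'   [compute_velocity()]).
#' @param onset_threshold Detection threshold, deg/s.
#' @param offset_threshold Start/end marking threshold, deg/s.
#' @param min_consecutive Minimum run length above `onset_threshold`.
#' @param first_only Return only the first event (the convention for
#'   reaction-time trials).
#' @return A tibble of events: `onset_ms`, `offset_ms`, `duration_ms`,
#'   `amplitude_deg` (Euclidean displacement start to end), `direction`
#'   (`"left"`/`"right"` by horizontal displacement), `peak_speed_deg_s`.
#'   An all-blink trace returns zero rows with attribute
#'   `"all_blink" = TRUE`.
#' @export
detect_saccades <- function(trace, onset_threshold = 15,
                            offset_threshold = 10, min_consecutive = 2,
                            first_only = FALSE) {
  stopifnot("speed_deg_s" %in% names(trace))
  empty <- tibble::tibble(
    onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
    amplitude_deg = numeric(), direction = character(),
    peak_speed_deg_s = numeric()
  )
  blink <- if ("blink" %in% names(trace)) trace$blink else
    rep(FALSE, nrow(trace))
  if (all(blink)) {
    attr(empty, "all_blink") <- TRUE
    return(empty)
  }
  v <- trace$speed_deg_s
  supra <- !is.na(v) & v >= onset_threshold
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_consecutive)
  if (length(runs) == 0) {
    return(empty)
  }
  above_off <- !is.na(v) & v >= offset_threshold
  events <- list()
  last_end <- 0L
  for (k in runs) {
    i0 <- starts[k]
    i1 <- ends[k]
    while (i0 > 1 && above_off[i0 - 1L]) i0 <- i0 - 1L
    while (i1 < length(v) && above_off[i1 + 1L]) i1 <- i1 + 1L
    if (i0 <= last_end) next # merged with previous event
    last_end <- i1
    if (any(blink[i0:i1])) next
    dx <- trace$x_deg[i1] - trace$x_deg[i0]
    dy <- trace$y_deg[i1] - trace$y_deg[i0]
    events[[length(events) + 1L]] <- tibble::tibble(
      onset_ms = trace$t_ms[i0],
      offset_ms = trace$t_ms[i1],
      duration_ms = trace$t_ms[i1] - trace$t_ms[i0],
      amplitude_deg = sqrt(dx^2 + dy^2),
      direction = if (dx < 0) "left" else "right",
      peak_speed_deg_s = max(v[i0:i1], na.rm = TRUE)
    )
  }
  if (length(events) == 0) {
    return(empty)
  }
  out <- dplyr::bind_rows(events)
  if (first_only) out <- out[1, ]
  out
}

#' Apply the offline trial-validity filters
#'
#' Classifies each trial as valid or excluded: latencies below
#' `min_srt_ms` are anticipatory, latencies above `max_srt_ms` too slow
#' (both bounds strict: 80 and 600 ms are included), first saccades
#' opposite to the target step are wrong-direction, and any blink before
#' or during the first saccade voids the trial. Precedence when several
#' apply: blink, anticipatory, too slow, wrong direction.
#'
#' @param trials A trial tibble with `srt_ms`; optional columns
#'   `saccade_direction` (compared against `direction`) and `blink`
#'   (logical).
#' @param min_srt_ms,max_srt_ms Validity window bounds in ms.
#' @return A list: `trials` (the tibble with recomputed `valid` and
#'   `exclusion_reason`), and `report` (tibble of counts per reason,
#'   whose `n` sums to the total) plus `inclusion_fraction` as an
#'   attribute of the report.
#' @export
filter_trials <- function(trials, min_srt_ms = 80, max_srt_ms = 600) {
  stopifnot(is.data.frame(trials), "srt_ms" %in% names(trials))
  if (any(is.na(trials$srt_ms))) {
    stop("trials without a measured srt_ms cannot be filtered",
         call. = FALSE)
  }
  n <- nrow(trials)
  blink <- if ("blink" %in% names(trials)) {
    !is.na(trials$blink) & trials$blink
  } else {
    rep(FALSE, n)
  }
  # choice trials (a competing target present) have no wrong direction:
  # either side is a legitimate choice
  is_choice <- if ("comp_eccentricity_deg" %in% names(trials)) {
    !is.na(trials$comp_eccentricity_deg)
  } else {
    rep(FALSE, n)
  }
  wrong_dir <- if ("saccade_direction" %in% names(trials)) {
    !is_choice & !is.na(trials$saccade_direction) &
      trials$saccade_direction != trials$direction
  } else {
    rep(FALSE, n)
  }
  reason <- rep("none", n)
  reason[wrong_dir] <- "wrong_direction"
  reason[trials$srt_ms > max_srt_ms] <- "too_slow"
  reason[trials$srt_ms < min_srt_ms] <- "anticipatory"
  reason[blink] <- "blink"
  out <- tibble::as_tibble(trials)
  out$exclusion_reason <- reason
  out$valid <- reason == "none"
  levels <- c("none", "anticipatory", "too_slow", "wrong_direction",
              "blink")
  counts <- vapply(levels, function(r) sum(reason == r), integer(1))
  report <- tibble::tibble(reason = levels, n = unname(counts))
  attr(report, "inclusion_fraction") <- sum(out$valid) / n
  list(trials = out, report = report)
}
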