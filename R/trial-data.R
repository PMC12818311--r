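# Canonical trial table, delimited-text readers/writers and per-condition
# summaries. One flat schema serves all three experimental designs,
# disambiguated by experiment_id; for choice trials the primary
# diameter/eccentricity columns describe the reference (ratio = 1) target
# and comp_* the competing target.

# mandatory columns of the trial schema
trial_schema_required <- c(
  "participant_id", "experiment_id", "diameter_deg", "eccentricity_deg",
  "direction", "foreperiod_ms", "srt_ms", "chosen_side", "valid",
  "exclusion_reason"
)

trial_schema_numeric <- c(
  "diameter_deg", "eccentricity_deg", "comp_diameter_deg",
  "comp_eccentricity_deg", "foreperiod_ms", "srt_ms", "amplitude_deg",
  "duration_ms"
)

trial_schema_optional <- c(
  "comp_diameter_deg", "comp_eccentricity_deg", "amplitude_deg",
  "duration_ms", "saccade_direction", "blink"
)

#' Read a trial table from delimited text
#'
#' Reads the documented comma-separated trial schema (degrees and
#' milliseconds throughout, `"."` decimal, UTF-8). Mandatory columns:
#' `participant_id`, `experiment_id`, `diameter_deg`, `eccentricity_deg`,
#' `direction`, `foreperiod_ms`, `srt_ms`, `chosen_side`, `valid`,
#' `exclusion_reason`; choice trials additionally carry
#' `comp_diameter_deg`/`comp_eccentricity_deg` for the competing target
#' (the primary condition columns always describe the reference,
#' ratio-1, target). Rows whose numeric fields fail to parse are never
#' silently dropped: they are removed from the result and collected in
#' the `"parse_errors"` attribute (row number, column, offending value).
#'
#' @param path Path to a CSV file.
#' @return A tibble of trials with attribute `"parse_errors"` (a tibble,
#'   zero rows when the file is clean).
#' @seealso [write_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(trial_schema_required, names(raw))
  if (length(missing_cols) > 0) {
    stop("trial file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  errors <- list()
  for (col in intersect(trial_schema_numeric, names(raw))) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    optional_blank <- col %in% trial_schema_optional & (is.na(vals) | vals == "")
    bad <- which(is.na(parsed) & !optional_blank)
    if (length(bad) > 0) {
      errors[[col]] <- tibble::tibble(
        row = bad, column = col, value = vals[bad]
      )
    }
    raw[[col]] <- parsed
  }
  errors <- if (length(errors) > 0) {
    dplyr::bind_rows(errors)
  } else {
    tibble::tibble(row = integer(), column = character(),
                   value = character())
  }
  if (nrow(errors) > 0) {
    raw <- raw[-unique(errors$row), , drop = FALSE]
  }
  if ("valid" %in% names(raw)) raw$valid <- as.logical(raw$valid)
  if ("blink" %in% names(raw)) raw$blink <- as.logical(raw$blink)
  attr(raw, "parse_errors") <- errors
  raw
}

#' Write a trial table to delimited text
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(x, f))`
#' reproduces `x` field for field. An empty table writes a header-only
#' file. A sidecar provenance log (`<path>.provenance.json` with row
#' count, content hash, package version and optional seed) accompanies
#' every file unless `provenance = FALSE`.
#'
#' @param trials A trial tibble.
#' @param path Output CSV path.
#' @param provenance Write the sidecar JSON log?
#' @param seed Optional seed recorded in the provenance log.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, provenance = TRUE, seed = NULL) {
  stopifnot(is.data.frame(trials))
  readr::write_csv(trials, path, progress = FALSE)
  if (provenance) {
    log <- list(
      file = basename(path),
      n_rows = nrow(trials),
      md5 = unname(tools::md5sum(path)),
      package = "saccadepay",
      version = as.character(utils::packageVersion("saccadepay")),
      seed = seed
    )
    jsonlite::write_json(log, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Summarise trials by participant and condition
#'
#' One row per distinct (participant, condition): trial counts, median
#' and mean SRT over valid trials, and for choice trials the probability
#' of choosing the reference (ratio = 1) target, `cp1`, with an exact
#' (Clopper--Pearson) binomial confidence interval. Conditions with no
#' valid trials are kept and flagged `empty` rather than fabricated.
#'
#' @param trials A trial tibble (see [read_trials()] for the schema).
#' @param by_direction Keep `direction` as part of the condition
#'   (default collapses across directions, as the ring experiments do).
#' @param conf_level Confidence level for the binomial interval.
#' @return A tibble of condition summaries with columns `n_trials`
#'   (valid count), `median_srt_ms`, `mean_srt_ms`, `ratio`, and for
#'   choice conditions `n_ratio1`, `cp1`, `cp1_lo`, `cp1_hi`.
#' @export
summarize_conditions <- function(trials, by_direction = FALSE,
                                 conf_level = 0.95) {
  stopifnot(is.data.frame(trials))
  if (!"comp_eccentricity_deg" %in% names(trials)) {
    trials$comp_eccentricity_deg <- NA_real_
    trials$comp_diameter_deg <- NA_real_
  }
  group_cols <- c(
    "participant_id", "experiment_id", "diameter_deg",
    "eccentricity_deg", "comp_diameter_deg", "comp_eccentricity_deg",
    if (by_direction) "direction"
  )
  chose_ref <- if ("chosen_side" %in% names(trials)) {
    trials$chosen_side == trials$direction
  } else {
    rep(NA, nrow(trials))
  }
  trials$.chose_ratio1 <- chose_ref
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_trials = sum(.data$valid),
      median_srt_ms = stats::median(.data$srt_ms[.data$valid]),
      mean_srt_ms = mean(.data$srt_ms[.data$valid]),
      n_ratio1 = sum(.data$.chose_ratio1[.data$valid]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      empty = .data$n_trials == 0,
      is_choice = !is.na(.data$comp_eccentricity_deg),
      ratio = ifelse(.data$diameter_deg > 0,
                     .data$eccentricity_deg / .data$diameter_deg, Inf),
      comp_ratio = ifelse(
        .data$is_choice & .data$comp_diameter_deg > 0,
        .data$comp_eccentricity_deg / .data$comp_diameter_deg, NA_real_
      )
    )
  ci <- purrr::pmap(
    list(out$n_ratio1, out$n_trials, out$is_choice),
    function(x, n, choice) {
      if (!choice || n == 0 || is.na(x)) {
        c(NA_real_, NA_real_)
      } else {
        binom_ci(x, n, conf_level)
      }
    }
  )
  out$cp1 <- ifelse(out$is_choice & out$n_trials > 0,
                    out$n_ratio1 / out$n_trials, NA_real_)
  out$cp1_lo <- purrr::map_dbl(ci, 1)
  out$cp1_hi <- purrr::map_dbl(ci, 2)
  out$n_ratio1[!out$is_choice] <- NA_integer_
  out
}
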