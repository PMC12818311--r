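# End-to-end orchestration: simulate -> filter -> summarise -> fit ->
# report, deterministic under a single seed.

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Executes the standard stage chain for one experiment template:
#' generate trials ([generate_experiment()]), apply the validity
#' filters ([filter_trials()]), summarise per condition
#' ([summarize_conditions()]), then the template-appropriate model
#' fits — the power law of SRT against eccentricity/diameter ratio and
#' a payoff-model fit for the ring templates, per-direction payoff fits
#' for the foveolar template, and the race-model choice pipeline
#' (recinormal fits of the single-target conditions, mutual-inhibition
#' and bias estimation, CP1 predictions and priority indices) for the
#' free-choice template. Identical seeds give identical reports.
#'
#' @param config A [synthetic_config()].
#' @param out_json Optional path; when given, the report (minus the raw
#'   trial table) is also written as a JSON file.
#' @return A list of class `pipeline_report`: `template`, `seed`,
#'   `n_trials`, `inclusion_fraction`, `exclusion_counts`, `summaries`,
#'   and the fits relevant to the template (`power_law`, `payoff_fit`,
#'   `choice` with per-condition CP1/priority indices), plus the
#'   generated `trials`.
#' @export
run_pipeline <- function(config, out_json = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  gen <- generate_experiment(config)
  filt <- filter_trials(gen$trials)
  trials <- filt$trials
  valid <- dplyr::filter(trials, .data$valid)
  summaries <- summarize_conditions(trials)

  report <- list(
    template = config$template,
    seed = config$seed,
    n_trials = nrow(trials),
    inclusion_fraction = attr(filt$report, "inclusion_fraction"),
    exclusion_counts = filt$report,
    summaries = summaries,
    trials = trials,
    truth = gen$truth
  )

  single <- dplyr::filter(summaries, !.data$is_choice, !.data$empty)
  group_medians <- single |>
    dplyr::group_by(.data$diameter_deg, .data$eccentricity_deg,
                    .data$ratio) |>
    dplyr::summarise(median_srt_ms = mean(.data$median_srt_ms),
                     .groups = "drop")

  if (config$template %in% c("exp1", "exp3")) {
    report$power_law <- fit_power_law(
      group_medians$ratio, group_medians$median_srt_ms
    )
    report$payoff_fit <- fit_payoff_model(
      group_medians, config$payoff, free = "ku"
    )
  } else {
    # foveolar template: per-direction one-parameter fits
    by_dir <- summarize_conditions(trials, by_direction = TRUE) |>
      dplyr::filter(!.data$empty) |>
      dplyr::group_by(.data$direction, .data$diameter_deg,
                      .data$eccentricity_deg) |>
      dplyr::summarise(median_srt_ms = mean(.data$median_srt_ms),
                       .groups = "drop")
    report$payoff_fit <- purrr::map(
      stats::setNames(c("left", "right"), c("left", "right")),
      function(d) {
        fit_payoff_model(
          dplyr::filter(by_dir, .data$direction == d),
          exp2_direction_params(config$payoff, d),
          free = "k"
        )
      }
    )
  }

  if (config$template == "exp3") {
    report$choice <- choice_pipeline(trials, config)
  }

  if (!is.null(out_json)) {
    slim <- report[setdiff(names(report), c("trials", "truth"))]
    slim$exclusion_counts <- as.data.frame(slim$exclusion_counts)
    slim$summaries <- as.data.frame(slim$summaries)
    if (!is.null(slim$power_law)) slim$power_law <- unclass(slim$power_law)
    slim$payoff_fit <- NULL
    if (!is.null(slim$choice)) {
      slim$choice <- list(
        beta = slim$choice$beta,
        conditions = as.data.frame(slim$choice$conditions)
      )
    }
    jsonlite::write_json(slim, out_json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report> %s, seed %d: %d trials, %.1f%% included\n",
    x$template, x$seed, x$n_trials, 100 * x$inclusion_fraction
  ))
  invisible(x)
}

# the free-choice analysis chain: single-target recinormal fits ->
# mutual inhibition -> directional bias -> CP1 predictions -> indices
choice_pipeline <- function(trials, config) {
  t0 <- config$payoff$sensory_window_ms
  singles <- dplyr::filter(
    trials, .data$experiment_id == "exp3_single", .data$valid
  )
  choices <- dplyr::filter(
    trials, .data$experiment_id == "exp3_choice", .data$valid
  )

  # pooled-across-participants recinormal fit per single condition
  unit_of <- singles |>
    dplyr::group_by(.data$diameter_deg, .data$eccentricity_deg) |>
    dplyr::summarise(
      fit = list(fit_recinormal(.data$srt_ms, t0)), .groups = "drop"
    )
  lookup_unit <- function(d, e) {
    row <- which(unit_of$diameter_deg == d &
                   unit_of$eccentricity_deg == e)
    unit_of$fit[[row]]$params
  }

  pair_grid <- generate_conditions("exp3_choice")
  pairs <- purrr::pmap(
    list(pair_grid$eccentricity_deg, pair_grid$diameter_deg,
         pair_grid$comp_eccentricity_deg),
    function(e1, d, e2) {
      list(ratio1 = lookup_unit(d, e1), comp = lookup_unit(d, e2))
    }
  )
  srts_by_pair <- purrr::pmap(
    list(pair_grid$diameter_deg, pair_grid$comp_eccentricity_deg),
    function(d, e2) {
      choices$srt_ms[choices$diameter_deg == d &
                       choices$comp_eccentricity_deg == e2]
    }
  )
  beta_fit <- fit_mutual_inhibition(srts_by_pair, pairs)

  bias_tbl <- estimate_directional_bias(
    choices,
    sigma_ref = mean(purrr::map_dbl(pairs,
                                    function(p) p$ratio1$sigma))
  )
  pooled_bias <- stats::qnorm(
    sum(bias_tbl$n_right) / sum(bias_tbl$n_trials)
  ) * sqrt(2) * mean(purrr::map_dbl(pairs, function(p) p$ratio1$sigma))

  cond <- pair_grid
  cond$cp_model <- purrr::map_dbl(pairs, function(p) {
    predict_cp1(p$ratio1, p$comp, beta = beta_fit$beta,
                bias = pooled_bias)
  })
  cond$cp_salience <- as.numeric(cond$comp_ratio > 1)
  obs <- purrr::pmap_dbl(
    list(cond$diameter_deg, cond$comp_eccentricity_deg),
    function(d, e2) {
      sel <- choices$diameter_deg == d &
        choices$comp_eccentricity_deg == e2
      mean(choices$chosen_side[sel] == choices$direction[sel])
    }
  )
  cond$cp_obs <- obs
  cond$n_trials <- purrr::pmap_int(
    list(cond$diameter_deg, cond$comp_eccentricity_deg),
    function(d, e2) {
      sum(choices$diameter_deg == d &
            choices$comp_eccentricity_deg == e2)
    }
  )
  cond$priority_index <- priority_index(cond$cp_obs, cond$cp_model,
                                        cond$cp_salience)

  # per-competing-ratio aggregation (conditions pooled across diameters)
  by_ratio <- cond |>
    dplyr::group_by(.data$comp_ratio) |>
    dplyr::summarise(
      cp_obs = stats::weighted.mean(.data$cp_obs, .data$n_trials),
      cp_model = stats::weighted.mean(.data$cp_model, .data$n_trials),
      cp_salience = .data$cp_salience[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(priority_index = priority_index(
      .data$cp_obs, .data$cp_model, .data$cp_salience
    ))

  list(
    units = unit_of,
    beta = beta_fit$beta,
    bias = bias_tbl,
    pooled_bias_rate = pooled_bias,
    conditions = cond,
    by_ratio = by_ratio,
    mean_priority_index = mean(by_ratio$priority_index)
  )
}
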