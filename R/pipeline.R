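# Pipeline orchestration, configuration, CSV schemas and manifests.

#' Default pipeline configuration
#'
#' The complete configuration of a two-area campaign in the default study
#' design: each area a 20-recorder 6 x 5 km grid, 60 stratified broadcast
#' sites over 3 nights x 3 periods (two sites excluded in the mid-mountain
#' area), default [environment_model()] physics, 200 ms reliability
#' threshold, per-estimate ("used") microphone hulls. All fields may be
#' overridden via YAML ([read_config()]) or by editing the returned list.
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 42L,
    areas = list(
      VM = list(n_sites = 60, n_excluded = 2),
      CM = list(n_sites = 60, n_excluded = 0)
    ),
    array = list(
      n_cols = 5, n_rows = 4, spacing = 1000,
      study_area = c(6000, 5000), jitter_sd = 0, channel_offset = 0.2
    ),
    sites = list(buffer = 1500),
    environment = list(
      detection_d50 = 1500, detection_slope = 300,
      snr0_db = 35, snr_ref_m = 100, atmos_alpha_db_per_m = 0.003,
      snr_noise_sd = 3, toa_noise_sd = 0.02
    ),
    howl = list(
      duration = 7, f0_start = 300, f0_end = 1000, n_harmonics = 4,
      sample_rate = 16000, sweep = "linear"
    ),
    localization = list(threshold_ms = 200, oracle_resolution = 10),
    evaluation = list(hull_mode = "used", drop_aberrant = FALSE),
    force_detection = FALSE
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Values absent from the file fall back to [default_config()].
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `read_config()`: a `pipeline_config`; `write_config()`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_cfg(base[[k]], over[[k]])
      } else {
        over[[k]]
      }
    }
    base
  }
  structure(merge_cfg(unclass(default_config()), user),
            class = "pipeline_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Output-file schemas
#'
#' Named list of the column names of every CSV the pipeline writes; used
#' by [read_table()] / [write_table()] to guard round-trips.
#'
#' @export
howlspot_schemas <- list(
  array = c("recorder_id", "channel", "x", "y"),
  sites = c("site_id", "x", "y", "stratum", "area_label"),
  plan = c("broadcast_id", "site_id", "night", "period", "t0_s"),
  detections = c(
    "broadcast_id", "site_id", "recorder_id", "channel", "distance_m",
    "detected", "snr_db", "toa_s", "true_toa_s", "night", "period",
    "area_label", "temp_c"
  ),
  temps = c("night", "period", "mean_temp_c"),
  estimates = c(
    "broadcast_id", "x_est", "y_est", "t0_est", "temporal_error_ms",
    "n_mics", "n_recorders", "condition_flag", "converged",
    "kept_after_filter"
  ),
  evaluation = c(
    "broadcast_id", "loc_accuracy", "dist", "areamic", "inout", "period",
    "night", "array", "temporal_error_ms", "kept_after_filter"
  ),
  summary = c("array", "n", "mean", "sd", "min", "max"),
  models = c("model", "fixed_effects", "k", "aic", "rank_deficient", "delta_aic"),
  toa = c("broadcast_id", "recorder_id", "channel", "toa_s", "snr_db", "detected")
)

#' Schema-checked CSV I/O
#'
#' RFC 4180 CSV with a fixed column set per file kind: writing serialises
#' doubles with 6 decimals and missing values as empty fields; reading
#' verifies the header and errors listing any missing or extra columns.
#'
#' @param x A tibble whose columns match the schema.
#' @param path CSV path.
#' @param schema Character vector of column names, e.g. an entry of
#'   [howlspot_schemas].
#' @return `write_table()`: `path` invisibly; `read_table()`: a tibble.
#' @export
write_table <- function(x, path, schema = names(x)) {
  missing_cols <- setdiff(schema, names(x))
  extra <- setdiff(names(x), schema)
  if (length(missing_cols) || length(extra)) {
    abort(paste0(
      "schema mismatch writing ", path,
      if (length(missing_cols)) paste0("; missing: ", toString(missing_cols)) else "",
      if (length(extra)) paste0("; extra: ", toString(extra)) else ""
    ))
  }
  out <- x[, schema, drop = FALSE] %>%
    mutate(across(
      dplyr::where(is.double),
      ~ ifelse(is.na(.x), NA_character_, sprintf("%.6f", .x))
    ))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(schema, header)
  extra <- setdiff(header, schema)
  if (length(missing_cols) || length(extra)) {
    abort(paste0(
      "schema mismatch in ", path,
      if (length(missing_cols)) paste0("; missing: ", toString(missing_cols)) else "",
      if (length(extra)) paste0("; extra: ", toString(extra)) else ""
    ))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full campaign pipeline
#'
#' Simulate -> localize -> filter -> evaluate for every configured study
#' area, then pool: grouped accuracy summaries and the AIC model
#' comparison. When `outdir` is given, all stage tables are written as
#' schema-checked CSVs plus a JSON run manifest (configuration, seed,
#' config hash, package version) so any stage can be re-run from its
#' intermediate files.
#'
#' @param config A [default_config()]-style list.
#' @param outdir Optional output directory (created if needed).
#' @param seed Campaign seed; overrides `config$seed` when given.
#' @return Invisibly, a list with `array`, `sites`, `plan`, `detections`,
#'   `estimates`, `evaluation`, `summary`, `models` (an `accuracy_models`
#'   or `NULL` when too few records) and `config`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- config$seed
  arr_cfg <- config$array
  array <- build_grid_array(
    n_cols = arr_cfg$n_cols, n_rows = arr_cfg$n_rows,
    spacing = arr_cfg$spacing, study_area = arr_cfg$study_area,
    jitter_sd = arr_cfg$jitter_sd, channel_offset = arr_cfg$channel_offset,
    seed = seed
  )
  env <- do.call(environment_model, config$environment)

  per_area <- purrr::imap(config$areas, function(a, label) {
    area_seed <- (seed + match(label, names(config$areas)) * 7919L) %%
      .Machine$integer.max
    sites <- sample_broadcast_sites(
      n_sites = a$n_sites, study_area = arr_cfg$study_area,
      buffer = config$sites$buffer, area_label = label, seed = area_seed
    )
    excluded <- utils::head(sites$site_id, a$n_excluded)
    plan <- schedule_campaign(sites, excluded_sites = excluded, seed = area_seed)
    det <- simulate_campaign(array, plan, sites, env, seed = area_seed,
                             force_detection = isTRUE(config$force_detection))
    list(sites = sites, plan = plan, detections = det)
  })
  sites <- bind_rows(purrr::map(per_area, "sites"))
  plan <- bind_rows(purrr::map(per_area, "plan"))
  detections <- bind_rows(purrr::map(per_area, "detections"))

  threshold <- config$localization$threshold_ms
  estimates <- localize_all(join_array(detections, array),
                            threshold_ms = threshold)
  evaluation <- if (nrow(estimates)) {
    evaluate_campaign(estimates, join_array(detections, array), sites,
                      array = array, hull_mode = config$evaluation$hull_mode)
  } else {
    tibble()
  }
  kept <- evaluation %>% filter(.data$kept_after_filter)
  if (isTRUE(config$evaluation$drop_aberrant) && nrow(kept)) {
    kept <- drop_aberrant(kept)
  }
  summary_tbl <- if (nrow(evaluation)) {
    summarize_records(evaluation, group_by = "array", var = "loc_accuracy")
  } else {
    tibble()
  }
  models <- tryCatch(fit_models_aic(kept), error = function(e) NULL)

  result <- list(
    array = array, sites = sites, plan = plan, detections = detections,
    estimates = estimates, evaluation = evaluation, summary = summary_tbl,
    models = models, config = config
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name) write_table(x, file.path(outdir, paste0(name, ".csv")),
                                       howlspot_schemas[[name]])
    w(as_tibble(array), "array")
    w(sites, "sites")
    w(plan, "plan")
    w(detections, "detections")
    w(env$temperature_c, "temps")
    if (nrow(estimates)) w(estimates, "estimates")
    if (nrow(evaluation)) w(evaluation, "evaluation")
    if (nrow(summary_tbl)) w(summary_tbl, "summary")
    if (!is.null(models)) w(glance(models), "models")
    manifest <- list(
      seed = seed,
      config = unclass(config),
      config_hash = rlang::hash(unclass(config)),
      package_version = as.character(utils::packageVersion("howlspot")),
      r_version = R.version.string
    )
    jsonlite::write_json(manifest, file.path(outdir, "run-manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}
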