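# File I/O and report assembly. CSV dialect is fixed (RFC 4180, UTF-8, '.'
# decimal separator) so outputs are bit-stable; machine CSVs carry full
# precision and any integer rounding happens only in human-readable text.

.sets_cols <- c("participant", "condition", "reps", "mass_kg", "distance_m",
                "exo_moment_nm")

#' Read a lifting-sets CSV
#'
#' Expected header: `participant,condition,reps,mass_kg,distance_m,
#' exo_moment_nm[,excluded]`. Every schema violation is reported with the
#' offending row number.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of lifting sets.
#' @export
read_sets_csv <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(.sets_cols, names(df))
  if (length(missing) > 0) {
    abort_schema(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort_schema("Empty sets file.")
  # row numbers in messages count the header line, matching the file
  bad_cond <- which(!df$condition %in% .condition_levels)
  if (length(bad_cond) > 0) {
    abort_schema(sprintf("Unknown condition label `%s` in row %d.",
                         df$condition[bad_cond[1]], bad_cond[1] + 1L))
  }
  reps_num <- suppressWarnings(as.numeric(df$reps))
  bad_reps <- which(is.na(reps_num) | reps_num != round(reps_num) | reps_num < 0)
  if (length(bad_reps) > 0) {
    abort_schema(sprintf("`reps` must be a non-negative integer (row %d: %s).",
                         bad_reps[1] + 1L, df$reps[bad_reps[1]]))
  }
  num_col <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | x < 0)
    if (length(bad) > 0) {
      abort_schema(sprintf("`%s` must be a non-negative number (row %d: %s).",
                           col, bad[1] + 1L, df[[col]][bad[1]]))
    }
    x
  }
  out <- tibble::tibble(
    participant = df$participant,
    condition = df$condition,
    reps = as.integer(reps_num),
    mass_kg = num_col("mass_kg"),
    distance_m = num_col("distance_m"),
    exo_moment_nm = num_col("exo_moment_nm"),
    excluded = if ("excluded" %in% names(df)) isTRUE_vec(df$excluded) else FALSE
  )
  bad_a <- which(.is_control(out$condition) & out$exo_moment_nm != 0)
  if (length(bad_a) > 0) {
    abort_schema(sprintf("Control set with nonzero exo moment in row %d.",
                         bad_a[1] + 1L))
  }
  out
}

#' Write a lifting-sets CSV
#'
#' Deterministic ordering (participant, then temporal condition order);
#' round-trips losslessly through [read_sets_csv()].
#'
#' @param sets Sets tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sets_csv <- function(sets, path) {
  sets <- sets[order(sets$participant,
                     match(sets$condition, .condition_levels)), , drop = FALSE]
  readr::write_csv(sets, path)
  invisible(path)
}

#' Read a lifting-tasks CSV
#'
#' Expected header: `participant,condition,mass_kg,distance_m,repetitions,
#' period_s,exo_moment_nm`.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of lifting tasks.
#' @export
read_tasks_csv <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("participant", "condition", "mass_kg", "distance_m",
                "repetitions", "period_s", "exo_moment_nm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_schema(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  bad <- which(df$repetitions != round(df$repetitions) | df$repetitions < 0)
  if (length(bad) > 0) {
    abort_schema(sprintf("`repetitions` must be a non-negative integer (row %d).",
                         bad[1]))
  }
  tibble::as_tibble(df)
}

#' Read a band force-displacement CSV
#'
#' Expected header: `displacement_m,force_n[,branch]` with branch labels
#' `loading`/`unloading` sharing displacements.
#'
#' @param path Path to the CSV file.
#' @return A [band_curve()].
#' @export
read_band_curve_csv <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("displacement_m", "force_n") %in% names(df))) {
    abort_schema("Band curve CSV needs columns displacement_m, force_n.")
  }
  if (!"branch" %in% names(df)) {
    return(band_curve(df$displacement_m, df$force_n))
  }
  load <- df[df$branch == "loading", , drop = FALSE]
  unl <- df[df$branch == "unloading", , drop = FALSE]
  if (nrow(unl) == 0) {
    return(band_curve(load$displacement_m, load$force_n))
  }
  if (!isTRUE(all.equal(load$displacement_m, unl$displacement_m))) {
    abort_schema("Loading and unloading branches must share displacements.")
  }
  band_curve(load$displacement_m, load$force_n, unloading_force = unl$force_n)
}

#' Write a band curve CSV
#'
#' @param curve A [band_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "band_curve"))
  df <- tibble::tibble(displacement_m = curve$displacement,
                       force_n = curve$force, branch = "loading")
  if (!is.null(curve$unloading_force)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      displacement_m = curve$displacement,
      force_n = curve$unloading_force, branch = "unloading"))
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Read an exosuit specification config
#'
#' YAML with keys `max_stretch_m`, `l5s1_to_skin_m`, `skin_to_band_m`,
#' `device_mass_kg`, `device_com_distance_m`, `hysteresis_factor`,
#' `timing_factor`, and `band_curve_csv` (path, resolved relative to the
#' config file). Unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return An [exo_spec()].
#' @export
read_exo_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("No such file: %s", path))
  cfg <- yaml::read_yaml(path)
  known <- c("max_stretch_m", "l5s1_to_skin_m", "skin_to_band_m",
             "device_mass_kg", "device_com_distance_m",
             "hysteresis_factor", "timing_factor", "band_curve_csv")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort_config(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  need <- c("max_stretch_m", "l5s1_to_skin_m", "skin_to_band_m", "band_curve_csv")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    abort_config(paste0("Missing config keys: ", paste(missing, collapse = ", ")))
  }
  curve_path <- cfg$band_curve_csv
  if (!file.exists(curve_path)) {
    curve_path <- file.path(dirname(path), cfg$band_curve_csv)
  }
  exo_spec(
    band_curve = read_band_curve_csv(curve_path),
    max_stretch = cfg$max_stretch_m,
    l5s1_to_skin = cfg$l5s1_to_skin_m,
    skin_to_band = cfg$skin_to_band_m,
    device_mass = cfg$device_mass_kg %||% 0,
    device_com_distance = cfg$device_com_distance_m %||% 0,
    hysteresis_factor = cfg$hysteresis_factor %||% 1,
    timing_factor = cfg$timing_factor %||% 1
  )
}

#' Read damage-model parameters from a config
#'
#' YAML with any of the keys `gravity`, `sn_intercept`, `sn_slope`,
#' `moment_to_load_offset`, `moment_to_load_gain`, `power_exponent_C`;
#' omitted keys take the package defaults, unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return A [damage_params()].
#' @export
read_damage_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("No such file: %s", path))
  cfg <- yaml::read_yaml(path)
  known <- c("gravity", "sn_intercept", "sn_slope", "moment_to_load_offset",
             "moment_to_load_gain", "power_exponent_C")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort_config(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(damage_params, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full case-series report
#'
#' End-to-end pipeline: read (or accept) a sets table, analyse every
#' participant, summarise the series, run the default parameter sweeps and
#' breakeven curves, and write everything as CSV under `out_dir`. Outputs are
#' deterministically ordered so re-runs are byte-identical.
#'
#' @param sets A sets tibble, or a path to a sets CSV.
#' @param out_dir Output directory (created if needed).
#' @param params A [damage_params()] object.
#' @param sweep_modes Sweep modes to run.
#' @return Invisibly, a named list of the output file paths.
#' @export
run_report <- function(sets, out_dir, params = damage_params(),
                       sweep_modes = c("repetitions", "weight")) {
  if (is.character(sets)) sets <- read_sets_csv(sets)
  if (nrow(sets) == 0) abort_schema("Empty sets table; nothing to report.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- analyze_case_series(sets, params)
  long <- results |>
    tidyr::pivot_longer(-c("participant", "reversal_reps", "reversal_damage"),
                        names_to = "metric", values_to = "value") |>
    dplyr::arrange(.data$participant, .data$metric)
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_series(results, "pct_reps_vs_mean_controls"),
                  metric = "pct_reps_vs_mean_controls", .before = 1),
    dplyr::mutate(summarize_series(results, "pct_damage_vs_mean_controls"),
                  metric = "pct_damage_vs_mean_controls", .before = 1)
  )

  paths <- list(
    participants = file.path(out_dir, "participants.csv"),
    summary = file.path(out_dir, "summary.csv")
  )
  readr::write_csv(long, paths$participants)
  readr::write_csv(summary, paths$summary)

  mass <- stats::median(sets$mass_kg)
  dist <- stats::median(sets$distance_m)
  for (mode in sweep_modes) {
    grid <- damage_change_grid(mode, nominal_mass = mass, distance = dist,
                               params = params)
    curve <- breakeven_curve(mode, nominal_mass = mass, distance = dist,
                             params = params)
    gp <- file.path(out_dir, sprintf("sweep_%s.csv", mode))
    bp <- file.path(out_dir, sprintf("breakeven_%s.csv", mode))
    readr::write_csv(grid, gp)
    readr::write_csv(curve, bp)
    paths[[paste0("sweep_", mode)]] <- gp
    paths[[paste0("breakeven_", mode)]] <- bp
  }
  invisible(paths)
}
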