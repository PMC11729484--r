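# Endurance and damage-change analytics for single-case lifting designs.
#
# A case series is a table of lifting sets: each row is one participant
# performing one set (condition A* = control without exo, B* = with exo) of
# repeated lifts to failure. The analytics compute percent changes in
# repetitions and in modelled cumulative damage with versus without the exo,
# and — for withdrawal (ABA) designs — whether each participant shows a
# reversal: the effect appears when the exo is donned and disappears when it
# is doffed.

# canonical temporal order of condition labels
.condition_levels <- c("A1", "B", "B1", "A2", "B2", "A3")

.is_control <- function(condition) grepl("^A", condition)

#' Percent change in lifting repetitions
#'
#' `(exo - control) / control * 100`. The headline endurance metric of a
#' lifting-to-failure protocol.
#'
#' @param exo_reps Repetitions completed with the exo.
#' @param control_reps Repetitions completed without the exo (> 0).
#' @return Percent change.
#' @examples
#' percent_change_reps(84, 53) # ~58.5% more lifts with the exo
#' @export
percent_change_reps <- function(exo_reps, control_reps) {
  check_nonneg(exo_reps, "exo_reps")
  if (any(!is.finite(control_reps)) || any(control_reps <= 0)) {
    rlang::abort(
      "Percent change is undefined when the control set has zero lifts.",
      class = c("exofatigue_comparison_error", "exofatigue_domain_error")
    )
  }
  100 * (exo_reps - control_reps) / control_reps
}

# validate and order one participant's sets; returns the tibble with a
# per-set cumulative damage column appended
.prepare_sets <- function(sets, params) {
  required <- c("condition", "reps", "mass_kg", "distance_m", "exo_moment_nm")
  missing <- setdiff(required, names(sets))
  if (length(missing) > 0) {
    abort_schema(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  bad <- !sets$condition %in% .condition_levels
  if (any(bad)) {
    abort_schema(sprintf("Unknown condition label(s): %s",
                         paste(unique(sets$condition[bad]), collapse = ", ")))
  }
  if (any(.is_control(sets$condition) & sets$exo_moment_nm != 0)) {
    abort_schema("Control (A*) sets must have exo_moment_nm = 0.")
  }
  if (!any(.is_control(sets$condition)) ||
      !any(!.is_control(sets$condition))) {
    abort_schema("Each participant needs at least one control (A*) and one exo (B*) set.")
  }
  sets <- sets[order(match(sets$condition, .condition_levels)), , drop = FALSE]
  lm <- load_moment(sets$mass_kg, sets$distance_m, params$gravity)
  em <- effective_moment(lm, sets$exo_moment_nm)
  sets$set_damage <- sets$reps * per_lift_damage(em, params)
  sets
}

#' Analyse one participant's lifting sets
#'
#' Computes the with-vs-without-exo percent changes in repetitions and in
#' modelled cumulative damage for one participant. Comparisons are made
#' against the first control set (A1), against the second control set (A2,
#' withdrawal designs only), and against the mean of all control sets; with
#' several exo sets (e.g., an ABABA design) the exo side of each comparison
#' is the mean over exo sets. Reversal flags — effect present on donning,
#' absent on doffing, judged with strict inequalities — are defined only when
#' an A2 set exists.
#'
#' @param sets Data frame of this participant's sets with columns
#'   `condition` (labels among A1, B/B1, A2, B2, A3), `reps`, `mass_kg`,
#'   `distance_m`, `exo_moment_nm`.
#' @param params A [damage_params()] object.
#' @return A one-row tibble: mean exo/control reps and damage, the percent
#'   changes (`pct_reps_vs_A1`, `pct_reps_vs_A2`, `pct_reps_vs_mean_controls`
#'   and the damage analogues), and logical `reversal_reps`,
#'   `reversal_damage` (NA for AB designs).
#' @examples
#' sets <- tibble::tibble(
#'   condition = c("A1", "B", "A2"), reps = c(14, 18, 13),
#'   mass_kg = 55, distance_m = 0.6, exo_moment_nm = c(0, 35, 0)
#' )
#' analyze_participant(sets)
#' @export
analyze_participant <- function(sets, params = damage_params()) {
  sets <- .prepare_sets(sets, params)
  ctrl <- sets[.is_control(sets$condition), , drop = FALSE]
  exo <- sets[!.is_control(sets$condition), , drop = FALSE]

  reps_A1 <- ctrl$reps[1]
  reps_A2 <- if (nrow(ctrl) >= 2) ctrl$reps[2] else NA_real_
  dmg_A1 <- ctrl$set_damage[1]
  dmg_A2 <- if (nrow(ctrl) >= 2) ctrl$set_damage[2] else NA_real_
  reps_B <- mean(exo$reps)
  dmg_B <- mean(exo$set_damage)

  pct_or_na <- function(f, x, ref) if (is.na(ref)) NA_real_ else f(x, ref)

  has_aba <- nrow(ctrl) >= 2
  reversal_reps <- if (has_aba) {
    exo$reps[1] > reps_A1 && ctrl$reps[2] < exo$reps[1]
  } else NA
  reversal_damage <- if (has_aba) {
    exo$set_damage[1] < dmg_A1 && ctrl$set_damage[2] > exo$set_damage[1]
  } else NA

  tibble::tibble(
    n_control_sets = nrow(ctrl),
    n_exo_sets = nrow(exo),
    reps_exo = reps_B,
    reps_controls = mean(ctrl$reps),
    damage_exo = dmg_B,
    damage_controls = mean(ctrl$set_damage),
    pct_reps_vs_A1 = percent_change_reps(reps_B, reps_A1),
    pct_reps_vs_A2 = pct_or_na(percent_change_reps, reps_B, reps_A2),
    pct_reps_vs_mean_controls = percent_change_reps(reps_B, mean(ctrl$reps)),
    pct_damage_vs_A1 = percent_change_damage(dmg_B, dmg_A1),
    pct_damage_vs_A2 = pct_or_na(percent_change_damage, dmg_B, dmg_A2),
    pct_damage_vs_mean_controls =
      percent_change_damage(dmg_B, mean(ctrl$set_damage)),
    reversal_reps = reversal_reps,
    reversal_damage = reversal_damage
  )
}

#' Analyse a whole case series
#'
#' Applies [analyze_participant()] to every participant in a sets table.
#' Rows with `excluded = TRUE` are dropped before analysis (exclusion reasons
#' are recorded upstream, never inferred here).
#'
#' @param sets Data frame with columns `participant`, `condition`, `reps`,
#'   `mass_kg`, `distance_m`, `exo_moment_nm`, and optionally `excluded`.
#' @param params A [damage_params()] object.
#' @return A tibble with one row per participant, ordered by participant.
#' @export
analyze_case_series <- function(sets, params = damage_params()) {
  if (!"participant" %in% names(sets)) {
    abort_schema("Missing column: participant")
  }
  if (nrow(sets) == 0) abort_schema("Empty sets table.")
  if ("excluded" %in% names(sets)) {
    keep <- !isTRUE_vec(sets$excluded)
    sets <- sets[keep, , drop = FALSE]
    if (nrow(sets) == 0) abort_schema("All rows excluded; nothing to analyse.")
  }
  sets |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(~ analyze_participant(.x, params)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant)
}

# vectorised isTRUE with NA -> FALSE
isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == "true" | x == 1)

#' Reversal counts for a withdrawal design
#'
#' Counts the participants whose repetitions increased on donning the exo and
#' decreased on doffing it (and, for damage, decreased then increased). AB
#' participants, for whom reversal is undefined, are excluded from both the
#' numerator and the denominator.
#'
#' @param results Per-participant tibble from [analyze_case_series()].
#' @return A one-row tibble: `n_aba`, `n_reversal_reps`, `n_reversal_damage`.
#' @export
reversal_counts <- function(results) {
  aba <- results[!is.na(results$reversal_reps), , drop = FALSE]
  tibble::tibble(
    n_aba = nrow(aba),
    n_reversal_reps = sum(aba$reversal_reps),
    n_reversal_damage = sum(aba$reversal_damage)
  )
}

#' Summarise exo effects across a case series
#'
#' For a chosen per-participant percent metric, counts who increased versus
#' decreased, and reports the range and mean — the summary style of a case
#' series, where no inferential statistics are attempted.
#'
#' @param results Per-participant tibble from [analyze_case_series()].
#' @param metric Name of the percent column to summarise (default
#'   `"pct_reps_vs_mean_controls"`).
#' @return A one-row tibble: `n`, `n_increase`, `n_decrease`, `range_low`,
#'   `range_high`, `mean`, and `n_reversal_confirmed` (reps reversal count).
#' @examples
#' sets <- simulate_case_series(generator_config(seed = 1))
#' summarize_series(analyze_case_series(sets))
#' @export
summarize_series <- function(results, metric = "pct_reps_vs_mean_controls") {
  if (nrow(results) == 0) abort_schema("Empty results table.")
  if (!metric %in% names(results)) {
    abort_schema(sprintf("No metric column `%s` in results.", metric))
  }
  x <- results[[metric]]
  x <- x[!is.na(x)]
  if (length(x) == 0) abort_schema("Metric is NA for every participant.")
  rc <- reversal_counts(results)
  tibble::tibble(
    n = length(x),
    n_increase = sum(x > 0),
    n_decrease = sum(x < 0),
    range_low = min(x),
    range_high = max(x),
    mean = mean(x),
    n_reversal_confirmed = rc$n_reversal_reps
  )
}
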