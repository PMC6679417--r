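#' Define the acclimation-study design
#'
#' Encodes the hierarchical structure of a two-group thermal-acclimation sperm
#' study: two acclimation temperatures (cold listed first), a fixed number of
#' males per group, a fixed number of measured normal cells per male, sperm
#' activation at each activation temperature, and a target cell count for the
#' deformity scan. Defaults reproduce the design this package emulates:
#' 8 males per group, 40 measured cells per male, acclimation and activation
#' at 8 and 13 degrees C, and a 100-cell deformity scan target.
#'
#' @param n_males_per_group Number of males in each acclimation group.
#' @param n_cells_per_male Number of normal cells measured per male.
#' @param acclimation_temps Numeric length-2, degrees C, cold first.
#' @param activation_temps Numeric, degrees C, the temperatures at which
#'   sperm are activated for speed measurement (crossed with acclimation).
#' @param target_scan_count Deformity-scan stopping target (cells).
#' @param cells_per_field_mean Mean cells per microscope field of view in the
#'   deformity scan (per-field counts are Poisson with this mean, min 1).
#' @param excluded_per_field_mean Mean number of indiscernible sperm
#'   aggregations per field; these are recorded but never counted.
#'
#' @return A list with class `"study_design"`.
#' @export
#' @examples
#' study_design()
study_design <- function(n_males_per_group = 8,
                         n_cells_per_male = 40,
                         acclimation_temps = c(8, 13),
                         activation_temps = c(8, 13),
                         target_scan_count = 100,
                         cells_per_field_mean = 25,
                         excluded_per_field_mean = 1) {
  design <- list(
    n_males_per_group = n_males_per_group,
    n_cells_per_male = n_cells_per_male,
    acclimation_temps = acclimation_temps,
    activation_temps = activation_temps,
    target_scan_count = target_scan_count,
    cells_per_field_mean = cells_per_field_mean,
    excluded_per_field_mean = excluded_per_field_mean
  )
  class(design) <- "study_design"
  validate_design(design)
  design
}

validate_design <- function(design) {
  count_fields <- c("n_males_per_group", "n_cells_per_male", "target_scan_count")
  for (f in count_fields) {
    v <- design[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v)) {
      abort(sprintf("`%s` must be a single integer >= 1 (got %s).", f, deparse(v)))
    }
  }
  if (length(design$acclimation_temps) != 2) {
    abort("`acclimation_temps` must have exactly two entries (cold, warm).")
  }
  if (design$acclimation_temps[1] >= design$acclimation_temps[2]) {
    abort("`acclimation_temps` must list the cold group before the warm group.")
  }
  if (length(design$activation_temps) < 1) {
    abort("`activation_temps` must be non-empty.")
  }
  if (design$cells_per_field_mean <= 0) {
    abort("`cells_per_field_mean` must be positive.")
  }
  if (design$excluded_per_field_mean < 0) {
    abort("`excluded_per_field_mean` must be non-negative.")
  }
  invisible(design)
}

#' Configure the generative effects for synthetic sperm data
#'
#' Parameters of the lognormal cell-size model used by [simulate_study()].
#' Head length, flagellum length and the head width-to-length fraction are
#' lognormal at the cell level; a shared per-male size factor (normal on the
#' log scale) induces intra-male correlation across all linear dimensions.
#' Group multipliers scale the warm group's head dimensions and flagellum
#' length (1 = null). Deformity-category probabilities govern the scan
#' generator; average-path-velocity (VAP) means and SDs are per activation
#' temperature and apply at the male level.
#'
#' Defaults describe a null study (no group effects) with salmonid-scale
#' dimensions: head about 3 x 2 um, flagellum about 32 um, roughly 30% of
#' scanned cells deformed.
#'
#' @param head_length_um Baseline mean head length, um.
#' @param head_width_fraction Mean head width as a fraction of head length
#'   (must be < 1: heads are prolate).
#' @param flagellum_length_um Baseline mean flagellum length, um.
#' @param cv_head,cv_width_fraction,cv_flagellum Cell-level coefficients of
#'   variation (lognormal sigma on the log scale, approximately).
#' @param sd_male_log Between-male SD of the shared size factor (log scale).
#' @param head_multiplier_warm Multiplier on warm-group head length (and so
#'   width); 1 = no group effect.
#' @param flagellum_multiplier_warm Multiplier on warm-group flagellum length.
#' @param deformity_probs Named numeric: probabilities for kink, coil, short,
#'   tailless. Each in [0, 1], sum < 1; remainder is "normal".
#' @param vap_mean_um_s Named numeric, mean VAP (um/s) per activation
#'   temperature; names are temperatures in degrees C.
#' @param vap_sd_um_s Between-male SD of VAP (um/s), shared across
#'   temperatures.
#' @param vap_multiplier_warm Optional multiplier on warm-group VAP means.
#'
#' @return A list with class `"effect_config"`.
#' @seealso [scenario_effects()] for named presets.
#' @export
effect_config <- function(head_length_um = 3.0,
                          head_width_fraction = 0.65,
                          flagellum_length_um = 32,
                          cv_head = 0.10,
                          cv_width_fraction = 0.05,
                          cv_flagellum = 0.08,
                          sd_male_log = 0.05,
                          head_multiplier_warm = 1.0,
                          flagellum_multiplier_warm = 1.0,
                          deformity_probs = c(kink = 0.12, coil = 0.08,
                                              short = 0.05, tailless = 0.05),
                          vap_mean_um_s = c("8" = 80, "13" = 90),
                          vap_sd_um_s = 12,
                          vap_multiplier_warm = 1.0) {
  effects <- list(
    head_length_um = head_length_um,
    head_width_fraction = head_width_fraction,
    flagellum_length_um = flagellum_length_um,
    cv_head = cv_head,
    cv_width_fraction = cv_width_fraction,
    cv_flagellum = cv_flagellum,
    sd_male_log = sd_male_log,
    head_multiplier_warm = head_multiplier_warm,
    flagellum_multiplier_warm = flagellum_multiplier_warm,
    deformity_probs = deformity_probs,
    vap_mean_um_s = vap_mean_um_s,
    vap_sd_um_s = vap_sd_um_s,
    vap_multiplier_warm = vap_multiplier_warm
  )
  class(effects) <- "effect_config"
  validate_effects(effects)
  effects
}

validate_effects <- function(effects) {
  positive <- c("head_length_um", "head_width_fraction", "flagellum_length_um",
                "cv_head", "cv_width_fraction", "cv_flagellum",
                "head_multiplier_warm", "flagellum_multiplier_warm",
                "vap_sd_um_s", "vap_multiplier_warm")
  for (f in positive) {
    v <- effects[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", f))
    }
  }
  if (effects$head_width_fraction >= 1) {
    abort("`head_width_fraction` must be < 1: heads are prolate (width < length).")
  }
  if (!is.numeric(effects$sd_male_log) || effects$sd_male_log < 0) {
    abort("`sd_male_log` must be a non-negative number.")
  }
  p <- effects$deformity_probs
  wanted <- setdiff(DEFORMITY_CATEGORIES, "normal")
  if (!is.numeric(p) || is.null(names(p)) || !setequal(names(p), wanted)) {
    abort("`deformity_probs` must be named numeric with entries kink, coil, short, tailless.")
  }
  if (any(p < 0) || any(p > 1) || sum(p) >= 1) {
    abort("`deformity_probs` entries must lie in [0, 1] and sum to < 1.")
  }
  v <- effects$vap_mean_um_s
  if (!is.numeric(v) || is.null(names(v)) || any(v <= 0)) {
    abort("`vap_mean_um_s` must be a positive named numeric (names = activation temps, degrees C).")
  }
  invisible(effects)
}

#' Named effect-configuration presets
#'
#' * `"null"`: no group effects anywhere (both multipliers 1).
#' * `"warm_head_reduction"`: warm-group head dimensions scaled by 0.95 with
#'   flagellum length and swimming speeds unchanged. Because head surface
#'   area scales as the square of the linear head multiplier, this yields a
#'   roughly 10% higher flagellum-to-head-surface-area ratio in the warm
#'   group while keeping absolute flagellum and total lengths identical in
#'   expectation - the pattern where relative, not absolute, dimensions
#'   respond to acclimation.
#'
#' @param scenario One of `"null"`, `"warm_head_reduction"`.
#' @param ... Overrides forwarded to [effect_config()].
#' @return An `"effect_config"` object.
#' @export
scenario_effects <- function(scenario = c("null", "warm_head_reduction"), ...) {
  scenario <- match.arg(scenario)
  args <- switch(scenario,
    null = list(),
    warm_head_reduction = list(head_multiplier_warm = 0.95)
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(effect_config, args)
}
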