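#' Simulate a complete two-group acclimation sperm study
#'
#' Draws a full synthetic dataset with the hierarchical structure of a
#' thermal-acclimation sperm-morphology study: two acclimation groups of
#' males, a shared per-male size factor on the log scale, lognormal per-cell
#' head length, head width (generated as a fraction < 1 of head length, so
#' every cell satisfies the prolate precondition) and flagellum length, a
#' deformity field-of-view scan per male, and one average path velocity (VAP)
#' per male per activation temperature.
#'
#' The generator is fully deterministic given `(design, effects, seed)`; the
#' global RNG state is left untouched.
#'
#' @param design A [study_design()].
#' @param effects An [effect_config()].
#' @param seed Integer seed.
#'
#' @return A list with class `"sperm_study"`:
#' \describe{
#'   \item{cells}{tibble of measured normal cells: `male_id`, `group`,
#'     `cell_id`, `L_H_um`, `W_H_um`, `L_F_um`, `category`.}
#'   \item{males}{tibble of male metadata: `male_id`, `group`, one
#'     `vap_um_per_s_at_<T>C` column per activation temperature.}
#'   \item{fields}{tibble of deformity-scan fields of view: `male_id`,
#'     `field_idx`, per-category counts, `excluded`.}
#'   \item{design, effects, seed}{the inputs, recorded for provenance.}
#' }
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' nrow(study$cells)  # 2 groups x 8 males x 40 cells = 640
simulate_study <- function(design = study_design(),
                           effects = effect_config(),
                           seed = 1) {
  validate_design(design)
  validate_effects(effects)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  missing_temp <- setdiff(as.character(design$activation_temps),
                          names(effects$vap_mean_um_s))
  if (length(missing_temp) > 0) {
    abort(sprintf(
      "`effects$vap_mean_um_s` has no entry for activation temperature(s): %s.",
      paste(missing_temp, collapse = ", ")
    ))
  }

  withr::with_seed(as.integer(seed), {
    n_g <- design$n_males_per_group
    n_c <- design$n_cells_per_male
    male_ids <- c(sprintf("C%02d", seq_len(n_g)), sprintf("W%02d", seq_len(n_g)))
    male_group <- rep(c("cold", "warm"), each = n_g)
    warm <- male_group == "warm"

    # per-male shared size factor, then all cells in one vectorised block
    b <- rnorm(length(male_ids), 0, effects$sd_male_log)
    cell_male <- rep(seq_along(male_ids), each = n_c)
    raw <- draw_cells(
      n = length(cell_male), effects = effects,
      male_log_effect = b[cell_male], warm = warm[cell_male]
    )
    cells <- tibble(
      male_id = male_ids[cell_male],
      group = male_group[cell_male],
      cell_id = sprintf("%s_c%03d", male_ids[cell_male],
                        rep(seq_len(n_c), times = length(male_ids))),
      L_H_um = raw$L_H_um, W_H_um = raw$W_H_um, L_F_um = raw$L_F_um,
      category = "normal"
    )

    mult <- ifelse(warm, effects$vap_multiplier_warm, 1)
    vap_means <- effects$vap_mean_um_s[as.character(design$activation_temps)]
    vap <- outer(mult, vap_means) +
      matrix(rnorm(length(male_ids) * length(design$activation_temps),
                   0, effects$vap_sd_um_s), nrow = length(male_ids))
    if (any(vap <= 0)) {
      abort("Generated a non-positive VAP; check `vap_mean_um_s` / `vap_sd_um_s`.")
    }
    males <- tibble(male_id = male_ids, group = male_group)
    for (j in seq_along(design$activation_temps)) {
      males[[sprintf("vap_um_per_s_at_%gC", design$activation_temps[j])]] <-
        vap[, j]
    }

    fields_list <- lapply(seq_along(male_ids), function(i) {
      f <- draw_field_scan(
        target = design$target_scan_count,
        cells_per_field_mean = design$cells_per_field_mean,
        excluded_per_field_mean = design$excluded_per_field_mean,
        deformity_probs = effects$deformity_probs
      )
      f$male_id <- male_ids[i]
      select(f, "male_id", dplyr::everything())
    })

    study <- list(
      cells = cells,
      males = males,
      fields = bind_rows(fields_list),
      design = design,
      effects = effects,
      seed = as.integer(seed)
    )
    class(study) <- "sperm_study"
    study
  })
}

# lognormal draws parameterised by arithmetic mean and CV, so that the
# configured means are the true expectations (sdlog = sqrt(log(1 + cv^2)))
rlnorm_mean_cv <- function(n, mean, cv, extra_log_shift = 0) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  exp(rnorm(n, meanlog + extra_log_shift, sdlog))
}

draw_cells <- function(n, effects, male_log_effect, warm) {
  h_mult <- ifelse(warm, effects$head_multiplier_warm, 1)
  f_mult <- ifelse(warm, effects$flagellum_multiplier_warm, 1)

  L_H <- rlnorm_mean_cv(n, effects$head_length_um * h_mult, effects$cv_head,
                        extra_log_shift = male_log_effect)
  frac <- rlnorm_mean_cv(n, effects$head_width_fraction, effects$cv_width_fraction)
  # heads must stay prolate: resample the rare fraction draws that reach 0.99
  while (any(bad <- frac >= 0.99)) {
    frac[bad] <- rlnorm_mean_cv(sum(bad), effects$head_width_fraction,
                                effects$cv_width_fraction)
  }
  L_F <- rlnorm_mean_cv(n, effects$flagellum_length_um * f_mult,
                        effects$cv_flagellum,
                        extra_log_shift = male_log_effect)
  tibble(L_H_um = L_H, W_H_um = L_H * frac, L_F_um = L_F)
}

draw_field_scan <- function(target, cells_per_field_mean,
                            excluded_per_field_mean, deformity_probs) {
  probs <- c(normal = 1 - sum(deformity_probs),
             deformity_probs[setdiff(DEFORMITY_CATEGORIES, "normal")])
  # draw field sizes in batches until the cumulative count reaches target
  sizes <- integer(0)
  while (sum(sizes) < target) {
    k <- max(4L, ceiling((target - sum(sizes)) / cells_per_field_mean) + 4L)
    sizes <- c(sizes, pmax(1L, rpois(k, cells_per_field_mean)))
  }
  n_fields <- which(cumsum(sizes) >= target)[1]
  sizes <- sizes[seq_len(n_fields)]
  total <- sum(sizes)
  cat_of_cell <- sample.int(5L, total, replace = TRUE, prob = probs)
  field_of_cell <- rep(seq_len(n_fields), times = sizes)
  counts <- matrix(tabulate(field_of_cell + n_fields * (cat_of_cell - 1L),
                            nbins = 5L * n_fields), nrow = n_fields)
  excluded <- rpois(n_fields, excluded_per_field_mean)
  tibble(
    field_idx = seq_len(n_fields),
    normal = counts[, 1], kink = counts[, 2], coil = counts[, 3],
    short = counts[, 4], tailless = counts[, 5],
    excluded = as.integer(excluded)
  )
}

#' Simulate one deformity field-of-view scan
#'
#' Generates a sequence of microscope fields of view, each with per-category
#' cell counts (normal, kink, coil, short, tailless) and a count of excluded
#' indiscernible aggregations, until the cumulative cell count reaches the
#' design's scan target. Deterministic given the seed.
#'
#' @param design A [study_design()]; supplies the target count and per-field
#'   cell-count distribution.
#' @param deformity_probs Named probabilities for kink, coil, short, tailless
#'   (remainder is normal).
#' @param seed Integer seed.
#' @return A tibble with one row per field of view.
#' @export
#' @examples
#' simulate_field_scan(study_design(), seed = 1)
simulate_field_scan <- function(design = study_design(),
                                deformity_probs = effect_config()$deformity_probs,
                                seed = 1) {
  validate_design(design)
  validate_effects(effect_config(deformity_probs = deformity_probs))
  withr::with_seed(as.integer(seed), {
    draw_field_scan(
      target = design$target_scan_count,
      cells_per_field_mean = design$cells_per_field_mean,
      excluded_per_field_mean = design$excluded_per_field_mean,
      deformity_probs = deformity_probs
    )
  })
}

#' @export
print.sperm_study <- function(x, ...) {
  cat(sprintf(
    "<sperm_study> %d males (%d per group), %d measured cells, seed %d\n",
    nrow(x$males), x$design$n_males_per_group, nrow(x$cells), x$seed
  ))
  invisible(x)
}
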