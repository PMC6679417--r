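#' Reference dynamic viscosity of pure water
#'
#' Standard literature values for the dynamic viscosity of pure water at
#' 5 degree-C steps (Korson-consistent values as tabulated in the CRC
#' Handbook), in Pa s. Shipped as a convenience default; every function that
#' consumes a viscosity table accepts a user-supplied one, so no analysis is
#' tied to these numbers.
#'
#' @return A tibble with columns `temp_C` and `mu_Pa_s`, viscosity strictly
#'   decreasing in temperature.
#' @export
#' @examples
#' water_viscosity_table()
water_viscosity_table <- function() {
  tibble(
    temp_C = c(0, 5, 10, 15, 20, 25, 30),
    mu_Pa_s = c(1.7918, 1.5192, 1.3069, 1.1382, 1.0016, 0.8902, 0.7975) * 1e-3
  )
}

validate_viscosity_table <- function(table) {
  check_columns(table, c("temp_C", "mu_Pa_s"), arg = "viscosity table")
  if (nrow(table) < 2) {
    abort("Viscosity table needs at least two entries.")
  }
  if (any(!is.finite(table$mu_Pa_s)) || any(table$mu_Pa_s <= 0)) {
    abort("Viscosities must be positive and finite.")
  }
  table <- arrange(as_tibble(table), .data$temp_C)
  if (any(duplicated(table$temp_C))) {
    abort("Viscosity table has duplicate temperatures.")
  }
  if (any(diff(table$mu_Pa_s) >= 0)) {
    abort("Viscosity must be strictly decreasing in temperature.")
  }
  table
}

#' Look up dynamic viscosity at a temperature
#'
#' Two lookup rules for temperatures between table entries:
#' `"bracket_mean"` (default) returns the plain arithmetic mean of the two
#' entries bracketing the query temperature - the averaging rule used when a
#' study quotes, e.g., the 5 and 10 degree values for an 8 degree bath -
#' while `"linear"` interpolates linearly. Exact table hits return the entry
#' itself under either mode.
#'
#' @param temp_C Query temperature(s), degrees C; must lie within the
#'   table's range.
#' @param table Viscosity table (`temp_C`, `mu_Pa_s`); defaults to
#'   [water_viscosity_table()].
#' @param mode `"bracket_mean"` or `"linear"`.
#' @return Dynamic viscosity in Pa s. Vectorised over `temp_C`.
#' @export
#' @examples
#' viscosity_at(8)                     # mean of the 5 and 10 degree entries
#' viscosity_at(8, mode = "linear")
viscosity_at <- function(temp_C, table = water_viscosity_table(),
                         mode = c("bracket_mean", "linear")) {
  mode <- match.arg(mode)
  table <- validate_viscosity_table(table)
  if (any(!is.finite(temp_C))) {
    abort("`temp_C` must be finite.")
  }
  rng <- range(table$temp_C)
  if (any(temp_C < rng[1] | temp_C > rng[2])) {
    abort(sprintf(
      "Temperature outside viscosity table range [%g, %g] degrees C.",
      rng[1], rng[2]
    ))
  }
  vapply(temp_C, function(t) {
    hit <- which(table$temp_C == t)
    if (length(hit) == 1) {
      return(table$mu_Pa_s[hit])
    }
    lo <- max(which(table$temp_C < t))
    hi <- min(which(table$temp_C > t))
    if (mode == "bracket_mean") {
      mean(table$mu_Pa_s[c(lo, hi)])
    } else {
      w <- (t - table$temp_C[lo]) / (table$temp_C[hi] - table$temp_C[lo])
      (1 - w) * table$mu_Pa_s[lo] + w * table$mu_Pa_s[hi]
    }
  }, numeric(1))
}

#' Stokes-law drag force
#'
#' Creeping-flow drag on a small sphere: `D = 6 * pi * mu * a * U`.
#' Appropriate for sperm heads, which move at very low Reynolds numbers.
#'
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @param a Sphere radius, m (> 0).
#' @param U Flow speed relative to the sphere, m/s (>= 0).
#' @return Drag force in Newtons. Vectorised; linear in each argument and
#'   zero exactly when `U` is zero.
#' @export
#' @examples
#' stokes_drag(1e-3, 1e-6, 1e-4)  # 6*pi*1e-13 N, about 1.885 pN
stokes_drag <- function(mu, a, U) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    abort("`mu` must be positive and finite.")
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    abort("`a` must be positive and finite.")
  }
  if (any(!is.finite(U)) || any(U < 0)) {
    abort("`U` must be non-negative and finite.")
  }
  6 * pi * mu * a * U
}

#' Per-cell theoretical drag at each activation temperature
#'
#' Builds the full drag table: one record per measured cell per activation
#' temperature. The head radius is half the cell's own head width
#' (`a = 0.5 * W_H`, converted um to m); the speed is the owning male's VAP
#' at that activation temperature (um/s to m/s); viscosity comes from the
#' lookup rule at that temperature. Drag is reported in pN.
#'
#' @param cells Tibble of measured cells (`male_id`, `cell_id`, `W_H_um`).
#' @param males Tibble with `male_id` and one `vap_um_per_s_at_<T>C` column
#'   per activation temperature (the `males` element of a
#'   [simulate_study()] result).
#' @param table Viscosity table; defaults to [water_viscosity_table()].
#' @param activation_temps Activation temperatures, degrees C.
#' @param mode Viscosity lookup mode, see [viscosity_at()].
#' @return A tibble with one row per (cell, activation temperature):
#'   `male_id`, `cell_id`, `activation_temp_C`, `a_m`, `U_m_per_s`,
#'   `mu_Pa_s`, `D_pN`. Row count is `nrow(cells) * length(activation_temps)`.
#' @export
drag_table <- function(cells, males, table = water_viscosity_table(),
                       activation_temps = c(8, 13),
                       mode = c("bracket_mean", "linear")) {
  mode <- match.arg(mode)
  check_columns(cells, c("male_id", "cell_id", "W_H_um"))
  check_columns(males, "male_id")
  if (length(activation_temps) < 1) {
    abort("`activation_temps` must be non-empty.")
  }
  vap_cols <- sprintf("vap_um_per_s_at_%gC", activation_temps)
  missing_cols <- setdiff(vap_cols, names(males))
  if (length(missing_cols) > 0) {
    abort(sprintf("`males` is missing VAP column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  vap_long <- males %>%
    select("male_id", all_of(vap_cols)) %>%
    tidyr::pivot_longer(all_of(vap_cols), names_to = "col",
                        values_to = "vap_um_per_s") %>%
    mutate(activation_temp_C = activation_temps[match(.data$col, vap_cols)]) %>%
    select(-"col")
  incomplete <- vap_long %>% filter(is.na(.data$vap_um_per_s))
  if (nrow(incomplete) > 0) {
    abort(sprintf(
      "Missing VAP for male %s at %g degrees C.",
      incomplete$male_id[1], incomplete$activation_temp_C[1]
    ))
  }
  orphan <- setdiff(cells$male_id, males$male_id)
  if (length(orphan) > 0) {
    abort(sprintf("Cells reference male(s) absent from `males`: %s.",
                  paste(orphan, collapse = ", ")))
  }
  mu_by_temp <- viscosity_at(activation_temps, table, mode)
  n_cells <- nrow(cells)
  n_temps <- length(activation_temps)
  idx <- rep(seq_len(n_cells), each = n_temps)
  t_idx <- rep(seq_len(n_temps), times = n_cells)
  vap_mat <- as.matrix(males[, vap_cols, drop = FALSE])
  m_idx <- match(cells$male_id[idx], males$male_id)
  out <- tibble(
    male_id = cells$male_id[idx],
    cell_id = cells$cell_id[idx],
    activation_temp_C = activation_temps[t_idx],
    a_m = 0.5 * cells$W_H_um[idx] * 1e-6,
    U_m_per_s = vap_mat[cbind(m_idx, t_idx)] * 1e-6,
    mu_Pa_s = mu_by_temp[t_idx]
  )
  out$D_pN <- stokes_drag(out$mu_Pa_s, out$a_m, out$U_m_per_s) * 1e12
  arrange(out, .data$male_id, .data$cell_id, .data$activation_temp_C)
}

#' Per-male mean drag at each activation temperature
#'
#' Averages per-cell drag over each male's measured cells within each
#' activation temperature, the per-male summary used for the drag model.
#'
#' @param drag A tibble from [drag_table()].
#' @param males Optional males tibble supplying a `group` column to carry
#'   through.
#' @return One row per male x activation temperature: `n_cells`,
#'   `mean_D_pN`.
#' @export
summarize_drag <- function(drag, males = NULL) {
  check_columns(drag, c("male_id", "activation_temp_C", "D_pN"))
  if (nrow(drag) == 0) {
    abort("Empty drag table.")
  }
  out <- drag %>%
    group_by(.data$male_id, .data$activation_temp_C) %>%
    summarise(n_cells = dplyr::n(), mean_D_pN = mean(.data$D_pN),
              .groups = "drop")
  if (!is.null(males) && "group" %in% names(males)) {
    out <- out %>%
      left_join(select(males, "male_id", "group"), by = "male_id") %>%
      select("male_id", "group", dplyr::everything())
  }
  out
}
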