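#' Ellipticity of a prolate spheroid
#'
#' Eccentricity of the meridional ellipse of a prolate spheroid with
#' equatorial radius `r_e` and polar radius `r_p`:
#' `e = sqrt(1 - r_e^2 / r_p^2)`, equivalently focal distance over polar
#' radius. Zero for a sphere, approaching 1 as the spheroid elongates.
#'
#' @param r_e Equatorial radius (> 0), same units as `r_p`.
#' @param r_p Polar radius; must satisfy `r_p >= r_e` (prolate).
#' @return Dimensionless ellipticity in `[0, 1)`. Vectorised.
#' @export
#' @examples
#' ellipticity(1, 2)  # sqrt(3)/2
ellipticity <- function(r_e, r_p) {
  if (any(!is.finite(r_e)) || any(!is.finite(r_p)) ||
      any(r_e <= 0) || any(r_p <= 0)) {
    abort("Radii must be positive and finite.")
  }
  if (any(r_e > r_p)) {
    abort("Equatorial radius exceeds polar radius: head wider than long violates the prolate assumption.")
  }
  sqrt(pmax(0, 1 - (r_e / r_p)^2))
}

#' Surface area of a prolate-spheroid sperm head
#'
#' Closed-form surface area of a prolate spheroid with polar axis along the
#' head length: with `r_e = W_H / 2`, `r_p = L_H / 2` and ellipticity
#' `e = sqrt(1 - r_e^2/r_p^2)`,
#' `A = 2 * pi * r_e^2 + 2 * pi * r_e * r_p * asin(e) / e`.
#' At the sphere limit (`e < 1e-9`) the formula degenerates to 0/0 and the
#' exact sphere value `4 * pi * r_e^2` is returned instead; the closed form
#' is continuous across the switch.
#'
#' @param L_H Head length (polar axis), um.
#' @param W_H Head width (equatorial axis), um; must satisfy
#'   `0 < W_H <= L_H`.
#' @return Surface area in um^2 (units follow the inputs squared). Vectorised.
#' @export
#' @examples
#' head_surface_area(2, 2)  # sphere of radius 1: 4*pi
#' head_surface_area(4, 2)  # approx 21.48
head_surface_area <- function(L_H, W_H) {
  if (any(!is.finite(L_H)) || any(!is.finite(W_H)) ||
      any(L_H <= 0) || any(W_H <= 0)) {
    abort("Head dimensions must be positive and finite.")
  }
  if (any(W_H > L_H)) {
    abort("Head width exceeds head length: head wider than long violates the prolate assumption.")
  }
  r_e <- W_H / 2
  r_p <- L_H / 2
  e <- sqrt(pmax(0, 1 - (r_e / r_p)^2))
  sphere <- e < 1e-9
  out <- numeric(length(e))
  out[sphere] <- 4 * pi * r_e[sphere]^2
  if (any(!sphere)) {
    es <- e[!sphere]
    out[!sphere] <- 2 * pi * r_e[!sphere]^2 +
      2 * pi * r_e[!sphere] * r_p[!sphere] * asin(es) / es
  }
  out
}

#' Derive per-cell morphometric quantities
#'
#' Appends the derived morphometry columns to a table of measured cells:
#' ellipticity `e`, head surface area `A_H_um2`, total length
#' `L_T_um = L_H + L_F`, flagellum-to-head-length ratio `ratio_LF_LH`
#' (dimensionless) and flagellum-to-head-surface-area ratio
#' `ratio_LF_AH_per_um` (1/um). Derivations are defined only for cells of
#' category `"normal"`: deformed cells were never measured in the protocol
#' this mirrors, so their presence is an error by default.
#'
#' @param cells Data frame with columns `L_H_um`, `W_H_um`, `L_F_um` and
#'   (optionally) `category`.
#' @param deformed How to treat rows whose category is not `"normal"`:
#'   `"error"` (default) or `"drop"`.
#' @return A tibble: the input rows (normal cells only if `deformed =
#'   "drop"`) with derived columns appended.
#' @seealso [validate_prolate()] for a strict-validation report of cells
#'   violating the prolate assumption.
#' @export
#' @examples
#' derive_cells(tibble::tibble(L_H_um = 4, W_H_um = 2, L_F_um = 30))
derive_cells <- function(cells, deformed = c("error", "drop")) {
  deformed <- match.arg(deformed)
  check_columns(cells, c("L_H_um", "W_H_um", "L_F_um"))
  cells <- as_tibble(cells)
  if ("category" %in% names(cells)) {
    bad <- cells$category != "normal"
    if (any(bad)) {
      if (deformed == "error") {
        abort(sprintf(
          "Morphometric derivation is only defined for normal cells; found %d deformed cell(s) (categories: %s).",
          sum(bad), paste(unique(cells$category[bad]), collapse = ", ")
        ))
      }
      cells <- cells[!bad, , drop = FALSE]
    }
  }
  if (nrow(cells) == 0) {
    abort("No normal cells to derive.")
  }
  violations <- validate_prolate(cells)
  if (nrow(violations) > 0) {
    abort(sprintf(
      "%d cell(s) have head width > head length (prolate violation); first offending row: %d. Use validate_prolate() to list them.",
      nrow(violations), violations$row[1]
    ))
  }
  cells %>%
    mutate(
      L_T_um = .data$L_H_um + .data$L_F_um,
      e = ellipticity(.data$W_H_um / 2, .data$L_H_um / 2),
      A_H_um2 = head_surface_area(.data$L_H_um, .data$W_H_um),
      ratio_LF_LH = .data$L_F_um / .data$L_H_um,
      ratio_LF_AH_per_um = .data$L_F_um / .data$A_H_um2
    )
}

#' Report cells violating the prolate-head assumption
#'
#' Lists rows whose head width exceeds head length, or with non-positive
#' measurements. These cells cannot be assigned an ellipticity or surface
#' area; they are reported rather than silently axis-swapped.
#'
#' @param cells Data frame with `L_H_um`, `W_H_um` columns.
#' @return A tibble of offending rows with a `row` index column and a
#'   `reason` column; zero rows if all cells are valid.
#' @export
validate_prolate <- function(cells) {
  check_columns(cells, c("L_H_um", "W_H_um"))
  cells <- as_tibble(cells)
  reason <- dplyr::case_when(
    !is.finite(cells$L_H_um) | !is.finite(cells$W_H_um) |
      cells$L_H_um <= 0 | cells$W_H_um <= 0 ~ "non-positive or missing dimension",
    cells$W_H_um > cells$L_H_um ~ "width exceeds length",
    TRUE ~ NA_character_
  )
  out <- cells %>%
    mutate(row = row_number(), reason = reason) %>%
    filter(!is.na(.data$reason))
  select(out, "row", dplyr::everything())
}

#' Per-male means of derived morphometry
#'
#' Averages every measured and derived quantity across a male's measured
#' cells, mirroring an analysis in which only per-male average speeds are
#' available so morphology must be averaged to the same level.
#'
#' @param derived A tibble from [derive_cells()] with a `male_id` column
#'   (and `group`, carried through if present).
#' @return One row per male: `n_cells` plus the mean of each quantity,
#'   columns named `mean_<quantity>`.
#' @export
summarize_males <- function(derived) {
  check_columns(derived, c("male_id", "L_H_um", "W_H_um", "L_F_um",
                           "L_T_um", "e", "A_H_um2", "ratio_LF_LH",
                           "ratio_LF_AH_per_um"))
  if (nrow(derived) == 0) {
    abort("No derived cells to summarise.")
  }
  quantities <- c("L_H_um", "W_H_um", "L_F_um", "L_T_um", "e", "A_H_um2",
                  "ratio_LF_LH", "ratio_LF_AH_per_um")
  keys <- intersect(c("male_id", "group"), names(derived))
  derived %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      n_cells = dplyr::n(),
      across(all_of(quantities), mean, .names = "mean_{.col}"),
      .groups = "drop"
    )
}
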