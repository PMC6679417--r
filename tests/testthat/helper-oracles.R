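# Numerical surface-of-revolution oracle for the prolate-spheroid head:
# rotate the meridional ellipse about the polar axis, parametrised
# z = r_p cos(t), x = r_e sin(t), t in [0, pi]. Independent of the
# closed form used by the package.
area_oracle <- function(L_H, W_H) {
  r_e <- W_H / 2
  r_p <- L_H / 2
  f <- function(t) r_e * sin(t) * sqrt(r_e^2 * cos(t)^2 + r_p^2 * sin(t)^2)
  2 * pi * integrate(f, 0, pi, rel.tol = 1e-13)$value
}

read_csv_meta_for_test <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

# toy viscosity tables for lookup arithmetic (values are not physical)
toy_viscosity <- function() {
  tibble::tibble(temp_C = c(5, 10), mu_Pa_s = c(2.0, 1.0))
}

# a small field-scan table with known per-field sizes and categories
make_fields <- function(sizes, deformed_per_field = 0) {
  n <- length(sizes)
  tibble::tibble(
    field_idx = seq_len(n),
    normal = sizes - deformed_per_field,
    kink = rep(deformed_per_field, n),
    coil = 0L, short = 0L, tailless = 0L,
    excluded = 0L
  )
}

# balanced per-male drag-mean table built from explicit group x temperature
# cell means plus optional per-male offsets (for constructed-recovery tests)
make_drag_means <- function(cell_means, n_per_group = 8, male_offsets = NULL) {
  # cell_means: named list like list(cold_8 = , cold_13 = , warm_8 = , warm_13 = )
  males <- tibble::tibble(
    male_id = c(sprintf("C%02d", 1:n_per_group), sprintf("W%02d", 1:n_per_group)),
    group = rep(c("cold", "warm"), each = n_per_group)
  )
  if (is.null(male_offsets)) {
    male_offsets <- rep(0, nrow(males))
  }
  tidyr::crossing(males, activation_temp_C = c(8, 13)) %>%
    dplyr::mutate(
      mean_D_pN = unlist(cell_means[paste(group, activation_temp_C, sep = "_")]) +
        male_offsets[match(male_id, males$male_id)]
    )
}
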