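test_that("identical deformity proportions give a zero group log-odds", {
  counts <- tibble::tibble(
    male_id = c("C1", "C2", "W1", "W2"),
    group = c("cold", "cold", "warm", "warm"),
    deformed = 30, total_counted = 100
  )
  fit <- compare_deformity(counts)
  t <- tidy(fit)
  expect_equal(t$estimate[t$term == "groupwarm"], 0, tolerance = 1e-10)
})

test_that("the degenerate 2x2 reproduces the contingency-table odds ratio", {
  counts <- tibble::tibble(
    male_id = c("C1", "W1"), group = c("cold", "warm"),
    deformed = c(20, 40), total_counted = c(100, 100)
  )
  fit <- compare_deformity(counts)
  t <- tidy(fit)
  # hand-computed: OR = (40/60) / (20/80) = 8/3
  expect_equal(exp(t$estimate[t$term == "groupwarm"]), 8 / 3,
               tolerance = 1e-8)
})

test_that("complete separation is flagged, not fatal", {
  counts <- tibble::tibble(
    male_id = c("C1", "C2", "W1", "W2"),
    group = c("cold", "cold", "warm", "warm"),
    deformed = c(0, 0, 100, 100), total_counted = 100
  )
  fit <- compare_deformity(counts)
  expect_true("separation" %in% fit$flags)
})

test_that("zero-variance morphology yields a degenerate flag, not an error", {
  cells <- tibble::tibble(
    male_id = rep(c("C1", "C2", "W1", "W2"), each = 2),
    group = rep(c("cold", "cold", "warm", "warm"), each = 2),
    L_H_um = 3, W_H_um = 2, L_F_um = 30
  )
  derived <- derive_cells(cells)
  fit <- compare_morphology(derived, "ratio_LF_AH")
  expect_true("degenerate" %in% fit$flags)
  t <- tidy(fit)
  expect_equal(t$estimate[t$term == "groupwarm"], 0)
  expect_true(glance(fit)$degenerate)
})

test_that("a constructed group shift in the ratio is recovered exactly", {
  # identical cells within each group, no male or residual noise:
  # warm flagella 20% longer, so the identity-scale group effect is exact
  cells <- tibble::tibble(
    male_id = rep(c("C1", "C2", "W1", "W2"), each = 2),
    group = rep(c("cold", "cold", "warm", "warm"), each = 2),
    L_H_um = 3, W_H_um = 2,
    L_F_um = rep(c(30, 30, 36, 36), each = 2)
  )
  derived <- derive_cells(cells)
  fit <- compare_morphology(derived, "ratio_LF_AH")
  t <- tidy(fit)
  A <- head_surface_area(3, 2)
  expect_equal(t$estimate[t$term == "groupwarm"], 6 / A, tolerance = 1e-8)
  # log-scale measures recover the multiplicative shift as log(1.2)
  fit_lf <- compare_morphology(derived, "L_F")
  expect_equal(tidy(fit_lf)$estimate[2], log(1.2), tolerance = 1e-8)
})

test_that("morphology design preconditions are enforced", {
  cells <- tibble::tibble(
    male_id = c("C1", "C1", "W1", "W1"),
    group = c("cold", "cold", "warm", "warm"),
    L_H_um = 3, W_H_um = 2, L_F_um = c(30, 31, 32, 33)
  )
  expect_error(compare_morphology(derive_cells(cells), "L_F"),
               "at least 2 males")
})

test_that("speed regression recovers an exact linear relationship", {
  data <- tibble::tibble(
    male_id = sprintf("m%d", 1:8),
    group = rep(c("cold", "warm"), each = 4),
    mean_ratio_LF_LH = c(10, 11, 12, 13, 14, 15, 16, 17),
    vap = 10 + 2 * c(10, 11, 12, 13, 14, 15, 16, 17)
  )
  fit <- speed_vs_morphology(data, "mean_ratio_LF_LH", "vap",
                             activation_temp_C = 8)
  t <- tidy(fit)
  expect_equal(t$estimate[t$term == "ratio"], 2.0, tolerance = 1e-8)
  expect_equal(t$estimate[t$term == "(Intercept)"], 10.0, tolerance = 1e-8)
  expect_equal(fit$transform, "identity")
  # warm activation default: log response
  fit13 <- speed_vs_morphology(data, "mean_ratio_LF_LH", "vap",
                               activation_temp_C = 13)
  expect_equal(fit13$transform, "log")
})

test_that("a constant morphology predictor is flagged as degenerate", {
  data <- tibble::tibble(
    male_id = sprintf("m%d", 1:8),
    group = rep(c("cold", "warm"), each = 4),
    mean_ratio_LF_LH = 12, vap = rnorm(8, 80, 5)
  )
  fit <- speed_vs_morphology(data, "mean_ratio_LF_LH", "vap")
  expect_true("degenerate" %in% fit$flags)
})

test_that("identical drag everywhere gives zero effects and zero contrasts", {
  dm <- make_drag_means(list(cold_8 = 2, cold_13 = 2, warm_8 = 2, warm_13 = 2))
  fit <- drag_model(dm)
  expect_true("degenerate" %in% fit$flags)
  t <- tidy(fit)
  expect_equal(t$estimate[t$term == "(Intercept)"], 2)
  expect_equal(t$estimate[t$term != "(Intercept)"], rep(0, 3))
  ctr <- activation_contrasts(fit)
  expect_equal(ctr$estimate, c(0, 0))
})

test_that("a pure activation effect is recovered to numerical precision", {
  dm <- make_drag_means(list(cold_8 = 5, cold_13 = 4, warm_8 = 5, warm_13 = 4))
  fit <- drag_model(dm)
  t <- tidy(fit)
  expect_equal(t$estimate[t$term == "activation13C"], -1.0, tolerance = 1e-8)
  expect_equal(t$estimate[t$term == "acclimationwarm:activation13C"], 0,
               tolerance = 1e-8)
  expect_equal(t$estimate[t$term == "acclimationwarm"], 0, tolerance = 1e-8)
})

test_that("a missing design cell is a named data error", {
  dm <- make_drag_means(list(cold_8 = 5, cold_13 = 4, warm_8 = 5, warm_13 = 4))
  expect_error(drag_model(dm[-1, ]), "C01.*8")
})

test_that("balanced-design contrasts equal raw marginal mean differences", {
  set.seed(55)
  dm <- make_drag_means(
    list(cold_8 = 5, cold_13 = 4.4, warm_8 = 4.6, warm_13 = 3.8),
    male_offsets = rnorm(16, 0, 0.3)
  )
  dm$mean_D_pN <- dm$mean_D_pN + rnorm(nrow(dm), 0, 0.2)
  fit <- drag_model(dm)
  ctr <- activation_contrasts(fit)
  raw <- dm %>%
    dplyr::group_by(group, activation_temp_C) %>%
    dplyr::summarise(m = mean(mean_D_pN), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = activation_temp_C, values_from = m) %>%
    dplyr::mutate(diff = `8` - `13`)
  expect_equal(ctr$estimate[ctr$acclimation == "cold"],
               raw$diff[raw$group == "cold"], tolerance = 1e-8)
  expect_equal(ctr$estimate[ctr$acclimation == "warm"],
               raw$diff[raw$group == "warm"], tolerance = 1e-8)
  # within-group contrast df for the 16-male, two-temperature design
  expect_equal(ctr$df, c(14, 14), tolerance = 1e-6)
})

test_that("fits are deterministic given the same input table", {
  study <- simulate_study(seed = 31)
  derived <- derive_cells(study$cells)
  f1 <- compare_morphology(derived, "ratio_LF_AH")
  f2 <- compare_morphology(derived, "ratio_LF_AH")
  expect_identical(tidy(f1), tidy(f2))
})

test_that("tidy and glance honour the uniform result contract", {
  study <- simulate_study(seed = 32)
  ana <- analyze_study(study)
  for (fit in ana$fits) {
    t <- tidy(fit)
    expect_true(all(c("term", "estimate", "std_error", "df", "statistic",
                      "p_value") %in% names(t)))
    p <- t$p_value[!is.na(t$p_value)]
    expect_true(all(p >= 0 & p <= 1))
    g <- glance(fit)
    expect_equal(nrow(g), 1)
  }
  expect_equal(glance(ana$fits$drag)$n_obs, 32L)
})
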