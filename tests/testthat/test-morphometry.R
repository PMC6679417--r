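test_that("ellipticity matches the focal-distance definition", {
  expect_equal(ellipticity(1, 1), 0)
  # foci of the ellipse with semi-axes (1, 2): c = sqrt(3), e = c / r_p
  expect_equal(ellipticity(1, 2), sqrt(3) / 2, tolerance = 1e-12)
  expect_error(ellipticity(2, 1), "prolate")
  expect_error(ellipticity(-1, 1), "positive")
})

test_that("head surface area matches frozen values and the sphere limit", {
  expect_equal(head_surface_area(2, 2), 4 * pi, tolerance = 1e-12)
  # frozen from the numerical surface-of-revolution oracle (helper-oracles.R)
  expect_equal(head_surface_area(4, 2), 21.4784353279, tolerance = 1e-9)
  # continuity at the sphere limit
  expect_equal(head_surface_area(2, 2 - 1e-10), 4 * pi, tolerance = 1e-6)
  expect_error(head_surface_area(2, 4), "prolate")
  expect_error(head_surface_area(0, 0), "positive")
})

test_that("closed form agrees with the integration oracle over wide aspect ratios", {
  set.seed(101)
  aspect <- exp(runif(200, log(1 + 1e-6), log(20)))
  W <- exp(runif(200, log(0.5), log(5)))
  L <- W * aspect
  closed <- head_surface_area(L, W)
  numeric <- vapply(seq_along(L), function(i) area_oracle(L[i], W[i]),
                    numeric(1))
  expect_lt(max(abs(closed - numeric) / numeric), 1e-9)
})

test_that("derived quantities obey the exact arithmetic contracts", {
  sphere <- derive_cells(tibble::tibble(L_H_um = 2, W_H_um = 2, L_F_um = 30))
  expect_equal(sphere$L_T_um, 32)
  expect_equal(sphere$ratio_LF_LH, 15)
  expect_equal(sphere$ratio_LF_AH_per_um, 30 / (4 * pi), tolerance = 1e-12)

  prolate <- derive_cells(tibble::tibble(L_H_um = 4, W_H_um = 2, L_F_um = 30))
  # frozen via the pinned oracle value for A(4, 2)
  expect_equal(prolate$ratio_LF_AH_per_um, 1.396750, tolerance = 1e-6)
  expect_equal(prolate$e, sqrt(3) / 2, tolerance = 1e-12)
})

test_that("deformed cells are rejected from derivation by name", {
  cells <- tibble::tibble(L_H_um = c(3, 3), W_H_um = c(2, 2),
                          L_F_um = c(30, 0),
                          category = c("normal", "tailless"))
  expect_error(derive_cells(cells), "tailless")
  dropped <- derive_cells(cells, deformed = "drop")
  expect_equal(nrow(dropped), 1)
})

test_that("prolate violations are reported, not silently swapped", {
  cells <- tibble::tibble(L_H_um = c(3, 2, 3), W_H_um = c(2, 3, -1),
                          L_F_um = 30)
  report <- validate_prolate(cells)
  expect_equal(report$row, c(2, 3))
  expect_match(report$reason[1], "width exceeds length")
  expect_error(derive_cells(cells), "prolate")
})

test_that("scaling laws hold: e, LF/LH invariant; A ~ s^2; LT ~ s; LF/AH ~ 1/s", {
  set.seed(7)
  for (i in 1:20) {
    W <- runif(1, 0.5, 3)
    L <- W * runif(1, 1.001, 6)
    F <- runif(1, 10, 50)
    s <- runif(1, 0.1, 10)
    base <- derive_cells(tibble::tibble(L_H_um = L, W_H_um = W, L_F_um = F))
    scaled <- derive_cells(tibble::tibble(L_H_um = s * L, W_H_um = s * W,
                                          L_F_um = s * F))
    expect_equal(scaled$e, base$e, tolerance = 1e-10)
    expect_equal(scaled$ratio_LF_LH, base$ratio_LF_LH, tolerance = 1e-10)
    expect_equal(scaled$A_H_um2, s^2 * base$A_H_um2, tolerance = 1e-10)
    expect_equal(scaled$L_T_um, s * base$L_T_um, tolerance = 1e-10)
    expect_equal(scaled$ratio_LF_AH_per_um, base$ratio_LF_AH_per_um / s,
                 tolerance = 1e-10)
  }
})

test_that("area grows with width at fixed length; e grows with elongation", {
  L <- 4
  widths <- seq(0.5, 4, length.out = 50)
  areas <- head_surface_area(rep(L, 50), widths)
  expect_true(all(diff(areas) > 0))
  W <- 2
  lengths <- seq(2, 40, length.out = 50)
  es <- ellipticity(rep(W / 2, 50), lengths / 2)
  expect_true(all(diff(es) > 0))
})

test_that("per-male summaries are plain means with n reported", {
  cells <- tibble::tibble(
    male_id = "m1",
    L_H_um = c(2, 2, 2), W_H_um = c(2, 2, 2), L_F_um = c(10, 20, 30)
  )
  derived <- derive_cells(cells)
  s <- summarize_males(derived)
  expect_equal(s$n_cells, 3)
  expect_equal(s$mean_L_F_um, 20)
  expect_equal(s$mean_ratio_LF_AH_per_um, mean(c(10, 20, 30) / (4 * pi)),
               tolerance = 1e-12)
  expect_error(summarize_males(derived[0, ]), "No derived cells")
})
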