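test_that("viscosity lookup: exact hits, bracket means, linear interpolation", {
  tab <- toy_viscosity()
  expect_equal(viscosity_at(10, tab), 1.0)
  expect_equal(viscosity_at(8, tab, mode = "bracket_mean"), 1.5)
  expect_equal(viscosity_at(8, tab, mode = "linear"), 1.4)
  expect_error(viscosity_at(12, tab), "range")
  expect_error(viscosity_at(8, tab[1, ]), "at least two")
  bad <- tibble::tibble(temp_C = c(5, 10), mu_Pa_s = c(1.0, 2.0))
  expect_error(viscosity_at(8, bad), "decreasing")
})

test_that("the shipped water table is physical and decreasing", {
  tab <- water_viscosity_table()
  expect_true(all(diff(tab$mu_Pa_s) < 0))
  expect_true(all(tab$mu_Pa_s > 0))
  # the two bracket means used at 8 and 13 degrees straddle each other
  expect_gt(viscosity_at(8, tab), viscosity_at(13, tab))
})

test_that("Stokes drag evaluates, vanishes without flow, and is linear", {
  expect_equal(stokes_drag(1e-3, 1e-6, 1e-4), 6 * pi * 1e-13, tolerance = 1e-12)
  expect_identical(stokes_drag(1e-3, 1e-6, 0), 0)
  set.seed(3)
  for (i in 1:10) {
    mu <- runif(1, 1e-4, 1e-2); a <- runif(1, 1e-7, 1e-5); U <- runif(1, 0, 1e-3)
    base <- stokes_drag(mu, a, U)
    expect_equal(stokes_drag(mu, 2 * a, U), 2 * base, tolerance = 1e-12)
    expect_equal(stokes_drag(3 * mu, a, U), 3 * base, tolerance = 1e-12)
    expect_equal(stokes_drag(mu, a, 5 * U), 5 * base, tolerance = 1e-12)
  }
  expect_error(stokes_drag(-1, 1, 1), "positive")
  expect_error(stokes_drag(1, 1, -1), "non-negative")
})

test_that("drag table: one record per cell per activation temperature", {
  study <- simulate_study(seed = 2)
  drag <- drag_table(study$cells, study$males)
  expect_equal(nrow(drag), 640 * 2)
  per_male <- dplyr::count(drag, male_id)
  expect_equal(per_male$n, rep(80, 16))
})

test_that("the unit-conversion chain reproduces hand arithmetic", {
  cells <- tibble::tibble(male_id = "m1", cell_id = "c1", W_H_um = 2)
  males <- tibble::tibble(male_id = "m1", group = "cold",
                          vap_um_per_s_at_8C = 100)
  tab <- tibble::tibble(temp_C = c(5, 10), mu_Pa_s = c(1e-3, 0.9e-3))
  drag <- drag_table(cells, males, tab, activation_temps = 8)
  # a = 1 um = 1e-6 m, U = 1e-4 m/s, mu = 0.95e-3 -> D = 6*pi*0.95e-13 N
  expect_equal(drag$mu_Pa_s, 0.95e-3)
  expect_equal(drag$D_pN, 6 * pi * 0.95e-3 * 1e-6 * 1e-4 * 1e12,
               tolerance = 1e-12)
  # with mu = 1e-3 the drag is the canonical 6*pi*1e-13 N ~ 1.885 pN
  tab1 <- tibble::tibble(temp_C = c(5, 10), mu_Pa_s = c(1.1e-3, 0.9e-3))
  d1 <- drag_table(cells, males, tab1, activation_temps = 8)
  expect_equal(d1$D_pN, 6 * pi * 1e-1, tolerance = 1e-12)
  expect_equal(d1$D_pN, 1.8850, tolerance = 1e-4)
})

test_that("zero speed propagates to zero drag; missing VAP is a named error", {
  cells <- tibble::tibble(male_id = "m1", cell_id = "c1", W_H_um = 2)
  males <- tibble::tibble(male_id = "m1", group = "cold",
                          vap_um_per_s_at_8C = 0, vap_um_per_s_at_13C = 50)
  drag <- drag_table(cells, males, activation_temps = c(8, 13))
  expect_equal(drag$D_pN[drag$activation_temp_C == 8], 0)
  expect_gt(drag$D_pN[drag$activation_temp_C == 13], 0)
  expect_error(drag_table(cells, males, activation_temps = c(8, 18)),
               "vap_um_per_s_at_18C")
  males$vap_um_per_s_at_8C <- NA_real_
  expect_error(drag_table(cells, males, activation_temps = c(8, 13)),
               "m1.*8")
})

test_that("warmer activation means lower drag for every cell at equal speed", {
  study <- simulate_study(seed = 4)
  males <- study$males
  males$vap_um_per_s_at_13C <- males$vap_um_per_s_at_8C  # pin speeds equal
  drag <- drag_table(study$cells, males)
  wide <- tidyr::pivot_wider(drag, id_cols = c(male_id, cell_id),
                             names_from = activation_temp_C,
                             values_from = D_pN, names_prefix = "D")
  expect_true(all(wide$D13 < wide$D8))
})

test_that("per-male mean drag is aggregation-consistent", {
  study <- simulate_study(seed = 6)
  drag <- drag_table(study$cells, study$males)
  means <- summarize_drag(drag, study$males)
  expect_equal(nrow(means), 32)
  sums <- drag %>%
    dplyr::group_by(male_id, activation_temp_C) %>%
    dplyr::summarise(s = sum(D_pN), n = dplyr::n(), .groups = "drop")
  joined <- dplyr::left_join(means, sums, by = c("male_id", "activation_temp_C"))
  expect_equal(joined$mean_D_pN * joined$n, joined$s, tolerance = 1e-12)
  expect_true("group" %in% names(means))
  expect_error(summarize_drag(drag[0, ]), "Empty")
})

test_that("SI and pN-consistent unit paths agree to 1e-12 relative", {
  mu <- 1.31e-3; W_um <- 1.8; U_um <- 75
  si_pN <- stokes_drag(mu, 0.5 * W_um * 1e-6, U_um * 1e-6) * 1e12
  # direct pN-consistent evaluation: pN = 1e12 N, um = 1e-6 m
  direct <- 6 * pi * mu * (0.5 * W_um) * U_um
  expect_equal(si_pN, direct, tolerance = 1e-12)
})
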