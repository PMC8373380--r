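test_that("the uninduced-reference gate has the designed false-positive rate", {
  m <- gal_model(0.0625, 0.0625)
  ref <- simulate_population(m, 2, n_cells = 20000, seed = 1, induced_fraction = 0)
  probe <- simulate_population(m, 2, n_cells = 20000, seed = 2, induced_fraction = 0)
  sp <- split_subpopulations(probe, ref)
  # binomial error on 1% of 20000 cells: 3 sd is about 0.002
  expect_lt(abs(sp$induced_fraction - 0.01), 0.004)
  expect_equal(sp$induced_fraction, mean(sp$induced))
})

test_that("gating recovers fully induced and mixed populations", {
  m <- gal_model(0.0625, 0.0625)
  ref <- simulate_population(m, 2, n_cells = 20000, seed = 1, induced_fraction = 0)
  full <- simulate_population(m, 0, n_cells = 20000, seed = 3, induced_fraction = 1)
  expect_gt(split_subpopulations(full, ref)$induced_fraction, 0.999)
  # known 30/70 mixture with well-separated modes: glucose far below E10
  m2 <- gal_model(1, 0.01)
  mix <- simulate_population(m2, 0.001, n_cells = 20000, seed = 4,
                             induced_fraction = 0.3)
  sp <- split_subpopulations(mix, ref)
  expect_lt(abs(sp$induced_fraction - 0.30), 0.02)
  # the simulator's own labels agree with the gate up to gate error
  expect_lt(abs(sp$induced_fraction - mean(mix$induced)), 0.02)
  expect_error(split_subpopulations(mix, numeric(0)), "non-empty")
  expect_error(split_subpopulations(mix, ref, gate_quantile = 1.2), "gate_quantile")
})

test_that("E10 and F90 are recovered from simulated profiles", {
  m <- gal_model(0.125, 0.0625)
  prof <- simulate_profile(m, n_cells = 20000, seed = 9)
  met <- profile_metrics(prof)
  expect_lt(abs(met$E10 - 0.125) / 0.125, 0.25)
  expect_lt(abs(met$F90 - 0.0625) / 0.0625, 0.25)
  expect_false(met$f90_lower_bound)
  expect_equal(met$max_level_log, -0.5, tolerance = 0.02)
  expect_equal(nrow(met$per_condition), 9)
  expect_equal(met$per_condition$glucose, sort(glucose_titration()))
  # wrapper forms agree with the full extraction
  expect_equal(as.numeric(compute_F90(prof)), met$F90)
  expect_equal(compute_E10(prof), met$E10)
})

test_that("thresholds outside the titration are reported, not invented", {
  # fraction never drops to 0.9 within the grid: F90 is a lower bound at
  # the top of the titration (level kept high so every cell is detected)
  m_hi <- gal_model(50, 50)
  prof_hi <- simulate_profile(m_hi, n_cells = 5000, seed = 10)
  met_hi <- profile_metrics(prof_hi)
  expect_equal(met_hi$F90, 1)
  expect_true(met_hi$f90_lower_bound)
  # fraction never reaches 0.9 anywhere: not reached
  m_lo <- gal_model(0.0625, 1e-4, n_frac = 2.95)
  prof_lo <- simulate_profile(m_lo, n_cells = 5000, seed = 11)
  expect_true(is.na(profile_metrics(prof_lo)$F90))
  # level curve flat at the maximum: E10 never crossed
  m_flat <- gal_model(1e6, 0.0625)
  prof_flat <- simulate_profile(m_flat, n_cells = 5000, seed = 12)
  expect_true(is.na(profile_metrics(prof_flat)$E10))
})

test_that("unimodal profiles get their F90 flagged as a lower bound", {
  m <- gal_model(0.0039, 0.25) # level-suppressed strain
  prof <- simulate_profile(m, n_cells = 20000, seed = 13)
  call <- classify_profile(prof)
  expect_false(call$profile_is_bimodal)
  met <- profile_metrics(prof, modality = call)
  expect_true(met$f90_lower_bound)
  # the measured value indeed underestimates the true threshold
  expect_lt(met$F90, 0.25)
})

test_that("E10 is invariant under a common rescaling of all expression", {
  m <- gal_model(0.125, 0.0625)
  prof <- simulate_profile(m, n_cells = 10000, seed = 14)
  shifted <- prof
  shifted$cells$log_expression <- prof$cells$log_expression + 2
  shifted$uninduced_ref$log_expression <-
    prof$uninduced_ref$log_expression + 2
  shifted$max_induction_ref$log_expression <-
    prof$max_induction_ref$log_expression + 2
  expect_equal(profile_metrics(shifted)$E10, profile_metrics(prof)$E10,
    tolerance = 1e-12
  )
})

test_that("Hill fits round-trip noise-free generated curves", {
  g <- glucose_titration()
  for (n_true in c(1.15, 0.84, 1.50)) {
    m <- gal_model(0.0625, 0.0625, n_level = n_true)
    fit <- fit_hill_coefficient(
      data.frame(glucose = g, response = mean_induced_log_level(g, m)),
      "level"
    )
    expect_true(fit$converged)
    expect_equal(fit$n, n_true, tolerance = 1e-3)
    expect_equal(fit$threshold, 0.0625, tolerance = 1e-3)
  }
  for (n_true in c(0.75, 1.69, 2.95)) {
    m <- gal_model(0.0625, 0.0625, n_frac = n_true)
    fit <- fit_hill_coefficient(
      data.frame(glucose = g, response = induced_fraction_model(g, m)),
      "fraction"
    )
    expect_true(fit$converged)
    expect_equal(fit$n, n_true, tolerance = 1e-3)
    expect_equal(fit$threshold, 0.0625, tolerance = 1e-3)
  }
  expect_error(
    fit_hill_coefficient(data.frame(glucose = c(1, 0.5), response = c(0.1, 0.9))),
    "at least 4"
  )
})

test_that("analyze_profile returns the one-row strain summary", {
  m <- gal_model(0.25, 0.0625)
  prof <- simulate_profile(m, n_cells = 20000, seed = 15)
  row <- analyze_profile(prof)
  expect_equal(nrow(row), 1)
  expect_identical(row$modality, "bimodal")
  expect_lt(abs(row$E10 - 0.25) / 0.25, 0.3)
  expect_false(row$f90_lower_bound)
})
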