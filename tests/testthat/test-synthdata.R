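test_that("generators are bit-identical under a fixed seed", {
  sc <- small_imaging_scenario(seed = 9)
  expect_identical(generate_image_stack(sc, 5), generate_image_stack(sc, 5))
  cs <- cv_scenario(seed = 9)
  expect_identical(generate_cv_session(cs, 4 * 3600),
                   generate_cv_session(cs, 4 * 3600))
  es <- eis_scenario(seed = 9)
  expect_identical(generate_eis_session(es, 4 * 3600),
                   generate_eis_session(es, 4 * 3600))
  # different seeds differ
  expect_false(identical(
    generate_cv_session(cv_scenario(seed = 1), 2 * 3600),
    generate_cv_session(cv_scenario(seed = 2), 2 * 3600)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(generate_cv_session(cv_scenario(seed = 5), 2 * 3600))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("no-growth imaging scenario renders only the border offset", {
  sc <- small_imaging_scenario(front_arrival_time_s = Inf,
                               scouting_colony_rate = 0, seed = 4)
  st <- generate_image_stack(sc, 5)
  expect_equal(st$ground_truth$fraction_pct, rep(30, 5))
  expect_true(all(st$ground_truth$progress == 0))
})

test_that("image ground truth rises from the offset over the expected span", {
  sc <- small_imaging_scenario(seed = 2)
  st <- generate_image_stack(sc, 15)
  gt <- st$ground_truth
  # monotone non-decreasing fractions; scouting colonies may add a little
  # area ahead of the front but never remove any
  expect_true(all(diff(gt$fraction_pct) >= 0))
  expect_equal(gt$fraction_pct[1], 30, tolerance = 0.5)
  expect_equal(max(gt$fraction_pct), 100, tolerance = 1e-6)
  # traversal spans ceiling(3900/600)+1 frames from first growth to full
  first_growth <- which(gt$progress > 0)[1]
  full <- which(gt$progress >= 1)[1]
  expect_lte(full - first_growth + 1L, ceiling(3900 / 600) + 1L)
})

test_that("noiseless CV sweeps satisfy the waveform closed forms", {
  sc <- cv_scenario(stray_noise_sd = 0, colonization_time_s = Inf,
                    peak_jitter_sd = 0)
  ses <- generate_cv_session(sc, 1800)
  sw <- ses$sweeps[[1]]
  fwd <- sw$direction > 0
  shared <- intersect(round(sw$potential[fwd], 9),
                      round(sw$potential[!fwd], 9))
  for (E in shared[c(1, 25, 50)]) {
    i_f <- sw$current[fwd][round(sw$potential[fwd], 9) == E]
    i_r <- sw$current[!fwd][round(sw$potential[!fwd], 9) == E]
    expect_equal(i_f - i_r, 2 * sc$baseline_capacitive_current,
                 tolerance = 1e-12)
  }
  # control: no peak component anywhere (currents are box + slope exactly)
  for (sw in ses$sweeps) {
    expect_equal(sw$current,
                 sw$direction * sc$baseline_capacitive_current +
                   sc$baseline_resistive_slope * sw$potential,
                 tolerance = 1e-15)
  }
})

test_that("steady-state CV peak amplification equals the injected ratios", {
  sc <- cv_scenario(stray_noise_sd = 0, peak_jitter_sd = 0,
                    colonization_time_s = 2 * 3600)
  ses <- generate_cv_session(sc, 30 * 3600)
  sw <- ses$sweeps[[length(ses$sweeps)]]  # long after stabilization
  fwd <- sw$direction > 0
  ia <- which.min(abs(sw$potential[fwd] - sc$E_pa))
  base_a <- sc$baseline_capacitive_current +
    sc$baseline_resistive_slope * sc$E_pa
  peak_E <- sw$potential[fwd][ia]
  base_at_grid <- sc$baseline_capacitive_current +
    sc$baseline_resistive_slope * peak_E
  amp <- (sw$current[fwd][ia] - base_at_grid) /
    exp(-(peak_E - sc$E_pa)^2 / (2 * sc$peak_width^2))
  expect_equal(amp / base_a + 1, sc$anodic_change_ratio, tolerance = 1e-3)
  rev_b <- !fwd
  ic <- which.min(abs(sw$potential[rev_b] - sc$E_pc))
  base_c <- -sc$baseline_capacitive_current +
    sc$baseline_resistive_slope * sc$E_pc
  peak_Ec <- sw$potential[rev_b][ic]
  base_cg <- -sc$baseline_capacitive_current +
    sc$baseline_resistive_slope * peak_Ec
  amp_c <- (sw$current[rev_b][ic] - base_cg) /
    exp(-(peak_Ec - sc$E_pc)^2 / (2 * sc$peak_width^2))
  expect_equal(amp_c / base_c + 1, sc$cathodic_change_ratio, tolerance = 1e-3)
})

test_that("noiseless EIS spectra equal the circuit model on the trajectory", {
  sc <- eis_scenario(rel_noise_sd = 0, seed = 6)
  ses <- generate_eis_session(sc, 20 * 3600)
  truth <- ses$ground_truth$params
  for (i in c(1, 10, 20, 30, 40)) {
    p <- circuit_params(truth[i, "R_elec"], truth[i, "C_belec"],
                        truth[i, "R_b"], truth[i, "Q_i"], truth[i, "n_i"])
    expect_equal(ses$spectra[[i]]$Z,
                 simplified_circuit_impedance(p, 2 * pi * sc$frequencies),
                 tolerance = 1e-12)
  }
  # before-regime spectrum: low-frequency |Z| dominates
  expect_gt(Mod(ses$spectra[[1]]$Z[1]), Mod(ses$spectra[[1]]$Z[25]))
})

test_that("scenario validation rejects invalid study conditions", {
  expect_error(cv_scenario(anodic_change_ratio = 0.5), "> 1")
  expect_error(cv_scenario(E_pa = -0.3, E_pc = 0.1), "below")
  expect_error(imaging_scenario(border_offset_fraction = 1.2), "0, 1")
  expect_error(eis_scenario(frequencies = c(500, 100)), "increasing")
  expect_error(eis_scenario(rel_noise_sd = -1), ">= 0")
  expect_error(generate_image_stack(small_imaging_scenario(), 1), ">= 2")
})
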