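test_that("split at the changepoint partitions sweep counts correctly", {
  ses <- generate_cv_session(cv_scenario(colonization_time_s = Inf,
                                         seed = 1), 5 * 3600)
  # 10 timepoints x 3 sweeps; event at the 4th timepoint: 9 before, 21 after
  ev <- ses$sweeps[[10]]$timestamp
  gr <- split_by_changepoint(ses, ev)
  expect_length(gr$before$sweeps, 9L)
  expect_length(gr$after$sweeps, 21L)
  expect_error(split_by_changepoint(ses, ses$sweeps[[1]]$timestamp),
               "non-empty")
  expect_error(split_by_changepoint(ses, 1e9), "non-empty")
})

test_that("per-potential variance follows the closed forms", {
  ses <- generate_cv_session(cv_scenario(stray_noise_sd = 0,
                                         colonization_time_s = Inf,
                                         peak_jitter_sd = 0, seed = 1),
                             2 * 3600)
  v <- per_potential_variance(ses)
  expect_equal(as.numeric(v), rep(0, 201))  # identical sweeps
  # two sweeps differing by a constant c at every point -> c^2 / 2
  s2 <- ses
  s2$sweeps <- ses$sweeps[1:2]
  s2$sweeps[[2]]$current <- s2$sweeps[[2]]$current + 3e-9
  v2 <- per_potential_variance(s2)
  expect_equal(as.numeric(v2), rep((3e-9)^2 / 2, 201), tolerance = 1e-12)
  # mismatched grids are rejected
  s3 <- s2
  s3$sweeps[[2]]$potential <- s3$sweeps[[2]]$potential + 0.001
  expect_error(per_potential_variance(s3), "grid")
})

test_that("colonized sessions put the variance maximum at the anodic peak", {
  sc <- cv_scenario(seed = 14)
  ses <- generate_cv_session(sc, 24 * 3600)
  vp <- cv_variance_series(ses)
  gr <- split_by_changepoint(ses, vp$changepoint$time_s)
  v <- per_potential_variance(gr$after)
  E <- attr(v, "potential")
  expect_lt(abs(E[which.max(v)] - sc$E_pa), sc$peak_width)
})

test_that("primary peak detection flags strict local extrema only", {
  ses <- generate_cv_session(cv_scenario(seed = 3), 3 * 3600)
  grid <- ses$sweeps[[1]]$potential
  mono <- structure(seq_along(grid) * 1e-18, potential = grid,
                    direction = ses$sweeps[[1]]$direction)
  expect_equal(nrow(find_primary_peaks(mono, ses)), 0L)
  bump <- structure(dnorm(grid, 0.14, 0.03), potential = grid,
                    direction = ses$sweeps[[1]]$direction)
  pk <- find_primary_peaks(bump, ses)
  pk_a <- pk[pk$polarity == "anodic", ]
  expect_equal(nrow(pk_a), 1L)
  expect_equal(pk_a$E, 0.14, tolerance = 0.011)
})

test_that("secondary peaks bracket a Gaussian bump and survive a flat line", {
  ses <- generate_cv_session(cv_scenario(seed = 3), 3 * 3600)
  grid <- ses$sweeps[[1]]$potential
  dirs <- ses$sweeps[[1]]$direction
  lin <- structure(1e-12 * (grid + 1), potential = grid, direction = dirs)
  expect_no_error(find_secondary_peaks(lin, ses))  # floor guard exercised
  bump <- structure(dnorm(grid, 0.14, 0.05), potential = grid,
                    direction = dirs)
  sec <- find_secondary_peaks(bump, ses)
  sec_a <- sec[sec$polarity == "anodic", ]
  expect_gt(nrow(sec_a), 0L)
  expect_lt(min(abs(sec_a$E - 0.14)), 0.06)
})

test_that("clustering keeps one representative per potential cluster", {
  cand <- structure(
    data.frame(index = c(65, 66, 67, 30),
               E = c(0.13, 0.14, 0.15, -0.21),
               i = c(1e-9, 5e-9, 2e-9, -4e-9),
               polarity = c("anodic", "anodic", "anodic", "cathodic"),
               tier = "primary", epoch = "after",
               stringsAsFactors = FALSE),
    class = c("peak_set", "data.frame"))
  cl <- cluster_peaks(cand)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$E[cl$polarity == "anodic"], 0.14)  # max |i| member
  expect_true(all(cl$redox_pair))
  # permutation invariance of candidate order
  cl2 <- cluster_peaks(cand[c(4, 2, 1, 3), ])
  expect_equal(cl2[order(cl2$E), ], cl[order(cl$E), ],
               ignore_attr = "row.names")
  # two candidates 0.34 V apart stay separate clusters
  far <- cand[c(1, 4), ]
  expect_equal(nrow(cluster_peaks(far)), 2L)
  empty <- cand[0, ]
  expect_equal(nrow(cluster_peaks(empty)), 0L)
})

test_that("peak change ratios recover the injected amplifications", {
  sc <- cv_scenario(seed = 8)
  ses <- generate_cv_session(sc, 24 * 3600)
  vp <- cv_variance_series(ses)
  gr <- split_by_changepoint(ses, vp$changepoint$time_s)
  pr <- peak_change_ratio(gr$before, gr$after)
  expect_equal(pr$anodic, 8.29, tolerance = 0.1)
  expect_equal(pr$cathodic, 6.07, tolerance = 0.1)
  # scale invariance: multiplying all currents by a constant
  ses2 <- ses
  ses2$sweeps <- lapply(ses$sweeps, function(s) {
    s$current <- s$current * 137
    s
  })
  gr2 <- split_by_changepoint(ses2, vp$changepoint$time_s)
  pr2 <- peak_change_ratio(gr2$before, gr2$after)
  expect_equal(pr2$anodic, pr$anodic, tolerance = 1e-9)
  expect_equal(pr2$cathodic, pr$cathodic, tolerance = 1e-9)
})

test_that("control sessions yield change ratios near one", {
  ses <- generate_cv_session(cv_scenario(colonization_time_s = Inf,
                                         seed = 10), 24 * 3600)
  gr <- split_by_changepoint(ses, 12 * 3600)
  pr <- peak_change_ratio(gr$before, gr$after)
  expect_equal(pr$anodic, 1, tolerance = 0.15)
  expect_equal(pr$cathodic, 1, tolerance = 0.15)
})

test_that("recovered peak potentials sit within one grid step", {
  sc <- cv_scenario(seed = 17)
  ses <- generate_cv_session(sc, 24 * 3600)
  vp <- cv_variance_series(ses)
  gr <- split_by_changepoint(ses, vp$changepoint$time_s)
  pk <- identify_peaks(gr$after, epoch = "after")
  sel <- pk[pk$redox_pair, ]
  Ea <- sel$E[sel$polarity == "anodic"]
  Ec <- sel$E[sel$polarity == "cathodic"]
  expect_lte(abs(Ea - sc$E_pa), 0.005)
  expect_lte(abs(Ec - sc$E_pc), 0.005)
})

test_that("formal potential and Ag/AgCl correction are exact arithmetic", {
  expect_equal(formal_potential(0.09, -0.059), 0.0155)
  expect_equal(formal_potential(0.2, -0.2), 0)
  expect_equal(formal_potential(0.1, 0), 0.05)
  expect_error(formal_potential(-0.1, 0.1), "below")

  ref <- agcl_correction(0.0155)
  expect_equal(ref$correction, 0.2255)
  expect_equal(agcl_correction(0.241)$correction, 0)
  expect_equal(agcl_correction(0)$correction, 0.241)
})

test_that("mean-voltammogram peak statistics recover a reversible couple", {
  # reversible-couple fixture: peak separation 129 mV around 15.5 mV
  sc <- cv_scenario(E_pa = 0.0795, E_pc = -0.0495, seed = 6)
  ses <- generate_cv_session(sc, 24 * 3600)
  vp <- cv_variance_series(ses)
  gr <- split_by_changepoint(ses, vp$changepoint$time_s)
  st <- mean_cv_peak_stats(gr$after)
  expect_true(st$found)
  expect_gt(st$i_pa, 0)
  expect_lt(st$i_pc, 0)
  expect_equal(st$delta_Ep, 0.129, tolerance = 0.011)
  # flat voltammogram: no extrema
  flat <- generate_cv_session(cv_scenario(colonization_time_s = Inf,
                                          stray_noise_sd = 0,
                                          baseline_resistive_slope = 0,
                                          seed = 2), 2 * 3600)
  expect_false(mean_cv_peak_stats(flat)$found)
})
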