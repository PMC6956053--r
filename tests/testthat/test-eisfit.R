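test_that("CPE impedance reduces to a capacitor and matches polar form", {
  expect_equal(cpe_impedance(1, 1, 1), complex(real = 0, imaginary = -1))
  w <- c(10, 1e3, 1e5)
  expect_equal(cpe_impedance(2e-6, 1, w), 1 / (1i * w * 2e-6))
  # polar-arithmetic oracle at the before-event CPE values
  Q <- 31.37848e-9; n <- 0.77428; w0 <- 2 * pi * 200
  z <- cpe_impedance(Q, n, w0)
  expect_equal(Mod(z), 1 / (Q * w0^n), tolerance = 1e-10)
  expect_equal(Arg(z), -n * pi / 2, tolerance = 1e-10)
  expect_error(cpe_impedance(1, 0.5, -1), "omega")
})

test_that("simplified circuit obeys its limit identities", {
  p <- reference_circuit_params("before")
  expect_equal(Re(simplified_circuit_impedance(p, 1e12)), p$R_elec,
               tolerance = 1e-3)
  expect_lt(Mod(simplified_circuit_impedance(p, 1e12)) / p$R_elec, 1.001)
  # low-frequency magnitude exceeds high-frequency magnitude (both regimes)
  for (ep in c("before", "after")) {
    q <- reference_circuit_params(ep)
    expect_gt(Mod(simplified_circuit_impedance(q, 2 * pi * 200)),
              Mod(simplified_circuit_impedance(q, 2 * pi * 50000)))
  }
  # faradaic branch removed -> series RC closed form
  rc <- circuit_params(R_elec = 1e4, C_belec = 1e-9, R_b = 1e12,
                       Q_i = 1e-15, n_i = 0.9)
  w <- 2 * pi * eis_freq_grid()
  expect_equal(simplified_circuit_impedance(rc, w),
               1e4 + 1 / (1i * w * 1e-9), tolerance = 1e-4)
  # Re(Z) is monotone non-increasing in frequency and bounded by R_elec
  for (ep in c("before", "after")) {
    q <- reference_circuit_params(ep)
    re_z <- Re(simplified_circuit_impedance(q, w))
    expect_true(all(diff(re_z) <= 1e-9))
    expect_true(all(re_z >= q$R_elec - 1e-9))
  }
})

test_that("full circuit reduces to the simplified model and its limits", {
  fp <- full_circuit_params(R_ELEC_a = 8e3, R_ELEC_c = 8e3, R_act = 0,
                            R_cct = 0, C_adl = 0, C_cdl = 0, C_elec = 0.5e-9,
                            C_b = 0.419e-9, R_b = 5.71e6, Q_i = 31.37848e-9,
                            n_i = 0.77428)
  sp <- circuit_params(R_elec = 16e3, C_belec = 0.919e-9, R_b = 5.71e6,
                       Q_i = 31.37848e-9, n_i = 0.77428)
  w <- 2 * pi * eis_freq_grid()
  expect_equal(full_circuit_impedance(fp, w),
               simplified_circuit_impedance(sp, w), tolerance = 1e-12)
  fp2 <- full_circuit_params(R_ELEC_a = 5e3, R_ELEC_c = 7e3, R_act = 2e3,
                             R_cct = 3e3, C_adl = 2e-10, C_cdl = 1e-10,
                             C_elec = 1e-9, C_b = 1e-9, R_b = 1e6,
                             Q_i = 5e-8, n_i = 0.8)
  expect_equal(Re(full_circuit_impedance(fp2, 1e13)), 12e3, tolerance = 1e-2)
  expect_true(all(Im(full_circuit_impedance(fp2, w[w > 2 * pi * 1e4])) < 0))
})

test_that("noiseless spectra are recovered to 0.1% from auto-initialization", {
  freq <- eis_freq_grid()
  for (ep in c("before", "after")) {
    p <- reference_circuit_params(ep)
    fit <- fit_circuit(list(frequency = freq,
                            Z = simplified_circuit_impedance(p, 2 * pi * freq)))
    expect_true(fit$converged)
    rel <- abs(unlist(fit$params) - unlist(p)) / unlist(p)
    expect_true(all(rel < 1e-3))
  }
})

test_that("round-trip recovery holds across random parameter draws", {
  freq <- eis_freq_grid()
  set.seed(41)
  for (i in 1:20) {
    p <- circuit_params(R_elec = 10^runif(1, 3.5, 4.5),
                        C_belec = 10^runif(1, -9.3, -8),
                        R_b = 10^runif(1, 5, 6.8),
                        Q_i = 10^runif(1, -7.7, -7),
                        n_i = runif(1, 0.7, 0.9))
    fit <- fit_circuit(list(frequency = freq,
                            Z = simplified_circuit_impedance(p, 2 * pi * freq)))
    rel <- abs(unlist(fit$params) - unlist(p)) / unlist(p)
    expect_true(all(rel < 1e-3),
                label = paste("draw", i, "max rel err", max(rel)))
  }
})

test_that("converged fit residual does not exceed the truth's residual", {
  freq <- eis_freq_grid()
  p <- reference_circuit_params("after")
  Z0 <- simplified_circuit_impedance(p, 2 * pi * freq)
  set.seed(7)
  Z <- Z0 + complex(real = rnorm(25), imaginary = rnorm(25)) *
    0.01 / sqrt(2) * Mod(Z0)
  fit <- fit_circuit(list(frequency = freq, Z = Z))
  w <- 1 / Mod(Z)
  res_truth <- sqrt(sum(Mod((Z0 - Z) * w)^2))
  expect_lte(fit$residual_norm, res_truth + 1e-8)
})

test_that("non-convergence is reported through the flag, not an error", {
  # two frequency points below the precondition raise an error
  expect_error(fit_circuit(list(frequency = c(200, 400), Z = c(1+0i, 1+0i))),
               "at least 5")
  # pathological data (all zero impedance) must not throw
  z <- rep(1e-30 + 0i, 25)
  expect_no_error(fit_circuit(list(frequency = eis_freq_grid(), Z = z)))
})

test_that("per-spectrum variances agree with the brute-force oracle", {
  ses <- generate_eis_session(eis_scenario(seed = 12), 12 * 3600)
  vs <- eis_variance_series(ses)
  mags <- lapply(ses$spectra, function(s) Mod(s$Z))
  expect_equal(vs$impedance$variance$sigma2,
               vapply(mags, bf_variance, numeric(1)), tolerance = 1e-12)
  phs <- lapply(ses$spectra, function(s) Arg(s$Z) * 180 / pi)
  expect_equal(vs$phase$variance$sigma2,
               vapply(phs, bf_variance, numeric(1)), tolerance = 1e-12)
})

test_that("max-change frequency finds the model's largest epoch difference", {
  # identical epochs -> degenerate
  sc0 <- eis_scenario(colonization_time_s = Inf, rel_noise_sd = 0, seed = 1)
  ses0 <- generate_eis_session(sc0, 6 * 3600)
  mc0 <- max_change_frequency(ses0, 3 * 3600 + 1)
  expect_true(mc0$degenerate)

  # noiseless colonization session: compare against the direct model
  # difference of epoch-mean spectra over the grid
  sc <- eis_scenario(rel_noise_sd = 0, seed = 2)
  ses <- generate_eis_session(sc, 20 * 3600)
  ev <- sc$colonization_time_s
  mc <- max_change_frequency(ses, ev)
  ts <- vapply(ses$spectra, function(s) s$timestamp, numeric(1))
  magm <- function(sel) rowMeans(vapply(ses$spectra[sel],
                                        function(s) Mod(s$Z), numeric(25)))
  dmag <- abs(magm(ts < ev) - magm(ts >= ev))
  expect_equal(mc$impedance_hz, sc$frequencies[which.max(dmag)])

  # invariance to row order of the frequency grid inside each spectrum
  shuf <- ses
  perm <- sample(25)
  shuf$spectra <- lapply(ses$spectra, function(s) {
    structure(list(frequency = s$frequency[perm], Z = s$Z[perm],
                   timestamp = s$timestamp), class = "impedance_sample")
  })
  mc2 <- max_change_frequency(shuf, ev)
  expect_equal(mc2$impedance_hz, mc$impedance_hz)
  expect_error(max_change_frequency(ses, -1), "non-empty")
})

test_that("parameter trajectories track the injected regimes", {
  # control at 1% noise: the well-identified elements stay flat
  sc0 <- eis_scenario(colonization_time_s = Inf, seed = 3)
  tr0 <- parameter_trajectory(generate_eis_session(sc0, 10 * 3600),
                              event_time_s = 5 * 3600)
  expect_true(all(tr0$params$converged))
  for (nm in c("R_elec", "C_belec")) {
    v <- tr0$params[[nm]]
    expect_lt(stats::sd(v) / mean(v), 0.05)
  }
  # noiseless colonization session: per-spectrum fits reproduce the injected
  # parameter trajectory (before-epoch CPE parameters are only identifiable
  # without noise, since no faradaic process exists before the event)
  sc <- eis_scenario(seed = 4, rel_noise_sd = 0)
  ses <- generate_eis_session(sc, 25 * 3600)
  tr <- parameter_trajectory(ses, sc$colonization_time_s)
  truth <- ses$ground_truth$params
  rel <- abs(as.matrix(tr$params[, 2:6]) - truth) / truth
  expect_lt(max(rel), 1e-3)
  expect_lt(tr$epoch_means["after", "R_b"], tr$epoch_means["before", "R_b"])
  expect_gt(tr$epoch_means["after", "Q_i"], tr$epoch_means["before", "Q_i"])
})
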