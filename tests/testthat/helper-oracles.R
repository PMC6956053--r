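# Independent oracles and small fixtures shared across tests.

# Brute-force single-changepoint scan: a direct translation of the
# segment-length-weighted log population-variance objective, independent of
# the package implementation.
bf_changepoint <- function(V, floor = 1e-12) {
  n <- length(V)
  pv <- function(x) {
    m <- sum(x) / length(x)
    max(sum((x - m)^2) / length(x), floor)
  }
  best_J <- Inf
  best_k <- NA_integer_
  for (k in 3:(n - 1)) {
    J <- (k - 1) * log(pv(V[1:(k - 1)])) + (n - k + 1) * log(pv(V[k:n]))
    if (J < best_J) {
      best_J <- J
      best_k <- k
    }
  }
  list(k = best_k, J = best_J)
}

# Two-pass unbiased variance by explicit summation.
bf_variance <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  s / (length(x) - 1)
}

# Small imaging scenario for fast unit tests (100 um segment).
small_imaging_scenario <- function(...) {
  imaging_scenario(segment_length_um = 100, ...)
}

# Matched CV + EIS session pair for one experiment class.
generate_experiment_pair <- function(class, seed, duration_s = 35 * 3600) {
  cv_sc <- switch(class,
    colonization = cv_scenario(seed = seed),
    control = cv_scenario(colonization_time_s = Inf, seed = seed),
    damage_after_colonization = cv_scenario(damage_mode = "electrode_damage",
                                            seed = seed),
    early_damage = cv_scenario(colonization_time_s = Inf, seed = seed))
  eis_sc <- switch(class,
    colonization = eis_scenario(seed = seed + 5000L),
    control = eis_scenario(colonization_time_s = Inf, seed = seed + 5000L),
    damage_after_colonization =
      eis_scenario(damage_mode = "post_colonization_damage",
                   seed = seed + 5000L),
    early_damage = eis_scenario(damage_mode = "early_damage",
                                seed = seed + 5000L))
  list(cv = generate_cv_session(cv_sc, duration_s),
       eis = generate_eis_session(eis_sc, duration_s))
}

classify_pair <- function(pair, config = monitor_config()) {
  cvs <- cv_variance_series(pair$cv)
  es <- eis_variance_series(pair$eis)
  classify_event(cvs, es$impedance, es$phase, config)
}

# Reference frequency grid of the study: 25 points, log-spaced 200 Hz-50 kHz.
eis_freq_grid <- function() 10^seq(log10(200), log10(50000), length.out = 25)
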