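#' EIS session scenario
#'
#' Study conditions for the synthetic electrochemical impedance spectroscopy
#' generator: 25 log-spaced frequencies between 200 Hz and 50 kHz, one
#' spectrum every 30 min, circuit-parameter regimes before and after the
#' colonization event, and optional electrode-damage failure modes.
#'
#' The colonization event is rendered as a sharp log-space jump of the
#' circuit parameters at `colonization_time_s` (spread over
#' `transition_duration_s`, centered on the event) to an intermediate
#' parameter point, followed by a slow settle to `params_after` as the
#' biofilm densifies. The intermediate point is solved (two nested
#' root-finds over a two-weight log blend of the regimes) so that at the jump
#' (a) the within-spectrum impedance variance lands at
#' `variance_drop_fraction` of the before-to-final variance range and (b) the
#' within-spectrum phase variance already lands at its after-event value —
#' the interface capacitance and CPE respond at contact while the charge
#' transfer resistance keeps falling. The settle is scheduled to be linear in
#' the impedance variance, so with the default 0.30 the post/pre change ratio
#' of the normalized impedance variance is ~0.15 by construction (the mean
#' of a linear decline from 0.30 to 0), while the phase variance steps once
#' at the event and then stays near its after value.
#'
#' @param frequencies Hz, strictly increasing within \[200, 50000\].
#' @param params_before,params_after [circuit_params()] regimes.
#' @param colonization_time_s event time, seconds (`Inf` for a control run).
#' @param transition_duration_s duration of the fast parameter jump, centered
#'   at the event.
#' @param variance_drop_fraction post-jump within-spectrum impedance-variance
#'   level as a fraction of the before-to-final range, in \[0, 1).
#' @param rel_noise_sd relative complex Gaussian noise: total complex sd per
#'   point is `rel_noise_sd * |Z|` (each quadrature gets `rel_noise_sd/sqrt(2)`).
#' @param measurement_interval_s seconds between spectra.
#' @param damage_mode `"none"`, `"post_colonization_damage"` (series
#'   resistance ramps up after colonization, noise inflated) or
#'   `"early_damage"` (resistance step with no faradaic change).
#' @param damage_time_s damage onset, seconds; defaults to the event time plus
#'   10 h (post-colonization damage) or 8 h (early damage).
#' @param damage_factor multiplier applied to R_elec after damage (ramped in
#'   over 1 h); defaults to 2 for post-colonization damage and 8 for early
#'   damage (a wear-off resistance step).
#' @param damage_rb_factor multiplier applied to R_b after damage; defaults
#'   to 8 for post-colonization damage — the degrading bacteria-electrode
#'   contact raises the charge-transfer resistance, which is what raises the
#'   phase variance — and 1 for early damage (no faradaic branch change).
#' @param damage_noise_boost multiplier on `rel_noise_sd` after damage
#'   (default 4; the measurement becomes less stable).
#' @param seed integer RNG seed; sessions are pure functions of
#'   (scenario, seed).
#' @return An object of class `eis_scenario`.
#' @export
eis_scenario <- function(frequencies = 10^seq(log10(200), log10(50000),
                                              length.out = 25),
                         params_before = reference_circuit_params("before"),
                         params_after = reference_circuit_params("after"),
                         colonization_time_s = 8 * 3600,
                         transition_duration_s = 1800,
                         variance_drop_fraction = 0.30,
                         rel_noise_sd = 0.01,
                         measurement_interval_s = 1800,
                         damage_mode = c("none", "post_colonization_damage",
                                         "early_damage"),
                         damage_time_s = NULL,
                         damage_factor = NULL,
                         damage_rb_factor = NULL,
                         damage_noise_boost = NULL,
                         seed = 1L) {
  damage_mode <- match.arg(damage_mode)
  if (!is.numeric(frequencies) || length(frequencies) < 2L ||
      any(diff(frequencies) <= 0) ||
      min(frequencies) < 200 - 1e-9 || max(frequencies) > 50000 + 1e-9) {
    stop("`frequencies` must be strictly increasing within [200, 50000] Hz",
         call. = FALSE)
  }
  if (!inherits(params_before, "circuit_params") ||
      !inherits(params_after, "circuit_params")) {
    stop("params_before/params_after must be `circuit_params`", call. = FALSE)
  }
  if (rel_noise_sd < 0) stop("`rel_noise_sd` must be >= 0", call. = FALSE)
  if (variance_drop_fraction < 0 || variance_drop_fraction >= 1) {
    stop("`variance_drop_fraction` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot_scalar(measurement_interval_s, "measurement_interval_s",
                   positive = TRUE)
  stopifnot_scalar(transition_duration_s, "transition_duration_s",
                   positive = TRUE)
  if (is.null(damage_time_s)) {
    damage_time_s <- switch(damage_mode,
                            none = Inf,
                            post_colonization_damage =
                              colonization_time_s + 10 * 3600,
                            early_damage = 8 * 3600)
  }
  if (is.null(damage_factor)) {
    damage_factor <- switch(damage_mode, none = 1,
                            post_colonization_damage = 2, early_damage = 8)
  }
  if (is.null(damage_rb_factor)) {
    damage_rb_factor <- switch(damage_mode, none = 1,
                               post_colonization_damage = 8,
                               early_damage = 1)
  }
  if (is.null(damage_noise_boost)) {
    damage_noise_boost <- if (damage_mode == "none") 1 else 4
  }
  structure(list(
    frequencies = frequencies, params_before = params_before,
    params_after = params_after, colonization_time_s = colonization_time_s,
    transition_duration_s = transition_duration_s,
    variance_drop_fraction = variance_drop_fraction,
    rel_noise_sd = rel_noise_sd,
    measurement_interval_s = measurement_interval_s,
    damage_mode = damage_mode, damage_time_s = damage_time_s,
    damage_factor = damage_factor, damage_rb_factor = damage_rb_factor,
    damage_noise_boost = damage_noise_boost,
    seed = seed
  ), class = "eis_scenario")
}

# Two-weight log-space blend of two parameter regimes: `u` drives the
# resistive elements (R_elec, R_b), `w` the interface elements
# (C_belec, Q_i, n_i). blend_circuit_params(pb, pa, u) is the diagonal case.
blend_circuit_params2 <- function(pb, pa, u, w) {
  f <- function(a, b, x) exp((1 - x) * log(a) + x * log(b))
  circuit_params(R_elec = f(pb$R_elec, pa$R_elec, u),
                 C_belec = f(pb$C_belec, pa$C_belec, w),
                 R_b = f(pb$R_b, pa$R_b, u),
                 Q_i = f(pb$Q_i, pa$Q_i, w),
                 n_i = min(f(pb$n_i, pa$n_i, w), 1))
}

blend_circuit_params <- function(pb, pa, u) blend_circuit_params2(pb, pa, u, u)

spectrum_mag_variance <- function(p, omega) {
  stats::var(Mod(simplified_circuit_impedance(p, omega)))
}

spectrum_phase_variance <- function(p, omega) {
  stats::var(Arg(simplified_circuit_impedance(p, omega)) * 180 / pi)
}

# Solve the intermediate parameter point reached right after the colonization
# jump: impedance variance at `s_drop` and phase variance at its after value.
# Falls back to the pure resistive-jump point (w = 0) when the second
# condition has no root for the given regimes.
solve_jump_params <- function(pb, pa, frequencies, drop_fraction) {
  omega <- 2 * pi * frequencies
  s_b <- spectrum_mag_variance(pb, omega)
  s_f <- spectrum_mag_variance(pa, omega)
  s_drop <- s_f + drop_fraction * (s_b - s_f)
  pv_target <- spectrum_phase_variance(pa, omega)
  u_for_w <- function(w) {
    f <- function(u) spectrum_mag_variance(blend_circuit_params2(pb, pa, u, w),
                                           omega) - s_drop
    if (f(0) <= 0 || f(1) >= 0) return(NA_real_)
    stats::uniroot(f, c(0, 1), tol = 1e-9)$root
  }
  g <- function(w) {
    u <- u_for_w(w)
    if (is.na(u)) return(NA_real_)
    spectrum_phase_variance(blend_circuit_params2(pb, pa, u, w), omega) -
      pv_target
  }
  ws <- seq(0, 0.95, by = 0.05)
  gs <- vapply(ws, g, numeric(1))
  ok <- which(!is.na(gs))
  w_star <- 0
  if (length(ok) >= 2L) {
    sign_change <- which(diff(sign(gs[ok])) != 0)
    if (length(sign_change) > 0L) {
      i <- ok[sign_change[1]]
      w_star <- stats::uniroot(g, c(ws[i], ws[i + 1L]), tol = 1e-7)$root
    } else {
      w_star <- ws[ok[which.min(abs(gs[ok]))]]
    }
  }
  u_star <- u_for_w(w_star)
  if (is.na(u_star)) {
    # degenerate regimes: jump straight onto the diagonal blend
    u_star <- 0.5
    w_star <- 0.5
  }
  blend_circuit_params2(pb, pa, u_star, w_star)
}

# Parameter schedule for the session timestamps: params_before until the
# event, a linear-in-time blend toward the jump point across the transition
# window, then a settle toward params_after scheduled to be linear in the
# within-spectrum impedance variance.
eis_param_schedule <- function(scenario, timestamps) {
  t0 <- scenario$colonization_time_s
  pb <- scenario$params_before
  pa <- scenario$params_after
  n <- length(timestamps)
  if (scenario$damage_mode == "early_damage" || !is.finite(t0) ||
      t0 > max(timestamps)) {
    return(list(params = rep(list(pb), n), progress = rep(0, n)))
  }
  omega <- 2 * pi * scenario$frequencies
  pm <- solve_jump_params(pb, pa, scenario$frequencies,
                          scenario$variance_drop_fraction)
  # settle table along the pm -> pa segment, indexed by impedance variance
  vgrid <- seq(0, 1, length.out = 201L)
  svals <- vapply(vgrid, function(v) {
    spectrum_mag_variance(blend_circuit_params(pm, pa, v), omega)
  }, numeric(1))
  s_env <- cummin(svals)  # monotone envelope for safe inversion
  invert_settle <- function(s_target) {
    idx <- min(max(findInterval(-s_target, -s_env), 1L), length(vgrid) - 1L)
    s1 <- s_env[idx]; s2 <- s_env[idx + 1L]
    frac <- if (s2 == s1) 0 else (s_target - s1) / (s2 - s1)
    min(max(vgrid[idx] + frac * (vgrid[idx + 1L] - vgrid[idx]), 0), 1)
  }
  s_drop <- svals[1]
  s_f <- svals[length(svals)]
  half <- scenario$transition_duration_s / 2
  t_end <- max(timestamps)
  params <- vector("list", n)
  progress <- numeric(n)
  for (i in seq_len(n)) {
    t <- timestamps[i]
    if (t <= t0 - half) {
      params[[i]] <- pb
      progress[i] <- 0
    } else if (t < t0 + half) {
      a <- (t - (t0 - half)) / (2 * half)
      params[[i]] <- blend_circuit_params(pb, pm, a)
      progress[i] <- a / 2
    } else if (t >= t_end) {
      params[[i]] <- pa
      progress[i] <- 1
    } else {
      s_t <- s_drop + (s_f - s_drop) * (t - (t0 + half)) / (t_end - (t0 + half))
      v <- invert_settle(s_t)
      params[[i]] <- blend_circuit_params(pm, pa, v)
      progress[i] <- 0.5 + v / 2
    }
  }
  list(params = params, progress = progress)
}

#' Generate a synthetic EIS session
#'
#' One spectrum per `measurement_interval_s`, computed from the simplified
#' equivalent circuit at parameters that follow the scenario's colonization
#' trajectory, with relative complex Gaussian noise. Damage modes perturb the
#' series resistance (ramp over 1 h) and inflate the noise after
#' `damage_time_s`. Ground truth (event time, per-spectrum blend weights and
#' parameter trajectory) is attached so that recovery tests never re-derive
#' truth from generator internals.
#'
#' @param scenario an [eis_scenario()].
#' @param total_duration_s session length in seconds
#'   (>= `measurement_interval_s`).
#' @return An object of class `eis_session`: list with `spectra` (each an
#'   `impedance_sample`: `frequency`, complex `Z`, `timestamp`) and
#'   `ground_truth`.
#' @export
generate_eis_session <- function(scenario, total_duration_s = 35 * 3600) {
  if (!inherits(scenario, "eis_scenario")) {
    stop("`scenario` must be an `eis_scenario`", call. = FALSE)
  }
  if (total_duration_s < scenario$measurement_interval_s) {
    stop("`total_duration_s` must cover at least one measurement interval",
         call. = FALSE)
  }
  ts <- seq(scenario$measurement_interval_s, total_duration_s,
            by = scenario$measurement_interval_s)
  sched <- eis_param_schedule(scenario, ts)
  omega <- 2 * pi * scenario$frequencies
  m <- length(scenario$frequencies)

  with_seed(scenario$seed, {
    spectra <- vector("list", length(ts))
    traj <- matrix(NA_real_, length(ts), 5,
                   dimnames = list(NULL,
                                   c("R_elec", "C_belec", "R_b", "Q_i", "n_i")))
    for (i in seq_along(ts)) {
      p <- sched$params[[i]]
      noise_sd <- scenario$rel_noise_sd
      if (ts[i] >= scenario$damage_time_s) {
        ramp <- min(1, (ts[i] - scenario$damage_time_s) / 3600)
        p$R_elec <- p$R_elec * (1 + (scenario$damage_factor - 1) * ramp)
        p$R_b <- p$R_b * (1 + (scenario$damage_rb_factor - 1) * ramp)
        noise_sd <- noise_sd * scenario$damage_noise_boost
      }
      traj[i, ] <- unlist(p)
      Z0 <- simplified_circuit_impedance(p, omega)
      Z <- Z0 + complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) *
        (noise_sd / sqrt(2)) * Mod(Z0)
      spectra[[i]] <- structure(
        list(frequency = scenario$frequencies, Z = Z, timestamp = ts[i]),
        class = "impedance_sample")
    }
    structure(list(
      spectra = spectra,
      ground_truth = list(
        event_time_s = scenario$colonization_time_s,
        damage_time_s = scenario$damage_time_s,
        damage_mode = scenario$damage_mode,
        progress = sched$progress,
        timestamps = ts,
        params = traj,
        variance_drop_fraction = scenario$variance_drop_fraction,
        target_variance_ratio = scenario$variance_drop_fraction / 2
      )
    ), class = "eis_session")
  })
}
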