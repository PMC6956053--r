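#' CV session scenario
#'
#' Study conditions for the synthetic cyclic voltammetry generator: a
#' triangular potential sweep from −0.5 V to 0.5 V and back at 50 mV/s,
#' sampled at `points_per_sweep` applied-potential points (forward branch
#' followed by the reverse branch), three sweeps per 30-min timepoint.
#'
#' Before the colonization event the current is non-faradaic: a capacitive
#' box (+/− `baseline_capacitive_current` by sweep direction), an ohmic slope
#' and stray Gaussian noise. After the event a Gaussian anodic peak at `E_pa`
#' is added on the forward branch and a cathodic peak at `E_pc` on the
#' reverse branch; their amplitudes rise along an onset-logistic envelope
#' (zero at the event, ~96% of steady state after `ramp_duration_s`) such
#' that the steady-state current at the peak potential is
#' `anodic_change_ratio` (resp. `cathodic_change_ratio`) times the pre-event
#' current magnitude there.
#'
#' @param potential_range volts, length-2 (default −0.5 to 0.5).
#' @param points_per_sweep total applied-potential points per triangular
#'   cycle (default 201; >= 3).
#' @param scan_rate V/s (default 0.05).
#' @param sweeps_per_timepoint sweeps recorded back-to-back per measurement
#'   block (default 3).
#' @param measurement_interval_s seconds between blocks (default 1800).
#' @param baseline_capacitive_current amperes (default 5 nA).
#' @param baseline_resistive_slope A/V (default 2 nA/V).
#' @param stray_noise_sd amperes (default 0.2 nA).
#' @param colonization_time_s event time, seconds; `Inf` for a control run.
#' @param anodic_change_ratio,cathodic_change_ratio steady-state peak
#'   amplification factors (> 1; defaults 8.29 and 6.07).
#' @param E_pa,E_pc anodic/cathodic peak potentials, volts (defaults 0.1398
#'   and −0.20455; `E_pc < E_pa`).
#' @param peak_width Gaussian peak width (sd), volts (default 0.03).
#' @param peak_jitter_sd relative per-sweep lognormal jitter of the faradaic
#'   peak amplitudes (default 0.05), mean-one; reflects the sweep-to-sweep
#'   peak-current scatter of colonized microsystems.
#' @param ramp_duration_s faradaic stabilization time (default 7200 s; the
#'   observed range is 2–5 h).
#' @param damage_mode `"none"` or `"electrode_damage"` (post-damage currents
#'   multiplied by a factor decaying toward `damage_floor`).
#' @param damage_time_s damage onset; defaults to the event time plus 10 h.
#' @param damage_floor asymptotic post-damage current multiplier
#'   (default 0.3).
#' @param seed integer RNG seed.
#' @return An object of class `cv_scenario`.
#' @export
cv_scenario <- function(potential_range = c(-0.5, 0.5),
                        points_per_sweep = 201L,
                        scan_rate = 0.05,
                        sweeps_per_timepoint = 3L,
                        measurement_interval_s = 1800,
                        baseline_capacitive_current = 5e-9,
                        baseline_resistive_slope = 2e-9,
                        stray_noise_sd = 2e-10,
                        colonization_time_s = 8 * 3600,
                        anodic_change_ratio = 8.29,
                        cathodic_change_ratio = 6.07,
                        E_pa = 0.1398,
                        E_pc = -0.20455,
                        peak_width = 0.03,
                        peak_jitter_sd = 0.05,
                        ramp_duration_s = 7200,
                        damage_mode = c("none", "electrode_damage"),
                        damage_time_s = NULL,
                        damage_floor = 0.3,
                        seed = 1L) {
  damage_mode <- match.arg(damage_mode)
  if (length(potential_range) != 2L || diff(potential_range) <= 0) {
    stop("`potential_range` must be an increasing pair of volts",
         call. = FALSE)
  }
  if (points_per_sweep < 3L) stop("`points_per_sweep` must be >= 3",
                                  call. = FALSE)
  if (E_pc >= E_pa) stop("`E_pc` must be below `E_pa`", call. = FALSE)
  if (anodic_change_ratio <= 1 || cathodic_change_ratio <= 1) {
    stop("change ratios must be > 1", call. = FALSE)
  }
  stopifnot_scalar(scan_rate, "scan_rate", positive = TRUE)
  stopifnot_scalar(peak_width, "peak_width", positive = TRUE)
  stopifnot_scalar(ramp_duration_s, "ramp_duration_s", positive = TRUE)
  if (stray_noise_sd < 0) stop("`stray_noise_sd` must be >= 0", call. = FALSE)
  if (is.null(damage_time_s)) {
    damage_time_s <- if (damage_mode == "none") Inf else
      colonization_time_s + 10 * 3600
  }
  structure(list(
    potential_range = potential_range,
    points_per_sweep = as.integer(points_per_sweep),
    scan_rate = scan_rate,
    sweeps_per_timepoint = as.integer(sweeps_per_timepoint),
    measurement_interval_s = measurement_interval_s,
    baseline_capacitive_current = baseline_capacitive_current,
    baseline_resistive_slope = baseline_resistive_slope,
    stray_noise_sd = stray_noise_sd,
    colonization_time_s = colonization_time_s,
    anodic_change_ratio = anodic_change_ratio,
    cathodic_change_ratio = cathodic_change_ratio,
    E_pa = E_pa, E_pc = E_pc, peak_width = peak_width,
    peak_jitter_sd = peak_jitter_sd,
    ramp_duration_s = ramp_duration_s,
    damage_mode = damage_mode, damage_time_s = damage_time_s,
    damage_floor = damage_floor,
    seed = seed
  ), class = "cv_scenario")
}

#' Triangular sweep grid of a CV scenario
#'
#' The applied-potential grid of one full cycle: the forward (anodic-going)
#' branch followed by the reverse branch, `points_per_sweep` points in total.
#'
#' @param scenario a [cv_scenario()].
#' @return A list with `potential` (volts), `direction` (+1 forward,
#'   −1 reverse) and `sweep_duration_s`.
#' @export
cv_sweep_grid <- function(scenario) {
  p <- scenario$points_per_sweep
  n_fwd <- ceiling((p + 1L) / 2)
  lo <- scenario$potential_range[1]
  hi <- scenario$potential_range[2]
  fwd <- seq(lo, hi, length.out = n_fwd)
  rev_branch <- seq(hi, lo, length.out = p - n_fwd + 1L)[-1L]
  list(
    potential = c(fwd, rev_branch),
    direction = c(rep(1, n_fwd), rep(-1, p - n_fwd)),
    sweep_duration_s = 2 * (hi - lo) / scenario$scan_rate
  )
}

# Onset-logistic amplitude envelope: 0 at the event, ~96% of steady state
# after ramp_duration_s/2 * 4 time scales; reaches 1 asymptotically.
onset_logistic <- function(t, t0, ramp) {
  s <- ramp / 8
  ifelse(t > t0, 2 * stats::plogis((t - t0) / s) - 1, 0)
}

# Noiseless current of one sweep at time t (vectorized over the grid);
# jit_a/jit_c scale the anodic/cathodic peak amplitudes (sweep-level jitter).
cv_model_current <- function(scenario, grid, t, jit_a = 1, jit_c = 1) {
  base <- grid$direction * scenario$baseline_capacitive_current +
    scenario$baseline_resistive_slope * grid$potential
  g <- onset_logistic(t, scenario$colonization_time_s,
                      scenario$ramp_duration_s)
  cur <- base
  if (g > 0) {
    i_pre_pa <- scenario$baseline_capacitive_current +
      scenario$baseline_resistive_slope * scenario$E_pa
    i_pre_pc <- -scenario$baseline_capacitive_current +
      scenario$baseline_resistive_slope * scenario$E_pc
    amp_a <- jit_a * g * (scenario$anodic_change_ratio - 1) * i_pre_pa
    amp_c <- jit_c * g * (scenario$cathodic_change_ratio - 1) * i_pre_pc
    fwd <- grid$direction > 0
    cur[fwd] <- cur[fwd] + amp_a *
      exp(-(grid$potential[fwd] - scenario$E_pa)^2 /
            (2 * scenario$peak_width^2))
    cur[!fwd] <- cur[!fwd] + amp_c *
      exp(-(grid$potential[!fwd] - scenario$E_pc)^2 /
            (2 * scenario$peak_width^2))
  }
  if (t >= scenario$damage_time_s) {
    decay <- scenario$damage_floor + (1 - scenario$damage_floor) *
      exp(-(t - scenario$damage_time_s) / 7200)
    cur <- cur * decay
  }
  cur
}

#' Generate a synthetic CV session
#'
#' `sweeps_per_timepoint` triangular sweeps every `measurement_interval_s`
#' for `total_duration_s` seconds, with ground truth (event time, injected
#' peak positions/ratios, per-timepoint peak amplitude envelopes) attached.
#'
#' @param scenario a [cv_scenario()].
#' @param total_duration_s session length, seconds
#'   (>= `measurement_interval_s`).
#' @return An object of class `cv_session`: list with `sweeps` (each a
#'   `voltammogram_sample`: `potential`, `current`, `direction`, `timestamp`,
#'   `sweep_id`) and `ground_truth`.
#' @export
generate_cv_session <- function(scenario, total_duration_s = 24 * 3600) {
  if (!inherits(scenario, "cv_scenario")) {
    stop("`scenario` must be a `cv_scenario`", call. = FALSE)
  }
  if (total_duration_s < scenario$measurement_interval_s) {
    stop("`total_duration_s` must cover at least one measurement interval",
         call. = FALSE)
  }
  grid <- cv_sweep_grid(scenario)
  blocks <- seq(scenario$measurement_interval_s, total_duration_s,
                by = scenario$measurement_interval_s)
  with_seed(scenario$seed, {
    sweeps <- vector("list", length(blocks) * scenario$sweeps_per_timepoint)
    env <- numeric(length(blocks))
    id <- 0L
    for (b in seq_along(blocks)) {
      env[b] <- onset_logistic(blocks[b], scenario$colonization_time_s,
                               scenario$ramp_duration_s)
      for (s in seq_len(scenario$sweeps_per_timepoint)) {
        id <- id + 1L
        t <- blocks[b] + (s - 1L) * grid$sweep_duration_s
        jsd <- scenario$peak_jitter_sd
        jit <- exp(stats::rnorm(2, mean = -jsd^2 / 2, sd = jsd))
        cur <- cv_model_current(scenario, grid, t, jit[1], jit[2]) +
          stats::rnorm(length(grid$potential), sd = scenario$stray_noise_sd)
        sweeps[[id]] <- structure(
          list(potential = grid$potential, current = cur,
               direction = grid$direction, timestamp = t, sweep_id = id),
          class = "voltammogram_sample")
      }
    }
    structure(list(
      sweeps = sweeps,
      ground_truth = list(
        event_time_s = scenario$colonization_time_s,
        damage_time_s = scenario$damage_time_s,
        E_pa = scenario$E_pa, E_pc = scenario$E_pc,
        anodic_change_ratio = scenario$anodic_change_ratio,
        cathodic_change_ratio = scenario$cathodic_change_ratio,
        block_times = blocks,
        peak_envelope = env
      )
    ), class = "cv_session")
  })
}

#' Per-sweep current variance pipeline of a CV session
#'
#' Builds the [sample_series()] of sweep currents and runs
#' [variance_pipeline()] — the CV channel of the colonization-event
#' detection.
#'
#' @param session a [cv_session].
#' @return The [variance_pipeline()] result.
#' @export
cv_variance_series <- function(session) {
  if (!inherits(session, "cv_session")) {
    stop("`session` must be a `cv_session`", call. = FALSE)
  }
  ts <- vapply(session$sweeps, function(s) s$timestamp, numeric(1))
  variance_pipeline(sample_series(lapply(session$sweeps, `[[`, "current"),
                                  ts))
}
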