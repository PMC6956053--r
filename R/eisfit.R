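#' Simplified equivalent-circuit parameters
#'
#' Parameters of the simplified interface circuit: the microsystem overall
#' resistance `R_elec` in series with the parallel combination of the
#' bacteria-electrode interface capacitance `C_belec` and the faradaic branch
#' (charge-transfer resistance of the bacteria `R_b` in series with a
#' constant phase element of magnitude `Q_i` and exponent `n_i`).
#'
#' @param R_elec microsystem overall resistance, ohm (> 0).
#' @param C_belec interface double-layer capacitance, farad (> 0).
#' @param R_b charge-transfer resistance of the bacteria, ohm (> 0).
#' @param Q_i CPE magnitude, S s^n_i (> 0).
#' @param n_i CPE exponent, 0 < n_i <= 1.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(R_elec, C_belec, R_b, Q_i, n_i) {
  for (nm in c("R_elec", "C_belec", "R_b", "Q_i", "n_i")) {
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  }
  if (n_i > 1) stop("`n_i` must lie in (0, 1]", call. = FALSE)
  structure(list(R_elec = R_elec, C_belec = C_belec, R_b = R_b,
                 Q_i = Q_i, n_i = n_i),
            class = "circuit_params")
}

#' Circuit parameter regimes of the studied microsystem
#'
#' The average fitted element values before and after the bacterial
#' colonization event (C_belec 0.919 / 6.72 nF, R_elec 15.96 / 3.904 kOhm,
#' R_b 5.71 / 0.107 MOhm, Q_i 31.37848 / 69.78041 nS s^n, n_i 0.77428 /
#' 0.865045), used as the default regimes of the synthetic EIS generator.
#'
#' @param epoch `"before"` or `"after"` the colonization event.
#' @return A [circuit_params()] object.
#' @export
reference_circuit_params <- function(epoch = c("before", "after")) {
  epoch <- match.arg(epoch)
  if (epoch == "before") {
    circuit_params(R_elec = 15.96e3, C_belec = 0.919e-9, R_b = 5.71e6,
                   Q_i = 31.37848e-9, n_i = 0.77428)
  } else {
    circuit_params(R_elec = 3.904e3, C_belec = 6.72e-9, R_b = 0.107e6,
                   Q_i = 69.78041e-9, n_i = 0.865045)
  }
}

#' Constant phase element impedance
#'
#' Z(omega) = 1 / (Q_i (j omega)^n_i), principal branch. With n_i = 1 this
#' reduces to an ideal capacitor of capacitance Q_i.
#'
#' @param Q_i CPE magnitude, S s^n_i (> 0).
#' @param n_i CPE exponent in (0, 1].
#' @param omega angular frequency, rad/s (> 0); vectorized.
#' @return Complex impedance in ohm.
#' @export
cpe_impedance <- function(Q_i, n_i, omega) {
  stopifnot_scalar(Q_i, "Q_i", positive = TRUE)
  stopifnot_scalar(n_i, "n_i", positive = TRUE)
  if (n_i > 1) stop("`n_i` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(omega) || any(omega <= 0)) {
    stop("`omega` must be > 0", call. = FALSE)
  }
  1 / (Q_i * complex(real = 0, imaginary = omega)^n_i)
}

#' Simplified circuit impedance
#'
#' Z(omega) = R_elec + \[ (jw C_belec) + 1 / (R_b + Z_CPE(omega)) \]^{-1}:
#' the series microsystem resistance plus the interface capacitance in
#' parallel with the faradaic branch.
#'
#' @param params a [circuit_params()] object.
#' @param omega angular frequency, rad/s (> 0); vectorized.
#' @return Complex impedance in ohm.
#' @export
simplified_circuit_impedance <- function(params, omega) {
  if (!inherits(params, "circuit_params")) {
    stop("`params` must be a `circuit_params`", call. = FALSE)
  }
  if (!is.numeric(omega) || any(omega <= 0)) {
    stop("`omega` must be > 0", call. = FALSE)
  }
  z_far <- params$R_b + cpe_impedance(params$Q_i, params$n_i, omega)
  y <- complex(real = 0, imaginary = omega * params$C_belec) + 1 / z_far
  params$R_elec + 1 / y
}

#' Full (generalized) circuit parameters
#'
#' Parameters of the generalized interface model: two Randles cells for the
#' microelectrodes (series resistances `R_ELEC_a`, `R_ELEC_c`; charge-transfer
#' resistances `R_act`, `R_cct` each paralleled by a double-layer capacitance
#' `C_adl`, `C_cdl`), a capacitive bridge `C_elec` between the electrodes, and
#' a modified Randles cell for the bacteria ((R_b + CPE) || C_b).
#'
#' @param R_ELEC_a,R_ELEC_c series electrode resistances, ohm.
#' @param R_act,R_cct electrode charge-transfer resistances, ohm.
#' @param C_adl,C_cdl electrode double-layer capacitances, farad.
#' @param C_elec inter-electrode bridge capacitance, farad.
#' @param C_b bacterial capacitance, farad.
#' @param R_b bacterial charge-transfer resistance, ohm.
#' @param Q_i,n_i CPE magnitude and exponent.
#' @return An object of class `full_circuit_params`.
#' @export
full_circuit_params <- function(R_ELEC_a, R_ELEC_c, R_act, R_cct,
                                C_adl, C_cdl, C_elec, C_b, R_b, Q_i, n_i) {
  vals <- list(R_ELEC_a = R_ELEC_a, R_ELEC_c = R_ELEC_c, R_act = R_act,
               R_cct = R_cct, C_adl = C_adl, C_cdl = C_cdl, C_elec = C_elec,
               C_b = C_b, R_b = R_b, Q_i = Q_i, n_i = n_i)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L ||
        vals[[nm]] < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  if (n_i <= 0 || n_i > 1) stop("`n_i` must lie in (0, 1]", call. = FALSE)
  structure(vals, class = "full_circuit_params")
}

#' Full circuit impedance
#'
#' Documented topology: the inner ladder — electrode interface cells
#' (R_act || C_adl) and (R_cct || C_cdl) in series with the bacterial cell
#' ((R_b + Z_CPE) || C_b) — bridged by C_elec in parallel, all between the two
#' series electrode resistances R_ELEC_a and R_ELEC_c. With the electrode
#' interface cells shorted (R_act = R_cct = 0, C_adl = C_cdl = 0) this reduces
#' to the simplified model with C_belec = C_elec + C_b.
#'
#' @param params a [full_circuit_params()] object.
#' @param omega angular frequency, rad/s (> 0); vectorized.
#' @return Complex impedance in ohm.
#' @export
full_circuit_impedance <- function(params, omega) {
  if (!inherits(params, "full_circuit_params")) {
    stop("`params` must be a `full_circuit_params`", call. = FALSE)
  }
  if (!is.numeric(omega) || any(omega <= 0)) {
    stop("`omega` must be > 0", call. = FALSE)
  }
  jw <- complex(real = 0, imaginary = omega)
  par_rc <- function(R, C) {
    if (R == 0) return(rep(0 + 0i, length(omega)))
    if (C == 0) return(rep(complex(real = R), length(omega)))
    1 / (1 / R + jw * C)
  }
  z_bact <- params$R_b + cpe_impedance(params$Q_i, params$n_i, omega)
  y_bact <- 1 / z_bact + if (params$C_b > 0) jw * params$C_b else 0
  z_inner <- par_rc(params$R_act, params$C_adl) +
    par_rc(params$R_cct, params$C_cdl) + 1 / y_bact
  y_core <- 1 / z_inner + if (params$C_elec > 0) jw * params$C_elec else 0
  params$R_ELEC_a + params$R_ELEC_c + 1 / y_core
}

# ---- fitting ---------------------------------------------------------------

# Pack/unpack parameters for unconstrained optimization: resistances,
# capacitance and Q in log space; n via logit on (0, 1].
pack_params <- function(p) {
  c(log(p$R_elec), log(p$C_belec), log(p$R_b), log(p$Q_i),
    stats::qlogis(min(p$n_i, 1 - 1e-9)))
}

unpack_params <- function(theta) {
  # clamp so optimizer excursions cannot underflow exp() to zero
  theta <- pmin(pmax(theta, -300), 300)
  circuit_params(R_elec = exp(theta[1]), C_belec = exp(theta[2]),
                 R_b = exp(theta[3]), Q_i = exp(theta[4]),
                 n_i = max(stats::plogis(theta[5]), 1e-12))
}

# Data-driven starting values: R_elec from the high-frequency real part,
# C_belec from the high-frequency imaginary part, R_b from the low-frequency
# magnitude excess, Q from the low-frequency faradaic-branch magnitude.
auto_init_params <- function(freq, Z, n0 = 0.8) {
  i_hi <- which.max(freq)
  i_lo <- which.min(freq)
  R_elec0 <- max(Re(Z[i_hi]), 1e-3)
  w_hi <- 2 * pi * freq[i_hi]
  C0 <- max(-1 / (w_hi * min(Im(Z[i_hi]), -1e-12)), 1e-15)
  excess <- max(Mod(Z[i_lo]) - R_elec0, 10 * R_elec0)
  R_b0 <- 5 * excess
  w_lo <- 2 * pi * freq[i_lo]
  Q0 <- max(1 / (excess * w_lo^n0), 1e-15)
  circuit_params(R_elec = R_elec0, C_belec = C0, R_b = R_b0,
                 Q_i = Q0, n_i = n0)
}

fit_residuals <- function(theta, freq, Z, w) {
  p <- unpack_params(theta)
  r <- (simplified_circuit_impedance(p, 2 * pi * freq) - Z) * w
  c(Re(r), Im(r))
}

#' Fit the simplified equivalent circuit to an impedance spectrum
#'
#' Complex nonlinear least squares: minimizes
#' sum_f |Z_model(f) - Z_data(f)|^2 / |Z_data(f)|^2 (modulus weighting) by
#' Levenberg-Marquardt over log-transformed positive parameters, with the CPE
#' exponent mapped through a logit onto (0, 1). A small deterministic
#' multistart around the data-driven initialization guards against local
#' minima. Non-convergence is reported through the `converged` flag, never as
#' an error.
#'
#' @param spectrum a list with numeric `frequency` (Hz, >= 5 points) and
#'   complex `Z` (ohm) of equal length — one `impedance_sample` of an
#'   [eis_session].
#' @param init optional [circuit_params()] starting values; by default an
#'   automatic initialization from the data is used.
#' @param multistart number of deterministic perturbed restarts around the
#'   initialization (default 8; ignored when `init` is supplied).
#' @return An object of class `circuit_fit`: list with `params`
#'   ([circuit_params()]), `residual_norm` (weighted), `relative_error`
#'   (approximate per-parameter relative standard errors from the Jacobian),
#'   `converged`, and `init` (the starting values used).
#' @export
fit_circuit <- function(spectrum, init = NULL, multistart = 8L) {
  freq <- spectrum$frequency
  Z <- spectrum$Z
  if (!is.numeric(freq) || length(freq) < 5L) {
    stop("spectrum must contain at least 5 frequency points", call. = FALSE)
  }
  if (length(Z) != length(freq)) {
    stop("`frequency` and `Z` must have equal length", call. = FALSE)
  }
  w <- 1 / pmax(Mod(Z), .Machine$double.eps)

  starts <- list()
  if (!is.null(init)) {
    if (!inherits(init, "circuit_params")) {
      stop("`init` must be a `circuit_params`", call. = FALSE)
    }
    starts[[1]] <- pack_params(init)
  } else {
    base <- auto_init_params(freq, Z)
    starts[[1]] <- pack_params(base)
    if (multistart > 1L) {
      rb_mult <- c(0.2, 1, 5, 25)
      n_alt <- c(0.65, 0.9)
      k <- 1L
      for (m in rb_mult) for (nn in n_alt) {
        if (length(starts) >= multistart) break
        p <- base
        p$R_b <- base$R_b * m
        p$n_i <- nn
        k <- k + 1L
        starts[[k]] <- pack_params(p)
      }
    }
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0, fn = fit_residuals, freq = freq, Z = Z, w = w,
        control = minpack.lm::nls.lm.control(
          maxiter = 400, ftol = 1e-15, ptol = 1e-15, gtol = 0)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }

  if (is.null(best)) {
    return(structure(
      list(params = if (is.null(init)) auto_init_params(freq, Z) else init,
           residual_norm = NA_real_, relative_error = rep(NA_real_, 5),
           converged = FALSE,
           init = if (is.null(init)) auto_init_params(freq, Z) else init),
      class = "circuit_fit"))
  }

  fit <- best$fit
  params <- unpack_params(fit$par)
  # Relative standard errors of the natural-scale parameters. For the
  # log-parameters the SE of the log IS the relative error; for n_i scale by
  # the logistic derivative.
  rel_err <- rep(NA_real_, 5)
  cov_try <- tryCatch({
    dof <- max(length(fit$fvec) - 5L, 1L)
    s2 <- sum(fit$fvec^2) / dof
    s2 * solve(fit$hessian)
  }, error = function(e) NULL)
  if (!is.null(cov_try)) {
    se_theta <- sqrt(pmax(diag(cov_try), 0))
    rel_err <- se_theta
    rel_err[5] <- se_theta[5] * stats::plogis(fit$par[5]) *
      (1 - stats::plogis(fit$par[5])) / stats::plogis(fit$par[5])
  }
  names(rel_err) <- c("R_elec", "C_belec", "R_b", "Q_i", "n_i")
  structure(
    list(params = params,
         residual_norm = best$rn,
         relative_error = rel_err,
         converged = fit$info %in% 1:4,
         init = unpack_params(starts[[1]])),
    class = "circuit_fit")
}

#' Per-spectrum circuit-parameter trajectory
#'
#' Fits the simplified circuit to every spectrum of a session, warm-starting
#' each fit from the previous converged parameters, and summarizes before /
#' after epoch means for every element.
#'
#' @param session an [eis_session].
#' @param event_time_s colonization event time in seconds used to split the
#'   epochs (e.g. the changepoint time from [variance_pipeline()]).
#' @return A list with `fits` (list of `circuit_fit`), `params` (data frame:
#'   timestamp_s, R_elec, C_belec, R_b, Q_i, n_i, converged) and
#'   `epoch_means` (data frame with rows `before` and `after`).
#' @export
parameter_trajectory <- function(session, event_time_s) {
  stopifnot_scalar(event_time_s, "event_time_s")
  spectra <- session$spectra
  fits <- vector("list", length(spectra))
  prev <- NULL
  for (i in seq_along(spectra)) {
    fit <- fit_circuit(spectra[[i]])  # auto-init multistart
    if (!is.null(prev)) {
      # warm start from the previous spectrum; keep the better residual
      warm <- fit_circuit(spectra[[i]], init = prev)
      if (isTRUE(warm$converged) &&
          (!isTRUE(fit$converged) ||
           (is.finite(warm$residual_norm) &&
            warm$residual_norm < fit$residual_norm))) {
        fit <- warm
      }
    }
    fits[[i]] <- fit
    prev <- if (isTRUE(fit$converged)) fit$params else NULL
  }
  ts <- vapply(spectra, function(s) s$timestamp, numeric(1))
  pmat <- t(vapply(fits, function(f) unlist(f$params), numeric(5)))
  out <- data.frame(timestamp_s = ts, pmat,
                    converged = vapply(fits, function(f) f$converged,
                                       logical(1)))
  before <- out$timestamp_s < event_time_s
  em <- rbind(
    before = colMeans(out[before, 2:6, drop = FALSE]),
    after = colMeans(out[!before, 2:6, drop = FALSE])
  )
  list(fits = fits, params = out, epoch_means = as.data.frame(em))
}

#' Impedance and phase variance series of an EIS session
#'
#' For every spectrum, the unbiased variance over the M frequency points is
#' computed separately for |Z| and for the phase (degrees), then each series
#' is min-max normalized — the inputs to the changepoint detection.
#'
#' @param session an [eis_session].
#' @return A list with `impedance` and `phase`, each the result of
#'   [variance_pipeline()] on the respective [sample_series()].
#' @export
eis_variance_series <- function(session) {
  spectra <- session$spectra
  if (length(spectra) < 2L) stop("need >= 2 spectra", call. = FALSE)
  ts <- vapply(spectra, function(s) s$timestamp, numeric(1))
  mag <- lapply(spectra, function(s) Mod(s$Z))
  ph <- lapply(spectra, function(s) Arg(s$Z) * 180 / pi)
  list(
    impedance = variance_pipeline(sample_series(mag, ts)),
    phase = variance_pipeline(sample_series(ph, ts))
  )
}

#' Frequency of maximal epoch change
#'
#' Frequency at which the absolute difference between the before-epoch and
#' after-epoch mean |Z| (and, separately, mean phase) is largest.
#'
#' @param session an [eis_session].
#' @param event_time_s event time splitting the epochs.
#' @return A list with `impedance_hz`, `phase_hz`, and `degenerate` (TRUE when
#'   the epoch difference is zero everywhere).
#' @export
max_change_frequency <- function(session, event_time_s) {
  stopifnot_scalar(event_time_s, "event_time_s")
  spectra <- session$spectra
  ts <- vapply(spectra, function(s) s$timestamp, numeric(1))
  before <- ts < event_time_s
  if (!any(before) || all(before)) {
    stop("both epochs must be non-empty", call. = FALSE)
  }
  freq <- spectra[[1]]$frequency
  magm <- function(idx) {
    rowMeans(vapply(spectra[idx], function(s) Mod(s$Z),
                    numeric(length(freq))))
  }
  phm <- function(idx) {
    rowMeans(vapply(spectra[idx], function(s) Arg(s$Z) * 180 / pi,
                    numeric(length(freq))))
  }
  dmag <- abs(magm(which(before)) - magm(which(!before)))
  dph <- abs(phm(which(before)) - phm(which(!before)))
  list(
    impedance_hz = freq[which.max(dmag)],
    phase_hz = freq[which.max(dph)],
    degenerate = max(dmag) == 0 && max(dph) == 0
  )
}
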