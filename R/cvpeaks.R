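#' Split a CV session at the colonization event
#'
#' Partitions sweeps into the before-event group (timestamp strictly below
#' `event_time_s`) and the after-event group (at or above).
#'
#' @param session a [cv_session].
#' @param event_time_s event time in seconds (e.g. the changepoint time from
#'   [cv_variance_series()]).
#' @return A list with `before` and `after`, both `cv_session` objects.
#' @export
split_by_changepoint <- function(session, event_time_s) {
  if (!inherits(session, "cv_session")) {
    stop("`session` must be a `cv_session`", call. = FALSE)
  }
  stopifnot_scalar(event_time_s, "event_time_s")
  ts <- vapply(session$sweeps, function(s) s$timestamp, numeric(1))
  before <- ts < event_time_s
  if (!any(before) || all(before)) {
    stop("`event_time_s` must split the session into two non-empty groups",
         call. = FALSE)
  }
  mk <- function(idx) structure(list(sweeps = session$sweeps[idx],
                                     ground_truth = session$ground_truth),
                                class = "cv_session")
  list(before = mk(which(before)), after = mk(which(!before)))
}

# Currents of a session as a sweeps x M matrix, checking the shared grid.
session_current_matrix <- function(session) {
  pots <- lapply(session$sweeps, `[[`, "potential")
  ref <- pots[[1]]
  same <- vapply(pots, function(p) length(p) == length(ref) &&
                   max(abs(p - ref)) < 1e-12, logical(1))
  if (!all(same)) stop("sweeps do not share a common potential grid",
                       call. = FALSE)
  t(vapply(session$sweeps, `[[`, numeric(length(ref)), "current"))
}

#' Per-potential current variance of a sweep group
#'
#' At each of the M applied-potential points, the unbiased variance of the
#' currents across the group's sweeps.
#'
#' @param group a [cv_session] with at least two sweeps.
#' @return Numeric vector of length M with attributes `potential` and
#'   `direction`.
#' @export
per_potential_variance <- function(group) {
  if (!inherits(group, "cv_session")) {
    stop("`group` must be a `cv_session`", call. = FALSE)
  }
  if (length(group$sweeps) < 2L) stop("need >= 2 sweeps", call. = FALSE)
  cur <- session_current_matrix(group)
  v <- apply(cur, 2L, sample_variance)
  attr(v, "potential") <- group$sweeps[[1]]$potential
  attr(v, "direction") <- group$sweeps[[1]]$direction
  v
}

mean_voltammogram <- function(group) {
  cur <- session_current_matrix(group)
  list(potential = group$sweeps[[1]]$potential,
       direction = group$sweeps[[1]]$direction,
       current = colMeans(cur))
}

peak_set <- function(idx, group, tier, epoch = NA_character_) {
  mv <- mean_voltammogram(group)
  if (length(idx) == 0L) {
    return(structure(
      data.frame(index = integer(0), E = numeric(0), i = numeric(0),
                 polarity = character(0), tier = character(0),
                 epoch = character(0)),
      class = c("peak_set", "data.frame")))
  }
  structure(
    data.frame(index = idx,
               E = mv$potential[idx],
               i = mv$current[idx],
               polarity = ifelse(mv$direction[idx] > 0, "anodic", "cathodic"),
               tier = tier,
               epoch = epoch,
               stringsAsFactors = FALSE),
    class = c("peak_set", "data.frame"))
}

#' Primary peak candidates from the per-potential variance curve
#'
#' Strict local maxima of the variance curve, mapped back to the potential
#' and mean-voltammogram current at those grid points. Peaks on the forward
#' branch are anodic, on the reverse branch cathodic.
#'
#' @param variance_curve output of [per_potential_variance()] (M >= 5).
#' @param group the [cv_session] the curve was computed from.
#' @param epoch optional label (`"before"`/`"after"`) stored with the peaks.
#' @return A `peak_set` data frame (possibly empty): columns `index`, `E`,
#'   `i`, `polarity`, `tier`, `epoch`.
#' @export
find_primary_peaks <- function(variance_curve, group, epoch = NA_character_) {
  if (length(variance_curve) < 5L) stop("need M >= 5", call. = FALSE)
  idx <- local_maxima(as.numeric(variance_curve))
  peak_set(idx, group, tier = "primary", epoch = epoch)
}

#' Secondary peak candidates from variance-derivative ratios
#'
#' Local maxima of |variance / variance'| and |variance' / variance''| with
#' central-difference derivatives on the potential grid and denominators
#' floored at 1e-15 — a fallback detector for peaks that the raw variance
#' curve does not resolve.
#'
#' @param variance_curve output of [per_potential_variance()] (M >= 7).
#' @param group the [cv_session] the curve was computed from.
#' @param epoch optional label stored with the peaks.
#' @param floor denominator floor (default 1e-15).
#' @return A `peak_set` data frame with tier `"secondary"`.
#' @export
find_secondary_peaks <- function(variance_curve, group,
                                 epoch = NA_character_, floor = 1e-15) {
  if (length(variance_curve) < 7L) stop("need M >= 7", call. = FALSE)
  v <- as.numeric(variance_curve)
  E <- attr(variance_curve, "potential")
  if (is.null(E)) E <- seq_along(v)
  n <- length(v)
  h <- diff(E)
  # central differences on a (possibly non-uniform) grid
  d1 <- c(NA, (v[3:n] - v[1:(n - 2)]) / (E[3:n] - E[1:(n - 2)]), NA)
  d2 <- c(NA, diff(diff(v) / h) / ((E[3:n] - E[1:(n - 2)]) / 2), NA)
  r1 <- abs(v) / pmax(abs(d1), floor)
  r2 <- abs(d1) / pmax(abs(d2), floor)
  idx <- sort(unique(c(local_maxima(r1), local_maxima(r2))))
  idx <- idx[idx > 1L & idx < n]
  peak_set(idx, group, tier = "secondary", epoch = epoch)
}

#' Cluster peak candidates on the potential axis
#'
#' Single-linkage 1-D clustering of candidate peaks by potential within each
#' polarity: candidates closer than `gap_v` merge into one cluster, and the
#' member with the largest |current| represents the cluster. The highest-|i|
#' anodic and cathodic representatives are flagged as the redox pair.
#'
#' @param candidates a `peak_set` (rows may mix tiers).
#' @param gap_v single-linkage merge distance in volts (default 0.05).
#' @return A `peak_set` of cluster representatives with an extra logical
#'   column `redox_pair`.
#' @export
cluster_peaks <- function(candidates, gap_v = 0.05) {
  if (nrow(candidates) == 0L) {
    candidates$redox_pair <- logical(0)
    return(candidates)
  }
  reps <- do.call(rbind, lapply(split(candidates, candidates$polarity),
                                function(df) {
    df <- df[order(df$E), , drop = FALSE]
    cl <- cumsum(c(1, diff(df$E) > gap_v))
    do.call(rbind, lapply(split(df, cl), function(g) {
      g[which.max(abs(g$i)), , drop = FALSE]
    }))
  }))
  rownames(reps) <- NULL
  reps$redox_pair <- FALSE
  for (pol in c("anodic", "cathodic")) {
    sel <- which(reps$polarity == pol)
    if (length(sel) > 0L) {
      reps$redox_pair[sel[which.max(abs(reps$i[sel]))]] <- TRUE
    }
  }
  structure(reps, class = c("peak_set", "data.frame"))
}

#' Full peak identification on one sweep group
#'
#' Convenience composition: per-potential variance, primary and secondary
#' candidates, clustering.
#'
#' @param group a [cv_session] group (>= 2 sweeps).
#' @param epoch optional label stored with the peaks.
#' @param gap_v clustering gap in volts.
#' @return The clustered `peak_set`.
#' @export
identify_peaks <- function(group, epoch = NA_character_, gap_v = 0.05) {
  v <- per_potential_variance(group)
  cand <- rbind(find_primary_peaks(v, group, epoch),
                find_secondary_peaks(v, group, epoch))
  cluster_peaks(cand, gap_v = gap_v)
}

#' Peak-current change ratios across the colonization event
#'
#' For each polarity, the ratio of the mean after-event current at the
#' detected peak potential to the mean before-event current at the same
#' potential (an Eq-7-style ratio evaluated at the redox-pair grid points
#' found on the after-event group).
#'
#' @param before,after [cv_session] groups from [split_by_changepoint()].
#' @param peaks optional `peak_set` with a `redox_pair` column; by default
#'   [identify_peaks()] is run on the after group.
#' @return A list with `anodic` and `cathodic` ratios (NA when that polarity
#'   is absent) and the `peaks` used.
#' @export
peak_change_ratio <- function(before, after, peaks = NULL) {
  if (is.null(peaks)) peaks <- identify_peaks(after, epoch = "after")
  sel <- peaks[peaks$redox_pair %in% TRUE, , drop = FALSE]
  mv_b <- mean_voltammogram(before)
  mv_a <- mean_voltammogram(after)
  ratio_at <- function(pol) {
    row <- sel[sel$polarity == pol, , drop = FALSE]
    if (nrow(row) == 0L) return(NA_real_)
    i <- row$index[1]
    if (mv_b$current[i] == 0) return(NA_real_)
    mv_a$current[i] / mv_b$current[i]
  }
  list(anodic = ratio_at("anodic"), cathodic = ratio_at("cathodic"),
       peaks = sel)
}

#' Formal potential of a redox couple
#'
#' Midpoint of the anodic and cathodic peak potentials.
#'
#' @param E_pa anodic peak potential, volts.
#' @param E_pc cathodic peak potential, volts (must be below `E_pa`).
#' @return (E_pa + E_pc) / 2 in volts.
#' @export
formal_potential <- function(E_pa, E_pc) {
  stopifnot_scalar(E_pa, "E_pa")
  stopifnot_scalar(E_pc, "E_pc")
  if (E_pc >= E_pa) stop("`E_pc` must be below `E_pa`", call. = FALSE)
  (E_pa + E_pc) / 2
}

#' Potential correction to the Ag/AgCl reference
#'
#' The ferro/ferricyanide couple serves as internal standard: the correction
#' to report potentials against Ag/AgCl is the standard redox potential of
#' the couple versus Ag/AgCl (241 mV) minus the measured formal potential.
#'
#' @param measured_formal measured formal potential, volts.
#' @param standard_vs_agcl standard redox potential of the couple vs Ag/AgCl,
#'   volts (default 0.241).
#' @return A list of class `potential_reference`: `measured_formal_potential`,
#'   `standard_vs_agcl`, `correction` (volts).
#' @export
agcl_correction <- function(measured_formal, standard_vs_agcl = 0.241) {
  stopifnot_scalar(measured_formal, "measured_formal")
  stopifnot_scalar(standard_vs_agcl, "standard_vs_agcl")
  structure(list(measured_formal_potential = measured_formal,
                 standard_vs_agcl = standard_vs_agcl,
                 correction = standard_vs_agcl - measured_formal),
            class = "potential_reference")
}

#' Peak statistics of the mean voltammogram
#'
#' Anodic peak (largest local maximum of the mean current on the forward
#' branch), cathodic peak (most negative local minimum on the reverse branch)
#' and their separation — the electrode-characterization numbers measured on
#' reversible-couple test fixtures.
#'
#' @param group a [cv_session] with >= 2 sweeps.
#' @return A list with `i_pa`, `E_pa`, `i_pc`, `E_pc`, `delta_Ep` (volts) and
#'   `found` (FALSE when either extremum is absent, remaining fields NA).
#' @export
mean_cv_peak_stats <- function(group) {
  if (length(group$sweeps) < 2L) stop("need >= 2 sweeps", call. = FALSE)
  mv <- mean_voltammogram(group)
  fwd <- which(mv$direction > 0)
  rev_b <- which(mv$direction < 0)
  i_max <- local_maxima(mv$current[fwd])
  i_min <- local_minima(mv$current[rev_b])
  if (length(i_max) == 0L || length(i_min) == 0L) {
    return(list(i_pa = NA_real_, E_pa = NA_real_, i_pc = NA_real_,
                E_pc = NA_real_, delta_Ep = NA_real_, found = FALSE))
  }
  ia <- fwd[i_max[which.max(mv$current[fwd][i_max])]]
  ic <- rev_b[i_min[which.min(mv$current[rev_b][i_min])]]
  list(i_pa = mv$current[ia], E_pa = mv$potential[ia],
       i_pc = mv$current[ic], E_pc = mv$potential[ic],
       delta_Ep = mv$potential[ia] - mv$potential[ic], found = TRUE)
}
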