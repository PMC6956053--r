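#' Monitoring configuration
#'
#' Thresholds of the event classifier. A channel "steps" when its
#' changepoint's change ratio falls outside \[1/theta, theta\] AND the
#' changepoint objective improves on the no-split cost by at least
#' `log(4) * n` (`improvement_margin` scales that margin). Channels agree in
#' time when their changepoints lie within `concurrence_intervals`
#' measurement intervals.
#'
#' @param ratio_threshold theta (default 2).
#' @param improvement_margin multiplier on the `log(4) * n` objective margin
#'   (default 1).
#' @param concurrence_intervals concurrence window in measurement intervals
#'   (default 2).
#' @param measurement_interval_s seconds per interval (default 1800).
#' @param max_image_offset_s image/electrochemistry concordance bound
#'   (default 2.5 h).
#' @return A list of class `monitor_config`.
#' @export
monitor_config <- function(ratio_threshold = 2,
                           improvement_margin = 1,
                           concurrence_intervals = 2,
                           measurement_interval_s = 1800,
                           max_image_offset_s = 2.5 * 3600) {
  structure(list(ratio_threshold = ratio_threshold,
                 improvement_margin = improvement_margin,
                 concurrence_intervals = concurrence_intervals,
                 measurement_interval_s = measurement_interval_s,
                 max_image_offset_s = max_image_offset_s),
            class = "monitor_config")
}

# Step evidence for one normalized-variance series: binary segmentation to
# depth two. The primary changepoint is complemented by sub-changepoints in
# the segments before and after it, so that a rise-then-fall series (e.g.
# colonization followed by electrode damage) yields both steps. Each step's
# change ratio is evaluated between its neighbouring steps, and a step is
# flagged when the ratio leaves [1/theta, theta] and its changepoint
# objective improves on the no-split cost of its segment by more than
# log(4) times the segment length.
channel_evidence <- function(V, timestamps, config) {
  n <- length(V)
  theta <- config$ratio_threshold
  out <- list(event_time = NA_real_, event_ratio = NA_real_,
              event_flag = FALSE, event_direction = "none",
              late_time = NA_real_, late_ratio = NA_real_,
              late_flag = FALSE, late_direction = "none")
  if (max(V) == min(V)) return(out)
  cp <- single_changepoint(V, timestamps)
  if (is.na(cp$k)) return(out)
  k1 <- cp$k

  sub_step <- function(lo, hi) {
    # flagged sub-changepoint inside V[lo:hi] (global index), or NA
    if (hi - lo + 1L < 4L) return(NULL)
    sub <- single_changepoint(V[lo:hi])
    if (is.na(sub$k)) return(NULL)
    ratio <- tryCatch(change_ratio(V[lo:hi], sub$k),
                      error = function(e) NA_real_)
    margin <- config$improvement_margin * log(4) * (hi - lo + 1L)
    if (is.na(ratio) || sub$improvement <= margin ||
        (ratio <= theta && ratio >= 1 / theta)) return(NULL)
    list(k = lo + sub$k - 1L)
  }
  before <- sub_step(1L, k1 - 1L)
  after <- sub_step(k1, n)
  cand <- sort(unique(c(if (!is.null(before)) before$k, k1,
                        if (!is.null(after)) after$k)))

  # J improvement of splitting V[a:b] at global index kc
  local_improvement <- function(a, b, kc) {
    seg <- V[a:b]
    left <- V[a:(kc - 1L)]
    right <- V[kc:b]
    length(seg) * log(pop_var_floored(seg)) -
      (length(left) * log(pop_var_floored(left)) +
         length(right) * log(pop_var_floored(right)))
  }

  steps <- list()
  for (i in seq_along(cand)) {
    kc <- cand[i]
    a <- if (i == 1L) 1L else cand[i - 1L]
    b <- if (i == length(cand)) n else cand[i + 1L] - 1L
    if (kc - a < 1L || b - kc + 1L < 1L) next
    ratio <- tryCatch(change_ratio(V[a:b], kc - a + 1L),
                      error = function(e) NA_real_)
    margin <- config$improvement_margin * log(4) * (b - a + 1L)
    flagged <- !is.na(ratio) && local_improvement(a, b, kc) > margin &&
      (ratio > theta || ratio < 1 / theta)
    if (flagged) {
      steps[[length(steps) + 1L]] <- list(
        time = timestamps[kc], ratio = ratio,
        direction = if (ratio > 1) "up" else "down")
    } else if (kc == k1 && length(cand) == 1L) {
      # unflagged primary: still report its time and ratio as evidence
      out$event_time <- timestamps[kc]
      out$event_ratio <- ratio
    }
  }
  if (length(steps) >= 1L) {
    out$event_time <- steps[[1]]$time
    out$event_ratio <- steps[[1]]$ratio
    out$event_flag <- TRUE
    out$event_direction <- steps[[1]]$direction
  }
  if (length(steps) >= 2L) {
    out$late_time <- steps[[2]]$time
    out$late_ratio <- steps[[2]]$ratio
    out$late_flag <- TRUE
    out$late_direction <- steps[[2]]$direction
  }
  out
}

evidence_from_result <- function(x, config) {
  if (is.list(x) && !is.null(x$variance) && !is.null(x$changepoint)) {
    return(channel_evidence(x$variance$normalized, x$variance$timestamps,
                            config))
  }
  stop("channel inputs must be variance_pipeline() results", call. = FALSE)
}

#' Classify a monitored experiment
#'
#' Combines the CV current, EIS impedance and EIS phase normalized-variance
#' changepoints into one of: `colonization` (concurrent steps on all three
#' channels — current up, impedance down, phase down),
#' `damage_after_colonization` (colonization followed by a current-variance
#' decrement and a phase-variance increment), `early_damage` (exactly two
#' stepping channels with no faradaic signature), `control` (no steps), or
#' `indeterminate` (a flag pattern matching none of these).
#'
#' @param cv_result,z_result,phase_result [variance_pipeline()] results for
#'   the CV current, EIS impedance magnitude and EIS phase channels (e.g.
#'   from [cv_variance_series()] and [eis_variance_series()]).
#' @param config a [monitor_config()].
#' @return An object of class `event_classification`: `label`,
#'   `event_time_s`, `damage_time_s` and `evidence` (per-channel ratios,
#'   flags and times).
#' @export
classify_event <- function(cv_result, z_result, phase_result,
                           config = monitor_config()) {
  span <- function(x) range(x$variance$timestamps)
  spans <- rbind(span(cv_result), span(z_result), span(phase_result))
  if (diff(range(spans[, 2])) > config$measurement_interval_s * 2) {
    stop("channel timelines are inconsistent", call. = FALSE)
  }
  ev <- list(current = evidence_from_result(cv_result, config),
             impedance = evidence_from_result(z_result, config),
             phase = evidence_from_result(phase_result, config))
  win <- config$concurrence_intervals * config$measurement_interval_s
  concurrent <- function(a, b) {
    !is.na(a) && !is.na(b) && abs(a - b) <= win
  }
  label <- "indeterminate"
  event_time <- NA_real_
  damage_time <- NA_real_
  n_flags <- sum(vapply(ev, function(e) e$event_flag, logical(1)))

  colonization_sig <- ev$current$event_flag &&
    ev$current$event_direction == "up" &&
    ev$impedance$event_flag && ev$impedance$event_direction == "down" &&
    ev$phase$event_flag && ev$phase$event_direction == "down" &&
    concurrent(ev$current$event_time, ev$impedance$event_time) &&
    concurrent(ev$current$event_time, ev$phase$event_time)

  if (colonization_sig) {
    event_time <- ev$current$event_time
    dmg <- ev$current$late_flag && ev$current$late_direction == "down" &&
      ev$phase$late_flag && ev$phase$late_direction == "up"
    if (dmg) {
      label <- "damage_after_colonization"
      damage_time <- ev$phase$late_time
    } else {
      label <- "colonization"
    }
  } else if (n_flags == 0L) {
    label <- "control"
  } else if (n_flags == 2L &&
             !(ev$current$event_flag &&
               ev$current$event_direction == "up")) {
    label <- "early_damage"
    flagged <- Filter(function(e) e$event_flag, ev)
    event_time <- flagged[[1]]$event_time
  }
  structure(list(label = label, event_time_s = event_time,
                 damage_time_s = damage_time, evidence = ev),
            class = "event_classification")
}

#' Concordance of electrochemical and image-based event detection
#'
#' Signed offset between the electrochemical colonization event time and the
#' image-derived stationary start (bacteria covering the analyzed segment),
#' flagged discordant beyond `config$max_image_offset_s`.
#'
#' @param image_curve a `growth_curve` from [extract_growth_phases()].
#' @param event an `event_classification` from [classify_event()].
#' @param config a [monitor_config()].
#' @return A list: `offset_s` (electrochemical minus image time),
#'   `concordant`, `comparable` (FALSE when either detection is missing,
#'   other fields NA).
#' @export
image_echem_concordance <- function(image_curve, event,
                                    config = monitor_config()) {
  if (is.null(image_curve) || !isTRUE(image_curve$detected) ||
      is.na(event$event_time_s)) {
    return(list(offset_s = NA_real_, concordant = NA, comparable = FALSE))
  }
  offset <- event$event_time_s - image_curve$stationary_start_s
  list(offset_s = offset,
       concordant = abs(offset) <= config$max_image_offset_s,
       comparable = TRUE)
}
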