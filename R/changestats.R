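#' Sample series container
#'
#' Bundles the ordered measurement vectors ("samples") of one monitored
#' channel — e.g. the 201 currents of each CV sweep, or the 25 impedance
#' magnitudes of each EIS spectrum — together with their acquisition times.
#'
#' @param samples list of numeric vectors, one per sample; every vector must
#'   hold at least two values.
#' @param timestamps numeric vector of acquisition times in seconds, strictly
#'   increasing, one per sample.
#' @return An object of class `sample_series`.
#' @export
sample_series <- function(samples, timestamps) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("`samples` must be a list of at least two measurement vectors",
         call. = FALSE)
  }
  if (any(!vapply(samples, is.numeric, logical(1)))) {
    stop("all samples must be numeric vectors", call. = FALSE)
  }
  if (any(vapply(samples, length, integer(1)) < 2L)) {
    stop("every sample must contain at least two values (M >= 2)",
         call. = FALSE)
  }
  if (length(timestamps) != length(samples)) {
    stop("`timestamps` must have one entry per sample", call. = FALSE)
  }
  if (any(diff(timestamps) <= 0)) {
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  }
  structure(list(samples = samples, timestamps = as.numeric(timestamps)),
            class = "sample_series")
}

#' Arithmetic mean of one measurement vector
#'
#' @param x numeric vector with at least one value.
#' @return The arithmetic mean.
#' @export
sample_mean <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  }
  mean(x)
}

#' Unbiased variance of one measurement vector
#'
#' Variance with the M − 1 denominator, used for the per-sample dynamic
#' characterization of the electrochemical response.
#'
#' @param x numeric vector with at least two values.
#' @return The unbiased sample variance (>= 0).
#' @export
sample_variance <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("`x` must be a numeric vector with at least two values (M >= 2)",
         call. = FALSE)
  }
  stats::var(x)
}

#' Min-max normalization of a variance series
#'
#' Maps the per-sample variances affinely onto \[0, 1\] so that experiments
#' whose absolute response levels differ by orders of magnitude (as observed
#' between microsystems) become comparable. A constant series cannot be
#' normalized; all values are then returned as 0 and the result is flagged
#' degenerate.
#'
#' @param sigma2 numeric vector of per-sample variances (n >= 2).
#' @return Numeric vector in \[0, 1\] with attribute `degenerate` (logical).
#' @export
normalize_series <- function(sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) < 2L) {
    stop("`sigma2` must be a numeric vector with n >= 2", call. = FALSE)
  }
  rng <- range(sigma2)
  if (rng[2] == rng[1]) {
    out <- rep(0, length(sigma2))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (sigma2 - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

# Population (1/count) variance with a floor, used inside the changepoint
# objective so that noiseless segments do not produce log(0).
pop_var_floored <- function(v, floor = 1e-12) {
  m <- mean(v)
  max(mean((v - m)^2), floor)
}

#' Single-step changepoint by log-variance segmentation
#'
#' Splits the normalized variance series into two segments at index k and
#' minimizes the segment-length-weighted sum of the logarithms of the
#' population variances,
#' J(k) = (k − 1) log var(V\[1..k−1\]) + (n − k + 1) log var(V\[k..n\]).
#' k indexes the first sample of the second segment; both segments must hold
#' at least two points, so k ranges over 3..(n − 1). Ties are broken toward
#' the smallest k (earliest event). Segment variances are floored at
#' `var_floor` before the logarithm.
#'
#' @param V numeric vector (typically a normalized variance series), n >= 4.
#' @param timestamps optional numeric vector of times; if supplied, the
#'   detected changepoint's time is reported.
#' @param var_floor lower floor applied to segment variances (default 1e-12).
#' @return An object of class `changepoint_result`: list with `k` (1-based
#'   index of the first post-change sample), `time_s`, `objective` (J over
#'   admissible k, named by k), `no_split_objective` (n log var(V)),
#'   `improvement` (no-split minus minimum J), and `degenerate` (TRUE when V
#'   is constant, in which case no changepoint is claimed and `k` is NA).
#' @export
single_changepoint <- function(V, timestamps = NULL, var_floor = 1e-12) {
  if (!is.numeric(V) || length(V) < 4L) {
    stop("`V` must be numeric with n >= 4 (each segment needs >= 2 points)",
         call. = FALSE)
  }
  n <- length(V)
  if (!is.null(timestamps) && length(timestamps) != n) {
    stop("`timestamps` must match the length of `V`", call. = FALSE)
  }
  if (max(V) == min(V)) {
    res <- list(k = NA_integer_, time_s = NA_real_, objective = NULL,
                no_split_objective = n * log(var_floor), improvement = 0,
                degenerate = TRUE)
    class(res) <- "changepoint_result"
    return(res)
  }
  ks <- 3:(n - 1L)
  J <- vapply(ks, function(k) {
    (k - 1L) * log(pop_var_floored(V[seq_len(k - 1L)], var_floor)) +
      (n - k + 1L) * log(pop_var_floored(V[k:n], var_floor))
  }, numeric(1))
  names(J) <- ks
  k_hat <- ks[which.min(J)]  # which.min takes the first minimum: smallest k
  J0 <- n * log(pop_var_floored(V, var_floor))
  res <- list(
    k = as.integer(k_hat),
    time_s = if (is.null(timestamps)) NA_real_ else timestamps[k_hat],
    objective = J,
    no_split_objective = J0,
    improvement = J0 - min(J),
    degenerate = FALSE
  )
  class(res) <- "changepoint_result"
  res
}

#' Change ratio across a changepoint
#'
#' Ratio of the mean of the post-change samples (x_k..x_n) to the mean of the
#' pre-change samples (x_1..x_{k−1}). Both segments are averaged by their
#' term counts; `denominator = "printed"` reproduces the n − k denominator of
#' the transcribed formula instead (kept for reference, not the default).
#'
#' @param x numeric vector of n values.
#' @param k changepoint index, 2 <= k <= n.
#' @param denominator `"count"` (true means, default) or `"printed"`.
#' @return The change ratio R.
#' @export
change_ratio <- function(x, k, denominator = c("count", "printed")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(x) || length(x) < 2L) {
    stop("`x` must be a numeric vector with n >= 2", call. = FALSE)
  }
  n <- length(x)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 2 || k > n) {
    stop("`k` must satisfy 2 <= k <= length(x)", call. = FALSE)
  }
  k <- as.integer(k)
  pre_mean <- mean(x[seq_len(k - 1L)])
  if (pre_mean == 0) {
    stop("pre-segment mean is zero; change ratio undefined", call. = FALSE)
  }
  post_sum <- sum(x[k:n])
  post <- switch(denominator,
                 count = post_sum / (n - k + 1L),
                 printed = post_sum / (n - k))
  post / pre_mean
}

#' Normalized-variance changepoint pipeline
#'
#' Composes the per-sample unbiased variance, min-max normalization,
#' single-step changepoint detection and the change ratio — the full
#' statistical chain used to locate the bacterial colonization event in CV
#' and EIS responses.
#'
#' @param series a [sample_series()].
#' @param var_floor floor for segment variances inside the changepoint
#'   objective.
#' @return A list with `variance` (list: `sigma2`, `normalized`, `timestamps`,
#'   `degenerate`; class `variance_series`) and `changepoint` (a
#'   `changepoint_result` whose `change_ratio` field holds the Eq-7 ratio of
#'   the normalized variances, NA when undefined).
#' @export
variance_pipeline <- function(series, var_floor = 1e-12) {
  if (!inherits(series, "sample_series")) {
    stop("`series` must be a `sample_series`", call. = FALSE)
  }
  sigma2 <- vapply(series$samples, sample_variance, numeric(1))
  V <- normalize_series(sigma2)
  vs <- structure(
    list(sigma2 = sigma2, normalized = as.numeric(V),
         timestamps = series$timestamps,
         degenerate = isTRUE(attr(V, "degenerate"))),
    class = "variance_series"
  )
  if (vs$degenerate) {
    cp <- list(k = NA_integer_, time_s = NA_real_, objective = NULL,
               no_split_objective = NA_real_, improvement = 0,
               degenerate = TRUE, change_ratio = NA_real_)
    class(cp) <- "changepoint_result"
    return(list(variance = vs, changepoint = cp))
  }
  cp <- single_changepoint(vs$normalized, series$timestamps, var_floor)
  cp$change_ratio <- if (is.na(cp$k)) NA_real_ else {
    tryCatch(change_ratio(vs$normalized, cp$k), error = function(e) NA_real_)
  }
  list(variance = vs, changepoint = cp)
}
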