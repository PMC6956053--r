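#' Preprocess a frame: luminance collapse and contrast stretch
#'
#' RGB frames (3-D arrays) are collapsed to luminance (0.299 R + 0.587 G +
#' 0.114 B), then intensities are linearly rescaled so the frame range maps
#' onto \[0, 255\]. A constant frame has no contrast to stretch and is
#' returned unchanged (as a matrix).
#'
#' @param frame 2-D numeric matrix or 3-D RGB array; 8- or 16-bit integer
#'   scales are accepted.
#' @return Numeric matrix on the 0-255 scale (or the unchanged constant
#'   frame).
#' @export
preprocess_frame <- function(frame) {
  if (is.array(frame) && length(dim(frame)) == 3L) {
    w <- c(0.299, 0.587, 0.114)[seq_len(dim(frame)[3])]
    w <- w / sum(w)
    frame <- apply(sweep(frame, 3L, w, `*`), c(1, 2), sum)
  }
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L) {
    stop("`frame` must be a non-empty 2-D numeric array", call. = FALSE)
  }
  rng <- range(frame)
  if (rng[2] == rng[1]) return(frame)
  (frame - rng[1]) / (rng[2] - rng[1]) * 255
}

# Clipped box sum over a (2r+1)^2 window via integral images; windows are
# clipped at the frame edges.
box_sum <- function(m, r) {
  n <- nrow(m); p <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(seq_len(n) + r, n) + 1L
  lo <- pmax(seq_len(n) - r - 1L, 0L) + 1L
  rowsum_m <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- cbind(0, t(apply(rowsum_m, 1, cumsum)))
  hi2 <- pmin(seq_len(p) + r, p) + 1L
  lo2 <- pmax(seq_len(p) - r - 1L, 0L) + 1L
  cs2[, hi2, drop = FALSE] - cs2[, lo2, drop = FALSE]
}

#' Local-variance texture statistic
#'
#' Population variance of intensities in a square window around every pixel
#' (clipped at the frame edges) — the texture operator behind the percentile
#' segmentation. Bacterial lawns and channel borders are strongly textured;
#' empty background is not.
#'
#' @param frame numeric matrix (use [preprocess_frame()] first).
#' @param window odd window side in pixels (default 5).
#' @return Matrix of local variances, same shape as `frame`.
#' @export
texture_statistic <- function(frame, window = 5L) {
  if (!is.matrix(frame)) stop("`frame` must be a matrix", call. = FALSE)
  if (window %% 2L != 1L || window < 3L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  r <- (window - 1L) %/% 2L
  n <- box_sum(matrix(1, nrow(frame), ncol(frame)), r)
  mu <- box_sum(frame, r) / n
  pmax(box_sum(frame^2, r) / n - mu^2, 0)
}

#' Segmentation threshold of an image set
#'
#' The texture-statistic percentile of the reference frame(s) of a set — the
#' paper-style threshold "determined individually for each image set", then
#' applied to every frame of the set.
#'
#' @param frames a single matrix or list of matrices (already preprocessed).
#' @param percentile_p percentile in (0, 100) (default 70).
#' @param window texture window (default 5).
#' @return The scalar threshold.
#' @export
texture_threshold <- function(frames, percentile_p = 70, window = 5L) {
  if (is.matrix(frames)) frames <- list(frames)
  vals <- unlist(lapply(frames, function(f) texture_statistic(f, window)))
  as.numeric(stats::quantile(vals, percentile_p / 100, names = FALSE))
}

#' Percentile texture segmentation
#'
#' Marks as foreground (1) every pixel whose local-variance texture statistic
#' exceeds the threshold. The threshold is taken from `threshold` when given
#' (the per-set convention: compute it once from a pre-growth reference frame
#' with [texture_threshold()]); otherwise it is the `percentile_p` percentile
#' of this frame's own statistic.
#'
#' @param frame preprocessed numeric matrix.
#' @param percentile_p percentile used when `threshold` is NULL (default 70).
#' @param threshold optional fixed threshold from [texture_threshold()].
#' @param window texture window (default 5).
#' @return Integer 0/1 matrix of the frame's shape.
#' @export
segment_bacteria <- function(frame, percentile_p = 70, threshold = NULL,
                             window = 5L) {
  stat <- texture_statistic(frame, window)
  if (is.null(threshold)) {
    threshold <- stats::quantile(stat, percentile_p / 100, names = FALSE)
  }
  mask <- matrix(0L, nrow(frame), ncol(frame))
  mask[stat > threshold] <- 1L
  mask
}

#' Colonized-area percentage of a binary mask
#'
#' @param mask 0/1 matrix from [segment_bacteria()].
#' @return 100 * foreground count / total pixels.
#' @export
colonized_fraction <- function(mask) {
  if (length(mask) == 0L) stop("`mask` is empty", call. = FALSE)
  if (!all(mask %in% c(0L, 1L))) stop("`mask` must be binary", call. = FALSE)
  100 * sum(mask == 1L) / length(mask)
}

#' Rotate a frame about a center (bilinear)
#'
#' Inverse-mapped bilinear rotation; pixels mapped from outside the source
#' are filled with `fill` (frame median by default).
#'
#' @param frame numeric matrix.
#' @param degrees rotation angle (counter-clockwise in row/col coordinates).
#' @param center optional (row, col) center; frame center by default.
#' @param fill fill value for out-of-frame samples.
#' @return Rotated matrix of the same shape.
#' @export
rotate_frame <- function(frame, degrees, center = NULL, fill = NULL) {
  if (degrees == 0) return(frame)
  n <- nrow(frame); p <- ncol(frame)
  if (is.null(center)) center <- c((n + 1) / 2, (p + 1) / 2)
  if (is.null(fill)) fill <- stats::median(frame)
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  rr <- rep(seq_len(n), times = p) - center[1]
  cc <- rep(seq_len(p), each = n) - center[2]
  # inverse rotation of target coordinates into the source frame
  sr <- co * rr + si * cc + center[1]
  sc <- -si * rr + co * cc + center[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get_px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= p
    out <- rep(fill, length(ri))
    out[ok] <- frame[cbind(ri[ok], ci[ok])]
    out
  }
  v <- (1 - fr) * (1 - fc) * get_px(r0, c0) +
    (1 - fr) * fc * get_px(r0, c0 + 1) +
    fr * (1 - fc) * get_px(r0 + 1, c0) +
    fr * fc * get_px(r0 + 1, c0 + 1)
  matrix(v, n, p)
}

#' Detect the channel borders by a straight-line Hough transform
#'
#' Thresholds the vertical intensity gradient at a per-frame quantile, then
#' accumulates the edge pixels over near-horizontal line orientations. The
#' two highest-scoring near-parallel lines separated by at least
#' `min_separation_px` are reported as the channel borders.
#'
#' @param frame preprocessed numeric matrix containing two dominant
#'   near-parallel dark lines.
#' @param angle_range_deg half-range of candidate inclinations (default 10).
#' @param angle_step_deg accumulator angle resolution (default 0.5).
#' @param edge_quantile gradient-magnitude quantile defining edge pixels
#'   (default 0.99).
#' @param min_separation_px minimum distance between the two borders
#'   (default 100).
#' @param min_score minimum accumulator count for a line, as a fraction of
#'   the frame width (default 0.25).
#' @return An object of class `channel_geometry`: `border_lines` (data frame
#'   with `angle_deg`, `offset_px`), `inclination_deg`, `width_px`,
#'   `weighted_center` (row, col).
#' @export
detect_channel_borders <- function(frame, angle_range_deg = 10,
                                   angle_step_deg = 0.5,
                                   edge_quantile = 0.99,
                                   min_separation_px = 100,
                                   min_score = 0.25) {
  if (!is.matrix(frame) || nrow(frame) < 5L) {
    stop("`frame` must be a matrix with >= 5 rows", call. = FALSE)
  }
  grad <- abs(diff(frame))
  thr <- stats::quantile(grad, edge_quantile, names = FALSE)
  if (thr <= 0) stop("channel border detection failed: no gradient contrast",
                     call. = FALSE)
  idx <- which(grad >= thr, arr.ind = TRUE)
  rr <- idx[, 1] + 0.5  # edge sits between the differenced rows
  cc <- idx[, 2]
  angles <- seq(-angle_range_deg, angle_range_deg, by = angle_step_deg)
  rho_max <- nrow(frame) + ncol(frame) * sin(angle_range_deg * pi / 180) + 2
  score_needed <- min_score * ncol(frame)
  acc_best <- NULL
  # accumulate per angle; rho = r*cos(a) - c*sin(a) is the line's row
  # intercept axis for near-horizontal lines
  best <- list()
  for (a in angles) {
    th <- a * pi / 180
    rho <- rr * cos(th) - cc * sin(th)
    bins <- round(rho)
    tab <- tabulate(bins - floor(-rho_max) + 1L)
    # 3-bin smoothing tolerates the rho smear of angles between grid steps
    n_t <- length(tab)
    tab <- tab + c(0L, tab[-n_t]) + c(tab[-1L], 0L)
    best[[as.character(a)]] <- tab
  }
  peak_table <- do.call(rbind, lapply(names(best), function(a) {
    tab <- best[[a]]
    keep <- which(tab >= score_needed)
    if (length(keep) == 0L) return(NULL)
    data.frame(angle_deg = as.numeric(a),
               offset_px = keep + floor(-rho_max) - 1L + 1L,
               score = tab[keep])
  }))
  if (is.null(peak_table) || nrow(peak_table) == 0L) {
    stop("channel border detection failed: no line candidates above score ",
         "threshold", call. = FALSE)
  }
  first <- peak_table[which.max(peak_table$score), ]
  cand <- peak_table[abs(peak_table$angle_deg - first$angle_deg) <= 5 &
                       abs(peak_table$offset_px - first$offset_px) >=
                       min_separation_px, ]
  if (nrow(cand) == 0L) {
    stop("channel border detection failed: fewer than two parallel line ",
         "candidates", call. = FALSE)
  }
  second <- cand[which.max(cand$score), ]
  # sub-bin refinement: least-squares line fit through each line's
  # supporting edge pixels removes both the 1 px rho quantization and the
  # 0.5 degree angle quantization of the accumulator
  refine <- function(line) {
    for (win in c(2.2, 1.2)) {  # refit once around the refined line
      th <- line$angle_deg * pi / 180
      rho_px <- rr * cos(th) - cc * sin(th)
      sel <- abs(rho_px - line$offset_px) <= win
      if (sum(sel) < 10L) break
      fit <- stats::lm.fit(cbind(1, cc[sel]), rr[sel])
      ang <- atan(fit$coefficients[2])
      line$angle_deg <- ang * 180 / pi
      # row intercept b0 with slope tan(ang): rho = b0 * cos(ang)
      line$offset_px <- fit$coefficients[1] * cos(ang)
    }
    line
  }
  first <- refine(first)
  second <- refine(second)
  lines <- rbind(first[, c("angle_deg", "offset_px")],
                 second[, c("angle_deg", "offset_px")])
  lines <- lines[order(lines$offset_px), ]
  rownames(lines) <- NULL
  incl <- mean(lines$angle_deg)
  cc_mid <- (ncol(frame) + 1) / 2
  row_at <- function(i) {
    th <- lines$angle_deg[i] * pi / 180
    (lines$offset_px[i] + cc_mid * sin(th)) / cos(th)
  }
  center_row <- (row_at(1) + row_at(2)) / 2
  structure(list(
    border_lines = lines,
    inclination_deg = incl,
    width_px = abs(diff(lines$offset_px)),  # |drho| is perpendicular distance
    weighted_center = c(row = center_row, col = cc_mid)
  ), class = "channel_geometry")
}

#' Rectify a frame and crop to the channel
#'
#' Rotates the frame by minus the detected inclination about the weighted
#' center (making the channel axis horizontal), then crops to the channel
#' plus `margin_px` rows beyond each border. Crops reaching outside the frame
#' are padded with the frame median.
#'
#' @param frame preprocessed numeric matrix.
#' @param geometry a `channel_geometry` from [detect_channel_borders()].
#' @param margin_px rows kept beyond each border line (default 10).
#' @param target_shape optional c(rows, cols) to bilinearly resize the crop
#'   to.
#' @return The rectified, cropped matrix.
#' @export
rectify_and_crop <- function(frame, geometry, margin_px = 6L,
                             target_shape = NULL) {
  if (!inherits(geometry, "channel_geometry")) {
    stop("`geometry` must be a `channel_geometry`", call. = FALSE)
  }
  # a line of inclination a maps to inclination a - d under rotate_frame(, d),
  # so rotating by the detected inclination levels the channel axis
  img <- if (abs(geometry$inclination_deg) > 0.25) {
    rotate_frame(frame, geometry$inclination_deg,
                 center = geometry$weighted_center)
  } else frame
  half <- geometry$width_px / 2
  r1 <- floor(geometry$weighted_center[1] - half) - margin_px
  r2 <- ceiling(geometry$weighted_center[1] + half) + margin_px
  rows <- r1:r2
  fill <- stats::median(img)
  out <- matrix(fill, length(rows), ncol(img))
  ok <- rows >= 1 & rows <= nrow(img)
  out[ok, ] <- img[rows[ok], ]
  if (!is.null(target_shape)) out <- resize_bilinear(out, target_shape)
  out
}

resize_bilinear <- function(m, shape) {
  n <- nrow(m); p <- ncol(m)
  ri <- seq(1, n, length.out = shape[1])
  ci <- seq(1, p, length.out = shape[2])
  r0 <- pmin(floor(ri), n - 1L); c0 <- pmin(floor(ci), p - 1L)
  fr <- ri - r0; fc <- ci - c0
  m00 <- m[r0, c0, drop = FALSE]; m01 <- m[r0, c0 + 1L, drop = FALSE]
  m10 <- m[r0 + 1L, c0, drop = FALSE]; m11 <- m[r0 + 1L, c0 + 1L,
                                                drop = FALSE]
  outer(1 - fr, 1 - fc) * m00 + outer(1 - fr, fc) * m01 +
    outer(fr, 1 - fc) * m10 + outer(fr, fc) * m11
}

#' Growth-phase extraction from a colonized-percentage series
#'
#' Identifies the lag, exponential and stationary phases of a segment growth
#' curve: the offset (robust mean of the pre-growth plateau), the lag end
#' (interpolated time at which the curve first exceeds offset +
#' `rise_margin_pct`), the stationary start (first frame after the rise whose
#' median-smoothed forward difference falls below `derivative_floor_pct`),
#' and the colonization duration (their difference).
#'
#' @param times seconds, one per frame (>= 4).
#' @param colonized_pct percentages from [colonized_fraction()].
#' @param rise_margin_pct rise detection margin above the offset, percentage
#'   points (default 3).
#' @param derivative_floor_pct stationary detection floor, percentage points
#'   per frame (default 0.5).
#' @param smooth_frames window of the running-median derivative smoother
#'   (odd, default 3).
#' @return An object of class `growth_curve`: `times`, `colonized_pct`,
#'   `offset_pct`, `lag_end_s`, `stationary_start_s`,
#'   `colonization_duration_s`, `detected` (FALSE for a lag-only curve, time
#'   fields NA).
#' @export
extract_growth_phases <- function(times, colonized_pct, rise_margin_pct = 3,
                                  derivative_floor_pct = 0.5,
                                  smooth_frames = 3L) {
  n <- length(times)
  if (n < 4L || length(colonized_pct) != n) {
    stop("need >= 4 time points with matching percentages", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing",
                                  call. = FALSE)
  base <- function(k) stats::median(colonized_pct[seq_len(k)])
  offset <- base(min(3L, n))
  rise_idx <- which(colonized_pct > offset + rise_margin_pct)[1]
  if (!is.na(rise_idx) && rise_idx > 1L) {
    offset <- base(rise_idx - 1L)
    rise_idx <- which(colonized_pct > offset + rise_margin_pct)[1]
  }
  out <- list(times = times, colonized_pct = colonized_pct,
              offset_pct = offset, lag_end_s = NA_real_,
              stationary_start_s = NA_real_,
              colonization_duration_s = NA_real_, detected = FALSE)
  class(out) <- "growth_curve"
  if (is.na(rise_idx) || rise_idx == 1L) return(out)
  # sub-frame interpolation of the crossing
  y0 <- colonized_pct[rise_idx - 1L]; y1 <- colonized_pct[rise_idx]
  tcross <- times[rise_idx - 1L] +
    (offset + rise_margin_pct - y0) / (y1 - y0) *
    (times[rise_idx] - times[rise_idx - 1L])
  d <- diff(colonized_pct)
  if (smooth_frames > 1L && length(d) >= smooth_frames) {
    d <- stats::runmed(d, smooth_frames)
  }
  flat <- which(d < derivative_floor_pct)
  flat <- flat[flat >= rise_idx]
  if (length(flat) == 0L) return(out)  # still rising at the end
  stat_idx <- flat[1]
  out$lag_end_s <- tcross
  out$stationary_start_s <- times[stat_idx]
  out$colonization_duration_s <- out$stationary_start_s - out$lag_end_s
  out$detected <- TRUE
  out
}

#' Between-segment lag time
#'
#' Difference of the lag-end times of two segment growth curves (the farther
#' segment minus the reference segment).
#'
#' @param curve_a,curve_b `growth_curve` objects with detected phases.
#' @return Lag difference in seconds.
#' @export
between_segment_lag <- function(curve_a, curve_b) {
  if (!inherits(curve_a, "growth_curve") ||
      !inherits(curve_b, "growth_curve")) {
    stop("inputs must be `growth_curve` objects", call. = FALSE)
  }
  if (!isTRUE(curve_a$detected) || !isTRUE(curve_b$detected)) {
    stop("both curves must have a detected lag phase", call. = FALSE)
  }
  curve_b$lag_end_s - curve_a$lag_end_s
}

#' Overlap width of adjacent segment masks
#'
#' Width (um) of the maximal contiguous column band inside the nominal
#' overlap region where both binarized masks agree on foreground (column
#' foreground fraction above 0.5 in both). The overlap region is the last
#' columns of mask A and the first columns of mask B.
#'
#' @param mask_a,mask_b binary masks of adjacent segments (same pixel scale).
#' @param nominal_overlap_um nominal image overlap (default 100).
#' @param pixel_scale pixels per micrometre (default 4).
#' @return Overlap width in micrometres (0, with a warning, when there is no
#'   overlap region).
#' @export
check_segment_overlap <- function(mask_a, mask_b, nominal_overlap_um = 100,
                                  pixel_scale = 4) {
  px <- min(round(nominal_overlap_um * pixel_scale), ncol(mask_a),
            ncol(mask_b))
  if (px < 1) {
    warning("no overlap region between the masks")
    return(0)
  }
  a <- mask_a[, (ncol(mask_a) - px + 1L):ncol(mask_a), drop = FALSE]
  b <- mask_b[, seq_len(px), drop = FALSE]
  agree <- colMeans(a) > 0.5 & colMeans(b) > 0.5
  if (!any(agree)) return(0)
  runs <- rle(agree)
  max(runs$lengths[runs$values]) / pixel_scale
}

#' Analyze a frame stack end to end
#'
#' The full image pipeline: preprocess every frame, detect the channel
#' borders on the reference frame, rectify and crop all frames, compute the
#' image-set segmentation threshold from the reference frame, segment, and
#' extract growth phases from the colonized-percentage series. Frames whose
#' shape disagrees with the reference are dropped with a warning.
#'
#' @param stack a [generate_image_stack()] result or equivalent `frame_stack`.
#' @param percentile_p segmentation percentile (default 70).
#' @param margin_px crop margin beyond the borders (default 6).
#' @param reference_frame index of the pre-growth reference frame used for
#'   geometry and threshold (default 1).
#' @param return_masks keep the per-frame masks in the result (default
#'   FALSE).
#' @param ... passed to [extract_growth_phases()].
#' @return A list with `geometry`, `threshold`, `colonized_pct`, `times`,
#'   `curve` (a `growth_curve`), and optionally `masks`.
#' @export
analyze_stack <- function(stack, percentile_p = 70, margin_px = 6L,
                          reference_frame = 1L, return_masks = FALSE, ...) {
  if (!inherits(stack, "frame_stack")) {
    stop("`stack` must be a `frame_stack`", call. = FALSE)
  }
  frames <- lapply(stack$frames, preprocess_frame)
  geom <- detect_channel_borders(frames[[reference_frame]])
  crops <- lapply(frames, rectify_and_crop, geometry = geom,
                  margin_px = margin_px)
  thr <- texture_threshold(crops[[reference_frame]], percentile_p)
  masks <- lapply(crops, segment_bacteria, threshold = thr)
  pct <- vapply(masks, colonized_fraction, numeric(1))
  curve <- extract_growth_phases(stack$timestamps, pct, ...)
  out <- list(geometry = geom, threshold = thr, colonized_pct = pct,
              times = stack$timestamps, curve = curve)
  if (return_masks) out$masks <- masks
  out
}
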