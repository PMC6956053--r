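#' Imaging scenario
#'
#' Study conditions for the synthetic time-lapse generator of one
#' microchannel segment: a horizontal channel bounded by two dark wall lines,
#' granular artifact bands flanking the walls (the "image analysis offset"
#' contributed by the borders and cumulative image errors), and a bacterial
#' colonization front that enters at `front_arrival_time_s` and traverses the
#' segment in `colonization_duration_s`, optionally preceded by scouting
#' colonies.
#'
#' @param channel_width_px channel width in pixels (default 240 = 60 um at
#'   4 px/um).
#' @param frame_interval_s seconds between frames (default 600).
#' @param pixel_scale pixels per micrometre (default 4).
#' @param segment_offset_mm distance of the segment from the culture chamber.
#' @param front_arrival_time_s lag before the front enters the segment.
#' @param colonization_duration_s front traversal time (default 3900 s =
#'   65 min).
#' @param border_offset_fraction fraction of the analyzed crop area
#'   contributed by walls and artifact bands, in \[0, 1) (default 0.30).
#' @param scouting_colony_rate expected count of new isolated colonies seeded
#'   ahead of the front per frame (Poisson; default 0.15).
#' @param noise_sd background intensity noise (default 0.02 on a 0–1 scale).
#' @param segment_length_um segment length (default 300 um).
#' @param crop_margin_px pixels beyond each wall included in the analyzed
#'   crop; must match the pipeline's rectification margin (default 6).
#' @param rotation_deg optional rotation applied to every rendered frame
#'   (default 0; used to exercise the rectification).
#' @param damage_mode `"none"` or `"electrode_damage"` (a dark blotch is
#'   rendered over the channel from `damage_time_s` on).
#' @param damage_time_s damage onset, seconds (default Inf).
#' @param seed integer RNG seed.
#' @return An object of class `imaging_scenario`.
#' @export
imaging_scenario <- function(channel_width_px = 240L,
                             frame_interval_s = 600,
                             pixel_scale = 4,
                             segment_offset_mm = 1.5,
                             front_arrival_time_s = 3000,
                             colonization_duration_s = 3900,
                             border_offset_fraction = 0.30,
                             scouting_colony_rate = 0.15,
                             noise_sd = 0.02,
                             segment_length_um = 300,
                             crop_margin_px = 6L,
                             rotation_deg = 0,
                             damage_mode = c("none", "electrode_damage"),
                             damage_time_s = Inf,
                             seed = 1L) {
  damage_mode <- match.arg(damage_mode)
  stopifnot_scalar(channel_width_px, "channel_width_px", positive = TRUE)
  stopifnot_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  stopifnot_scalar(pixel_scale, "pixel_scale", positive = TRUE)
  stopifnot_scalar(colonization_duration_s, "colonization_duration_s",
                   positive = TRUE)
  stopifnot_scalar(front_arrival_time_s, "front_arrival_time_s",
                   finite = FALSE)
  if (border_offset_fraction < 0 || border_offset_fraction >= 1) {
    stop("`border_offset_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (scouting_colony_rate < 0) stop("`scouting_colony_rate` must be >= 0",
                                     call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(
    channel_width_px = as.integer(channel_width_px),
    frame_interval_s = frame_interval_s,
    pixel_scale = pixel_scale,
    segment_offset_mm = segment_offset_mm,
    front_arrival_time_s = front_arrival_time_s,
    colonization_duration_s = colonization_duration_s,
    border_offset_fraction = border_offset_fraction,
    scouting_colony_rate = scouting_colony_rate,
    noise_sd = noise_sd,
    segment_length_um = segment_length_um,
    crop_margin_px = as.integer(crop_margin_px),
    rotation_deg = rotation_deg,
    damage_mode = damage_mode,
    damage_time_s = damage_time_s,
    seed = seed
  ), class = "imaging_scenario")
}

# Rendering constants (0-1 intensity scale).
IMG_BG <- 0.75
IMG_WALL <- 0.08
IMG_TEXTURE_MEAN <- 0.45
IMG_TEXTURE_SD <- 0.22
WALL_PX <- 3L

# Artifact band thickness realizing the border offset fraction. The analyzed
# crop spans channel + walls + 2*margin rows; each wall contributes its own
# 3 px plus ~4 px of edge smear of the 5x5 texture window, so the two bands
# supply the remainder of fraction*crop_height.
artifact_band_px <- function(scenario) {
  crop_h <- scenario$channel_width_px + 2L * WALL_PX +
    2L * scenario$crop_margin_px + 1L
  t_px <- round((scenario$border_offset_fraction * crop_h - 14) / 2)
  max(t_px, 0L)
}

#' Generate a synthetic time-lapse image stack
#'
#' Renders `n_frames` frames at the scenario's frame interval: dark wall
#' lines delimiting the channel, granular artifact bands flanking the walls,
#' a colonization front filling the channel interior between
#' `front_arrival_time_s` and arrival + `colonization_duration_s`, and
#' persisting scouting colonies seeded ahead of the front. Ground truth
#' (per-frame colonized fraction model, event times) is attached.
#'
#' @param scenario an [imaging_scenario()].
#' @param n_frames number of frames (>= 2).
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   numeric matrices in \[0, 1\]), `timestamps`, `pixel_scale`,
#'   `segment_offset_mm`, `geometry` (wall rows, band thickness) and
#'   `ground_truth` (`times`, `fraction_pct`, `progress`, `offset_pct`, ...).
#' @export
generate_image_stack <- function(scenario, n_frames = 15L) {
  if (!inherits(scenario, "imaging_scenario")) {
    stop("`scenario` must be an `imaging_scenario`", call. = FALSE)
  }
  if (n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  W <- as.integer(round(scenario$segment_length_um * scenario$pixel_scale))
  if (W < 10L || scenario$channel_width_px < 10L) {
    stop("scenario dimensions too small to render", call. = FALSE)
  }
  pad <- 20L
  wa <- pad + 1L                                   # wall A rows wa..wa+2
  wb <- wa + scenario$channel_width_px             # wall B rows wb..wb+2
  H <- wb + 2L + pad
  t_px <- artifact_band_px(scenario)
  interior <- (wa + WALL_PX):(wb - 1L)             # channel interior rows
  band_a <- if (t_px > 0) (wa + WALL_PX):(wa + WALL_PX + t_px - 1L) else
    integer(0)
  band_b <- if (t_px > 0) (wb - t_px):(wb - 1L) else integer(0)

  times <- (seq_len(n_frames) - 1L) * scenario$frame_interval_s
  progress <- pmin(pmax((times - scenario$front_arrival_time_s) /
                          scenario$colonization_duration_s, 0), 1)

  with_seed(scenario$seed, {
    frames <- vector("list", n_frames)
    colonies <- data.frame(row = numeric(0), col = numeric(0),
                           r = numeric(0))
    colony_px <- numeric(n_frames)
    n_int <- length(interior) * W
    for (f in seq_len(n_frames)) {
      img <- matrix(IMG_BG + stats::rnorm(H * W, sd = scenario$noise_sd),
                    H, W)
      wall_rows <- c(wa:(wa + 2L), wb:(wb + 2L))
      img[wall_rows, ] <- IMG_WALL +
        stats::rnorm(length(wall_rows) * W, sd = scenario$noise_sd / 2)
      texture <- function(n) {
        pmin(pmax(stats::rnorm(n, IMG_TEXTURE_MEAN, IMG_TEXTURE_SD), 0), 1)
      }
      if (t_px > 0) {
        img[band_a, ] <- texture(length(band_a) * W)
        img[band_b, ] <- texture(length(band_b) * W)
      }
      front_col <- as.integer(floor(progress[f] * W))
      if (front_col > 0L) {
        img[interior, seq_len(front_col)] <-
          texture(length(interior) * front_col)
      }
      # scouting colonies ahead of the front, persisting across frames
      if (scenario$scouting_colony_rate > 0 && progress[f] < 1) {
        n_new <- stats::rpois(1, scenario$scouting_colony_rate)
        if (n_new > 0L && front_col < W - 8L) {
          colonies <- rbind(colonies, data.frame(
            row = stats::runif(n_new, min(interior) + 6, max(interior) - 6),
            col = stats::runif(n_new, front_col + 8, W - 2),
            r = stats::runif(n_new, 3, 6)))
        }
      }
      cpx <- 0
      if (nrow(colonies) > 0L) {
        for (ci in seq_len(nrow(colonies))) {
          if (colonies$col[ci] <= front_col) next  # swallowed by the front
          rr <- colonies$row[ci]; cc <- colonies$col[ci]; r <- colonies$r[ci]
          rows <- max(min(interior), floor(rr - r)):
            min(max(interior), ceiling(rr + r))
          cols <- max(1, floor(cc - r)):min(W, ceiling(cc + r))
          d2 <- outer((rows - rr)^2, (cols - cc)^2, `+`)
          sel <- d2 <= r^2
          if (any(sel)) {
            block <- img[rows, cols, drop = FALSE]
            block[sel] <- texture(sum(sel))
            img[rows, cols] <- block
            cpx <- cpx + sum(sel)
          }
        }
      }
      if (times[f] >= scenario$damage_time_s) {
        # electrode damage: dark blotch across the channel centre
        dcols <- max(1, W %/% 2 - 40):min(W, W %/% 2 + 40)
        img[interior, dcols] <- IMG_WALL +
          stats::rnorm(length(interior) * length(dcols),
                       sd = scenario$noise_sd)
      }
      colony_px[f] <- cpx
      if (scenario$rotation_deg != 0) {
        img <- rotate_frame(img, scenario$rotation_deg)
      }
      frames[[f]] <- img
    }
    covered <- pmin(progress + colony_px / n_int, 1)
    f0 <- scenario$border_offset_fraction
    structure(list(
      frames = frames,
      timestamps = times,
      pixel_scale = scenario$pixel_scale,
      segment_offset_mm = scenario$segment_offset_mm,
      geometry = list(wall_a_row = wa, wall_b_row = wb, rows = H, cols = W,
                      band_px = t_px, wall_px = WALL_PX),
      ground_truth = list(
        times = times,
        progress = progress,
        fraction_pct = 100 * (f0 + (1 - f0) * covered),
        offset_pct = 100 * f0,
        front_arrival_time_s = scenario$front_arrival_time_s,
        colonization_duration_s = scenario$colonization_duration_s,
        colony_px = colony_px
      )
    ), class = "frame_stack")
  })
}
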