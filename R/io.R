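#' Write / read a CV session as CSV
#'
#' Dialect: header `timestamp_s,sweep_id,potential_V,current_A,direction`,
#' UTF-8, '.' decimal separator, one row per applied-potential point. The
#' round trip is lossless to better than 1e-12 relative.
#'
#' @param session a [cv_session] (ground truth is not serialized).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_session <- function(session, path) {
  if (!inherits(session, "cv_session")) {
    stop("`session` must be a `cv_session`", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(session$sweeps, function(s) {
    data.frame(timestamp_s = s$timestamp, sweep_id = s$sweep_id,
               potential_V = s$potential, current_A = s$current,
               direction = s$direction)
  }))
  utils::write.csv(format(rows, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cv_session
#' @param path CSV file produced by [write_cv_session()]; shuffled rows are
#'   reassembled by (timestamp, sweep id, point order).
#' @return For `read_cv_session`: a [cv_session].
#' @export
read_cv_session <- function(path) {
  df <- read_session_csv(path, c("timestamp_s", "sweep_id", "potential_V",
                                 "current_A", "direction"))
  sweeps <- lapply(split(df, df$sweep_id), function(g) {
    g <- g[order(-g$direction, g$direction * g$potential), ]
    structure(list(potential = g$potential_V, current = g$current_A,
                   direction = g$direction, timestamp = g$timestamp_s[1],
                   sweep_id = g$sweep_id[1]),
              class = "voltammogram_sample")
  })
  ord <- order(vapply(sweeps, function(s) s$timestamp, numeric(1)),
               vapply(sweeps, function(s) s$sweep_id, numeric(1)))
  structure(list(sweeps = sweeps[ord], ground_truth = NULL),
            class = "cv_session")
}

#' Write / read an EIS session as CSV
#'
#' Dialect: header `timestamp_s,spectrum_id,frequency_Hz,Zre_ohm,Zim_ohm`,
#' UTF-8, '.' decimal separator, one row per frequency. Lossless to better
#' than 1e-12 relative.
#'
#' @param session an [eis_session].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eis_session <- function(session, path) {
  if (!inherits(session, "eis_session")) {
    stop("`session` must be an `eis_session`", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_along(session$spectra), function(i) {
    s <- session$spectra[[i]]
    data.frame(timestamp_s = s$timestamp, spectrum_id = i,
               frequency_Hz = s$frequency, Zre_ohm = Re(s$Z),
               Zim_ohm = Im(s$Z))
  }))
  utils::write.csv(format(rows, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eis_session
#' @return For `read_eis_session`: an [eis_session].
#' @export
read_eis_session <- function(path) {
  df <- read_session_csv(path, c("timestamp_s", "spectrum_id",
                                 "frequency_Hz", "Zre_ohm", "Zim_ohm"))
  spectra <- lapply(split(df, df$spectrum_id), function(g) {
    g <- g[order(g$frequency_Hz), ]
    structure(list(frequency = g$frequency_Hz,
                   Z = complex(real = g$Zre_ohm, imaginary = g$Zim_ohm),
                   timestamp = g$timestamp_s[1]),
              class = "impedance_sample")
  })
  ord <- order(vapply(spectra, function(s) s$timestamp, numeric(1)))
  spectra <- spectra[ord]
  grids <- vapply(spectra, function(s) length(s$frequency), integer(1))
  if (length(unique(grids)) != 1L) {
    stop("mixed frequency grids in ", path, call. = FALSE)
  }
  structure(list(spectra = spectra, ground_truth = NULL),
            class = "eis_session")
}

read_session_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, fileEncoding = "UTF-8"),
                 error = function(e) {
                   stop("malformed CSV ", path, ": ", conditionMessage(e),
                        call. = FALSE)
                 })
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[cols]))
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  }
  df
}

#' Write / read an image stack as numbered PNGs with a JSON sidecar
#'
#' Frames are stored as 8-bit grayscale PNGs (`frame_0001.png`, ...) plus
#' `stack.json` carrying the timestamps, pixel scale, segment offset and
#' intensity range. Intensities are quantized to 8 bits (ample for the
#' texture segmentation, which is bit-depth invariant).
#'
#' @param stack a `frame_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  if (!inherits(stack, "frame_stack")) {
    stop("`stack` must be a `frame_stack`", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lo <- min(vapply(stack$frames, min, numeric(1)))
  hi <- max(vapply(stack$frames, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  for (i in seq_along(stack$frames)) {
    png::writePNG((stack$frames[[i]] - lo) / scale,
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  meta <- list(timestamps = stack$timestamps,
               pixel_scale = stack$pixel_scale,
               segment_offset_mm = stack$segment_offset_mm,
               intensity_range = c(lo, hi),
               n_frames = length(stack$frames))
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(stack$ground_truth)) {
    jsonlite::write_json(stack$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_stack
#' @return For `read_stack`: a `frame_stack` (without generator geometry).
#' @export
read_stack <- function(dir) {
  meta_path <- file.path(dir, "stack.json")
  if (!file.exists(meta_path)) {
    stop("no stack.json sidecar in ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- file.path(dir, sprintf("frame_%04d.png", seq_len(meta$n_frames)))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) stop("missing frame file: ", missing[1],
                                 call. = FALSE)
  lo <- meta$intensity_range[1]; hi <- meta$intensity_range[2]
  frames <- lapply(files, function(fp) {
    png::readPNG(fp) * (hi - lo) + lo
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  } else NULL
  structure(list(frames = frames, timestamps = meta$timestamps,
                 pixel_scale = meta$pixel_scale,
                 segment_offset_mm = meta$segment_offset_mm,
                 geometry = NULL, ground_truth = gt),
            class = "frame_stack")
}
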