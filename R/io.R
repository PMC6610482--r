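#' Write a fluorescence movie as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 16-bit TIFF pages (one page per frame); the
#' acquisition metadata (frame interval, pixel pitch, stimulation log,
#' seeds) goes to a JSON sidecar next to the TIFF, since TIFF has no
#' standard slot for it.
#'
#' @param movie A `fluorescence_movie`.
#' @param path Output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "fluorescence_movie"))
  d <- dim(movie$frames)
  if (max(movie$frames) > 65535) {
    abort("intensities exceed the 16-bit camera range.",
          class = "atrialmap_io_error")
  }
  pages <- lapply(seq_len(d[1]), function(t) movie$frames[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(
    frame_interval_ms = movie$frame_interval_ms,
    pixel_pitch_um = movie$pixel_pitch_um,
    stim_log = movie$stim_log,
    meta = movie$meta
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fluorescence movie written by [write_movie()]
#'
#' @param path TIFF path with its `.json` sidecar alongside.
#' @return A `fluorescence_movie`.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "atrialmap_io_error")
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0(
      "metadata sidecar not found: ", sidecar,
      " (required keys: frame_interval_ms, pixel_pitch_um, stim_log)"
    ), class = "atrialmap_io_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("frame_interval_ms", "pixel_pitch_um")) {
    if (is.null(meta[[key]])) {
      abort(sprintf("metadata sidecar is missing the field `%s`.", key),
            class = "atrialmap_io_error")
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 0) {
    abort("movie has no frames.", class = "atrialmap_io_error")
  }
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("non-uniform page shapes in TIFF.", class = "atrialmap_io_error")
  }
  H <- dims[1, 1]; W <- dims[2, 1]; Tn <- length(pages)
  frames <- array(0, dim = c(Tn, H, W))
  for (t in seq_len(Tn)) frames[t, , ] <- round(pages[[t]] * 65535)

  stim <- meta$stim_log
  stim_log <- if (is.null(stim) || length(stim) == 0) {
    tibble(onset_ms = numeric(), width_ms = numeric(),
           freq_hz = numeric(), spontaneous = logical())
  } else {
    as_tibble(stim)
  }
  structure(
    list(
      frames = frames,
      frame_interval_ms = meta$frame_interval_ms,
      pixel_pitch_um = meta$pixel_pitch_um,
      stim_log = stim_log,
      meta = meta$meta
    ),
    class = "fluorescence_movie"
  )
}
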