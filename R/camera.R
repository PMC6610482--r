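#' Render a membrane-potential movie as voltage-dye fluorescence
#'
#' Applies the camera model of a negative-polarity voltage-sensitive dye:
#' fluorescence decreases on depolarization,
#' `F(t) = F0 * (1 - gain * Vnorm(t)) + drift(t) + noise`,
#' where `Vnorm` is the normalized membrane potential clipped to `[0, 1]`,
#' `drift(t)` is a polynomial in seconds (photobleaching/illumination
#' drift, camera units), and the noise is additive Gaussian per frame.
#' Background (non-tissue) pixels emit a dim baseline with reduced noise,
#' kept below 10 percent of the foreground maximum. Output intensities are
#' digitized to non-negative integer camera counts.
#'
#' @param vm A [simulate_tissue()] result.
#' @param f0 Diastolic fluorescence, camera counts; must be positive.
#' @param gain Fractional fluorescence drop at full depolarization
#'   (`Vnorm = 1`); must be non-negative.
#' @param drift_coeffs Polynomial drift coefficients, counts per s, s^2,
#'   s^3, ... (no constant term).
#' @param noise_sd Gaussian noise SD, camera counts.
#' @param frame_interval_ms Output frame interval; must be a multiple of
#'   the simulation recording interval (frames are subsampled).
#' @param seed Camera noise seed.
#' @param background_level Background baseline as a fraction of `f0`.
#' @return A `fluorescence_movie`: list with `frames` (T x H x W counts),
#'   `frame_interval_ms`, `pixel_pitch_um`, `stim_log` and provenance
#'   metadata (`meta`).
#' @export
render_fluorescence <- function(vm, f0 = 2000, gain = 0.08,
                                drift_coeffs = c(8, -1.2, 0.06),
                                noise_sd = 0.01 * f0,
                                frame_interval_ms = vm$frame_interval_ms,
                                seed = 1L, background_level = 0.03) {
  stopifnot(inherits(vm, "vm_movie"))
  if (f0 <= 0) abort("`f0` must be positive.", class = "atrialmap_camera_error")
  if (gain < 0) abort("`gain` must be non-negative.", class = "atrialmap_camera_error")

  step <- frame_interval_ms / vm$frame_interval_ms
  if (abs(step - round(step)) > 1e-8 || step < 1) {
    abort("`frame_interval_ms` must be a multiple of the simulation frame interval.",
          class = "atrialmap_camera_error")
  }
  step <- as.integer(round(step))
  d <- dim(vm$vm)
  keep <- seq(1L, d[1], by = step)
  u <- vm$vm[keep, , , drop = FALSE]
  Tn <- length(keep); H <- d[2]; W <- d[3]

  u <- pmin(pmax(u, 0), 1)
  fg <- vm$geometry$excitable
  t_s <- (keep - 1) * vm$frame_interval_ms / 1000
  drift <- drift_poly(t_s, drift_coeffs)

  frames <- array(0, dim = c(Tn, H, W))
  fg_t <- array(rep(as.vector(fg), each = Tn), dim = c(Tn, H, W))
  frames[fg_t] <- f0 * (1 - gain * u[fg_t])
  frames[!fg_t] <- background_level * f0
  frames <- frames + array(drift, dim = c(Tn, H, W)) * ifelse(fg_t, 1, 0.2)
  if (noise_sd > 0) {
    noise <- withr_seed(seed, array(rnorm(Tn * H * W), dim = c(Tn, H, W)))
    frames <- frames + noise * noise_sd * ifelse(fg_t, 1, 0.5)
  }
  frames <- round(pmax(frames, 0))

  structure(
    list(
      frames = frames,
      frame_interval_ms = frame_interval_ms,
      pixel_pitch_um = vm$pixel_pitch_um,
      stim_log = vm$stim_log,
      meta = list(
        geometry_kind = vm$geometry$kind,
        preset = vm$preset,
        f0 = f0, gain = gain, noise_sd = noise_sd,
        drift_coeffs = drift_coeffs,
        camera_seed = as.integer(seed),
        cell_seed = vm$cell_seed,
        jitter_seed = vm$jitter_seed,
        fb_fraction = vm$fb_fraction
      )
    ),
    class = "fluorescence_movie"
  )
}

drift_poly <- function(t_s, coeffs) {
  if (length(coeffs) == 0) return(rep(0, length(t_s)))
  rowSums(outer(t_s, seq_along(coeffs), `^`) *
            matrix(coeffs, length(t_s), length(coeffs), byrow = TRUE))
}

#' @export
print.fluorescence_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<fluorescence_movie> %d frames x %d x %d px @ %g ms, pitch %g um\n",
    d[1], d[2], d[3], x$frame_interval_ms, x$pixel_pitch_um
  ))
  invisible(x)
}
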