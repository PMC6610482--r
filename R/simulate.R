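#' Simulate membrane potential on a tissue geometry
#'
#' Integrates a two-variable excitable medium (activator `u`, recovery
#' `v`) with diffusive coupling over the geometry's excitable mask.
#' Cardiomyocyte pixels follow the Aliev--Panfilov reaction; fibroblast
#' pixels are passive (a leak toward a less-negative rest level, no
#' upstroke) but remain coupled, so they load their neighbours. Field
#' stimulation is a spatially uniform suprathreshold current over the
#' pacing zone for the configured pulse width; spontaneous pacemaking is
#' the same source fired at the preset's intrinsic rate. No-flux boundary
#' conditions apply at all tissue borders.
#'
#' @param geometry A `tissue_geometry`.
#' @param config A [sim_config()].
#' @param cellmap Optional [assign_cells()] map; defaults to all-CM.
#' @return A `vm_movie`: list with `vm` (frames x height x width array of
#'   normalized membrane potential), `frame_interval_ms`,
#'   `pixel_pitch_um`, `stim_log` (tibble of pulse onsets), and the
#'   geometry.
#' @examples
#' g <- recording_window("uniform", pixel_pitch_um = 240)
#' cfg <- sim_config("atrial_like", pacing_hz = 2, duration_ms = 800)
#' vm <- simulate_tissue(g, cfg)
#' dim(vm$vm)
#' @export
simulate_tissue <- function(geometry, config, cellmap = NULL) {
  stopifnot(inherits(geometry, "tissue_geometry"),
            inherits(config, "sim_config"))
  p <- config$params
  check_stability(config, geometry$pixel_pitch_um)

  if (is.null(cellmap)) cellmap <- assign_cells(geometry, 0, seed = 1L)
  type <- cellmap$classes
  if (!all(dim(type) == dim(geometry$excitable))) {
    abort("cell map and geometry dimensions differ.",
          class = "atrialmap_sim_error")
  }

  stim_mask <- geometry$zones == 1L
  if (length(config$pulse_times_ms) > 0 && !any(stim_mask)) {
    abort("pacing requested but the pacing zone is empty.",
          class = "atrialmap_sim_error")
  }

  H <- nrow(type); W <- ncol(type)
  amap <- matrix(p$a, H, W)
  if (p$excitability_sd > 0) {
    jit <- withr_seed(config$jitter_seed, matrix(rnorm(H * W), H, W))
    # 3x3 smoothing sets the heterogeneity scale above single pixels;
    # the x3 factor restores the SD the smoothing removes
    amap <- amap * (1 + 3 * p$excitability_sd * smooth3(jit))
  }
  dmap <- matrix(0, H, W)
  dmap[type > 0L] <- p$D
  dmap[type == 2L] <- p$D * p$fb$coupling

  dx <- geometry$pixel_pitch_um / 1000
  record_every <- round(config$frame_interval_ms / p$dt_ms)
  n_steps <- round(config$duration_ms / p$dt_ms)

  vm <- sim_core(
    type, amap, dmap,
    p$k, p$eps0, p$mu1, p$mu2, p$time_scale,
    p$fb$g_leak, p$fb$u_rest,
    dx, p$dt_ms, n_steps, record_every,
    stim_mask, as.numeric(config$pulse_times_ms),
    p$stim$width_ms, p$stim$amp
  )

  structure(
    list(
      vm = vm,
      frame_interval_ms = config$frame_interval_ms,
      pixel_pitch_um = geometry$pixel_pitch_um,
      stim_log = tibble(
        onset_ms = as.numeric(config$pulse_times_ms),
        width_ms = p$stim$width_ms,
        freq_hz = if (config$spontaneous) NA_real_ else config$pacing_hz,
        spontaneous = config$spontaneous
      ),
      geometry = geometry,
      preset = p$preset,
      jitter_seed = config$jitter_seed,
      cell_seed = cellmap$seed,
      fb_fraction = cellmap$fb_fraction
    ),
    class = "vm_movie"
  )
}

# mean over the 3x3 neighbourhood, shrinking at the borders
smooth3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  s <- matrix(0, H, W)
  n <- matrix(0, H, W)
  for (di in -1:1) {
    for (dj in -1:1) {
      ri <- max(1, 1 + di):min(H, H + di)
      rj <- max(1, 1 + dj):min(W, W + dj)
      si <- max(1, 1 - di):min(H, H - di)
      sj <- max(1, 1 - dj):min(W, W - dj)
      s[si, sj] <- s[si, sj] + m[ri, rj]
      n[si, sj] <- n[si, sj] + 1
    }
  }
  s / n
}

#' @export
print.vm_movie <- function(x, ...) {
  d <- dim(x$vm)
  cat(sprintf(
    "<vm_movie> %d frames x %d x %d px @ %g ms (%s, %s)\n",
    d[1], d[2], d[3], x$frame_interval_ms, x$preset,
    if (isTRUE(x$stim_log$spontaneous[1])) "spontaneous" else
      sprintf("paced %.1f Hz", x$stim_log$freq_hz[1])
  ))
  invisible(x)
}
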