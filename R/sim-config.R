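#' Simulation presets
#'
#' Named parameter sets for the two-variable excitable-medium model
#' (an Aliev--Panfilov reaction with diffusive coupling). The
#' `atrial_like` and `control` presets are calibrated so that the full
#' pipeline (simulation, camera rendering, signal conditioning, metrics)
#' recovers the spontaneous cycle length and Bazett-corrected APD90 of
#' ATRA-treated (atrial-like) and untreated (control) hiPSC-CM
#' monolayers. The calibration constants live here, in the preset, not
#' in the model code.
#'
#' Parameters: `k`, `a`, `eps0`, `mu1`, `mu2` are the dimensionless
#' reaction constants (`a` is the excitation threshold); `time_scale`
#' converts one dimensionless time unit to milliseconds; `D` is the
#' diffusion coefficient (mm^2/ms); `excitability_sd` is the relative SD
#' of smoothed per-pixel jitter on `a` (per-preparation heterogeneity);
#' `fb` holds the passive fibroblast parameters (leak conductance, rest
#' level on the normalized potential scale, and the coupling factor
#' applied to `D` at fibroblast pixels); `spontaneous_cl_ms` is the
#' intrinsic pacemaking interval; `stim` gives the field-stimulation
#' pulse (suprathreshold amplitude on the dimensionless current scale,
#' width ms).
#'
#' @param preset `"atrial_like"` or `"control"`.
#' @return Named list of model parameters.
#' @export
sim_preset <- function(preset = c("atrial_like", "control")) {
  preset <- match.arg(preset)
  base <- list(
    k = 8,
    D = 0.05,
    excitability_sd = 0.01,
    fb = list(g_leak = 0.35, u_rest = 0.1, coupling = 0.6),
    stim = list(amp = 3, width_ms = 10),
    dt_ms = 0.05
  )
  cal <- switch(preset,
    atrial_like = list(
      a = 0.16, eps0 = 0.002, mu1 = 0.10, mu2 = 0.3,
      time_scale = 5.09, spontaneous_cl_ms = 402.5
    ),
    # slower recovery kinetics: long plateau sustained at a high
    # APD-to-cycle-length duty without capture failure
    control = list(
      a = 0.14, eps0 = 0.002, mu1 = 0.06, mu2 = 0.1,
      time_scale = 12.05, spontaneous_cl_ms = 927.6
    )
  )
  c(base, cal, list(preset = preset))
}

#' Build a simulation configuration
#'
#' Combines a preset with a pacing protocol, duration and sampling. With
#' `pacing_hz = NULL` the tissue beats spontaneously: the pacemaking site
#' (the pacing zone) fires at the preset's intrinsic cycle length. With a
#' pacing frequency, field stimulation is applied as a spatially uniform
#' suprathreshold current over the pacing zone for the pulse width.
#'
#' @param preset Preset name or a list from [sim_preset()].
#' @param pacing_hz Pacing frequency in Hz, `NULL` for spontaneous
#'   beating at the preset rate, or `0` to disable every source (a
#'   quiescent run).
#' @param duration_ms Total simulated duration, ms.
#' @param frame_interval_ms Recording interval of the membrane-potential
#'   movie, ms (5 or 10 by default elsewhere in the pipeline).
#' @param start_ms Onset of the first pulse, ms.
#' @param jitter_seed Seed for the per-preparation excitability jitter.
#' @param overrides Named list of preset fields to replace.
#' @return A `sim_config` list; `pulse_times_ms` holds the stimulus log.
#' @export
sim_config <- function(preset = "atrial_like", pacing_hz = NULL,
                       duration_ms = 10000, frame_interval_ms = 10,
                       start_ms = 10, jitter_seed = 1L,
                       overrides = list()) {
  p <- if (is.character(preset)) sim_preset(preset) else preset
  if (length(overrides)) p[names(overrides)] <- overrides
  if (!is.null(pacing_hz) && pacing_hz < 0) {
    abort("`pacing_hz` must be non-negative.", class = "atrialmap_config_error")
  }
  pulse_times <- if (!is.null(pacing_hz) && pacing_hz == 0) {
    numeric(0)
  } else {
    period <- if (is.null(pacing_hz)) p$spontaneous_cl_ms else 1000 / pacing_hz
    seq(start_ms, duration_ms - p$stim$width_ms, by = period)
  }
  cfg <- list(
    params = p,
    pacing_hz = pacing_hz,
    spontaneous = is.null(pacing_hz),
    pulse_times_ms = pulse_times,
    duration_ms = duration_ms,
    frame_interval_ms = frame_interval_ms,
    jitter_seed = as.integer(jitter_seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Explicit stability check for a configuration on a geometry
#'
#' The forward-Euler scheme requires the diffusive bound
#' `dt <= dx^2 / (4 D)` and a reaction bound set by the model stiffness
#' (`dt <= time_scale / (2 k)`); configurations violating either are
#' rejected before stepping.
#'
#' @param config A [sim_config()].
#' @param pixel_pitch_um Grid step, micrometres.
#' @return Invisibly `TRUE`; aborts when unstable.
#' @export
check_stability <- function(config, pixel_pitch_um) {
  p <- config$params
  dx <- pixel_pitch_um / 1000
  bound_diff <- dx^2 / (4 * p$D)
  bound_react <- p$time_scale / (2 * p$k)
  if (p$dt_ms > min(bound_diff, bound_react)) {
    abort(sprintf(
      "unstable configuration: dt = %g ms exceeds the stability bound %g ms",
      p$dt_ms, min(bound_diff, bound_react)
    ), class = "atrialmap_stability_error")
  }
  invisible(TRUE)
}

#' Pacing sweep grid
#'
#' Strictly increasing frequencies in 0.5 Hz increments, the protocol
#' used for the conduction-success experiments.
#'
#' @param from,to Sweep limits, Hz.
#' @param by Increment, Hz.
#' @return Numeric vector of frequencies.
#' @export
pacing_sweep <- function(from = 5, to = 7, by = 0.5) {
  if (by <= 0 || to < from) {
    abort("pacing frequencies must be strictly increasing.",
          class = "atrialmap_config_error")
  }
  seq(from, to, by = by)
}
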