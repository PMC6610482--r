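#' Deterministic per-component seeds from one master seed
#'
#' One master seed reproducibly spawns the seeds of every stochastic
#' component (cell placement, excitability jitter, camera noise), so
#' stages can be rerun independently.
#'
#' @param master Master seed (integer).
#' @param n Number of seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
spawn_seeds <- function(master, n) {
  withr_seed(master, sample.int(.Machine$integer.max, n))
}

#' Assemble a simulated preparation
#'
#' A preparation is one plated sample: a recording-window geometry, a
#' cell map at the requested fibroblast fraction, and the per-preparation
#' seeds spawned from its own seed.
#'
#' @param kind `"isthmus"` or `"uniform"`.
#' @param fb_fraction Fibroblast fraction.
#' @param preset Simulation preset name.
#' @param seed Preparation seed.
#' @param strand_width_mm Optional strand width override, mm.
#' @param pixel_pitch_um Grid pitch, micrometres.
#' @return A `preparation` list.
#' @export
simulate_preparation <- function(kind = c("isthmus", "uniform"),
                                 fb_fraction = 0, preset = "atrial_like",
                                 seed = 1L, strand_width_mm = NULL,
                                 pixel_pitch_um = 120) {
  kind <- match.arg(kind)
  seeds <- spawn_seeds(seed, 3)
  geometry <- recording_window(kind, strand_width_mm = strand_width_mm,
                               pixel_pitch_um = pixel_pitch_um)
  cellmap <- assign_cells(geometry, fb_fraction, seed = seeds[1])
  structure(
    list(
      geometry = geometry, cellmap = cellmap, preset = preset,
      kind = kind, fb_fraction = fb_fraction, seed = as.integer(seed),
      jitter_seed = seeds[2], camera_seed = seeds[3]
    ),
    class = "preparation"
  )
}

#' Record one epoch of a preparation as a fluorescence movie
#'
#' Simulates the membrane potential (paced or spontaneous) and renders it
#' through the camera model.
#'
#' @param prep A [simulate_preparation()] object.
#' @param pacing_hz Pacing frequency, Hz, or `NULL` for spontaneous.
#' @param duration_ms Epoch duration, ms.
#' @param frame_interval_ms Camera frame interval, ms (5 or 10).
#' @param camera Named list of [render_fluorescence()] overrides.
#' @return A `fluorescence_movie`.
#' @export
record_preparation <- function(prep, pacing_hz = NULL, duration_ms = 3000,
                               frame_interval_ms = 10, camera = list()) {
  stopifnot(inherits(prep, "preparation"))
  cfg <- sim_config(prep$preset, pacing_hz = pacing_hz,
                    duration_ms = duration_ms,
                    frame_interval_ms = frame_interval_ms,
                    jitter_seed = prep$jitter_seed)
  vm <- simulate_tissue(prep$geometry, cfg, prep$cellmap)
  args <- c(list(vm = vm, seed = prep$camera_seed), camera)
  do.call(render_fluorescence, args)
}

#' Conduction outcomes over a pacing-frequency sweep
#'
#' For each frequency: simulate an epoch, render, condition, extract the
#' strand and distal ROI traces, and classify the outcome over the
#' analysis window (the final part of the epoch, skipping the initial
#' adaptation).
#'
#' @param prep A [simulate_preparation()] object.
#' @param freqs_hz Increasing pacing frequencies, Hz.
#' @param epoch_ms Epoch length per frequency, ms.
#' @param skip_ms Adaptation time dropped from the start, ms.
#' @param frame_interval_ms Camera frame interval, ms.
#' @param latency_ms Stimulus-to-beat matching bound, ms.
#' @param poly_order Drift-correction order.
#' @return Tibble: one row per frequency with the classification columns
#'   of [classify_conduction()] plus `prep`, `freq_hz`.
#' @export
sweep_conduction <- function(prep, freqs_hz, epoch_ms = 3000,
                             skip_ms = 1000, frame_interval_ms = 10,
                             latency_ms = 120, poly_order = 3) {
  stopifnot(inherits(prep, "preparation"))
  rois <- conduction_rois(prep$geometry)
  purrr::map_dfr(freqs_hz, function(f) {
    movie <- record_preparation(prep, pacing_hz = f, duration_ms = epoch_ms,
                                frame_interval_ms = frame_interval_ms)
    cond <- preprocess_movie(movie, poly_order = poly_order)
    traces <- extract_traces(cond, rois)
    window <- c(skip_ms, epoch_ms)
    stim <- movie$stim_log$onset_ms
    stim <- stim[stim >= window[1] & stim <= window[2] - latency_ms]
    beats_of <- function(id) {
      df <- traces[traces$roi == id & traces$t_ms >= window[1] &
                     traces$t_ms <= window[2], ]
      detect_beats(df)$t_peak_ms
    }
    strand_id <- rois$roi[rois$role == "strand"]
    distal_ids <- rois$roi[rois$role == "distal"]
    out <- classify_conduction(
      stim_times_ms = stim,
      strand_beats_ms = beats_of(strand_id),
      distal_beats_ms = lapply(distal_ids, beats_of),
      latency_ms = latency_ms,
      distal_y_mm = rois$y_mm[rois$role == "distal"]
    )
    mutate(out, prep = prep$seed, freq_hz = f, .before = 1)
  })
}

#' Spontaneous OAP parameters of a preparation
#'
#' Records a spontaneous epoch, conditions it, places ROIs along the
#' conduction axis and summarizes the OAP parameters.
#'
#' @param prep A [simulate_preparation()] object.
#' @param duration_ms Recording length, ms.
#' @param frame_interval_ms Camera frame interval, ms.
#' @param n_rois,n_beats ROIs placed and beats averaged.
#' @param poly_order Drift-correction order.
#' @return An [summarize_oap()] object.
#' @export
measure_oap <- function(prep, duration_ms = 10000, frame_interval_ms = 5,
                        n_rois = 5, n_beats = 5, poly_order = 3) {
  movie <- record_preparation(prep, pacing_hz = NULL,
                              duration_ms = duration_ms,
                              frame_interval_ms = frame_interval_ms)
  cond <- preprocess_movie(movie, poly_order = poly_order)
  rois <- place_rois(cond, n = n_rois)
  traces <- extract_traces(cond, rois)
  summarize_oap(traces, n_beats = n_beats)
}

#' Run configuration for a full reproducible study
#'
#' Serializable description of a multi-preparation experiment: groups of
#' preparations (kind, fibroblast fraction, number), the pacing sweep,
#' processing options, and the master seed from which all preparation
#' seeds are spawned.
#'
#' @param groups Tibble with `group`, `kind`, `fb_fraction`, `n_preps`.
#' @param freqs_hz Pacing sweep.
#' @param preset Simulation preset name.
#' @param master_seed Master seed.
#' @param epoch_ms,frame_interval_ms,poly_order,latency_ms Processing
#'   options, as in [sweep_conduction()].
#' @param pixel_pitch_um Simulation grid pitch, micrometres.
#' @return A `run_config` list.
#' @export
run_config <- function(groups, freqs_hz = pacing_sweep(5, 7),
                       preset = "atrial_like", master_seed = 1L,
                       epoch_ms = 3000, frame_interval_ms = 10,
                       poly_order = 3, latency_ms = 120,
                       pixel_pitch_um = 120) {
  stopifnot(all(c("group", "kind", "fb_fraction", "n_preps") %in%
                  names(groups)))
  cfg <- list(
    groups = as_tibble(groups), freqs_hz = freqs_hz, preset = preset,
    master_seed = as.integer(master_seed), epoch_ms = epoch_ms,
    frame_interval_ms = frame_interval_ms, poly_order = poly_order,
    latency_ms = latency_ms, pixel_pitch_um = pixel_pitch_um
  )
  class(cfg) <- "run_config"
  cfg
}

#' Execute a run configuration
#'
#' Runs every preparation of every group through the sweep, tabulates the
#' success rates, and (optionally) writes `outcomes.csv`,
#' `success_table.csv` and a JSON run log with the configuration, seeds
#' and a config hash. Output numbers use fixed formatting (three decimals
#' for ms, one for percentages), so repeated runs of the same
#' configuration produce byte-identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `outcomes`, `success`, and the paths written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  prep_seeds <- spawn_seeds(config$master_seed,
                            sum(config$groups$n_preps))
  k <- 0L
  outcomes <- purrr::pmap_dfr(
    config$groups,
    function(group, kind, fb_fraction, n_preps) {
      purrr::map_dfr(seq_len(n_preps), function(i) {
        k <<- k + 1L
        prep <- simulate_preparation(
          kind = kind, fb_fraction = fb_fraction,
          preset = config$preset, seed = prep_seeds[k],
          pixel_pitch_um = config$pixel_pitch_um
        )
        out <- sweep_conduction(
          prep, config$freqs_hz, epoch_ms = config$epoch_ms,
          frame_interval_ms = config$frame_interval_ms,
          latency_ms = config$latency_ms, poly_order = config$poly_order
        )
        mutate(out, group = group, prep = paste0(group, "_", i), .before = 1)
      })
    }
  )
  success <- success_table(outcomes)

  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p1 <- file.path(out_dir, "outcomes.csv")
    readr::write_csv(outcomes, p1)
    p2 <- file.path(out_dir, "success_table.csv")
    st <- success
    st$success_rate <- sprintf("%.1f", st$success_rate)
    readr::write_csv(st, p2)
    p3 <- file.path(out_dir, "run_log.json")
    jsonlite::write_json(
      list(
        config = unclass(config),
        config_hash = rlang::hash(unclass(config)),
        prep_seeds = prep_seeds,
        package_version = as.character(utils::packageVersion("atrialmap"))
      ),
      p3, auto_unbox = TRUE, digits = NA
    )
    paths <- c(outcomes = p1, success = p2, log = p3)
  }
  list(outcomes = outcomes, success = success, paths = paths)
}
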