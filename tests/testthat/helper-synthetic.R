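# Fixtures are built in code: small movies, analytic traces, and cheap
# simulated preparations shared across test files.

make_movie <- function(frames, frame_interval_ms = 10, pixel_pitch_um = 120,
                       stim_log = NULL) {
  if (is.null(stim_log)) {
    stim_log <- tibble::tibble(onset_ms = numeric(), width_ms = numeric(),
                               freq_hz = numeric(), spontaneous = logical())
  }
  structure(
    list(frames = frames, frame_interval_ms = frame_interval_ms,
         pixel_pitch_um = pixel_pitch_um, stim_log = stim_log,
         meta = list()),
    class = "fluorescence_movie"
  )
}

make_cond <- function(dff, frame_interval_ms = 10, mask = NULL,
                      pixel_pitch_um = 120) {
  d <- dim(dff)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  structure(
    list(dff = dff, frame_interval_ms = frame_interval_ms,
         pixel_pitch_um = pixel_pitch_um,
         stim_log = tibble::tibble(), mask = mask,
         provenance = list(steps = character())),
    class = "conditioned_movie"
  )
}

# triangular OAP: flat baseline, one-frame upstroke to 1 at t = t_up,
# linear repolarization to 0 over `fall_ms`
tri_trace <- function(t_up = 100, fall_ms = 300, dt = 1, total = 700) {
  t <- seq(0, total, by = dt)
  v <- numeric(length(t))
  ramp <- t >= t_up & t <= t_up + fall_ms
  v[ramp] <- 1 - (t[ramp] - t_up) / fall_ms
  tibble::tibble(t_ms = t, value = v)
}

# periodic train of smooth OAP-like bumps with known period
bump_train <- function(period_ms = 1000, n = 6, dt = 5, width_ms = 120,
                       amp = 1) {
  t <- seq(0, period_ms * n, by = dt)
  v <- numeric(length(t))
  for (k in seq_len(n)) {
    tc <- (k - 0.5) * period_ms
    v <- v + amp * exp(-((t - tc) / width_ms)^2)
  }
  tibble::tibble(t_ms = t, value = v)
}

# small uniform-window preparation at coarse pitch for fast simulations
small_prep <- function(kind = "uniform", fb_fraction = 0, seed = 1,
                       pitch = 240) {
  simulate_preparation(kind, fb_fraction, "atrial_like", seed = seed,
                       pixel_pitch_um = pitch)
}

# flatten a T x H x W array and select the pixels of a 2D logical mask
px <- function(frames, mask) {
  matrix(frames, dim(frames)[1], length(mask))[, as.vector(mask), drop = FALSE]
}
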