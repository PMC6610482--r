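#' Background mask from signal intensity
#'
#' A pixel is analyzable when its maximum intensity over time reaches the
#' threshold, defined as 10 percent of the highest signal intensity within
#' the field (boundary inclusive). Masked-out pixels are excluded from all
#' downstream statistics.
#'
#' @param movie A `fluorescence_movie`.
#' @param threshold_frac Threshold as a fraction of the field maximum.
#' @return A `pixel_mask`: list with the logical `mask` and the
#'   `threshold` in camera units.
#' @export
mask_background <- function(movie, threshold_frac = 0.10) {
  stopifnot(inherits(movie, "fluorescence_movie"))
  peak <- pixel_max(movie$frames)
  global_max <- max(peak)
  if (global_max <= 0) {
    abort("no foreground: the movie is identically zero.",
          class = "atrialmap_preprocess_error")
  }
  thr <- threshold_frac * global_max
  structure(list(mask = peak >= thr, threshold = thr), class = "pixel_mask")
}

pixel_max <- function(frames) apply(frames, c(2, 3), max)

#' Fractional fluorescence change
#'
#' Per masked-in pixel, `dF/F(t) = (F(t) - F0) / F0` with `F0` the
#' per-pixel 90th percentile of raw intensity over time. Diastole is
#' bright under a negative-polarity dye and occupies most frames, so a
#' high percentile is a drift-robust diastolic baseline.
#'
#' @param movie A `fluorescence_movie`.
#' @param mask A [mask_background()] result.
#' @param baseline_prob Percentile used for `F0`.
#' @return A `conditioned_movie` with `dff` (T x H x W, `NA` off-mask)
#'   and a provenance record.
#' @export
compute_dff <- function(movie, mask, baseline_prob = 0.9) {
  stopifnot(inherits(movie, "fluorescence_movie"),
            inherits(mask, "pixel_mask"))
  if (!any(mask$mask)) {
    abort("mask is empty.", class = "atrialmap_preprocess_error")
  }
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, d[1], d[2] * d[3])
  keep <- as.vector(mask$mask)
  f0 <- rep(NA_real_, d[2] * d[3])
  f0[keep] <- apply(flat[, keep, drop = FALSE], 2, quantile,
                    probs = baseline_prob, names = FALSE)
  if (any(f0[keep] <= 0)) {
    abort("non-positive baseline F0 at a masked-in pixel.",
          class = "atrialmap_preprocess_error")
  }
  dff <- sweep(sweep(flat, 2, f0, `-`), 2, f0, `/`)
  dff[, !keep] <- NA_real_
  new_conditioned(
    array(dff, d), movie, mask,
    steps = c("mask_background", "dff"),
    baseline_prob = baseline_prob
  )
}

new_conditioned <- function(dff, source, mask, steps, ...) {
  prov <- if (inherits(source, "conditioned_movie")) source$provenance else
    list(threshold = mask$threshold)
  prov <- utils::modifyList(prov, list(...))
  prov$steps <- steps
  structure(
    list(
      dff = dff,
      frame_interval_ms = source$frame_interval_ms,
      pixel_pitch_um = source$pixel_pitch_um,
      stim_log = source$stim_log,
      mask = mask$mask,
      provenance = prov
    ),
    class = "conditioned_movie"
  )
}

#' 3 x 3 uniform spatial binning
#'
#' Each masked-in pixel is replaced by the unweighted mean of the
#' masked-in pixels in its 3 x 3 neighbourhood; at mask edges the mean
#' runs over the valid neighbours only (no zero padding), which avoids
#' rim artifacts.
#'
#' @param cond A `conditioned_movie`.
#' @return The binned `conditioned_movie`.
#' @export
spatial_bin <- function(cond) {
  stopifnot(inherits(cond, "conditioned_movie"))
  d <- dim(cond$dff)
  Tn <- d[1]; H <- d[2]; W <- d[3]
  mask <- cond$mask
  x <- cond$dff
  x[is.na(x)] <- 0
  acc <- array(0, d)
  cnt <- matrix(0, H, W)
  for (di in -1:1) {
    for (dj in -1:1) {
      ri <- max(1, 1 + di):min(H, H + di)
      rj <- max(1, 1 + dj):min(W, W + dj)
      si <- max(1, 1 - di):min(H, H - di)
      sj <- max(1, 1 - dj):min(W, W - dj)
      m_src <- mask[ri, rj, drop = FALSE]
      acc[, si, sj] <- acc[, si, sj, drop = FALSE] +
        x[, ri, rj, drop = FALSE] * array(rep(m_src, each = Tn),
                                          c(Tn, length(si), length(sj)))
      cnt[si, sj] <- cnt[si, sj, drop = FALSE] + m_src
    }
  }
  out <- acc / array(rep(cnt, each = Tn), d)
  out_flat <- matrix(out, Tn, H * W)
  out_flat[, !as.vector(mask)] <- NA_real_
  new_conditioned(array(out_flat, d), cond, list(mask = mask),
                  steps = c(cond$provenance$steps, "spatial_bin"))
}

#' Signal inversion
#'
#' The dye signal decreases on depolarization; negation turns the
#' downward deflection into an upright optical action potential.
#'
#' @param cond A `conditioned_movie`.
#' @return The inverted `conditioned_movie`.
#' @export
invert_signal <- function(cond) {
  stopifnot(inherits(cond, "conditioned_movie"))
  new_conditioned(-cond$dff, cond, list(mask = cond$mask),
                  steps = c(cond$provenance$steps, "invert"))
}

#' FFT low-pass with a hard cutoff at one tenth of the sampling rate
#'
#' Per pixel, the discrete Fourier coefficients at frequencies strictly
#' above `fs / 10` (with `fs = 1000 / frame_interval_ms` Hz) are zeroed
#' and the real part of the inverse transform is returned. This is a hard
#' bin cutoff over the full-length DFT, not a windowed filter.
#'
#' @param cond A `conditioned_movie`, or a numeric trace when
#'   `frame_interval_ms` is given.
#' @param frame_interval_ms Sampling interval for the trace form, ms.
#' @return Same shape as the input.
#' @export
fft_lowpass <- function(cond, frame_interval_ms = NULL) {
  if (is.numeric(cond)) {
    return(as.numeric(fft_lowpass_mat(cbind(cond), frame_interval_ms)))
  }
  stopifnot(inherits(cond, "conditioned_movie"))
  d <- dim(cond$dff)
  flat <- matrix(cond$dff, d[1], d[2] * d[3])
  keep <- as.vector(cond$mask)
  flat[, keep] <- fft_lowpass_mat(flat[, keep, drop = FALSE],
                                  cond$frame_interval_ms)
  new_conditioned(
    array(flat, d), cond, list(mask = cond$mask),
    steps = c(cond$provenance$steps, "fft_lowpass"),
    cutoff_hz = 100 / cond$frame_interval_ms
  )
}

fft_lowpass_mat <- function(m, frame_interval_ms) {
  n <- nrow(m)
  if (n < 8) {
    abort("fft_lowpass needs at least 8 frames.",
          class = "atrialmap_preprocess_error")
  }
  fs <- 1000 / frame_interval_ms
  cutoff <- fs / 10
  freq <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  zero <- freq > cutoff * (1 + 1e-12)
  co <- mvfft(m)
  co[zero, ] <- 0
  Re(mvfft(co, inverse = TRUE)) / n
}

#' Polynomial drift correction
#'
#' Fits a polynomial of the given order to the running diastolic baseline
#' of each trace and subtracts it. Baseline samples are the
#' lowest-residual quartile within each of several time windows (once the
#' signal is upright, beats sit above the baseline and diastole below),
#' refined over a few fit-and-reselect iterations; the windowing keeps
#' the selection spread over the whole record. Exact polynomial inputs
#' are recovered exactly, since any subset of points on a polynomial
#' determines it.
#'
#' @param x A `conditioned_movie` or a numeric trace.
#' @param order Polynomial order (`>= 0`).
#' @param iterations Baseline-selection refits.
#' @return Same shape as the input, with the fitted baseline removed.
#' @export
detrend_poly <- function(x, order = 3, iterations = 3) {
  if (is.numeric(x)) return(detrend_vec(x, order, iterations))
  stopifnot(inherits(x, "conditioned_movie"))
  d <- dim(x$dff)
  flat <- matrix(x$dff, d[1], d[2] * d[3])
  keep <- which(as.vector(x$mask))
  for (j in keep) flat[, j] <- detrend_vec(flat[, j], order, iterations)
  new_conditioned(
    array(flat, d), x, list(mask = x$mask),
    steps = c(x$provenance$steps, "detrend_poly"),
    poly_order = order,
    baseline_rule = "lowest-quartile residuals, iterative"
  )
}

detrend_vec <- function(v, order, iterations = 3) {
  n <- length(v)
  if (order < 0) abort("`order` must be >= 0.", class = "atrialmap_preprocess_error")
  if (n <= order + 1) {
    abort("trace too short for the requested polynomial order.",
          class = "atrialmap_preprocess_error")
  }
  t <- seq_len(n) / n
  basis <- outer(t, 0:order, `^`)
  # running baseline: the lowest-residual quartile within each of several
  # time windows, so the selection always spans the record and the
  # polynomial never extrapolates
  nw <- min(8L, max(1L, n %/% 16L))
  windows <- split(seq_len(n), cut(seq_len(n), nw, labels = FALSE))
  base <- rep(0, n)
  eps <- 1e-12 * max(1, diff(range(v)))
  for (it in seq_len(iterations)) {
    res <- v - base
    sel <- unlist(lapply(windows, function(idx) {
      idx[res[idx] <= quantile(res[idx], 0.25, names = FALSE) + eps]
    }), use.names = FALSE)
    if (length(sel) <= order + 1) break
    fit <- .lm.fit(basis[sel, , drop = FALSE], v[sel])
    if (fit$rank < order + 1) {
      abort("degenerate polynomial fit (rank-deficient basis).",
            class = "atrialmap_preprocess_error")
    }
    base <- as.vector(basis %*% fit$coefficients)
  }
  v - base
}

#' Full conditioning chain
#'
#' Applies the processing chain in its fixed order: background masking,
#' dF/F, 3 x 3 uniform binning, inversion, FFT low-pass at one tenth of
#' the sampling frequency, then polynomial drift correction. The
#' provenance record of the result lists the steps in the order applied.
#'
#' @param movie A `fluorescence_movie`.
#' @param poly_order Drift-correction polynomial order.
#' @return A `conditioned_movie`.
#' @examples
#' \donttest{
#' g <- recording_window("uniform", pixel_pitch_um = 240)
#' vm <- simulate_tissue(g, sim_config(pacing_hz = 2, duration_ms = 1500))
#' mov <- render_fluorescence(vm, seed = 1)
#' cond <- preprocess_movie(mov)
#' cond$provenance$steps
#' }
#' @export
preprocess_movie <- function(movie, poly_order = 3) {
  mask <- mask_background(movie)
  cond <- compute_dff(movie, mask)
  cond <- spatial_bin(cond)
  cond <- invert_signal(cond)
  cond <- fft_lowpass(cond)
  detrend_poly(cond, order = poly_order)
}

#' @export
print.conditioned_movie <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf(
    "<conditioned_movie> %d frames x %d x %d px @ %g ms\n  steps: %s\n",
    d[1], d[2], d[3], x$frame_interval_ms,
    paste(x$provenance$steps, collapse = " -> ")
  ))
  invisible(x)
}
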