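#' Detect beats in a conditioned OAP trace
#'
#' Peaks are local maxima with prominence of at least
#' `prominence_frac` of the trace's amplitude range and a minimum
#' separation of `min_separation_ms` (the higher peak wins a conflict).
#' The prominence rule rejects residual filtered noise while admitting
#' pacing rates up to 7 Hz (period about 143 ms). The average cycle
#' length is the mean of consecutive peak-to-peak intervals; with fewer
#' than two peaks it is undefined (`NA`) rather than an error.
#'
#' @param trace Tibble with `t_ms` and `value` (one ROI), or a numeric
#'   vector with `frame_interval_ms` supplied.
#' @param frame_interval_ms Sampling interval for the vector form.
#' @param prominence_frac Prominence threshold as a fraction of the
#'   trace's range.
#' @param min_separation_ms Minimum peak separation, ms.
#' @return Tibble of beats (`beat`, `t_peak_ms`, `peak_value`,
#'   `prominence`) with the average cycle length in attribute `cl_ms`.
#' @examples
#' t <- seq(0, 4000, by = 5)
#' v <- pmax(sin(2 * pi * t / 1000), 0)^4
#' beats <- detect_beats(tibble::tibble(t_ms = t, value = v))
#' attr(beats, "cl_ms")
#' @export
detect_beats <- function(trace, frame_interval_ms = NULL,
                         prominence_frac = 0.3, min_separation_ms = 100) {
  tv <- as_trace(trace, frame_interval_ms)
  v <- tv$value
  t <- tv$t_ms
  if (any(!is.finite(v))) {
    abort("trace contains non-finite values.", class = "atrialmap_metrics_error")
  }
  rng <- diff(range(v))
  empty <- tibble(beat = integer(), t_peak_ms = numeric(),
                  peak_value = numeric(), prominence = numeric())
  if (rng == 0) return(structure(empty, cl_ms = NA_real_))

  n <- length(v)
  cand <- which(v > c(-Inf, v[-n]) & v >= c(v[-1], -Inf))
  if (length(cand) == 0) return(structure(empty, cl_ms = NA_real_))

  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom >= prominence_frac * rng
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) > 1) {
    ord <- order(v[cand], decreasing = TRUE)
    sel <- logical(length(cand))
    t_sel <- numeric(0)
    for (o in ord) {
      if (all(abs(t[cand[o]] - t_sel) >= min_separation_ms)) {
        sel[o] <- TRUE
        t_sel <- c(t_sel, t[cand[o]])
      }
    }
    cand <- cand[sel]
    prom <- prom[sel]
    o <- order(cand)
    cand <- cand[o]
    prom <- prom[o]
  }
  beats <- tibble(
    beat = seq_along(cand),
    t_peak_ms = t[cand],
    peak_value = v[cand],
    prominence = prom
  )
  cl <- if (nrow(beats) >= 2) mean(diff(beats$t_peak_ms)) else NA_real_
  structure(beats, cl_ms = cl, idx = cand)
}

peak_prominence <- function(v, i) {
  n <- length(v)
  side_min <- function(dir, lim) {
    if (i == lim) return(-Inf) # peak sits on the boundary itself
    m <- v[i]
    j <- i
    while (j != lim && v[j + dir] <= v[i]) {
      j <- j + dir
      if (v[j] < m) m <- v[j]
    }
    m
  }
  v[i] - max(side_min(-1L, 1L), side_min(1L, n))
}

as_trace <- function(trace, frame_interval_ms = NULL) {
  if (is.numeric(trace)) {
    if (is.null(frame_interval_ms)) {
      abort("supply `frame_interval_ms` with a numeric trace.",
            class = "atrialmap_metrics_error")
    }
    return(list(t_ms = (seq_along(trace) - 1) * frame_interval_ms,
                value = as.numeric(trace)))
  }
  stopifnot(all(c("t_ms", "value") %in% names(trace)))
  list(t_ms = trace$t_ms, value = trace$value)
}

#' Average cycle length from detected beats
#'
#' @param beats A [detect_beats()] result.
#' @return Mean peak-to-peak interval, ms (`NA` with fewer than 2 peaks).
#' @export
cycle_length <- function(beats) {
  if (nrow(beats) < 2) return(NA_real_)
  mean(diff(beats$t_peak_ms))
}

#' Per-beat OAP parameters
#'
#' For each detected beat: the pre-upstroke diastolic baseline (median of
#' the 50 ms preceding the upstroke foot, a same-beat reference robust to
#' residual drift), the amplitude, the 50-percent-upstroke time on the
#' rising limb (linear sub-frame interpolation), `APD_x` as the interval
#' from that time to x-percent repolarization toward the baseline on the
#' falling limb, and the maximal upstroke slope of the
#' amplitude-normalized signal, per frame and per ms. A beat whose
#' repolarization does not reach the requested level before the next
#' upstroke gets `NA` there (flagged, not an error).
#'
#' @param trace Trace as in [detect_beats()].
#' @param beats A [detect_beats()] result for that trace.
#' @param frame_interval_ms Sampling interval for the vector form.
#' @param apd_levels Repolarization percentages.
#' @param baseline_window_ms Span before the foot used for the baseline.
#' @return `beats` with columns `baseline`, `amplitude`, `t50_up_ms`,
#'   `apd20`, `apd50`, `apd90` (ms), `dfdt_per_frame`, `dfdt_per_ms`.
#' @export
beat_params <- function(trace, beats, frame_interval_ms = NULL,
                        apd_levels = c(20, 50, 90),
                        baseline_window_ms = 50) {
  tv <- as_trace(trace, frame_interval_ms)
  v <- tv$value
  t <- tv$t_ms
  idx <- attr(beats, "idx")
  if (is.null(idx)) {
    idx <- vapply(beats$t_peak_ms, function(tp) which.min(abs(t - tp)),
                  integer(1))
  }
  n <- length(v)
  nb <- nrow(beats)
  out <- beats
  cols <- c("baseline", "amplitude", "t50_up_ms",
            paste0("apd", apd_levels), "dfdt_per_frame", "dfdt_per_ms")
  for (cc in cols) out[[cc]] <- NA_real_

  for (b in seq_len(nb)) {
    pk <- idx[b]
    lo <- if (b == 1) 1L else idx[b - 1]
    hi <- if (b == nb) n else idx[b + 1]
    seg <- lo:pk
    foot <- seg[which.min(v[seg])]
    base_lo <- which(t >= t[foot] - baseline_window_ms)[1]
    baseline <- median(v[max(base_lo, lo):foot])
    amp <- v[pk] - baseline
    if (!is.finite(amp) || amp <= 0) next
    out$baseline[b] <- baseline
    out$amplitude[b] <- amp

    thr <- baseline + 0.5 * amp
    ri <- foot:pk
    above <- which(v[ri] >= thr)
    if (length(above) == 0) next
    i2 <- ri[above[1]]
    t50 <- if (i2 == foot) t[foot] else {
      i1 <- i2 - 1L
      t[i1] + (thr - v[i1]) / (v[i2] - v[i1]) * (t[i2] - t[i1])
    }
    out$t50_up_ms[b] <- t50

    # repolarization: falling limb up to the next beat's foot
    next_seg <- pk:hi
    next_foot <- next_seg[which.min(v[next_seg])]
    fall <- pk:next_foot
    for (x in apd_levels) {
      level <- v[pk] - x / 100 * amp
      below <- which(v[fall] <= level)
      below <- below[below > 1]
      if (length(below) == 0) next
      j2 <- fall[below[1]]
      j1 <- j2 - 1L
      t_x <- t[j1] + (v[j1] - level) / (v[j1] - v[j2]) * (t[j2] - t[j1])
      out[[paste0("apd", x)]][b] <- t_x - t50
    }

    up <- foot:pk
    if (length(up) >= 2) {
      slopes <- diff(v[up]) / amp
      out$dfdt_per_frame[b] <- max(slopes)
      out$dfdt_per_ms[b] <- max(slopes / diff(t[up]))
    }
  }
  out
}

#' APD for one beat
#'
#' Convenience wrapper around [beat_params()] for a single beat and one
#' repolarization level.
#'
#' @inheritParams beat_params
#' @param beat Row index into `beats`.
#' @param x Repolarization percentage.
#' @return `APD_x` in ms (`NA` when repolarization is not reached).
#' @export
compute_apd <- function(trace, beats, beat, x, frame_interval_ms = NULL) {
  bp <- beat_params(trace, beats, frame_interval_ms, apd_levels = x)
  bp[[paste0("apd", x)]][beat]
}

#' Maximal normalized upstroke slope for one beat
#'
#' @inheritParams compute_apd
#' @return Named vector with `per_frame` and `per_ms`.
#' @export
dfdt_max <- function(trace, beats, beat, frame_interval_ms = NULL) {
  bp <- beat_params(trace, beats, frame_interval_ms)
  if (!is.finite(bp$amplitude[beat]) || bp$amplitude[beat] <= 0) {
    abort("beat has zero amplitude.", class = "atrialmap_metrics_error")
  }
  c(per_frame = bp$dfdt_per_frame[beat], per_ms = bp$dfdt_per_ms[beat])
}

#' Bazett rate correction
#'
#' `cAPD = APD / sqrt(CL / 1000)` with the cycle length in ms; at
#' CL = 1000 ms the correction is the identity.
#'
#' @param apd_ms APD, ms.
#' @param cl_ms Average cycle length, ms; must be positive.
#' @return Corrected APD, ms.
#' @examples
#' bazett(300, 1000)
#' bazett(600, 4000)
#' @export
bazett <- function(apd_ms, cl_ms) {
  if (any(!is.finite(cl_ms)) || any(cl_ms <= 0)) {
    abort("`cl_ms` must be positive.", class = "atrialmap_metrics_error")
  }
  apd_ms / sqrt(cl_ms / 1000)
}

#' Beat-to-beat alternans ratios
#'
#' Alternans magnitude for amplitude and APD90:
#' `|mean(odd beats) - mean(even beats)| / mean(all beats)`. With fewer
#' than four beats the ratio is undefined (`NA`, flagged).
#'
#' @param params A [beat_params()] result.
#' @return Tibble with `alt_amp` and `alt_apd90`.
#' @export
alternans_ratio <- function(params) {
  alt <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 4) return(NA_real_)
    odd <- x[seq(1, length(x), by = 2)]
    even <- x[seq(2, length(x), by = 2)]
    abs(mean(odd) - mean(even)) / mean(x)
  }
  tibble(alt_amp = alt(params$amplitude), alt_apd90 = alt(params$apd90))
}

#' Summarize OAP parameters over ROIs
#'
#' Per ROI, every parameter is the mean over the first `n_beats`
#' consecutive beats with complete measurements; ROIs without such a run
#' are flagged and excluded. Corrected APDs use Bazett's formula with the
#' ROI's average cycle length. The preparation-level value is the mean
#' over the usable ROIs.
#'
#' @param traces Long trace tibble (`roi`, `t_ms`, `value`) from
#'   [extract_traces()].
#' @param n_beats Consecutive beats averaged per ROI.
#' @param prominence_frac,min_separation_ms Passed to [detect_beats()].
#' @return An `oap_summary`; [tidy()] gives the per-ROI table, [glance()]
#'   the one-row preparation means.
#' @export
summarize_oap <- function(traces, n_beats = 5, prominence_frac = 0.3,
                          min_separation_ms = 100) {
  stopifnot(all(c("roi", "t_ms", "value") %in% names(traces)))
  per_roi <- traces |>
    group_by(.data$roi) |>
    group_map(function(df, key) {
      beats <- detect_beats(df, prominence_frac = prominence_frac,
                            min_separation_ms = min_separation_ms)
      if (nrow(beats) < n_beats) {
        return(tibble(roi = key$roi, usable = FALSE))
      }
      bp <- beat_params(df, beats)
      ok <- is.finite(bp$apd20) & is.finite(bp$apd50) & is.finite(bp$apd90) &
        is.finite(bp$amplitude)
      run <- first_run(ok, n_beats)
      if (is.na(run)) {
        return(tibble(roi = key$roi, usable = FALSE))
      }
      sel <- bp[run:(run + n_beats - 1), ]
      cl <- mean(diff(sel$t_peak_ms))
      alt <- alternans_ratio(sel)
      tibble(
        roi = key$roi, usable = TRUE,
        cl_ms = cl,
        apd20 = mean(sel$apd20), apd50 = mean(sel$apd50),
        apd90 = mean(sel$apd90),
        capd20 = bazett(mean(sel$apd20), cl),
        capd50 = bazett(mean(sel$apd50), cl),
        capd90 = bazett(mean(sel$apd90), cl),
        dfdt_per_frame = mean(sel$dfdt_per_frame),
        dfdt_per_ms = mean(sel$dfdt_per_ms),
        amplitude = mean(sel$amplitude),
        alt_amp = alt$alt_amp, alt_apd90 = alt$alt_apd90,
        n_beats = n_beats
      )
    }) |>
    purrr::list_rbind()

  usable <- per_roi[per_roi$usable, , drop = FALSE]
  if (nrow(usable) == 0) {
    abort(sprintf("no ROI has %d consecutive usable beats.", n_beats),
          class = "atrialmap_metrics_error")
  }
  prep <- usable |>
    summarise(across(c("cl_ms", "apd20", "apd50", "apd90",
                       "capd20", "capd50", "capd90",
                       "dfdt_per_frame", "dfdt_per_ms", "amplitude",
                       "alt_amp", "alt_apd90"), mean),
              n_rois = dplyr::n())
  structure(list(roi = per_roi, prep = prep, n_beats = n_beats),
            class = "oap_summary")
}

first_run <- function(ok, len) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' @export
print.oap_summary <- function(x, ...) {
  cat(sprintf("<oap_summary> %d ROI(s), %d usable, %d beats each\n",
              nrow(x$roi), sum(x$roi$usable), x$n_beats))
  print(x$prep)
  invisible(x)
}

#' @describeIn summarize_oap Per-ROI parameter table.
#' @param x An `oap_summary`.
#' @param ... Unused.
#' @export
tidy.oap_summary <- function(x, ...) x$roi

#' @describeIn summarize_oap One-row preparation means.
#' @export
glance.oap_summary <- function(x, ...) x$prep

#' @export
autoplot.oap_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object$roi[object$roi$usable, ],
                            c("capd20", "capd50", "capd90"),
                            names_to = "parameter", values_to = "ms")
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$ms)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "corrected APD (ms)") +
    ggplot2::theme_minimal()
}
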