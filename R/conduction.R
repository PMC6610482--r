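#' Activation map over one beat window
#'
#' Local activation time is the time at which the OAP reaches peak
#' intensity at each pixel, within a window containing at most one
#' stimulus cycle. A pixel is defined only when a beat occurs there: the
#' in-window peak must be strictly interior to the window and rise by at
#' least `prominence_frac` of the pixel's whole-trace range, which keeps
#' the late repolarization of a previous OAP in a blocked region from
#' being read as activation.
#'
#' @param cond A `conditioned_movie`.
#' @param window `c(t0, t1)` in ms.
#' @param prominence_frac In-window rise threshold, fraction of the
#'   pixel's whole-trace range.
#' @return An `activation_map`: matrix of times (ms, `NA` undefined) with
#'   attributes `window` and `total_activation_ms` (max minus min of the
#'   defined times).
#' @export
activation_map <- function(cond, window, prominence_frac = 0.3) {
  stopifnot(inherits(cond, "conditioned_movie"))
  d <- dim(cond$dff)
  t_ms <- (seq_len(d[1]) - 1) * cond$frame_interval_ms
  sel <- which(t_ms >= window[1] & t_ms <= window[2])
  if (length(sel) < 3) {
    abort("empty or too-short beat window.", class = "atrialmap_conduction_error")
  }
  H <- d[2]; W <- d[3]
  amap <- matrix(NA_real_, H, W)
  flat <- matrix(cond$dff, d[1], H * W)
  dt <- cond$frame_interval_ms
  for (p in which(as.vector(cond$mask))) {
    v <- flat[, p]
    w <- v[sel]
    i <- which.max(w)
    if (i == 1 || i == length(w)) next
    rise <- w[i] - min(w[1:i])
    if (rise < prominence_frac * diff(range(v))) next
    # parabolic sub-frame refinement of the peak time
    den <- w[i - 1] - 2 * w[i] + w[i + 1]
    delta <- if (den < 0) 0.5 * (w[i - 1] - w[i + 1]) / den else 0
    amap[p] <- t_ms[sel[i]] + max(-0.5, min(0.5, delta)) * dt
  }
  ok <- is.finite(amap)
  structure(amap,
            class = "activation_map",
            window = window,
            total_activation_ms = if (any(ok)) diff(range(amap[ok])) else NA_real_)
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> window %g-%g ms, %d defined px, total activation %s ms\n",
    attr(x, "window")[1], attr(x, "window")[2], sum(is.finite(x)),
    format(attr(x, "total_activation_ms"))
  ))
  invisible(x)
}

#' @export
tidy.activation_map <- function(x, ...) {
  H <- nrow(x); W <- ncol(x)
  tibble(
    row = rep(seq_len(H), W),
    col = rep(seq_len(W), each = H),
    activation_ms = as.vector(unclass(x))
  )
}

#' @export
autoplot.activation_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$activation_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activation (ms)") +
    ggplot2::theme_minimal()
}

#' Classify the conduction outcome of one pacing epoch
#'
#' A preparation is `maintained` when every stimulus in the analysis
#' window elicits a strand beat and a beat at every distal ROI within the
#' latency bound (1:1 conduction into the distal area); `no_capture` when
#' the strand itself follows fewer beats than stimuli (local capture
#' failure); otherwise `impaired`, with a block pattern inferred from the
#' distal following counts and ROI positions (`two_to_one`,
#' `omnidirectional`, `unidirectional`, `regional`).
#'
#' @param stim_times_ms Stimulus onsets inside the analysis window, ms.
#' @param strand_beats_ms Beat (peak) times at the strand ROI, ms.
#' @param distal_beats_ms List of beat-time vectors, one per distal ROI.
#' @param latency_ms Stimulus-to-beat matching bound, ms; the default
#'   accommodates slow monolayer conduction across the field.
#' @param distal_y_mm Optional lateral positions of the distal ROIs, used
#'   to separate unidirectional from regional block.
#' @return One-row tibble: `stim_n`, `strand_n`, `distal_n`, `category`,
#'   `pattern`.
#' @export
classify_conduction <- function(stim_times_ms, strand_beats_ms,
                                distal_beats_ms, latency_ms = 120,
                                distal_y_mm = NULL) {
  if (is.null(strand_beats_ms)) {
    abort("strand ROI is required.", class = "atrialmap_conduction_error")
  }
  if (!is.list(distal_beats_ms)) distal_beats_ms <- list(distal_beats_ms)
  n_stim <- length(stim_times_ms)
  follows <- function(beats) {
    vapply(stim_times_ms, function(s) {
      any(beats > s & beats <= s + latency_ms)
    }, logical(1))
  }
  strand_f <- follows(strand_beats_ms)
  distal_f <- vapply(distal_beats_ms, function(b) sum(follows(b)), numeric(1))
  strand_n <- sum(strand_f)
  distal_n <- min(distal_f)

  if (strand_n < n_stim) {
    category <- "no_capture"
    pattern <- "none"
  } else if (all(distal_f == n_stim)) {
    category <- "maintained"
    pattern <- "one_to_one"
  } else {
    category <- "impaired"
    frac <- distal_f / n_stim
    half <- abs(frac - 0.5) <= 0.5 / max(n_stim, 2) + 1e-9
    if (all(distal_f == 0)) {
      pattern <- "omnidirectional"
    } else if (all(half | frac == 0.5)) {
      pattern <- "two_to_one"
    } else if (!is.null(distal_y_mm) && sides_split(frac, distal_y_mm)) {
      pattern <- "unidirectional"
    } else {
      pattern <- "regional"
    }
  }
  tibble(
    stim_n = n_stim, strand_n = strand_n, distal_n = distal_n,
    category = category, pattern = pattern
  )
}

# one angular half follows (>= 0.6), the other does not (< 0.2)
sides_split <- function(frac, y) {
  up <- frac[y > 0]
  dn <- frac[y < 0]
  if (length(up) == 0 || length(dn) == 0) return(FALSE)
  (mean(up) >= 0.6 && mean(dn) < 0.2) || (mean(dn) >= 0.6 && mean(up) < 0.2)
}

#' Classify the spatial block pattern from per-beat activation maps
#'
#' Operationalizes the block vocabulary on the distal zone: per beat, the
#' activated fraction of distal pixels and its distribution over angular
#' sectors around the isthmus mouth decide the pattern
#' (`omnidirectional` below 0.1 activated; `unidirectional` when one
#' angular half activates at 0.6 or more while the other stays below 0.2;
#' `regional` -- crab-claw -- when the flank sectors activate but the
#' central sector distal to the mouth is blocked; `two_to_one` when
#' alternate beats fully activate). A pattern that varies across beats is
#' reported with `intermittent = TRUE`.
#'
#' @param maps List of [activation_map()]s for consecutive beats.
#' @param geometry The `tissue_geometry` the movie was recorded on.
#' @param full_frac Activated fraction from which a beat counts as fully
#'   conducted.
#' @return One-row tibble: `pattern`, `intermittent`, and the per-beat
#'   activated fractions in a list column `activated_fraction`.
#' @export
classify_block_pattern <- function(maps, geometry, full_frac = 0.9) {
  stopifnot(inherits(geometry, "tissue_geometry"))
  distal <- geometry$zones == 3L
  if (!any(distal)) {
    abort("geometry has no distal zone.", class = "atrialmap_conduction_error")
  }
  xm <- matrix(geometry$x_mm, nrow(distal), ncol(distal), byrow = TRUE)
  ym <- matrix(geometry$y_mm, nrow(distal), ncol(distal))
  theta <- atan2(ym[distal], pmax(xm[distal], 1e-9))
  central <- abs(theta) <= pi / 6
  upper <- theta > 0

  per_beat <- vapply(maps, function(m) {
    act <- is.finite(unclass(m))[distal]
    c(
      frac = mean(act),
      up = if (any(upper)) mean(act[upper]) else NA_real_,
      dn = if (any(!upper)) mean(act[!upper]) else NA_real_,
      cen = if (any(central)) mean(act[central]) else NA_real_,
      fla = if (any(!central)) mean(act[!central]) else NA_real_
    )
  }, numeric(5))

  beat_pattern <- apply(per_beat, 2, function(s) {
    if (s["frac"] >= full_frac) return("one_to_one")
    if (s["frac"] < 0.1) return("omnidirectional")
    if ((s["up"] >= 0.6 && s["dn"] < 0.2) ||
        (s["dn"] >= 0.6 && s["up"] < 0.2)) return("unidirectional")
    if (s["fla"] >= 0.6 && s["cen"] < 0.2) return("regional")
    "regional"
  })

  full <- per_beat["frac", ] >= full_frac
  pattern <- if (length(full) >= 2 && all(full[c(TRUE, FALSE)]) &&
                 !any(full[c(FALSE, TRUE)])) {
    "two_to_one"
  } else if (length(full) >= 2 && all(full[c(FALSE, TRUE)]) &&
             !any(full[c(TRUE, FALSE)])) {
    "two_to_one"
  } else {
    blocked <- beat_pattern[beat_pattern != "one_to_one"]
    if (length(blocked) == 0) "one_to_one" else
      names(sort(table(blocked), decreasing = TRUE))[1]
  }
  tibble(
    pattern = pattern,
    intermittent = length(unique(beat_pattern)) > 1,
    activated_fraction = list(unname(per_beat["frac", ]))
  )
}

#' Success-rate table over a pacing sweep
#'
#' Applies the carry-forward rule -- a preparation that has already shown
#' impaired conduction (or capture failure) at a lower pacing frequency
#' stays in the impaired group at all higher frequencies -- then tabulates
#' per group and frequency the number of preparations, the maintained
#' count, and the success rate as a percentage rounded half-up to one
#' decimal.
#'
#' @param outcomes Tibble with `group`, `prep`, `freq_hz`, `category`.
#' @return Tibble with `group`, `freq_hz`, `n`, `maintained`,
#'   `success_rate`.
#' @export
success_table <- function(outcomes) {
  need <- c("group", "prep", "freq_hz", "category")
  stopifnot(all(need %in% names(outcomes)))
  grids <- outcomes |>
    group_by(.data$group, .data$prep) |>
    summarise(grid = paste(sort(.data$freq_hz), collapse = ","),
              .groups = "drop_last") |>
    summarise(n_grids = dplyr::n_distinct(.data$grid), .groups = "drop")
  if (any(grids$n_grids > 1)) {
    abort("inconsistent pacing-frequency grids within a group.",
          class = "atrialmap_conduction_error")
  }
  cf <- outcomes |>
    group_by(.data$group, .data$prep) |>
    arrange(.data$freq_hz, .by_group = TRUE) |>
    mutate(failed = cumsum(.data$category != "maintained") > 0,
           category_cf = ifelse(.data$failed & .data$category == "maintained",
                                "impaired", .data$category)) |>
    ungroup()
  out <- cf |>
    group_by(.data$group, .data$freq_hz) |>
    summarise(
      n = dplyr::n(),
      maintained = sum(.data$category_cf == "maintained"),
      .groups = "drop"
    ) |>
    mutate(success_rate = round_half_up(100 * .data$maintained / .data$n, 1))
  class(out) <- c("success_table", class(out))
  out
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Fisher's exact test on maintained counts
#'
#' Two-sided exact p-value comparing the maintained proportion of two
#' groups at one pacing frequency, by summation of hypergeometric
#' probabilities no larger than the observed table's.
#'
#' @param maintained_a,n_a Maintained count and group size, group A.
#' @param maintained_b,n_b Maintained count and group size, group B.
#' @return Two-sided p-value.
#' @examples
#' fisher_success(3, 3, 0, 4)
#' @export
fisher_success <- function(maintained_a, n_a, maintained_b, n_b) {
  counts <- c(maintained_a, n_a, maintained_b, n_b)
  if (any(counts < 0) || maintained_a > n_a || maintained_b > n_b) {
    abort("counts must be non-negative and no larger than group sizes.",
          class = "atrialmap_conduction_error")
  }
  if (n_a == 0 || n_b == 0) {
    abort("group sizes must be positive.", class = "atrialmap_conduction_error")
  }
  tab <- matrix(c(maintained_a, n_a - maintained_a,
                  maintained_b, n_b - maintained_b), 2, 2)
  stats::fisher.test(tab)$p.value
}

#' @export
autoplot.success_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq_hz, .data$success_rate,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pacing frequency (Hz)", y = "success rate (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
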