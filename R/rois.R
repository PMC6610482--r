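#' Place regions of interest along the conduction axis
#'
#' Default ROI layout for OAP parameter extraction: `n` square ROIs of
#' `size` x `size` pixels, evenly spaced along the x (conduction) axis of
#' the masked-in region, each centred on the mask's vertical midline at
#' its column. Manual ROI tables with columns `roi`, `row`, `col`, and
#' optionally `size`, are accepted everywhere an ROI spec is.
#'
#' @param x A `conditioned_movie`, `pixel_mask`, or logical matrix.
#' @param n Number of ROIs.
#' @param size ROI side length, pixels.
#' @param margin Fraction of the x-extent left free at either end.
#' @return Tibble with `roi`, `row`, `col`, `size`.
#' @export
place_rois <- function(x, n = 5, size = 3, margin = 0.15) {
  mask <- roi_mask(x)
  cols_in <- which(colSums(mask) > 0)
  if (length(cols_in) < n) {
    abort("mask too small for the requested number of ROIs.",
          class = "atrialmap_roi_error")
  }
  lo <- quantile(cols_in, margin, names = FALSE)
  hi <- quantile(cols_in, 1 - margin, names = FALSE)
  cols <- round(seq(lo, hi, length.out = n))
  rows <- vapply(cols, function(j) round(median(which(mask[, j]))), numeric(1))
  tibble(roi = seq_len(n), row = as.integer(rows), col = as.integer(cols),
         size = as.integer(size))
}

roi_mask <- function(x) {
  if (inherits(x, "conditioned_movie")) return(x$mask)
  if (inherits(x, "pixel_mask")) return(x$mask)
  if (is.logical(x) && is.matrix(x)) return(x)
  if (inherits(x, "tissue_geometry")) return(x$excitable)
  abort("cannot derive a pixel mask from this object.",
        class = "atrialmap_roi_error")
}

#' ROI layout for conduction classification
#'
#' One strand ROI just proximal to the isthmus mouth plus a grid of
#' distal ROIs inside the distal zone at or beyond `min_dist_mm` from the
#' mouth: three along the conduction axis and one on either flank. Roles
#' are recorded in a `role` column (`"strand"` / `"distal"`).
#'
#' @param geometry A `tissue_geometry` (typically a [recording_window()]).
#' @param n_axis Distal ROIs along the conduction axis.
#' @param min_dist_mm Minimum distance of distal ROIs from the mouth, mm.
#' @param size ROI side length, pixels.
#' @return Tibble with `roi`, `row`, `col`, `size`, `role`, `x_mm`, `y_mm`.
#' @export
conduction_rois <- function(geometry, n_axis = 3, min_dist_mm = 0.5,
                            size = 3) {
  stopifnot(inherits(geometry, "tissue_geometry"))
  if (!any(geometry$zones == 3L)) {
    abort("geometry has no distal zone.", class = "atrialmap_roi_error")
  }
  x <- geometry$x_mm
  y <- geometry$y_mm
  x_max <- max(x[colSums(geometry$zones == 3L) > 0])
  ax_x <- seq(max(min_dist_mm, 1), x_max - 0.5, length.out = n_axis)
  mid_x <- mean(ax_x)
  flank_y <- c(-1.2, 1.2)
  pts <- rbind(
    data.frame(x_mm = -0.7, y_mm = 0, role = "strand"),
    data.frame(x_mm = ax_x, y_mm = 0, role = "distal"),
    data.frame(x_mm = mid_x, y_mm = flank_y, role = "distal")
  )
  pts$row <- vapply(pts$y_mm, function(v) which.min(abs(y - v)), integer(1))
  pts$col <- vapply(pts$x_mm, function(v) which.min(abs(x - v)), integer(1))
  out <- tibble(
    roi = seq_len(nrow(pts)),
    row = pts$row, col = pts$col, size = as.integer(size),
    role = pts$role,
    x_mm = x[pts$col], y_mm = y[pts$row]
  )
  bad <- !geometry$excitable[cbind(out$row, out$col)]
  if (any(bad)) {
    abort("an ROI centre fell outside the excitable mask.",
          class = "atrialmap_roi_error")
  }
  out
}

#' Extract ROI traces from a conditioned movie
#'
#' Each ROI trace is the mean of the conditioned signal over the ROI's
#' masked-in footprint at every frame, in long (tidy) form.
#'
#' @param cond A `conditioned_movie`.
#' @param rois ROI tibble (`roi`, `row`, `col`, `size`, ...).
#' @return Tibble with `roi`, `t_ms`, `value`.
#' @export
extract_traces <- function(cond, rois) {
  stopifnot(inherits(cond, "conditioned_movie"))
  d <- dim(cond$dff)
  t_ms <- (seq_len(d[1]) - 1) * cond$frame_interval_ms
  half <- (rois$size - 1L) %/% 2L
  out <- purrr::pmap_dfr(
    list(rois$roi, rois$row, rois$col, half),
    function(id, r, c, h) {
      ri <- max(1, r - h):min(d[2], r + h)
      ci <- max(1, c - h):min(d[3], c + h)
      sub <- cond$dff[, ri, ci, drop = FALSE]
      m <- cond$mask[ri, ci, drop = FALSE]
      if (!any(m)) {
        abort(sprintf("ROI %s has no masked-in pixels.", id),
              class = "atrialmap_roi_error")
      }
      vals <- apply(sub, 1, function(fr) mean(fr[m]))
      tibble(roi = id, t_ms = t_ms, value = vals)
    }
  )
  out
}
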