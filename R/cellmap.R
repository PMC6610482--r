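#' Assign cell classes over a tissue geometry
#'
#' Labels each excitable pixel as cardiomyocyte (CM) or fibroblast (Fb),
#' with fibroblasts placed independently and uniformly at the requested
#' fraction. Fibroblast pixels are electrically passive in the simulator:
#' they never fire an upstroke but stay diffusively coupled, so they act
#' as an electrotonic load and a physical barrier (the heterocellular
#' coculture condition).
#'
#' @param geometry A [build_geometry()] / [recording_window()] object.
#' @param fb_fraction Fibroblast fraction in `[0, 1]`.
#' @param seed Integer seed for reproducible placement.
#' @return A `cell_map`: list with `classes` (integer matrix, 0 background,
#'   1 CM, 2 Fb), `fb_fraction`, `realized_fraction` and `seed`.
#' @examples
#' g <- recording_window("isthmus")
#' cm <- assign_cells(g, 0.3, seed = 1)
#' cm$realized_fraction
#' @export
assign_cells <- function(geometry, fb_fraction = 0, seed = 1L) {
  stopifnot(inherits(geometry, "tissue_geometry"))
  if (!is.numeric(fb_fraction) || length(fb_fraction) != 1 ||
      is.na(fb_fraction) || fb_fraction < 0 || fb_fraction > 1) {
    abort("`fb_fraction` must be a single value in [0, 1].",
          class = "atrialmap_cellmap_error")
  }
  classes <- matrix(0L, nrow(geometry$excitable), ncol(geometry$excitable))
  classes[geometry$excitable] <- 1L
  n <- sum(geometry$excitable)
  if (fb_fraction > 0) {
    fb <- withr_seed(seed, runif(n) < fb_fraction)
    idx <- which(geometry$excitable)
    classes[idx[fb]] <- 2L
  }
  structure(
    list(
      classes = classes,
      fb_fraction = fb_fraction,
      realized_fraction = sum(classes == 2L) / n,
      seed = as.integer(seed)
    ),
    class = "cell_map"
  )
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf(
    "<cell_map> fb_fraction %.2f (realized %.3f), seed %d\n",
    x$fb_fraction, x$realized_fraction, x$seed
  ))
  invisible(x)
}
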