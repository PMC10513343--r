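#' Seedable gradient-noise source
#'
#' Builds the lattice gradient-noise ("Perlin-style") source that drives the
#' flow field. The source is a fractal sum of `octaves` gradient-noise
#' layers with amplitude ratio `persistence`, rescaled to `[0, 1]`. Output
#' is a pure function of `(seed, coordinates)`.
#'
#' @param seed integer seed for the permutation table.
#' @param octaves number of octaves in the fractal sum (default 4).
#' @param persistence amplitude ratio between successive octaves, in (0, 1].
#' @param spatial_scale frequency multiplier applied to canvas-normalized
#'   coordinates before noise lookup (default 3.0).
#' @param time_step time units per frame for the third noise coordinate
#'   (default 0.005), so the field drifts slowly relative to 30 fps.
#' @return an object of class `noise_source`.
#' @export
#' @examples
#' s <- noise_source(1)
#' noise3(s, 0.2, 0.4, 0)
noise_source <- function(seed, octaves = 4L, persistence = 0.5,
                         spatial_scale = 3.0, time_step = 0.005) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  octaves <- as.integer(octaves)
  if (octaves < 1L) stop("octaves must be a positive integer")
  if (!is.numeric(persistence) || persistence <= 0 || persistence > 1)
    stop("persistence must lie in (0, 1]")
  if (spatial_scale <= 0) stop("spatial_scale must be positive")
  if (time_step <= 0) stop("time_step must be positive")
  # permutation table drawn once from the seed; repeated so hashed lattice
  # lookups never index out of range
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  p <- sample.int(256L) - 1L
  structure(
    list(seed = as.integer(seed), octaves = octaves, persistence = persistence,
         spatial_scale = spatial_scale, time_step = time_step,
         perm = c(p, p)),
    class = "noise_source"
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate the noise field
#'
#' Vectorized 3-D gradient noise in `[0, 1]`. Coordinates are used as-is
#' (no canvas normalization); see [direction_at()] for the flow-field
#' convention.
#'
#' @param source a [noise_source()].
#' @param x,y,z numeric coordinate vectors (recycled to a common length).
#' @return numeric vector of noise values in `[0, 1]`.
#' @export
noise3 <- function(source, x, y, z) {
  stopifnot(inherits(source, "noise_source"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("non-finite coordinate")
  noise3_cpp(source$perm, x, y, z, source$octaves, source$persistence)
}

#' Flow-field direction
#'
#' The movement direction of a particle at canvas-normalized position
#' `(x_norm, y_norm)` and time `t` is `noise * c`, where the noise lookup is
#' scaled by the source's `spatial_scale`. With the default `c = pi/2` all
#' directions lie in `[0, 90]` degrees, so particles drift right/down.
#'
#' @param source a [noise_source()].
#' @param x_norm,y_norm canvas-normalized coordinates in `[0, 1]`.
#' @param t time coordinate (already scaled, i.e. `frame * time_step`).
#' @param c direction range constant in radians (default `pi/2`).
#' @return direction angle(s) in radians, in `[0, c]`.
#' @export
direction_at <- function(source, x_norm, y_norm, t, c = pi / 2) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0)
    stop("direction range constant c must be positive")
  noise3(source, x_norm * source$spatial_scale,
         y_norm * source$spatial_scale, t) * c
}
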