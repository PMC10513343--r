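#' Generative-system configuration
#'
#' All initialization-phase parameters of the flow-field particle system:
#' canvas geometry, particle count and velocity, frame rate and duration,
#' the sampling interval, the color parameters (HSB), the direction range
#' constant `c`, and the seeds. Hue limits given in the wrong order are
#' swapped (the hue map needs an ordered interval).
#'
#' @param canvas_width,canvas_height canvas size in pixels (default 400).
#' @param n_particles number of particles (default 2000).
#' @param velocity particle speed in pixels per frame. The default `1/60`
#'   (0.5 px/s at 30 fps) sets the painted-path budget at which the canvas
#'   approaches a balanced light/dark ratio by the end of the 144-s
#'   drawing phase, the regime the feature battery is calibrated for; see
#'   the methods vignette for the reasoning.
#' @param fps frames rendered per second (default 30).
#' @param duration drawing-phase length in seconds (default 144).
#' @param sample_interval seconds between sampled images (default 12); must
#'   divide `duration`.
#' @param hue_lower,hue_upper hue range limits in degrees, within \[0, 360\].
#' @param saturation,brightness HSB saturation/brightness in percent.
#' @param c direction range constant in radians (default `pi/2`).
#' @param particle_seed,noise_seed integer seeds for particle placement
#'   (including boundary re-initialization) and for the noise field.
#' @param octaves,persistence,spatial_scale,time_step noise-field
#'   parameters, see [noise_source()].
#' @return an object of class `gen_config`.
#' @export
gen_config <- function(canvas_width = 400L, canvas_height = 400L,
                       n_particles = 2000L, velocity = 1 / 60, fps = 30L,
                       duration = 144, sample_interval = 12,
                       hue_lower = 0, hue_upper = 360,
                       saturation = 100, brightness = 100,
                       c = pi / 2, particle_seed = 1L, noise_seed = 2L,
                       octaves = 4L, persistence = 0.5,
                       spatial_scale = 3.0, time_step = 0.005) {
  if (hue_upper < hue_lower) {
    tmp <- hue_lower; hue_lower <- hue_upper; hue_upper <- tmp
    warning("hue limits were swapped so that hue_lower <= hue_upper")
  }
  stopifnot(canvas_width >= 1, canvas_height >= 1, n_particles >= 1,
            velocity > 0, fps >= 1, duration > 0, sample_interval > 0,
            hue_lower >= 0, hue_upper <= 360,
            saturation >= 0, saturation <= 100,
            brightness >= 0, brightness <= 100, c > 0)
  if (abs(duration / sample_interval - round(duration / sample_interval)) > 1e-9)
    stop("sample_interval must divide duration")
  structure(
    list(canvas_width = as.integer(canvas_width),
         canvas_height = as.integer(canvas_height),
         n_particles = as.integer(n_particles), velocity = velocity,
         fps = as.integer(fps), duration = duration,
         sample_interval = sample_interval,
         hue_lower = hue_lower, hue_upper = hue_upper,
         saturation = saturation, brightness = brightness, c = c,
         particle_seed = as.integer(particle_seed),
         noise_seed = as.integer(noise_seed),
         octaves = as.integer(octaves), persistence = persistence,
         spatial_scale = spatial_scale, time_step = time_step),
    class = "gen_config"
  )
}

#' Initialize particle positions
#'
#' Positions are i.i.d. uniform over the canvas, deterministic given
#' `config$particle_seed`.
#'
#' @param config a [gen_config()].
#' @return data frame with columns `x`, `y` (pixel coordinates).
#' @export
init_particles <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(config$particle_seed)
  data.frame(x = stats::runif(config$n_particles, 0, config$canvas_width),
             y = stats::runif(config$n_particles, 0, config$canvas_height))
}

#' Saturating additive blend
#'
#' Per-channel sum of source and destination, clipped at 255. This is the
#' canvas blending mode: pixels only ever brighten.
#'
#' @param src,dst numeric RGB vectors/arrays with channels in \[0, 255\].
#' @return blended values, same shape as the inputs.
#' @export
#' @examples
#' blend_add(c(200, 200, 200), c(100, 0, 0))
blend_add <- function(src, dst) {
  pmin(src + dst, 255)
}

#' Direction-to-hue map
#'
#' Linear map of the direction's magnitude (in degrees, over the 0--90
#' range) onto the configured hue interval:
#' `hue = d_deg / 90 * (hue_upper - hue_lower) + hue_lower`.
#'
#' @param d direction angle(s) in radians, in `[0, pi/2]`.
#' @param config a [gen_config()].
#' @return hue value(s) in degrees.
#' @export
particle_hue <- function(d, config) {
  stopifnot(inherits(config, "gen_config"))
  (d * 180 / pi) / 90 * (config$hue_upper - config$hue_lower) + config$hue_lower
}

#' HSB to 8-bit RGB
#'
#' Standard hue/saturation/brightness conversion; hue in degrees, the
#' other channels in percent.
#'
#' @param hue hue in degrees.
#' @param saturation,brightness percent in \[0, 100\].
#' @return integer matrix with columns R, G, B in \[0, 255\].
#' @export
#' @examples
#' hsb_to_rgb(120, 100, 100)  # pure green
hsb_to_rgb <- function(hue, saturation, brightness) {
  n <- max(length(hue), length(saturation), length(brightness))
  hue <- rep_len(hue, n); saturation <- rep_len(saturation, n)
  brightness <- rep_len(brightness, n)
  if (any(saturation < 0 | saturation > 100) ||
      any(brightness < 0 | brightness > 100))
    stop("saturation and brightness must lie in [0, 100]")
  m <- hsb_to_rgb_cpp(as.numeric(hue), as.numeric(saturation),
                      as.numeric(brightness))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Advance one particle by one frame
#'
#' Reference implementation of the per-frame update used by the simulator:
#' direction from the flow field, displacement `(cos d, sin d) * v`, and
#' uniform re-initialization when the target leaves the canvas. The frame
#' loop in [run_simulation()] applies the same rules to all particles.
#'
#' @param p list or one-row data frame with `x`, `y`.
#' @param t frame index (0-based).
#' @param config a [gen_config()].
#' @param source a [noise_source()]; defaults to the config's field.
#' @return list with new `x`, `y`, the direction `d` and the `hue` assigned
#'   this frame.
#' @export
step_particle <- function(p, t, config, source = NULL) {
  stopifnot(inherits(config, "gen_config"))
  if (is.null(source)) source <- .config_source(config)
  d <- direction_at(source, p$x / config$canvas_width,
                    p$y / config$canvas_height,
                    t * config$time_step, config$c)
  hue <- particle_hue(d, config)
  xn <- p$x + cos(d) * config$velocity
  yn <- p$y + sin(d) * config$velocity
  if (xn < 0 || xn >= config$canvas_width ||
      yn < 0 || yn >= config$canvas_height) {
    xn <- stats::runif(1, 0, config$canvas_width)
    yn <- stats::runif(1, 0, config$canvas_height)
  }
  list(x = xn, y = yn, d = d, hue = hue)
}

.config_source <- function(config) {
  noise_source(config$noise_seed, config$octaves, config$persistence,
               config$spatial_scale, config$time_step)
}

#' Run the particle simulation
#'
#' Runs `fps * duration` frames. Each frame every particle takes a
#' flow-field step and deposits a 1-pixel dot of its HSB color onto the
#' canvas with saturating additive blending; the canvas state after frame
#' `k * sample_interval * fps` becomes the k-th sampled image. A color log
#' records every distinct hue (rounded to 1 degree) ever assigned.
#'
#' @param config a [gen_config()].
#' @param sequence_id label for the produced sequence.
#' @return an `image_sequence`: list with `sequence_id`, `images` (list of
#'   `height x width x 3` integer arrays in \[0, 255\]), `sample_times`
#'   (seconds), `color_log` (data frame of distinct hue/saturation/
#'   brightness triples) and the `config`.
#' @export
run_simulation <- function(config, sequence_id = "seq1") {
  stopifnot(inherits(config, "gen_config"))
  source <- .config_source(config)
  p0 <- init_particles(config)
  n_frames <- as.integer(round(config$fps * config$duration))
  sample_every <- as.integer(round(config$fps * config$sample_interval))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(config$particle_seed + 1L)  # boundary re-initialization stream
  res <- run_sim_cpp(source$perm, config$octaves, config$persistence,
                     config$spatial_scale, config$time_step,
                     config$canvas_width, config$canvas_height,
                     config$velocity, config$c,
                     config$hue_lower, config$hue_upper,
                     config$saturation, config$brightness,
                     n_frames, sample_every, p0$x, p0$y)
  npix <- config$canvas_width * config$canvas_height
  images <- vector("list", res$n_samples)
  for (k in seq_len(res$n_samples)) {
    off <- (k - 1) * npix * 3
    images[[k]] <- array(res$images[(off + 1):(off + npix * 3)],
                         dim = c(config$canvas_height, config$canvas_width, 3))
  }
  structure(
    list(sequence_id = sequence_id, images = images,
         sample_times = seq_len(res$n_samples) * config$sample_interval,
         color_log = data.frame(sequence_id = sequence_id,
                                hue_deg = res$hues,
                                saturation = config$saturation,
                                brightness = config$brightness),
         config = config),
    class = "image_sequence"
  )
}

#' Generate the full stimulus set
#'
#' Draws independent color parameters for `n_sequences` artworks --
#' saturation and brightness uniform on \[0, 100\], hue limits uniform on
#' \[0, 360\] (swapped into order) -- and runs the simulator for each. All
#' sequences share the base canvas/particle/timing parameters and differ
#' only in color parameters and seeds.
#'
#' @param base_config a [gen_config()] providing the shared parameters.
#' @param n_sequences number of artworks (default 8).
#' @param master_seed integer; per-sequence seeds and color parameters are
#'   derived from it.
#' @return list of `image_sequence` objects.
#' @export
make_study_stimuli <- function(base_config = gen_config(), n_sequences = 8L,
                               master_seed = 1L) {
  stopifnot(n_sequences >= 1)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(master_seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_sequences),
                  ncol = 2)
  hues <- matrix(stats::runif(2L * n_sequences, 0, 360), ncol = 2)
  sat <- stats::runif(n_sequences, 0, 100)
  bri <- stats::runif(n_sequences, 0, 100)
  out <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    cfg <- base_config
    cfg$hue_lower <- min(hues[i, ]); cfg$hue_upper <- max(hues[i, ])
    cfg$saturation <- sat[i]; cfg$brightness <- bri[i]
    cfg$particle_seed <- seeds[i, 1]; cfg$noise_seed <- seeds[i, 2]
    out[[i]] <- run_simulation(cfg, sequence_id = sprintf("IS%d", i))
  }
  out
}

#' Write a sequence's images as PNG files
#'
#' Files are named `{sequence_id}_{time}s.png` (8-bit RGB).
#'
#' @param seq an `image_sequence`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_sequence_png <- function(seq, dir) {
  stopifnot(inherits(seq, "image_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(seq$images))
  for (k in seq_along(seq$images)) {
    paths[k] <- file.path(dir, sprintf("%s_%ds.png", seq$sequence_id,
                                       as.integer(seq$sample_times[k])))
    png::writePNG(seq$images[[k]] / 255, paths[k])
  }
  invisible(paths)
}

#' Read a PNG image into the 0..255 array convention
#'
#' @param path PNG file path.
#' @return `height x width x 3` numeric array in \[0, 255\].
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}
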