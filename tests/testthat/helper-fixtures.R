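# Small deterministic fixtures shared across test files. Heavyweight
# stimuli (full 400x400 runs) live in helper-acceptance.R with lazy
# caching; everything here is cheap.

# a small, fast generator configuration for property tests
small_config <- function(...) {
  defaults <- list(canvas_width = 128L, canvas_height = 128L,
                   n_particles = 300L, velocity = 1 / 60, duration = 48,
                   sample_interval = 12, hue_lower = 80, hue_upper = 220,
                   saturation = 75, brightness = 85, particle_seed = 101L,
                   noise_seed = 202L)
  do.call(gen_config, utils::modifyList(defaults, list(...)))
}

# deterministic RGB test image (h x w x 3 in 0..255)
random_image <- function(h = 64, w = 64, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3) * 255, dim = c(h, w, 3))
}

gray_image <- function(m) {
  array(rep(m, 3), dim = c(dim(m), 3))
}

# single-color log
tiny_log <- function(hues = c(100, 200), s = 50, b = 60) {
  data.frame(sequence_id = "t", hue_deg = hues, saturation = s,
             brightness = b)
}

# synthetic balanced panel with known structure:
# response = sum(beta_j x_j) + entity effect + noise
synthetic_panel <- function(n_entities = 8, n_times = 12, betas,
                            entity_sd = 0.5, noise_sd = 0.3, seed = 1,
                            n_extra = 0) {
  set.seed(seed)
  n <- n_entities * n_times
  ent <- factor(rep(sprintf("E%02d", seq_len(n_entities)), each = n_times))
  tt <- rep(seq_len(n_times) * 12, n_entities)
  p <- length(betas)
  X <- matrix(rnorm(n * (p + n_extra)), n)
  colnames(X) <- c(names(betas),
                   if (n_extra > 0) paste0("noise", seq_len(n_extra)))
  u <- rnorm(n_entities, 0, entity_sd)
  y <- as.vector(X[, seq_len(p), drop = FALSE] %*% betas) +
    u[as.integer(ent)] + rnorm(n, 0, noise_sd)
  d <- data.frame(entity = ent, time = tt, response = y)
  cbind(d, as.data.frame(X))
}
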