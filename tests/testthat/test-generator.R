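test_that("particle initialization is uniform, in-canvas and seeded", {
  cfg <- gen_config(particle_seed = 5)
  p <- init_particles(cfg)
  expect_equal(nrow(p), 2000)
  expect_true(all(p$x >= 0 & p$x < 400 & p$y >= 0 & p$y < 400))
  expect_identical(p, init_particles(cfg))
  # CLT bound on the mean of a uniform: 3 sigma/sqrt(n)
  expect_lt(abs(mean(p$x) - 200), 3 * 400 / sqrt(12 * 2000))
  expect_lt(abs(mean(p$y) - 200), 3 * 400 / sqrt(12 * 2000))
})

test_that("additive blending clips at 255 and has black as identity", {
  expect_equal(blend_add(c(10, 20, 30), c(5, 5, 5)), c(15, 25, 35))
  expect_equal(blend_add(c(200, 200, 200), c(100, 0, 0)), c(255, 200, 200))
  x <- c(13, 77, 254)
  expect_equal(blend_add(x, c(0, 0, 0)), x)
})

test_that("direction-to-hue map is the linear interpolant of the hue range", {
  cfg <- gen_config(hue_lower = 100, hue_upper = 200)
  expect_equal(particle_hue(0, cfg), 100)
  expect_equal(particle_hue(pi / 2, cfg), 200)
  expect_equal(particle_hue(pi / 4, cfg), 150)
})

test_that("hue limits in the wrong order are swapped with a warning", {
  expect_warning(cfg <- gen_config(hue_lower = 300, hue_upper = 100),
                 "swapped")
  expect_lte(cfg$hue_lower, cfg$hue_upper)
  expect_equal(c(cfg$hue_lower, cfg$hue_upper), c(100, 300))
})

test_that("HSB conversion hits the RGB primaries and gray axis", {
  expect_equal(unname(hsb_to_rgb(0, 100, 100)[1, ]), c(255, 0, 0))
  expect_equal(unname(hsb_to_rgb(120, 100, 100)[1, ]), c(0, 255, 0))
  expect_equal(unname(hsb_to_rgb(240, 100, 100)[1, ]), c(0, 0, 255))
  expect_equal(unname(hsb_to_rgb(77, 0, 100)[1, ]), c(255, 255, 255))
  expect_equal(unname(hsb_to_rgb(0, 0, 0)[1, ]), c(0, 0, 0))
  expect_error(hsb_to_rgb(0, 150, 50), "\\[0, 100\\]")
})

test_that("particle steps follow the axis cases and the boundary rule", {
  cfg <- small_config()
  src <- genart:::.config_source(cfg)
  # a zero-direction step moves exactly (v, 0); pi/2 moves (0, v)
  # (exercise the displacement arithmetic directly)
  v <- cfg$velocity
  expect_equal(c(cos(0), sin(0)) * v, c(v, 0))
  expect_equal(c(cos(pi / 2), sin(pi / 2)) * v, c(0, v),
               tolerance = 1e-12)
  # boundary: a particle at the right edge moving right is re-initialized
  set.seed(1)
  p <- step_particle(list(x = cfg$canvas_width - 1e-9, y = 60), t = 0,
                     config = cfg, source = src)
  expect_true(p$x >= 0 && p$x < cfg$canvas_width)
  expect_true(p$y >= 0 && p$y < cfg$canvas_height)
  # interior step matches the field direction
  set.seed(1)
  q <- step_particle(list(x = 30, y = 40), t = 5, config = cfg, source = src)
  d <- direction_at(src, 30 / cfg$canvas_width, 40 / cfg$canvas_height,
                    5 * cfg$time_step, cfg$c)
  expect_equal(q$x, 30 + cos(d) * cfg$velocity)
  expect_equal(q$y, 40 + sin(d) * cfg$velocity)
  expect_equal(q$hue, particle_hue(d, cfg))
})

test_that("simulation yields the sampled sequence with monotone luminance", {
  cfg <- small_config()
  s <- run_simulation(cfg, "t1")
  expect_s3_class(s, "image_sequence")
  expect_length(s$images, cfg$duration / cfg$sample_interval)
  expect_equal(s$sample_times, seq(12, 48, by = 12))
  expect_equal(dim(s$images[[1]]), c(128, 128, 3))
  # additive blending forces non-decreasing per-pixel values
  for (k in 2:length(s$images))
    expect_true(all(s$images[[k]] >= s$images[[k - 1]]))
  gm <- vapply(s$images, function(im) mean(to_gray(im)), numeric(1))
  expect_true(all(diff(gm) >= 0))
})

test_that("simulation is bit-reproducible from config and seeds", {
  cfg <- small_config()
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$color_log, s2$color_log)
  # different noise seed changes the output
  cfg2 <- small_config(noise_seed = 999L)
  s3 <- run_simulation(cfg2)
  expect_false(identical(s1$images, s3$images))
})

test_that("color log hues stay in the configured range", {
  cfg <- small_config()
  s <- run_simulation(cfg)
  expect_true(all(s$color_log$hue_deg >= cfg$hue_lower - 0.5))
  expect_true(all(s$color_log$hue_deg <= cfg$hue_upper + 0.5))
  expect_equal(unique(s$color_log$saturation), cfg$saturation)
})

test_that("study stimuli share timing but differ in colors and seeds", {
  base <- small_config()
  seqs <- make_study_stimuli(base, n_sequences = 3, master_seed = 9)
  expect_length(seqs, 3)
  expect_equal(sum(vapply(seqs, function(s) length(s$images), integer(1))),
               3 * 4)
  cfgs <- lapply(seqs, `[[`, "config")
  for (cfg in cfgs) {
    expect_equal(cfg$canvas_width, base$canvas_width)
    expect_equal(cfg$n_particles, base$n_particles)
    expect_lte(cfg$hue_lower, cfg$hue_upper)
    expect_true(cfg$saturation >= 0 && cfg$saturation <= 100)
  }
  expect_gt(length(unique(vapply(cfgs, `[[`, numeric(1), "hue_lower"))), 1)
  # reproducible end to end
  seqs2 <- make_study_stimuli(base, n_sequences = 3, master_seed = 9)
  expect_identical(seqs[[2]]$images, seqs2[[2]]$images)
})

test_that("PNG round trip preserves the image", {
  cfg <- small_config()
  s <- run_simulation(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sequence_png(s, dir)
  expect_true(all(file.exists(paths)))
  back <- read_image_png(paths[2])
  expect_equal(back, s$images[[2]], ignore_attr = TRUE, tolerance = 1e-8)
})
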