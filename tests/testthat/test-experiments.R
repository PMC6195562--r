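test_that("summary statistics satisfy the RMS identity", {
  s <- summarize_errors(c(1, 1, 1))
  expect_equal(c(s$mean, s$std, s$rms), c(1, 0, 1))
  expect_equal(summarize_errors(c(3, 4))$rms, sqrt(12.5))
  withr::with_seed(8, {
    for (k in 1:10) {
      x <- rnorm(sample(3:30, 1), sd = runif(1, 0.1, 3))
      s <- summarize_errors(x)
      expect_equal(s$rms^2, s$mean^2 + s$std^2)
      expect_gte(s$rms, abs(s$mean))
    }
  })
  expect_error(summarize_errors(numeric(0)), "non-empty")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  expect_equal(anova_one_way(list(a = c(2, 2), b = c(2, 2)))$statistic, 0)
  expect_equal(anova_one_way(list(a = 1:3, b = 1:3))$statistic, 0)
  res <- anova_one_way(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(res$statistic, 8)                  # SSB/1 / (SSW/2) = 4/0.5
  expect_equal(res$p_value, 1 - pf(8, 1, 2))
  expect_error(anova_one_way(list(a = 1:3)), "2 groups")
  expect_error(anova_one_way(list(a = 1, b = 1:3)), "2 values")
})

test_that("tracking in water without deflection is pixel-accurate", {
  tr <- run_tracking_experiment("water", seed = 1)
  expect_equal(nrow(tr), 10)
  expect_equal(sum(tr$truth_mm), 13)               # 10 steps of 1.3 mm
  expect_true(all(tr$found))
  geom <- transducer_geometry()
  expect_true(all(tr$error_mm <= geom$pitch))
  expect_identical(tr, run_tracking_experiment("water", seed = 1))
})

test_that("tracking error reflects the deflection distribution", {
  # Monte-Carlo oracle: per-step error |  ||(d + dx, dz)|| - d  | with
  # dx, dz differences of two independent N(0, sigma^2) deflections
  sigma <- 1
  d <- 1.3
  withr::with_seed(99, {
    dx <- rnorm(1e4, sd = sigma * sqrt(2))
    dz <- rnorm(1e4, sd = sigma * sqrt(2))
  })
  oracle <- abs(sqrt((d + dx)^2 + dz^2) - d)
  errs <- unlist(lapply(1:3, function(s) {
    tr <- run_tracking_experiment("water", deflection_sigma = sigma,
                                  seed = s)
    tr$error_mm[tr$found]
  }))
  se <- sd(oracle) / sqrt(length(errs))
  expect_lt(abs(mean(errs) - mean(oracle)), 3 * se)
})

test_that("the centering experiment is reproducible and converges in water", {
  ce <- run_centering_experiment("water", n_trials = 3, seed = 0)
  expect_equal(nrow(ce), 3)
  expect_true(all(ce$success))
  expect_true(all(ce$d_p_mm <= transducer_geometry()$pitch))
  expect_true(all(abs(ce$initial_offset_mm) <= 15))
  expect_identical(ce, run_centering_experiment("water", n_trials = 3,
                                                seed = 0))
})

test_that("the fluence column reproduces the energy conversion exactly", {
  sw <- run_fluence_sweep(presets = "water", energies = c(0.3, 1.58, 3.4),
                          n_acq = 2, seed = 1,
                          geom = small_geom(), n_samples = 512L,
                          source_depth = 12)
  expect_equal(sw$fluence_mj_cm2,
               energy_to_fluence(c(0.3, 1.58, 3.4), 1))
  expect_equal(sw$fluence_mj_cm2[2], 201.2, tolerance = 0.05 / 201.2)
  expect_true(all(sw$detected_frac == 1))
})

test_that("the clutter layer lowers channel SNR at every energy", {
  sw <- run_fluence_sweep(presets = c("chicken_thigh",
                                      "chicken_thigh_clutter"),
                          energies = c(0.65, 1.58, 3.4), n_acq = 3,
                          seed = 2, geom = small_geom(),
                          n_samples = 512L, source_depth = 12)
  clean <- sw[sw$preset == "chicken_thigh", ]
  clut <- sw[sw$preset == "chicken_thigh_clutter", ]
  expect_true(all(clut$channel_snr < clean$channel_snr))
})

test_that("energies below the noise floor are flagged as undetectable", {
  med <- tissue_preset("muscle")
  geom <- small_geom()
  grid <- small_grid(geom)
  # at default energy the tip is found; with the signal amplitude below
  # the electronic noise floor it is not
  strong <- acquire_image(fiber_source(c(0, 0, 12)), geom, med, grid,
                          seed = 3, n_samples = 512L)
  expect_true(segment_frame(strong)$found)
  img <- acquire_image(fiber_source(c(0, 0, 12), pulse_energy = 0.02),
                       geom, med, grid, seed = 3, n_samples = 512L)
  expect_false(segment_frame(img)$found)
})

test_that("scaling energy scales the ratio metrics as expected", {
  geom <- small_geom()
  grid <- small_grid(geom)
  # clutter-only medium: doubling energy scales the whole frame, so
  # contrast and channel SNR are exactly unchanged
  med <- tissue_preset("chicken_thigh_clutter")
  med$noise_sigma <- 0
  roi <- list(inside = cbind(row = 74:84, col = 16),
              outside = cbind(row = 74:84, col = 28))
  src1 <- fiber_source(c(0, 0, 12), pulse_energy = 1)
  src2 <- fiber_source(c(0, 0, 12), pulse_energy = 2)
  gates <- default_snr_gates(src1, geom, med, n_samples = 512L)
  f1 <- simulate_channel_frame(src1, geom, med, seed = 6, n_samples = 512L)
  f2 <- simulate_channel_frame(src2, geom, med, seed = 6, n_samples = 512L)
  expect_equal(f2$samples, 2 * f1$samples)
  expect_equal(channel_snr(f2, gates$signal_gate, gates$noise_gate),
               channel_snr(f1, gates$signal_gate, gates$noise_gate))
  e1 <- pa_image(envelope_detect(das_beamform(f1, geom, grid,
                                              med$sound_speed)), grid)
  e2 <- pa_image(envelope_detect(das_beamform(f2, geom, grid,
                                              med$sound_speed)), grid)
  expect_equal(contrast(e2, roi$inside, roi$outside),
               contrast(e1, roi$inside, roi$outside))
  # fixed electronic noise, same realization: channel SNR ~doubles
  med2 <- tissue_preset("chicken_thigh")
  n1 <- simulate_channel_frame(src1, geom, med2, seed = 6, n_samples = 512L)
  n2 <- simulate_channel_frame(src2, geom, med2, seed = 6, n_samples = 512L)
  r <- channel_snr(n2, gates$signal_gate, gates$noise_gate) /
    channel_snr(n1, gates$signal_gate, gates$noise_gate)
  expect_equal(r, 2, tolerance = 0.05)
})

test_that("halving the noise floor does not worsen tracking", {
  quiet <- tissue_preset("liver")
  quiet$noise_sigma <- quiet$noise_sigma / 2
  seeds <- 0:4
  noisy_err <- unlist(lapply(seeds, function(s) {
    tr <- run_tracking_experiment("liver", seed = s)
    tr$error_mm[tr$found]
  }))
  quiet_err <- unlist(lapply(seeds, function(s) {
    tr <- run_tracking_experiment(quiet, seed = s)
    tr$error_mm[tr$found]
  }))
  expect_lte(mean(quiet_err), mean(noisy_err) + 0.05)
})

test_that("servo and detection logs round-trip to disk", {
  dir <- withr::local_tempdir()
  geom <- small_geom()
  grid <- small_grid(geom)
  log <- run_servo_loop(c(0, 0, 12), tissue_preset("water"), n_steps = 6,
                        seed = 1, geom = geom, grid = grid,
                        n_samples = 512L)
  write_servo_log(log, file.path(dir, "run"))
  back <- read.csv(file.path(dir, "run_trajectory.csv"))
  expect_equal(nrow(back), 6)
  expect_equal(back$probe_x, log$trajectory$probe_x)
  dets <- list(make_detection(1, 10), make_detection(NA, NA, found = FALSE))
  write_detection_log(dets, file.path(dir, "det.csv"))
  dd <- read.csv(file.path(dir, "det.csv"))
  expect_equal(dd$found, c(TRUE, FALSE))
  cfgf <- file.path(dir, "servo.yaml")
  write_config(servo_config(scan_span = 44), cfgf)
  cfg <- read_config(cfgf, as = "servo_config")
  expect_s3_class(cfg, "servo_config")
  expect_equal(cfg$scan_span, 44)
})
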