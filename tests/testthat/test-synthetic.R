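test_that("default profiles reproduce the published kinematic table", {
  p <- default_profiles()
  expect_named(p, adl_classes())
  tab <- list(walking = c(7, 62, 0.94), jogging = c(7, 62, 1.4),
              stair_ascent = c(13, 94, 0.56), stair_descent = c(14, 98, 0.58),
              sitting_down = c(6, 94, 0.16), standing_up = c(6, 94, 0.16),
              knee_bending = c(4, 98, 0.13), standing_still = c(7, 13, 0.1))
  for (nm in names(tab)) {
    expect_equal(p[[nm]]$rom_min, tab[[nm]][1], info = nm)
    expect_equal(p[[nm]]$rom_max, tab[[nm]][2], info = nm)
    expect_equal(p[[nm]]$rate, tab[[nm]][3], info = nm)
  }
  for (pr in p) {
    expect_lt(pr$rom_min, pr$rom_max)
    expect_true(pr$rate > 0 && pr$rate <= 2)
  }
})

test_that("flexion waveform hits range extremes and stays in range", {
  w <- default_profiles()$walking
  expect_equal(flexion_waveform(w, 0), 7)
  expect_equal(flexion_waveform(w, 0.5 / 0.94), 62, tolerance = 1e-10)
  t <- seq(0, 10, by = 0.02)
  th <- flexion_waveform(w, t)
  expect_true(all(th >= 7 - 1e-9 & th <= 62 + 1e-9))

  ss <- default_profiles()$standing_still
  th_ss <- flexion_waveform(ss, t)
  expect_true(all(th_ss >= 7 - 1e-9 & th_ss <= 13 + 1e-9))

  # half cycles ramp monotonically and hold
  sd_ <- default_profiles()$sitting_down
  th_sd <- flexion_waveform(sd_, t)
  ramp_end <- 1 / (2 * sd_$rate)
  expect_true(all(diff(th_sd[t <= ramp_end]) >= 0))
  expect_equal(th_sd[t >= ramp_end][1], 94, tolerance = 1e-6)
  expect_true(all(abs(th_sd[t >= ramp_end] - 94) < 1e-9))
  su <- default_profiles()$standing_up
  expect_equal(flexion_waveform(su, 0), 94)
  expect_equal(flexion_waveform(su, 100), 6)

  expect_error(flexion_waveform(w, -0.1), "non-negative")
})

test_that("segment kinematics preserve the flexion identity exactly", {
  t <- seq(0, 4, by = 0.02)
  for (nm in c("walking", "sitting_down", "standing_up", "knee_bending")) {
    p <- default_profiles()[[nm]]
    th <- flexion_waveform(p, t)
    kin <- segment_kinematics(th, p, 0.02)
    expect_equal(kin$tibial_deg - kin$femoral_deg, -th, info = nm)
  }
  # constant flexion -> zero angular velocity away from endpoints
  p <- default_profiles()$walking
  kin <- segment_kinematics(rep(30, 100), p, 0.02)
  expect_equal(kin$femoral_dps, rep(0, 100))
  expect_equal(kin$tibial_dps, rep(0, 100))
  # femoral_share = 0 puts all flexion in the tibia
  p0 <- activity_profile("walking", 7, 62, 0.94, "periodic",
                         femoral_share = 0)
  th <- flexion_waveform(p0, t)
  kin0 <- segment_kinematics(th, p0, 0.02)
  expect_equal(kin0$femoral_deg, rep(0, length(t)))
  expect_equal(kin0$tibial_deg, -th)
})

test_that("walking tibial angular velocity peaks at the cycle rate", {
  p <- default_profiles()$walking
  dt <- 0.02
  t <- seq(0, 30, by = dt)
  kin <- segment_kinematics(flexion_waveform(p, t), p, dt)
  v <- kin$tibial_dps - mean(kin$tibial_dps)
  sp <- Mod(fft(v))^2
  freqs <- (seq_along(v) - 1) / (length(v) * dt)
  half <- freqs <= 1 / (2 * dt) & freqs > 0
  peak <- freqs[half][which.max(sp[half])]
  expect_lt(abs(peak - 0.94), 0.1)
})

test_that("static gravity recovery: accelerometer norm near g", {
  cfg <- quiet_config()
  set.seed(1)
  n <- 500
  st <- synthesize_imu(rep(5, n), rep(0, n), cfg, "tibial")
  norms <- sqrt(st$samples$ax_mps2^2 + st$samples$ay_mps2^2 +
                  st$samples$az_mps2^2)
  expect_lt(abs(mean(norms) - 9.81), 0.05)

  # with default noise a standing-still recording stays in [9.6, 10.0]
  set.seed(7)
  cfg_n <- sim_config(seed = 7)
  p <- default_profiles()$standing_still
  th <- flexion_waveform(p, seq(0, 20, by = 0.02))
  kin <- segment_kinematics(th, p, 0.02)
  st2 <- synthesize_imu(kin$tibial_deg, kin$tibial_dps, cfg_n, "tibial")
  norms2 <- sqrt(st2$samples$ax_mps2^2 + st2$samples$ay_mps2^2 +
                   st2$samples$az_mps2^2)
  expect_gt(mean(norms2), 9.6)
  expect_lt(mean(norms2), 10.0)
})

test_that("gyro integration recovers the flexion range of motion", {
  cfg <- quiet_config()
  p <- default_profiles()$walking
  dt <- 1 / cfg$sample_rate
  t <- seq(0, 5 / p$rate, by = dt)
  th <- flexion_waveform(p, t)
  kin <- segment_kinematics(th, p, dt)
  set.seed(3)
  fem <- synthesize_imu(kin$femoral_deg, kin$femoral_dps, cfg, "femoral")
  set.seed(3)
  tib <- synthesize_imu(kin$tibial_deg, kin$tibial_dps, cfg, "tibial")
  d <- tib$samples$gx_dps - fem$samples$gx_dps   # = -d(theta)/dt
  # trapezoidal cumulative integral; excursion over cycles = ROM
  ci <- cumsum(c(0, (d[-1] + d[-length(d)]) / 2 * dt))
  expect_lt(abs((max(ci) - min(ci)) - 55), 2)
})

test_that("stream synthesis is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11)
  p <- default_profiles()$walking
  t <- seq(0, 3, by = 0.02)
  kin <- segment_kinematics(flexion_waveform(p, t), p, 0.02)
  set.seed(11)
  a <- synthesize_imu(kin$femoral_deg, kin$femoral_dps, cfg, "femoral", p)
  set.seed(11)
  b <- synthesize_imu(kin$femoral_deg, kin$femoral_dps, cfg, "femoral", p)
  expect_identical(a, b)
})

test_that("generate_dataset writes a complete, reproducible dataset", {
  cfg <- sim_config(reps_per_class = 2, reps_per_recording = 2, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, default_profiles(), d1)
  m2 <- generate_dataset(cfg, default_profiles(), d2)

  acts <- vapply(m1$recordings, `[[`, "", "activity")
  reps <- vapply(m1$recordings, function(r) r$reps, 0)
  per_class <- tapply(reps, acts, sum)
  expect_setequal(names(per_class), adl_classes())
  expect_true(all(per_class >= 2))

  for (r in m1$recordings) {
    expect_true(file.exists(file.path(d1, r$femoral_csv)))
    expect_true(file.exists(file.path(d1, r$tibial_csv)))
  }
  # byte-identical reproduction
  for (r in m1$recordings) {
    expect_identical(readLines(file.path(d1, r$femoral_csv)),
                     readLines(file.path(d2, r$femoral_csv)))
  }
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))

  # asynchrony: device start offsets differ by at most start_offset_max
  r <- m1$recordings[[1]]
  fem <- read_stream(file.path(d1, r$femoral_csv))
  tib <- read_stream(file.path(d1, r$tibial_csv))
  diff0 <- abs(fem$samples$t_ms[1] - tib$samples$t_ms[1])
  expect_lte(diff0, cfg$start_offset_max)
})
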