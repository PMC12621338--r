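#' Simulation configuration
#'
#' Parameters of the synthetic dual-IMU generator. Defaults emulate the
#' acquisition conditions of the embedded-device experiment: 50 Hz sampling,
#' at least 100 repetitions per activity class, asynchronous device start
#' (uniform up to 200 ms) and occasional missed samples (1% per sample).
#' Noise magnitudes are consumer-IMU scale. Lever arms are short because the
#' sensors sit inside the prosthesis chambers, centimetres from the joint
#' line.
#'
#' @param sample_rate sampling rate, Hz (must divide 1000 evenly).
#' @param reps_per_class repetitions per activity class (>= 1).
#' @param seed integer RNG seed.
#' @param accel_noise_sd accelerometer white-noise SD, m/s^2.
#' @param gyro_noise_sd gyroscope white-noise SD, deg/s.
#' @param gyro_bias_walk_sd gyroscope bias random-walk intensity,
#'   deg/s per sqrt(s).
#' @param start_offset_max maximum device start offset, ms.
#' @param dropout_prob per-sample probability of a missed sample, in
#'   `[0, 0.5)`.
#' @param segment_length_femur,segment_length_tibia sensor lever arms from
#'   the knee axis, metres.
#' @param reps_per_recording for continuous activities, how many cycles are
#'   emitted per recording file.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 50, reps_per_class = 100, seed = 42,
                       accel_noise_sd = 0.5, gyro_noise_sd = 1,
                       gyro_bias_walk_sd = 0.05, start_offset_max = 200,
                       dropout_prob = 0.01,
                       segment_length_femur = 0.05,
                       segment_length_tibia = 0.04,
                       reps_per_recording = 10) {
  if (sample_rate <= 0 || 1000 %% sample_rate != 0)
    stop("sim_config: sample_rate must be positive and divide 1000 ms evenly")
  if (dropout_prob < 0 || dropout_prob >= 0.5)
    stop("sim_config: dropout_prob must lie in [0, 0.5)")
  if (reps_per_class < 1) stop("sim_config: reps_per_class must be >= 1")
  structure(list(sample_rate = sample_rate, reps_per_class = reps_per_class,
                 seed = as.integer(seed), accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd,
                 gyro_bias_walk_sd = gyro_bias_walk_sd,
                 start_offset_max = start_offset_max,
                 dropout_prob = dropout_prob,
                 segment_length_femur = segment_length_femur,
                 segment_length_tibia = segment_length_tibia,
                 reps_per_recording = reps_per_recording),
            class = "sim_config")
}

#' Rigid-body segment kinematics from a flexion series
#'
#' Distributes a knee-flexion angle series over the two body segments. The
#' femoral (thigh) world-frame orientation is `femoral_share * theta` plus an
#' activity-specific thigh-inclination profile; sit/stand transitions ramp
#' the thigh between `thigh_start` and `thigh_end` degrees synchronously with
#' the flexion ramp (the ramp is driven by the normalised flexion progress,
#' so it is exactly synchronous whatever the time grid). The tibial
#' orientation is `femoral - theta`, so the difference between the two
#' segment orientations is always exactly `-theta`. Angular velocities are
#' central finite differences (one-sided at the endpoints).
#'
#' @param theta_series flexion angles, degrees, one per time step.
#' @param profile an [activity_profile()].
#' @param dt time step, seconds.
#' @return List with numeric vectors `femoral_deg`, `tibial_deg`,
#'   `femoral_dps`, `tibial_dps`.
#' @export
segment_kinematics <- function(theta_series, profile, dt) {
  stopifnot(length(theta_series) >= 1, dt > 0,
            inherits(profile, "activity_profile"))
  rng <- profile$rom_max - profile$rom_min
  if (profile$waveform == "half_cycle_up") {
    progress <- (profile$rom_max - theta_series) / rng
  } else {
    progress <- (theta_series - profile$rom_min) / rng
  }
  thigh <- profile$thigh_start +
    (profile$thigh_end - profile$thigh_start) * progress
  if (profile$thigh_start == profile$thigh_end)
    thigh <- rep(profile$thigh_start, length(theta_series))
  femoral <- profile$femoral_share * theta_series + thigh
  tibial <- femoral - theta_series
  list(femoral_deg = femoral, tibial_deg = tibial,
       femoral_dps = central_diff(femoral, dt),
       tibial_dps = central_diff(tibial, dt))
}

central_diff <- function(x, dt) {
  n <- length(x)
  if (n == 1L) return(0)
  v <- numeric(n)
  if (n > 2L) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

#' Synthesise one device's IMU stream from segment kinematics
#'
#' Produces a 6-channel IMU stream for the femoral or tibial device. The
#' accelerometer reads the gravity reaction vector rotated into the sensor
#' frame by the segment orientation (knee flexion axis is sensor x; gravity
#' lies along sensor -z at full extension, so `ay = g sin(sigma)`,
#' `az = g cos(sigma)`), plus tangential (`r * alpha`) and centripetal
#' (`-r * omega^2`) lever-arm terms, plus white noise, plus exponentially
#' decaying footstrike transients when the profile's `impact_amplitude` is
#' positive. The gyroscope x channel is the segment angular velocity in
#' deg/s plus a bias random walk and white noise; y and z carry noise only.
#' Timestamps are integer milliseconds starting at a device-specific offset
#' drawn uniformly from `[0, start_offset_max]` ms and advancing at
#' `1000 / sample_rate` ms. Every sample after the first is independently
#' dropped with probability `dropout_prob` (the first is kept so the stream
#' start marks the device activation time). Randomness comes from the
#' session RNG; seed it for reproducibility.
#'
#' @param orientation_deg segment world-frame orientation series, degrees.
#' @param angvel_dps segment angular velocity series, deg/s.
#' @param config a [sim_config()].
#' @param device `"femoral"` or `"tibial"`.
#' @param profile optional [activity_profile()], used for impact transients.
#' @return An `imu_stream` (see [imu_stream()]).
#' @export
synthesize_imu <- function(orientation_deg, angvel_dps, config,
                           device = c("femoral", "tibial"),
                           profile = NULL) {
  device <- match.arg(device)
  n <- length(orientation_deg)
  stopifnot(length(angvel_dps) == n, inherits(config, "sim_config"))
  g <- 9.81
  dt <- 1 / config$sample_rate
  sigma <- orientation_deg * pi / 180
  omega <- angvel_dps * pi / 180
  alpha <- central_diff(omega, dt)
  r <- if (device == "femoral") config$segment_length_femur else
    config$segment_length_tibia

  ax <- stats::rnorm(n, 0, config$accel_noise_sd)
  ay <- g * sin(sigma) + r * alpha +
    stats::rnorm(n, 0, config$accel_noise_sd)
  az <- g * cos(sigma) - r * omega^2 +
    stats::rnorm(n, 0, config$accel_noise_sd)

  if (!is.null(profile) && profile$impact_amplitude > 0) {
    t <- (seq_len(n) - 1) * dt
    period <- 1 / profile$rate
    tau <- 0.05
    phase <- t %% period
    az <- az + profile$impact_amplitude * exp(-phase / tau)
  }

  bias <- cumsum(stats::rnorm(n, 0, config$gyro_bias_walk_sd * sqrt(dt)))
  gx <- angvel_dps + bias + stats::rnorm(n, 0, config$gyro_noise_sd)
  gy <- stats::rnorm(n, 0, config$gyro_noise_sd)
  gz <- stats::rnorm(n, 0, config$gyro_noise_sd)

  offset <- sample.int(config$start_offset_max + 1L, 1L) - 1L
  step_ms <- as.integer(1000 / config$sample_rate)
  t_ms <- offset + (seq_len(n) - 1L) * step_ms
  keep <- c(TRUE, stats::runif(n - 1L) >= config$dropout_prob)

  imu_stream(device,
             data.frame(t_ms = as.integer(t_ms[keep]),
                        ax_mps2 = ax[keep], ay_mps2 = ay[keep],
                        az_mps2 = az[keep], gx_dps = gx[keep],
                        gy_dps = gy[keep], gz_dps = gz[keep]))
}

# Duration (s) and evaluation clock for one recording of a profile.
# Continuous activities pack `reps` cycles; transitional ones hold 0.6 s of
# the neutral posture, ramp for half a cycle, then hold the final posture so
# each recording comfortably spans one 3 s analysis window.
recording_plan <- function(profile, reps) {
  if (profile$waveform %in% c("periodic", "quasi_static")) {
    list(duration = reps / profile$rate, lead = 0)
  } else {
    list(duration = 0.6 + 1 / (2 * profile$rate) + 0.8, lead = 0.6)
  }
}

simulate_recording <- function(profile, config, reps) {
  plan <- recording_plan(profile, reps)
  dt <- 1 / config$sample_rate
  n <- floor(plan$duration / dt) + 1L
  t <- (seq_len(n) - 1) * dt
  theta <- flexion_waveform(profile, pmax(0, t - plan$lead))
  kin <- segment_kinematics(theta, profile, dt)
  fem <- synthesize_imu(kin$femoral_deg, kin$femoral_dps, config,
                        "femoral", profile)
  tib <- synthesize_imu(kin$tibial_deg, kin$tibial_dps, config,
                        "tibial", profile)
  list(femoral = fem, tibial = tib)
}

#' Generate a labelled dual-IMU dataset on disk
#'
#' Simulates every activity class and writes one femoral and one tibial
#' stream CSV per recording plus a JSON manifest. Continuous activities
#' (walking, jogging, stair ascent/descent, standing still) are emitted as
#' multi-cycle recordings of `reps_per_recording` cycles each; transitional
#' activities (sitting down, standing up, knee bending) are emitted as
#' one-repetition segments running from the neutral posture to the end of
#' the movement. Every class receives at least `reps_per_class` repetitions.
#' Output is byte-reproducible for a fixed config (seed included).
#'
#' @param config a [sim_config()].
#' @param profiles named list of [activity_profile()]s
#'   (default [default_profiles()]).
#' @param output_dir directory to write into (created if needed).
#' @return The dataset manifest (see [load_manifest()]), invisibly written
#'   to `manifest.json` in `output_dir`.
#' @export
generate_dataset <- function(config, profiles = default_profiles(),
                             output_dir) {
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("generate_dataset: cannot create output directory ", output_dir)
  set.seed(config$seed)
  records <- list()
  for (profile in profiles) {
    continuous <- profile$waveform %in% c("periodic", "quasi_static")
    if (continuous) {
      n_rec <- ceiling(config$reps_per_class / config$reps_per_recording)
      reps_each <- config$reps_per_recording
    } else {
      n_rec <- config$reps_per_class
      reps_each <- 1L
    }
    for (i in seq_len(n_rec)) {
      rec_id <- sprintf("%s_%03d", profile$name, i)
      rec <- simulate_recording(profile, config, reps_each)
      fem_path <- file.path(output_dir, paste0(rec_id, "_femoral.csv"))
      tib_path <- file.path(output_dir, paste0(rec_id, "_tibial.csv"))
      write_stream(rec$femoral, fem_path)
      write_stream(rec$tibial, tib_path)
      records[[length(records) + 1L]] <- list(
        recording_id = rec_id, activity = profile$name,
        femoral_csv = basename(fem_path), tibial_csv = basename(tib_path),
        reps = reps_each)
    }
  }
  manifest <- dataset_manifest(records)
  save_manifest(manifest, file.path(output_dir, "manifest.json"))
  invisible(manifest)
}
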