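# Shared fixtures: everything is generated in code, no stored data files.

# stream with given timestamps, deterministic channel values
make_stream <- function(t_ms, device = "femoral") {
  n <- length(t_ms)
  imu_stream(device, data.frame(
    t_ms = as.integer(t_ms),
    ax_mps2 = seq_len(n) * 0.1, ay_mps2 = seq_len(n) * 0.2,
    az_mps2 = rep(9.81, n), gx_dps = seq_len(n) * 1.0,
    gy_dps = rep(0, n), gz_dps = rep(0, n)))
}

# noiseless simulation config for kinematic-fidelity checks
quiet_config <- function(...) {
  sim_config(accel_noise_sd = 0, gyro_noise_sd = 0, gyro_bias_walk_sd = 0,
             dropout_prob = 0, start_offset_max = 0, ...)
}

# brute-force binning oracle: scan all (sample, bin) pairs
bin_oracle <- function(stream, bin_width) {
  t <- stream$samples$t_ms
  ks <- sort(unique(t %/% bin_width))
  vals <- matrix(0, length(ks), 6)
  for (j in seq_along(ks)) {
    k <- ks[j]
    inbin <- which(t >= k * bin_width & t < (k + 1) * bin_width)
    pick <- inbin[which.max(t[inbin])]
    vals[j, ] <- as.numeric(stream$samples[pick, -1])
  }
  list(bin = as.integer(ks), values = vals,
       bin_width = as.integer(bin_width))
}

# random irregular stream for property tests
random_stream <- function(n, device = "femoral", t_max = 5000) {
  t <- sort(sample.int(t_max, n))
  make_stream(t, device)
}

# a tiny aligned series built directly (bypassing alignment)
make_series <- function(n_frames, start_bin = 0L, value = NULL) {
  frames <- if (is.null(value))
    matrix(rnorm(n_frames * 12), n_frames, 12)
  else matrix(value, n_frames, 12)
  structure(list(bin_width = 100L, start_bin = start_bin, frames = frames,
                 fill_mask = matrix(FALSE, n_frames, 2)),
            class = "aligned_series")
}

make_window <- function(frames = matrix(rnorm(30 * 12), 30, 12),
                        label = "walking") {
  structure(list(frames = frames, label = label,
                 origin = list(recording_id = "fx", start_bin = 0L)),
            class = "adl_window")
}

# small random classification dataset for model tests
tiny_dataset <- function(n_per_class = 2, k = 8, seed = 1) {
  set.seed(seed)
  n <- n_per_class * k
  labels <- rep(seq_len(k), each = n_per_class)
  windows <- array(rnorm(n * 30 * 12), c(n, 30, 12))
  # make classes trivially separable via a per-class offset
  for (i in seq_len(n)) windows[i, , ] <- windows[i, , ] + labels[i]
  tensors <- array(0, c(n, 8, 8, 12))
  for (i in seq_len(n))
    tensors[i, , , ] <- spectrogram_tensor(windows[i, , ])
  list(windows = windows, tensors = tensors, labels = labels)
}

small_model_config <- function(...) {
  model_config(lstm_units = c(16, 12), conv_filters = 8,
               cnn_dense_units = 12, fusion_units = 24, ...)
}
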