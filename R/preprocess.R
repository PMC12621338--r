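#' Filter specification
#'
#' Describes one Butterworth filtering path. Filtering operates on the
#' binned 10 Hz series (effective Nyquist 5 Hz), after the two device
#' streams have been synchronised. Defaults used by the pipeline: low-pass
#' order 4 at 2 Hz for accelerometer channels (locomotor content at the
#' simulated cycle rates lies below ~2 Hz), high-pass order 2 at 0.25 Hz for
#' gyroscope channels (drift rejection); both zero-phase.
#'
#' @param kind `"low_pass"` or `"high_pass"`.
#' @param cutoff cutoff frequency, Hz; must satisfy `0 < cutoff < fs / 2`.
#' @param order filter order, >= 1.
#' @param zero_phase apply forward-backward (no phase lag) if `TRUE`.
#' @param fs sampling rate of the series the filter runs on, Hz
#'   (default 10, the binned rate).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("low_pass", "high_pass"), cutoff, order = 2,
                        zero_phase = TRUE, fs = 10) {
  kind <- match.arg(kind)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("filter_spec: cutoff must lie in (0, ", fs / 2, ") Hz, got ",
         cutoff)
  if (order < 1) stop("filter_spec: order must be >= 1")
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase), fs = fs),
            class = "filter_spec")
}

# Real polynomial coefficients from complex roots (descending powers).
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  Re(p)
}

#' Digital Butterworth coefficients
#'
#' Designs an order-`n` digital Butterworth filter by bilinear transform of
#' the analog prototype (matching the conventional scipy/matlab `butter`
#' design): prototype poles on the unit left-half-plane circle, frequency
#' pre-warping, low-pass or high-pass transformation, then the bilinear map.
#'
#' @param order filter order.
#' @param cutoff -3 dB cutoff, Hz.
#' @param fs sampling rate, Hz.
#' @param kind `"low_pass"` or `"high_pass"`.
#' @return List with numerator `b` and denominator `a` (both length
#'   `order + 1`, `a[1] = 1`).
#' @export
butter_coef <- function(order, cutoff, fs, kind = c("low_pass", "high_pass")) {
  kind <- match.arg(kind)
  n <- as.integer(order)
  Wn <- cutoff / (fs / 2)
  if (Wn <= 0 || Wn >= 1) stop("butter_coef: cutoff out of (0, Nyquist)")
  # analog prototype: poles at exp(i*pi*(2k + n - 1) / (2n)), k = 1..n
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2
  warped <- 2 * fs2 * tan(pi * Wn / 2)
  if (kind == "low_pass") {
    p <- warped * p
    z <- complex(0)
    gain <- warped^n
  } else {
    gain <- 1        # hp transform of unity-gain prototype keeps k = 1
    z <- rep(0 + 0i, n)
    p <- warped / p
  }
  # bilinear transform s -> 2*fs2*(z-1)/(z+1)
  pz <- (2 * fs2 + p) / (2 * fs2 - p)
  zz <- if (length(z)) (2 * fs2 + z) / (2 * fs2 - z) else complex(0)
  gain <- gain * Re(prod(2 * fs2 - z) / prod(2 * fs2 - p))
  # pad zeros at z = -1 to full order (low-pass has no finite analog zeros)
  zz <- c(zz, rep(-1 + 0i, n - length(zz)))
  b <- gain * poly_from_roots(zz)
  a <- poly_from_roots(pz)
  list(b = b, a = a)
}

#' Closed-form Butterworth magnitude response
#'
#' Magnitude of the digital Butterworth filter described by the spec at
#' frequency `f` Hz. The bilinear design warps frequencies, so the analog
#' form `1 / sqrt(1 + (f / fc)^(2n))` holds in the warped variable
#' `tan(pi f / fs)`: the gain is `1 / sqrt(1 + r^(2n))` with
#' `r = tan(pi f / fs) / tan(pi fc / fs)` for low-pass (reciprocal for
#' high-pass). For `f << fs / 2` this reduces to the familiar analog
#' expression; near Nyquist the digital filter attenuates much harder.
#' Squared when the spec is zero-phase (the filter is applied twice). Used
#' as the independent oracle for attenuation tests.
#'
#' @param spec a [filter_spec()].
#' @param f frequency, Hz (vectorised).
#' @return Expected amplitude gain at `f`.
#' @export
butter_gain <- function(spec, f) {
  wf <- tan(pi * f / spec$fs)
  wc <- tan(pi * spec$cutoff / spec$fs)
  ratio <- if (spec$kind == "low_pass") wf / wc else wc / wf
  g <- 1 / sqrt(1 + ratio^(2 * spec$order))
  if (spec$zero_phase) g^2 else g
}

# Single-pass IIR filtering, direct form I via stats::filter (C speed):
# moving-average part by one-sided convolution, recursion by stats::filter.
iir_filter <- function(x, b, a) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive")
    as.numeric(y)
  } else v
}

#' Zero-phase Butterworth filtering of one series
#'
#' Applies the spec's filter; when `zero_phase` the filter runs forward then
#' backward so the net phase response is zero and the magnitude response is
#' squared. Edges are handled by odd-reflection padding of up to one window
#' length (30 samples), which preserves both the endpoint values and slopes
#' and keeps start-up transients out of the returned series.
#'
#' @param x numeric series.
#' @param spec a [filter_spec()].
#' @return Filtered series, same length as `x`.
#' @export
apply_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  min_len <- 3 * spec$order
  if (n < min_len)
    stop("apply_filter: series of length ", n,
         " too short for order ", spec$order, " (need >= ", min_len, ")")
  co <- butter_coef(spec$order, spec$cutoff, spec$fs, spec$kind)
  pad <- min(n - 1L, 30L)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter(ext, co$b, co$a)
  if (spec$zero_phase) y <- rev(iir_filter(rev(y), co$b, co$a))
  y[(pad + 1):(pad + n)]
}

#' Filter accelerometer / gyroscope channels
#'
#' `filter_accel` low-passes an accelerometer series (removing
#' high-frequency noise and vibration while preserving DC, i.e. gravity);
#' `filter_gyro` high-passes a gyroscope series (removing bias drift; the
#' mean of a constant input maps to ~0).
#'
#' @param series numeric channel series.
#' @param spec a [filter_spec()] of the matching kind.
#' @return Filtered series.
#' @export
filter_accel <- function(series, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$kind != "low_pass")
    stop("filter_accel: spec must be low_pass")
  apply_filter(series, spec)
}

#' @rdname filter_accel
#' @export
filter_gyro <- function(series, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$kind != "high_pass")
    stop("filter_gyro: spec must be high_pass")
  apply_filter(series, spec)
}

default_accel_spec <- function(fs = 10)
  filter_spec("low_pass", cutoff = 2, order = 4, zero_phase = TRUE, fs = fs)

default_gyro_spec <- function(fs = 10)
  filter_spec("high_pass", cutoff = 0.25, order = 2, zero_phase = TRUE,
              fs = fs)

ACCEL_CHANNELS <- c(1:3, 7:9)
GYRO_CHANNELS <- c(4:6, 10:12)

# Dual-path filtering of an n x 12 frame matrix (columns: femoral
# ax,ay,az,gx,gy,gz then tibial same).
filter_frames <- function(frames, accel_spec = default_accel_spec(),
                          gyro_spec = default_gyro_spec()) {
  stopifnot(ncol(frames) == 12)
  out <- frames
  for (j in ACCEL_CHANNELS) out[, j] <- filter_accel(frames[, j], accel_spec)
  for (j in GYRO_CHANNELS) out[, j] <- filter_gyro(frames[, j], gyro_spec)
  out
}

#' Apply dual-path filtering to one window
#'
#' Low-passes the six accelerometer channels (columns 1--3 and 7--9) and
#' high-passes the six gyroscope channels (columns 4--6 and 10--12),
#' channel-locally; label and origin are unchanged. The pipeline default is
#' to filter whole aligned segments before cutting windows (fewer edge
#' artifacts); this per-window entry point supports the alternative order.
#'
#' @param window an `adl_window` from [cut_windows()].
#' @param accel_spec low-pass [filter_spec()] for accelerometer channels.
#' @param gyro_spec high-pass [filter_spec()] for gyroscope channels.
#' @return The filtered window.
#' @export
preprocess_window <- function(window, accel_spec = default_accel_spec(),
                              gyro_spec = default_gyro_spec()) {
  stopifnot(inherits(window, "adl_window"))
  window$frames <- filter_frames(window$frames, accel_spec, gyro_spec)
  window
}
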