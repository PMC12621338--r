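#' Default short-time Fourier parameters
#'
#' The parameters that turn a 30-sample window channel into an 8 x 8
#' time-frequency image: 8-sample Hann-tapered segments, hop 3
#' (`floor((30 - 8) / 3) + 1 = 8` time frames), zero-padded to transform
#' length 14 (`14 / 2 + 1 = 8` one-sided frequency bins), power scaled as
#' `log(1 + power)`.
#'
#' @return Named list of STFT parameters.
#' @export
stft_params <- function() {
  list(segment_length = 8L, hop = 3L, transform_length = 14L,
       scaling = "log1p_power", taper = "hann")
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Spectrogram image of one window channel
#'
#' Short-time Fourier transform of a 30-sample series: sliding Hann-tapered
#' segments, zero-padded FFT, one-sided power, `log(1 + power)` scaling.
#' Rows are frequency bins (DC first), columns time frames.
#'
#' @param series numeric vector of length 30.
#' @param params STFT parameters, see [stft_params()].
#' @return An 8 x 8 numeric matrix.
#' @export
spectrogram_channel <- function(series, params = stft_params()) {
  L <- params$segment_length
  if (length(series) != 30)
    stop("spectrogram_channel: series must have length 30, got ",
         length(series))
  starts <- seq(1L, length(series) - L + 1L, by = params$hop)
  nf <- params$transform_length %/% 2L + 1L
  w <- hann_window(L)
  out <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- series[starts[j]:(starts[j] + L - 1L)] * w
    X <- stats::fft(c(seg, rep(0, params$transform_length - L)))
    out[, j] <- log1p(Mod(X[1:nf])^2)
  }
  out
}

#' Spectrogram tensor of a 12-channel window
#'
#' Stacks the 12 per-channel spectrogram images of a window in the fixed
#' channel order (femoral ax, ay, az, gx, gy, gz, then tibial likewise),
#' yielding the 8 x 8 x 12 tensor consumed by the convolutional branch.
#'
#' @param window an `adl_window` (30 x 12 frames).
#' @param params STFT parameters, see [stft_params()].
#' @return Object of class `spectrogram_tensor`: an 8 x 8 x 12 array with a
#'   `params` attribute.
#' @export
spectrogram_tensor <- function(window, params = stft_params()) {
  frames <- if (inherits(window, "adl_window")) window$frames else window
  if (!is.matrix(frames) || nrow(frames) != 30 || ncol(frames) != 12)
    stop("spectrogram_tensor: window frames must be 30 x 12")
  imgs <- vapply(seq_len(12),
                 function(c) spectrogram_channel(frames[, c], params),
                 matrix(0, 8, 8))
  structure(imgs, params = params, class = c("spectrogram_tensor", "array"))
}

#' Per-channel standardisation of spectrogram tensors
#'
#' Standardises each of the 12 channels using mean and SD computed from a
#' training set only; the returned statistics are persisted with the model
#' and reapplied verbatim to validation/test tensors. Channels with SD below
#' `1e-8` are floored to avoid division blow-up (a constant channel maps to
#' zero).
#'
#' @param tensors an N x 8 x 8 x 12 array (or list of tensors).
#' @param stats `NULL` to compute statistics from `tensors` (training), or
#'   a previously returned `stats` list to apply.
#' @return List with `tensors` (standardised array) and `stats`
#'   (`mean`, `sd` per channel).
#' @export
normalize_tensors <- function(tensors, stats = NULL) {
  if (is.list(tensors) && !is.array(tensors))
    tensors <- tensor_stack(tensors)
  stopifnot(length(dim(tensors)) == 4)
  nc <- dim(tensors)[4]
  if (is.null(stats)) {
    m <- vapply(seq_len(nc), function(c) mean(tensors[, , , c]), 0)
    s <- vapply(seq_len(nc), function(c) stats::sd(as.vector(tensors[, , , c])), 0)
    s[!is.finite(s)] <- 0
    stats <- list(mean = m, sd = pmax(s, 1e-8))
  }
  if (is.null(stats$mean) || is.null(stats$sd))
    stop("normalize_tensors: stats must carry mean and sd ",
         "(compute them on the training set first)")
  out <- tensors
  for (c in seq_len(nc))
    out[, , , c] <- (tensors[, , , c] - stats$mean[c]) / stats$sd[c]
  list(tensors = out, stats = stats)
}

# list of 8x8x12 tensors -> N x 8 x 8 x 12 array
tensor_stack <- function(tensors) {
  n <- length(tensors)
  out <- array(0, dim = c(n, 8, 8, 12))
  for (i in seq_len(n)) out[i, , , ] <- tensors[[i]]
  out
}

# list of adl_windows -> N x 30 x 12 array
window_stack <- function(windows) {
  n <- length(windows)
  out <- array(0, dim = c(n, 30, 12))
  for (i in seq_len(n)) out[i, , ] <- windows[[i]]$frames
  out
}

# per-channel standardisation of the time-domain windows (same contract as
# normalize_tensors; the recurrent branch needs inputs on tanh scale)
normalize_windows <- function(windows, stats = NULL) {
  stopifnot(length(dim(windows)) == 3)
  nc <- dim(windows)[3]
  if (is.null(stats)) {
    m <- vapply(seq_len(nc), function(c) mean(windows[, , c]), 0)
    s <- vapply(seq_len(nc), function(c) stats::sd(as.vector(windows[, , c])), 0)
    s[!is.finite(s)] <- 0
    stats <- list(mean = m, sd = pmax(s, 1e-8))
  }
  out <- windows
  for (c in seq_len(nc))
    out[, , c] <- (windows[, , c] - stats$mean[c]) / stats$sd[c]
  list(windows = out, stats = stats)
}
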