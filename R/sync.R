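#' Bin an IMU stream onto a fixed time grid
#'
#' Maps samples onto consecutive `bin_width` ms bins; bin `k` covers the
#' half-open interval `[k * bin_width, (k + 1) * bin_width)` of the recording
#' epoch (bin indices are absolute, not relative to the device's first
#' sample, so both devices share one time base). Each occupied bin retains
#' only the most recent sample strictly before the bin's upper boundary;
#' bins containing no sample are simply absent from the result.
#'
#' @param stream an [imu_stream()].
#' @param bin_width bin width in ms (default 100).
#' @return List with `bin` (sorted integer bin indices), `values` (matrix,
#'   one row per occupied bin, 6 channels) and `bin_width`.
#' @export
bin_stream <- function(stream, bin_width = 100) {
  stopifnot(inherits(stream, "imu_stream"), bin_width > 0)
  s <- stream$samples
  if (!nrow(s)) stop("bin_stream: empty stream")
  k <- s$t_ms %/% bin_width
  # timestamps are strictly increasing, so the last row of each bin group
  # is the most recent sample below the boundary
  last <- !duplicated(k, fromLast = TRUE)
  vals <- as.matrix(s[last, STREAM_COLUMNS[-1], drop = FALSE])
  dimnames(vals) <- NULL
  list(bin = as.integer(k[last]), values = vals,
       bin_width = as.integer(bin_width))
}

#' Align two binned device streams onto a common grid
#'
#' Restricts both devices to the intersection of their occupied bin ranges,
#' fills each device's empty bins by carrying its previous retained sample
#' forward (flagged in `fill_mask`), and splits the output wherever either
#' device is empty for a run of more than `max_gap` consecutive bins —
#' carry-forward over bounded gaps extends the "most recent sample" rule,
#' but long outages must not fabricate data. Femoral channels always occupy
#' columns 1--6 of each frame and tibial channels columns 7--12.
#'
#' @param femoral_bins,tibial_bins results of [bin_stream()].
#' @param max_gap maximum run of empty bins (per device) bridged by
#'   carry-forward before the series is split (default 3, i.e. 300 ms).
#' @return List of `aligned_series` segments; each has `bin_width`,
#'   `start_bin`, `frames` (n x 12 matrix) and `fill_mask` (n x 2 logical,
#'   columns femoral/tibial).
#' @export
align_dual <- function(femoral_bins, tibial_bins, max_gap = 3) {
  stopifnot(femoral_bins$bin_width == tibial_bins$bin_width)
  lo <- max(min(femoral_bins$bin), min(tibial_bins$bin))
  hi <- min(max(femoral_bins$bin), max(tibial_bins$bin))
  if (lo > hi)
    stop("align_dual: no overlap between device bin ranges [",
         min(femoral_bins$bin), ", ", max(femoral_bins$bin), "] and [",
         min(tibial_bins$bin), ", ", max(tibial_bins$bin), "]")
  bins <- lo:hi
  n <- length(bins)

  expand <- function(dev) {
    occupied <- dev$bin %in% bins
    idx <- match(bins, dev$bin)           # NA where the device bin is empty
    filled <- is.na(idx)
    # carry forward: last occupied device bin at or before each grid bin
    src <- findInterval(bins, dev$bin)    # dev rows are sorted by bin
    vals <- dev$values[src, , drop = FALSE]
    list(values = vals, filled = filled)
  }
  fem <- expand(femoral_bins)
  tib <- expand(tibial_bins)

  # a bin is unusable if it lies inside a > max_gap empty run on either side
  bad <- long_run_mask(fem$filled, max_gap) | long_run_mask(tib$filled, max_gap)
  frames <- cbind(fem$values, tib$values)
  mask <- cbind(femoral = fem$filled, tibial = tib$filled)

  good <- !bad
  if (!any(good)) return(list())
  runs <- rle(good)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- which(runs$values)
  lapply(segs, function(s) {
    i <- starts[s]:ends[s]
    structure(list(bin_width = femoral_bins$bin_width,
                   start_bin = bins[starts[s]],
                   frames = frames[i, , drop = FALSE],
                   fill_mask = mask[i, , drop = FALSE]),
              class = "aligned_series")
  })
}

long_run_mask <- function(filled, max_gap) {
  out <- logical(length(filled))
  r <- rle(filled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values & r$lengths > max_gap))
    out[starts[j]:ends[j]] <- TRUE
  out
}

#' Cut fixed-length windows from an aligned series
#'
#' Extracts the maximal set of windows of exactly `length` consecutive
#' frames, starting at multiples of `stride` from the segment start; a
#' trailing partial window is discarded. With the default 100 ms bins and 30
#' frames, every window spans exactly 3 s of activity.
#'
#' @param series an `aligned_series` segment from [align_dual()].
#' @param length window length in frames (default 30).
#' @param stride start-to-start spacing in frames (default 30,
#'   non-overlapping).
#' @param label optional activity label attached to each window.
#' @param recording_id optional provenance identifier.
#' @return List of `adl_window` objects, each with a `frames` 30 x 12
#'   matrix, `label` and `origin`; empty list if the series is shorter than
#'   `length`.
#' @export
cut_windows <- function(series, length = 30, stride = 30, label = NULL,
                        recording_id = NULL) {
  stopifnot(inherits(series, "aligned_series"), length >= 1, stride >= 1)
  n <- nrow(series$frames)
  if (n < length) return(list())
  starts <- seq(1L, n - length + 1L, by = stride)
  lapply(starts, function(s) {
    structure(list(frames = series$frames[s:(s + length - 1L), ,
                                          drop = FALSE],
                   label = label,
                   origin = list(recording_id = recording_id,
                                 start_bin = series$start_bin + s - 1L)),
              class = "adl_window")
  })
}
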