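STREAM_COLUMNS <- c("t_ms", "ax_mps2", "ay_mps2", "az_mps2",
                    "gx_dps", "gy_dps", "gz_dps")

#' IMU stream container
#'
#' A stream is one device's timestamped 6-channel series: integer
#' milliseconds since the stream epoch plus three accelerometer channels
#' (m/s^2) and three gyroscope channels (deg/s). Timestamps must be strictly
#' increasing; the nominal inter-sample gap is 20 ms (50 Hz), with larger
#' gaps permitted where samples were missed.
#'
#' @param device_id `"femoral"` or `"tibial"`.
#' @param samples data.frame with columns `t_ms, ax_mps2, ay_mps2, az_mps2,
#'   gx_dps, gy_dps, gz_dps`.
#' @return Object of class `imu_stream`.
#' @export
imu_stream <- function(device_id = c("femoral", "tibial"), samples) {
  device_id <- match.arg(device_id)
  stopifnot(is.data.frame(samples))
  missing <- setdiff(STREAM_COLUMNS, names(samples))
  if (length(missing))
    stop("imu_stream: missing columns: ", paste(missing, collapse = ", "))
  samples <- samples[, STREAM_COLUMNS, drop = FALSE]
  if (nrow(samples)) {
    bad <- !apply(is.finite(as.matrix(samples)), 1L, all)
    if (any(bad))
      stop("imu_stream: ", sum(bad), " rows contain non-finite values")
    d <- diff(samples$t_ms)
    if (length(d) && any(d <= 0))
      stop("imu_stream: timestamps not strictly increasing at row ",
           which(d <= 0)[1] + 1L)
  }
  rownames(samples) <- NULL
  structure(list(device_id = device_id, samples = samples),
            class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat("<imu_stream> device:", x$device_id, "-", nrow(x$samples), "samples")
  if (nrow(x$samples))
    cat(", t =", x$samples$t_ms[1], "..",
        x$samples$t_ms[nrow(x$samples)], "ms")
  cat("\n")
  invisible(x)
}

#' Read an IMU stream CSV
#'
#' Parses the stream CSV dialect (`device_id,t_ms,ax_mps2,ay_mps2,az_mps2,
#' gx_dps,gy_dps,gz_dps`). Rows containing non-finite channel values are
#' rejected with a message reporting the count. CRLF and trailing-newline
#' variants are accepted. Non-monotone timestamps raise a validation error
#' naming the first offending row.
#'
#' @param path file path.
#' @return An [imu_stream()].
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("read_stream: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device_id", STREAM_COLUMNS)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_stream: ", path, " missing columns: ",
         paste(missing, collapse = ", "))
  device <- if (nrow(df)) df$device_id[1] else "femoral"
  num <- as.matrix(df[, STREAM_COLUMNS, drop = FALSE])
  storage.mode(num) <- "double"
  finite <- apply(is.finite(num), 1L, all)
  if (any(!finite)) {
    message("read_stream: dropped ", sum(!finite),
            " rows with non-finite values from ", basename(path))
    df <- df[finite, , drop = FALSE]
  }
  d <- diff(df$t_ms)
  if (length(d) && any(d <= 0))
    stop("read_stream: timestamps not strictly increasing at data row ",
         which(d <= 0)[1] + 1L, " of ", path)
  samples <- df[, STREAM_COLUMNS, drop = FALSE]
  samples$t_ms <- as.integer(samples$t_ms)
  imu_stream(device, samples)
}

#' Write an IMU stream CSV
#'
#' Deterministic formatting: integer timestamps and fixed 6-decimal channel
#' values, LF line endings, so identical streams always produce identical
#' bytes. An empty stream writes a header-only file.
#'
#' @param stream an [imu_stream()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "imu_stream"))
  header <- paste(c("device_id", STREAM_COLUMNS), collapse = ",")
  s <- stream$samples
  lines <- character(0)
  if (nrow(s)) {
    lines <- sprintf("%s,%d,%.6f,%.6f,%.6f,%.6f,%.6f,%.6f",
                     stream$device_id, s$t_ms, s$ax_mps2, s$ay_mps2,
                     s$az_mps2, s$gx_dps, s$gy_dps, s$gz_dps)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Dataset manifest container
#'
#' @param recordings list of records, each a list with fields
#'   `recording_id`, `activity` (one of [adl_classes()]), `femoral_csv`,
#'   `tibial_csv` and optionally `reps`.
#' @return Object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(recordings = list()) {
  for (r in recordings) {
    need <- c("recording_id", "activity", "femoral_csv", "tibial_csv")
    missing <- setdiff(need, names(r))
    if (length(missing))
      stop("dataset_manifest: record missing fields: ",
           paste(missing, collapse = ", "))
    if (!r$activity %in% adl_classes())
      stop("dataset_manifest: unknown activity '", r$activity,
           "'; allowed: ", paste(adl_classes(), collapse = ", "))
  }
  structure(list(recordings = recordings), class = "dataset_manifest")
}

#' Save / load a dataset manifest (JSON)
#'
#' @param manifest a [dataset_manifest()].
#' @param path JSON file path.
#' @return `save_manifest` returns `path` invisibly; `load_manifest`
#'   returns the validated [dataset_manifest()].
#' @export
save_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  jsonlite::write_json(list(recordings = manifest$recordings), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("load_manifest: no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  dataset_manifest(raw$recordings)
}
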