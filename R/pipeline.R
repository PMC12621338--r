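#' Default pipeline configuration
#'
#' One nested configuration object for the whole pipeline. Every default
#' reproduces the pipeline's printed constants: 50 Hz simulation, 100 reps
#' per class, 100 ms bins, 30-frame (3 s) windows, 12 channels, 8 x 8 x 12
#' spectrogram tensors, LSTM 384/256 with 20%/45% dropout, 128-filter
#' convolution with 40% dropout and 256-unit projection, 256-unit fusion,
#' 8 classes, 70/11/19 split. The training schedule is the desk-scale
#' benchmark one: at most 50 epochs with early-stopping patience 10.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 42) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(sample_rate = 50, reps_per_class = 100,
                    accel_noise_sd = 0.5, gyro_noise_sd = 1,
                    gyro_bias_walk_sd = 0.05, start_offset_max = 200,
                    dropout_prob = 0.01, reps_per_recording = 10),
    sync = list(bin_ms = 100, max_gap = 3, stride = 30),
    filters = list(accel = list(kind = "low_pass", cutoff = 2, order = 4,
                                zero_phase = TRUE),
                   gyro = list(kind = "high_pass", cutoff = 0.25, order = 2,
                               zero_phase = TRUE)),
    features = stft_params(),
    model = list(lstm_units = c(384, 256), lstm_dropout = c(0.20, 0.45),
                 conv_filters = 128, conv_dropout = 0.40,
                 cnn_dense_units = 256, fusion_units = 256, n_classes = 8,
                 learning_rate = 1e-3, batch_size = 32, max_epochs = 50,
                 early_stop_patience = 10,
                 cnn_dense_after_flatten = FALSE, branch = "fused"),
    split = list(fractions = c(train = 0.70, validation = 0.11,
                               test = 0.19),
                 stratified = TRUE, group_by_recording = TRUE),
    classes = adl_classes()), class = "pipeline_config")
}

# multiplicative-congruential substream seeds (always < 2^31)
derive_seed <- function(master, k) {
  s <- (as.double(master) %% 2147483646) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

#' Validate a pipeline configuration
#'
#' Accepts a `pipeline_config`, a plain nested list, or a path to a JSON
#' file with the same schema. Unknown keys are rejected with suggestions;
#' constraint violations are aggregated into one readable error.
#'
#' @param config config object, list or JSON path.
#' @return The normalised `pipeline_config` (invisible errors impossible:
#'   invalid input raises).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("validate_config: no such file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_pipeline_config()
  errs <- character(0)
  known <- names(base)
  extra <- setdiff(names(config), known)
  for (e in extra) {
    hint <- known[which.min(utils::adist(e, known))]
    errs <- c(errs, sprintf("unknown key '%s' (did you mean '%s'?)", e, hint))
  }
  merged <- utils::modifyList(unclass(base), config[intersect(names(config), known)])
  if (!is.numeric(merged$sync$bin_ms) || merged$sync$bin_ms <= 0)
    errs <- c(errs, "sync$bin_ms must be > 0")
  if (merged$sync$stride < 1) errs <- c(errs, "sync$stride must be >= 1")
  fr <- merged$split$fractions
  if (length(fr) != 3 || abs(sum(fr) - 1) > 1e-9)
    errs <- c(errs, sprintf("split$fractions must sum to 1 (got %.3f)", sum(fr)))
  if (merged$simulate$sample_rate <= 0 ||
      1000 %% merged$simulate$sample_rate != 0)
    errs <- c(errs, "simulate$sample_rate must divide 1000 ms")
  if (merged$simulate$dropout_prob < 0 || merged$simulate$dropout_prob >= 0.5)
    errs <- c(errs, "simulate$dropout_prob must lie in [0, 0.5)")
  bad_cls <- setdiff(merged$classes, adl_classes())
  if (length(bad_cls))
    errs <- c(errs, paste0("unknown classes: ", paste(bad_cls, collapse = ", ")))
  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  structure(merged, class = "pipeline_config")
}

config_sim <- function(config) {
  s <- config$simulate
  sim_config(sample_rate = s$sample_rate, reps_per_class = s$reps_per_class,
             seed = derive_seed(config$seed, 1),
             accel_noise_sd = s$accel_noise_sd,
             gyro_noise_sd = s$gyro_noise_sd,
             gyro_bias_walk_sd = s$gyro_bias_walk_sd,
             start_offset_max = s$start_offset_max,
             dropout_prob = s$dropout_prob,
             reps_per_recording = s$reps_per_recording)
}

config_specs <- function(config) {
  fs <- 1000 / config$sync$bin_ms
  a <- config$filters$accel
  g <- config$filters$gyro
  list(accel = filter_spec(a$kind, a$cutoff, a$order, a$zero_phase, fs),
       gyro = filter_spec(g$kind, g$cutoff, g$order, g$zero_phase, fs))
}

#' Prepare a windowed dataset from a simulated/recorded dataset directory
#'
#' For every manifest recording: read both device streams, bin onto the
#' common grid, align (filling short gaps, splitting on long ones), filter
#' each contiguous aligned segment (low-pass accelerometer channels,
#' high-pass gyroscope channels), cut 30-frame windows and compute their
#' spectrogram tensors.
#'
#' @param dataset_dir directory containing `manifest.json` and stream CSVs.
#' @param config a validated `pipeline_config`.
#' @return List with `windows` (N x 30 x 12), `tensors` (N x 8 x 8 x 12),
#'   `labels` (integer, indexing `classes`), `groups` (recording ids),
#'   `classes`.
#' @export
prepare_dataset <- function(dataset_dir, config = default_pipeline_config()) {
  manifest <- load_manifest(file.path(dataset_dir, "manifest.json"))
  specs <- config_specs(config)
  classes <- config$classes
  windows <- list()
  labels <- integer(0)
  groups <- character(0)
  for (rec in manifest$recordings) {
    if (!rec$activity %in% classes) next
    fem <- read_stream(file.path(dataset_dir, rec$femoral_csv))
    tib <- read_stream(file.path(dataset_dir, rec$tibial_csv))
    fb <- bin_stream(fem, config$sync$bin_ms)
    tb <- bin_stream(tib, config$sync$bin_ms)
    segs <- align_dual(fb, tb, config$sync$max_gap)
    for (seg in segs) {
      if (nrow(seg$frames) < 30) next
      seg$frames <- filter_frames(seg$frames, specs$accel, specs$gyro)
      ws <- cut_windows(seg, length = 30, stride = config$sync$stride,
                        label = rec$activity,
                        recording_id = rec$recording_id)
      for (w in ws) {
        windows[[length(windows) + 1L]] <- w
        labels <- c(labels, match(rec$activity, classes))
        groups <- c(groups, rec$recording_id)
      }
    }
  }
  if (!length(windows)) stop("prepare_dataset: no windows produced")
  tens <- lapply(windows, spectrogram_tensor, params = config$features)
  list(windows = window_stack(windows), tensors = tensor_stack(tens),
       labels = labels, groups = groups, classes = classes)
}

subset_split <- function(data, idx) {
  list(windows = data$windows[idx, , , drop = FALSE],
       tensors = data$tensors[idx, , , , drop = FALSE],
       labels = data$labels[idx])
}

#' Run the end-to-end synthetic benchmark
#'
#' simulate -> synchronise -> filter -> spectrogram -> split -> train ->
#' evaluate, writing the dataset, trained model, evaluation report and a
#' provenance file into `out_dir`. All randomness derives from
#' `config$seed`.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir output directory.
#' @param verbose log stage progress via `message()`.
#' @return List with the test-set `report` (an `eval_report`), the trained
#'   `model`, and the `split` index sets.
#' @export
run_benchmark <- function(config = default_pipeline_config(), out_dir,
                          verbose = TRUE) {
  config <- validate_config(unclass(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message("[benchmark] ", ...)

  data_dir <- file.path(out_dir, "dataset")
  say("simulate: ", config$simulate$reps_per_class, " reps x ",
      length(config$classes), " classes at ",
      config$simulate$sample_rate, " Hz")
  profiles <- default_profiles()[config$classes]
  generate_dataset(config_sim(config), profiles, data_dir)

  say("prepare: binning at ", config$sync$bin_ms,
      " ms, 30-frame windows, stride ", config$sync$stride)
  data <- prepare_dataset(data_dir, config)
  say("prepare: ", length(data$labels), " windows from ",
      length(unique(data$groups)), " recordings")

  sp <- split_spec(config$split$fractions, config$split$stratified,
                   seed = derive_seed(config$seed, 2))
  groups <- if (isTRUE(config$split$group_by_recording)) data$groups else NULL
  split <- split_dataset(data$labels, sp, groups)
  say("split: train ", length(split$train), " / val ",
      length(split$validation), " / test ", length(split$test))

  m <- config$model
  mc <- model_config(lstm_units = m$lstm_units, lstm_dropout = m$lstm_dropout,
                     conv_filters = m$conv_filters,
                     conv_dropout = m$conv_dropout,
                     cnn_dense_units = m$cnn_dense_units,
                     fusion_units = m$fusion_units,
                     n_classes = length(config$classes),
                     learning_rate = m$learning_rate,
                     batch_size = m$batch_size, max_epochs = m$max_epochs,
                     early_stop_patience = m$early_stop_patience,
                     seed = derive_seed(config$seed, 3),
                     cnn_dense_after_flatten = m$cnn_dense_after_flatten,
                     branch = m$branch)
  model <- build_model(mc)
  model$classes <- config$classes
  say("train: ", m$branch, " branch, ", param_count(mc), " parameters, <= ",
      m$max_epochs, " epochs")
  model <- train_model(model, subset_split(data, split$train),
                       subset_split(data, split$validation),
                       verbose = verbose)
  say("train: best epoch ", model$best_epoch)
  save_model(model, file.path(out_dir, "model"))

  test <- subset_split(data, split$test)
  probs <- predict_model(model, test$windows, test$tensors)
  pred <- model$classes[max.col(probs, ties.method = "first")]
  truth <- config$classes[test$labels]
  report <- class_metrics(confusion(truth, pred, classes = config$classes))
  write_report(report, file.path(out_dir, "report"))
  say(sprintf("evaluate: accuracy %.4f, macro F1 %.4f on %d test windows",
              report$accuracy, report$macro$f1, report$total))

  prov <- list(seed = config$seed,
               config_hash = digest_config(config),
               r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("kneeadl")),
               timestamp = format(Sys.time(), tz = "UTC"),
               n_windows = length(data$labels),
               split_sizes = vapply(split, length, 0L),
               best_epoch = model$best_epoch)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(report = report, model = model, split = split, data = data)
}

digest_config <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest-package dependency
  bytes <- utf8ToInt(as.character(js))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
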