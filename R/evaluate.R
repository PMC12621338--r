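#' Split specification
#'
#' Train/validation/test fractions (defaults 0.70 / 0.11 / 0.19),
#' stratified by class. Per-class counts use largest-remainder rounding of
#' the fractions with any remainder going to the training split, so no
#' window is ever lost and a tiny class always contributes at least its
#' rounded share to training.
#'
#' @param fractions numeric length-3 vector summing to 1.
#' @param stratified stratify by class (always recommended).
#' @param seed RNG seed for the shuffle.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.70, validation = 0.11,
                                     test = 0.19),
                       stratified = TRUE, seed = 1) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stop("split_spec: fractions must be 3 values summing to 1 (got sum ",
         sum(fractions), ")")
  structure(list(fractions = fractions, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

# largest-remainder apportionment of n into 3 fractions, remainder to train
apportion <- function(n, fractions) {
  base <- floor(n * fractions)
  base[1] <- base[1] + (n - sum(base))
  as.integer(base)
}

#' Split a windowed dataset into train / validation / test
#'
#' Stratified by class: within each class, windows are shuffled and
#' apportioned by largest-remainder rounding of the fractions (remainders to
#' train). With `groups` (recording identifiers), whole recordings are kept
#' inside one split — windows cut from the same repetition never straddle a
#' split boundary, preventing leakage; recordings are assigned greedily
#' until each split's window target is reached, while guaranteeing every
#' split at least one recording per class when the class has three or more.
#'
#' @param labels integer or factor class labels, one per window.
#' @param spec a [split_spec()].
#' @param groups optional recording identifier per window.
#' @return List of integer index vectors `train`, `validation`, `test`;
#'   disjoint and exhaustive.
#' @export
split_dataset <- function(labels, spec = split_spec(), groups = NULL) {
  if (!length(labels))
    stop("split_dataset: every class needs at least one window")
  labels <- as.integer(as.factor(labels))
  classes <- sort(unique(labels))
  set.seed(spec$seed)
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (cl in classes) {
    idx <- which(labels == cl)
    if (is.null(groups)) {
      idx <- idx[sample.int(length(idx))]
      n3 <- apportion(length(idx), spec$fractions)
      out$train <- c(out$train, idx[seq_len(n3[1])])
      out$validation <- c(out$validation,
                          idx[seq_len(n3[2]) + n3[1]])
      out$test <- c(out$test, idx[seq_len(n3[3]) + n3[1] + n3[2]])
    } else {
      g <- groups[idx]
      recs <- unique(g)
      recs <- recs[sample.int(length(recs))]
      n3 <- apportion(length(idx), spec$fractions)
      sizes <- vapply(recs, function(r) sum(g == r), 0L)
      assign <- rep(1L, length(recs))
      # fill validation and test up to target; keep >=1 recording each
      cum <- 0L
      tgt_val <- n3[2]
      tgt_test <- n3[3]
      take <- function(target, avail) {
        sel <- integer(0)
        tot <- 0L
        for (r in avail) {
          if (tot >= target) break
          sel <- c(sel, r)
          tot <- tot + sizes[r]
        }
        sel
      }
      avail <- seq_along(recs)
      if (length(recs) >= 3) {
        sel_test <- take(max(tgt_test, 1L), avail)
        avail <- setdiff(avail, sel_test)
        sel_val <- take(max(tgt_val, 1L), avail)
        avail <- setdiff(avail, sel_val)
        assign[sel_test] <- 3L
        assign[sel_val] <- 2L
      } else if (length(recs) == 2) {
        assign[2] <- 3L
      }
      for (j in seq_along(recs)) {
        dest <- c("train", "validation", "test")[assign[j]]
        out[[dest]] <- c(out[[dest]], idx[g == recs[j]])
      }
    }
  }
  out <- lapply(out, sort)
  stopifnot(length(Reduce(union, out)) == length(labels))
  out
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples with true class `i` predicted as class
#' `j`; rows are true labels, columns predictions, row sums the supports.
#'
#' @param true,predicted label vectors of equal length (character, factor
#'   or integer).
#' @param classes class levels fixing row/column order (default
#'   [adl_classes()] restricted to observed labels).
#' @return Integer matrix with dimnames `true` x `predicted`.
#' @export
confusion <- function(true, predicted, classes = NULL) {
  if (length(true) != length(predicted))
    stop("confusion: label vectors differ in length")
  if (is.null(classes)) {
    classes <- intersect(adl_classes(), unique(c(true, predicted)))
    if (!length(classes)) classes <- sort(unique(c(true, predicted)))
  }
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad))
    stop("confusion: unknown labels: ", paste(bad, collapse = ", "))
  ti <- match(true, classes)
  pi <- match(predicted, classes)
  k <- length(classes)
  m <- matrix(tabulate((ti - 1L) * k + pi, nbins = k * k),
              nrow = k, byrow = TRUE,
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class and aggregate classification metrics
#'
#' From a confusion matrix computes per-class precision
#' (`diag / column sum`), recall (`diag / row sum`), F1 (harmonic mean) and
#' support, plus overall accuracy (`trace / total`), macro (unweighted) and
#' weighted (support-weighted) averages. Zero-denominator cases yield 0 and
#' are flagged.
#'
#' @param matrix square nonnegative integer confusion matrix.
#' @return Object of class `eval_report`: list with `per_class` data frame,
#'   `accuracy`, `macro`, `weighted`, `confusion`, `total` and
#'   `zero_division` flag vector.
#' @export
class_metrics <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            all(matrix >= 0))
  k <- nrow(matrix)
  diag_ <- diag(matrix)
  support <- rowSums(matrix)
  colsum <- colSums(matrix)
  zflag <- logical(k)
  precision <- ifelse(colsum > 0, diag_ / colsum, 0)
  recall <- ifelse(support > 0, diag_ / support, 0)
  zflag <- colsum == 0 | support == 0 | (precision + recall) == 0
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  total <- sum(matrix)
  w <- if (total > 0) support / total else rep(0, k)
  classes <- rownames(matrix)
  if (is.null(classes)) classes <- as.character(seq_len(k))
  structure(list(
    per_class = data.frame(class = classes, precision = precision,
                           recall = recall, f1 = f1,
                           support = as.integer(support),
                           row.names = NULL),
    accuracy = if (total > 0) sum(diag_) / total else 0,
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    weighted = list(precision = sum(w * precision),
                    recall = sum(w * recall), f1 = sum(w * f1)),
    confusion = matrix, total = as.integer(total),
    zero_division = zflag), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>  accuracy", sprintf("%.4f", x$accuracy),
      " macro F1", sprintf("%.4f", x$macro$f1), "\n")
  df <- x$per_class
  df$precision <- round(df$precision, 2)
  df$recall <- round(df$recall, 2)
  df$f1 <- round(df$f1, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report (JSON + CSV)
#'
#' The CSV mirrors the published results-table layout: one row per class
#' (precision, recall, F1, support to two decimals), an overall-accuracy
#' row and a weighted-average row. The JSON carries full precision and the
#' complete confusion matrix.
#'
#' @param report an `eval_report` from [class_metrics()].
#' @param path_prefix output path without extension; writes
#'   `<prefix>.json` and `<prefix>.csv`.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "eval_report"))
  jpath <- paste0(path_prefix, ".json")
  cpath <- paste0(path_prefix, ".csv")
  jsonlite::write_json(list(
    per_class = report$per_class, accuracy = report$accuracy,
    macro = report$macro, weighted = report$weighted,
    confusion = report$confusion, total = report$total,
    classes = rownames(report$confusion)), jpath,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pc <- report$per_class
  rows <- c(sprintf("%s,%.2f,%.2f,%.2f,%d", pc$class, pc$precision,
                    pc$recall, pc$f1, pc$support),
            sprintf("accuracy_overall,,,%.2f,%d", report$accuracy,
                    report$total),
            sprintf("weighted_average,%.2f,%.2f,%.2f,%d",
                    report$weighted$precision, report$weighted$recall,
                    report$weighted$f1, report$total))
  writeLines(c("activity,precision,recall,f1,support", rows), cpath)
  invisible(c(jpath, cpath))
}

#' Read back a JSON evaluation report
#'
#' @param path the `.json` file written by [write_report()].
#' @return An `eval_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.matrix(raw$confusion)
  dimnames(m) <- list(true = raw$classes, predicted = raw$classes)
  class_metrics(m)
}
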