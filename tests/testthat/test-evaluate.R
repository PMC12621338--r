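test_that("stratified splitting apportions 70/11/19 with largest remainder", {
  labels <- rep(1:8, each = 100)
  sp <- split_spec(seed = 3)
  s <- split_dataset(labels, sp)
  expect_length(s$train, 560)
  expect_length(s$validation, 88)
  expect_length(s$test, 152)
  for (cl in 1:8) {
    expect_equal(sum(labels[s$train] == cl), 70)
    expect_equal(sum(labels[s$validation] == cl), 11)
    expect_equal(sum(labels[s$test] == cl), 19)
  }
  # disjoint and exhaustive
  all_idx <- c(s$train, s$validation, s$test)
  expect_equal(sort(all_idx), seq_along(labels))

  # same seed -> identical split; different seed -> different
  expect_identical(s, split_dataset(labels, sp))
  expect_false(identical(s, split_dataset(labels, split_spec(seed = 4))))
})

test_that("tiny classes keep at least one training window, none lost", {
  labels <- c(rep(1, 3), rep(2, 100))
  s <- split_dataset(labels, split_spec(seed = 1))
  # largest-remainder on n=3: floor(2.1, .33, .57) = (2,0,0), remainder 1
  # to train -> all 3 in train
  expect_equal(sum(labels[s$train] == 1), 3)
  expect_equal(sort(c(s$train, s$validation, s$test)), seq_along(labels))
  expect_error(split_dataset(integer(0), split_spec()), "class")
})

test_that("recording-grouped splitting never straddles a recording", {
  labels <- rep(1:2, each = 60)
  groups <- paste0("r", rep(1:12, each = 10))
  s <- split_dataset(labels, split_spec(seed = 5), groups = groups)
  for (part in s) {
    gs <- unique(groups[part])
    for (g in gs) expect_true(all(which(groups == g) %in% part))
  }
  expect_equal(sort(unname(unlist(s))), seq_along(labels))
  # every split non-empty for both classes
  for (cl in 1:2) for (part in s)
    expect_gt(sum(labels[part] == cl), 0)
})

test_that("confusion matrix matches a brute-force pairwise count", {
  cls <- adl_classes()
  # hand cases
  all_good <- confusion(cls, cls)
  expect_equal(all_good, diag(8), ignore_attr = TRUE)
  one_off <- confusion("stair_descent", "stair_ascent", classes = cls)
  expect_equal(sum(one_off), 1)
  expect_equal(one_off["stair_descent", "stair_ascent"], 1)
  expect_error(confusion("walking", "sprinting", classes = cls), "unknown")

  set.seed(14)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    true <- sample(cls, n, replace = TRUE)
    pred <- sample(cls, n, replace = TRUE)
    m <- confusion(true, pred, classes = cls)
    brute <- matrix(0L, 8, 8, dimnames = list(true = cls, predicted = cls))
    for (i in seq_len(n))
      brute[true[i], pred[i]] <- brute[true[i], pred[i]] + 1L
    expect_equal(m, brute)
    expect_equal(rowSums(m), vapply(cls, function(c) sum(true == c), 0))
  }
})

test_that("class metrics reproduce published worked examples", {
  # recall 21/24 = 0.875 (the downstairs row's support and recall)
  m <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m[1, 1] <- 21
  m[1, 2] <- 3
  m[2, 2] <- 10
  r <- class_metrics(m)
  expect_equal(r$per_class$recall[1], 0.875)
  expect_equal(r$per_class$support[1], 24)

  # F1 from printed precision/recall pairs
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(round(f1(0.95, 0.88), 2), 0.91)  # walking downstairs
  expect_equal(round(f1(0.88, 0.97), 2), 0.92)  # walking upstairs
})

test_that("metrics agree with brute-force definitions on random matrices", {
  set.seed(15)
  for (rep in 1:15) {
    k <- sample(2:8, 1)
    m <- matrix(rpois(k * k, 3), k, k)
    r <- class_metrics(m)
    prec <- rec <- f1 <- numeric(k)
    for (c in seq_len(k)) {
      tp <- m[c, c]
      prec[c] <- if (sum(m[, c]) > 0) tp / sum(m[, c]) else 0
      rec[c] <- if (sum(m[c, ]) > 0) tp / sum(m[c, ]) else 0
      f1[c] <- if (prec[c] + rec[c] > 0)
        2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
    }
    expect_equal(r$per_class$precision, prec)
    expect_equal(r$per_class$recall, rec)
    expect_equal(r$per_class$f1, f1)
    expect_equal(r$accuracy, sum(diag(m)) / sum(m))
    expect_equal(r$macro$f1, mean(f1))
    w <- rowSums(m) / sum(m)
    expect_equal(r$weighted$f1, sum(w * f1))
    # micro accuracy equals support-weighted recall
    expect_equal(r$accuracy, r$weighted$recall)
    # macro F1 bounded by per-class extremes
    expect_lte(r$macro$f1, max(f1))
    expect_gte(r$macro$f1, min(f1))
    # support conservation
    expect_equal(sum(r$per_class$support), r$total)
  }
})

test_that("reports round-trip through JSON and the CSV mirrors the table", {
  set.seed(16)
  cls <- adl_classes()
  true <- sample(cls, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.9, true, sample(cls, 200, replace = TRUE))
  r <- class_metrics(confusion(true, pred, classes = cls))
  prefix <- file.path(withr::local_tempdir(), "report")
  write_report(r, prefix)
  back <- read_report(paste0(prefix, ".json"))
  expect_equal(back$per_class, r$per_class)
  expect_equal(back$accuracy, r$accuracy)
  expect_equal(back$confusion, r$confusion, ignore_attr = TRUE)

  csv <- readLines(paste0(prefix, ".csv"))
  expect_length(csv, 11)            # header + 8 classes + accuracy + weighted
  expect_match(csv[10], "^accuracy_overall")
  acc_cell <- as.numeric(strsplit(csv[10], ",")[[1]][4])
  expect_equal(acc_cell, round(sum(diag(r$confusion)) / sum(r$confusion), 2))
})
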