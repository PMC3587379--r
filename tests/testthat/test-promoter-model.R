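test_that("training sets pair each positive with a non-overlapping same-record negative", {
  recs <- gen_promoters(20, flank = 1000, seed = 41)
  w <- default_window()
  ts <- build_training_set(recs, w, seed = 41)
  expect_length(ts$positives, 20L)
  expect_length(ts$negatives, 20L)
  expect_true(all(nchar(ts$positives) == 300L))
  expect_true(all(nchar(ts$negatives) == 300L))
  # determinism
  ts2 <- build_training_set(recs, w, seed = 41)
  expect_identical(ts, ts2)
  # negatives truly avoid the positive window: check by locating them
  for (i in seq_along(recs)) {
    idx <- rel_to_index(w, recs[[i]]$tss_index, nchar(recs[[i]]$seq))
    n_start <- as.integer(regexpr(ts$negatives[[i]], recs[[i]]$seq,
                                  fixed = TRUE)) - 1L
    expect_gte(n_start, 0L)
    expect_true(n_start + 300L <= idx[["start"]] || n_start >= idx[["end"]])
  }
})

test_that("feature vectors have the fused 204-dimension OR+NC+DS schema", {
  hex <- head(all_words(6), 100)
  for (w in candidate_windows()) {
    L <- length(setdiff(w$start_rel:w$end_rel, 0L))
    x <- assemble_features(strrep("A", L), hex)
    expect_equal(ncol(x), 204L)
    nc <- x[, grepl("^NC_", colnames(x)), drop = FALSE]
    expect_equal(ncol(nc), 84L)
    expect_equal(sum(nc), 3, tolerance = 1e-9)  # one simplex per k
  }
})

test_that("feature blocks take their closed-form values on poly-A windows", {
  tab <- load_nn_table()
  L <- 300L
  hex <- c("AAAAAA", "ACGTAC", head(setdiff(all_words(6), c("AAAAAA", "ACGTAC")), 98))
  x <- assemble_features(strrep("A", L), hex)
  expect_equal(unname(x[1, "OR_AAAAAA"]), (L - 5) / L)
  expect_equal(unname(x[1, "OR_ACGTAC"]), 0)
  expect_equal(unname(x[1, "NC_A"]), 1)
  expect_equal(unname(x[1, "NC_AA"]), 1)
  expect_equal(unname(x[1, "NC_AAA"]), 1)
  expect_equal(unname(x[1, "NC_C"]), 0)
  ds <- x[1, grepl("^DS_", colnames(x))]
  expect_length(ds, 20L)
  expect_true(all(ds == 14 * tab[["AA"]]))
  expect_error(assemble_features("ACGNACGT", hex), "N-free")
})

test_that("confusion metrics follow the printed formulas", {
  m <- confusion_metrics(80, 20, 80, 20)
  expect_equal(unname(m), c(0.80, 0.80, 0.80, 0.80))
  m2 <- confusion_metrics(10, 0, 10, 0)
  expect_equal(unname(m2), c(1, 1, 1, 1))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("the SVM separates separable toy data and is near-chance on shuffled labels", {
  set.seed(43)
  n <- 100
  x <- rbind(matrix(rnorm(2 * n, mean = 3, sd = 0.3), ncol = 2),
             matrix(rnorm(2 * n, mean = -3, sd = 0.3), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(1, 0), each = n)
  fit <- train_branch(x, y, seed = 43)
  expect_true(all((decision_values(fit, x) > 0) == (y == 1)))
  expect_error(train_branch(x, rep(1, 2 * n)), "both classes")

  # permutation null: shuffled labels give ~50% CV accuracy
  y_shuf <- sample(y)
  folds <- sample(rep(1:5, length.out = 2 * n))
  acc <- mean(vapply(1:5, function(f) {
    fit <- train_branch(x[folds != f, ], y_shuf[folds != f], seed = f)
    mean((decision_values(fit, x[folds == f, , drop = FALSE]) > 0) ==
           (y_shuf[folds == f] == 1))
  }, numeric(1)))
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("cross-validation balances folds, reports coherent metrics, and is deterministic", {
  recs <- gen_promoters(23, flank = 600, seed = 47)
  rep1 <- cross_validate(recs, relative_window(-100, 50), k = 5, seed = 47)
  # record-level folds of nearly equal size
  per_fold <- rowSums(rep1$folds[, c("TP", "FP", "TN", "FN")]) / 2
  expect_lte(max(per_fold) - min(per_fold), 1)
  # metric identities recomputed from the pooled confusion counts
  p <- rep1$pooled
  expect_equal(rep1$metrics[["accuracy"]],
               (p[["TP"]] + p[["TN"]]) / sum(p))
  expect_equal(rep1$metrics[["sensitivity"]],
               p[["TP"]] / (p[["TP"]] + p[["FN"]]))
  # byte-identical under the same seed
  rep2 <- cross_validate(recs, relative_window(-100, 50), k = 5, seed = 47)
  expect_identical(rep1, rep2)
  expect_error(cross_validate(recs, k = 1), ">= 2")
})

test_that("the trained bundle finds a synthetic promoter and rarely fires on background", {
  recs_with <- gen_promoters(40, flank = 1000, cpg_class = "WITH_CPG", seed = 51)
  recs_without <- gen_promoters(40, flank = 1000, cpg_class = "WITHOUT_CPG", seed = 52)
  bundle <- train_promoter_model(recs_with, recs_without,
                                 window = default_window(), seed = 51)
  # a held-out with-CpG promoter: predicted region overlapping the true window
  test_rec <- gen_promoters(1, flank = 1000, cpg_class = "WITH_CPG", seed = 99)[[1]]
  pred <- predict_promoters(test_rec$seq, bundle, stride = 25)
  idx <- rel_to_index(default_window(), test_rec$tss_index, nchar(test_rec$seq))
  expect_gt(nrow(pred$regions), 0L)
  expect_true(any(pred$regions$start < idx[["end"]] &
                    pred$regions$end > idx[["start"]]))
  # pure background: few positive windows at the default threshold
  bg <- gen_background(1, 3000, seed = 98)[[1]]
  pred_bg <- predict_promoters(bg, bundle, stride = 25)
  expect_lte(mean(pred_bg$windows$score > 0, na.rm = TRUE), 0.05)
  # stride larger than the sequence: single window
  one <- predict_promoters(substr(bg, 1, 300), bundle, stride = 10000)
  expect_equal(nrow(one$windows), 1L)
})
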