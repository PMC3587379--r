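# CpG-stratified proximal-promoter SVM.
#
# Positive examples are the TSS-relative candidate windows of training
# promoters; negatives are equal-length windows sampled from the same
# records outside the positive window. Each window becomes a 204-dimension
# feature vector:
#   OR block (100): overlapping-count density of the top 100 over-represented
#     hexamers of the training set,
#   NC block (84): window-wide occurrence rates of all mono-, di- and
#     tri-nucleotides (one simplex per k, so the block sums to 3),
#   DS block (20): the 15-nt nearest-neighbor free-energy profile averaged
#     into 20 equal-width position bins.
# Two RBF-kernel SVMs (libsvm via e1071) are trained, one per CpG class, and
# prediction routes each candidate window to a branch by CpG-island overlap.

#' The five candidate proximal-promoter windows
#'
#' @return Named list of [relative_window()]s: `(-60,+20)`, `(-100,+50)`,
#'   `(-200,+100)` (the default working window), `(-300,+150)`,
#'   `(-400,+200)`.
#' @export
candidate_windows <- function() {
  list("-60..+20" = relative_window(-60, 20),
       "-100..+50" = relative_window(-100, 50),
       "-200..+100" = relative_window(-200, 100),
       "-300..+150" = relative_window(-300, 150),
       "-400..+200" = relative_window(-400, 200))
}

#' Default working window (-200..+100)
#' @return A [relative_window()].
#' @export
default_window <- function() relative_window(-200, 100)

# bp spanned by a relative window (inclusive endpoints, no position 0)
window_length <- function(window) {
  length(setdiff(window$start_rel:window$end_rel, 0L))
}

#' Build positive and negative training windows
#'
#' One positive window (the candidate window around the declared TSS) and
#' one negative window per record; the negative is sampled uniformly from
#' the same record with zero overlap with the positive window. Records too
#' short to host a non-overlapping negative, or whose windows contain N, are
#' dropped with a warning.
#'
#' @param records List of [promoter_record()]s.
#' @param window A [relative_window()], default -200..+100.
#' @param seed Integer seed for negative sampling.
#' @return List with character vectors `positives` and `negatives` (named by
#'   gene id) and `window`.
#' @export
build_training_set <- function(records, window = default_window(), seed = 1L) {
  set.seed(seed)
  wlen <- window_length(window)
  pos <- character(0); neg <- character(0); ids <- character(0)
  dropped <- 0L
  for (r in records) {
    L <- nchar(r$seq)
    idx <- tryCatch(rel_to_index(window, r$tss_index, L), error = function(e) NULL)
    if (is.null(idx)) { dropped <- dropped + 1L; next }
    p_seq <- substr(r$seq, idx[["start"]] + 1L, idx[["end"]])
    # candidate negative starts: all 0-based starts with no overlap
    starts <- 0:(L - wlen)
    ok <- starts + wlen <= idx[["start"]] | starts >= idx[["end"]]
    starts <- starts[ok]
    if (grepl("N", p_seq, fixed = TRUE) || !length(starts)) {
      dropped <- dropped + 1L; next
    }
    n_start <- sample(starts, 1L)
    n_seq <- substr(r$seq, n_start + 1L, n_start + wlen)
    if (grepl("N", n_seq, fixed = TRUE)) { dropped <- dropped + 1L; next }
    pos <- c(pos, p_seq); neg <- c(neg, n_seq); ids <- c(ids, r$gene_id)
  }
  if (dropped > 0L) warning(dropped, " record(s) dropped (out of bounds, N, or no room for a negative)")
  names(pos) <- ids; names(neg) <- ids
  list(positives = pos, negatives = neg, window = window)
}

#' Assemble the fused OR+NC+DS feature matrix
#'
#' @param window_seqs Character vector of N-free window sequences of equal
#'   length.
#' @param top_hexamers Character vector of hexamers (the OR block schema).
#' @param features Which blocks to include: subset of `c("OR","NC","DS")`.
#' @param ds_bins Number of positional bins for the stability block,
#'   default 20.
#' @param stab_window Stability profile window, default 15 nt.
#' @return Numeric matrix, one row per window, with named columns
#'   (`OR_<hexamer>`, `NC_<kmer>`, `DS_bin<i>`).
#' @export
assemble_features <- function(window_seqs, top_hexamers,
                              features = c("OR", "NC", "DS"),
                              ds_bins = 20L, stab_window = 15L) {
  features <- match.arg(features, c("OR", "NC", "DS"), several.ok = TRUE)
  if (any(grepl("N", window_seqs, fixed = TRUE))) {
    stop("window sequences must be N-free (pre-filter upstream)")
  }
  L <- unique(nchar(window_seqs))
  if (length(L) != 1L) stop("all windows must have equal length")
  set <- Biostrings::DNAStringSet(window_seqs)
  blocks <- list()
  if ("OR" %in% features) {
    hexcnt <- Biostrings::oligonucleotideFrequency(set, width = 6L)
    or <- hexcnt[, top_hexamers, drop = FALSE] / L
    colnames(or) <- paste0("OR_", top_hexamers)
    blocks$OR <- or
  }
  if ("NC" %in% features) {
    nc <- do.call(cbind, lapply(1:3, function(k) {
      cnt <- Biostrings::oligonucleotideFrequency(set, width = k)
      cnt / (L - k + 1L)
    }))
    colnames(nc) <- paste0("NC_", colnames(nc))
    blocks$NC <- nc
  }
  if ("DS" %in% features) {
    n_prof <- L - stab_window + 1L
    bin_id <- cut(seq_len(n_prof), breaks = ds_bins, labels = FALSE)
    ds <- t(vapply(window_seqs, function(s) {
      prof <- stability_profile(s, window = stab_window)$delta_g
      as.numeric(tapply(prof, bin_id, mean))
    }, numeric(ds_bins)))
    colnames(ds) <- paste0("DS_bin", seq_len(ds_bins))
    rownames(ds) <- NULL
    blocks$DS <- ds
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

#' Train one branch SVM (RBF kernel)
#'
#' Features are z-standardized with parameters fitted on the training data
#' only (constant features get unit scale). When `C` or `gamma` is `NULL`,
#' they are selected by an inner 3-fold grid search over
#' `C = 2^(-3..7)`, `gamma = 2^(-9..1)` (odd exponents).
#'
#' @param x Feature matrix.
#' @param y Labels (logical or 0/1; `TRUE`/1 = promoter).
#' @param C,gamma RBF-SVM hyperparameters; default `C = 1`,
#'   `gamma = 1/ncol(x)`. Pass `NULL` to grid-search.
#' @param seed Integer seed (grid-search fold assignment).
#' @return List of class `promoter_svm` with the fitted model and scaling.
#' @export
train_branch <- function(x, y, C = 1, gamma = 1 / ncol(x), seed = 1L) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("need both classes to train")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  if (is.null(C) || is.null(gamma)) {
    hp <- .grid_search(xs, y, seed)
    C <- hp$C; gamma <- hp$gamma
  }
  fit <- e1071::svm(xs, factor(y, levels = c(0, 1)), type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl, C = C, gamma = gamma,
                 schema = colnames(x)),
            class = "promoter_svm")
}

.grid_search <- function(xs, y, seed) {
  set.seed(seed)
  grid <- expand.grid(C = 2^seq(-3, 7, by = 2), gamma = 2^seq(-9, 1, by = 2))
  folds <- sample(rep(1:3, length.out = length(y)))
  best <- NULL; best_acc <- -1
  for (i in seq_len(nrow(grid))) {
    acc <- 0
    for (f in 1:3) {
      tr <- folds != f
      fit <- e1071::svm(xs[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
                        type = "C-classification", kernel = "radial",
                        cost = grid$C[i], gamma = grid$gamma[i], scale = FALSE)
      pred <- stats::predict(fit, xs[!tr, , drop = FALSE])
      acc <- acc + mean(pred == y[!tr])
    }
    if (acc / 3 > best_acc) { best_acc <- acc / 3; best <- grid[i, ] }
  }
  list(C = best$C, gamma = best$gamma)
}

#' Decision values of a trained branch on new windows
#' @param model A `promoter_svm`.
#' @param x Feature matrix with the training schema.
#' @return Numeric decision values (positive = promoter side).
#' @export
decision_values <- function(model, x) {
  xs <- scale(x[, model$schema, drop = FALSE], center = model$center,
              scale = model$scale)
  dv <- attr(stats::predict(model$fit, xs, decision.values = TRUE),
             "decision.values")
  # libsvm's sign depends on which label it saw first; orient to "1 = promoter"
  if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
}

#' Confusion-matrix performance measures
#'
#' Precision = TP/(TP+FP), Sensitivity = TP/(TP+FN),
#' Specificity = TN/(TN+FP), Accuracy = (TP+TN)/(TP+FP+TN+FN).
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Named numeric vector with the four measures.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  c(precision = tp / (tp + fp),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Five-fold cross-validation of one branch
#'
#' Folds are split at the record level so a record's positive and negative
#' windows share a fold. Per training fold, the top hexamers are re-selected
#' from the fold's positive windows against a background model fitted on the
#' fold's negative windows, so no information leaks from validation records.
#'
#' @param records List of [promoter_record()]s (one CpG class).
#' @param window A [relative_window()].
#' @param k Number of folds, default 5.
#' @param seed Integer seed (fold assignment and negative sampling).
#' @param C,gamma SVM hyperparameters (see [train_branch()]).
#' @param features Feature blocks, subset of `c("OR","NC","DS")`.
#' @param n_hexamers OR-block size, default 100.
#' @return List of class `cv_report`: `folds` (per-fold confusion), `pooled`
#'   confusion counts, and `metrics`.
#' @export
cross_validate <- function(records, window = default_window(), k = 5L,
                           seed = 1L, C = 1, gamma = NULL,
                           features = c("OR", "NC", "DS"),
                           n_hexamers = 100L) {
  if (k < 2L) stop("k must be >= 2")
  ts <- build_training_set(records, window, seed = seed)
  n <- length(ts$positives)
  if (n < k) stop("need at least k records")
  set.seed(seed + 1L)
  folds <- sample(rep(seq_len(k), length.out = n))
  fold_rows <- list()
  use_or <- "OR" %in% features
  for (f in seq_len(k)) {
    tr <- folds != f
    hex <- character(0)
    if (use_or) {
      bg <- background_model(seqs = ts$negatives[tr], order = 0L)
      zs <- hexamer_zscores(ts$positives[tr], bg)
      hex <- top_hexamers(zs, n = n_hexamers)
    }
    x_tr <- assemble_features(c(ts$positives[tr], ts$negatives[tr]), hex,
                              features = features)
    y_tr <- rep(c(1L, 0L), c(sum(tr), sum(tr)))
    g <- if (is.null(gamma)) 1 / ncol(x_tr) else gamma
    model <- train_branch(x_tr, y_tr, C = C, gamma = g, seed = seed)
    x_va <- assemble_features(c(ts$positives[!tr], ts$negatives[!tr]), hex,
                              features = features)
    y_va <- rep(c(1L, 0L), c(sum(!tr), sum(!tr)))
    pred <- as.integer(decision_values(model, x_va) > 0)
    fold_rows[[f]] <- c(fold = f,
                        TP = sum(pred == 1 & y_va == 1),
                        FP = sum(pred == 1 & y_va == 0),
                        TN = sum(pred == 0 & y_va == 0),
                        FN = sum(pred == 0 & y_va == 1))
  }
  folds_df <- as.data.frame(do.call(rbind, fold_rows))
  pooled <- colSums(folds_df[, c("TP", "FP", "TN", "FN")])
  structure(list(folds = folds_df, pooled = pooled,
                 metrics = confusion_metrics(pooled[["TP"]], pooled[["FP"]],
                                             pooled[["TN"]], pooled[["FN"]]),
                 window = window, k = k, n_records = n),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV on %d records, window %+d..%+d\n",
              x$k, x$n_records, x$window$start_rel, x$window$end_rel))
  cat(sprintf("  pooled: TP=%d FP=%d TN=%d FN=%d\n", x$pooled[["TP"]],
              x$pooled[["FP"]], x$pooled[["TN"]], x$pooled[["FN"]]))
  m <- x$metrics
  cat(sprintf("  Prec=%.3f Sn=%.3f Sp=%.3f Acc=%.3f\n", m[["precision"]],
              m[["sensitivity"]], m[["specificity"]], m[["accuracy"]]))
  invisible(x)
}

#' Train the CpG-stratified model bundle
#'
#' Trains one RBF-SVM per CpG class on the full training sets, with a shared
#' window. Each branch carries its own top-hexamer schema.
#'
#' @param records_with,records_without Lists of [promoter_record()]s.
#' @param window A [relative_window()].
#' @param seed Integer seed.
#' @param C,gamma SVM hyperparameters (see [train_branch()]).
#' @param features Feature blocks.
#' @param n_hexamers OR-block size.
#' @return List of class `model_bundle`.
#' @export
train_promoter_model <- function(records_with, records_without,
                                 window = default_window(), seed = 1L,
                                 C = 1, gamma = NULL,
                                 features = c("OR", "NC", "DS"),
                                 n_hexamers = 100L) {
  train_one <- function(records, sd_off) {
    ts <- build_training_set(records, window, seed = seed + sd_off)
    hex <- character(0)
    if ("OR" %in% features) {
      bg <- background_model(seqs = ts$negatives, order = 0L)
      hex <- top_hexamers(hexamer_zscores(ts$positives, bg), n = n_hexamers)
    }
    x <- assemble_features(c(ts$positives, ts$negatives), hex,
                           features = features)
    y <- rep(c(1L, 0L), c(length(ts$positives), length(ts$negatives)))
    g <- if (is.null(gamma)) 1 / ncol(x) else gamma
    list(model = train_branch(x, y, C = C, gamma = g, seed = seed),
         top_hexamers = hex)
  }
  b_with <- train_one(records_with, 0L)
  b_without <- train_one(records_without, 1000L)
  structure(list(with_cpg = b_with, without_cpg = b_without,
                 window = window, features = features, seed = seed,
                 version = as.character(utils::packageVersion("promkit"))),
            class = "model_bundle")
}

#' Predict proximal promoter regions in a novel sequence
#'
#' Slides the bundle's window along the sequence; each candidate window is
#' routed to the with-CpG or without-CpG branch depending on whether a CpG
#' island overlaps a flank-padded context around the window, then scored by
#' that branch's SVM. Overlapping positive windows are merged into regions
#' keeping the maximum decision score.
#'
#' @param seq DNA string (or single named character).
#' @param bundle A `model_bundle` from [train_promoter_model()].
#' @param stride Window slide step in bp, default 10.
#' @param threshold Decision-value threshold, default 0.
#' @param context_pad Flank padding for CpG routing, default 500 bp.
#' @return List with `windows` (every scored window: `start`, `branch`,
#'   `score`) and `regions` (merged positive regions: `start`, `end`,
#'   `score`). Coordinates 0-based.
#' @export
predict_promoters <- function(seq, bundle, stride = 10L, threshold = 0,
                              context_pad = 500L) {
  if (!inherits(bundle, "model_bundle")) stop("bundle must be a model_bundle")
  if (length(seq) == 1L && !is.null(names(seq))) seq <- seq[[1]]
  wlen <- window_length(bundle$window)
  L <- nchar(seq)
  if (L < wlen) stop("sequence shorter than the model window")
  starts <- seq.int(0L, L - wlen, by = max(1L, as.integer(stride)))
  islands <- find_cpg_islands(seq)
  win_seqs <- substring(seq, starts + 1L, starts + wlen)
  ok <- !grepl("N", win_seqs, fixed = TRUE)
  branch <- vapply(starts, function(s) {
    cs <- max(0L, s - context_pad); ce <- min(L, s + wlen + context_pad)
    if (nrow(islands) && any(islands$start < ce & islands$end > cs)) "with_cpg"
    else "without_cpg"
  }, character(1))
  score <- rep(NA_real_, length(starts))
  for (br in c("with_cpg", "without_cpg")) {
    sel <- which(branch == br & ok)
    if (!length(sel)) next
    b <- bundle[[br]]
    x <- assemble_features(win_seqs[sel], b$top_hexamers,
                           features = bundle$features)
    score[sel] <- decision_values(b$model, x)
  }
  windows <- data.frame(start = starts, branch = branch, score = score)
  pos <- windows[!is.na(score) & score > threshold, , drop = FALSE]
  if (nrow(pos)) {
    ir <- IRanges::IRanges(start = pos$start + 1L, width = wlen)
    red <- IRanges::reduce(ir)
    hitsel <- IRanges::findOverlaps(red, ir)
    mx <- tapply(pos$score[S4Vectors::subjectHits(hitsel)],
                 S4Vectors::queryHits(hitsel), max)
    regions <- data.frame(start = IRanges::start(red) - 1L,
                          end = IRanges::end(red),
                          score = as.numeric(mx))
  } else {
    regions <- data.frame(start = integer(0), end = integer(0),
                          score = numeric(0))
  }
  list(windows = windows, regions = regions)
}
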