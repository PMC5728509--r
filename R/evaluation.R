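#' Confusion counts from true and predicted labels
#'
#' For two classes the first class name (first appearance in the truth) is
#' taken as the positive class and TP/TN/FP/FN are tabulated with the
#' standard confusion-matrix semantics; for any number of classes per-class
#' correct/total counts are recorded.
#'
#' @param truth,predicted Character vectors of equal length.
#' @param positive Positive class for the binary tabulation; defaults to the
#'   first class in order of appearance in `truth`.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(truth, predicted, positive = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0L) stop("no evaluated samples")
  classes <- unique(truth)
  if (is.null(positive)) positive <- classes[1L]
  out <- list(
    per_class_correct = vapply(classes, function(k) sum(truth == k & predicted == k), integer(1)),
    per_class_total = vapply(classes, function(k) sum(truth == k), integer(1)),
    n = length(truth)
  )
  if (length(classes) == 2L) {
    out$TP <- sum(truth == positive & predicted == positive)
    out$FN <- sum(truth == positive & predicted != positive)
    out$TN <- sum(truth != positive & predicted != positive)
    out$FP <- sum(truth != positive & predicted == positive)
    out$positive <- positive
  }
  structure(out, class = "confusion_counts")
}

#' Classification accuracy
#'
#' For binary counts, (TP + TN) / (TP + FN + TN + FP); for multiclass, the
#' overall fraction of correctly labeled samples (to which the binary
#' formula degenerates).
#'
#' @param counts A [confusion_counts()] object, or a list with fields
#'   TP, TN, FP, FN.
#' @return Accuracy as a fraction in \[0, 1\].
#' @export
accuracy <- function(counts) {
  if (!is.null(counts$TP)) {
    denom <- counts$TP + counts$FN + counts$TN + counts$FP
    if (denom == 0) stop("zero evaluated samples")
    return((counts$TP + counts$TN) / denom)
  }
  total <- sum(counts$per_class_total)
  if (is.null(total) || total == 0) stop("zero evaluated samples")
  sum(counts$per_class_correct) / total
}

#' @export
print.confusion_counts <- function(x, ...) {
  if (!is.null(x$TP)) {
    cat(sprintf("confusion (positive = %s): TP=%d FN=%d TN=%d FP=%d, accuracy %.4f\n",
                x$positive, x$TP, x$FN, x$TN, x$FP, accuracy(x)))
  } else {
    cat(sprintf("confusion: %d classes, accuracy %.4f\n",
                length(x$per_class_total), accuracy(x)))
  }
  invisible(x)
}

.cv_result <- function(scheme, k, repeats, per_repeat_accuracy, seed, config,
                       counts = NULL) {
  structure(
    list(scheme = scheme, k = k, repeats = repeats,
         per_repeat_accuracy = per_repeat_accuracy,
         mean_accuracy = mean(per_repeat_accuracy),
         seed = seed, config = config, counts = counts),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s%s: mean accuracy %.4f over %d repeat(s)\n",
              x$scheme, if (!is.null(x$k)) sprintf(" (k=%d)", x$k) else "",
              x$mean_accuracy, x$repeats))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Each sample is classified by a model built from the remaining n - 1
#' samples; with per-fold filtering the gene filter is refit on each
#' training portion. With a fixed pipeline (fixed projection seed and
#' lambda) the procedure is fully deterministic. A class with a single
#' sample cannot be classified correctly by construction; it is still
#' evaluated, with a warning.
#'
#' @param data An [expression_set()].
#' @param config A [crc_pipeline()] configuration.
#' @return A `cv_result` with one accuracy entry and pooled
#'   [confusion_counts()].
#' @export
loocv <- function(data, config = crc_pipeline()) {
  stopifnot(inherits(data, "expression_set"))
  n <- ncol(data$values)
  if (n < 2L) stop("need at least 2 samples for LOOCV")
  cnt <- table(data$labels)
  if (any(cnt == 1L)) {
    warning("class(es) with a single sample cannot be predicted correctly in LOOCV: ",
            paste(names(cnt)[cnt == 1L], collapse = ", "))
  }
  g <- .apply_global_filter(data, config)
  pred <- character(n)
  for (i in seq_len(n)) {
    train <- subset_expression_set(g$data, samples = -i)
    pred[i] <- .fit_predict(train, g$data$values[, i, drop = FALSE], g$config)
  }
  counts <- confusion_counts(g$data$labels, pred)
  .cv_result("loocv", k = NULL, repeats = 1L,
             per_repeat_accuracy = accuracy(counts),
             seed = config$projection_seed, config = config, counts = counts)
}

# stratified (or plain) assignment of n samples to k folds
.make_folds <- function(labels, k, stratified) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(sample.int(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(sample.int(k), n)
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repetition, samples are shuffled into k near-equal folds (stratified
#' by class by default, so per-class proportions are preserved within one
#' sample per fold); each fold is held out once and the repetition's
#' accuracy pools all folds' predictions (correct / n). The mean over
#' repetitions is reported; 100 repetitions is the conventional default for
#' stable averages.
#'
#' @param data An [expression_set()].
#' @param k Number of folds, 2 <= k <= n.
#' @param repeats Number of repetitions.
#' @param seed Seed for the fold shuffles (and projection redraws when
#'   `config$redraw_projection` is set).
#' @param config A [crc_pipeline()] configuration.
#' @return A `cv_result` with per-repetition accuracies.
#' @export
kfold_cv <- function(data, k = 10, repeats = 100, seed = 1,
                     config = crc_pipeline()) {
  stopifnot(inherits(data, "expression_set"))
  n <- ncol(data$values)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop(sprintf("k = %d folds exceed n = %d samples", k, n))
  g <- .apply_global_filter(data, config)
  acc <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(repeats), function(rep_i) {
      fold <- .make_folds(g$data$labels, k, config$stratified)
      proj_seed <- if (config$redraw_projection) {
        config$projection_seed + rep_i
      } else {
        config$projection_seed
      }
      pred <- character(n)
      for (f in seq_len(k)) {
        test_idx <- which(fold == f)
        if (!length(test_idx)) next
        train <- subset_expression_set(g$data, samples = -test_idx)
        if (length(unique(train$labels)) < length(unique(g$data$labels))) {
          warning("fold ", f, " lost an entire class from training")
        }
        pred[test_idx] <- .fit_predict(
          train, g$data$values[, test_idx, drop = FALSE], g$config,
          projection_seed = proj_seed)
      }
      accuracy(confusion_counts(g$data$labels, pred))
    }, numeric(1))
  })
  .cv_result("kfold", k = as.integer(k), repeats = as.integer(repeats),
             per_repeat_accuracy = acc, seed = as.integer(seed),
             config = config)
}

#' Accuracy versus reduced dimension
#'
#' Runs the cross-validation protocol at each requested projection
#' dimension M and tabulates mean accuracy against M, the protocol behind
#' reduced-dimension profiles: on redundant (effectively low-rank) data the
#' accuracy stays flat down to very small M. Dimensions exceeding the
#' (filtered) feature count are skipped with a warning; duplicates are
#' dropped.
#'
#' @param data An [expression_set()].
#' @param dims Integer vector of target dimensions M.
#' @param config A [crc_pipeline()] configuration; its `projection_dim` is
#'   overridden by each M in turn.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k,repeats,seed Passed to [kfold_cv()] when `scheme = "kfold"`.
#' @return A data.frame with columns `M` and `mean_accuracy`, ordered by M.
#' @export
dimension_sweep <- function(data, dims, config = crc_pipeline(),
                            scheme = c("loocv", "kfold"),
                            k = 10, repeats = 10, seed = 1) {
  scheme <- match.arg(scheme)
  if (anyDuplicated(dims)) {
    warning("duplicate dimensions dropped from sweep")
    dims <- unique(dims)
  }
  dims <- sort(as.integer(dims))
  n_feat <- nrow(data$values)
  rows <- lapply(dims, function(M) {
    if (M > n_feat) {
      warning("M = ", M, " exceeds feature count ", n_feat, "; skipped")
      return(NULL)
    }
    cfg <- config
    cfg$projection_dim <- M
    res <- if (scheme == "loocv") {
      loocv(data, cfg)
    } else {
      kfold_cv(data, k = k, repeats = repeats, seed = seed, config = cfg)
    }
    data.frame(M = M, mean_accuracy = res$mean_accuracy)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a cross-validation result with its configuration sidecar
#'
#' Writes a TSV of per-repetition accuracies plus a JSON sidecar capturing
#' the scheme, seeds and full pipeline configuration, sufficient to
#' regenerate the result.
#'
#' @param x A `cv_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_cv_result <- function(x, dir, prefix = "cv") {
  stopifnot(inherits(x, "cv_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, "_accuracy.tsv"))
  utils::write.table(
    data.frame(repeat_index = seq_along(x$per_repeat_accuracy),
               accuracy = x$per_repeat_accuracy),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- file.path(dir, paste0(prefix, "_config.json"))
  cfg <- unclass(x$config)
  cfg$max_nonzeros <- if (is.null(cfg$max_nonzeros)) NA else cfg$max_nonzeros
  cfg$projection_dim <- if (is.null(cfg$projection_dim)) NA else cfg$projection_dim
  jsonlite::write_json(
    list(scheme = x$scheme, k = x$k, repeats = x$repeats, seed = x$seed,
         mean_accuracy = x$mean_accuracy, config = cfg),
    side, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(tsv, side))
}
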