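#' Classification pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline (gene prefilter ->
#' random projection -> dictionary normalization -> coding -> residual
#' decision) into one reproducible record used by [loocv()], [kfold_cv()]
#' and [dimension_sweep()].
#'
#' @param classifier `"crc"` (ridge collaborative coding) or `"src"`
#'   (orthogonal-matching-pursuit sparse coding).
#' @param lambda Ridge parameter for the CRC coding operator.
#' @param filter Gene prefilter mode: `"fold"` refits the t-test filter on
#'   each training fold (no information leakage, the default), `"global"`
#'   fits it once on the full dataset before splitting (the classical
#'   dataset-wide protocol), `"none"` disables it.
#' @param alpha Filter significance level.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param projection_dim Target dimension M for the sparse random
#'   projection, or `NULL` to disable projection.
#' @param rho Projection sparsity parameter.
#' @param projection_seed Seed for the sensing matrix; fixed per experiment
#'   so the (data-independent) matrix is shared across folds.
#' @param row_normalize Row-normalized sensing matrix instead of the
#'   1/sqrt(M) scaling.
#' @param redraw_projection Draw a fresh sensing matrix per repetition in
#'   [kfold_cv()] instead of reusing one.
#' @param max_nonzeros,residual_tol Sparse-coder budget and stopping
#'   tolerance (SRC only); `max_nonzeros = NULL` defaults to
#'   min(atoms, dims).
#' @param stratified Stratify k-fold splits by class.
#' @return A `crc_pipeline` configuration list.
#' @export
crc_pipeline <- function(classifier = c("crc", "src"), lambda = 1e-3,
                         filter = c("fold", "global", "none"), alpha = 0.05,
                         var_equal = FALSE,
                         projection_dim = NULL, rho = 3,
                         projection_seed = 1, row_normalize = FALSE,
                         redraw_projection = FALSE,
                         max_nonzeros = NULL, residual_tol = 1e-8,
                         stratified = TRUE) {
  structure(
    list(classifier = match.arg(classifier), lambda = lambda,
         filter = match.arg(filter), alpha = alpha, var_equal = var_equal,
         projection_dim = projection_dim, rho = rho,
         projection_seed = as.integer(projection_seed),
         row_normalize = row_normalize,
         redraw_projection = redraw_projection,
         max_nonzeros = max_nonzeros, residual_tol = residual_tol,
         stratified = stratified),
    class = "crc_pipeline"
  )
}

# Train on `train`, predict labels for raw query columns `test_values`
# (full feature space, same row order as `train`). Runs the per-fold filter
# when configured; `projection_seed` may be overridden (per-repeat redraws).
.fit_predict <- function(train, test_values, config,
                         projection_seed = config$projection_seed) {
  if (config$filter == "fold") {
    # degenerate training folds (a vanished class, a singleton class) cannot
    # support the filter; fall back to all features rather than abort the fold
    keep <- tryCatch(
      t_test_filter(train, alpha = config$alpha,
                    var_equal = config$var_equal)$kept,
      error = function(e) {
        warning("gene filter skipped on this fold: ", conditionMessage(e))
        seq_len(nrow(train$values))
      })
    if (length(keep) == 0L) keep <- seq_len(nrow(train$values))  # nothing passes: keep all
    train <- subset_expression_set(train, features = keep)
    test_values <- test_values[keep, , drop = FALSE]
  }
  proj <- NULL
  if (!is.null(config$projection_dim)) {
    N <- nrow(train$values)
    M <- min(config$projection_dim, N)
    proj <- make_sparse_projection(N, M, rho = config$rho,
                                   seed = projection_seed,
                                   row_normalize = config$row_normalize)
  }
  dict <- build_dictionary(train, projection = proj)
  if (config$classifier == "crc") {
    model <- fit_crc(dict, lambda = config$lambda)
    vapply(seq_len(ncol(test_values)),
           function(j) classify_crc(model, test_values[, j])$predicted_class,
           character(1))
  } else {
    vapply(seq_len(ncol(test_values)),
           function(j) classify_src(dict, test_values[, j],
                                    max_nonzeros = config$max_nonzeros,
                                    residual_tol = config$residual_tol)$predicted_class,
           character(1))
  }
}

# apply the global (dataset-wide) filter once, returning the reduced data
# and a config whose per-fold filter is off
.apply_global_filter <- function(data, config) {
  if (config$filter != "global") return(list(data = data, config = config))
  keep <- t_test_filter(data, alpha = config$alpha,
                        var_equal = config$var_equal)$kept
  if (length(keep) == 0L) keep <- seq_len(nrow(data$values))
  config$filter <- "none"
  list(data = subset_expression_set(data, features = keep), config = config)
}
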