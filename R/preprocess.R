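#' Differential-expression gene prefilter
#'
#' Screens features for class association before classification. With two
#' classes each feature gets a two-sided two-sample t-test (Welch by default,
#' pooled variance with `var_equal = TRUE`); with more than two classes a
#' one-way ANOVA F-test at the same level. Features with p < `alpha` are
#' kept in their original order. Features with zero variance everywhere are
#' assigned p = 1 and never selected. No multiple-testing correction is
#' applied by default; `adjust = "BH"` switches the threshold to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param data An [expression_set()] with at least two samples per class.
#' @param alpha Significance level for retention (default 0.05).
#' @param var_equal Pooled-variance t-test / classic ANOVA instead of Welch.
#' @param adjust `"none"` (raw p-values, default) or `"BH"`.
#' @return A `feature_filter_result` list: `kept` (increasing feature row
#'   indices), `p_values`, `alpha`.
#' @export
t_test_filter <- function(data, alpha = 0.05, var_equal = FALSE,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(data, "expression_set"))
  f <- factor(data$labels, levels = data$class_names)
  if (nlevels(f) < 2L) stop("need at least two classes to filter")
  cnt <- table(f)
  if (any(cnt < 2L)) {
    stop("class with fewer than 2 samples (variance not estimable): ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  }
  two_class <- nlevels(f) == 2L
  grp1 <- f == levels(f)[1L]
  p <- apply(data$values, 1L, function(x) {
    tryCatch({
      if (two_class) {
        stats::t.test(x[grp1], x[!grp1], var.equal = var_equal)$p.value
      } else {
        stats::oneway.test(x ~ f, var.equal = TRUE)$p.value
      }
    }, error = function(e) 1)
  })
  p[is.na(p)] <- 1
  crit <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  structure(
    list(kept = which(crit < alpha), p_values = unname(p), alpha = alpha),
    class = "feature_filter_result"
  )
}

#' @export
print.feature_filter_result <- function(x, ...) {
  cat(sprintf("feature filter: kept %d of %d features at alpha = %g\n",
              length(x$kept), length(x$p_values), x$alpha))
  invisible(x)
}

#' Export a filter result as a two-column table
#'
#' @param x A `feature_filter_result`.
#' @param feature_ids Feature identifiers, one per tested feature.
#' @param path Output TSV path.
#' @export
write_filter_result <- function(x, feature_ids, path) {
  stopifnot(length(feature_ids) == length(x$p_values))
  utils::write.table(
    data.frame(feature_id = feature_ids, p_value = x$p_values),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' log2(x + 1) transform
#'
#' Standard variance-stabilizing transform for non-negative expression units
#' such as RPKM. Errors on negative input, where the transform is undefined
#' for the intended units.
#'
#' @param data An [expression_set()].
#' @return The transformed [expression_set()].
#' @export
log_transform <- function(data) {
  stopifnot(inherits(data, "expression_set"))
  if (any(data$values < 0)) {
    stop("log2(x+1) transform requires non-negative values")
  }
  data$values <- log2(data$values + 1)
  data
}

#' Scale matrix columns to unit Euclidean norm
#'
#' Dictionary columns and query vectors are placed on the unit sphere before
#' coding. All-zero columns are left as zeros with a warning; they contribute
#' nothing to any coding.
#'
#' @param m Numeric matrix.
#' @return Matrix with every nonzero column of norm 1.
#' @export
normalize_columns <- function(m) {
  stopifnot(is.matrix(m) || inherits(m, "Matrix"), ncol(m) >= 1L)
  nrm <- sqrt(colSums(m^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero column(s) left unnormalized")
    nrm[zero] <- 1
  }
  sweep(m, 2L, nrm, "/")
}
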