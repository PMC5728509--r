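#' Build a class-partitioned training dictionary
#'
#' Arranges training samples as the columns of a dictionary matrix
#' X = [X_1, ..., X_K], grouped contiguously by class in first-appearance
#' order, optionally after projecting each sample to a reduced dimension,
#' and finally scales every column to unit Euclidean norm. Queries coded
#' over this dictionary must go through the same projection/normalization
#' (handled by [classify_crc()] and [classify_src()]).
#'
#' @param train An [expression_set()] with K >= 2 classes (K = 1 is allowed
#'   only as a degenerate case and every query is then assigned that class).
#' @param projection Optional [make_sparse_projection()] result whose `N`
#'   equals the training feature count.
#' @return A `crc_dictionary`: `X` (m x n matrix, unit-norm columns),
#'   `class_slices` (list of K contiguous column index vectors),
#'   `class_names`, `projection` (or `NULL`).
#' @export
build_dictionary <- function(train, projection = NULL) {
  stopifnot(inherits(train, "expression_set"))
  if (ncol(train$values) == 0L) stop("empty training set")
  classes <- train$class_names
  slices_in <- lapply(classes, function(k) which(train$labels == k))
  if (any(lengths(slices_in) == 0L)) stop("class with zero training samples")
  ord <- unlist(slices_in)
  V <- train$values[, ord, drop = FALSE]
  if (!is.null(projection)) {
    stopifnot(inherits(projection, "sparse_projection"))
    if (projection$N != nrow(V)) {
      stop(sprintf("projection expects %d features, training data has %d",
                   projection$N, nrow(V)))
    }
    V <- apply_projection(projection, V)
  }
  V <- normalize_columns(V)
  ends <- cumsum(lengths(slices_in))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(
    list(X = V,
         class_slices = Map(seq.int, starts, ends),
         class_names = classes,
         projection = projection),
    class = "crc_dictionary"
  )
}

#' @export
print.crc_dictionary <- function(x, ...) {
  cat(sprintf("crc_dictionary: %d x %d, %d classes (%s)\n",
              nrow(x$X), ncol(x$X), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Fit the collaborative-representation coding operator
#'
#' Precomputes P = (X'X + lambda I)^{-1} X', the ridge coding operator of
#' the collaborative representation classifier. P depends only on the
#' dictionary and lambda, never on any query, so it is computed once and
#' reused for every sample to be classified: P y is the unique minimizer of
#' ||y - X a||^2 + lambda ||a||^2.
#'
#' The operator is obtained by a symmetric positive-definite solve of
#' (X'X + lambda I) Z = X' rather than an explicit inverse.
#'
#' @param dict A [build_dictionary()] result.
#' @param lambda Ridge parameter, > 0. With more atoms than dimensions
#'   (n > m) the unregularized Gram matrix is singular, which is precisely
#'   the regime the regularization addresses.
#' @return A `crc_model`: `P` (n x m), `lambda`, `dictionary`.
#' @export
fit_crc <- function(dict, lambda = 1e-3) {
  stopifnot(inherits(dict, "crc_dictionary"))
  if (!is.numeric(lambda) || lambda <= 0) {
    stop("lambda must be > 0 (lambda = 0 is rank-deficient when n > m)")
  }
  X <- dict$X
  A <- crossprod(X)
  diag(A) <- diag(A) + lambda
  U <- chol(A)
  P <- backsolve(U, forwardsolve(t(U), t(X)))
  structure(list(P = P, lambda = lambda, dictionary = dict),
            class = "crc_model")
}

#' @export
print.crc_model <- function(x, ...) {
  cat(sprintf("crc_model: %d atoms x %d dims, lambda = %g\n",
              nrow(x$P), ncol(x$P), x$lambda))
  invisible(x)
}

# project + unit-normalize a raw query to the dictionary's convention
.prepare_query <- function(dict, y) {
  if (!is.null(dict$projection)) {
    y <- drop(apply_projection(dict$projection, matrix(y, ncol = 1L)))
  }
  if (length(y) != nrow(dict$X)) {
    stop(sprintf("query has dimension %d, dictionary rows %d",
                 length(y), nrow(dict$X)))
  }
  nrm <- sqrt(sum(y^2))
  if (nrm > 0) y <- y / nrm
  y
}

#' Code a query over the dictionary
#'
#' Applies the stored coding operator: coefficients = P y, after putting the
#' query through the same projection and unit-normalization as the
#' dictionary columns (`prepare = FALSE` skips that and takes `y` as already
#' living in the dictionary's row space).
#'
#' @param model A [fit_crc()] model.
#' @param y Numeric query vector.
#' @param prepare Apply the dictionary's projection/normalization first.
#' @return A `coding_vector`: `coefficients` (length n), `by_class` (list of
#'   K sub-vectors aligned with the class slices), `residual_vector`
#'   (y - X coefficients), `query` (the prepared y).
#' @export
code_sample <- function(model, y, prepare = TRUE) {
  stopifnot(inherits(model, "crc_model"))
  dict <- model$dictionary
  if (prepare) y <- .prepare_query(dict, y)
  if (length(y) != ncol(model$P)) {
    stop(sprintf("query has dimension %d, model expects %d",
                 length(y), ncol(model$P)))
  }
  coef <- drop(model$P %*% y)
  structure(
    list(coefficients = coef,
         by_class = lapply(dict$class_slices, function(s) coef[s]),
         residual_vector = y - drop(dict$X %*% coef),
         query = y),
    class = "coding_vector"
  )
}

# shared residual-report construction; regularize divides by ||coef_i||
.residual_report <- function(dict, y, coding, regularize) {
  K <- length(dict$class_slices)
  r <- numeric(K)
  for (i in seq_len(K)) {
    s <- dict$class_slices[[i]]
    recon <- drop(dict$X[, s, drop = FALSE] %*% coding$coefficients[s])
    res <- sqrt(sum((y - recon)^2))
    if (regularize) {
      cn <- sqrt(sum(coding$coefficients[s]^2))
      r[i] <- if (cn == 0) Inf else res / cn
    } else {
      r[i] <- res
    }
  }
  if (all(is.infinite(r))) {
    # every class coding sub-vector is exactly zero: fall back to the
    # unregularized residual, which is then ||y|| for all classes
    warning("all class coding norms are zero; falling back to unregularized residuals")
    r <- rep(sqrt(sum(y^2)), K)
  }
  idx <- which.min(r)
  if (sum(r == r[idx]) > 1L) {
    message("residual tie between classes; lowest class index chosen")
  }
  structure(
    list(per_class_residuals = stats::setNames(r, dict$class_names),
         predicted_class = dict$class_names[idx],
         predicted_index = idx),
    class = "residual_report"
  )
}

#' @export
print.residual_report <- function(x, ...) {
  cat("predicted:", x$predicted_class, "\nresiduals:\n")
  print(round(x$per_class_residuals, 6))
  invisible(x)
}

#' Classify a query by collaborative representation
#'
#' Codes the query with the precomputed ridge operator and computes the
#' regularized residual r_i = ||y - X_i p_i|| / ||p_i|| for each class; the
#' predicted class is the argmin (ties broken toward the lowest class
#' index). Dividing by the coding norm folds the discriminative information
#' in ||p_i|| into the decision alongside the reconstruction error. A class
#' whose coding sub-vector is exactly zero gets r_i = Inf.
#'
#' @param model A [fit_crc()] model.
#' @param y Numeric query vector (raw feature space; projected and
#'   normalized internally, see `prepare`).
#' @param prepare Apply the dictionary's projection/normalization first.
#' @return A `residual_report`: `per_class_residuals`, `predicted_class`,
#'   `predicted_index`.
#' @export
classify_crc <- function(model, y, prepare = TRUE) {
  coding <- code_sample(model, y, prepare = prepare)
  .residual_report(model$dictionary, coding$query, coding, regularize = TRUE)
}

#' Batch prediction for a CRC model
#'
#' @param object A `crc_model`.
#' @param newdata Numeric matrix, one query per column (raw feature space).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.crc_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, ncol = 1L)
  vapply(seq_len(ncol(newdata)),
         function(j) classify_crc(object, newdata[, j])$predicted_class,
         character(1))
}

#' Orthogonal matching pursuit
#'
#' Greedy sparse coder: at each step selects the dictionary column with the
#' largest absolute correlation to the current residual, refits least
#' squares on the selected support, and stops when the residual norm drops
#' to `residual_tol` or the support reaches `max_nonzeros`. If the selected
#' support becomes numerically rank-deficient the solver stops early and
#' returns the current solution with `rank_deficient = TRUE`.
#'
#' @param X Dictionary matrix with unit-normalized columns.
#' @param y Query vector of length nrow(X).
#' @param max_nonzeros Maximum support size, >= 1.
#' @param residual_tol Stop when the residual Euclidean norm falls below
#'   this value.
#' @return A list: `coefficients` (length ncol(X), zero off-support),
#'   `support` (selected column indices in selection order),
#'   `residual_vector`, `rank_deficient`.
#' @export
solve_omp <- function(X, y, max_nonzeros, residual_tol = 1e-10) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (max_nonzeros < 1) stop("max_nonzeros must be >= 1")
  max_nonzeros <- min(max_nonzeros, ncol(X))
  support <- integer(0)
  coef_s <- numeric(0)
  resid <- y
  rank_deficient <- FALSE
  while (length(support) < max_nonzeros && sqrt(sum(resid^2)) > residual_tol) {
    corr <- abs(drop(crossprod(X, resid)))
    corr[support] <- -Inf
    j <- which.max(corr)
    cand <- c(support, j)
    Xs <- X[, cand, drop = FALSE]
    qr_s <- qr(Xs)
    if (qr_s$rank < length(cand)) {
      rank_deficient <- TRUE
      break
    }
    coef_cand <- qr.coef(qr_s, y)
    support <- cand
    coef_s <- coef_cand
    resid <- y - drop(Xs %*% coef_cand)
  }
  coefficients <- numeric(ncol(X))
  coefficients[support] <- coef_s
  list(coefficients = coefficients, support = support,
       residual_vector = resid, rank_deficient = rank_deficient)
}

#' Classify a query by sparse representation (SRC baseline)
#'
#' Codes the query sparsely over the full dictionary with orthogonal
#' matching pursuit and assigns the class minimizing the unregularized
#' per-class reconstruction error e_i = ||y - X_i a_i||, with the same
#' lowest-index tie-break as the collaborative classifier.
#'
#' @param dict A [build_dictionary()] result.
#' @param y Numeric query vector (raw feature space).
#' @param max_nonzeros Support budget for the sparse coder; defaults to the
#'   smallest class size (capped at the dictionary row count), so a query is
#'   representable by its own class block while the code stays sparse —
#'   exhausting the support would reduce the sparse coder to an ordinary
#'   least-squares fit and void the sparsity assumption the decision rule
#'   rests on.
#' @param residual_tol Residual stopping tolerance for [solve_omp()].
#' @param prepare Apply the dictionary's projection/normalization first.
#' @return A `residual_report`.
#' @export
classify_src <- function(dict, y, max_nonzeros = NULL, residual_tol = 1e-8,
                         prepare = TRUE) {
  stopifnot(inherits(dict, "crc_dictionary"))
  if (prepare) y <- .prepare_query(dict, y)
  if (is.null(max_nonzeros)) {
    max_nonzeros <- min(min(lengths(dict$class_slices)), nrow(dict$X))
  }
  fit <- solve_omp(dict$X, y, max_nonzeros = max_nonzeros,
                   residual_tol = residual_tol)
  coding <- list(coefficients = fit$coefficients)
  .residual_report(dict, y, coding, regularize = FALSE)
}
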