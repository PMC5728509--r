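#' Very sparse random projection matrix
#'
#' Draws an M x N sensing matrix whose entries are, before scaling,
#' sqrt(rho) with probability 1/(2 rho), 0 with probability 1 - 1/rho and
#' -sqrt(rho) with probability 1/(2 rho). With `rho = 1` the matrix is a
#' dense Rademacher matrix; `rho = 3` gives the classic sparse construction;
#' both satisfy the Johnson-Lindenstrauss lemma, so pairwise distances of
#' sparse vectors are approximately preserved after projection.
#'
#' Two scalings are offered. The default (`row_normalize = FALSE`) divides
#' the matrix by sqrt(M), making each per-entry variance 1/M so that
#' E||Rx||^2 = ||x||^2 and squared distances can be compared to the identity
#' scale directly (the convention [estimate_distortion()] assumes). With
#' `row_normalize = TRUE` each row is instead rescaled to unit Euclidean
#' norm; the two modes differ only by per-row scale.
#'
#' The matrix is stored sparsely; generation is deterministic given `seed`.
#'
#' @param N Input dimension (number of features).
#' @param M Target dimension, 1 <= M <= N.
#' @param rho Sparsity parameter >= 1; the expected fraction of zeros is
#'   1 - 1/rho. Typical values are 1 and 3.
#' @param seed Integer seed; same arguments give a bit-identical matrix.
#' @param row_normalize Rescale rows to unit norm instead of the 1/sqrt(M)
#'   variance scaling.
#' @return A `sparse_projection` object with fields `R` (a sparse
#'   `Matrix`), `N`, `M`, `rho`, `seed`, `row_normalized`.
#' @examples
#' p <- make_sparse_projection(100, 20, rho = 3, seed = 1)
#' x <- rnorm(100)
#' v <- apply_projection(p, matrix(x))
#' @export
make_sparse_projection <- function(N, M, rho = 3, seed = 1,
                                   row_normalize = FALSE) {
  if (M < 1 || M > N) stop(sprintf("need 1 <= M <= N, got M = %d, N = %d", M, N))
  if (rho < 1) stop("rho must be >= 1 (outcome probabilities invalid otherwise)")
  u <- withr::with_seed(as.integer(seed), stats::runif(as.numeric(M) * N))
  sgn <- integer(length(u))
  sgn[u < 1 / (2 * rho)] <- 1L
  sgn[u > 1 - 1 / (2 * rho)] <- -1L
  nz <- which(sgn != 0L)
  i <- ((nz - 1L) %% M) + 1L
  j <- ((nz - 1L) %/% M) + 1L
  x <- sqrt(rho) * sgn[nz]
  R <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(M, N))
  if (row_normalize) {
    rn <- sqrt(Matrix::rowSums(R^2))
    if (any(rn == 0)) {
      warning("projection has ", sum(rn == 0), " all-zero row(s); left as zero")
      rn[rn == 0] <- 1
    }
    R <- Matrix::Diagonal(x = 1 / rn) %*% R
  } else {
    R <- R * (1 / sqrt(M))
  }
  R <- methods::as(R, "CsparseMatrix")
  structure(
    list(R = R, N = as.integer(N), M = as.integer(M), rho = rho,
         seed = as.integer(seed), row_normalized = row_normalize),
    class = "sparse_projection"
  )
}

#' @export
print.sparse_projection <- function(x, ...) {
  cat(sprintf(
    "sparse_projection: %d -> %d, rho = %g, seed = %d, %s scaling, %.1f%% nonzero\n",
    x$N, x$M, x$rho, x$seed,
    if (x$row_normalized) "row-normalized" else "1/sqrt(M)",
    100 * length(x$R@x) / (as.numeric(x$M) * x$N)))
  invisible(x)
}

#' Serialize / restore a projection as a small config record
#'
#' Only the generator arguments are stored; the matrix is regenerated
#' deterministically from them, so experiments are reproducible without
#' storing R itself.
#'
#' @param proj A `sparse_projection`.
#' @return `projection_config()`: a named list; `projection_from_config()`:
#'   the regenerated `sparse_projection`.
#' @export
projection_config <- function(proj) {
  proj[c("N", "M", "rho", "seed", "row_normalized")]
}

#' @rdname projection_config
#' @param config A list as returned by `projection_config()`.
#' @export
projection_from_config <- function(config) {
  make_sparse_projection(config$N, config$M, rho = config$rho,
                         seed = config$seed,
                         row_normalize = isTRUE(config$row_normalized))
}

#' Project feature vectors to the reduced space
#'
#' Computes R x for every column of `X`.
#'
#' @param proj A `sparse_projection`.
#' @param X Numeric matrix with `proj$N` rows; columns are samples.
#' @return A dense M x s numeric matrix, columns aligned with `X`.
#' @export
apply_projection <- function(proj, X) {
  stopifnot(inherits(proj, "sparse_projection"))
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  if (nrow(X) != proj$N) {
    stop(sprintf("projection expects %d input rows, got %d", proj$N, nrow(X)))
  }
  out <- as.matrix(proj$R %*% X)
  colnames(out) <- colnames(X)
  out
}

#' Empirical distance-distortion audit
#'
#' For each pair (x1, x2) checks the restricted-isometry-style bounds
#' (1 - eps) ||x1 - x2||^2 <= ||R x1 - R x2||^2 <= (1 + eps) ||x1 - x2||^2
#' and reports the fraction of pairs satisfying both, plus the worst
#' relative squared-distance distortion. Pairs with x1 = x2 are skipped
#' (their ratio is undefined) and counted in `skipped`.
#'
#' The bounds are stated on the identity scale and are meaningful for the
#' default 1/sqrt(M) scaling, under which ||Rx||^2 is unbiased for ||x||^2.
#'
#' @param proj A `sparse_projection`.
#' @param pairs List of two-element lists/lists of vectors, each of
#'   dimension `proj$N`.
#' @param epsilon Distortion bound, > 0.
#' @return A `distortion_report`: `epsilon`, `pair_count`, `skipped`,
#'   `fraction_within`, `worst_ratio`.
#' @export
estimate_distortion <- function(proj, pairs, epsilon) {
  stopifnot(inherits(proj, "sparse_projection"), epsilon > 0, length(pairs) > 0)
  ratios <- vapply(pairs, function(p) {
    x1 <- p[[1L]]; x2 <- p[[2L]]
    if (length(x1) != proj$N || length(x2) != proj$N) {
      stop("pair vectors must have dimension ", proj$N)
    }
    d2 <- sum((x1 - x2)^2)
    if (d2 == 0) return(NA_real_)
    v <- apply_projection(proj, cbind(x1, x2))
    sum((v[, 1L] - v[, 2L])^2) / d2
  }, numeric(1))
  skipped <- sum(is.na(ratios))
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) stop("all pairs identical; no distances to audit")
  structure(
    list(epsilon = epsilon,
         pair_count = length(ratios),
         skipped = skipped,
         fraction_within = mean(ratios >= 1 - epsilon & ratios <= 1 + epsilon),
         worst_ratio = max(abs(ratios - 1))),
    class = "distortion_report"
  )
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf(
    "distortion audit: %d pairs (%d skipped), eps = %g, %.1f%% within bounds, worst |ratio-1| = %.4f\n",
    x$pair_count, x$skipped, x$epsilon, 100 * x$fraction_within, x$worst_ratio))
  invisible(x)
}
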