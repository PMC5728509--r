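# Shared fixtures, built in code at test time.

# Six prostate samples over seven genes with alternating Normal/Cancer
# labels; the canonical small worked example used across the I/O and
# dictionary tests.
prostate_example <- function() {
  vals <- rbind(
    G1 = c(9, -1, -1, -2, -9, 0),
    G2 = c(-11.4, 17, -1, 0, -19, 0),
    G3 = c(2.7, 0, 0, -1, 0, 0),
    G4 = c(0.6, 3, -1, -2, 0, -2),
    G5 = c(4.3, 6, 3, 6, 76, 2),
    G6 = c(28, -6, 0, 3, 9, 0),
    Gn = c(37.3, 14, 26, 25, -21, 21)
  )
  colnames(vals) <- paste0("X", 1:6)
  expression_set(vals, labels = rep(c("Normal", "Cancer"), 3))
}

# random unit-column dictionary with two equal class blocks
random_dictionary <- function(m, n, seed = 1) {
  withr::with_seed(seed, {
    X <- normalize_columns(matrix(rnorm(m * n), m))
  })
  half <- floor(n / 2)
  structure(
    list(X = X,
         class_slices = list(seq_len(half), seq.int(half + 1L, n)),
         class_names = c("A", "B"),
         projection = NULL),
    class = "crc_dictionary"
  )
}

# independent ridge oracle: augmented least squares via QR, never the
# package's cholesky path
ridge_oracle <- function(X, lambda, y) {
  qr.solve(rbind(X, sqrt(lambda) * diag(ncol(X))), c(y, numeric(ncol(X))))
}

# forge a projection whose matrix is the identity (module-level test hook)
identity_projection <- function(N) {
  p <- make_sparse_projection(N, N, rho = 1, seed = 1)
  p$R <- Matrix::Diagonal(N)
  p
}

# separable two-class study conditions used by the recovery checks
separable_spec <- function(seed = 42) {
  synthetic_spec(n_classes = 2, samples_per_class = 20, n_features = 500,
                 n_informative = 20, effect_size = 5, noise_sigma = 1,
                 seed = seed)
}
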