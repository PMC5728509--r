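#' Specification for a synthetic expression dataset
#'
#' Describes a labeled expression-like dataset with controlled class
#' separation: a small block of informative features carries class-specific
#' mean shifts, all remaining features are pure noise, and an optional
#' low-rank mode makes features coherent through shared latent factors.
#' The shapes emulate typical two-to-four-class microarray/RNA-seq panels
#' (tens to hundreds of samples, hundreds to thousands of features).
#'
#' @param n_classes Number of classes, >= 2.
#' @param samples_per_class Integer (recycled) or vector of per-class sizes.
#' @param n_features Total feature count.
#' @param n_informative Number of class-associated features,
#'   <= `n_features`. Ignored in low-rank mode, where the class signal lives
#'   in the latent space and loads on all features.
#' @param effect_size Class-mean gap, in units of `noise_sigma`. The
#'   informative block is split into K near-equal marker sub-blocks, one per
#'   class; a marker feature has mean `effect_size * noise_sigma` in its own
#'   class and 0 elsewhere, so every informative feature separates its class
#'   from the rest by exactly that gap and all pairwise class distances over
#'   the block are equal (a simplex-like layout). Marker sub-blocks also
#'   keep the class signal subspaces distinct, which any
#'   representation-based classifier requires.
#' @param noise_sigma Gaussian noise standard deviation, > 0.
#' @param redundancy_rank Optional latent dimension r: the noiseless part of
#'   the data becomes (loadings) x (latent factors) of rank <= r, so the
#'   features are highly redundant and the class signal survives aggressive
#'   dimension reduction.
#' @param log_normal Exponentiate the Gaussian draw (log-normal intensities)
#'   for heavier-tailed, strictly positive values.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 2, samples_per_class = 20,
                           n_features = 500, n_informative = 20,
                           effect_size = 5, noise_sigma = 1,
                           redundancy_rank = NULL, log_normal = FALSE,
                           seed = 1) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  samples_per_class <- rep_len(as.integer(samples_per_class), n_classes)
  if (any(samples_per_class < 1) || n_features < 1) stop("all counts must be positive")
  if (n_informative > n_features) stop("n_informative must be <= n_features")
  if (!is.null(redundancy_rank) && redundancy_rank > n_features) {
    stop("redundancy_rank must be <= n_features")
  }
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  structure(
    list(n_classes = as.integer(n_classes),
         samples_per_class = samples_per_class,
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sigma = noise_sigma,
         redundancy_rank = if (is.null(redundancy_rank)) NULL else as.integer(redundancy_rank),
         log_normal = isTRUE(log_normal),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic labeled expression dataset
#'
#' @param spec A [synthetic_spec()].
#' @return An [expression_set()] (features x samples) with attribute
#'   `truth`: a list with `informative` (row indices carrying signal),
#'   `class_means` (per-class mean matrix over informative features, dense
#'   mode only) and `spec`.
#' @examples
#' es <- generate_dataset(synthetic_spec(seed = 7))
#' table(es$labels)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$n_classes
  n <- sum(spec$samples_per_class)
  p <- spec$n_features
  labels <- rep(paste0("C", seq_len(K)), times = spec$samples_per_class)
  gap <- spec$effect_size * spec$noise_sigma
  cls <- rep(seq_len(K), times = spec$samples_per_class)

  out <- withr::with_seed(spec$seed, {
    if (is.null(spec$redundancy_rank)) {
      mu <- matrix(0, nrow = p, ncol = K)
      if (spec$n_informative > 0 && spec$effect_size != 0) {
        # one marker sub-block per class, elevated by `gap` in that class only
        block <- rep_len(seq_len(K), spec$n_informative)
        for (j in seq_len(spec$n_informative)) mu[j, block[j]] <- gap
      }
      vals <- mu[, cls, drop = FALSE] +
        matrix(stats::rnorm(p * n, sd = spec$noise_sigma), nrow = p)
      truth_means <- mu[seq_len(spec$n_informative), , drop = FALSE]
      list(vals = vals,
           informative = seq_len(spec$n_informative),
           class_means = truth_means)
    } else {
      r <- spec$redundancy_rank
      # marker layout in latent space: class c is elevated on latent dim c
      mu_lat <- matrix(0, nrow = r, ncol = K)
      for (c in seq_len(K)) mu_lat[((c - 1) %% r) + 1, c] <- mu_lat[((c - 1) %% r) + 1, c] + gap
      Z <- mu_lat[, cls, drop = FALSE] + matrix(stats::rnorm(r * n), nrow = r)
      W <- matrix(stats::rnorm(p * r, sd = 1 / sqrt(r)), nrow = p)
      vals <- W %*% Z +
        matrix(stats::rnorm(p * n, sd = spec$noise_sigma), nrow = p)
      list(vals = vals, informative = seq_len(p), class_means = NULL)
    }
  })
  vals <- out$vals
  if (spec$log_normal) vals <- exp(vals)
  es <- expression_set(vals, labels = labels,
                       feature_ids = paste0("G", seq_len(p)),
                       sample_ids = paste0("S", seq_len(n)))
  attr(es, "truth") <- list(informative = out$informative,
                            class_means = out$class_means, spec = spec)
  es
}

#' Generate a sparse test signal with known support
#'
#' Produces a length-N vector with exactly K nonzero entries at seeded
#' positions, magnitudes drawn uniformly from `amplitude` with random sign.
#' The planted support is returned for oracle comparison in sparse-recovery
#' tests.
#'
#' @param N Signal dimension.
#' @param K Number of nonzeros, 0 <= K <= N.
#' @param amplitude Length-2 range of nonzero magnitudes.
#' @param seed Integer seed.
#' @return A list: `x` (numeric length N), `support` (sorted indices).
#' @export
generate_sparse_signal <- function(N, K, amplitude = c(1, 3), seed = 1) {
  if (K > N) stop("K must be <= N")
  if (K < 0) stop("K must be >= 0")
  withr::with_seed(as.integer(seed), {
    x <- numeric(N)
    support <- sort(sample.int(N, K))
    if (K > 0) {
      mag <- stats::runif(K, amplitude[1], amplitude[2])
      x[support] <- mag * sample(c(-1, 1), K, replace = TRUE)
    }
    list(x = x, support = support)
  })
}
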