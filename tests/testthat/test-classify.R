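test_that("dictionary construction groups unit-norm columns by class", {
  withr::with_seed(1, vals <- matrix(rnorm(20 * 6), 20))
  es <- expression_set(vals, labels = c("a", "b", "a", "b", "a", "b"))
  d <- build_dictionary(es)
  expect_equal(ncol(d$X), 6L)
  expect_equal(d$class_slices, list(1:3, 4:6))
  expect_equal(unname(sqrt(colSums(d$X^2))), rep(1, 6), tolerance = 1e-12)
  # columns grouped: class a first (first appearance), original within-class order
  expect_equal(unname(d$X[, 1]), vals[, 1] / sqrt(sum(vals[, 1]^2)))
  expect_equal(unname(d$X[, 4]), vals[, 2] / sqrt(sum(vals[, 2]^2)))
  # identity projection leaves the dictionary unchanged
  d_id <- build_dictionary(es, projection = identity_projection(20))
  expect_equal(d_id$X, d$X, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the prostate example forms the column-sample dictionary", {
  es <- prostate_example()
  d <- build_dictionary(es)
  expect_equal(d$class_names, c("Normal", "Cancer"))
  x1 <- c(9, -11.4, 2.7, 0.6, 4.3, 28, 37.3)
  expect_equal(unname(d$X[, 1]), x1 / sqrt(sum(x1^2)))
  x2 <- c(-1, 17, 0, 3, 6, -6, 14)
  expect_equal(unname(d$X[, 4]), x2 / sqrt(sum(x2^2)))  # first Cancer column
})

test_that("coding operator equals the independent ridge solve", {
  withr::with_seed(31, {
    cases <- replicate(30, {
      m <- sample(10:50, 1); n <- sample(20:200, 1)
      list(X = normalize_columns(matrix(rnorm(m * n), m)),
           lambda = 10^runif(1, -4, 0), y = rnorm(m))
    }, simplify = FALSE)
  })
  for (cs in cases) {
    half <- floor(ncol(cs$X) / 2)
    d <- structure(list(X = cs$X,
                        class_slices = list(seq_len(half),
                                            seq.int(half + 1, ncol(cs$X))),
                        class_names = c("A", "B"), projection = NULL),
                   class = "crc_dictionary")
    model <- fit_crc(d, cs$lambda)
    got <- drop(model$P %*% cs$y)
    want <- ridge_oracle(cs$X, cs$lambda, cs$y)
    expect_lt(sqrt(sum((got - want)^2)), 1e-8 * (1 + sqrt(sum(cs$y^2))))
  }
})

test_that("orthonormal dictionary at vanishing lambda recovers X'y and the orthogonal projection", {
  withr::with_seed(32, {
    X <- qr.Q(qr(matrix(rnorm(30 * 10), 30)))
    y <- rnorm(30)
  })
  d <- structure(list(X = X, class_slices = list(1:5, 6:10),
                      class_names = c("A", "B"), projection = NULL),
                 class = "crc_dictionary")
  model <- fit_crc(d, 1e-12)
  coef <- drop(model$P %*% y)
  expect_equal(coef, drop(crossprod(X, y)), tolerance = 1e-6)
  # X rho at the least-squares limit is the orthogonal projection onto span(X)
  expect_equal(drop(X %*% coef), drop(X %*% crossprod(X, y)), tolerance = 1e-6)
  resid <- y - drop(X %*% coef)
  expect_lt(max(abs(crossprod(X, resid))), 1e-6)
})

test_that("lambda is validated and shrinks the coding norm monotonically", {
  d <- random_dictionary(20, 50, seed = 33)
  expect_error(fit_crc(d, 0), "lambda")
  expect_error(fit_crc(d, -1), "lambda")
  withr::with_seed(34, ys <- replicate(5, rnorm(20), simplify = FALSE))
  for (y in ys) {
    norms <- vapply(10^seq(-4, 2), function(l) {
      sqrt(sum((fit_crc(d, l)$P %*% y)^2))
    }, numeric(1))
    expect_true(all(diff(norms) <= 1e-10))
  }
})

test_that("coding a sample populates slices and residual consistently", {
  d <- random_dictionary(20, 30, seed = 35)
  model <- fit_crc(d, 0.01)
  # zero query codes to zero
  z <- code_sample(model, numeric(20), prepare = FALSE)
  expect_equal(z$coefficients, numeric(30))
  expect_equal(z$residual_vector, numeric(20))

  withr::with_seed(36, y <- rnorm(20))
  cv <- code_sample(model, y)
  expect_equal(unlist(cv$by_class), cv$coefficients,
               ignore_attr = TRUE)
  expect_equal(cv$residual_vector,
               cv$query - drop(d$X %*% cv$coefficients))
  # stored-P coding equals a fresh independent solve
  yn <- y / sqrt(sum(y^2))
  expect_equal(cv$coefficients, ridge_oracle(d$X, 0.01, yn),
               tolerance = 1e-8)
})

test_that("a training column queries back to its own class at tiny lambda", {
  d <- random_dictionary(30, 10, seed = 37)  # under-complete: independent columns
  model <- fit_crc(d, 1e-12)
  cv <- code_sample(model, d$X[, 3], prepare = FALSE)
  expect_lt(sqrt(sum(cv$residual_vector^2)), 1e-6)
  rep <- classify_crc(model, d$X[, 3], prepare = FALSE)
  expect_equal(rep$predicted_class, "A")
})

test_that("CRC predictions are scale-robust and permutation-covariant", {
  es <- generate_dataset(separable_spec())
  train <- subset_expression_set(es, samples = c(1:15, 21:35))
  test_y <- es$values[, c(16, 36)]
  d <- build_dictionary(train)
  model <- fit_crc(d, 1e-3)
  for (j in 1:2) {
    base <- classify_crc(model, test_y[, j])
    scaled <- classify_crc(model, 5 * test_y[, j])
    expect_equal(scaled$predicted_class, base$predicted_class)
    expect_equal(scaled$per_class_residuals, base$per_class_residuals,
                 tolerance = 1e-10)
  }
  # permute training columns within a class: residuals unchanged
  perm <- withr::with_seed(38, c(sample(15), 15 + sample(15)))
  train_p <- subset_expression_set(train, samples = perm)
  model_p <- fit_crc(build_dictionary(train_p), 1e-3)
  for (j in 1:2) {
    expect_equal(classify_crc(model_p, test_y[, j])$per_class_residuals,
                 classify_crc(model, test_y[, j])$per_class_residuals,
                 tolerance = 1e-8)
  }
})

test_that("well-separated classes are classified perfectly, agreeing with nearest mean", {
  spec <- synthetic_spec(n_classes = 2, samples_per_class = 10, n_features = 20,
                         n_informative = 20, effect_size = 5, seed = 51)
  es <- generate_dataset(spec)
  withr::with_seed(52, {
    # 50 fresh queries from the same class-conditional law
    truth_attr <- attr(es, "truth")
    mu <- matrix(0, 20, 2)
    mu[seq_len(nrow(truth_attr$class_means)), ] <- truth_attr$class_means
    q_lab <- sample(c("C1", "C2"), 50, replace = TRUE)
    Q <- sapply(q_lab, function(k) mu[, match(k, c("C1", "C2"))] + rnorm(20))
  })
  model <- fit_crc(build_dictionary(es), 0.01)
  pred <- predict(model, Q)
  expect_equal(unname(pred), q_lab)
  # nearest-class-mean oracle agrees
  m1 <- rowMeans(es$values[, es$labels == "C1"])
  m2 <- rowMeans(es$values[, es$labels == "C2"])
  ncm <- apply(Q, 2, function(y) {
    if (sum((y - m1)^2) < sum((y - m2)^2)) "C1" else "C2"
  })
  expect_equal(unname(pred), unname(ncm))
})

test_that("degenerate decisions: single class, orthogonal query sentinel", {
  withr::with_seed(53, vals <- matrix(rnorm(10 * 4), 10))
  es1 <- expression_set(vals, labels = rep("only", 4))
  model1 <- fit_crc(build_dictionary(es1), 0.01)
  withr::with_seed(54, expect_equal(classify_crc(model1, rnorm(10))$predicted_class, "only"))

  # queries orthogonal to the training span code to zero: sentinel fallback
  X <- rbind(diag(4), matrix(0, 2, 4))
  es2 <- expression_set(X, labels = c("a", "a", "b", "b"))
  model2 <- fit_crc(build_dictionary(es2), 0.01)
  y_orth <- c(0, 0, 0, 0, 1, 1)
  expect_warning(rep <- classify_crc(model2, y_orth), "zero")
  expect_equal(rep$predicted_class, "a")  # lowest class index fallback
})

test_that("orthogonal matching pursuit recovers exact and planted supports", {
  d <- random_dictionary(30, 50, seed = 61)
  # single-atom signal: one iteration, exact coefficient
  fit <- solve_omp(d$X, 3 * d$X[, 7], max_nonzeros = 5)
  expect_equal(fit$support, 7L)
  expect_equal(fit$coefficients[7], 3, tolerance = 1e-10)
  expect_lt(sqrt(sum(fit$residual_vector^2)), 1e-10)

  # planted 5-sparse codes in the known recovery regime
  hits <- 0
  for (s in 1:100) {
    X <- withr::with_seed(s, normalize_columns(matrix(rnorm(30 * 50), 30)))
    sig <- generate_sparse_signal(50, 5, amplitude = c(1, 3), seed = 1000 + s)
    fit <- solve_omp(X, drop(X %*% sig$x), max_nonzeros = 5,
                     residual_tol = 1e-10)
    if (setequal(fit$support, sig$support)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("OMP with a full support budget attains the least-squares residual", {
  d <- random_dictionary(30, 10, seed = 62)
  withr::with_seed(63, y <- rnorm(30))
  fit <- solve_omp(d$X, y, max_nonzeros = 10, residual_tol = 0)
  ls_res <- y - d$X %*% qr.coef(qr(d$X), y)
  expect_lte(sum(fit$residual_vector^2), sum(ls_res^2) + 1e-10)
  expect_error(solve_omp(d$X, y, max_nonzeros = 0), "max_nonzeros")
})

test_that("SRC classifies self-queries and separable data, agreeing with CRC", {
  es <- generate_dataset(separable_spec(seed = 71))
  train <- subset_expression_set(es, samples = c(1:15, 21:35))
  held <- c(16:20, 36:40)
  d <- build_dictionary(train)
  # noiseless self-query
  rep <- classify_src(d, train$values[, 20], max_nonzeros = 5)
  expect_equal(rep$predicted_class, "C2")
  # held-out queries: perfect and >= 90% agreement with CRC
  model <- fit_crc(d, 1e-3)
  src_pred <- vapply(held, function(i) {
    classify_src(d, es$values[, i])$predicted_class
  }, character(1))
  crc_pred <- vapply(held, function(i) {
    classify_crc(model, es$values[, i])$predicted_class
  }, character(1))
  expect_equal(src_pred, es$labels[held])
  expect_gte(mean(src_pred == crc_pred), 0.9)
})
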