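test_that("make_folds balances, reproduces, and groups", {
  f <- make_folds(10, k = 5, seed = 3)
  expect_equal(unname(table(f$fold_index)), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(make_folds(10, 5, 3)$fold_index, f$fold_index)
  expect_false(identical(make_folds(10, 5, 4)$fold_index, f$fold_index))
  # uneven n: sizes differ by at most 1
  f2 <- make_folds(23, 5, 1)
  expect_lte(diff(range(table(f2$fold_index))), 1)
  # grouped mode: participants never span folds
  grp <- rep(sprintf("p%02d", 1:8), each = 3)
  fg <- make_folds(24, 5, 2, groups = grp)
  expect_true(all(tapply(fg$fold_index, grp,
                         function(z) length(unique(z))) == 1))
  expect_error(make_folds(3, 5, 1), "at least k")
  expect_error(make_folds(10, 5, 1, groups = rep(c("a", "b"), 5)),
               "distinct participants")
})

test_that("the linear SVM solves separable toy problems", {
  # symmetric pair: boundary at zero
  m <- fit_linear_svm(matrix(c(-1, 1), ncol = 1), c("a", "b"))
  expect_lt(abs(m$intercept), 1e-3)
  expect_identical(predict_linear_model(m, matrix(c(-5, 5), ncol = 1)),
                   c("a", "b"))
  # separable 2-D blobs
  X <- withr::with_seed(7, rbind(matrix(rnorm(60, -3, 0.5), ncol = 2),
                                 matrix(rnorm(60, 3, 0.5), ncol = 2)))
  y <- rep(c("f", "m"), each = 30)
  m2 <- fit_linear_svm(X, y)
  expect_equal(mean(predict_linear_model(m2, X) == y), 1.0)
  expect_error(fit_linear_svm(X, rep("f", 60)), "two classes")
})

test_that("SVM accuracy on permuted labels sits in the binomial null band", {
  # 5-fold CV on pure noise with an imbalanced permuted labelling; mean
  # accuracy must fall within the central 99% binomial band around the
  # majority rate
  n <- 60
  X <- withr::with_seed(8, matrix(rnorm(n * 10), n))
  y <- withr::with_seed(9, sample(rep(c("f", "m"), c(42, 18))))
  folds <- make_folds(n, 5, 10)
  res <- crossval_experiment(
    labeled_dataset(X, sprintf("p%02d", 1:n), rep("s1", n),
                    data.frame(participant = sprintf("p%02d", 1:n),
                               gender = y)),
    "gender", "svm", folds)
  p <- 42 / 60
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_gte(res$evaluation$mean_accuracy, p - half)
  expect_lte(res$evaluation$mean_accuracy, p + half)
  expect_equal(sum(res$evaluation$confusion_counts), n)
})

test_that("Bayesian regression recovers linear targets and handles degeneracy", {
  X <- withr::with_seed(11, matrix(rnorm(50 * 3), 50))
  y <- 2 * X[, 1] + 1
  tr <- 1:40; te <- 41:50
  m <- fit_bayesian_regression(X[tr, ], y[tr])
  ev <- evaluate_regression(y[te], predict_linear_model(m, X[te, ]))
  expect_gte(ev$r2, 0.99)
  # constant response -> intercept-only
  mc <- fit_bayesian_regression(X, rep(3, 50))
  expect_lt(sqrt(sum(mc$weights^2)), 1e-8)
  expect_equal(predict_linear_model(mc, X), rep(3, 50))
})

test_that("Bayesian predictive uncertainty grows away from the data", {
  # conjugate 1-D check: the posterior-variance term x' S x is a parabola
  # in x, so an extrapolated point must beat the training centroid
  X <- withr::with_seed(12, matrix(rnorm(40, 0, 1), ncol = 1))
  y <- 1.5 * X[, 1] + withr::with_seed(13, rnorm(40, 0, 0.3))
  m <- fit_bayesian_regression(X, y)
  pr <- predict_linear_model(m, matrix(c(mean(X), 25), ncol = 1), se = TRUE)
  expect_gt(pr$se[2], pr$se[1])
  expect_gte(pr$se[1] + 1e-12, m$predictive_noise)
})

test_that("PCR keeps the promised variance and composes weights exactly", {
  # rank-1 data -> a single component
  base <- withr::with_seed(14, rnorm(30))
  X1 <- cbind(base, 2 * base, -base)
  m1 <- fit_pcr(X1, base)
  expect_equal(m1$n_components, 1L)
  # variance_kept = 1 on full-rank tall X equals ordinary least squares
  X <- withr::with_seed(15, matrix(rnorm(40 * 4), 40))
  y <- withr::with_seed(16, rnorm(40))
  m <- fit_pcr(X, y, variance_kept = 1.0)
  ols <- stats::lm(y ~ X)
  expect_equal(predict_linear_model(m, X), unname(fitted(ols)),
               tolerance = 1e-10)
  # composed weight vector reproduces the component-space fit
  m95 <- fit_pcr(X, y, variance_kept = 0.95)
  xm <- colMeans(X)
  sv <- svd(sweep(X, 2, xm))
  nc <- m95$n_components
  scores <- sweep(X, 2, xm) %*% sv$v[, 1:nc, drop = FALSE]
  comp_fit <- stats::lm.fit(cbind(1, scores), y)
  expect_equal(as.numeric(X %*% m95$weights) + m95$intercept,
               as.numeric(cbind(1, scores) %*% comp_fit$coefficients),
               tolerance = 1e-10)
  expect_error(fit_pcr(X, y, variance_kept = 1.2), "variance_kept")
})

test_that("evaluate_regression matches hand computations", {
  y <- c(1, 2, 3)
  expect_equal(evaluate_regression(y, y), list(r2 = 1, rmse = 0))
  expect_equal(evaluate_regression(y, rep(mean(y), 3))$r2, 0)
  # SSres = 1, SStot = 2
  ev <- evaluate_regression(c(1, 2, 3), c(1, 2, 4))
  expect_equal(ev$r2, 0.5)
  expect_equal(ev$rmse, sqrt(1 / 3))
  expect_error(evaluate_regression(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("crossval_experiment returns one model per fold and mean metrics", {
  n <- 40
  X <- withr::with_seed(17, matrix(rnorm(n * 6), n))
  labels <- data.frame(participant = sprintf("p%02d", 1:n),
                       gender = rep(c("f", "m"), n / 2),
                       extraversion = 3 + X[, 1])
  data <- labeled_dataset(X, labels$participant, rep("s1", n), labels)
  folds <- make_folds(n, 5, 20)
  res <- crossval_experiment(data, "extraversion", "bayesian", folds)
  expect_length(res$models, 5)
  expect_equal(res$evaluation$mean_r2, mean(res$evaluation$per_fold_r2))
  expect_equal(res$evaluation$mean_rmse, mean(res$evaluation$per_fold_rmse))
  expect_gte(res$evaluation$mean_r2, 0.99)   # realizable noiseless target
  # reproducibility: same seed, same data -> identical results
  res2 <- crossval_experiment(data, "extraversion", "bayesian",
                              make_folds(n, 5, 20))
  expect_identical(res$evaluation$per_fold_r2, res2$evaluation$per_fold_r2)
  # family/target mismatches
  expect_error(crossval_experiment(data, "extraversion", "svm", folds),
               "classifier")
  expect_error(crossval_experiment(data, "gender", "bayesian", folds),
               "svm")
})

test_that("all regression families pass the realizable / permuted-null check", {
  n <- 60
  X <- withr::with_seed(21, matrix(rnorm(n * 8), n))
  w <- withr::with_seed(22, rnorm(8))
  y <- as.numeric(X %*% w) + 2
  ids <- sprintf("p%02d", 1:n)
  for (family in c("bayesian", "pcr")) {
    labels <- data.frame(participant = ids, gender = rep(c("f", "m"), n / 2),
                         extraversion = y)
    data <- labeled_dataset(X, ids, rep("s1", n), labels)
    res <- crossval_experiment(data, "extraversion", family,
                               make_folds(n, 5, 23))
    expect_gte(res$evaluation$mean_r2, 0.99)
    # permuted targets: mean held-out R2 <= 0.05 over 20 seeds
    r2s <- vapply(1:20, function(s) {
      labels$extraversion <- withr::with_seed(100 + s, sample(y))
      dperm <- labeled_dataset(X, ids, rep("s1", n), labels)
      crossval_experiment(dperm, "extraversion", family,
                          make_folds(n, 5, s))$evaluation$mean_r2
    }, numeric(1))
    expect_lte(mean(r2s), 0.05)
  }
})
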