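# Cross-validated linear decoding: linear SVM for gender, Bayesian linear
# regression (evidence-maximised ridge) and principal-component regression
# for traits and genre preferences.
#
# No SVM or Bayesian-ridge implementation ships in this stack, so both are
# implemented here directly: the SVM as the smooth squared-hinge primal
# (optimised in the span of the training rows when F > N), the Bayesian
# model by MacKay-style evidence maximisation over the two Gaussian
# precision hyperparameters using the SVD of the centred design.

#' Assemble a labelled feature dataset
#'
#' One row per (participant, stimulus) feature vector; participant-level
#' labels (gender, five traits in \[1, 5\], optionally twelve genre
#' preferences in \[1, 7\]) are resolved onto each sample row.
#'
#' @param features N x F numeric matrix (default F = 1770).
#' @param participants,stimuli length-N identifier vectors.
#' @param labels data frame with a `participant` column, a `gender`
#'   column, trait columns, and optional preference columns.
#' @param trait_names,preference_names which label columns are traits /
#'   preferences.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, participants, stimuli, labels,
                            trait_names = intersect(big_five_traits(),
                                                    names(labels)),
                            preference_names = intersect(stomp_genres(),
                                                         names(labels))) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(participants) == n, length(stimuli) == n,
            "participant" %in% names(labels))
  if (anyNA(features) || !all(is.finite(features)))
    stop("features must be complete and finite", call. = FALSE)
  row <- match(as.character(participants), as.character(labels$participant))
  if (anyNA(row))
    stop("some samples have no label row for their participant", call. = FALSE)
  resolved <- labels[row, , drop = FALSE]
  rownames(resolved) <- NULL
  structure(list(features = features,
                 sample_ids = data.frame(participant = as.character(participants),
                                         stimulus = as.character(stimuli),
                                         stringsAsFactors = FALSE),
                 labels = resolved,
                 trait_names = trait_names,
                 preference_names = preference_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples (%d participants) x %d features; %d traits, %d preferences\n",
              nrow(x$features), length(unique(x$sample_ids$participant)),
              ncol(x$features), length(x$trait_names),
              length(x$preference_names)))
  invisible(x)
}

#' Big-Five trait names
#' @return Character vector of the five trait names used throughout.
#' @export
big_five_traits <- function()
  c("openness", "conscientiousness", "extraversion", "agreeableness",
    "neuroticism")

#' STOMP-R genre names
#' @return Character vector of the twelve genre-preference names.
#' @export
stomp_genres <- function()
  c("blues", "country", "dance", "funk", "jazz", "metal", "oldies", "pop",
    "rap", "reggae", "rock", "soul")

#' Cross-validation fold assignment
#'
#' Random mode shuffles samples (seeded) and deals them into `k` folds
#' whose sizes differ by at most one. Grouped mode partitions participants
#' instead, so no participant spans folds (avoids leakage across stimuli
#' of the same dancer, at the price of unequal fold sizes).
#'
#' @param n sample count.
#' @param k number of folds.
#' @param seed integer seed; the assignment is a pure function of
#'   `(n, k, seed, groups)`.
#' @param groups optional length-`n` participant ids enabling grouped mode.
#' @return An object of class `fold_assignment` with `fold_index` (values
#'   in `1..k`), `k`, `seed` and `mode`.
#' @export
make_folds <- function(n, k = 5, seed = 1, groups = NULL) {
  if (n < k) stop("need at least k samples", call. = FALSE)
  if (is.null(groups)) {
    idx <- withr::with_seed(seed, sample.int(n))
    fold <- integer(n)
    fold[idx] <- rep_len(seq_len(k), n)
    mode <- "random"
  } else {
    stopifnot(length(groups) == n)
    g <- unique(as.character(groups))
    if (length(g) < k)
      stop("grouped mode needs at least k distinct participants", call. = FALSE)
    gidx <- withr::with_seed(seed, sample(g))
    gfold <- stats::setNames(rep_len(seq_len(k), length(g)), gidx)
    fold <- unname(gfold[as.character(groups)])
    mode <- "grouped-by-participant"
  }
  structure(list(fold_index = fold, k = as.integer(k), seed = seed,
                 mode = mode), class = "fold_assignment")
}

new_linear_model <- function(weights, intercept, family, fold = NA_integer_,
                             extra = list()) {
  structure(c(list(weights = as.numeric(weights),
                   intercept = as.numeric(intercept),
                   family = family, fold = fold), extra),
            class = "trained_linear_model")
}

#' @export
print.trained_linear_model <- function(x, ...) {
  cat(sprintf("<trained_linear_model> family = %s, %d weights, intercept = %.4g\n",
              x$family, length(x$weights), x$intercept))
  invisible(x)
}

#' Linear support vector machine (squared-hinge primal)
#'
#' Trains a linear two-class SVM by minimising
#' \deqn{\tfrac{1}{2}\|w\|^2 + C \sum_i \max(0, 1 - y_i (w x_i + b))^2}
#' (L2 penalty on margin violations). The smooth primal is optimised with
#' L-BFGS until the projected gradient falls below `tol`; when F > N the
#' weight vector is parameterised in the span of the training rows, which
#' is exact for this objective and much faster at F = 1770.
#'
#' @param X N x F matrix.
#' @param y two-class labels (factor, character or numeric).
#' @param tol stopping tolerance on the projected gradient.
#' @param C margin-violation cost.
#' @return A `trained_linear_model` (`family = "svm"`) with `classes`
#'   recording the negative/positive label order.
#' @export
fit_linear_svm <- function(X, y, tol = 1e-5, C = 1.0) {
  X <- as.matrix(X)
  f <- factor(y)
  if (nlevels(f) != 2L)
    stop("need exactly two classes present", call. = FALSE)
  ys <- ifelse(as.integer(f) == 2L, 1, -1)
  n <- nrow(X); F <- ncol(X)
  if (F > n) {
    G <- tcrossprod(X)                      # n x n
    obj <- function(par) {
      beta <- par[-length(par)]; b <- par[length(par)]
      Gb <- as.numeric(G %*% beta)
      m <- 1 - ys * (Gb + b)
      act <- m > 0
      0.5 * sum(beta * Gb) + C * sum(m[act]^2)
    }
    grad <- function(par) {
      beta <- par[-length(par)]; b <- par[length(par)]
      Gb <- as.numeric(G %*% beta)
      m <- 1 - ys * (Gb + b)
      act <- m > 0
      r <- numeric(n); r[act] <- ys[act] * m[act]
      c(Gb - 2 * C * as.numeric(G %*% r), -2 * C * sum(r))
    }
    fit <- stats::optim(numeric(n + 1L), obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 2000L, pgtol = tol, factr = 10))
    w <- as.numeric(crossprod(X, fit$par[-(n + 1L)]))
    b <- fit$par[n + 1L]
  } else {
    obj <- function(par) {
      w <- par[-length(par)]; b <- par[length(par)]
      m <- 1 - ys * (as.numeric(X %*% w) + b)
      act <- m > 0
      0.5 * sum(w^2) + C * sum(m[act]^2)
    }
    grad <- function(par) {
      w <- par[-length(par)]; b <- par[length(par)]
      m <- 1 - ys * (as.numeric(X %*% w) + b)
      act <- m > 0
      r <- numeric(n); r[act] <- ys[act] * m[act]
      c(w - 2 * C * as.numeric(crossprod(X, r)), -2 * C * sum(r))
    }
    fit <- stats::optim(numeric(F + 1L), obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 2000L, pgtol = tol, factr = 10))
    w <- fit$par[-(F + 1L)]
    b <- fit$par[F + 1L]
  }
  new_linear_model(w, b, "svm", extra = list(classes = levels(f), C = C,
                                             tol = tol))
}

#' Bayesian linear regression by evidence maximisation
#'
#' Gaussian prior `w ~ N(0, alpha^-1 I)` and Gaussian noise
#' `y ~ N(Xw + b, beta^-1)`; the two precision hyperparameters are set by
#' maximising the marginal likelihood (MacKay's fixed-point iteration on
#' the SVD of the centred design). Returns posterior-mean weights; the
#' posterior over weights also yields per-sample predictive standard
#' deviations through [predict_linear_model()].
#'
#' @param X N x F matrix.
#' @param y numeric response.
#' @param max_iter,rel_tol iteration controls for the hyperparameter
#'   fixed point.
#' @return A `trained_linear_model` (`family = "bayesian"`) with fields
#'   `alpha`, `beta` and `predictive_noise` (= `1/sqrt(beta)`).
#' @export
fit_bayesian_regression <- function(X, y, max_iter = 300, rel_tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2, all(is.finite(y)))
  n <- nrow(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  vy <- stats::var(y)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d[1], 0) * 1e-12
  if (vy < 1e-24 || !any(pos)) {
    # constant response or constant features: intercept-only model
    return(new_linear_model(numeric(ncol(X)), ym, "bayesian",
                            extra = list(alpha = Inf, beta = Inf,
                                         predictive_noise = 0,
                                         x_mean = xm,
                                         svd = NULL)))
  }
  d <- sv$d[pos]; U <- sv$u[, pos, drop = FALSE]; V <- sv$v[, pos, drop = FALSE]
  d2 <- d^2
  uty <- as.numeric(crossprod(U, yc))
  alpha <- 1
  beta <- 1 / vy
  for (it in seq_len(max_iter)) {
    coef <- d * uty / (alpha / beta + d2)     # V-space posterior mean
    gamma <- sum(beta * d2 / (alpha + beta * d2))
    rss <- sum(yc^2) - 2 * sum(coef * d * uty) + sum(coef^2 * d2)
    alpha_new <- gamma / max(sum(coef^2), 1e-300)
    beta_new <- max(n - gamma, 1e-12) / max(rss, 1e-300)
    if (abs(alpha_new - alpha) <= rel_tol * alpha &&
        abs(beta_new - beta) <= rel_tol * beta) {
      alpha <- alpha_new; beta <- beta_new; break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  coef <- d * uty / (alpha / beta + d2)
  w <- as.numeric(V %*% coef)
  new_linear_model(w, ym - sum(xm * w), "bayesian",
                   extra = list(alpha = alpha, beta = beta,
                                predictive_noise = 1 / sqrt(beta),
                                x_mean = xm,
                                svd = list(d = d, V = V)))
}

#' Predict from a trained linear model
#'
#' @param model a `trained_linear_model`.
#' @param X matrix of samples.
#' @param se for Bayesian models, also return per-sample predictive
#'   standard deviations (noise plus posterior weight uncertainty).
#' @return Numeric predictions; with `se = TRUE` a list with `fit` and
#'   `se`. SVM models return the class labels.
#' @export
predict_linear_model <- function(model, X, se = FALSE) {
  X <- as.matrix(X)
  score <- as.numeric(X %*% model$weights) + model$intercept
  if (model$family == "svm")
    return(model$classes[(score >= 0) + 1L])
  if (!se) return(score)
  if (model$family != "bayesian")
    stop("predictive uncertainty is only available for Bayesian models",
         call. = FALSE)
  if (is.null(model$svd)) return(list(fit = score, se = rep(0, nrow(X))))
  Xc <- sweep(X, 2, model$x_mean)
  proj <- Xc %*% model$svd$V                     # N x r
  resid2 <- rowSums(Xc^2) - rowSums(proj^2)      # orthogonal complement
  resid2[resid2 < 0] <- 0
  varw <- proj^2 %*% (1 / (model$beta * model$svd$d^2 + model$alpha))
  v <- 1 / model$beta + as.numeric(varw) + resid2 / model$alpha
  list(fit = score, se = sqrt(v))
}

#' Principal-component regression
#'
#' Projects the centred design onto the leading principal components
#' capturing at least `variance_kept` of the variance, runs ordinary least
#' squares in component space, and composes the solution back into a
#' length-F weight vector.
#'
#' @param X N x F matrix.
#' @param y numeric response.
#' @param variance_kept fraction of variance to retain, in (0, 1].
#' @return A `trained_linear_model` (`family = "pcr"`) with `n_components`.
#' @export
fit_pcr <- function(X, y, variance_kept = 0.95) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) >= 2, nrow(X) == length(y))
  if (!(variance_kept > 0 && variance_kept <= 1))
    stop("variance_kept must be in (0, 1]", call. = FALSE)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  lam <- sv$d^2
  pos <- lam > max(lam[1], 0) * 1e-12
  if (!any(pos)) return(new_linear_model(numeric(ncol(X)), ym, "pcr",
                                         extra = list(n_components = 0L)))
  lam <- lam[pos]
  nc <- which(cumsum(lam) / sum(lam) >= variance_kept - 1e-12)[1]
  d <- sv$d[seq_len(nc)]
  U <- sv$u[, seq_len(nc), drop = FALSE]
  V <- sv$v[, seq_len(nc), drop = FALSE]
  gamma <- as.numeric(crossprod(U, y - ym)) / d   # OLS on scores
  w <- as.numeric(V %*% gamma)
  new_linear_model(w, ym - sum(xm * w), "pcr",
                   extra = list(n_components = nc,
                                variance_kept = variance_kept))
}

#' Regression performance: R-squared and RMSE
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`;
#' `RMSE = sqrt(mean((y - yhat)^2))`.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return A list with `r2` and `rmse`.
#' @export
evaluate_regression <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0)
    stop("R-squared undefined: y_true has zero variance", call. = FALSE)
  sse <- sum((y_true - y_pred)^2)
  list(r2 = 1 - sse / sst, rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Cross-validated decoding experiment
#'
#' For each fold, trains the requested model family on the complement and
#' evaluates on the held-out fold. Returns the per-fold metrics, their
#' arithmetic means, and the k trained models (consumed by the
#' joint-importance attribution).
#'
#' @param data a [labeled_dataset()].
#' @param target `"gender"`, a trait name or a genre name.
#' @param family `"svm"` (gender only), `"bayesian"` or `"pcr"`.
#' @param folds a [make_folds()] assignment matching the dataset.
#' @param ... passed to the fitting function.
#' @return A list with `evaluation` (class `classification_evaluation` or
#'   `regression_evaluation`) and `models` (list of k
#'   `trained_linear_model`s).
#' @export
crossval_experiment <- function(data, target, family = c("bayesian", "pcr", "svm"),
                                folds, ...) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(folds, "fold_assignment"))
  family <- match.arg(family)
  n <- nrow(data$features)
  stopifnot(length(folds$fold_index) == n)
  if (family == "svm" && target != "gender")
    stop("the SVM family is a classifier; use it with target = 'gender'",
         call. = FALSE)
  if (family != "svm" && target == "gender")
    stop("gender is decoded with family = 'svm'", call. = FALSE)
  if (!target %in% names(data$labels))
    stop(sprintf("target '%s' not present in the labels", target), call. = FALSE)
  yall <- data$labels[[target]]
  models <- vector("list", folds$k)
  if (family == "svm") {
    acc <- numeric(folds$k)
    yf <- factor(yall)
    conf <- matrix(0L, 2, 2, dimnames = list(truth = levels(yf),
                                             pred = levels(yf)))
    for (f in seq_len(folds$k)) {
      te <- folds$fold_index == f
      m <- fit_linear_svm(data$features[!te, , drop = FALSE], yall[!te], ...)
      m$fold <- f
      pred <- predict_linear_model(m, data$features[te, , drop = FALSE])
      acc[f] <- mean(pred == as.character(yall[te]))
      for (lv in levels(yf)) for (pv in levels(yf))
        conf[lv, pv] <- conf[lv, pv] + sum(yall[te] == lv & pred == pv)
      models[[f]] <- m
    }
    ev <- structure(list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
                         confusion_counts = conf, target_name = target,
                         family = family, k = folds$k),
                    class = "classification_evaluation")
  } else {
    fitfun <- if (family == "bayesian") fit_bayesian_regression else fit_pcr
    r2 <- numeric(folds$k); rmse <- numeric(folds$k)
    for (f in seq_len(folds$k)) {
      te <- folds$fold_index == f
      m <- fitfun(data$features[!te, , drop = FALSE], yall[!te], ...)
      m$fold <- f
      pred <- predict_linear_model(m, data$features[te, , drop = FALSE])
      e <- evaluate_regression(yall[te], pred)
      r2[f] <- e$r2; rmse[f] <- e$rmse
      models[[f]] <- m
    }
    ev <- structure(list(per_fold_r2 = r2, per_fold_rmse = rmse,
                         mean_r2 = mean(r2), mean_rmse = mean(rmse),
                         target_name = target, family = family, k = folds$k),
                    class = "regression_evaluation")
  }
  list(evaluation = ev, models = models)
}

#' @export
print.regression_evaluation <- function(x, ...) {
  cat(sprintf("<regression_evaluation> %s (%s, %d-fold): mean R2 = %.3f, mean RMSE = %.3f\n",
              x$target_name, x$family, x$k, x$mean_r2, x$mean_rmse))
  invisible(x)
}

#' @export
print.classification_evaluation <- function(x, ...) {
  cat(sprintf("<classification_evaluation> %s (%s, %d-fold): mean accuracy = %.3f\n",
              x$target_name, x$family, x$k, x$mean_accuracy))
  invisible(x)
}
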