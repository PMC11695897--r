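#' Train a ridge-penalized logistic regression base learner
#'
#' Minimizes the L2-penalized mean negative log-likelihood
#' `-(1/N) * loglik + l2_strength/2 * ||beta||^2` (intercept unpenalized),
#' the conventional ridge-logistic objective.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (0/1).
#' @param l2_strength ridge penalty strength (lambda).
#' @param tol convergence threshold.
#' @param max_iter iteration cap.
#' @param feature_name optional name of the encoder this model consumes.
#' @param nonneg constrain coefficients to be non-negative (used by the
#'   stacking meta-learner, where every input is a probability that should
#'   not enter with inverted sign).
#' @return object of class `dephos_plr`.
#' @export
train_plr <- function(X, y, l2_strength = 1e-3, tol = 1e-8, max_iter = 1e5,
                      feature_name = NULL, nonneg = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (!all(is.finite(X))) stop("non-finite values in X")
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  padded <- FALSE
  if (ncol(X) < 2L) { X <- cbind(X, 0); padded <- TRUE }
  # a short geometric lambda path warm-starts the coordinate descent; only
  # the target lambda's coefficients are kept. Sparse storage where the
  # encoding is mostly zeros (one-hot, k-spaced pairs, property flags).
  if (mean(X != 0) < 0.4) X <- Matrix::Matrix(X, sparse = TRUE)
  lam <- l2_strength * c(1000, 100, 10, 3, 1)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lam, standardize = FALSE,
                        thresh = tol, maxit = max_iter,
                        lower.limits = if (nonneg) 0 else -Inf)
  beta <- as.numeric(fit$beta[, length(lam)])
  if (padded) beta <- beta[1L]
  structure(list(kind = "PLR", feature_name = feature_name,
                 coef = beta, intercept = as.numeric(fit$a0[length(lam)]),
                 l2_strength = l2_strength),
            class = c("dephos_plr", "dephos_base_model"))
}

#' @export
predict.dephos_plr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coef))
    stop("feature dimension mismatch: model expects ", length(object$coef),
         ", got ", ncol(newdata))
  as.numeric(stats::plogis(newdata %*% object$coef + object$intercept))
}

#' @export
print.dephos_plr <- function(x, ...) {
  cat("Ridge logistic base learner (", length(x$coef), " features, lambda = ",
      x$l2_strength, ")\n", sep = "")
  invisible(x)
}

#' Train an alternative integrator over the stacking vectors
#'
#' Conventional classifiers (support vector machine, random forest, Gaussian
#' naive Bayes) over the 22-score stacking vectors, exposed for the
#' integration-method comparison. All return probability scores in [0,1].
#'
#' @param V_matrix matrix of stacking vectors (one row per site).
#' @param y binary labels.
#' @param method `"SVM"`, `"RF"` or `"GNB"`.
#' @param seed integer seed.
#' @return object of class `dephos_integrator` with a `predict()` method.
#' @export
alt_integrator <- function(V_matrix, y, method = c("SVM", "RF", "GNB"), seed = 1L) {
  method <- match.arg(method)
  V_matrix <- as.matrix(V_matrix)
  yf <- factor(y, levels = c(0, 1))
  fit <- withr_seed(seed, switch(method,
    SVM = e1071::svm(V_matrix, yf, probability = TRUE, kernel = "radial"),
    RF  = randomForest::randomForest(V_matrix, yf),
    GNB = {
      # variance floor keeps constant features from producing degenerate
      # likelihoods
      m <- e1071::naiveBayes(V_matrix, yf)
      m$tables <- lapply(m$tables, function(tb) { tb[, 2L] <- pmax(tb[, 2L], 1e-6); tb })
      m
    }))
  structure(list(method = method, fit = fit),
            class = "dephos_integrator")
}

#' @export
predict.dephos_integrator <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- switch(object$method,
    SVM = attr(stats::predict(object$fit, newdata, probability = TRUE), "probabilities")[, "1"],
    RF  = stats::predict(object$fit, newdata, type = "prob")[, "1"],
    GNB = stats::predict(object$fit, newdata, type = "raw")[, "1"])
  as.numeric(pmin(pmax(p, 0), 1))
}
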