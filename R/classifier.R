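#' Ridge-regularized logistic classifier
#'
#' A thin, deterministic binary classifier used by the encoder-classifier
#' predictor: logistic regression with a small L2 penalty on the weights
#' (not the intercept), fitted by Newton/IRLS iterations. The ridge keeps
#' the optimum finite even on separable embedding features, and the fit is
#' fully deterministic; `seed` is recorded only so the classifier is
#' interchangeable with stochastic ones behind the same contract.
#'
#' @param features Numeric matrix, one row per example.
#' @param labels Binary labels (0/1 or logical), at least one per class.
#' @param seed Integer seed (recorded; the ridge fit is deterministic).
#' @param lambda Ridge penalty.
#' @param max_iter,tol Newton iteration cap and gradient tolerance.
#' @return An `lp_classifier` model.
#' @export
classifier_learn <- function(features, labels, seed = 1L, lambda = 1e-3,
                             max_iter = 100L, tol = 1e-10) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary (0/1).")
  if (length(unique(labels)) < 2L) {
    abort("training set must contain both classes.")
  }
  X <- cbind(1, features) # intercept first
  p <- ncol(X)
  beta <- numeric(p)
  pen <- c(0, rep(lambda, p - 1L)) # intercept unpenalized
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, labels - mu)) - pen * beta
    if (max(abs(grad)) < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(pen + 1e-12, p)
    beta <- beta + solve(H, grad)
  }
  structure(
    list(
      weights = beta[-1L],
      intercept = beta[1L],
      lambda = lambda, seed = seed, n_train = length(labels),
      iterations = it
    ),
    class = "lp_classifier"
  )
}

#' @rdname classifier_learn
#' @param model An `lp_classifier` model.
#' @return `classifier_predict()`: probabilities of the positive class,
#'   one per row of `features`, in `[0, 1]`.
#' @export
classifier_predict <- function(model, features) {
  if (!inherits(model, "lp_classifier")) abort("`model` must be an lp_classifier.")
  features <- as.matrix(features)
  eta <- drop(features %*% model$weights) + model$intercept
  1 / (1 + exp(-eta))
}

#' @export
tidy.lp_classifier <- function(x, ...) {
  tibble(
    term = c("(Intercept)", paste0("x", seq_along(x$weights))),
    estimate = c(x$intercept, x$weights)
  )
}

#' @export
glance.lp_classifier <- function(x, ...) {
  tibble(n_train = x$n_train, lambda = x$lambda, n_features = length(x$weights))
}
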