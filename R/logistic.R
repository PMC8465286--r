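#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression fitted with Newton-Raphson / IRLS.
#' The covariance matrix of the coefficients is the inverse observed Fisher
#' information (X' W X)^-1 at the MLE. Perfect separation is detected as a
#' diverging coefficient (max |coefficient| beyond `separation_bound` on
#' standardized-scale inputs) and raised as an error naming the offending
#' column.
#'
#' @param design Numeric design matrix, one column per slope term. An
#'   intercept column is prepended automatically unless `intercept = FALSE`
#'   (a column named `"(Intercept)"` is never duplicated).
#' @param y Binary 0/1 response.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum IRLS iterations.
#' @param intercept Include an intercept (default TRUE).
#' @param separation_bound Coefficient magnitude treated as divergence.
#' @return A `pclr_logit` list: `coefficients`, `covariance`,
#'   `log_likelihood`, `converged`, `iterations`, `n`, `fitted`, `gradient`.
#' @export
fit_logistic <- function(design, y, tol = 1e-8, max_iter = 100L,
                         intercept = TRUE, separation_bound = 15) {
  X <- as.matrix(design)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (intercept && !"(Intercept)" %in% colnames(X)) {
    X <- cbind("(Intercept)" = 1, X)
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(X)) stop("length of y does not match design matrix")
  if (n <= ncol(X)) stop("need more observations than coefficients")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(y)) < 2) stop("y contains a single class")
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    # Newton step on the working response
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    step <- tryCatch(solve(XtWX, score), error = function(e)
      stop("singular information matrix (collinear design?)"))
    beta <- beta + drop(step)
    if (any(abs(beta) > separation_bound)) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop("perfect or quasi-perfect separation detected (column ", worst, ")")
    }
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta)))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged) stop("IRLS did not converge in ", max_iter, " iterations")
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X, X * w)
  cov <- solve(info)
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 covariance = cov,
                 log_likelihood = sum(y * log(mu) + (1 - y) * log(1 - mu)),
                 converged = converged, iterations = it, n = n,
                 fitted = mu, gradient = drop(crossprod(X, y - mu)),
                 design_names = colnames(X)),
            class = "pclr_logit")
}

#' @export
print.pclr_logit <- function(x, ...) {
  cat("<pclr_logit> n = ", x$n, ", logLik = ", sprintf("%.3f", x$log_likelihood),
      ", ", x$iterations, " iterations\n", sep = "")
  se <- sqrt(diag(x$covariance))
  print(round(cbind(estimate = x$coefficients, se = se,
                    z = x$coefficients / se), 4))
  invisible(x)
}

#' Classify observations from a logistic fit
#'
#' Predicted class is 1 when the fitted probability meets the threshold.
#' The default threshold of 0.6 follows the source analysis.
#'
#' @param fit A `pclr_logit`.
#' @param design Design matrix on the scale of the fit (intercept added if
#'   the fit had one).
#' @param threshold Probability threshold in (0, 1); default 0.6.
#' @return Integer vector of 0/1 predictions.
#' @export
classify <- function(fit, design, threshold = 0.6) {
  stopifnot(inherits(fit, "pclr_logit"), threshold > 0, threshold < 1)
  X <- as.matrix(design)
  if ("(Intercept)" %in% fit$design_names && !"(Intercept)" %in% colnames(X)) {
    X <- cbind("(Intercept)" = 1, X)
  }
  X <- X[, fit$design_names, drop = FALSE]
  as.integer(stats::plogis(drop(X %*% fit$coefficients)) >= threshold)
}
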