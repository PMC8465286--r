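#' Back-transform component-space coefficients to variable space
#'
#' Maps the slope vector a of a logistic fit on r component scores back to
#' per-variable coefficients lambda = L a (L the p x r rotated loadings) with
#' delta-method covariance Cov(lambda) = L Cov(a) L'. Wald statistics are
#' mu_i = lambda_i / sqrt(var(lambda_i)) with two-sided normal p-values
#' (the source prints the statistic as lambda/var(lambda), treated here as a
#' typo for the conventional Wald z). When the scores were rescaled to unit
#' variance, the slopes and their covariance are first mapped back to the
#' raw-score scale, so lambda always refers to the standardized predictors.
#'
#' @param fit A `pclr_logit` on r component scores (intercept plus r slopes).
#' @param model A `pclr_pca` with matching retained components.
#' @param scores The `pclr_scores` used for the fit (optional; supplies the
#'   score scaling and, for regression-method scores, the weight matrix that
#'   keeps the back-transformation consistent with the scores).
#' @return A `pclr_backtransform` list: `lambda`, `lambda_var`, `lambda_cov`,
#'   `wald_z`, `p_values`, `names`.
#' @export
back_transform <- function(fit, model, scores = NULL) {
  stopifnot(inherits(fit, "pclr_logit"), inherits(model, "pclr_pca"))
  slope_idx <- setdiff(fit$design_names, "(Intercept)")
  a <- fit$coefficients[slope_idx]
  Va <- fit$covariance[slope_idx, slope_idx, drop = FALSE]
  M <- if (!is.null(scores)) scores$weights else model$rotated_loadings
  if (length(a) != ncol(M)) {
    stop("fit has ", length(a), " slopes but the model retains ", ncol(M),
         " components")
  }
  if (!is.null(scores) && scores$standardized) {
    a <- a / scores$score_sds
    Va <- Va / outer(scores$score_sds, scores$score_sds)
  }
  lambda <- drop(M %*% a)
  Vl <- M %*% Va %*% t(M)
  v <- pmax(diag(Vl), 0)
  z <- ifelse(v > 0, lambda / sqrt(v), NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  names(lambda) <- names(v) <- names(z) <- names(p) <- model$names
  structure(list(lambda = lambda, lambda_var = v, lambda_cov = Vl,
                 wald_z = z, p_values = p, names = model$names),
            class = "pclr_backtransform")
}

#' @export
print.pclr_backtransform <- function(x, ...) {
  print(round(cbind(lambda = x$lambda, se = sqrt(x$lambda_var),
                    z = x$wald_z, p = x$p_values), 4))
  invisible(x)
}

#' Significance stars in the published convention
#'
#' `"*"` for p < 0.001, `"**"` for p < 0.05, otherwise `""` (note the
#' inverted convention of the source tables: one star is the stronger claim).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "*", ifelse(p < 0.05, "**", "")))
}
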