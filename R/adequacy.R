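#' Sampling-adequacy diagnostics (KMO and Bartlett)
#'
#' Kaiser-Meyer-Olkin measure of sampling adequacy, overall and per variable,
#' and Bartlett's test of sphericity. KMO compares raw correlations with the
#' anti-image partial correlations q_ij = -S_ij / sqrt(S_ii S_jj) (S = R^-1):
#' KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2) over i != j. Bartlett's
#' statistic is chi^2 = -(n - 1 - (2p + 5)/6) * ln det(R) on p(p-1)/2 degrees
#' of freedom, testing R = I.
#'
#' @param R Correlation matrix (or a `pclr_screen`).
#' @param n Number of observations behind `R`.
#' @return A `pclr_adequacy` list: `kmo_overall`, `kmo_per_variable`,
#'   `bartlett_chi2`, `bartlett_df`, `bartlett_p`.
#' @export
adequacy <- function(R, n) {
  if (inherits(R, "pclr_screen")) { n <- R$n; R <- R$R }
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(isTRUE(all.equal(R, t(R), tolerance = 1e-8)), n > 1)
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix is singular (det <= 0)")
  S <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix not invertible; KMO undefined"))
  d <- 1 / sqrt(diag(S))
  Q <- -S * outer(d, d)      # anti-image partial correlations, off-diagonal
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  kmo <- sum(r2) / (sum(r2) + sum(q2))
  kmo_i <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(kmo_i) <- colnames(R)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  structure(list(kmo_overall = kmo, kmo_per_variable = kmo_i,
                 bartlett_chi2 = chi2, bartlett_df = df,
                 bartlett_p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "pclr_adequacy")
}

#' @export
print.pclr_adequacy <- function(x, ...) {
  cat(sprintf("KMO overall: %.3f\nBartlett chi2 = %.2f on %d df, p = %.3g\n",
              x$kmo_overall, x$bartlett_chi2, x$bartlett_df, x$bartlett_p))
  invisible(x)
}
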