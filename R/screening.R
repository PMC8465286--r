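#' Bivariate Pearson correlation screen
#'
#' Computes the p x p Pearson correlation matrix among predictors together
#' with two-sided p-values from the exact t transform
#' t = r * sqrt((n - 2) / (1 - r^2)), plus each predictor's correlation with
#' the binary outcome. Plain Pearson on the ordinal codes is used throughout,
#' matching common practice for this kind of screen (a documented
#' approximation; no polychoric correction).
#'
#' @param std A `pclr_standardized` (correlations are affine-invariant, so a
#'   `pclr_coded` is accepted too).
#' @param y Binary outcome vector; taken from `std` when omitted.
#' @return A `pclr_screen` list: `names`, `R`, `P` (diagonal `NA`),
#'   `outcome_r`, `outcome_p`, `n`, `eliminated` (empty until
#'   [screen_predictors()] runs).
#' @export
pearson_matrix <- function(std, y = NULL) {
  X <- if (inherits(std, "pclr_standardized")) std$Xstar
       else if (inherits(std, "pclr_coded")) std$X
       else as.matrix(std)
  if (is.null(y) && is.list(std)) y <- std$y
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations for correlation p-values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  P <- r_to_p(R, n)
  diag(P) <- NA_real_
  out_r <- out_p <- NULL
  if (!is.null(y)) {
    out_r <- as.vector(stats::cor(X, y))
    out_p <- r_to_p(out_r, n)
    names(out_r) <- names(out_p) <- colnames(X)
  }
  structure(list(names = colnames(X), R = R, P = P,
                 outcome_r = out_r, outcome_p = out_p, n = n,
                 eliminated = data.frame(acronym = character(),
                                         reason = character(),
                                         stringsAsFactors = FALSE),
                 retained = colnames(X)),
            class = "pclr_screen")
}

# two-sided p for a Pearson r at sample size n via the exact t transform
r_to_p <- function(r, n) {
  r2 <- pmin(abs(r), 1)
  t <- r2 * sqrt((n - 2) / pmax(1 - r2^2, .Machine$double.eps))
  p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p
}

#' @export
print.pclr_screen <- function(x, ...) {
  cat("<pclr_screen> ", length(x$names), " predictors, n = ", x$n, "\n", sep = "")
  if (nrow(x$eliminated)) {
    cat("eliminated:", paste(x$eliminated$acronym, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Eliminate weakly connected predictors
#'
#' A predictor is eliminated when its number of significant (p < `alpha`)
#' pairwise correlations with the other predictors falls below `min_links`
#' ("not significant to connect other variables"). The retained set is what
#' the component extraction consumes.
#'
#' @param screen A `pclr_screen` from [pearson_matrix()].
#' @param alpha Significance level, in (0, 1).
#' @param min_links Minimum count of significant links to survive; default
#'   half the other predictors, `ceiling((p - 1) / 2)`.
#' @param bonferroni Apply a Bonferroni correction over the p(p-1)/2 pairs
#'   before thresholding (off by default; the source analysis used none).
#' @return The screen with `eliminated` and `retained` filled in.
#' @export
screen_predictors <- function(screen, alpha = 0.05, min_links = NULL,
                              bonferroni = FALSE) {
  stopifnot(inherits(screen, "pclr_screen"), alpha > 0, alpha < 1)
  p <- length(screen$names)
  if (is.null(min_links)) min_links <- ceiling((p - 1) / 2)
  a <- if (bonferroni) alpha / (p * (p - 1) / 2) else alpha
  sig <- screen$P < a
  diag(sig) <- FALSE
  links <- rowSums(sig, na.rm = TRUE)
  out <- links < min_links
  if (all(out)) stop("all predictors eliminated at alpha = ", alpha)
  screen$eliminated <- data.frame(
    acronym = screen$names[out],
    reason = sprintf("only %d of %d inter-predictor correlations significant at p < %g (min_links = %d)",
                     links[out], p - 1L, a, min_links),
    stringsAsFactors = FALSE)
  screen$retained <- screen$names[!out]
  screen$links <- links
  screen
}

#' Outcome-association screen
#'
#' Flags predictors whose correlation with the outcome is not significant at
#' `alpha` (two-sided).
#'
#' @param screen A `pclr_screen` with outcome correlations.
#' @param alpha Significance level.
#' @return Data frame with `acronym`, `r`, `p`, `pass`.
#' @export
outcome_screen <- function(screen, alpha = 0.05) {
  stopifnot(inherits(screen, "pclr_screen"))
  if (is.null(screen$outcome_p)) {
    return(data.frame(acronym = character(), r = numeric(), p = numeric(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  data.frame(acronym = screen$names, r = unname(screen$outcome_r),
             p = unname(screen$outcome_p),
             pass = unname(screen$outcome_p) < alpha,
             stringsAsFactors = FALSE)
}

#' Render the correlation screen in the published lower-triangular layout
#'
#' "r/p" cell strings in a lower-triangular matrix, with a final outcome row.
#'
#' @param screen A `pclr_screen`.
#' @param digits Rounding for r and p.
#' @return Character matrix suitable for [utils::write.table()].
#' @export
format_correlation_table <- function(screen, digits = 2) {
  p <- length(screen$names)
  out <- matrix("", p + 1, p, dimnames = list(c(screen$names, "HS"), screen$names))
  fmt <- function(r, pv) sprintf("%s/%s", format(round(r, digits)),
                                 format(round(pv, digits)))
  for (i in seq_len(p)) for (j in seq_len(i)) {
    out[i, j] <- if (i == j) "1/0.00" else fmt(screen$R[i, j], screen$P[i, j])
  }
  if (!is.null(screen$outcome_r)) {
    out[p + 1, ] <- fmt(screen$outcome_r, screen$outcome_p)
  }
  out
}
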