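#' Extract principal components of the predictor correlation matrix
#'
#' Eigendecomposition of the sample correlation matrix, eigenvalues in
#' descending order, unrotated loadings = eigenvector * sqrt(eigenvalue)
#' (so that L L' reproduces R when all components are kept), and retention of
#' the r components whose eigenvalue strictly exceeds `retain_threshold`
#' (Kaiser rule by default). A deterministic sign convention — the
#' largest-magnitude entry of each loading column is made positive — removes
#' the eigenvector sign ambiguity.
#'
#' @param x A `pclr_standardized`, a `pclr_screen`, or a correlation matrix.
#' @param retain_threshold Eigenvalue retention threshold (strict `>`).
#' @return A `pclr_pca` list: `eigenvalues`, `unrotated_loadings` (p x p),
#'   `r`, `rotation` (identity until [varimax_rotate()]), `rotated_loadings`
#'   (p x r), `communalities`, `variance_explained_cum`, `R`, `names`.
#' @export
extract_components <- function(x, retain_threshold = 1) {
  if (inherits(x, "pclr_standardized")) {
    R <- stats::cor(x$Xstar)
  } else if (inherits(x, "pclr_screen")) {
    R <- x$R
  } else {
    R <- as.matrix(x)
  }
  if (any(!is.finite(R))) stop("non-finite entries in correlation matrix")
  p <- ncol(R)
  if (p < 2) stop("need at least two predictors")
  e <- eigen(R, symmetric = TRUE)
  ev <- e$values
  V <- e$vectors
  sgn <- apply(V, 2, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  V <- sweep(V, 2, sgn, "*")
  L <- V %*% diag(sqrt(pmax(ev, 0)), p)
  dimnames(L) <- list(colnames(R), paste0("PC", seq_len(p)))
  r <- sum(ev > retain_threshold)
  if (r == 0) {
    warning("no eigenvalue exceeds the retention threshold; retaining 1 component")
    r <- 1L
  }
  near <- sum(abs(ev - retain_threshold) < 0.05)
  if (near >= p / 2) {
    warning("eigenvalues cluster at the retention threshold; ",
            "retention is unstable (near-identity correlation matrix)")
  }
  Lr <- L[, seq_len(r), drop = FALSE]
  structure(list(eigenvalues = ev, unrotated_loadings = L, r = r,
                 rotation = diag(r), rotated_loadings = Lr,
                 communalities = stats::setNames(rowSums(Lr^2), colnames(R)),
                 variance_explained_cum = sum(ev[seq_len(r)]) / p,
                 iterations_used = 0L, R = R, names = colnames(R)),
            class = "pclr_pca")
}

#' @export
print.pclr_pca <- function(x, ...) {
  cat("<pclr_pca> p = ", length(x$eigenvalues), ", retained r = ", x$r,
      sprintf(" (%.1f%% cumulative variance)\n", 100 * x$variance_explained_cum),
      sep = "")
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' Communalities of a component model
#'
#' Row sums of squared retained loadings: the variance share of each variable
#' explained by the common components. Variables below `cutoff` are flagged
#' with a warning (never excluded automatically; set `enforce = TRUE` to get
#' the names of the offenders as an attribute for exclusion upstream).
#'
#' @param model A `pclr_pca`.
#' @param cutoff Flagging threshold (default 0.7).
#' @param enforce Attach `attr(, "below_cutoff")` with the offending names.
#' @return Named numeric vector of communalities, each in \[0, 1\].
#' @export
communalities <- function(model, cutoff = 0.7, enforce = FALSE) {
  stopifnot(inherits(model, "pclr_pca"))
  h2 <- rowSums(model$rotated_loadings^2)
  names(h2) <- model$names
  low <- names(h2)[h2 < cutoff]
  if (length(low)) {
    warning("communalities below ", cutoff, ": ", paste(low, collapse = ", "))
  }
  if (enforce) attr(h2, "below_cutoff") <- low
  h2
}

#' Assign variables to factors by loading magnitude
#'
#' Lists, per retained factor, the variables whose absolute rotated loading
#' meets `cutoff`. With `cutoff = 0` every variable is assigned to its
#' maximum-|loading| factor; with an impossible cutoff all factors come back
#' empty with a warning.
#'
#' @param model A `pclr_pca` (rotated).
#' @param cutoff Absolute-loading threshold (default 0.7).
#' @return Named list (one element per factor) of character vectors.
#' @export
interpret_loadings <- function(model, cutoff = 0.7) {
  stopifnot(inherits(model, "pclr_pca"))
  L <- model$rotated_loadings
  out <- vector("list", ncol(L))
  names(out) <- colnames(L)
  if (cutoff <= 0) {
    best <- apply(abs(L), 1, which.max)
    for (j in seq_len(ncol(L))) out[[j]] <- rownames(L)[best == j]
  } else {
    for (j in seq_len(ncol(L))) out[[j]] <- rownames(L)[abs(L[, j]) >= cutoff]
  }
  if (all(lengths(out) == 0)) {
    warning("no loading reaches the cutoff of ", cutoff)
  }
  out
}

#' Component scores
#'
#' Scores each respondent on the retained components. The default
#' (`method = "loading"`) applies the loading weights directly,
#' Z = X* L, the literal score definition of the component-score equation;
#' under it the back-transformation lambda = L a is exactly the
#' variable-space coefficient vector induced by the component fit, for any
#' number of retained components and any orthogonal rotation.
#' `method = "regression"` uses regression-method weights W = R^-1 L, whose
#' scores are exactly uncorrelated with unit variance even after rotation
#' (but which break the loading-based back-transformation identity; the
#' score object carries its weights so [back_transform()] stays consistent).
#'
#' @param std A `pclr_standardized` whose columns match the model.
#' @param model A `pclr_pca`.
#' @param method `"loading"` (default) or `"regression"`.
#' @param standardized Scale score columns to unit sample variance
#'   (default TRUE); the scaling factors are recorded for back-transformation.
#' @return A `pclr_scores` list: `Z` (n x r), `weights` (p x r),
#'   `score_sds` (scaling divisors; 1 when `standardized = FALSE`),
#'   `standardized`, `method`.
#' @export
component_scores <- function(std, model, method = c("loading", "regression"),
                             standardized = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(std, "pclr_standardized"), inherits(model, "pclr_pca"))
  if (ncol(std$Xstar) != length(model$names)) {
    stop("column count of standardized matrix does not match the model")
  }
  L <- model$rotated_loadings
  W <- switch(method, loading = L, regression = solve(model$R, L))
  Z <- std$Xstar %*% W
  if (standardized) {
    s <- apply(Z, 2, stats::sd)
    Z <- sweep(Z, 2, s, "/")
  } else {
    s <- rep(1, ncol(Z))
  }
  colnames(Z) <- colnames(L)
  names(s) <- colnames(L)
  structure(list(Z = Z, weights = W, score_sds = s,
                 standardized = standardized, method = method),
            class = "pclr_scores")
}
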