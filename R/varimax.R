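#' Varimax criterion of a loading matrix
#'
#' The raw varimax criterion: the sum over columns of the variance of squared
#' loadings, sum_j [ mean(l_j^4) - mean(l_j^2)^2 ]. Larger values mean simpler
#' structure. Used internally by [varimax_rotate()] and exposed for the
#' exhaustive-search test oracle.
#'
#' @param L p x r loading matrix.
#' @return A single number.
#' @export
varimax_criterion <- function(L) {
  L2 <- L^2
  sum(colMeans(L2^2) - colMeans(L2)^2)
}

# optimal planar rotation of columns (j, k), classic quartic solution
varimax_pair_angle <- function(x, y) {
  p <- length(x)
  u <- x^2 - y^2
  v <- 2 * x * y
  A <- sum(u); B <- sum(v)
  C <- sum(u^2 - v^2); D <- sum(2 * u * v)
  num <- D - 2 * A * B / p
  den <- C - (A^2 - B^2) / p
  atan2(num, den) / 4
}

#' Varimax rotation with Kaiser normalization
#'
#' Rotates the retained loading columns of a component model to (approximate)
#' simple structure by maximizing the varimax criterion over orthogonal
#' rotations, using the classic pairwise (Jacobi-style) planar-rotation
#' algorithm. With `kaiser_normalize = TRUE` each row is scaled to unit
#' communality before rotation and rescaled after, so high- and
#' low-communality variables carry equal weight. Communalities are invariant
#' under the rotation; columns are re-sorted by explained variance and the
#' deterministic sign convention (largest-magnitude entry per column made
#' positive) is re-applied.
#'
#' @param model A `pclr_pca` from [extract_components()], or a bare loading
#'   matrix (a rotated copy of the matrix is then returned).
#' @param kaiser_normalize Row-normalize during rotation (default TRUE).
#' @param tol Convergence tolerance on the relative criterion change per
#'   sweep.
#' @param max_iter Maximum number of sweeps; exceeding it is an error
#'   carrying the last criterion value.
#' @return The model with `rotated_loadings`, `rotation` (r x r orthogonal),
#'   `iterations_used` and `criterion_trace` filled in; or the rotated matrix
#'   when a matrix was supplied.
#' @export
varimax_rotate <- function(model, kaiser_normalize = TRUE, tol = 1e-10,
                           max_iter = 1000L) {
  bare <- !inherits(model, "pclr_pca")
  L <- if (bare) as.matrix(model) else
    model$unrotated_loadings[, seq_len(model$r), drop = FALSE]
  p <- nrow(L); r <- ncol(L)
  if (r < 1) stop("no retained components to rotate")
  h <- sqrt(rowSums(L^2))
  if (kaiser_normalize) {
    scale <- ifelse(h > 0, h, 1)
    B <- L / scale
  } else B <- L
  Tmat <- diag(r)
  trace <- varimax_criterion(B)
  iter <- 0L
  if (r > 1) {
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop(sprintf("varimax did not converge in %d sweeps (criterion %.10g)",
                     max_iter, trace[length(trace)]))
      }
      for (j in seq_len(r - 1)) for (k in seq((j + 1), r)) {
        phi <- varimax_pair_angle(B[, j], B[, k])
        if (abs(phi) < 1e-14) next
        G <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
        B[, c(j, k)] <- B[, c(j, k)] %*% G
        Tmat[, c(j, k)] <- Tmat[, c(j, k)] %*% G
      }
      crit <- varimax_criterion(B)
      trace <- c(trace, crit)
      if (crit - trace[length(trace) - 1L] < tol * max(crit, 1e-12)) break
    }
  }
  Lrot <- if (kaiser_normalize) B * scale else B
  # sort columns by explained variance, re-apply sign convention
  ord <- order(colSums(Lrot^2), decreasing = TRUE)
  Lrot <- Lrot[, ord, drop = FALSE]
  Tmat <- Tmat[, ord, drop = FALSE]
  sgn <- apply(Lrot, 2, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  Lrot <- sweep(Lrot, 2, sgn, "*")
  Tmat <- sweep(Tmat, 2, sgn, "*")
  colnames(Lrot) <- paste0("PC", seq_len(r))
  if (bare) {
    attr(Lrot, "rotation") <- Tmat
    attr(Lrot, "criterion_trace") <- trace
    return(Lrot)
  }
  model$rotated_loadings <- Lrot
  model$rotation <- Tmat
  model$iterations_used <- iter
  model$criterion_trace <- trace
  model$communalities <- rowSums(Lrot^2)
  names(model$communalities) <- rownames(Lrot)
  model
}
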