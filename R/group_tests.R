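#' Independent-samples t-test
#'
#' Two-sample t-test on a score vector split by a binary grouping, in both
#' the pooled-variance ("equal variances assumed", df = n1 + n2 - 2) and
#' Welch ("not assumed", Welch-Satterthwaite df) conventions, with a
#' confidence interval on the mean difference (group 1 minus group 2, groups
#' in sorted label order).
#'
#' @param scores Numeric vector.
#' @param groups Vector with exactly two distinct labels.
#' @param equal_var Pooled-variance (TRUE) or Welch (FALSE).
#' @param alpha Significance level for the interval (CI level 1 - alpha).
#' @return A `pclr_ttest` list: `t`, `df`, `p`, `ci_low`, `ci_high`,
#'   `mean_diff`, `equal_variances_assumed`.
#' @export
independent_t_test <- function(scores, groups, equal_var = TRUE, alpha = 0.05) {
  g <- sort(unique(groups))
  if (length(g) != 2) stop("need exactly two groups")
  x <- scores[groups == g[1]]
  y <- scores[groups == g[2]]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two members")
  v1 <- stats::var(x); v2 <- stats::var(y)
  d <- mean(x) - mean(y)
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    t <- 0; p <- 1
  } else {
    t <- d / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  q <- stats::qt(1 - alpha / 2, df)
  structure(list(t = t, df = df, p = p, mean_diff = d,
                 ci_low = d - q * se, ci_high = d + q * se,
                 equal_variances_assumed = equal_var),
            class = "pclr_ttest")
}

#' One-way ANOVA F-test with linear-term decomposition
#'
#' Standard one-way ANOVA F = MS_between / MS_within over the supplied
#' groups, plus a decomposition of the between-group sum of squares into a
#' weighted linear-trend contrast on the groups' ordinal codes (group-size
#' weighted, the SPSS "Weighted" row) and the deviation remainder. With two
#' groups the deviation term has zero degrees of freedom and is reported as
#' `NA`.
#'
#' @param scores Numeric vector.
#' @param groups Ordered categorical labels (coerced to numeric codes for the
#'   trend contrast; factor levels are coded 1..k in level order).
#' @return A `pclr_ftest` list: `F`, `df_between`, `df_within`, `p`,
#'   `ss_between`, `ss_within`, `ms_within` and `linear_term`, a data frame
#'   with Combined / Weighted / Deviation rows (`df`, `ss`, `mean_square`,
#'   `F`, `p`).
#' @export
oneway_f_test <- function(scores, groups) {
  f <- factor(groups)
  k <- nlevels(f)
  if (k < 2) stop("need at least two groups")
  ns <- tabulate(f)
  if (any(ns == 0)) stop("empty group")
  means <- tapply(scores, f, mean)
  grand <- mean(scores)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((scores - means[f])^2)
  df_b <- k - 1
  df_w <- length(scores) - k
  ms_w <- ss_w / df_w
  Fval <- if (ms_w == 0) 0 else (ss_b / df_b) / ms_w
  p <- stats::pf(Fval, df_b, df_w, lower.tail = FALSE)
  # weighted linear contrast on ordinal group codes
  codes <- suppressWarnings(as.numeric(as.character(f)))
  if (any(is.na(codes))) codes <- as.numeric(f)
  xg <- tapply(codes, f, mean)
  xbar <- sum(ns * xg) / sum(ns)
  cg <- xg - xbar
  denom <- sum(ns * cg^2)
  ss_lin <- if (denom > 0) sum(ns * cg * means)^2 / denom else 0
  ss_dev <- max(ss_b - ss_lin, 0)
  df_dev <- df_b - 1
  lt <- data.frame(
    term = c("Combined", "Weighted", "Deviation"),
    df = c(df_b, 1, df_dev),
    ss = c(ss_b, ss_lin, ss_dev),
    stringsAsFactors = FALSE)
  lt$mean_square <- ifelse(lt$df > 0, lt$ss / lt$df, NA_real_)
  lt$F <- ifelse(lt$df > 0 & ms_w > 0, lt$mean_square / ms_w, NA_real_)
  lt$p <- ifelse(is.na(lt$F), NA_real_,
                 stats::pf(lt$F, lt$df, df_w, lower.tail = FALSE))
  structure(list(F = Fval, df_between = df_b, df_within = df_w, p = p,
                 ss_between = ss_b, ss_within = ss_w, ms_within = ms_w,
                 linear_term = lt),
            class = "pclr_ftest")
}

#' Validate factor scores against the outcome grouping
#'
#' For each retained component, runs the independent-samples t-test in both
#' variance conventions and the one-way ANOVA F-test against the binary
#' health-status grouping (or any categorical grouping supplied).
#'
#' @param scores A `pclr_scores` (or bare n x r matrix).
#' @param y Grouping vector (binary outcome for the headline validation).
#' @param alpha Significance level.
#' @return A `pclr_validation` list with a `table` data frame (one row per
#'   component and convention) and the raw `t_tests` / `f_tests` lists.
#' @export
validate_factors <- function(scores, y, alpha = 0.05) {
  Z <- if (inherits(scores, "pclr_scores")) scores$Z else as.matrix(scores)
  if (nrow(Z) != length(y)) stop("scores and grouping are not conformable")
  if (length(unique(y)) < 2) stop("grouping has a single class")
  t_tests <- list(); f_tests <- list(); rows <- list()
  for (j in seq_len(ncol(Z))) {
    nm <- colnames(Z)[j] %||% paste0("PC", j)
    tt_eq <- independent_t_test(Z[, j], y, equal_var = TRUE, alpha = alpha)
    tt_w <- independent_t_test(Z[, j], y, equal_var = FALSE, alpha = alpha)
    ft <- oneway_f_test(Z[, j], y)
    t_tests[[nm]] <- list(assumed = tt_eq, not_assumed = tt_w)
    f_tests[[nm]] <- ft
    rows[[nm]] <- data.frame(
      component = nm,
      equal_variances = c("assumed", "not assumed"),
      t = c(tt_eq$t, tt_w$t), df = c(tt_eq$df, tt_w$df),
      p = c(tt_eq$p, tt_w$p),
      ci_low = c(tt_eq$ci_low, tt_w$ci_low),
      ci_high = c(tt_eq$ci_high, tt_w$ci_high),
      F = ft$F, F_p = ft$p,
      pass = c(tt_eq$p < alpha, tt_w$p < alpha) & ft$p < alpha,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 t_tests = t_tests, f_tests = f_tests, alpha = alpha),
            class = "pclr_validation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
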