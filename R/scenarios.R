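#' Expand coded variables into referent-contrast dummies
#'
#' One indicator column per non-referent level of each requested variable,
#' named `ACR.code`, with the codebook referent as the omitted category.
#'
#' @param coded A `pclr_coded`.
#' @param variables Acronyms to expand (default all predictors present).
#' @return Numeric matrix of 0/1 dummies.
#' @export
dummy_expand <- function(coded, variables = NULL) {
  stopifnot(inherits(coded, "pclr_coded"))
  if (is.null(variables)) variables <- coded$predictor_names
  cols <- list()
  for (acr in variables) {
    ref <- codebook_referent(coded$codebook, acr)
    for (code in setdiff(codebook_levels(coded$codebook, acr), ref)) {
      cols[[paste(acr, code, sep = ".")]] <-
        as.numeric(coded$X[, acr] == code)
    }
  }
  do.call(cbind, cols)
}

scenario_names <- c("unadjusted_LA", "adjusted_LA",
                    "pca_unadjusted", "pca_adjusted")

or_row <- function(stratum, scenario, acr, code, label, n, pct,
                   or = NA_real_, lo = NA_real_, hi = NA_real_,
                   p = NA_real_, referent = FALSE, degenerate = FALSE) {
  data.frame(stratum = stratum, scenario = scenario, acronym = acr,
             code = code, label = label, n = n, percent = pct,
             or = or, ci_low = lo, ci_high = hi, p = p,
             stars = significance_stars(p), referent = referent,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

level_meta <- function(coded, acr) {
  lv <- coded$codebook$variables[[acr]]$levels
  cnt <- vapply(lv$code, function(cd) sum(coded$X[, acr] == cd), numeric(1))
  data.frame(code = lv$code, label = lv$label, n = cnt,
             percent = 100 * cnt / nrow(coded$X), stringsAsFactors = FALSE)
}

#' Odds-ratio rows for one variable
#'
#' Builds the per-level odds-ratio block of a scenario table. For a direct
#' logistic fit on dummies, the odds ratio of level k is exp(coef) of its
#' dummy with a Wald confidence interval. For a back-transformed component
#' fit, the level-k odds ratio of variable i is
#' exp(lambda_i * (code_k - code_ref) / sd_i) — the standardized-contrast
#' rule, which collapses to the direct odds ratio under full retention — with
#' the interval from var(lambda_i) scaled by the same contrast.
#'
#' @param x A `pclr_logit` on dummies, or a `pclr_backtransform`.
#' @param coded The `pclr_coded` stratum the fit was run on (supplies level
#'   counts and the codebook).
#' @param acr Variable acronym.
#' @param sds Named vector of standardization sds (required for the
#'   back-transformed case).
#' @param conf Confidence level (default 0.95).
#' @param stratum,scenario Labels carried into the rows.
#' @return Data frame of rows, referent first with OR fixed at 1.
#' @export
odds_ratio_table <- function(x, coded, acr, sds = NULL, conf = 0.95,
                             stratum = "all", scenario = "adjusted_LA") {
  ref <- codebook_referent(coded$codebook, acr)
  if (is.null(ref)) stop("no referent declared for ", acr)
  meta <- level_meta(coded, acr)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    cd <- meta$code[i]
    if (cd == ref) {
      rows[[i]] <- or_row(stratum, scenario, acr, cd, meta$label[i],
                          meta$n[i], meta$percent[i], or = 1,
                          referent = TRUE)
    } else if (inherits(x, "pclr_backtransform")) {
      if (is.null(sds)) stop("sds required for back-transformed odds ratios")
      contrast <- (cd - ref) / sds[[acr]]
      est <- x$lambda[[acr]] * contrast
      se <- sqrt(x$lambda_var[[acr]]) * abs(contrast)
      rows[[i]] <- or_row(stratum, scenario, acr, cd, meta$label[i],
                          meta$n[i], meta$percent[i],
                          or = exp(est), lo = exp(est - zq * se),
                          hi = exp(est + zq * se), p = x$p_values[[acr]])
    } else {
      nm <- paste(acr, cd, sep = ".")
      est <- x$coefficients[[nm]]
      se <- sqrt(x$covariance[nm, nm])
      z <- est / se
      rows[[i]] <- or_row(stratum, scenario, acr, cd, meta$label[i],
                          meta$n[i], meta$percent[i],
                          or = exp(est), lo = exp(est - zq * se),
                          hi = exp(est + zq * se),
                          p = 2 * stats::pnorm(-abs(z)))
    }
  }
  do.call(rbind, rows)
}

degenerate_block <- function(coded, acr, stratum, scenario) {
  meta <- level_meta(coded, acr)
  ref <- codebook_referent(coded$codebook, acr)
  do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    or_row(stratum, scenario, acr, meta$code[i], meta$label[i], meta$n[i],
           meta$percent[i], or = if (meta$code[i] == ref) 1 else NA_real_,
           referent = meta$code[i] == ref,
           degenerate = meta$code[i] != ref)
  }))
}

#' Run one model scenario on one stratum
#'
#' The four scenarios of the headline comparison:
#' \describe{
#'   \item{unadjusted_LA}{one logistic fit per variable alone, on its
#'     referent-contrast dummies.}
#'   \item{adjusted_LA}{one logistic fit on all retained variables' dummies
#'     simultaneously.}
#'   \item{pca_unadjusted}{one logistic fit per retained component score
#'     alone; each variable is reported through the back-transformation of
#'     the component it loads highest on.}
#'   \item{pca_adjusted}{one logistic fit on all r component scores, reported
#'     through the full back-transformation.}
#' }
#' Degenerate fits (perfect separation, non-convergence) downgrade the
#' affected variable block to flagged rows rather than failing the scenario.
#'
#' @param coded A single-stratum `pclr_coded` (see [subset_stratum()]).
#' @param std Matching `pclr_standardized`; computed when `NULL`.
#' @param model A `pclr_pca` (required for the PCA scenarios).
#' @param scenario One of the four scenario names.
#' @param variables Variables to report (default: the model's variables for
#'   PCA scenarios, all predictors otherwise).
#' @param conf Confidence level for intervals.
#' @param score_method Passed to [component_scores()].
#' @return A `pclr_scenario` data frame of odds-ratio rows with a
#'   `warnings` attribute listing degenerate blocks.
#' @export
run_scenario <- function(coded, std = NULL, model = NULL,
                         scenario = c("pca_adjusted", "pca_unadjusted",
                                      "adjusted_LA", "unadjusted_LA"),
                         variables = NULL, conf = 0.95,
                         score_method = "loading") {
  scenario <- match.arg(scenario)
  stopifnot(inherits(coded, "pclr_coded"))
  stratum <- as.character(unique(coded$stratum))
  if (length(stratum) != 1) stratum <- "pooled"
  if (length(unique(coded$y)) < 2) {
    stop("outcome has a single class in stratum ", stratum)
  }
  notes <- character()
  if (startsWith(scenario, "pca")) {
    if (is.null(model)) stop("PCA scenarios need a fitted component model")
    if (is.null(variables)) variables <- model$names
    if (is.null(std)) {
      sub <- coded; sub$X <- coded$X[, model$names, drop = FALSE]
      sub$predictor_names <- model$names
      std <- standardize(sub)
    }
    sc <- component_scores(std, model, method = score_method)
    assign_f <- apply(abs(model$rotated_loadings), 1, which.max)
    names(assign_f) <- model$names
    rows <- list()
    if (scenario == "pca_adjusted") {
      bt <- tryCatch(back_transform(
        fit_logistic(sc$Z, coded$y), model, sc), error = function(e) e)
      for (acr in variables) {
        if (inherits(bt, "error")) {
          notes <- c(notes, sprintf("%s/%s/%s: %s", stratum, scenario, acr,
                                    conditionMessage(bt)))
          rows[[acr]] <- degenerate_block(coded, acr, stratum, scenario)
        } else {
          rows[[acr]] <- odds_ratio_table(bt, coded, acr, std$column_sds,
                                          conf, stratum, scenario)
        }
      }
    } else {
      bts <- lapply(seq_len(model$r), function(j) {
        sub_model <- model
        sub_model$rotated_loadings <- model$rotated_loadings[, j, drop = FALSE]
        sub_sc <- sc
        sub_sc$Z <- sc$Z[, j, drop = FALSE]
        sub_sc$weights <- sc$weights[, j, drop = FALSE]
        sub_sc$score_sds <- sc$score_sds[j]
        tryCatch(back_transform(fit_logistic(sub_sc$Z, coded$y),
                                sub_model, sub_sc), error = function(e) e)
      })
      for (acr in variables) {
        bt <- bts[[assign_f[[acr]]]]
        if (inherits(bt, "error")) {
          notes <- c(notes, sprintf("%s/%s/%s: %s", stratum, scenario, acr,
                                    conditionMessage(bt)))
          rows[[acr]] <- degenerate_block(coded, acr, stratum, scenario)
        } else {
          rows[[acr]] <- odds_ratio_table(bt, coded, acr, std$column_sds,
                                          conf, stratum, scenario)
        }
      }
    }
  } else {
    if (is.null(variables)) variables <- coded$predictor_names
    rows <- list()
    if (scenario == "adjusted_LA") {
      D <- dummy_expand(coded, variables)
      fit <- tryCatch(fit_logistic(D, coded$y), error = function(e) e)
      for (acr in variables) {
        if (inherits(fit, "error")) {
          notes <- c(notes, sprintf("%s/%s/%s: %s", stratum, scenario, acr,
                                    conditionMessage(fit)))
          rows[[acr]] <- degenerate_block(coded, acr, stratum, scenario)
        } else {
          rows[[acr]] <- odds_ratio_table(fit, coded, acr, NULL, conf,
                                          stratum, scenario)
        }
      }
    } else {
      for (acr in variables) {
        D <- dummy_expand(coded, acr)
        fit <- tryCatch(fit_logistic(D, coded$y), error = function(e) e)
        if (inherits(fit, "error")) {
          notes <- c(notes, sprintf("%s/%s/%s: %s", stratum, scenario, acr,
                                    conditionMessage(fit)))
          rows[[acr]] <- degenerate_block(coded, acr, stratum, scenario)
        } else {
          rows[[acr]] <- odds_ratio_table(fit, coded, acr, NULL, conf,
                                          stratum, scenario)
        }
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "warnings") <- notes
  class(out) <- c("pclr_scenario", class(out))
  out
}
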