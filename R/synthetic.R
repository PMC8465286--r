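#' Synthetic-cohort generator
#'
#' @section Synthetic cohorts:
#' The generator emulates the structure of the source data: three insurance
#' strata of configurable size; nine ordinal predictors driven by four
#' independent standard-normal latent factors through a 9 x 4 loading matrix
#' (ordered-probit discretization against per-stratum cutpoints fitted to the
#' published category marginals); five noise predictors (standing in for
#' SEX/RACE/EM/CVD/DT) independent of the factors and the outcome; and a
#' binary health-status outcome drawn from a logistic model on the true
#' factor scores with per-stratum intercepts calibrated to the published
#' health-status prevalences. Stratifier fields (age, income, household size,
#' insurance flags) are drawn to satisfy [classify_insurance()] exactly.
#' @name pclr-synthetic
#' @keywords internal
NULL

factor_predictors <- function() c("NRC", "LCT", "NSD", "SMC", "CS",
                                  "AS", "LDC", "ED", "MS")
noise_predictor_names <- function() c("SEX", "RACE", "EM", "CVD", "DT")
strata_names <- function() c("above_poverty", "medicaid", "medicaid_gap")

#' Default latent loading matrix of the generator
#'
#' A 9 x 4 block structure mimicking the published rotated solution without
#' copying its values: two strong loadings (0.85-0.9) per factor, one
#' moderately communal variable (NSD), cross-loadings at or below 0.25.
#' Factor 1 = health-conditions (NRC, LCT), factor 2 = education/cost
#' barriers (ED, SMC), factor 3 = age/dependent-children (AS, -LDC),
#' factor 4 = marital status/smoking (MS, CS).
#'
#' @return A 9 x 4 matrix with predictor acronym row names.
#' @export
default_true_loadings <- function() {
  m <- rbind(
    NRC = c(0.88,  0.15,  0.05,  0.05),
    LCT = c(0.90,  0.05,  0.10,  0.00),
    NSD = c(0.25,  0.40,  0.10,  0.15),
    SMC = c(0.15,  0.86,  0.00,  0.10),
    CS  = c(0.00,  0.10,  0.05,  0.87),
    AS  = c(-0.10, -0.15, 0.88, -0.05),
    LDC = c(0.05,  0.15, -0.85,  0.10),
    ED  = c(0.10,  0.85,  0.05,  0.05),
    MS  = c(0.05,  0.10,  0.00,  0.86)
  )
  colnames(m) <- paste0("F", 1:4)
  m
}

marginal_cutpoints <- function(marginals = reference_marginals()) {
  out <- list()
  for (s in strata_names()) {
    out[[s]] <- list()
    for (acr in unique(marginals$acronym)) {
      d <- marginals[marginals$acronym == acr, ]
      d <- d[order(d$code), ]
      p <- d[[s]] / 100
      out[[s]][[acr]] <- list(codes = d$code,
                              cuts = stats::qnorm(cumsum(p)[-length(p)]))
    }
  }
  out
}

#' Build a synthetic-cohort generator configuration
#'
#' Defaults state the world the package is tested in: stratum sizes in the
#' published 54,754 / 4,615 / 3,714 proportions scaled to 50,000 total;
#' discretization cutpoints matched to the published per-stratum category
#' marginals; the block loading matrix of [default_true_loadings()]; outcome
#' coefficients (0.4, -0.5, -0.6, -0.25) on the four factor scores with
#' per-stratum intercepts calibrated so the analytic health-status prevalence
#' equals the published 67.3% / 82.1% / 27.5%.
#'
#' @param n_per_stratum Named counts for `above_poverty`, `medicaid`,
#'   `medicaid_gap`.
#' @param true_loadings 9 x 4 latent loading matrix (rows in
#'   [factor_predictors()] order).
#' @param outcome_coefficients Length-4 coefficients on the factor scores.
#' @param outcome_prevalence Named per-stratum target prevalences used to
#'   calibrate intercepts (ignored when `outcome_intercepts` given).
#' @param outcome_intercepts Optional named per-stratum intercepts.
#' @param marginals Marginal table in the [reference_marginals()] layout,
#'   driving the discretization cutpoints.
#' @param seed Integer seed; every draw in [generate_cohort()] flows from it.
#' @return A `pclr_genconfig` list.
#' @export
generator_config <- function(n_per_stratum = c(above_poverty = 43400,
                                               medicaid = 3650,
                                               medicaid_gap = 2950),
                             true_loadings = default_true_loadings(),
                             outcome_coefficients = c(0.4, -0.5, -0.6, -0.25),
                             outcome_prevalence = c(above_poverty = 0.673,
                                                    medicaid = 0.821,
                                                    medicaid_gap = 0.275),
                             outcome_intercepts = NULL,
                             marginals = reference_marginals(),
                             seed = 20130101) {
  stopifnot(all(strata_names() %in% names(n_per_stratum)),
            all(n_per_stratum >= 0),
            nrow(true_loadings) == 9, ncol(true_loadings) == 4,
            length(outcome_coefficients) == 4)
  h2 <- rowSums(true_loadings^2)
  if (any(h2 > 1)) stop("latent loading rows imply communality > 1")
  cuts <- marginal_cutpoints(marginals)
  for (s in names(cuts)) for (acr in names(cuts[[s]])) {
    cc <- cuts[[s]][[acr]]$cuts
    if (length(cc) > 1 && any(diff(cc) <= 0)) {
      stop("cutpoints not strictly increasing for ", acr, " in ", s)
    }
    if (any(!is.finite(cc))) {
      stop("infeasible marginals (degenerate cutpoint) for ", acr, " in ", s)
    }
  }
  if (is.null(outcome_intercepts)) {
    outcome_intercepts <- vapply(strata_names(), function(s)
      calibrate_intercept(outcome_prevalence[[s]], outcome_coefficients),
      numeric(1))
  }
  structure(list(n_per_stratum = n_per_stratum[strata_names()],
                 true_loadings = true_loadings,
                 outcome_coefficients = outcome_coefficients,
                 outcome_intercepts = outcome_intercepts,
                 cutpoints = cuts, marginals = marginals, seed = seed),
            class = "pclr_genconfig")
}

#' Analytic outcome prevalence of the logistic factor model
#'
#' E\[plogis(b0 + b'F)\] with F ~ N(0, I4), computed as a one-dimensional
#' Gaussian integral over the linear predictor.
#'
#' @param b0 Intercept.
#' @param coefs Factor coefficients.
#' @return Implied prevalence.
#' @export
implied_prevalence <- function(b0, coefs) {
  s <- sqrt(sum(coefs^2))
  if (s == 0) return(stats::plogis(b0))
  stats::integrate(function(u) stats::plogis(b0 + s * u) * stats::dnorm(u),
                   -8, 8, rel.tol = 1e-10)$value
}

calibrate_intercept <- function(target, coefs) {
  stats::uniroot(function(b0) implied_prevalence(b0, coefs) - target,
                 c(-15, 15), tol = 1e-10)$root
}

# discretize a standard-normal latent vector into level codes
discretize <- function(z, codes, cuts) codes[findInterval(z, cuts) + 1L]

#' Generate a synthetic BRFSS-like cohort
#'
#' Draws the cohort described by a [generator_config()]: latent factors,
#' discretized factor-driven and noise predictors, logistic outcome, and
#' stratifier fields consistent with the requested stratum (so that
#' [classify_insurance()] reproduces it for every record). Fully reproducible
#' under the config seed.
#'
#' @param config A `pclr_genconfig`.
#' @param codebook Codebook used to validate the result.
#' @return A `pclr_survey` (see [validate_survey()]) with attributes
#'   `config` and `latent_factors` (the true per-respondent factor scores,
#'   rows in cohort order).
#' @export
generate_cohort <- function(config = generator_config(),
                            codebook = default_codebook()) {
  stopifnot(inherits(config, "pclr_genconfig"))
  set.seed(config$seed)
  yc <- reference_year_counts()
  fp <- factor_predictors()
  np <- noise_predictor_names()
  h2 <- rowSums(config$true_loadings^2)
  uniq_sd <- sqrt(pmax(1 - h2, 0))
  blocks <- list(); factors <- list()
  for (s in strata_names()) {
    n <- config$n_per_stratum[[s]]
    if (n == 0) next
    Fm <- matrix(stats::rnorm(n * 4), n, 4)
    lat <- Fm %*% t(config$true_loadings) +
      matrix(stats::rnorm(n * 9), n, 9) %*% diag(uniq_sd, 9)
    d <- as.data.frame(matrix(nrow = n, ncol = 0))
    for (j in seq_along(fp)) {
      ct <- config$cutpoints[[s]][[fp[j]]]
      d[[fp[j]]] <- discretize(lat[, j], ct$codes, ct$cuts)
    }
    for (acr in np) {
      ct <- config$cutpoints[[s]][[acr]]
      d[[acr]] <- discretize(stats::rnorm(n), ct$codes, ct$cuts)
    }
    eta <- config$outcome_intercepts[[s]] +
      drop(Fm %*% config$outcome_coefficients)
    d$HS <- as.integer(stats::runif(n) < stats::plogis(eta))
    # stratifier fields consistent with the stratum
    age_lo <- c(18, 26, 45, 56)[d$AS]
    age_hi <- c(25, 44, 55, if (s == "medicaid_gap") 64 else 90)[d$AS]
    d$age_years <- age_lo + floor(stats::runif(n) * (age_hi - age_lo + 1))
    d$household_size <- sample(1:4, n, replace = TRUE,
                               prob = c(0.30, 0.35, 0.20, 0.15))
    thr <- 35000 + 12000 * (d$household_size - 1)
    d$annual_income_usd <- switch(
      s,
      above_poverty = thr + stats::runif(n, 5000, 90000),
      medicaid = stats::runif(n, 0, 18000),
      medicaid_gap = stats::runif(n, 2000, thr - 1))
    d$has_private_insurance <- s == "above_poverty"
    d$has_medicaid <- s == "medicaid"
    wt <- yc[[s]]
    d$year <- sample(yc$year, n, replace = TRUE, prob = wt / sum(wt))
    d$respondent_id <- sprintf("%s-%06d", substr(s, 1, 2), seq_len(n))
    blocks[[s]] <- d
    factors[[s]] <- Fm
  }
  if (!length(blocks)) {
    empty <- validate_survey(
      cbind(data.frame(respondent_id = character(), age_years = integer(),
                       household_size = integer(), annual_income_usd = numeric(),
                       has_private_insurance = logical(), has_medicaid = logical(),
                       year = integer()),
            stats::setNames(as.data.frame(matrix(integer(), 0, 15)),
                            names(codebook$variables))),
      codebook)
    attr(empty, "config") <- config
    return(empty)
  }
  df <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  df <- df[c(stratifier_fields, names(codebook$variables))]
  out <- validate_survey(df, codebook)
  attr(out, "config") <- config
  attr(out, "latent_factors") <- do.call(rbind, factors)
  out
}

# ---- analytic (integration-based) moments of the discretized codes ----

# P(a1 < U <= b1, a2 < V <= b2) for standard bivariate normal with corr rho
bvn_rect <- function(a1, b1, a2, b2, rho) {
  if (abs(rho) < 1e-12) {
    return((stats::pnorm(b1) - stats::pnorm(a1)) *
             (stats::pnorm(b2) - stats::pnorm(a2)))
  }
  s <- sqrt(1 - rho^2)
  lo <- max(a1, -8); hi <- min(b1, 8)
  if (hi <= lo) return(0)
  stats::integrate(function(u) {
    stats::dnorm(u) * (stats::pnorm((b2 - rho * u) / s) -
                         stats::pnorm((a2 - rho * u) / s))
  }, lo, hi, rel.tol = 1e-9)$value
}

code_moments_1d <- function(codes, cuts) {
  bounds <- c(-Inf, cuts, Inf)
  p <- diff(stats::pnorm(bounds))
  list(p = p, m1 = sum(codes * p), m2 = sum(codes^2 * p))
}

code_cross_moment <- function(codes1, cuts1, codes2, cuts2, rho) {
  b1 <- c(-Inf, cuts1, Inf); b2 <- c(-Inf, cuts2, Inf)
  acc <- 0
  for (i in seq_along(codes1)) for (j in seq_along(codes2)) {
    acc <- acc + codes1[i] * codes2[j] *
      bvn_rect(b1[i], b1[i + 1], b2[j], b2[j + 1], rho)
  }
  acc
}

#' Analytic code-scale correlation of two discretized latents
#'
#' Pearson correlation between two ordinal codes obtained by cutting
#' correlated standard-normal latents, computed by numerical integration of
#' bivariate-normal rectangle probabilities. This is the independent oracle
#' for the generator's sample correlations and the basis of the recovery
#' ground truth.
#'
#' @param rho Latent correlation.
#' @param codes1,codes2 Level codes (ascending).
#' @param cuts1,cuts2 Cutpoints (length one less than the codes).
#' @return Pearson correlation of the two codes.
#' @export
code_correlation <- function(rho, codes1, cuts1, codes2, cuts2) {
  m1 <- code_moments_1d(codes1, cuts1)
  m2 <- code_moments_1d(codes2, cuts2)
  cross <- code_cross_moment(codes1, cuts1, codes2, cuts2, rho)
  (cross - m1$m1 * m2$m1) /
    sqrt((m1$m2 - m1$m1^2) * (m2$m2 - m2$m1^2))
}

# pooled analytic moments of the nine factor-driven codes across strata
analytic_code_R <- function(config) {
  fp <- factor_predictors()
  latR <- tcrossprod(config$true_loadings)
  diag(latR) <- 1
  w <- config$n_per_stratum / sum(config$n_per_stratum)
  strata <- names(w)[w > 0]
  p <- length(fp)
  M1 <- matrix(0, length(strata), p, dimnames = list(strata, fp))
  M2 <- M1
  Cross <- array(0, c(length(strata), p, p))
  for (si in seq_along(strata)) {
    s <- strata[si]
    for (i in seq_len(p)) {
      ct <- config$cutpoints[[s]][[fp[i]]]
      m <- code_moments_1d(ct$codes, ct$cuts)
      M1[si, i] <- m$m1; M2[si, i] <- m$m2
      Cross[si, i, i] <- m$m2
    }
    for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
      ci <- config$cutpoints[[s]][[fp[i]]]
      cj <- config$cutpoints[[s]][[fp[j]]]
      cm <- code_cross_moment(ci$codes, ci$cuts, cj$codes, cj$cuts, latR[i, j])
      Cross[si, i, j] <- Cross[si, j, i] <- cm
    }
  }
  ws <- w[strata]
  Em1 <- drop(ws %*% M1)
  Ecross <- apply(Cross, c(2, 3), function(v) sum(ws * v))
  Cov <- Ecross - outer(Em1, Em1)
  D <- 1 / sqrt(diag(Cov))
  R <- Cov * outer(D, D)
  dimnames(R) <- list(fp, fp)
  R
}

#' Ground truth of a generator configuration
#'
#' Exposes every quantity the recovery tests compare against: the latent
#' loading matrix, the analytic pooled code-scale correlation matrix (see
#' [code_correlation()]; discretization attenuates correlations, so this —
#' not the latent matrix — is what component extraction on coded data
#' estimates), the eigenvalues and varimax-rotated loadings of that analytic
#' matrix, the retained-component count, the outcome model, the implied
#' per-stratum prevalences, and the noise predictors the screening stage
#' should eliminate.
#'
#' @param config A `pclr_genconfig`.
#' @param retain_threshold Eigenvalue retention threshold used on the
#'   analytic matrix.
#' @return A list with elements `latent_loadings`, `analytic_R`,
#'   `eigenvalues`, `r`, `expected_rotated_loadings`,
#'   `outcome_coefficients`, `outcome_intercepts`, `implied_prevalence`,
#'   `expected_eliminations`.
#' @export
truth <- function(config = generator_config(), retain_threshold = 1) {
  stopifnot(inherits(config, "pclr_genconfig"))
  R <- analytic_code_R(config)
  model <- extract_components(R, retain_threshold)
  if (model$r > 1) model <- varimax_rotate(model)
  list(latent_loadings = config$true_loadings,
       analytic_R = R,
       eigenvalues = model$eigenvalues,
       r = model$r,
       expected_rotated_loadings = model$rotated_loadings,
       outcome_coefficients = config$outcome_coefficients,
       outcome_intercepts = config$outcome_intercepts,
       implied_prevalence = vapply(strata_names(), function(s)
         implied_prevalence(config$outcome_intercepts[[s]],
                            config$outcome_coefficients), numeric(1)),
       expected_eliminations = noise_predictor_names())
}

#' Deterministic 12-record worked-example cohort
#'
#' A hard-coded tiny cohort covering all three insurance strata and every
#' classification branch (Medicaid-flag dominance, the 18-64 age window, the
#' household-size income schedule), used in documentation and smoke tests.
#'
#' @return A `pclr_survey` of 12 records with no missing cells.
#' @export
fixture_small <- function() {
  base <- function(id, age, hh, inc, priv, mcd, yr, codes, hs) {
    c(list(respondent_id = id, age_years = age, household_size = hh,
           annual_income_usd = inc, has_private_insurance = priv,
           has_medicaid = mcd, year = yr),
      stats::setNames(as.list(codes),
                      c("NRC", "LCT", "NSD", "SMC", "CVD", "DT", "CS", "AS",
                        "SEX", "RACE", "EM", "LDC", "ED", "MS")),
      list(HS = hs))
  }
  rows <- list(
    # above-poverty: private insurance, high income
    base("ap-01", 30, 2, 82000, TRUE, FALSE, 2014, c(1,1,1,1,2,2,1,2,1,1,1,1,1,1), 1L),
    base("ap-02", 58, 1, 60000, TRUE, FALSE, 2015, c(1,1,1,2,2,2,1,4,2,2,1,1,2,2), 1L),
    base("ap-03", 47, 3, 90000, TRUE, FALSE, 2016, c(2,2,1,2,1,2,2,3,1,3,2,1,3,2), 0L),
    base("ap-04", 70, 1, 30000, FALSE, FALSE, 2017, c(1,1,1,1,2,1,1,4,2,1,2,1,1,1), 1L),  # uninsured but over 64
    base("ap-05", 40, 1, 41000, FALSE, FALSE, 2018, c(1,2,1,1,2,2,1,2,1,2,1,2,2,1), 1L),  # uninsured, income above schedule
    # traditional Medicaid: flag dominates income and age
    base("md-01", 35, 2, 12000, FALSE, TRUE, 2013, c(2,1,1,1,2,2,1,2,2,2,2,1,2,1), 1L),
    base("md-02", 62, 1, 9000, FALSE, TRUE, 2019, c(2,1,2,1,1,1,1,4,2,1,2,1,3,1), 0L),
    base("md-03", 28, 4, 25000, TRUE, TRUE, 2014, c(1,1,1,1,2,2,2,2,1,4,1,2,1,2), 1L),
    # Medicaid gap: 18-64, below schedule, uninsured
    base("mg-01", 40, 1, 30000, FALSE, FALSE, 2015, c(2,2,2,2,2,2,1,2,2,2,2,2,3,2), 0L),
    base("mg-02", 23, 2, 41000, FALSE, FALSE, 2016, c(2,2,2,2,1,1,2,1,1,2,1,2,2,2), 0L),
    base("mg-03", 55, 1, 20000, FALSE, FALSE, 2017, c(1,2,2,2,2,1,1,3,2,3,2,1,3,1), 0L),
    base("mg-04", 64, 3, 50000, FALSE, FALSE, 2018, c(2,1,1,2,2,2,1,4,1,1,2,2,1,2), 1L)
  )
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  validate_survey(df, default_codebook())
}

#' Write a cohort to the CSV dialect load_survey reads
#'
#' @param survey A `pclr_survey`.
#' @param path Output path (`.tsv` for tab-separated, `.csv` otherwise).
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  stopifnot(inherits(survey, "pclr_survey"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(survey$records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
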