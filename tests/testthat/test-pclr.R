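test_that("fit_logistic: closed forms, cross-product oracle, glm agreement", {
  # intercept-only, y = (1,1,1,0): intercept = logit(3/4) = ln 3
  f <- fit_logistic(matrix(nrow = 4, ncol = 0), c(1, 1, 1, 0))
  expect_equal(unname(f$coefficients["(Intercept)"]), log(3), tolerance = 1e-8)

  # saturated 2x2 with cells (10, 20, 30, 40): slope OR = (10*40)/(20*30)
  x <- c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40))
  y <- c(rep(1, 30), rep(0, 70))
  f2 <- fit_logistic(cbind(exposure = x), y)
  expect_equal(unname(exp(f2$coefficients["exposure"])), 2 / 3,
               tolerance = 1e-8)

  # gradient at the MLE vanishes; covariance symmetric PSD
  expect_lt(max(abs(f2$gradient)), 1e-6)
  expect_equal(f2$covariance, t(f2$covariance))
  expect_true(all(eigen(f2$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))

  # separation: y identical to a binary column
  ysep <- rbinom(100, 1, 0.5)
  expect_error(fit_logistic(cbind(bad = ysep), ysep), "separation.*bad")

  # random fit matches glm coefficients and covariance
  set.seed(30)
  X <- matrix(rnorm(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  yr <- rbinom(300, 1, plogis(0.3 + X %*% c(0.5, -0.4, 0.2)))
  mine <- fit_logistic(X, yr)
  g <- glm(yr ~ X, family = binomial)
  expect_equal(unname(mine$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(mine$covariance), unname(vcov(g)), tolerance = 1e-6)
  expect_equal(mine$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-8)

  expect_error(fit_logistic(X, rep(1, 300)), "single class")
  expect_error(fit_logistic(X[1:3, ], yr[1:3]), "more observations")
})

test_that("classify applies the probability threshold elementwise", {
  set.seed(31)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, plogis(X %*% c(1, -1)))
  f <- fit_logistic(X, y)
  pred <- classify(f, X)           # default threshold 0.6
  probs <- plogis(cbind(1, X) %*% f$coefficients)
  expect_identical(pred, as.integer(probs >= 0.6))
  expect_identical(classify(f, X, 0.5), as.integer(probs >= 0.5))
  # intercept-only fit on balanced y: all predictions identical
  f0 <- fit_logistic(matrix(nrow = 100, ncol = 0), rep(c(0, 1), 50))
  expect_equal(length(unique(classify(f0, matrix(nrow = 100, ncol = 0), 0.5))), 1)
  expect_error(classify(f, X, 1.5), "threshold")
})

test_that("back_transform: identity, null case, brute-force covariance oracle", {
  set.seed(32)
  # L = identity (r = p): lambda = a, var(lambda) = diag Cov(a)
  X <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(500, 1, plogis(X %*% c(0.4, 0, -0.3)))
  f <- fit_logistic(X, y)
  ident <- structure(list(rotated_loadings = diag(3), R = diag(3),
                          names = c("a", "b", "c"), r = 3,
                          eigenvalues = rep(1, 3)), class = "pclr_pca")
  bt <- back_transform(f, ident)
  expect_equal(unname(bt$lambda), unname(f$coefficients[-1]), tolerance = 1e-12)
  expect_equal(unname(bt$lambda_var), unname(diag(f$covariance)[-1]),
               tolerance = 1e-12)

  # null slopes: lambda = 0, z = 0, p = 1
  f0 <- f
  f0$coefficients[] <- 0
  bt0 <- back_transform(f0, ident)
  expect_equal(unname(bt0$lambda), rep(0, 3))
  expect_equal(unname(bt0$wald_z), rep(0, 3))
  expect_equal(unname(bt0$p_values), rep(1, 3))

  # random 4-component fit: Cov(lambda) matches the elementwise double sum
  cfg <- single_stratum_config(1500, seed = 33)
  parts <- nine_standardized(cfg)
  m <- varimax_rotate(extract_components(parts$std))
  sc <- component_scores(parts$std, m)
  fit <- fit_logistic(sc$Z, parts$coded$y)
  bt4 <- back_transform(fit, m, sc)
  a_cov <- fit$covariance[-1, -1] / outer(sc$score_sds, sc$score_sds)
  L <- m$rotated_loadings
  for (i in c(1, 5, 9)) {
    brute <- 0
    for (j in seq_len(m$r)) for (k in seq_len(m$r)) {
      brute <- brute + L[i, j] * L[i, k] * a_cov[j, k]
    }
    expect_equal(unname(bt4$lambda_var[i]), brute, tolerance = 1e-12)
  }
  expect_equal(unname(bt4$wald_z),
               unname(bt4$lambda / sqrt(bt4$lambda_var)), tolerance = 1e-12)

  # dimension mismatch
  expect_error(back_transform(f, m), "slopes")
})

test_that("full-retention equivalence: lambda equals the direct standardized fit", {
  cfg <- single_stratum_config(2000, seed = 34)
  parts <- nine_standardized(cfg)
  m <- extract_components(parts$std, retain_threshold = 0)  # keep all 9
  expect_equal(m$r, 9)
  sc <- component_scores(parts$std, m)
  bt <- back_transform(fit_logistic(sc$Z, parts$coded$y), m, sc)
  direct <- fit_logistic(parts$std$Xstar, parts$coded$y)
  expect_equal(unname(bt$lambda), unname(direct$coefficients[-1]),
               tolerance = 1e-6)
  expect_equal(unname(bt$lambda_var), unname(diag(direct$covariance)[-1]),
               tolerance = 1e-6)
})

test_that("Wald-z^2 tracks the likelihood-ratio statistic asymptotically", {
  cfg <- single_stratum_config(20000, seed = 35)
  parts <- nine_standardized(cfg)
  m <- varimax_rotate(extract_components(parts$std))
  sc <- component_scores(parts$std, m)
  full <- fit_logistic(sc$Z, parts$coded$y)
  for (j in 1:2) {
    reduced <- fit_logistic(sc$Z[, -j, drop = FALSE], parts$coded$y)
    lr <- 2 * (full$log_likelihood - reduced$log_likelihood)
    z2 <- (full$coefficients[j + 1] / sqrt(diag(full$covariance)[j + 1]))^2
    expect_lt(abs(z2 - lr) / lr, 0.10)
  }
})

test_that("odds_ratio_table: null coefficient, contrast closed form, stars", {
  expect_equal(significance_stars(c(0.0005, 0.03, 0.2, NA)),
               c("*", "**", "", ""))

  cfg <- single_stratum_config(1500, seed = 36)
  parts <- nine_standardized(cfg)
  m <- varimax_rotate(extract_components(parts$std))
  sc <- component_scores(parts$std, m)
  fit <- fit_logistic(sc$Z, parts$coded$y)
  bt <- back_transform(fit, m, sc)

  # binary variable coded 1/2: OR = exp(lambda/sd), CI width exp(2*1.96*se/sd)
  tab <- odds_ratio_table(bt, parts$coded, "NRC", parts$std$column_sds)
  sdn <- parts$std$column_sds[["NRC"]]
  row2 <- tab[tab$code == 2, ]
  expect_equal(row2$or, exp(bt$lambda[["NRC"]] / sdn), tolerance = 1e-10)
  expect_equal(row2$ci_high / row2$ci_low,
               exp(2 * qnorm(0.975) * sqrt(bt$lambda_var[["NRC"]]) / sdn),
               tolerance = 1e-10)
  expect_true(tab$referent[tab$code == 1])
  expect_equal(tab$or[tab$code == 1], 1)
  # CI brackets the point estimate; ORs positive; monotone in lambda
  expect_true(row2$ci_low < row2$or && row2$or < row2$ci_high)
  expect_true(all(tab$or > 0))

  # 4-level variable: ORs are a monotone geometric ladder in the contrast
  tab_as <- odds_ratio_table(bt, parts$coded, "AS", parts$std$column_sds)
  lam <- bt$lambda[["AS"]] / parts$std$column_sds[["AS"]]
  ors <- tab_as$or[match(2:4, tab_as$code)]
  expect_equal(unname(ors), exp(lam * (2:4 - 1)), tolerance = 1e-10)
  expect_true(all(diff(ors) > 0) || all(diff(ors) < 0))

  # null coefficient: OR 1, CI spans 1
  bt0 <- bt
  bt0$lambda[] <- 0
  t0 <- odds_ratio_table(bt0, parts$coded, "NRC", parts$std$column_sds)
  expect_equal(t0$or[t0$code == 2], 1)
  expect_true(t0$ci_low[t0$code == 2] < 1 && t0$ci_high[t0$code == 2] > 1)
})

test_that("odds ratios are invariant to shifting a predictor's codes", {
  # same data, codes shifted by +2 for NRC via a custom codebook
  set.seed(37)
  cb <- default_codebook()
  cfg <- single_stratum_config(1200, seed = 37)
  coded <- recode(generate_cohort(cfg),
                  predictors = reference_retained_predictors())
  shifted <- coded
  shifted$X[, "NRC"] <- shifted$X[, "NRC"] + 2L
  vars <- shifted$codebook$variables
  vars$NRC$levels$code <- vars$NRC$levels$code + 2L
  vars$NRC$referent_code <- vars$NRC$referent_code + 2L
  shifted$codebook <- codebook(vars)

  for (cd in list(coded, shifted)) {
    std <- standardize(cd)
    m <- varimax_rotate(extract_components(std))
    sc <- component_scores(std, m)
    bt <- back_transform(fit_logistic(sc$Z, cd$y), m, sc)
    tab <- odds_ratio_table(bt, cd, "NRC", std$column_sds)
    assign(if (identical(cd, coded)) "or_a" else "or_b",
           tab$or[!tab$referent])
  }
  expect_equal(or_a, or_b, tolerance = 1e-10)
})

test_that("run_scenario: determinism, structure, generator-truth significance", {
  cfg <- single_stratum_config(1500, seed = 38)
  parts <- nine_standardized(cfg)
  m <- varimax_rotate(extract_components(parts$std))

  for (scn in c("unadjusted_LA", "adjusted_LA", "pca_unadjusted",
                "pca_adjusted")) {
    r1 <- run_scenario(parts$coded, parts$std, m, scn)
    r2 <- run_scenario(parts$coded, parts$std, m, scn)
    expect_identical(r1, r2)
    # structural contract: every variable block has exactly one referent row
    refs <- tapply(r1$referent, r1$acronym, sum)
    expect_true(all(refs == 1))
    expect_true(all(r1$stars[!is.na(r1$p) & r1$p < 0.001] == "*"))
  }

  # effect on factor 1 only: NRC/LCT flagged, null variables near level
  res <- vapply(1:100, function(seed) {
    cfgb <- generator_config(
      n_per_stratum = c(above_poverty = 3000, medicaid = 0, medicaid_gap = 0),
      true_loadings = block_loadings(),
      outcome_coefficients = c(0.6, 0, 0, 0), seed = seed)
    parts <- nine_standardized(cfgb)
    m <- varimax_rotate(extract_components(parts$std))
    sc <- component_scores(parts$std, m)
    bt <- back_transform(fit_logistic(sc$Z, parts$coded$y), m, sc)
    sig <- bt$p_values < 0.05
    c(both = sig[["NRC"]] && sig[["LCT"]],
      null_rate = mean(sig[setdiff(names(sig), c("NRC", "LCT"))]))
  }, numeric(2))
  expect_gte(mean(res["both", ]), 0.90)
  expect_lt(mean(res["null_rate", ]), 0.10)
})
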