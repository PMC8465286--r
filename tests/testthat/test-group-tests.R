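test_that("independent_t_test: hand formulas, oracle agreement, edge cases", {
  # identical groups: t = 0, p = 1, CI symmetric about 0
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  tt <- independent_t_test(x, g)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_equal(tt$ci_low, -tt$ci_high)

  # (1,2,3) vs (4,5,6), pooled: t = -3/sqrt(2/3), df = 4
  tt2 <- independent_t_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(tt2$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt2$df, 4)

  # equal variances and equal n: pooled and Welch coincide
  set.seed(40)
  v <- rnorm(20)
  gg <- rep(c("a", "b"), each = 10)
  tp <- independent_t_test(v, gg, equal_var = TRUE)
  tw <- independent_t_test(v, gg, equal_var = FALSE)
  expect_equal(tp$t, tw$t, tolerance = 1e-12)
  expect_lte(tw$df, tp$df)

  # 100 seeded cases against stats::t.test in both conventions
  set.seed(41)
  for (i in 1:100) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    z <- c(rnorm(n1, 0, 1), rnorm(n2, 0.3, 1.5))
    lab <- rep(c("a", "b"), c(n1, n2))
    for (ev in c(TRUE, FALSE)) {
      mine <- independent_t_test(z, lab, equal_var = ev)
      ref <- t.test(z[lab == "a"], z[lab == "b"], var.equal = ev)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
      expect_equal(c(mine$ci_low, mine$ci_high),
                   unname(ref$conf.int), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }

  expect_error(independent_t_test(1:5, c("a", "a", "a", "a", "b")),
               "at least two")
  expect_error(independent_t_test(1:6, rep(c("a", "b", "c"), 2)),
               "exactly two")
})

test_that("CI excludes zero exactly when p < alpha", {
  set.seed(42)
  for (i in 1:50) {
    z <- rnorm(24, mean = rep(c(0, runif(1, 0, 1)), each = 12))
    lab <- rep(c("a", "b"), each = 12)
    tt <- independent_t_test(z, lab, equal_var = (i %% 2 == 0), alpha = 0.05)
    excludes <- tt$ci_low > 0 || tt$ci_high < 0
    expect_identical(excludes, tt$p < 0.05)
  }
})

test_that("oneway_f_test: hand ANOVA, t^2 identity, SS decomposition, aov oracle", {
  # (1,2,3) and (2,3,4): F = 1.5 on (1, 4) df
  ft <- oneway_f_test(c(1, 2, 3, 2, 3, 4), rep(c(1, 2), each = 3))
  expect_equal(ft$F, 1.5, tolerance = 1e-12)
  expect_equal(c(ft$df_between, ft$df_within), c(1, 4))

  # all observations equal: F = 0
  expect_equal(oneway_f_test(rep(2, 8), rep(c(1, 2), 4))$F, 0)

  # two groups: F = pooled t^2
  set.seed(43)
  z <- rnorm(30)
  lab <- rep(c(1, 2), 15)
  ft2 <- oneway_f_test(z, lab)
  tt <- independent_t_test(z, lab, equal_var = TRUE)
  expect_equal(ft2$F, tt$t^2, tolerance = 1e-10)
  expect_true(is.na(ft2$linear_term$F[3]))  # deviation df = 0 with k = 2

  # total SS = between SS + within SS exactly
  z3 <- rnorm(60)
  g3 <- sample(1:4, 60, TRUE)
  ft3 <- oneway_f_test(z3, g3)
  expect_equal(ft3$ss_between + ft3$ss_within,
               sum((z3 - mean(z3))^2), tolerance = 1e-10)
  # combined df = weighted df + deviation df; combined SS splits exactly
  lt <- ft3$linear_term
  expect_equal(lt$df[1], lt$df[2] + lt$df[3])
  expect_equal(lt$ss[1], lt$ss[2] + lt$ss[3], tolerance = 1e-10)

  # independent oracle: aov F and p
  ref <- anova(aov(z3 ~ factor(g3)))
  expect_equal(ft3$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ft3$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # weighted linear term against the explicit contrast formula
  ns <- tabulate(factor(g3))
  means <- tapply(z3, factor(g3), mean)
  cg <- as.numeric(names(means))
  cg <- cg - sum(ns * cg) / sum(ns)
  ss_lin <- sum(ns * cg * means)^2 / sum(ns * cg^2)
  expect_equal(lt$ss[2], ss_lin, tolerance = 1e-10)

  expect_error(oneway_f_test(1:5, rep(1, 5)), "at least two")
})

test_that("pooled and Welch converge as the sample-variance ratio tends to 1", {
  set.seed(44)
  a <- rnorm(20)
  braw <- rnorm(20)
  # rescale group b so its sample variance is exactly ratio * var(a)
  b_unit <- (braw - mean(braw)) / sd(braw)
  lab <- rep(c("a", "b"), each = 20)
  last <- NA
  for (ratio in c(1.5, 1.1, 1.0001)) {
    b <- mean(a) + 0.4 + b_unit * sd(a) * sqrt(ratio)
    d <- abs(independent_t_test(c(a, b), lab, TRUE)$p -
               independent_t_test(c(a, b), lab, FALSE)$p)
    last <- d
  }
  expect_lt(last, 1e-6)
})

test_that("validate_factors: signal detection, permutation null, errors", {
  # outcome driven by factor 1 only
  cfgb <- generator_config(
    n_per_stratum = c(above_poverty = 3000, medicaid = 0, medicaid_gap = 0),
    true_loadings = block_loadings(),
    outcome_coefficients = c(0.8, 0, 0, 0), seed = 45)
  parts <- nine_standardized(cfgb)
  m <- varimax_rotate(extract_components(parts$std))
  sc <- component_scores(parts$std, m)
  val <- validate_factors(sc, parts$coded$y)
  # the factor carrying NRC/LCT must be flagged in both conventions
  f1 <- which.max(abs(m$rotated_loadings["NRC", ]))
  f1_rows <- val$table[val$table$component == paste0("PC", f1), ]
  expect_true(all(f1_rows$p < 0.05))
  expect_true(all(f1_rows$F_p < 0.05))
  # F = t^2 identity carries through the bundle (binary grouping)
  expect_equal(f1_rows$F[1], f1_rows$t[1]^2, tolerance = 1e-10)

  # null factors reject at about the nominal rate over replicates
  set.seed(46)
  null_p <- replicate(60, {
    yperm <- sample(parts$coded$y)
    v <- validate_factors(sc, yperm)
    v$table$p[v$table$equal_variances == "assumed"]
  })
  expect_gt(mean(null_p < 0.05), 0.0)
  expect_lt(mean(null_p < 0.05), 0.12)

  expect_error(validate_factors(sc, rep(1, parts$coded$n)), "single class")
  expect_error(validate_factors(sc, c(0, 1)), "conformable")
})
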