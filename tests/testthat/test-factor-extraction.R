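test_that("adequacy reproduces closed forms and the anti-image oracle", {
  # p = 2: partial equals marginal, KMO = 0.5 exactly for any r != 0
  for (r in c(-0.7, 0.2, 0.9)) {
    R <- matrix(c(1, r, r, 1), 2, 2)
    expect_equal(adequacy(R, 100)$kmo_overall, 0.5, tolerance = 1e-12)
  }
  # identity correlation: Bartlett chi2 = 0, p = 1
  ad <- adequacy(diag(4), 50)
  expect_equal(ad$bartlett_chi2, 0, tolerance = 1e-12)
  expect_equal(ad$bartlett_p, 1)
  expect_equal(ad$bartlett_df, 6)

  # 5-variable random correlation matrix vs explicit elementwise anti-image sums
  set.seed(14)
  R <- cor(matrix(rnorm(200 * 5), 200, 5))
  n <- 200
  ad <- adequacy(R, n)
  S <- solve(R)
  p <- ncol(R)
  r2 <- q2 <- 0
  for (i in 1:p) for (j in 1:p) {
    if (i == j) next
    r2 <- r2 + R[i, j]^2
    q2 <- q2 + (-S[i, j] / sqrt(S[i, i] * S[j, j]))^2
  }
  expect_equal(ad$kmo_overall, r2 / (r2 + q2), tolerance = 1e-12)
  expect_equal(ad$bartlett_chi2,
               -(n - 1 - (2 * p + 5) / 6) * log(det(R)), tolerance = 1e-10)
  expect_true(all(ad$kmo_per_variable >= 0 & ad$kmo_per_variable <= 1))

  # singular matrix
  Rs <- matrix(1, 3, 3)
  expect_error(adequacy(Rs, 10), "singular|invertible")
})

test_that("extract_components: closed form, retention, reconstruction", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- extract_components(R)
  expect_equal(m$eigenvalues, c(1.5, 0.5))
  expect_equal(m$r, 1)

  # eigenvalues of a correlation matrix sum to p; full reconstruction
  cfg <- single_stratum_config(1500, seed = 17)
  parts <- nine_standardized(cfg)
  m9 <- extract_components(parts$std)
  expect_equal(sum(m9$eigenvalues), 9, tolerance = 1e-8)
  L <- m9$unrotated_loadings
  expect_lt(max(abs(L %*% t(L) - m9$R)), 1e-8)
  # sign convention: largest-magnitude entry of each column positive
  expect_true(all(apply(L, 2, function(cl) cl[which.max(abs(cl))] > 0)))
  # cumulative variance identity: sum of communalities / p
  expect_equal(m9$variance_explained_cum, sum(m9$communalities) / 9,
               tolerance = 1e-12)

  # near-identity correlation: retention flagged unstable
  set.seed(18)
  Xi <- matrix(rnorm(60000), 10000, 6, dimnames = list(NULL, letters[1:6]))
  expect_warning(extract_components(cor(Xi)), "unstable")

  expect_error(extract_components(matrix(c(1, NA, NA, 1), 2, 2)), "non-finite")
})

test_that("generator-truth Monte-Carlo: r = 4 in >= 95% of replicates", {
  hits <- vapply(1:100, function(seed) {
    parts <- nine_standardized(single_stratum_config(2000, seed = seed))
    extract_components(parts$std)$r == 4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("varimax: fixed point, r = 1 identity, planar grid-search oracle", {
  # perfect simple structure is a fixed point up to permutation/sign
  L <- rbind(c(0.9, 0, 0), c(0.8, 0, 0), c(0, 0.7, 0),
             c(0, 0.85, 0), c(0, 0, 0.6), c(0, 0, 0.95))
  rot <- varimax_rotate(L)
  expect_lt(max(abs(align_loadings(L, rot) - L)), 1e-8)

  # r = 1: no rotational freedom
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- varimax_rotate(extract_components(R))
  expect_equal(m$rotation, matrix(1))

  # 6 x 2 random loadings vs brute-force grid over the planar angle
  set.seed(20)
  for (rep in 1:3) {
    L2 <- matrix(runif(12, -1, 1), 6, 2) * 0.8
    rot2 <- varimax_rotate(L2, kaiser_normalize = FALSE)
    grid <- seq(-pi / 4, pi / 4, by = 1e-4)
    best <- max(vapply(grid, function(a) {
      G <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      varimax_criterion(L2 %*% G)
    }, numeric(1)))
    expect_gte(varimax_criterion(rot2), best - 1e-6)
  }
})

test_that("varimax conserves communalities, ascends monotonically, matches stats::varimax", {
  set.seed(22)
  for (rep in 1:10) {
    L <- matrix(rnorm(9 * 3), 9, 3) * 0.55
    rot <- varimax_rotate(L)
    expect_lt(max(abs(rowSums(L^2) - rowSums(rot^2))), 1e-10)
    tr <- attr(rot, "criterion_trace")
    expect_true(all(diff(tr) >= -1e-12))
    Tm <- attr(rot, "rotation")
    expect_lt(max(abs(t(Tm) %*% Tm - diag(3))), 1e-10)
    # independent oracle: base R's varimax reaches the same criterion value
    ref <- stats::varimax(L, normalize = TRUE, eps = 1e-12)
    expect_equal(varimax_criterion(rot),
                 varimax_criterion(L %*% ref$rotmat), tolerance = 1e-4)
  }
})

test_that("communalities and loading interpretation follow the published conventions", {
  ref <- reference_rotated_loadings()
  model <- structure(list(rotated_loadings = ref, names = rownames(ref),
                          eigenvalues = rep(1, 9), r = 4, R = diag(9)),
                     class = "pclr_pca")
  h2 <- suppressWarnings(communalities(model))
  expect_equal(unname(round(h2["LCT"], 3)), 0.849)
  expect_equal(unname(round(h2["NSD"], 3)), 0.274)
  expect_warning(communalities(model, cutoff = 0.7), "NSD")

  # zero loadings row -> communality 0
  m0 <- model
  m0$rotated_loadings <- rbind(ref, ZZ = rep(0, 4))
  m0$names <- c(model$names, "ZZ")
  h0 <- suppressWarnings(communalities(m0))
  expect_equal(unname(h0["ZZ"]), 0)

  # cutoff 0.7 reproduces the published factor-1 assignment
  fac <- interpret_loadings(model, 0.7)
  expect_setequal(fac$PC1, c("LCT", "NRC"))
  expect_setequal(fac$PC2, "ED")
  expect_setequal(fac$PC3, "AS")
  expect_setequal(fac$PC4, "MS")

  expect_warning(f2 <- interpret_loadings(model, 1.1), "no loading")
  expect_true(all(lengths(f2) == 0))

  f0 <- interpret_loadings(model, 0)
  expect_equal(sum(lengths(f0)), 9)   # every variable assigned once
})

test_that("component scores: identity map, orthogonality, collinear collapse", {
  cfg <- single_stratum_config(1200, seed = 25)
  parts <- nine_standardized(cfg)
  m <- extract_components(parts$std)

  # identity loadings (p = r, no rotation) -> Z = X*
  ident <- structure(list(rotated_loadings = diag(9), R = diag(9),
                          names = parts$coded$predictor_names, r = 9,
                          eigenvalues = rep(1, 9)), class = "pclr_pca")
  dimnames(ident$rotated_loadings) <- list(parts$coded$predictor_names,
                                           paste0("PC", 1:9))
  sc_id <- component_scores(parts$std, ident, standardized = FALSE)
  expect_equal(unname(sc_id$Z), unname(parts$std$Xstar), tolerance = 1e-12)

  # standardized unrotated loading-weight scores are exactly uncorrelated
  sc <- component_scores(parts$std, m)
  C <- cor(sc$Z)
  expect_lt(max(abs(C - diag(m$r))), 1e-8)
  expect_equal(unname(apply(sc$Z, 2, var)), rep(1, m$r), tolerance = 1e-8)

  # regression-method scores stay uncorrelated after rotation
  mrot <- varimax_rotate(m)
  sc_r <- component_scores(parts$std, mrot, method = "regression")
  expect_lt(max(abs(cor(sc_r$Z) - diag(mrot$r))), 1e-8)

  # rotation leaves communalities untouched on a fitted model
  expect_equal(rowSums(mrot$rotated_loadings^2),
               rowSums(m$rotated_loadings^2), tolerance = 1e-10)

  # two perfectly correlated variables collapse onto one component
  z <- rnorm(100)
  X <- cbind(a = z, b = z)
  stdc <- standardize(X)
  mc <- extract_components(cor(stdc$Xstar))
  expect_equal(mc$r, 1)
  scc <- component_scores(stdc, mc)
  expect_equal(abs(cor(scc$Z[, 1], z)), 1, tolerance = 1e-10)

  expect_error(component_scores(standardize(X), m), "does not match")
})
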