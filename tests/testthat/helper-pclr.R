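# shared fixtures and alignment utilities

# single-stratum generator config (keeps noise predictors truly independent)
single_stratum_config <- function(n = 2000, seed = 1,
                                  coefs = c(0.4, -0.5, -0.6, -0.25), ...) {
  generator_config(n_per_stratum = c(above_poverty = n, medicaid = 0,
                                     medicaid_gap = 0),
                   outcome_coefficients = coefs, seed = seed, ...)
}

# block loading matrix with exact zeros off-block (clean separation for MC)
block_loadings <- function() {
  m <- rbind(NRC = c(0.88, 0, 0, 0), LCT = c(0.90, 0, 0, 0),
             NSD = c(0, 0.45, 0, 0), SMC = c(0, 0.86, 0, 0),
             CS  = c(0, 0, 0, 0.87), AS  = c(0, 0, 0.88, 0),
             LDC = c(0, 0, -0.85, 0), ED = c(0, 0.85, 0, 0),
             MS  = c(0, 0, 0, 0.86))
  colnames(m) <- paste0("F", 1:4)
  m
}

# align columns of B to A by greedy permutation + sign flip
align_loadings <- function(A, B) {
  r <- ncol(A)
  used <- integer(0)
  out <- B
  for (j in seq_len(r)) {
    ip <- vapply(seq_len(r), function(k)
      if (k %in% used) -Inf else abs(sum(A[, j] * B[, k])), numeric(1))
    k <- which.max(ip)
    used <- c(used, k)
    out[, j] <- B[, k] * sign(sum(A[, j] * B[, k]))
  }
  out
}

# wrap a bare matrix + outcome into a pclr_coded against a codebook
coded_from_matrix <- function(X, y, cb = default_codebook(),
                              stratum = "above_poverty") {
  structure(list(X = X, y = y,
                 stratum = factor(rep(stratum, nrow(X)),
                                  levels = c("above_poverty", "medicaid",
                                             "medicaid_gap")),
                 predictor_names = colnames(X), n = nrow(X),
                 codebook = cb, dropped = integer(0)),
            class = "pclr_coded")
}

# standardized cohort of the nine factor predictors from a config
nine_standardized <- function(cfg) {
  coded <- recode(generate_cohort(cfg),
                  predictors = reference_retained_predictors())
  list(coded = coded, std = standardize(coded))
}
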