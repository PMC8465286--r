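#' Cohort containers
#'
#' @section Survey records:
#' A cohort is held as a plain data frame with one row per respondent:
#' stratifier fields (`respondent_id`, `age_years`, `household_size`,
#' `annual_income_usd`, `has_private_insurance`, `has_medicaid`, `year`)
#' followed by one integer column per codebook variable (predictors and the
#' outcome), named by acronym. Missing answers are `NA`.
#' @name pclr-cohort
#' @keywords internal
NULL

stratifier_fields <- c("respondent_id", "age_years", "household_size",
                       "annual_income_usd", "has_private_insurance",
                       "has_medicaid", "year")

#' Load and validate a survey file
#'
#' Reads a CSV/TSV of per-respondent records, resolves the header against the
#' codebook, and validates each row: stratifier bounds (age 0-120, year
#' 2013-2020, positive household size, non-negative income) and declared
#' level codes per variable. Rows failing validation are kept in the returned
#' object but flagged with reasons; downstream complete-case recoding excludes
#' them.
#'
#' @param path Path to a delimited text file with a header row.
#' @param codebook A [codebook()]; defaults to [default_codebook()].
#' @param sep Field separator; `","` or `"\t"` (guessed from the extension
#'   when `NULL`).
#' @return A list of class `pclr_survey` with elements `records` (data frame),
#'   `flagged` (data frame of `row`, `reason`) and `codebook`.
#' @export
load_survey <- function(path, codebook = default_codebook(), sep = NULL) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_survey(raw, codebook)
}

#' Validate an in-memory cohort data frame
#'
#' @param records Data frame in the layout described under
#'   [load_survey()]; logical flags may be coded 0/1 or TRUE/FALSE.
#' @inheritParams load_survey
#' @return A `pclr_survey` list (see [load_survey()]).
#' @export
validate_survey <- function(records, codebook = default_codebook()) {
  stopifnot(inherits(codebook, "pclr_codebook"))
  needed <- c(stratifier_fields, names(codebook$variables))
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records$has_private_insurance <- as.logical(records$has_private_insurance)
  records$has_medicaid <- as.logical(records$has_medicaid)
  if (any(records$annual_income_usd < 0, na.rm = TRUE)) {
    stop("negative annual income encountered")
  }
  n <- nrow(records)
  flags <- list()
  note <- function(rows, reason) {
    if (length(rows)) flags[[length(flags) + 1L]] <<-
        data.frame(row = rows, reason = reason, stringsAsFactors = FALSE)
  }
  note(which(is.na(records$age_years) | records$age_years < 0 |
               records$age_years > 120), "age_years outside [0, 120]")
  note(which(is.na(records$year) | records$year < 2013 | records$year > 2020),
       "year outside [2013, 2020]")
  note(which(is.na(records$household_size) | records$household_size < 1),
       "household_size not positive")
  for (acr in names(codebook$variables)) {
    ok_codes <- codebook_levels(codebook, acr)
    bad <- which(!is.na(records[[acr]]) & !(records[[acr]] %in% ok_codes))
    note(bad, paste0("unknown level code for ", acr))
  }
  flagged <- if (length(flags)) do.call(rbind, flags) else
    data.frame(row = integer(), reason = character(), stringsAsFactors = FALSE)
  structure(list(records = records, flagged = flagged, codebook = codebook),
            class = "pclr_survey")
}

#' @export
print.pclr_survey <- function(x, ...) {
  cat("<pclr_survey> ", nrow(x$records), " records, ",
      length(unique(x$flagged$row)), " flagged\n", sep = "")
  invisible(x)
}

#' Classify records into insurance strata
#'
#' Applies the coverage-gap eligibility rule: a respondent falls in the
#' Medicaid gap when aged 18-64, with household income below the
#' household-size income schedule, and holding neither private insurance nor
#' Medicaid. Medicaid enrollment dominates (any enrollee is `medicaid`
#' regardless of income); everyone else is `above_poverty`. The default
#' schedule is the published Texas one — below USD 35,000 for a one-person
#' household, 47,000 for two — extended linearly (+12,000 per additional
#' member) beyond the published sizes.
#'
#' @param records Data frame of survey records (or a `pclr_survey`).
#' @param income_schedule Numeric vector; element k is the threshold for a
#'   k-person household. Extended linearly using its last increment.
#' @return Factor with levels `above_poverty`, `medicaid`, `medicaid_gap`.
#' @export
classify_insurance <- function(records,
                               income_schedule = c(35000, 47000)) {
  if (inherits(records, "pclr_survey")) records <- records$records
  stopifnot(length(income_schedule) >= 1)
  if (any(records$annual_income_usd < 0, na.rm = TRUE)) {
    stop("negative annual income encountered")
  }
  hh <- pmax(1L, as.integer(records$household_size))
  inc_step <- if (length(income_schedule) > 1)
    diff(income_schedule)[length(income_schedule) - 1L] else 12000
  thr <- ifelse(hh <= length(income_schedule),
                income_schedule[pmin(hh, length(income_schedule))],
                income_schedule[length(income_schedule)] +
                  inc_step * (hh - length(income_schedule)))
  gap <- records$age_years >= 18 & records$age_years <= 64 &
    records$annual_income_usd < thr &
    !records$has_private_insurance & !records$has_medicaid
  out <- ifelse(records$has_medicaid, "medicaid",
                ifelse(gap, "medicaid_gap", "above_poverty"))
  factor(out, levels = c("above_poverty", "medicaid", "medicaid_gap"))
}

#' Recode a validated survey into a coded matrix
#'
#' Maps predictor answers to their codebook integer codes, binarizes the
#' outcome (good health = 1, fair/poor = 0), applies complete-case filtering
#' (rows flagged at load time or with any missing retained column are
#' dropped), and attaches the per-row insurance stratum.
#'
#' @param survey A `pclr_survey` from [load_survey()] / [validate_survey()].
#' @param predictors Acronyms to retain as predictor columns; default all
#'   codebook predictors.
#' @param income_schedule Passed to [classify_insurance()].
#' @return A `pclr_coded` list: `X` (n x p integer matrix), `y` (0/1 vector),
#'   `stratum` (factor), `predictor_names`, `n`, `codebook`, `dropped`
#'   (row indices removed).
#' @export
recode <- function(survey, predictors = NULL, income_schedule = c(35000, 47000)) {
  stopifnot(inherits(survey, "pclr_survey"))
  cb <- survey$codebook
  if (is.null(predictors)) predictors <- predictor_names(cb)
  stopifnot(all(predictors %in% predictor_names(cb)))
  rec <- survey$records
  out_acr <- outcome_name(cb)
  keep_cols <- c(predictors, out_acr)
  bad_rows <- unique(survey$flagged$row)
  incomplete <- which(!stats::complete.cases(rec[keep_cols]))
  drop <- sort(unique(c(bad_rows, incomplete)))
  keep <- setdiff(seq_len(nrow(rec)), drop)
  if (!length(keep)) stop("empty complete-case set")
  rec <- rec[keep, , drop = FALSE]
  X <- as.matrix(rec[predictors])
  storage.mode(X) <- "integer"
  # outcome: map through interpretation (good -> 1) rather than trusting codes
  lv <- cb$variables[[out_acr]]$levels
  good_codes <- lv$code[lv$interpretation == "good"]
  y <- as.integer(rec[[out_acr]] %in% good_codes)
  stratum <- classify_insurance(rec, income_schedule)
  structure(list(X = X, y = y, stratum = stratum,
                 predictor_names = predictors, n = nrow(X),
                 codebook = cb, dropped = drop),
            class = "pclr_coded")
}

#' @export
print.pclr_coded <- function(x, ...) {
  cat("<pclr_coded> n = ", x$n, ", p = ", ncol(x$X),
      " (", paste(x$predictor_names, collapse = ", "), ")\n", sep = "")
  print(table(x$stratum))
  invisible(x)
}

#' Subset a coded matrix to one stratum
#' @param coded A `pclr_coded`.
#' @param stratum Stratum label.
#' @return A `pclr_coded` restricted to that stratum.
#' @export
subset_stratum <- function(coded, stratum) {
  stopifnot(inherits(coded, "pclr_coded"))
  idx <- which(coded$stratum == stratum)
  if (!length(idx)) stop("stratum ", stratum, " is empty")
  out <- coded
  out$X <- coded$X[idx, , drop = FALSE]
  out$y <- coded$y[idx]
  out$stratum <- droplevels(coded$stratum[idx])
  out$n <- length(idx)
  out
}

#' Standardize predictor columns
#'
#' Centers and scales every predictor column to mean 0, standard deviation 1
#' (sample, n-1 convention by default), recording the moments so odds ratios
#' can be mapped back to level contrasts.
#'
#' @param coded A `pclr_coded` (or a plain numeric matrix).
#' @param sd_convention `"sample"` (n-1 denominator) or `"population"` (n).
#' @return A `pclr_standardized` list: `Xstar`, `column_means`, `column_sds`,
#'   `sd_convention`, plus `y` and `stratum` carried over when available.
#' @export
standardize <- function(coded, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  X <- if (inherits(coded, "pclr_coded")) coded$X else as.matrix(coded)
  n <- nrow(X)
  mu <- colMeans(X)
  ss <- colSums(sweep(X, 2, mu)^2)
  sds <- sqrt(ss / if (sd_convention == "sample") (n - 1) else n)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  }
  Xstar <- sweep(sweep(X, 2, mu), 2, sds, "/")
  structure(list(Xstar = Xstar, column_means = mu, column_sds = sds,
                 sd_convention = sd_convention,
                 y = if (inherits(coded, "pclr_coded")) coded$y else NULL,
                 stratum = if (inherits(coded, "pclr_coded")) coded$stratum else NULL),
            class = "pclr_standardized")
}

#' Undo standardization
#' @param std A `pclr_standardized`.
#' @return The original-scale matrix.
#' @export
unstandardize <- function(std) {
  stopifnot(inherits(std, "pclr_standardized"))
  sweep(sweep(std$Xstar, 2, std$column_sds, "*"), 2, std$column_means, "+")
}

#' Per-variable, per-stratum level percentages
#'
#' Tabulates the percentage of respondents per level of each coded variable
#' within each insurance stratum (the sample-composition table layout).
#' Empty strata are omitted with a warning.
#'
#' @param coded A `pclr_coded`.
#' @return Data frame with columns `acronym`, `code` and one percentage
#'   column per non-empty stratum; percentages sum to 100 within each
#'   variable and stratum.
#' @export
marginal_table <- function(coded) {
  stopifnot(inherits(coded, "pclr_coded"), coded$n > 0)
  strata <- levels(coded$stratum)
  counts <- table(coded$stratum)
  empty <- strata[counts[strata] == 0 | is.na(counts[strata])]
  if (length(empty)) {
    warning("empty stratum omitted: ", paste(empty, collapse = ", "))
    strata <- setdiff(strata, empty)
  }
  rows <- list()
  for (acr in coded$predictor_names) {
    lev <- codebook_levels(coded$codebook, acr)
    block <- data.frame(acronym = acr, code = lev, stringsAsFactors = FALSE)
    for (s in strata) {
      xs <- coded$X[coded$stratum == s, acr]
      block[[s]] <- 100 * vapply(lev, function(l) mean(xs == l), numeric(1))
    }
    rows[[acr]] <- block
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
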