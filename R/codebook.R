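#' Survey codebook
#'
#' A codebook declares every variable the pipeline understands: its role
#' (predictor, outcome or stratifier), the small-integer level codes a raw
#' file may contain, a human label and good/bad/neutral interpretation per
#' level, and the referent level used when odds ratios are reported.
#'
#' @param variables A list of variable descriptors, each a list with elements
#'   `name`, `acronym`, `role` (one of `"predictor"`, `"outcome"`,
#'   `"stratifier"`), `levels` (data frame with columns `code`, `label`,
#'   `interpretation`) and, for predictors, `referent_code`.
#' @return An object of class `pclr_codebook`.
#' @seealso [default_codebook()] for the bundled BRFSS-style codebook.
#' @export
codebook <- function(variables) {
  stopifnot(is.list(variables), length(variables) > 0)
  acr <- vapply(variables, function(v) v$acronym, character(1))
  if (anyDuplicated(acr)) {
    stop("duplicate acronyms in codebook: ",
         paste(unique(acr[duplicated(acr)]), collapse = ", "))
  }
  roles <- vapply(variables, function(v) v$role, character(1))
  if (!all(roles %in% c("predictor", "outcome", "stratifier"))) {
    stop("unknown role in codebook")
  }
  if (sum(roles == "outcome") != 1L) {
    stop("codebook must declare exactly one outcome variable")
  }
  for (v in variables) {
    lv <- v$levels
    stopifnot(is.data.frame(lv), all(c("code", "label", "interpretation") %in% names(lv)))
    if (anyDuplicated(lv$code)) {
      stop("duplicate level codes for variable ", v$acronym)
    }
    if (identical(v$role, "predictor")) {
      if (is.null(v$referent_code) || !(v$referent_code %in% lv$code)) {
        stop("predictor ", v$acronym, " lacks a declared referent level")
      }
    }
  }
  names(variables) <- acr
  structure(list(variables = variables), class = "pclr_codebook")
}

cb_var <- function(acronym, name, role, codes, labels, interp,
                   referent = if (role == "predictor") codes[1] else NULL) {
  list(name = name, acronym = acronym, role = role,
       levels = data.frame(code = as.integer(codes), label = labels,
                           interpretation = interp, stringsAsFactors = FALSE),
       referent_code = referent)
}

#' Default BRFSS-style codebook
#'
#' The bundled codebook mirrors the variable table of the published Texas
#' insurance-strata analysis: a binary self-reported health-status outcome
#' (1 = good, 0 = fair/poor), seven health-condition indicators, demographic
#' codes (4-level age structure, sex, 4-level race, marital status), economic
#' condition codes (employment, living with dependent children) and a 3-level
#' education code. Referents follow the published odds-ratio tables: code 1
#' throughout (no-barrier / youngest age band / college graduate / married).
#'
#' @return A `pclr_codebook`.
#' @export
default_codebook <- function() {
  yn <- function(acr, name, good_first = TRUE) {
    cb_var(acr, name, "predictor", c(1L, 2L),
           c("No", "Yes"),
           if (good_first) c("good", "bad") else c("bad", "good"))
  }
  codebook(list(
    yn("NRC", "No regular source of care"),
    yn("LCT", "Last check-up more than a year ago"),
    yn("NSD", "Could not see a doctor due to cost"),
    yn("SMC", "Skipped medication due to cost"),
    cb_var("CVD", "Cardiovascular disease", "predictor", c(1L, 2L),
           c("Yes", "No"), c("bad", "good")),
    cb_var("DT", "Diabetes", "predictor", c(1L, 2L),
           c("Yes", "No"), c("bad", "good")),
    yn("CS", "Current smoker"),
    cb_var("AS", "Age structure", "predictor", 1:4,
           c("<=25", "25-44", "44-55", ">55"), rep("neutral", 4)),
    cb_var("SEX", "Sex", "predictor", c(1L, 2L),
           c("Male", "Female"), c("neutral", "neutral")),
    cb_var("RACE", "Race/ethnicity", "predictor", 1:4,
           c("White", "Hispanic", "Black", "Other"), rep("neutral", 4)),
    cb_var("EM", "Employment", "predictor", c(1L, 2L),
           c("Yes", "No"), c("good", "bad")),
    yn("LDC", "Living with dependent children"),
    cb_var("ED", "Education", "predictor", 1:3,
           c("College graduate", "High school graduate/GED",
             "Did not finish high school"), rep("neutral", 3)),
    cb_var("MS", "Marital status", "predictor", c(1L, 2L),
           c("Married", "Single"), c("neutral", "neutral")),
    cb_var("HS", "Health status", "outcome", c(0L, 1L),
           c("Fair/poor", "Good"), c("bad", "good"))
  ))
}

#' @export
print.pclr_codebook <- function(x, ...) {
  roles <- vapply(x$variables, function(v) v$role, character(1))
  cat("<pclr_codebook> ", length(x$variables), " variables (",
      sum(roles == "predictor"), " predictors, outcome: ",
      names(x$variables)[roles == "outcome"], ")\n", sep = "")
  invisible(x)
}

#' Names of predictor variables in a codebook
#' @param cb A `pclr_codebook`.
#' @return Character vector of predictor acronyms, in codebook order.
#' @export
predictor_names <- function(cb) {
  stopifnot(inherits(cb, "pclr_codebook"))
  roles <- vapply(cb$variables, function(v) v$role, character(1))
  names(cb$variables)[roles == "predictor"]
}

outcome_name <- function(cb) {
  roles <- vapply(cb$variables, function(v) v$role, character(1))
  names(cb$variables)[roles == "outcome"]
}

codebook_levels <- function(cb, acronym) cb$variables[[acronym]]$levels$code

codebook_referent <- function(cb, acronym) cb$variables[[acronym]]$referent_code
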