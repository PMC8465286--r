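#' Pipeline configuration
#'
#' @param input Path to a survey CSV/TSV, or `NULL` to simulate.
#' @param generator A [generator_config()] used when simulating.
#' @param retained Explicit retained-variable override for the component
#'   stage; default the published nine. Set `NULL` to let the correlation
#'   screen decide.
#' @param alpha Significance level for screens and stars.
#' @param eigen_threshold Eigenvalue retention threshold.
#' @param loading_cutoff Loading-interpretation cutoff.
#' @param communality_cutoff Communality warning cutoff.
#' @param class_threshold Classification probability threshold.
#' @param pca_mode `"pooled"` (one extraction on the pooled sample, default)
#'   or `"per_stratum"`.
#' @param out_dir Output directory for the TSV artifacts.
#' @param seed Seed for the simulate path (overrides the generator's).
#' @param verbosity 0 (quiet), 1 (stage lines), 2 (chatty).
#' @return A `pclr_config` list.
#' @export
pipeline_config <- function(input = NULL, generator = generator_config(),
                            retained = reference_retained_predictors(),
                            alpha = 0.05, eigen_threshold = 1,
                            loading_cutoff = 0.7, communality_cutoff = 0.7,
                            class_threshold = 0.6,
                            pca_mode = c("pooled", "per_stratum"),
                            out_dir = tempfile("pclr_run_"), seed = NULL,
                            verbosity = 1) {
  pca_mode <- match.arg(pca_mode)
  stopifnot(alpha > 0, alpha < 1, class_threshold > 0, class_threshold < 1,
            eigen_threshold >= 0, loading_cutoff >= 0)
  if (!is.null(seed)) generator$seed <- seed
  structure(list(input = input, generator = generator, retained = retained,
                 alpha = alpha, eigen_threshold = eigen_threshold,
                 loading_cutoff = loading_cutoff,
                 communality_cutoff = communality_cutoff,
                 class_threshold = class_threshold, pca_mode = pca_mode,
                 out_dir = out_dir, verbosity = verbosity),
            class = "pclr_config")
}

say <- function(cfg, level, ...) {
  if (cfg$verbosity >= level) message(...)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the published order — load or simulate, correlation
#' screen, adequacy diagnostics, component extraction with varimax rotation,
#' the four logistic scenarios per stratum, and the t-/F-test validation —
#' writing TSV artifacts and a JSON run manifest to the output directory.
#' A degenerate fit in one stratum downgrades to flagged rows; any other
#' stage failure aborts with a stage-tagged error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pclr_run` list with every stage result and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pclr_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    say(config, 1, "stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    list(value = val, elapsed = proc.time()[["elapsed"]] - t0)
  }
  timings <- list()

  s <- stage("load", {
    survey <- if (is.null(config$input)) generate_cohort(config$generator)
              else load_survey(config$input)
    list(survey = survey, coded = recode(survey))
  })
  survey <- s$value$survey; coded <- s$value$coded
  timings$load <- s$elapsed

  s <- stage("screen", {
    std_all <- standardize(coded)
    sc <- pearson_matrix(std_all, coded$y)
    sc <- tryCatch(screen_predictors(sc, alpha = config$alpha),
                   error = function(e) {
                     if (is.null(config$retained)) stop(e)
                     warning("correlation screen degenerate (",
                             conditionMessage(e),
                             "); falling back to the retained-variable override")
                     sc
                   })
    list(std = std_all, screen = sc, outcome = outcome_screen(sc, config$alpha))
  })
  screen <- s$value$screen; std_all <- s$value$std
  timings$screen <- s$elapsed
  retained <- if (!is.null(config$retained)) config$retained else screen$retained
  say(config, 1, "retained predictors: ", paste(retained, collapse = ", "))

  s <- stage("pca", {
    coded9 <- coded
    coded9$X <- coded$X[, retained, drop = FALSE]
    coded9$predictor_names <- retained
    std9 <- standardize(coded9)
    adeq <- tryCatch(adequacy(stats::cor(std9$Xstar), coded$n),
                     error = function(e) {
                       warning("adequacy diagnostics unavailable: ",
                               conditionMessage(e))
                       NULL
                     })
    model <- extract_components(std9, config$eigen_threshold)
    if (model$r > 1) model <- varimax_rotate(model)
    h2 <- suppressWarnings(communalities(model, config$communality_cutoff))
    structure_map <- interpret_loadings(model, config$loading_cutoff)
    list(coded9 = coded9, std9 = std9, adequacy = adeq, model = model,
         communalities = h2, structure = structure_map)
  })
  pca <- s$value; timings$pca <- s$elapsed

  s <- stage("scenarios", {
    strata <- levels(droplevels(coded$stratum))
    res <- list(); notes <- character()
    for (st in strata) {
      c9 <- subset_stratum(pca$coded9, st)
      setup <- tryCatch({
        std_s <- standardize(c9)
        model_s <- if (config$pca_mode == "pooled") pca$model else {
          m <- extract_components(std_s, config$eigen_threshold)
          if (m$r > 1) varimax_rotate(m) else m
        }
        list(std = std_s, model = model_s)
      }, error = function(e) e)
      for (sc_name in scenario_names) {
        r <- if (inherits(setup, "error")) {
          # whole stratum degenerate (e.g. constant column in a tiny stratum)
          notes <- c(notes, sprintf("%s/%s: %s", st, sc_name,
                                    conditionMessage(setup)))
          blk <- do.call(rbind, lapply(c9$predictor_names, function(acr)
            degenerate_block(c9, acr, st, sc_name)))
          class(blk) <- c("pclr_scenario", class(blk))
          blk
        } else {
          run_scenario(c9, setup$std, setup$model, sc_name)
        }
        notes <- c(notes, attr(r, "warnings"))
        res[[paste(st, sc_name, sep = ".")]] <- r
      }
    }
    list(results = res, notes = notes)
  })
  scenarios <- s$value; timings$scenarios <- s$elapsed

  s <- stage("validate", {
    sc <- component_scores(pca$std9, pca$model)
    validate_factors(sc, pca$coded9$y, config$alpha)
  })
  validation <- s$value; timings$validate <- s$elapsed

  s <- stage("report", {
    run <- list(coded = coded, screen = screen, pca = pca,
                scenarios = scenarios, validation = validation,
                config = config)
    render_tables(run, config$out_dir)
  })
  timings$report <- s$elapsed

  manifest <- list(
    stages = names(timings),
    timings = lapply(timings, function(x) round(x, 3)),
    seed = config$generator$seed,
    n = coded$n,
    stratum_counts = as.list(table(coded$stratum)),
    eliminated = screen$eliminated$acronym,
    retained = retained,
    r = pca$model$r,
    degenerate = scenarios$notes,
    r_version = as.character(getRversion()),
    config = list(alpha = config$alpha,
                  eigen_threshold = config$eigen_threshold,
                  loading_cutoff = config$loading_cutoff,
                  communality_cutoff = config$communality_cutoff,
                  class_threshold = config$class_threshold,
                  pca_mode = config$pca_mode))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- structure(list(survey = survey, coded = coded, screen = screen,
                        pca = pca, scenarios = scenarios,
                        validation = validation, manifest = manifest,
                        out_dir = config$out_dir, config = config),
                   class = "pclr_run")
  say(config, 1, "artifacts in ", config$out_dir)
  invisible(out)
}

fmt_or <- function(or, lo, hi, stars, referent, degenerate) {
  ifelse(referent, "1.00 (referent)",
         ifelse(degenerate, "degenerate",
                sprintf("%.2f [%.2f, %.2f] %s", or, lo, hi, stars)))
}

#' Render pipeline results as TSV files
#'
#' Writes the published-table analogues: category marginals, correlation
#' screen, eigenvalue table, rotated component matrix (Extraction column plus
#' one column per component), adequacy report, per-stratum and combined
#' scenario odds-ratio tables ("1.00 (referent)" rows, "OR \[low, high\]"
#' cells, star annotations), and t-/F-test validation tables.
#'
#' @param run A list with the stage results (as assembled by
#'   [run_pipeline()]).
#' @param out_dir Output directory.
#' @return Character vector of files written.
#' @export
render_tables <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(x, name, row_names = FALSE) {
    path <- file.path(out_dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = row_names,
                       col.names = if (row_names) NA else TRUE)
    files <<- c(files, path)
  }
  wr(marginal_table(run$coded), "marginals.tsv")
  wr(format_correlation_table(run$screen), "correlations.tsv", TRUE)
  model <- run$pca$model
  wr(data.frame(component = seq_along(model$eigenvalues),
                eigenvalue = round(model$eigenvalues, 4),
                cumulative = round(cumsum(model$eigenvalues) /
                                     length(model$eigenvalues), 4)),
     "eigenvalues.tsv")
  rot <- data.frame(acronym = model$names,
                    extraction = round(run$pca$communalities, 3),
                    round(model$rotated_loadings, 3),
                    stringsAsFactors = FALSE)
  wr(rot, "rotated_components.tsv")
  ad <- run$pca$adequacy
  wr(data.frame(statistic = c("kmo_overall", "bartlett_chi2", "bartlett_df",
                              "bartlett_p"),
                value = if (is.null(ad)) rep(NA_real_, 4) else
                  c(ad$kmo_overall, ad$bartlett_chi2, ad$bartlett_df,
                    ad$bartlett_p)),
     "adequacy.tsv")
  all_rows <- list()
  for (nm in names(run$scenarios$results)) {
    r <- run$scenarios$results[[nm]]
    if (!nrow(r)) {
      warning("empty scenario ", nm)
    }
    tab <- data.frame(variable = r$acronym, level = r$label, n = r$n,
                      percent = sprintf("%.1f%%", r$percent),
                      `OR (95% CI)` = fmt_or(r$or, r$ci_low, r$ci_high,
                                             r$stars, r$referent, r$degenerate),
                      check.names = FALSE, stringsAsFactors = FALSE)
    wr(tab, paste0("scenario_", nm, ".tsv"))
    all_rows[[nm]] <- r
  }
  wr(do.call(rbind, c(all_rows, list(make.row.names = FALSE))),
     "scenarios_combined.tsv")
  v <- run$validation$table
  v[c("t", "df", "p", "ci_low", "ci_high", "F", "F_p")] <-
    lapply(v[c("t", "df", "p", "ci_low", "ci_high", "F", "F_p")],
           function(x) round(x, 4))
  wr(v, "validation.tsv")
  lt <- do.call(rbind, lapply(names(run$validation$f_tests), function(nm) {
    d <- run$validation$f_tests[[nm]]$linear_term
    cbind(component = nm, d)
  }))
  num <- vapply(lt, is.numeric, logical(1))
  lt[num] <- lapply(lt[num], function(x) round(x, 4))
  wr(lt, "f_linear_term.tsv")
  files
}

#' Summarize a pipeline run
#'
#' Prints stage timings, eliminated variables, retained components and any
#' degenerate-fit warnings; a single line at verbosity 0.
#'
#' @param run A `pclr_run` (or its manifest list).
#' @param verbosity 0 for one line, 1+ for the full summary.
#' @return The manifest, invisibly.
#' @export
summarize_run <- function(run, verbosity = 1) {
  m <- if (inherits(run, "pclr_run")) run$manifest else run
  if (verbosity < 1) {
    cat(sprintf("pclr run: n = %d, r = %d, %d degenerate block(s)\n",
                m$n, m$r, length(m$degenerate)))
    return(invisible(m))
  }
  cat("pclr pipeline run\n")
  cat("  n =", m$n, "; strata:",
      paste(names(m$stratum_counts), unlist(m$stratum_counts),
            sep = "=", collapse = ", "), "\n")
  cat("  stage timings (s):",
      paste(names(m$timings), unlist(m$timings), sep = "=", collapse = ", "), "\n")
  cat("  eliminated by screen:",
      if (length(m$eliminated)) paste(m$eliminated, collapse = ", ") else "none", "\n")
  cat("  retained predictors:", paste(m$retained, collapse = ", "), "\n")
  cat("  retained components:", m$r, "\n")
  if (length(m$degenerate)) {
    cat("  degenerate fits:\n")
    for (d in m$degenerate) cat("    -", d, "\n")
  }
  invisible(m)
}

#' @export
print.pclr_run <- function(x, ...) {
  summarize_run(x)
  invisible(x)
}
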