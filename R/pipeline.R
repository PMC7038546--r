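#' Fit the diabetes-type algorithm-selection procedure
#'
#' The package's top-level fitting function.  Starting from raw event
#' tables and reference labels it (1) builds the cohort
#' ([build_cohort()]), (2) randomises it 2:1 into derivation and
#' validation sets ([randomize_split()]), (3) screens every candidate code
#' and prescription rule on the derivation cohort and picks the letters
#' A--D ([select_algorithms()]), (4) evaluates the twelve single and
#' combination algorithms on the derivation cohort and identifies the
#' highest-sensitivity, highest-PPV and highest-kappa ("optimized")
#' algorithms, and (5) reports age-stratified test characteristics of the
#' three headline algorithms on the held-out validation cohort.
#'
#' @param tables an [event_tables] object.
#' @param labels reference labels (default `tables$labels`).
#' @param cfg an [onset_config()].
#' @param seed integer seed for the derivation/validation split.
#' @param fraction_derivation expected derivation fraction.
#' @param strata age-at-diagnosis cut points for the validation report.
#' @param candidates candidate rule set (default [candidate_registry()]).
#' @return an object of class `dm_select` with components `cohort`,
#'   `selection`, `candidate_metrics`, `derivation_metrics`,
#'   `validation`, `specs` (the three headline [algorithm_spec]s by role),
#'   `cfg` and `seed`.
#' @seealso [predict.dm_select()], [plot.dm_select()]
#' @examples
#' \donttest{
#' sim <- generate_ehr(synthetic_config(n_persons = 3000, seed = 7))
#' fit <- dm_select(sim$tables, seed = 7)
#' fit
#' }
#' @export
dm_select <- function(tables, labels = tables$labels, cfg = onset_config(),
                      seed = 1, fraction_derivation = 2 / 3,
                      strata = c(20, 40), candidates = candidate_registry()) {
  cohort <- build_cohort(tables, labels, cfg)
  cohort <- randomize_split(cohort, seed, fraction_derivation)
  deriv <- cohort[cohort$split == "derivation", , drop = FALSE]
  valid <- cohort[cohort$split == "validation", , drop = FALSE]
  if (!nrow(deriv) || !sum(deriv$true_type == "T1D")) {
    stop("derivation cohort has no T1D cases; cannot select algorithms",
         call. = FALSE)
  }

  cand_metrics <- evaluate_algorithms(tables, deriv, candidates, cfg)
  letters <- select_algorithms(cand_metrics)

  singles <- list(A = candidates[[letters$A]], B = candidates[[letters$B]],
                  C = candidates[[letters$C]], D = candidates[[letters$D]])
  twelve <- singles
  for (cn in c("A", "B")) for (rn in c("C", "D")) for (op in c("and", "or")) {
    nm <- paste(cn, op, rn, sep = "_")
    twelve[[nm]] <- alg_combo(singles[[cn]], singles[[rn]], op, name = nm)
  }
  deriv_metrics <- evaluate_algorithms(tables, deriv, twelve, cfg)
  selection <- select_algorithms(cand_metrics, deriv_metrics)

  specs <- list(high_sensitivity_t1 = twelve[[selection$best_sensitivity]],
                high_ppv_t1 = twelve[[selection$best_ppv]],
                optimized = twelve[[selection$best_kappa]])
  calls <- lapply(specs, function(s) classify(tables, valid, s, cfg))
  validation <- if (nrow(valid)) evaluate_stratified(valid, calls, strata)
                else NULL

  structure(list(cohort = cohort, selection = selection,
                 candidate_metrics = cand_metrics,
                 derivation_metrics = deriv_metrics,
                 validation = validation, specs = specs, twelve = twelve,
                 cfg = cfg, seed = seed, strata = strata,
                 tables = tables), class = "dm_select")
}

#' @export
print.dm_select <- function(x, ...) {
  cat("Diabetes-type algorithm selection\n")
  cat(sprintf("  cohort: %d persons (%d derivation / %d validation), seed %d\n",
              nrow(x$cohort),
              sum(x$cohort$split == "derivation"),
              sum(x$cohort$split == "validation"), x$seed))
  print(x$selection)
  invisible(x)
}

#' @export
summary.dm_select <- function(object, ...) {
  structure(list(selection = object$selection,
                 validation = object$validation,
                 cohort_n = nrow(object$cohort),
                 exclusions = attr(object$cohort, "exclusions")),
            class = "summary.dm_select")
}

#' @export
print.summary.dm_select <- function(x, ...) {
  cat(sprintf("Cohort: %d persons; exclusions: %s\n", x$cohort_n,
              paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
                    collapse = ", ")))
  print(x$selection)
  if (!is.null(x$validation)) {
    cat("\nValidation-cohort test characteristics (percent):\n")
    v <- x$validation
    out <- data.frame(
      algorithm = v$algorithm, stratum = v$stratum,
      TP = v$tp, FP = v$fp, FN = v$fn, TN = v$tn,
      sens = round_half_up(v$sensitivity * 100, 1),
      spec = round_half_up(v$specificity * 100, 1),
      ppv = round_half_up(v$ppv * 100, 1),
      npv = round_half_up(v$npv * 100, 1),
      kappa = round_half_up(v$kappa, 2))
    print(out, row.names = FALSE)
  }
  invisible(x)
}

#' Classify new persons with a fitted selection
#'
#' Applies one of the three headline algorithms (or any algorithm evaluated
#' during fitting) to new event tables.
#'
#' @param object a `dm_select` fit.
#' @param tables an [event_tables] object for the new persons (defaults to
#'   the fitting tables).
#' @param cohort a `dm_cohort` for the new persons; built from `tables`
#'   when omitted.
#' @param algorithm `"optimized"` (default), `"high_sensitivity_t1"`,
#'   `"high_ppv_t1"`, or the name of any of the twelve evaluated
#'   algorithms.
#' @param ... unused.
#' @return data frame `person_id`, `call`.
#' @export
predict.dm_select <- function(object, tables = object$tables, cohort = NULL,
                              algorithm = "optimized", ...) {
  spec <- object$specs[[algorithm]]
  if (is.null(spec)) spec <- object$twelve[[algorithm]]
  if (is.null(spec)) stop("unknown algorithm: ", algorithm, call. = FALSE)
  if (is.null(cohort)) {
    cohort <- if (identical(tables, object$tables)) object$cohort
              else build_cohort(tables, cfg = object$cfg)
  }
  classify(tables, cohort, spec, object$cfg)
}

#' Proportion-of-T1D-by-age curves for a fitted selection
#'
#' Plots the smoothed (15-year moving average by default) proportion of
#' diabetes cases classified as T1D against age at diagnosis on the
#' validation cohort, for the reference standard and each headline
#' algorithm.
#'
#' @param x a `dm_select` fit.
#' @param window_years moving-window width.
#' @param ... passed to [graphics::plot()].
#' @return the curves, invisibly (list of data frames).
#' @export
plot.dm_select <- function(x, window_years = 15, ...) {
  valid <- x$cohort[x$cohort$split == "validation", , drop = FALSE]
  curves <- list(reference = proportion_curve(valid, NULL, window_years))
  for (nm in names(x$specs)) {
    calls <- classify(x$tables, valid, x$specs[[nm]], x$cfg)
    curves[[nm]] <- proportion_curve(valid, calls, window_years)
  }
  cols <- c(reference = "black", high_sensitivity_t1 = "#D55E00",
            high_ppv_t1 = "#0072B2", optimized = "#009E73")
  ylim <- c(0, max(vapply(curves, function(d) max(d$proportion), numeric(1))))
  graphics::plot(curves$reference$age, curves$reference$proportion,
                 type = "l", lwd = 2, lty = 2, col = cols["reference"],
                 xlab = "Age at diagnosis (years)",
                 ylab = "Proportion classified T1D", ylim = ylim, ...)
  for (nm in names(x$specs)) {
    graphics::lines(curves[[nm]]$age, curves[[nm]]$proportion,
                    col = cols[nm], lwd = 2)
  }
  graphics::legend("topright", bty = "n", lwd = 2,
                   lty = c(2, 1, 1, 1), col = cols,
                   legend = c("reference standard", names(x$specs)))
  invisible(curves)
}

#' Run the whole pipeline from a configuration list
#'
#' Convenience front end used by the command-line script: simulate (or
#' read) event tables, fit the selection procedure, and optionally write
#' the cohort, per-algorithm calls and a machine-readable JSON report.
#' All randomness flows from the single `seed` entry, and re-running with
#' an identical configuration reproduces identical outputs.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `seed`; either `simulate` (a list of [synthetic_config()] arguments)
#'   or `input_dir` (a directory for [read_event_tables()]); optional
#'   `onset` (list of [onset_config()] arguments), `strata`, and
#'   `output_dir`.
#' @return the `dm_select` fit, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg <- do.call(onset_config, as.list(config$onset))
  tables <- if (!is.null(config$simulate)) {
    sim_args <- as.list(config$simulate)
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    generate_ehr(do.call(synthetic_config, sim_args), cfg)$tables
  } else if (!is.null(config$input_dir)) {
    read_event_tables(config$input_dir)
  } else {
    stop("config needs either 'simulate' or 'input_dir'", call. = FALSE)
  }
  strata <- if (is.null(config$strata)) c(20, 40) else as.numeric(config$strata)
  fit <- dm_select(tables, cfg = cfg, seed = seed, strata = strata)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    cohort_out <- as.data.frame(fit$cohort)
    utils::write.csv(cohort_out, file.path(config$output_dir, "cohort.csv"),
                     row.names = FALSE)
    for (nm in names(fit$specs)) {
      calls <- predict(fit, algorithm = nm)
      utils::write.csv(calls, file.path(config$output_dir,
                                        paste0("calls_", nm, ".csv")),
                       row.names = FALSE)
    }
    report <- list(
      schema_version = "1.0", seed = seed,
      selection = lapply(unclass(fit$selection), identity),
      exclusions = as.list(attr(fit$cohort, "exclusions")),
      derivation_metrics = fit$derivation_metrics,
      validation = fit$validation)
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(fit)
}
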