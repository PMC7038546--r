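#' Cross-tabulate algorithm calls against reference labels
#'
#' Builds the 2x2 confusion matrix with T1D as the positive class:
#' `tp` = call T1D and label T1D, `fp` = call T1D and label T2D,
#' `fn` = call T2D and label T1D, `tn` = call T2D and label T2D.
#'
#' @param calls data frame `person_id`, `call` from [classify()].
#' @param labels data frame `person_id`, `true_type` with binary labels
#'   covering every called person (a called person without a label is an
#'   error).
#' @param positive the positive class (default `"T1D"`).
#' @return a `confusion_matrix` object (fields `tp`, `fp`, `fn`, `tn`).
#' @export
confusion <- function(calls, labels, positive = "T1D") {
  if (!nrow(calls)) stop("no calls to evaluate", call. = FALSE)
  truth <- labels$true_type[match(calls$person_id, labels$person_id)]
  if (anyNA(truth)) {
    stop("persons with a call but no label: ",
         paste(utils::head(calls$person_id[is.na(truth)], 5), collapse = ", "),
         call. = FALSE)
  }
  pos_call <- calls$call == positive
  pos_true <- truth == positive
  confusion_matrix(sum(pos_call & pos_true), sum(pos_call & !pos_true),
                   sum(!pos_call & pos_true), sum(!pos_call & !pos_true))
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative cell counts (total >= 1).
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn >= 1)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(call = c("T1D", "T2D"), truth = c("T1D", "T2D")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The equal-tailed exact interval obtained by inverting binomial tests,
#' in its beta-quantile form: the lower bound is the 2.5% quantile of
#' `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper bound the 97.5%
#' quantile of `Beta(x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of successes, `0 <= x <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` on the proportion scale.
#' @examples
#' round(exact_ci(41, 43) * 100, 1)  # 84.2 99.4
#' @export
exact_ci <- function(x, n, level = 0.95) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  stopifnot(x >= 0, x <= n, level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Cohen's kappa for a 2x2 confusion matrix
#'
#' Chance-corrected agreement between the algorithm and the reference
#' standard: `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (tp + tn) / N` and chance agreement
#' `p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / N^2`.  When both raters are
#' constant (`p_e = 1`) the statistic is defined as 1 if agreement is
#' perfect and 0 otherwise.  The formula is symmetric in the choice of
#' positive class.
#'
#' @param cm a `confusion_matrix`.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  fn <- as.numeric(cm$fn); tn <- as.numeric(cm$tn)
  n <- tp + fp + fn + tn
  stopifnot(n >= 1)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# display rounding: half-up (matching how the source tables round), not
# banker's rounding
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Test characteristics of a confusion matrix
#'
#' Sensitivity, specificity, PPV and NPV, each with an exact 95% (by
#' default) Clopper-Pearson interval, plus Cohen's kappa and the calculated
#' and true positive-class proportions.  Metrics with a zero denominator
#' are `NA` (reported as undefined, never as an error).  Two PPV-undefined
#' conventions exist: the default `"tp_zero"` marks PPV undefined whenever
#' no true positive was identified (even if `fp > 0`, so 0/1 displays as
#' undefined); `"standard"` only when `tp + fp = 0`.
#'
#' @param cm a `confusion_matrix`.
#' @param level confidence level.
#' @param ppv_convention `"tp_zero"` or `"standard"`.
#' @return a `test_characteristics` object: for each metric a
#'   `c(est, lower, upper)` proportion triple, plus `kappa`, `ppv_defined`,
#'   `calculated_t1_proportion`, `true_t1_proportion` and the original
#'   counts.
#' @export
characteristics <- function(cm, level = 0.95,
                            ppv_convention = c("tp_zero", "standard")) {
  ppv_convention <- match.arg(ppv_convention)
  metric <- function(x, n) {
    if (n == 0) return(c(est = NA_real_, lower = NA_real_, upper = NA_real_))
    c(est = x / n, exact_ci(x, n, level))
  }
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  ppv_defined <- if (ppv_convention == "tp_zero") cm$tp > 0 else cm$tp + cm$fp > 0
  structure(list(
    sensitivity = metric(cm$tp, cm$tp + cm$fn),
    specificity = metric(cm$tn, cm$tn + cm$fp),
    ppv = if (ppv_defined) metric(cm$tp, cm$tp + cm$fp)
          else c(est = NA_real_, lower = NA_real_, upper = NA_real_),
    npv = metric(cm$tn, cm$tn + cm$fn),
    kappa = cohen_kappa(cm),
    ppv_defined = ppv_defined,
    calculated_t1_proportion = (cm$tp + cm$fp) / n,
    true_t1_proportion = (cm$tp + cm$fn) / n,
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
    level = level
  ), class = "test_characteristics")
}

fmt_pct <- function(triple) {
  if (is.na(triple[["est"]])) return("undefined")
  sprintf("%.1f (%.1f, %.1f)",
          round_half_up(triple[["est"]] * 100, 1),
          round_half_up(triple[["lower"]] * 100, 1),
          round_half_up(triple[["upper"]] * 100, 1))
}

#' @export
print.test_characteristics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat("  sensitivity:", fmt_pct(x$sensitivity), "\n")
  cat("  specificity:", fmt_pct(x$specificity), "\n")
  cat("  PPV:        ", fmt_pct(x$ppv), "\n")
  cat("  NPV:        ", fmt_pct(x$npv), "\n")
  cat(sprintf("  kappa: %.2f\n", round_half_up(x$kappa, 2)))
  cat(sprintf("  T1D proportion: calculated %.1f%%, true %.1f%%\n",
              round_half_up(x$calculated_t1_proportion * 100, 1),
              round_half_up(x$true_t1_proportion * 100, 1)))
  invisible(x)
}

stratum_labels <- function(edges) {
  edges <- sort(edges)
  labs <- c(paste0("<", edges[1]))
  if (length(edges) > 1) {
    labs <- c(labs, paste0(edges[-length(edges)], "-", edges[-1] - 1))
  }
  c("all", labs, paste0(">=", edges[length(edges)]))
}

#' Age-stratified test characteristics
#'
#' Evaluates one or more algorithms' calls against the cohort labels in the
#' whole cohort ("all") and within age-at-diagnosis strata.  Default strata
#' edges `c(20, 40)` give `<20`, `20-39` and `>=40` years.  The stratified
#' matrices partition the all-ages matrix; an empty stratum yields a row of
#' undefined metrics rather than an error.
#'
#' @param cohort a `dm_cohort` with `age_at_diagnosis` and `true_type`.
#' @param calls a calls data frame from [classify()], or a named list of
#'   them (one per algorithm).
#' @param strata numeric vector of age cut points.
#' @param ... passed to [characteristics()].
#' @return data frame with one row per (algorithm, stratum): counts,
#'   point estimates, CI bounds, kappa and the T1D proportions (all on the
#'   proportion scale).
#' @export
evaluate_stratified <- function(cohort, calls, strata = c(20, 40), ...) {
  if (is.data.frame(calls)) calls <- list(algorithm = calls)
  edges <- sort(strata)
  labs <- stratum_labels(edges)
  bins <- cut(cohort$age_at_diagnosis, breaks = c(-Inf, edges, Inf),
              labels = labs[-1], right = FALSE)
  rows <- list()
  for (alg in names(calls)) {
    cl <- calls[[alg]]
    for (st in labs) {
      ids <- if (st == "all") cohort$person_id else cohort$person_id[bins == st]
      sub <- cl[cl$person_id %in% ids, , drop = FALSE]
      if (!nrow(sub)) {
        rows[[length(rows) + 1]] <- data.frame(
          algorithm = alg, stratum = st, tp = 0L, fp = 0L, fn = 0L, tn = 0L,
          sensitivity = NA_real_, sens_lower = NA_real_, sens_upper = NA_real_,
          specificity = NA_real_, spec_lower = NA_real_, spec_upper = NA_real_,
          ppv = NA_real_, ppv_lower = NA_real_, ppv_upper = NA_real_,
          npv = NA_real_, npv_lower = NA_real_, npv_upper = NA_real_,
          kappa = NA_real_, calculated_t1_proportion = NA_real_,
          true_t1_proportion = NA_real_, stringsAsFactors = FALSE)
        next
      }
      cm <- confusion(sub, cohort)
      ch <- characteristics(cm, ...)
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = alg, stratum = st, tp = cm$tp, fp = cm$fp, fn = cm$fn,
        tn = cm$tn,
        sensitivity = ch$sensitivity[["est"]],
        sens_lower = ch$sensitivity[["lower"]], sens_upper = ch$sensitivity[["upper"]],
        specificity = ch$specificity[["est"]],
        spec_lower = ch$specificity[["lower"]], spec_upper = ch$specificity[["upper"]],
        ppv = ch$ppv[["est"]],
        ppv_lower = ch$ppv[["lower"]], ppv_upper = ch$ppv[["upper"]],
        npv = ch$npv[["est"]],
        npv_lower = ch$npv[["lower"]], npv_upper = ch$npv[["upper"]],
        kappa = ch$kappa,
        calculated_t1_proportion = ch$calculated_t1_proportion,
        true_t1_proportion = ch$true_t1_proportion, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smoothed proportion of T1D calls by age at diagnosis
#'
#' For each integer age on the grid, the proportion of cohort members whose
#' age at diagnosis lies in the centred moving window
#' `[a - w/2, a + w/2]` (default 15-year window) that are classified -- or
#' labelled -- T1D.  Windows are truncated at the cohort age range and grid
#' ages with empty windows are omitted.
#'
#' @param cohort a `dm_cohort`.
#' @param calls a calls data frame from [classify()], or `NULL` to use the
#'   reference labels.
#' @param window_years moving-window width in years (>= 1).
#' @return data frame `age`, `proportion`, `n` (window size).
#' @export
proportion_curve <- function(cohort, calls = NULL, window_years = 15) {
  stopifnot(window_years >= 1)
  if (!nrow(cohort)) {
    return(data.frame(age = numeric(0), proportion = numeric(0), n = integer(0)))
  }
  t1d <- if (is.null(calls)) {
    cohort$true_type == "T1D"
  } else {
    calls$call[match(cohort$person_id, calls$person_id)] == "T1D"
  }
  age <- cohort$age_at_diagnosis
  half <- window_years / 2
  grid <- seq(floor(min(age)), ceiling(max(age)))
  rows <- lapply(grid, function(a) {
    sel <- age >= a - half & age <= a + half
    n <- sum(sel)
    if (!n) return(NULL)
    data.frame(age = a, proportion = mean(t1d[sel]), n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
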