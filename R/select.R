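#' Evaluate a set of algorithms on a cohort (all ages)
#'
#' Classifies every cohort member with each spec and summarises the
#' resulting confusion matrix.  The output rows carry the spec's family and
#' window metadata so they can be fed straight into [select_algorithms()].
#'
#' @param tables an [event_tables] object.
#' @param cohort a `dm_cohort`.
#' @param specs named list of [algorithm_spec] objects.
#' @param cfg an [onset_config()].
#' @return data frame: `name`, `kind`, `family`, `window_days`, `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `ppv`, `kappa` (proportion scale, unrounded).
#' @export
evaluate_algorithms <- function(tables, cohort, specs, cfg = onset_config()) {
  rows <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    cm <- confusion(classify(tables, cohort, spec, cfg), cohort)
    data.frame(
      name = nm, kind = spec$kind,
      family = if (is.null(spec$family)) NA_character_ else spec$family,
      window_days = if (identical(spec$kind, "rx")) spec$window_days else NA_real_,
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
      sensitivity = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_,
      ppv = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_,
      kappa = cohen_kappa(cm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# argmax with the published tiebreak: primary metric, then greatest
# sensitivity + PPV, then input order
pick_best <- function(df, metric, eps = 1e-9) {
  m <- df[[metric]]
  ok <- !is.na(m)
  if (!any(ok)) stop("no defined '", metric, "' among candidates", call. = FALSE)
  df <- df[ok, , drop = FALSE]; m <- m[ok]
  tied <- which(m >= max(m) - eps)
  if (length(tied) > 1) {
    s <- df$sensitivity[tied] + ifelse(is.na(df$ppv[tied]), 0, df$ppv[tied])
    tied <- tied[which(s >= max(s) - eps)]
  }
  df$name[tied[1]]
}

#' The derivation-cohort algorithm-selection procedure
#'
#' Reproduces the published two-stage selection.  Stage 1 screens the
#' candidate code and prescription rules separately: `A`/`C` are the
#' highest-sensitivity code/prescription rules and `B`/`D` the highest-PPV
#' ones, with ties resolved by the greatest sum of sensitivity and PPV.
#' Within the sensitivity arm, prescription candidates that are time-window
#' variants of the same rule family and sit within one reference-positive
#' case of the family's best sensitivity are treated as tied and resolved
#' by the same sum -- a single extra case should not decide between
#' otherwise equivalent windows of one rule, and this prefers the window
#' with better PPV.  Code rules have no window axis, so their ties stay
#' strict.  Stage 2 takes the metrics of the twelve single and combination
#' algorithms and returns the arg-max by sensitivity, by PPV and by kappa
#' (the "optimized" pick), each with the same tiebreak and residual ties
#' broken by input order.  The procedure is a pure function of its input
#' metrics.
#'
#' @param candidates metrics for all candidate rules (one row each), as
#'   produced by [evaluate_algorithms()] on the candidate registry: columns
#'   `name`, `kind` (`"code_count"`/`"code_ratio"`/`"rx"`), `family`,
#'   `window_days`, `tp`, `fn`, `sensitivity`, `ppv` (proportion scale).
#' @param combos metrics for the twelve evaluated algorithms (`A` ... `D`
#'   and the eight pairings): columns `name`, `sensitivity`, `ppv`,
#'   `kappa`.  When `NULL`, only the stage-1 letters are returned.
#' @return an `algorithm_selection` list: `A`, `B`, `C`, `D` and (when
#'   `combos` is given) `best_sensitivity`, `best_ppv`, `best_kappa`, each
#'   a candidate name.
#' @export
select_algorithms <- function(candidates, combos = NULL) {
  stopifnot(all(c("name", "kind", "sensitivity", "ppv") %in% names(candidates)))
  code <- candidates[candidates$kind %in% c("code_count", "code_ratio"), , drop = FALSE]
  rx <- candidates[candidates$kind == "rx", , drop = FALSE]
  if (!nrow(code) || !nrow(rx)) {
    stop("candidates must include both code and prescription algorithms",
         call. = FALSE)
  }

  sel <- list(
    A = pick_best(code, "sensitivity"),
    B = pick_best(code, "ppv"),
    C = pick_best(pool_window_ties(rx), "sensitivity"),
    D = pick_best(rx, "ppv")
  )
  if (!is.null(combos)) {
    sel$best_sensitivity <- pick_best(combos, "sensitivity")
    sel$best_ppv <- pick_best(combos, "ppv")
    sel$best_kappa <- pick_best(combos, "kappa")
  }
  structure(sel, class = "algorithm_selection")
}

# lift window variants of the strict-best rx family that lie within one
# positive case of its sensitivity up to that sensitivity, so pick_best
# treats them as tied and applies the sens+PPV tiebreak
pool_window_ties <- function(rx, eps = 1e-9) {
  best <- which.max(rx$sensitivity)
  tol <- if (all(c("tp", "fn") %in% names(rx)) &&
             is.finite(rx$tp[best] + rx$fn[best]) &&
             rx$tp[best] + rx$fn[best] > 0) {
    1 / (rx$tp[best] + rx$fn[best])
  } else 0
  if (tol > 0 && !is.na(rx$family[best])) {
    pool <- !is.na(rx$family) & rx$family == rx$family[best] &
      rx$sensitivity >= rx$sensitivity[best] - tol - eps
    rx$sensitivity[pool] <- max(rx$sensitivity[pool])
  }
  rx
}

#' @export
print.algorithm_selection <- function(x, ...) {
  cat("Selected algorithms\n")
  cat("  A (code, highest sensitivity):", x$A, "\n")
  cat("  B (code, highest PPV):        ", x$B, "\n")
  cat("  C (rx, highest sensitivity):  ", x$C, "\n")
  cat("  D (rx, highest PPV):          ", x$D, "\n")
  if (!is.null(x$best_sensitivity)) {
    cat("  high sensitivity for T1D:", x$best_sensitivity, "\n")
    cat("  high PPV for T1D:        ", x$best_ppv, "\n")
    cat("  optimized (kappa):       ", x$best_kappa, "\n")
  }
  invisible(x)
}
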