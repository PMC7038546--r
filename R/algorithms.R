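#' @name algorithm_spec
#' @title Declarative classification-rule specifications
#'
#' @description
#' An `algorithm_spec` describes one deterministic T1D/T2D classification
#' rule.  Four kinds exist:
#'
#' * `alg_code_count(code_class, source, min_count)` -- positive when the
#'   person has at least `min_count` post-diagnosis encounter codes of the
#'   given class (`type1`/`type2`), optionally restricted to `principal` or
#'   `mixed` sources.
#' * `alg_code_ratio(threshold)` -- positive when the ratio of type 1 to
#'   type 2 codes meets the threshold.  With zero type 2 codes the ratio is
#'   treated as infinite, so the rule is positive whenever at least one
#'   type 1 code exists, and negative when the person has no typed codes at
#'   all.
#' * `alg_rx(variant, window_days)` -- insulin/prescription rules, see
#'   [rx_positive()] for the variant semantics.  `window_days = Inf` means
#'   all follow-up.
#' * `alg_combo(left, right, op)` -- boolean `and`/`or` pairing of two
#'   non-combo rules (single pairing depth).
#'
#' A positive rule classifies the person as T1D, negative as T2D; rules are
#' total and never abstain.
#'
#' @param code_class `"type1"` or `"type2"`.
#' @param source `"any"`, `"principal"` or `"mixed"`.
#' @param min_count minimum number of matching codes.
#' @param threshold ratio threshold (> 0).
#' @param variant prescription-rule variant, see [rx_positive()].
#' @param window_days window from the diagnosis date, in days (`Inf` for
#'   all follow-up).
#' @param left,right operand specs (non-combo).
#' @param op `"and"` or `"or"`.
#' @param name optional registry key; a descriptive name is generated when
#'   omitted.
#' @return an object of class `algorithm_spec`.
#' @examples
#' optimized <- alg_combo(alg_code_ratio(4), alg_rx("any_insulin", 90), "and")
#' @export
alg_code_count <- function(code_class = c("type1", "type2"),
                           source = c("any", "principal", "mixed"),
                           min_count = 1L, name = NULL) {
  code_class <- match.arg(code_class)
  source <- match.arg(source)
  stopifnot(min_count >= 1)
  if (is.null(name)) {
    name <- sprintf("ge%d_%s%s", min_count, code_class,
                    if (source == "any") "" else paste0("_", source))
  }
  structure(list(kind = "code_count", code_class = code_class, source = source,
                 min_count = as.integer(min_count), name = name),
            class = "algorithm_spec")
}

#' @rdname algorithm_spec
#' @export
alg_code_ratio <- function(threshold, name = NULL) {
  stopifnot(threshold > 0)
  if (is.null(name)) name <- sprintf("ratio_ge_%g", threshold)
  structure(list(kind = "code_ratio", threshold = threshold, name = name),
            class = "algorithm_spec")
}

RX_VARIANTS <- c("any_insulin", "insulin_no_other_glm",
                 "insulin_no_other_glm_except_metformin",
                 "mdi", "mdi_no_other_glm", "mdi_no_other_glm_except_metformin",
                 "any_metformin", "other_glm_only")

#' @rdname algorithm_spec
#' @export
alg_rx <- function(variant = RX_VARIANTS, window_days = Inf, name = NULL) {
  variant <- match.arg(variant)
  stopifnot(window_days > 0)
  if (is.null(name)) {
    name <- if (is.finite(window_days)) sprintf("%s_%dd", variant, as.integer(window_days))
            else variant
  }
  structure(list(kind = "rx", variant = variant, window_days = window_days,
                 name = name), class = "algorithm_spec")
}

#' @rdname algorithm_spec
#' @export
alg_combo <- function(left, right, op = c("and", "or"), name = NULL) {
  op <- match.arg(op)
  stopifnot(inherits(left, "algorithm_spec"), inherits(right, "algorithm_spec"))
  if (left$kind == "combo" || right$kind == "combo") {
    stop("combo operands must be non-combo specs", call. = FALSE)
  }
  if (is.null(name)) name <- sprintf("%s_%s_%s", left$name, op, right$name)
  structure(list(kind = "combo", left = left, right = right, op = op,
                 name = name), class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat("algorithm:", x$name, "\n")
  describe <- function(s) switch(s$kind,
    code_count = sprintf(">= %d %s code(s)%s", s$min_count, s$code_class,
                         if (s$source == "any") "" else paste0(" (", s$source, ")")),
    code_ratio = sprintf("ratio of type 1 to type 2 codes >= %g", s$threshold),
    rx = sprintf("%s%s", s$variant,
                 if (is.finite(s$window_days))
                   sprintf(" within %d days", as.integer(s$window_days)) else ""),
    combo = sprintf("(%s) %s (%s)", describe(s$left), s$op, describe(s$right)))
  cat(" ", describe(x), "\n")
  invisible(x)
}

#' Count post-diagnosis diabetes-typed encounter codes
#'
#' Counts encounters dated in `[diagnosis_date, horizon_end]` whose code is
#' a type 1 or type 2 diabetes code, split by coding source (principal
#' hospital-discharge diagnosis versus mixed).  Each encounter row counts
#' once.
#'
#' @param encounters encounter data frame for one person.
#' @param diagnosis_date the person's diabetes diagnosis date.
#' @param horizon_end last date counted (default: no upper bound, i.e. all
#'   available follow-up).
#' @return a `code_counts` list: `n_type1`, `n_type2`,
#'   `n_type1_principal`, `n_type1_mixed`, `n_type2_principal`,
#'   `n_type2_mixed`.
#' @export
count_codes <- function(encounters, diagnosis_date, horizon_end = NULL) {
  diagnosis_date <- as.Date(diagnosis_date)
  if (is.null(encounters) || !nrow(encounters)) {
    enc <- data.frame(type = character(0), source = character(0))
  } else {
    d <- as.Date(encounters$date)
    keep <- d >= diagnosis_date
    if (!is.null(horizon_end)) keep <- keep & d <= as.Date(horizon_end)
    enc <- data.frame(type = code_type(encounters$icd9[keep]),
                      source = encounters$source[keep])
  }
  n <- function(type, source = NULL) {
    sel <- enc$type == type
    if (!is.null(source)) sel <- sel & enc$source == source
    sum(sel)
  }
  structure(list(
    n_type1 = n("type1"), n_type2 = n("type2"),
    n_type1_principal = n("type1", "principal"),
    n_type1_mixed = n("type1", "mixed"),
    n_type2_principal = n("type2", "principal"),
    n_type2_mixed = n("type2", "mixed")
  ), class = "code_counts")
}

#' Is a code-ratio rule positive?
#'
#' Positive when `n_type1 / n_type2 >= r` (inclusive).  A person with type 1
#' codes but no type 2 codes has an infinite ratio and is positive at every
#' threshold; a person with no typed codes at all is negative.
#'
#' @param counts a `code_counts` object from [count_codes()].
#' @param r ratio threshold (> 0).
#' @return logical.
#' @export
code_ratio_positive <- function(counts, r) {
  stopifnot(r > 0)
  if (counts$n_type2 > 0) counts$n_type1 / counts$n_type2 >= r
  else counts$n_type1 >= 1
}

#' Evaluate a prescription rule for one person
#'
#' An insulin prescription qualifies when its class is any insulin type and
#' its duration is at least 28 days (long-term insulin); non-insulin
#' glucose-lowering prescriptions have no duration minimum.  "Within `w`
#' days" restricts prescription start dates to
#' `[diagnosis_date, diagnosis_date + w]`; `window_days = Inf` means all
#' follow-up (bounded by `followup_end` when given).  Variants:
#'
#' * `any_insulin`: at least one qualifying insulin prescription in the
#'   window.
#' * `insulin_no_other_glm`: additionally no non-insulin glucose-lowering
#'   prescription starts in the same window; the `_except_metformin` form
#'   permits metformin.
#' * `mdi` (multiple daily injections): at least one qualifying long-acting
#'   and one short-acting insulin, both starting in the window and within
#'   `mdi_coinit_days` of each other (the basal-bolus regimen typical of
#'   T1D).  `mdi_no_other_glm` and `mdi_no_other_glm_except_metformin` add
#'   the corresponding co-medication restriction.
#' * `any_metformin`: at least one metformin prescription in the window.
#' * `other_glm_only`: at least one glucose-lowering prescription other than
#'   insulin and metformin in the window.
#'
#' Only prescriptions on or after the diagnosis date are considered.
#'
#' @param prescriptions prescription data frame for one person.
#' @param diagnosis_date the person's diagnosis date.
#' @param variant one of the variants above.
#' @param window_days window length in days, `Inf` for all follow-up.
#' @param mdi_coinit_days maximum days between the long- and short-acting
#'   starts for them to count as co-initiated (default 31, one month).
#' @param followup_end optional end of follow-up bounding the unlimited
#'   window.
#' @param insulin_min_duration minimum qualifying insulin duration in days.
#' @return logical.
#' @export
rx_positive <- function(prescriptions, diagnosis_date,
                        variant = RX_VARIANTS, window_days = Inf,
                        mdi_coinit_days = 31L, followup_end = NULL,
                        insulin_min_duration = 28L) {
  variant <- match.arg(variant)
  diagnosis_date <- as.Date(diagnosis_date)
  if (is.null(prescriptions) || !nrow(prescriptions)) return(FALSE)

  start <- as.Date(prescriptions$start_date)
  in_win <- start >= diagnosis_date
  if (is.finite(window_days)) {
    in_win <- in_win & start <= diagnosis_date + as.integer(window_days)
  } else if (!is.null(followup_end)) {
    in_win <- in_win & start <= as.Date(followup_end)
  }
  rx <- prescriptions[in_win, , drop = FALSE]
  start <- start[in_win]
  if (!nrow(rx)) return(FALSE)

  qual_ins <- rx$drug_class %in% INSULIN_CLASSES &
    rx$duration_days >= insulin_min_duration
  other_glm <- rx$drug_class %in% NON_INSULIN_CLASSES
  other_glm_xmet <- other_glm & rx$drug_class != "metformin"

  mdi_hit <- function() {
    long <- start[qual_ins & rx$drug_class == "insulin_long"]
    short <- start[qual_ins & rx$drug_class == "insulin_short"]
    if (!length(long) || !length(short)) return(FALSE)
    any(abs(outer(as.numeric(long), as.numeric(short), "-")) <= mdi_coinit_days)
  }

  switch(variant,
    any_insulin = any(qual_ins),
    insulin_no_other_glm = any(qual_ins) && !any(other_glm),
    insulin_no_other_glm_except_metformin = any(qual_ins) && !any(other_glm_xmet),
    mdi = mdi_hit(),
    mdi_no_other_glm = mdi_hit() && !any(other_glm),
    mdi_no_other_glm_except_metformin = mdi_hit() && !any(other_glm_xmet),
    any_metformin = any(rx$drug_class == "metformin"),
    other_glm_only = any(other_glm_xmet)
  )
}

# positivity of an arbitrary spec for one person
spec_positive <- function(spec, encounters, prescriptions, diagnosis_date,
                          horizon_end = NULL, mdi_coinit_days = 31L,
                          insulin_min_duration = 28L) {
  switch(spec$kind,
    code_count = {
      counts <- count_codes(encounters, diagnosis_date, horizon_end)
      field <- paste0("n_", spec$code_class,
                      if (spec$source == "any") "" else paste0("_", spec$source))
      counts[[field]] >= spec$min_count
    },
    code_ratio = code_ratio_positive(
      count_codes(encounters, diagnosis_date, horizon_end), spec$threshold),
    rx = rx_positive(prescriptions, diagnosis_date, spec$variant,
                     spec$window_days, mdi_coinit_days, horizon_end,
                     insulin_min_duration),
    combo = {
      l <- spec_positive(spec$left, encounters, prescriptions, diagnosis_date,
                         horizon_end, mdi_coinit_days, insulin_min_duration)
      r <- spec_positive(spec$right, encounters, prescriptions, diagnosis_date,
                         horizon_end, mdi_coinit_days, insulin_min_duration)
      if (spec$op == "and") l && r else l || r
    },
    stop("unknown spec kind: ", spec$kind)
  )
}

#' Classify every cohort member with one algorithm
#'
#' Evaluates the rule on each person's post-diagnosis events and maps
#' positive to `T1D`, negative to `T2D`.  The rule is total: every person
#' receives a call.
#'
#' @param tables an [event_tables] object.
#' @param cohort a `dm_cohort` (needs `person_id` and `diagnosis_date`).
#' @param spec an [algorithm_spec].
#' @param horizon_end last date whose codes/prescriptions are used
#'   (default: the configured end of follow-up; `NULL` for no bound).
#' @param mdi_coinit_days see [rx_positive()].
#' @param cfg an [onset_config()], supplying `followup_end` and the
#'   long-term insulin duration minimum.
#' @return data frame `person_id`, `call` (`"T1D"`/`"T2D"`).
#' @export
classify <- function(tables, cohort, spec, cfg = onset_config(),
                     horizon_end = cfg$followup_end, mdi_coinit_days = 31L) {
  stopifnot(inherits(spec, "algorithm_spec"))
  ids <- cohort$person_id
  enc_by <- if (nrow(tables$encounters))
    split(tables$encounters, factor(tables$encounters$person_id, levels = ids))
  rx_by <- if (nrow(tables$prescriptions))
    split(tables$prescriptions, factor(tables$prescriptions$person_id, levels = ids))
  pos <- logical(length(ids))
  for (i in seq_along(ids)) {
    pos[i] <- spec_positive(
      spec,
      if (is.null(enc_by)) NULL else enc_by[[i]],
      if (is.null(rx_by)) NULL else rx_by[[i]],
      cohort$diagnosis_date[i], horizon_end, mdi_coinit_days,
      cfg$insulin_min_duration)
  }
  data.frame(person_id = ids, call = ifelse(pos, "T1D", "T2D"),
             stringsAsFactors = FALSE)
}

#' The evaluated algorithm registry
#'
#' The four selected single rules and their eight boolean pairings:
#'
#' * `A`: ratio of type 1 to type 2 codes >= 0.5 (highest-sensitivity code
#'   rule)
#' * `B`: ratio >= 4 (highest-PPV code rule)
#' * `C`: at least 1 insulin prescription within 90 days
#'   (highest-sensitivity prescription rule)
#' * `D`: multiple daily injections with no other glucose-lowering
#'   medication (highest-PPV prescription rule)
#' * `A_and_C` ... `B_or_D`: the eight combinations
#'
#' plus three aliases naming the headline algorithms:
#' `high_sensitivity_t1` (= `B_or_C`), `high_ppv_t1` (= `B_and_D`) and
#' `optimized` (= `B_and_C`, the highest-kappa rule).
#'
#' @return named list of [algorithm_spec] objects.
#' @export
algorithm_registry <- function() {
  A <- alg_code_ratio(0.5, name = "A")
  B <- alg_code_ratio(4, name = "B")
  C <- alg_rx("any_insulin", 90, name = "C")
  D <- alg_rx("mdi_no_other_glm", Inf, name = "D")
  singles <- list(A = A, B = B, C = C, D = D)
  combos <- list()
  for (cn in c("A", "B")) {
    for (rn in c("C", "D")) {
      for (op in c("and", "or")) {
        nm <- paste(cn, op, rn, sep = "_")
        combos[[nm]] <- alg_combo(singles[[cn]], singles[[rn]], op, name = nm)
      }
    }
  }
  reg <- c(singles, combos)
  reg$high_sensitivity_t1 <- reg$B_or_C
  reg$high_ppv_t1 <- reg$B_and_D
  reg$optimized <- reg$B_and_C
  reg
}

#' The full candidate-algorithm set used for selection
#'
#' Every rule screened on the derivation cohort: twelve code rules (count
#' rules for one or more type 1 / type 2 codes by source, and ratio rules at
#' thresholds 0.5, 0.75, 1, 2, 3, 4) and twenty-six prescription rules (six
#' insulin variants crossed with all-follow-up/90/180/365-day windows, plus
#' metformin and other-GLM screens).  Each entry carries `family` and
#' `window_days` attributes used by [select_algorithms()] to recognise
#' time-window variants of the same rule.
#'
#' @return named list of [algorithm_spec] objects with `family` fields.
#' @export
candidate_registry <- function() {
  out <- list()
  add <- function(spec, family) {
    spec$family <- family
    out[[spec$name]] <<- spec
  }
  for (cls in c("type1", "type2")) {
    for (src in c("any", "principal", "mixed")) {
      add(alg_code_count(cls, src), family = paste0("ge1_", cls, "_", src))
    }
  }
  for (r in c(0.5, 0.75, 1, 2, 3, 4)) add(alg_code_ratio(r), family = "code_ratio")
  windowed <- c("any_insulin", "insulin_no_other_glm",
                "insulin_no_other_glm_except_metformin",
                "mdi", "mdi_no_other_glm", "mdi_no_other_glm_except_metformin")
  for (v in windowed) {
    for (w in c(Inf, 90, 180, 365)) add(alg_rx(v, w), family = v)
  }
  add(alg_rx("any_metformin", Inf), family = "any_metformin")
  add(alg_rx("other_glm_only", Inf), family = "other_glm_only")
  out
}
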