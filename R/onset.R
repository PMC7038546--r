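#' Configuration for diabetes-onset detection and cohort eligibility
#'
#' Bundles every tunable threshold of the onset definition.  Diabetes onset
#' is the first occurrence of any of four criteria: outpatient HbA1c at or
#' above `hba1c_threshold` (%), outpatient fasting plasma glucose at or
#' above `fpg_threshold` (mmol/L), any non-insulin glucose-lowering
#' prescription, or a long-term insulin prescription (duration of at least
#' `insulin_min_duration` days).  Inpatient glucose measurements are ignored
#' to avoid mistaking acute stress hyperglycaemia for diabetes; by default
#' inpatient HbA1c is excluded on the same footing, with
#' `exclude_inpatient_hba1c = FALSE` available to exempt it (HbA1c is not an
#' acute-stress measure).
#'
#' Gestational-diabetes shielding discards candidate events inside
#' `[delivery - delivery_pre_window, delivery + delivery_post_window]` for
#' each delivery, and inside `+/- pregnancy_window` of any pregnancy-related
#' encounter outside those periods.  Windows are calendar months with
#' end-of-month clamping.
#'
#' @param hba1c_threshold HbA1c onset threshold in percent.
#' @param fpg_threshold fasting plasma glucose onset threshold in mmol/L.
#' @param insulin_min_duration minimum insulin prescription duration in days
#'   for the prescription to count as long-term.
#' @param delivery_pre_window,delivery_post_window months shielded before
#'   and after a delivery.
#' @param pregnancy_window months shielded either side of a
#'   pregnancy-related encounter.
#' @param enrol_start,enrol_end enrolment window for the diagnosis date.
#' @param followup_end last date of available follow-up.
#' @param exclude_inpatient_hba1c also drop inpatient HbA1c measurements
#'   (default `TRUE`).
#' @return an object of class `onset_config`.
#' @export
onset_config <- function(hba1c_threshold = 6.5,
                         fpg_threshold = 7.0,
                         insulin_min_duration = 28L,
                         delivery_pre_window = 9L,
                         delivery_post_window = 6L,
                         pregnancy_window = 9L,
                         enrol_start = as.Date("2002-01-01"),
                         enrol_end = as.Date("2015-12-31"),
                         followup_end = as.Date("2016-12-31"),
                         exclude_inpatient_hba1c = TRUE) {
  enrol_start <- as.Date(enrol_start); enrol_end <- as.Date(enrol_end)
  followup_end <- as.Date(followup_end)
  stopifnot(hba1c_threshold > 0, fpg_threshold > 0, insulin_min_duration >= 1,
            enrol_start < enrol_end, enrol_end <= followup_end)
  structure(list(
    hba1c_threshold = hba1c_threshold,
    fpg_threshold = fpg_threshold,
    insulin_min_duration = as.integer(insulin_min_duration),
    delivery_pre_window = as.integer(delivery_pre_window),
    delivery_post_window = as.integer(delivery_post_window),
    pregnancy_window = as.integer(pregnancy_window),
    enrol_start = enrol_start, enrol_end = enrol_end,
    followup_end = followup_end,
    exclude_inpatient_hba1c = isTRUE(exclude_inpatient_hba1c)
  ), class = "onset_config")
}

#' Shift a date by whole calendar months, clamping at month end
#'
#' `2010-01-31` plus one month is `2010-02-28`: the day of month is kept
#' where possible and clamped to the last day of the target month
#' otherwise.  This is the month arithmetic used for gestational windows.
#'
#' @param date a `Date` vector.
#' @param months integer number of months (may be negative).
#' @return a `Date` vector.
#' @export
add_months <- function(date, months) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  day <- lt$mday
  total <- lt$year * 12L + lt$mon + as.integer(months)
  yr <- total %/% 12L
  mo <- total %% 12L
  first <- as.Date(sprintf("%04d-%02d-01", yr + 1900L, mo + 1L))
  last_day <- as.POSIXlt(add_days(first_of_next_month(first), -1L))$mday
  first + pmin(day, last_day) - 1L
}

first_of_next_month <- function(first) {
  lt <- as.POSIXlt(first)
  total <- lt$year * 12L + lt$mon + 1L
  as.Date(sprintf("%04d-%02d-01", total %/% 12L + 1900L, total %% 12L + 1L))
}

add_days <- function(date, n) as.Date(date) + as.integer(n)

#' Gestational exclusion windows for one person
#'
#' Returns the merged set of closed date intervals inside which onset
#' candidates are discarded: `[delivery - 9 months, delivery + 6 months]`
#' around each delivery, plus `+/- 9 months` around each pregnancy-related
#' encounter (chapter codes 630--676) that is not already inside a delivery
#' window -- the latter catching aborted pregnancies and deliveries outside
#' the data system.  Overlapping intervals are merged.
#'
#' @param deliveries data frame of delivery events for one person
#'   (columns `date`, optionally `kind`).
#' @param pregnancy_encounters data frame of encounters for one person;
#'   rows whose `icd9` is not a pregnancy code are ignored.
#' @param cfg an [onset_config()].
#' @return data frame with columns `start`, `end` (`Date`), possibly empty.
#' @export
gestational_windows <- function(deliveries, pregnancy_encounters = NULL,
                                cfg = onset_config()) {
  starts <- as.Date(character(0)); ends <- as.Date(character(0))
  if (!is.null(deliveries) && nrow(deliveries)) {
    d <- as.Date(deliveries$date)
    starts <- c(starts, add_months(d, -cfg$delivery_pre_window))
    ends <- c(ends, add_months(d, cfg$delivery_post_window))
  }
  if (!is.null(pregnancy_encounters) && nrow(pregnancy_encounters)) {
    enc <- pregnancy_encounters
    if ("icd9" %in% names(enc)) enc <- enc[is_pregnancy_code(enc$icd9), , drop = FALSE]
    if (nrow(enc)) {
      e <- as.Date(enc$date)
      inside <- vapply(e, function(x) in_windows(x, starts, ends), logical(1))
      e <- e[!inside]
      starts <- c(starts, add_months(e, -cfg$pregnancy_window))
      ends <- c(ends, add_months(e, cfg$pregnancy_window))
    }
  }
  merge_intervals(starts, ends)
}

merge_intervals <- function(starts, ends) {
  if (!length(starts)) {
    return(data.frame(start = as.Date(character(0)), end = as.Date(character(0))))
  }
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  out_s <- starts[1]; out_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    k <- length(out_s)
    if (starts[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

in_windows <- function(date, starts, ends) {
  length(starts) > 0 && any(date >= starts & date <= ends)
}

#' Detect diabetes onset for one person
#'
#' Builds the candidate set -- outpatient HbA1c at/above threshold,
#' outpatient fasting glucose at/above threshold, any non-insulin
#' glucose-lowering prescription, any insulin prescription of at least the
#' minimum long-term duration -- discards candidates inside the gestational
#' windows, and returns the earliest survivor.  Same-day ties are broken by
#' a fixed criterion priority: `hba1c` > `fpg` > `glm_non_insulin` >
#' `long_term_insulin`.
#'
#' @param events an [event_tables] object holding one person's events (only
#'   `labs` and `prescriptions` are consulted).
#' @param windows interval data frame from [gestational_windows()].
#' @param cfg an [onset_config()].
#' @return `list(date =, criterion =)` or `NULL` when no candidate survives.
#' @export
detect_onset <- function(events, windows = NULL, cfg = onset_config()) {
  dates <- as.Date(character(0)); crit <- character(0)

  labs <- events$labs
  if (!is.null(labs) && nrow(labs)) {
    hba <- labs$test == "hba1c" & labs$value >= cfg$hba1c_threshold
    if (cfg$exclude_inpatient_hba1c) hba <- hba & labs$setting == "outpatient"
    fpg <- labs$test == "fpg" & labs$value >= cfg$fpg_threshold &
      labs$setting == "outpatient"
    dates <- c(dates, as.Date(labs$date[hba]), as.Date(labs$date[fpg]))
    crit <- c(crit, rep("hba1c", sum(hba)), rep("fpg", sum(fpg)))
  }
  rx <- events$prescriptions
  if (!is.null(rx) && nrow(rx)) {
    glm <- rx$drug_class %in% NON_INSULIN_CLASSES
    ins <- rx$drug_class %in% INSULIN_CLASSES &
      rx$duration_days >= cfg$insulin_min_duration
    dates <- c(dates, as.Date(rx$start_date[glm]), as.Date(rx$start_date[ins]))
    crit <- c(crit, rep("glm_non_insulin", sum(glm)),
              rep("long_term_insulin", sum(ins)))
  }
  if (!length(dates)) return(NULL)

  if (!is.null(windows) && nrow(windows)) {
    keep <- !vapply(dates, function(x) in_windows(x, windows$start, windows$end),
                    logical(1))
    dates <- dates[keep]; crit <- crit[keep]
    if (!length(dates)) return(NULL)
  }

  priority <- match(crit, c("hba1c", "fpg", "glm_non_insulin", "long_term_insulin"))
  pick <- order(dates, priority)[1]
  list(date = dates[pick], criterion = crit[pick])
}
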