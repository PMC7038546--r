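#' Build the analysis cohort from raw event tables
#'
#' Runs onset detection for every person, applies the eligibility rules and
#' attaches the reference-standard label.  A person is kept when:
#' onset was detected; the diagnosis date falls inside the enrolment window;
#' age at diagnosis (exact day difference / 365.25) is between 1.5 years --
#' excluding neonatal diabetes -- and 100 years; and the reference label is
#' binary (`T1D`/`T2D`).  Exclusions are tallied in application order
#' (`no_onset`, `out_of_window`, `age`, `monogenic_secondary`,
#' `missing_label`) in the `"exclusions"` attribute; the counts always sum
#' to the number of input persons minus the cohort size.
#'
#' @param tables an [event_tables] object covering all persons.
#' @param labels reference labels (data frame `person_id`, `true_type`);
#'   defaults to `tables$labels`.  A person with detected onset but no label
#'   row is an error.
#' @param cfg an [onset_config()].
#' @return a `dm_cohort` data frame with columns `person_id`,
#'   `diagnosis_date`, `age_at_diagnosis`, `onset_criterion`, `true_type`,
#'   `split` (`NA` until [randomize_split()] is applied), and attribute
#'   `exclusions`.
#' @export
build_cohort <- function(tables, labels = tables$labels, cfg = onset_config()) {
  stopifnot(inherits(tables, "event_tables"))
  persons <- tables$persons
  if (!nrow(persons)) stop("no persons in the event tables", call. = FALSE)
  labels <- validate_table(labels, "labels")

  ids <- persons$person_id
  # pre-split the big tables once; much faster than per-person subsetting
  by_id <- function(df) if (nrow(df)) split(df, factor(df$person_id, levels = ids)) else NULL
  labs_by <- by_id(tables$labs)
  rx_by <- by_id(tables$prescriptions)
  del_by <- by_id(tables$deliveries)
  # only pregnancy-coded encounters can create shielding windows
  preg_enc <- tables$encounters[is_pregnancy_code(tables$encounters$icd9), ,
                                drop = FALSE]
  preg_by <- by_id(preg_enc)

  excl <- c(no_onset = 0L, out_of_window = 0L, age = 0L,
            monogenic_secondary = 0L, missing_label = 0L)
  n <- length(ids)
  keep <- logical(n)
  diag_date <- rep(as.Date(NA), n)
  age_at <- numeric(n)
  criterion <- character(n)
  true_type <- character(n)
  missing_label_ids <- character(0)
  lab_of <- labels$true_type[match(ids, labels$person_id)]
  birth <- as.Date(persons$birth_date)

  for (i in seq_len(n)) {
    ev <- list(labs = if (is.null(labs_by)) NULL else labs_by[[i]],
               prescriptions = if (is.null(rx_by)) NULL else rx_by[[i]])
    del <- if (is.null(del_by)) NULL else del_by[[i]]
    pe <- if (is.null(preg_by)) NULL else preg_by[[i]]
    win <- if ((!is.null(del) && nrow(del)) || (!is.null(pe) && nrow(pe))) {
      gestational_windows(del, pe, cfg)
    } else NULL
    onset <- detect_onset(ev, win, cfg)
    if (is.null(onset)) { excl["no_onset"] <- excl["no_onset"] + 1L; next }
    if (onset$date < cfg$enrol_start || onset$date > cfg$enrol_end) {
      excl["out_of_window"] <- excl["out_of_window"] + 1L; next
    }
    age <- as.numeric(onset$date - birth[i]) / 365.25
    if (age < 1.5 || age > 100) { excl["age"] <- excl["age"] + 1L; next }
    lab <- lab_of[i]
    if (is.na(lab)) { missing_label_ids <- c(missing_label_ids, ids[i]); next }
    if (lab == "monogenic_secondary") {
      excl["monogenic_secondary"] <- excl["monogenic_secondary"] + 1L; next
    }
    if (lab == "missing") { excl["missing_label"] <- excl["missing_label"] + 1L; next }
    keep[i] <- TRUE
    diag_date[i] <- onset$date; age_at[i] <- age
    criterion[i] <- onset$criterion; true_type[i] <- lab
  }
  if (length(missing_label_ids)) {
    stop("persons with detected onset but no label row: ",
         paste(missing_label_ids, collapse = ", "), call. = FALSE)
  }
  cohort <- data.frame(
    person_id = ids[keep], diagnosis_date = diag_date[keep],
    age_at_diagnosis = age_at[keep], onset_criterion = criterion[keep],
    true_type = true_type[keep], split = rep(NA_character_, sum(keep)),
    stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  structure(cohort, exclusions = excl, class = c("dm_cohort", "data.frame"))
}

#' @export
print.dm_cohort <- function(x, ...) {
  cat(sprintf("Diabetes cohort: %d persons (%d T1D, %d T2D)\n",
              nrow(x), sum(x$true_type == "T1D"), sum(x$true_type == "T2D")))
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && sum(excl)) {
    cat("Exclusions:", paste(sprintf("%s=%d", names(excl), excl), collapse = ", "), "\n")
  }
  if (!all(is.na(x$split))) {
    cat(sprintf("Split: %d derivation / %d validation\n",
                sum(x$split == "derivation", na.rm = TRUE),
                sum(x$split == "validation", na.rm = TRUE)))
  }
  NextMethod()
}

## 32-bit mixing hash in exact double arithmetic, so split assignment is a
## pure, machine-independent function of (seed, person_id)
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}
mul32 <- function(a, b) {
  (((a %/% 65536 * b) %% 65536) * 65536 + (a %% 65536) * b) %% 4294967296
}
fmix32 <- function(h) {
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2246822507)
  h <- xor32(h, h %/% 8192)
  h <- mul32(h, 3266489909)
  xor32(h, h %/% 65536)
}

# uniform variate in [0, 1) from (seed, id): FNV-1a over the bytes of
# "seed:id" followed by a murmur-style finalizer for avalanche
split_unit <- function(seed, id) {
  s <- paste0(format(seed, scientific = FALSE), ":", id)
  bytes <- lapply(s, utf8ToInt)
  len <- lengths(bytes)
  h <- rep(2166136261, length(s))
  for (k in seq_len(max(len, 1L))) {
    b <- vapply(bytes, function(x) if (k <= length(x)) x[[k]] else 0L, integer(1))
    h <- mul32(xor32(h, b), 16777619)
  }
  fmix32(xor32(h, len)) / 4294967296
}

#' Randomise a cohort into derivation and validation sets
#'
#' Each person is assigned independently at random with expected derivation
#' fraction `fraction_derivation` (two thirds by default).  Assignment is a
#' pure hash of `(seed, person_id)`, so it is reproducible across machines
#' and stable under re-ordering of the input rows.
#'
#' @param cohort a `dm_cohort` (or any data frame with `person_id`).
#' @param seed integer seed driving the assignment.
#' @param fraction_derivation expected derivation fraction in (0, 1], where
#'   1 assigns everyone to derivation.
#' @return the cohort with its `split` column filled in.
#' @export
randomize_split <- function(cohort, seed, fraction_derivation = 2 / 3) {
  stopifnot(fraction_derivation > 0, fraction_derivation <= 1)
  u <- split_unit(seed, cohort$person_id)
  cohort$split <- ifelse(u < fraction_derivation, "derivation", "validation")
  cohort
}
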