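#' @name event_tables
#' @title Normalised EHR event tables
#'
#' @description
#' The shared data model for every rule in the package: a list of up to six
#' per-person longitudinal tables, validated against fixed column schemas.
#'
#' * `persons`: `person_id`, `sex` (`female`/`male`), `birth_date`
#' * `encounters`: `person_id`, `date`, `icd9`, `source`
#'   (`principal` = principal diagnosis on a hospital discharge abstract,
#'   `mixed` = secondary discharge diagnoses and outpatient encounter codes),
#'   `setting` (`inpatient`/`outpatient`)
#' * `prescriptions`: `person_id`, `drug_class`, `start_date`,
#'   `duration_days` (>= 1)
#' * `labs`: `person_id`, `date`, `test` (`hba1c` in %, `fpg` in mmol/L,
#'   `egfr` in mL/min/1.73m2), `value` (> 0), `setting`
#' * `deliveries`: `person_id`, `date`, `kind`
#'   (`delivery`/`pregnancy_related`)
#' * `labels`: `person_id`, `true_type`
#'   (`T1D`/`T2D`/`monogenic_secondary`/`missing`), one row per person
#'
#' Dates are calendar dates (`Date`); all comparisons in the package are
#' date-level.  Extra columns are preserved untouched.  Omitted tables
#' default to empty tables with the right schema.
#'
#' @param persons,encounters,prescriptions,labs,deliveries,labels data frames
#'   conforming to the schemas above (or `NULL` for an empty table).
#' @return an object of class `event_tables`: a named list of validated
#'   data frames.
#' @examples
#' tabs <- event_tables(
#'   persons = data.frame(person_id = "p1", sex = "female",
#'                        birth_date = as.Date("1980-05-01")),
#'   labs = data.frame(person_id = "p1", date = as.Date("2010-03-01"),
#'                     test = "hba1c", value = 7.2, setting = "outpatient")
#' )
#' tabs$labs
NULL

DRUG_CLASSES <- c(
  "metformin", "sulfonylurea", "thiazolidinedione", "dpp4", "glp1",
  "sglt2", "agi", "other_glm",
  "insulin_long", "insulin_intermediate", "insulin_short", "insulin_premixed"
)
INSULIN_CLASSES <- c(
  "insulin_long", "insulin_intermediate", "insulin_short", "insulin_premixed"
)
NON_INSULIN_CLASSES <- setdiff(DRUG_CLASSES, INSULIN_CLASSES)

TABLE_SCHEMAS <- list(
  persons = list(
    cols = c("person_id", "sex", "birth_date"),
    dates = "birth_date",
    enums = list(sex = c("female", "male"))
  ),
  encounters = list(
    cols = c("person_id", "date", "icd9", "source", "setting"),
    dates = "date",
    enums = list(source = c("principal", "mixed"),
                 setting = c("inpatient", "outpatient"))
  ),
  prescriptions = list(
    cols = c("person_id", "drug_class", "start_date", "duration_days"),
    dates = "start_date",
    enums = list(drug_class = DRUG_CLASSES)
  ),
  labs = list(
    cols = c("person_id", "date", "test", "value", "setting"),
    dates = "date",
    enums = list(test = c("hba1c", "fpg", "egfr"),
                 setting = c("inpatient", "outpatient"))
  ),
  deliveries = list(
    cols = c("person_id", "date", "kind"),
    dates = "date",
    enums = list(kind = c("delivery", "pregnancy_related"))
  ),
  labels = list(
    cols = c("person_id", "true_type"),
    dates = character(0),
    enums = list(true_type = c("T1D", "T2D", "monogenic_secondary", "missing"))
  )
)

empty_table <- function(name) {
  sch <- TABLE_SCHEMAS[[name]]
  out <- lapply(sch$cols, function(col) {
    if (col %in% sch$dates) as.Date(character(0))
    else if (col %in% c("duration_days")) integer(0)
    else if (col %in% c("value")) numeric(0)
    else character(0)
  })
  names(out) <- sch$cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

validate_table <- function(df, name, file = NULL) {
  sch <- TABLE_SCHEMAS[[name]]
  where <- if (is.null(file)) name else file
  missing <- setdiff(sch$cols, names(df))
  if (length(missing)) {
    stop(sprintf("table '%s' is missing required column(s): %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in sch$dates) {
    if (!inherits(df[[col]], "Date")) {
      raw <- as.character(df[[col]])
      parsed <- as.Date(raw, format = "%Y-%m-%d")
      bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
      if (length(bad)) {
        stop(sprintf(
          "table '%s', column '%s': unparseable date '%s' at row %d (expecting ISO-8601)",
          where, col, raw[bad[1]], bad[1]), call. = FALSE)
      }
      df[[col]] <- parsed
    }
  }
  for (col in names(sch$enums)) {
    df[[col]] <- as.character(df[[col]])
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% sch$enums[[col]]))
    if (length(bad)) {
      stop(sprintf("table '%s', column '%s': invalid value '%s' at row %d",
                   where, col, df[[col]][bad[1]], bad[1]), call. = FALSE)
    }
  }
  if (name == "prescriptions" && nrow(df)) {
    df$duration_days <- as.integer(df$duration_days)
    if (any(is.na(df$duration_days) | df$duration_days < 1L)) {
      stop(sprintf("table '%s': duration_days must be a positive integer", where),
           call. = FALSE)
    }
  }
  if (name == "labs" && nrow(df)) {
    df$value <- as.numeric(df$value)
    if (any(is.na(df$value) | df$value <= 0)) {
      stop(sprintf("table '%s': lab values must be positive", where), call. = FALSE)
    }
  }
  if (name == "labels" && anyDuplicated(df$person_id)) {
    stop(sprintf("table '%s': more than one label per person", where), call. = FALSE)
  }
  if ("icd9" %in% names(df)) df$icd9 <- as.character(df$icd9)
  df$person_id <- as.character(df$person_id)
  df
}

#' @rdname event_tables
#' @export
event_tables <- function(persons = NULL, encounters = NULL,
                         prescriptions = NULL, labs = NULL,
                         deliveries = NULL, labels = NULL) {
  given <- list(persons = persons, encounters = encounters,
                prescriptions = prescriptions, labs = labs,
                deliveries = deliveries, labels = labels)
  out <- lapply(names(TABLE_SCHEMAS), function(name) {
    df <- given[[name]]
    if (is.null(df)) empty_table(name) else validate_table(df, name)
  })
  names(out) <- names(TABLE_SCHEMAS)
  structure(out, class = "event_tables")
}

#' @export
print.event_tables <- function(x, ...) {
  cat("EHR event tables\n")
  for (name in names(x)) {
    cat(sprintf("  %-14s %6d rows\n", name, nrow(x[[name]])))
  }
  invisible(x)
}

#' Read and write event tables as delimited text
#'
#' One file per table (`persons.csv`, `encounters.csv`, `prescriptions.csv`,
#' `labs.csv`, `deliveries.csv`, `labels.csv`), UTF-8 with a header row.
#' Files that do not exist yield empty tables.  Undotted ICD-9 codes in
#' claims dialects (`"25001"`) are normalised by inserting the dot after the
#' three leading digits.  Writing then re-reading a valid set of tables is
#' the identity; unknown columns are preserved.
#'
#' @param dir directory containing (or to receive) the table files.
#' @param sep field separator, comma by default.
#' @param tables an `event_tables` object.
#' @return `read_event_tables()` returns an [event_tables] object;
#'   `write_event_tables()` returns the vector of files written, invisibly.
#' @export
read_event_tables <- function(dir, sep = ",") {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  found <- FALSE
  out <- list()
  for (name in names(TABLE_SCHEMAS)) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (file.exists(path)) {
      found <- TRUE
      df <- utils::read.table(path, sep = sep, header = TRUE,
                              colClasses = "character",
                              stringsAsFactors = FALSE, fileEncoding = "UTF-8")
      if ("icd9" %in% names(df)) df$icd9 <- normalize_icd9(df$icd9)
      out[[name]] <- validate_table(df, name, file = basename(path))
    } else {
      out[[name]] <- empty_table(name)
    }
  }
  if (!found) {
    stop("no event-table files found in ", dir, call. = FALSE)
  }
  structure(out, class = "event_tables")
}

#' @rdname read_event_tables
#' @export
write_event_tables <- function(tables, dir, sep = ",") {
  stopifnot(inherits(tables, "event_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (name in names(TABLE_SCHEMAS)) {
    path <- file.path(dir, paste0(name, ".csv"))
    df <- tables[[name]]
    for (col in TABLE_SCHEMAS[[name]]$dates) df[[col]] <- format(df[[col]])
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    written <- c(written, path)
  }
  invisible(written)
}

# all events of one person, as a plain list of filtered data frames
person_events <- function(tables, id) {
  structure(lapply(tables, function(df) df[df$person_id == id, , drop = FALSE]),
            class = "event_tables")
}
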