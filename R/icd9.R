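#' Classify an ICD-9 code as a type 1 or type 2 diabetes code
#'
#' Type 1 codes are the dotted ICD-9 codes `250.x1` and `250.x3` (fifth digit
#' 1 or 3, any fourth digit); type 2 codes are `250.x1`'s counterparts
#' `250.x0` and `250.x2`.  Every other string -- including non-diabetes codes
#' and malformed `250.*` codes such as `"250.1"` without a fifth digit --
#' is `"other"`.  The function is total: it never errors on odd input.
#'
#' Codes are expected in dotted form.  Undotted claims dialects
#' (`"25001"`) are normalised at read time by [read_event_tables()], not
#' here.
#'
#' @param icd9 character vector of ICD-9 codes.
#' @return character vector, one of `"type1"`, `"type2"`, `"other"`.
#' @examples
#' code_type(c("250.01", "250.00", "428.0", "250.1"))
#' @export
code_type <- function(icd9) {
  icd9 <- as.character(icd9)
  out <- rep("other", length(icd9))
  out[grepl("^250\\.[0-9][13]$", icd9)] <- "type1"
  out[grepl("^250\\.[0-9][02]$", icd9)] <- "type2"
  out[is.na(icd9)] <- "other"
  out
}

# integer chapter prefix (text before the first dot), NA when non-numeric
icd9_chapter <- function(icd9) {
  prefix <- sub("\\..*$", "", as.character(icd9))
  suppressWarnings(as.integer(prefix))
}

#' Pregnancy- and delivery-related ICD-9 code predicates
#'
#' `is_pregnancy_code()` is true for codes whose integer chapter prefix lies
#' in 630--676 (pregnancy, childbirth and puerperium complications);
#' `is_delivery_code()` for chapter prefixes 72--75 (the obstetric delivery
#' procedure range).  Both compare the integer value of the text before the
#' first dot, so `"650"`, `"650.1"` and `"74.1"` behave as expected, and
#' codes with non-numeric prefixes are simply `FALSE`.
#'
#' @param icd9 character vector of ICD-9 codes.
#' @return logical vector.
#' @examples
#' is_pregnancy_code(c("650", "677", "V22.1"))
#' is_delivery_code("74.1")
#' @export
is_pregnancy_code <- function(icd9) {
  ch <- icd9_chapter(icd9)
  !is.na(ch) & ch >= 630L & ch <= 676L
}

#' @rdname is_pregnancy_code
#' @export
is_delivery_code <- function(icd9) {
  ch <- icd9_chapter(icd9)
  !is.na(ch) & ch >= 72L & ch <= 75L
}

# Insert the dot into undotted all-digit codes ("25001" -> "250.01").
# Codes that already contain a dot, are <= 3 digits, or contain non-digits
# are returned unchanged.
normalize_icd9 <- function(icd9) {
  icd9 <- as.character(icd9)
  undotted <- !is.na(icd9) & !grepl("\\.", icd9) & grepl("^[0-9]{4,}$", icd9)
  icd9[undotted] <- paste0(
    substr(icd9[undotted], 1L, 3L), ".",
    substring(icd9[undotted], 4L)
  )
  icd9
}
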