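# Data model and I/O.
#
# A study dataset is a plain data frame in a NONMEM-inspired layout, one
# measurement per row, with columns:
#   ID      animal label (character or integer)
#   GROUP   "control" or "irradiated"
#   ROUTE   "gavage" or "iv"
#   DOSE_UG administered lisinopril in micrograms per animal
#   TIME    hours since dosing (>= 0)
#   CMT     observed compartment, "plasma" or "urine"
#   DV      measured value: umol/L for plasma, cumulative umol for urine
#   EFF     extraction efficiency in (0, 1] for that measurement
# DV holds the raw (uncorrected) measurement; modelling functions divide
# by EFF (see correct_extraction) before fitting.  Negative DV values
# are permitted: the additive error model can produce them.

.PK_COLUMNS <- c("ID", "GROUP", "ROUTE", "DOSE_UG", "TIME", "CMT", "DV", "EFF")

#' Convert an administered dose from micrograms to micromoles
#'
#' Divides by the molar mass of lisinopril, 405.5 g/mol.
#'
#' @param dose_ug dose in micrograms (non-negative).
#' @return dose in micromoles.
#' @examples
#' dose_to_umol(300)  # 0.7398 umol
#' @export
dose_to_umol <- function(dose_ug) {
  if (!is.numeric(dose_ug) || any(dose_ug < 0, na.rm = TRUE))
    stop("'dose_ug' must be non-negative", call. = FALSE)
  dose_ug / LISINOPRIL_MW
}

#' @rdname dose_to_umol
#' @param dose_umol dose in micromoles.
#' @export
umol_to_ug <- function(dose_umol) {
  if (!is.numeric(dose_umol) || any(dose_umol < 0, na.rm = TRUE))
    stop("'dose_umol' must be non-negative", call. = FALSE)
  dose_umol * LISINOPRIL_MW
}

#' Correct a measured value for extraction efficiency
#'
#' Measured concentrations/amounts are divided by the spike-in extraction
#' efficiency of the corresponding matrix before any modelling.
#'
#' @param value measured value(s).
#' @param efficiency extraction efficiency in (0, 1]; recycled against
#'   `value`.
#' @return corrected value(s), `value / efficiency`.
#' @export
correct_extraction <- function(value, efficiency) {
  if (!is.numeric(efficiency) || any(!is.finite(efficiency)) ||
      any(efficiency <= 0) || any(efficiency > 1))
    stop("'efficiency' must lie in (0, 1]", call. = FALSE)
  value / efficiency
}

#' Validate a study dataset
#'
#' Checks a data frame against the dataset schema and returns a
#' character vector of row-numbered diagnostics (empty when the dataset
#' is valid).  Checked: required columns present; GROUP, ROUTE, CMT
#' levels; non-negative dose and time; finite DV; efficiency in (0, 1].
#' Tissue compartments (lung, liver, kidney) are rejected: only plasma
#' and urine enter the model.
#'
#' @param data a data frame.
#' @return Character vector of diagnostics, invisibly empty if valid.
#' @export
validate_pk_dataset <- function(data) {
  if (!is.data.frame(data)) return("not a data frame")
  missing_cols <- setdiff(.PK_COLUMNS, names(data))
  if (length(missing_cols))
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  bad <- character(0)
  note <- function(rows, col, msg) {
    if (any(rows, na.rm = TRUE))
      sprintf("row %d, column %s: %s", which(rows), col, msg)
    else character(0)
  }
  bad <- c(bad,
    note(is.na(data$ID) | !nzchar(as.character(data$ID)), "ID", "empty animal id"),
    note(!data$GROUP %in% c("control", "irradiated"), "GROUP",
         "must be 'control' or 'irradiated'"),
    note(!data$ROUTE %in% c("gavage", "iv"), "ROUTE",
         "must be 'gavage' or 'iv'"),
    note(!is.finite(data$DOSE_UG) | data$DOSE_UG < 0, "DOSE_UG",
         "must be a non-negative dose in ug"),
    note(!is.finite(data$TIME) | data$TIME < 0, "TIME",
         "must be a non-negative time in hours"),
    note(!data$CMT %in% c("plasma", "urine"), "CMT",
         "must be 'plasma' or 'urine' (tissue records are not fitted)"),
    note(!is.finite(data$DV), "DV", "must be a finite number"),
    note(!is.finite(data$EFF) | data$EFF <= 0 | data$EFF > 1, "EFF",
         "extraction efficiency must lie in (0, 1]"))
  bad
}

.assert_pk_dataset <- function(data) {
  diag <- validate_pk_dataset(data)
  if (length(diag))
    stop("invalid study dataset:\n  ", paste(head(diag, 10), collapse = "\n  "),
         if (length(diag) > 10) sprintf("\n  ... and %d more", length(diag) - 10),
         call. = FALSE)
  invisible(data)
}

#' Read / write a study dataset
#'
#' Comma-separated UTF-8 text with the schema documented in
#' [validate_pk_dataset()].  `read_pk_dataset()` rejects malformed files
#' with row-numbered diagnostics; `write_pk_dataset()` and
#' `read_pk_dataset()` round-trip valid datasets exactly (up to numeric
#' printing precision, 15 significant digits).
#'
#' @param path file path.
#' @param data a valid study dataset (data frame).
#' @return `read_pk_dataset()` returns the dataset as a data frame;
#'   `write_pk_dataset()` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("ID", "GROUP", "ROUTE", "CMT"))
    if (col %in% names(data)) data[[col]] <- as.character(data[[col]])
  .assert_pk_dataset(data)
  data
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(data, path) {
  .assert_pk_dataset(data)
  out <- data[, .PK_COLUMNS]
  for (col in c("DOSE_UG", "TIME", "DV", "EFF"))
    out[[col]] <- format(out[[col]], digits = 15, trim = TRUE,
                         scientific = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
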