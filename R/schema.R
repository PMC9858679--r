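#' @useDynLib genochain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical class alphabets -------------------------------------------------

#' Genetic disorder classes
#'
#' The three aetiological disorder classes in code order: code 0 is
#' mitochondrial, 1 multifactorial, 2 single-gene.
#'
#' @return Character vector of length 3 (code order 0, 1, 2).
#' @export
disorder_classes <- function() {
  c("Mitochondrial genetic inheritance disorders",
    "Multifactorial genetic inheritance disorders",
    "Single-gene inheritance diseases")
}

#' Disorder subclass classes
#'
#' The nine disease subclasses in code order 0--8.
#'
#' @return Character vector of length 9.
#' @export
subclass_classes <- function() {
  c("Leber's hereditary optic neuropathy",
    "Diabetes",
    "Leigh syndrome",
    "Cancer",
    "Cystic fibrosis",
    "Tay-Sachs",
    "Hemochromatosis",
    "Mitochondrial myopathy",
    "Alzheimer's")
}

yes_no        <- c("Yes", "No")
yes_no_na     <- c("Yes", "No", "Not applicable")

# Column registry -----------------------------------------------------------

#' The genomes patient-table column registry
#'
#' Single source of truth for the patient-table schema: 44 required columns
#' (two of which are the targets 'Genetic Disorder' and 'Disorder Subclass')
#' plus the optional identifier column 'Parental consent', which real exports
#' of the dataset carry but the canonical 44-column listing omits. All other
#' modules (reader, encoder, generator) consume this registry and never
#' re-declare column names.
#'
#' @return A data.frame with one row per column spec and fields `name`,
#'   `role` (identifier/feature/target), `value_kind`
#'   (numeric/categorical/free_text), `allowed_values` (list column; NULL for
#'   non-categorical), `nullable`, and `optional`.
#' @export
genome_schema <- function() {
  spec <- function(name, role, kind, allowed = NULL, nullable = TRUE,
                   optional = FALSE) {
    list(name = name, role = role, value_kind = kind,
         allowed_values = list(allowed), nullable = nullable,
         optional = optional)
  }
  rows <- list(
    spec("Patient Id", "identifier", "free_text"),
    spec("Patient Age", "feature", "numeric"),
    spec("Genes in mother's side", "feature", "categorical", yes_no),
    spec("Inherited from father", "feature", "categorical", yes_no),
    spec("Maternal gene", "feature", "categorical", yes_no),
    spec("Paternal gene", "feature", "categorical", yes_no),
    spec("Blood cell count (mcL)", "feature", "numeric"),
    spec("Patient First Name", "identifier", "free_text"),
    spec("Family Name", "identifier", "free_text"),
    spec("Father's name", "identifier", "free_text"),
    spec("Mother's age", "feature", "numeric"),
    spec("Father's age", "feature", "numeric"),
    spec("Institute Name", "identifier", "free_text"),
    spec("Location of Institute", "identifier", "free_text"),
    spec("Status", "feature", "categorical", c("Deceased", "Alive")),
    spec("Respiratory Rate (breaths/min)", "feature", "categorical",
         c("Normal (30-60)", "Tachypnea")),
    # header printed with an unmatched parenthesis; kept verbatim
    spec("Heart Rate (rates/min", "feature", "categorical",
         c("Normal", "Tachypnea")),
    spec("Test 1", "feature", "numeric"),
    spec("Test 2", "feature", "numeric"),
    spec("Test 3", "feature", "numeric"),
    spec("Test 4", "feature", "numeric"),
    spec("Test 5", "feature", "numeric"),
    spec("Follow-up", "feature", "categorical", c("Low", "High")),
    spec("Gender", "feature", "categorical",
         c("Male", "Female", "Ambiguous")),
    spec("Birth asphyxia", "feature", "categorical",
         c("No record", "Not available", "No", "Yes")),
    spec("Autopsy shows birth defect (if applicable)", "feature",
         "categorical", c("None", "No", "Yes", "Not applicable")),
    spec("Place of birth", "identifier", "free_text"),
    spec("Folic acid details (peri-conceptional)", "feature", "categorical",
         yes_no),
    spec("H/O serious maternal illness", "feature", "categorical", yes_no),
    spec("H/O radiation exposure (X-ray)", "feature", "categorical",
         yes_no_na),
    spec("H/O substance abuse", "feature", "categorical", yes_no_na),
    spec("Assisted conception IVF/ART", "feature", "categorical", yes_no),
    spec("History of anomalies in previous pregnancies", "feature",
         "categorical", yes_no),
    spec("No. of previous abortion", "feature", "numeric"),
    spec("Birth defects", "feature", "categorical",
         c("Singular", "Multiple")),
    spec("White Blood cell count (thousand per microliter)", "feature",
         "numeric"),
    spec("Blood test result", "feature", "categorical",
         c("normal", "abnormal")),
    spec("Symptom 1", "feature", "numeric"),
    spec("Symptom 2", "feature", "numeric"),
    spec("Symptom 3", "feature", "numeric"),
    spec("Symptom 4", "feature", "numeric"),
    spec("Symptom 5", "feature", "numeric"),
    spec("Genetic Disorder", "target", "categorical", disorder_classes()),
    spec("Disorder Subclass", "target", "categorical", subclass_classes()),
    spec("Parental consent", "identifier", "free_text", optional = TRUE)
  )
  out <- data.frame(
    name = vapply(rows, `[[`, "", "name"),
    role = vapply(rows, `[[`, "", "role"),
    value_kind = vapply(rows, `[[`, "", "value_kind"),
    nullable = vapply(rows, `[[`, TRUE, "nullable"),
    optional = vapply(rows, `[[`, TRUE, "optional"),
    stringsAsFactors = FALSE
  )
  out$allowed_values <- lapply(rows, function(r) r$allowed_values[[1]])
  out
}

#' Names of the two target columns
#' @return Character vector `c("Genetic Disorder", "Disorder Subclass")`.
#' @export
target_columns <- function() c("Genetic Disorder", "Disorder Subclass")

# Header aliasing: printed headers use curly apostrophes in some renderings
# and exports occasionally carry trailing whitespace. Both map onto the
# canonical ASCII names.
canonical_column_name <- function(x) {
  x <- sub("[ \t]+$", "", x)
  x <- gsub("’", "'", x)
  x
}

# PatientTable --------------------------------------------------------------

#' Construct and validate a patient table
#'
#' A `patient_table` is a plain data.frame whose columns follow
#' [genome_schema()]: categorical and free-text columns are character
#' (NA = missing), numeric columns are numeric. Validation checks that every
#' required column is present and that non-null target values belong to the
#' registered class alphabets.
#'
#' @param df A data.frame keyed by canonical column names.
#' @param strict Reject unknown columns (TRUE) or drop them with a warning.
#' @return The validated data.frame with class `patient_table`.
#' @export
patient_table <- function(df, strict = FALSE) {
  stopifnot(is.data.frame(df))
  schema <- genome_schema()
  names(df) <- canonical_column_name(names(df))

  unknown <- setdiff(names(df), schema$name)
  if (length(unknown)) {
    if (strict) {
      stop("unknown columns: ", paste(unknown, collapse = ", "))
    }
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }

  required <- schema$name[!schema$optional]
  absent <- setdiff(required, names(df))
  if (any(target_columns() %in% absent)) {
    stop("schema error: missing target column(s): ",
         paste(intersect(target_columns(), absent), collapse = ", "))
  }
  if (length(absent)) {
    stop("schema error: missing required column(s): ",
         paste(absent, collapse = ", "))
  }

  # order columns as registered (optional ones only if present)
  keep <- schema$name[schema$name %in% names(df)]
  df <- df[, keep, drop = FALSE]

  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(df)) next
    if (schema$value_kind[i] == "numeric") {
      if (!is.numeric(df[[nm]])) {
        suppressWarnings(conv <- as.numeric(df[[nm]]))
        bad <- which(!is.na(df[[nm]]) & df[[nm]] != "" & is.na(conv))
        if (length(bad)) {
          stop(sprintf("unparseable numeric cell(s) in column '%s', row(s) %s",
                       nm, paste(utils::head(bad, 5), collapse = ", ")))
        }
        df[[nm]] <- conv
      }
    } else {
      df[[nm]] <- as.character(df[[nm]])
      df[[nm]][!is.na(df[[nm]]) & df[[nm]] == ""] <- NA_character_
    }
  }

  for (tgt in target_columns()) {
    allowed <- schema$allowed_values[[match(tgt, schema$name)]]
    vals <- df[[tgt]]
    bad <- !is.na(vals) & !vals %in% allowed
    if (any(bad)) {
      stop(sprintf("invalid %s value(s): %s", tgt,
                   paste(unique(vals[bad]), collapse = ", ")))
    }
  }

  class(df) <- c("patient_table", "data.frame")
  df
}

#' Read a patient table from CSV
#'
#' CSV dialect: comma-separated, UTF-8, mandatory header row, empty string =
#' null. Headers are matched exactly against the registry (after alias
#' normalization of curly apostrophes / trailing whitespace).
#'
#' @param path Path to a CSV file.
#' @param strict Reject unknown columns instead of dropping them.
#' @return A `patient_table`.
#' @export
read_patient_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "",
                        fileEncoding = "UTF-8")
  patient_table(df, strict = strict)
}

#' Write a patient table to CSV
#'
#' Inverse of [read_patient_csv()]: nulls become empty cells, so a
#' read-after-write reproduces the table cell for cell.
#'
#' @param table A `patient_table`.
#' @param path Output path.
#' @export
write_patient_csv <- function(table, path) {
  stopifnot(inherits(table, "patient_table") || is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Class distribution of the two targets
#'
#' Counts non-null target values per registered class (zero for classes that
#' never occur).
#'
#' @param table A `patient_table`.
#' @return List with integer vectors `disorder` (length 3, named) and
#'   `subclass` (length 9, named).
#' @export
class_distribution <- function(table) {
  cnt <- function(values, classes) {
    v <- values[!is.na(values)]
    out <- vapply(classes, function(k) sum(v == k), 0L)
    names(out) <- classes
    out
  }
  list(disorder = cnt(table[["Genetic Disorder"]], disorder_classes()),
       subclass = cnt(table[["Disorder Subclass"]], subclass_classes()))
}
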