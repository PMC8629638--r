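#' Canonical claim field levels
#'
#' The closed category sets used throughout the package for inpatient
#' cerebrovascular claims. One claim is one hospitalization; the cohort is
#' defined by a principal ICD-10 diagnosis in the I60--I69 block.
#'
#' @return A named list of character vectors, one per categorical field.
#' @export
#' @examples
#' claim_levels()$hospital_level
claim_levels <- function() {
  list(
    gender = c("male", "female"),
    insurance = c("urban", "rural"),
    hospital_level = c("secondary_B", "secondary_A", "tertiary_B", "tertiary_A"),
    hospital_type = c("comprehensive", "township", "community", "school", "other"),
    surgery = c("yes", "no", "unknown"),
    discharge = c("recovery", "transfer", "death", "other", "midway_checkout"),
    cc = c("ischemic_supply", "lacunar_infarction", "cerebral_infarction",
           "chronic_ischemia", "other"),
    icd = paste0("I6", 0:9)
  )
}

claim_columns <- function() {
  c("patient_id", "gender", "age", "insurance", "hospital_level",
    "hospital_type", "los", "surgery", "discharge", "cc", "htn3", "icd",
    "cost", "in_city")
}

# Columns that must be present in an input CSV (patient_id is optional and
# synthesized from the row number when absent).
mandatory_columns <- function() setdiff(claim_columns(), "patient_id")

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

# Coerce one raw character column to its canonical type, returning the parsed
# vector plus a per-row failure message (NA when the row is fine).
parse_claim_column <- function(x, field) {
  lv <- claim_levels()
  msg <- rep(NA_character_, length(x))
  x <- trimws(as.character(x))
  blank <- is.na(x) | x == ""
  if (field %in% c("age", "los")) {
    v <- suppressWarnings(as.numeric(x))
    bad <- !blank & (is.na(v) | v < 0 | v != floor(v))
    msg[blank] <- paste(field, "missing")
    msg[bad] <- paste(field, "not a nonnegative integer")
    v[blank | bad] <- NA
    return(list(value = as.integer(v), problem = msg))
  }
  if (field == "cost") {
    v <- suppressWarnings(as.numeric(x))
    msg[blank] <- "cost missing"
    msg[!blank & is.na(v)] <- "cost unparseable"
    msg[!blank & !is.na(v) & v < 0] <- "cost negative"
    v[!is.na(msg)] <- NA
    return(list(value = v, problem = msg))
  }
  if (field %in% c("htn3", "in_city")) {
    v <- parse_flag(x)
    msg[is.na(v)] <- paste(field, "not a logical flag")
    return(list(value = v, problem = msg))
  }
  if (field == "icd") {
    bad <- !grepl("^I6[0-9]$", x)
    msg[bad] <- "icd outside I60-I69"
    x[bad] <- NA_character_
    return(list(value = x, problem = msg))
  }
  if (field %in% names(lv)) {
    bad <- !(x %in% lv[[field]])
    msg[bad] <- paste0(field, " not one of {", paste(lv[[field]], collapse = ", "), "}")
    v <- factor(ifelse(bad, NA_character_, x), levels = lv[[field]])
    return(list(value = v, problem = msg))
  }
  list(value = x, problem = msg)
}

#' Read an inpatient claims CSV
#'
#' Reads a UTF-8, comma-separated claims table with a header row into the
#' canonical claims tibble. Unknown columns are ignored. An optional schema
#' maps a foreign dialect's column names and category labels (for instance
#' numeric codes such as `"1"` for male) onto the canonical ones, so other
#' claims extracts can be ingested without code changes.
#'
#' Rows that violate a field invariant (negative cost, ICD code outside
#' I60--I69, unknown category label, ...) are excluded -- never silently
#' coerced -- and reported with their row number and offending field in the
#' problems table attached to the result; retrieve it with [claim_problems()].
#'
#' @param path Path to a CSV file.
#' @param schema Optional list with elements `columns` (named character
#'   vector, canonical name -> file column name) and `levels` (named list of
#'   named character vectors, foreign label -> canonical label, per field).
#'   May also be a path to a YAML file with those two keys.
#' @return A claims tibble (one row per hospitalization, canonical types),
#'   with a `problems` attribute (tibble with `row`, `field`, `message`).
#' @seealso [write_claims()], [clean_claims()]
#' @export
read_claims <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("claims file not found: ", path))
  if (is.character(schema) && length(schema) == 1L) {
    schema <- yaml::read_yaml(schema)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema$columns)) {
    cmap <- schema$columns
    for (canon in names(cmap)) {
      if (cmap[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == cmap[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(mandatory_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"patient_id" %in% names(raw)) {
    raw$patient_id <- sprintf("row%06d", seq_len(nrow(raw)))
  }
  if (!is.null(schema$levels)) {
    for (field in names(schema$levels)) {
      if (!field %in% names(raw)) next
      lmap <- unlist(schema$levels[[field]])
      hit <- raw[[field]] %in% names(lmap)
      raw[[field]][hit] <- unname(lmap[raw[[field]][hit]])
    }
  }

  parsed <- list(patient_id = as.character(raw$patient_id))
  problems <- list()
  for (field in mandatory_columns()) {
    p <- parse_claim_column(raw[[field]], field)
    parsed[[field]] <- p$value
    bad <- which(!is.na(p$problem))
    if (length(bad) > 0) {
      problems[[field]] <- tibble::tibble(row = bad, field = field,
                                          message = p$problem[bad])
    }
  }
  problems <- if (length(problems) > 0) {
    dplyr::arrange(dplyr::bind_rows(problems), .data$row, .data$field)
  } else {
    tibble::tibble(row = integer(), field = character(), message = character())
  }
  claims <- tibble::as_tibble(parsed)[, claim_columns()]
  keep <- !seq_len(nrow(claims)) %in% problems$row
  claims <- claims[keep, ]
  attr(claims, "problems") <- problems
  claims
}

#' Row-level problems recorded while reading claims
#'
#' @param claims A claims tibble returned by [read_claims()].
#' @return A tibble with columns `row`, `field`, `message` (empty when every
#'   row parsed cleanly).
#' @export
claim_problems <- function(claims) {
  attr(claims, "problems") %||%
    tibble::tibble(row = integer(), field = character(), message = character())
}

#' Write claims to the canonical CSV dialect
#'
#' UTF-8, comma-separated, header row, canonical column names and category
#' labels, logicals as `TRUE`/`FALSE`. Reading the file back with
#' [read_claims()] reproduces every retained field.
#'
#' @param claims A claims tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  out <- dplyr::mutate(claims, dplyr::across(dplyr::where(is.factor), as.character))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
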