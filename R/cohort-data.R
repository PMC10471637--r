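#' @importFrom rlang .data
NULL

# Fixed long-format CSV schema: one tendon measurement per row, patient
# fields repeated. UTF-8, comma separator, "." decimal mark — not sniffed.
COHORT_COLUMNS <- c(
  "patient_id", "age_years", "sex", "side", "actual_graft_mm",
  "reader", "session", "tendon", "major_mm", "minor_mm"
)

SESSIONS <- c("t0", "t1month")
TENDONS <- c("ST", "GT")
SEXES <- c("M", "F")
SIDES <- c("left", "right")

#' Construct a graft cohort
#'
#' A cohort is a long-format table of tendon measurements — one row per
#' patient x reader x session x tendon — together with free-form provenance
#' metadata. A complete patient record has 2 readers x 2 sessions x 2
#' tendons = 8 rows. Diameters are in mm on a 0.1-mm grid (the resolution of
#' the MRI measurement software); the constructor snaps them to that grid.
#'
#' @param data Data frame with columns `patient_id`, `age_years`, `sex`
#'   (`"M"`/`"F"`), `side` (`"left"`/`"right"`), `actual_graft_mm` (integer
#'   mm from the surgical report; may be `NA` for prediction-only use),
#'   `reader`, `session` (`"t0"`/`"t1month"`), `tendon` (`"ST"`/`"GT"`),
#'   `major_mm`, `minor_mm`.
#' @param metadata Named list of provenance (source, generation seed and
#'   config if synthetic). Stored as an attribute, never written to CSV.
#' @return An object of class `graft_cohort` (a tibble subclass).
#' @seealso [read_cohort_csv()], [validate_cohort()], [simulate_cohort()]
#' @export
graft_cohort <- function(data, metadata = list()) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(COHORT_COLUMNS, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[COHORT_COLUMNS]
  data$patient_id <- as.character(data$patient_id)
  data$reader <- as.character(data$reader)
  data$age_years <- as.integer(data$age_years)
  data$actual_graft_mm <- as.integer(data$actual_graft_mm)
  data$major_mm <- snap_tenth(as.numeric(data$major_mm))
  data$minor_mm <- snap_tenth(as.numeric(data$minor_mm))
  structure(data,
            metadata = metadata,
            class = c("graft_cohort", class(data)))
}

#' Cohort metadata
#'
#' @param cohort A [graft_cohort()].
#' @return The provenance metadata list.
#' @export
cohort_metadata <- function(cohort) attr(cohort, "metadata") %||% list()

#' Number of patients in a cohort
#'
#' @param cohort A [graft_cohort()].
#' @return Integer count of distinct patients.
#' @export
n_patients <- function(cohort) length(unique(cohort$patient_id))

#' @export
print.graft_cohort <- function(x, ...) {
  cat(sprintf("<graft_cohort> %d patients, %d measurement rows\n",
              n_patients(x), nrow(x)))
  meta <- cohort_metadata(x)
  if (!is.null(meta$source)) cat("  source:", meta$source, "\n")
  NextMethod()
}

#' Read a cohort CSV file
#'
#' Reads the fixed long-format schema (header exactly
#' `patient_id,age_years,sex,side,actual_graft_mm,reader,session,tendon,major_mm,minor_mm`)
#' and returns a validated cohort. Rows violating the measurement invariants
#' (non-positive diameters, minor > major, off-grid values, unknown factor
#' levels) are rejected with row-addressed diagnostics.
#'
#' @param path Path to a CSV file.
#' @return A [graft_cohort()] whose rows satisfy the per-measurement
#'   invariants. Record-level problems (incomplete records, age below 18,
#'   missing actual size) are reported by [validate_cohort()], not here.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # readr's parse warnings are converted to row-addressed errors below
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      age_years = readr::col_integer(),
      sex = readr::col_character(),
      side = readr::col_character(),
      actual_graft_mm = readr::col_integer(),
      reader = readr::col_character(),
      session = readr::col_character(),
      tendon = readr::col_character(),
      major_mm = readr::col_double(),
      minor_mm = readr::col_double()
    ),
    locale = readr::locale(decimal_mark = ".", encoding = "UTF-8"),
    progress = FALSE
  ))
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("CSV schema error in '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_problems <- readr::problems(raw)
  if (nrow(parse_problems) > 0) {
    stop("parse error in '", path, "' at row(s) ",
         paste(unique(parse_problems$row), collapse = ", "),
         ": expected numeric/integer values", call. = FALSE)
  }
  issues <- measurement_row_issues(raw)
  if (nrow(issues) > 0) {
    stop("invalid measurement rows in '", path, "':\n",
         paste(sprintf("  row %d: %s", issues$row, issues$message),
               collapse = "\n"),
         call. = FALSE)
  }
  graft_cohort(raw, metadata = list(source = path))
}

# Per-row (measurement-level) invariant checks; row indices are data rows
# (header excluded). Returns a tibble with columns row, message.
measurement_row_issues <- function(data) {
  msgs <- list()
  add <- function(bad, message) {
    if (any(bad)) {
      msgs[[length(msgs) + 1]] <<- tibble::tibble(row = which(bad), message = message)
    }
  }
  add(is.na(data$major_mm) | is.na(data$minor_mm), "missing diameter value")
  ok <- !is.na(data$major_mm) & !is.na(data$minor_mm)
  add(ok & data$minor_mm <= 0, "non-positive minor diameter")
  add(ok & data$minor_mm > data$major_mm, "minor_mm exceeds major_mm")
  add(ok & (!on_tenth_grid(data$major_mm) | !on_tenth_grid(data$minor_mm)),
      "diameter not on the 0.1-mm grid")
  add(!data$session %in% SESSIONS,
      paste0("unknown session (expected ", paste(SESSIONS, collapse = "/"), ")"))
  add(!data$tendon %in% TENDONS,
      paste0("unknown tendon (expected ", paste(TENDONS, collapse = "/"), ")"))
  add(!is.na(data$sex) & !data$sex %in% SEXES, "unknown sex code")
  add(!is.na(data$side) & !data$side %in% SIDES, "unknown side code")
  if (length(msgs) == 0) {
    return(tibble::tibble(row = integer(), message = character()))
  }
  out <- dplyr::bind_rows(msgs)
  out[order(out$row), ]
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: the written file re-reads to a cohort
#' with identical values (diameters are formatted with exactly one decimal,
#' so the round trip is lossless at the 0.1-mm grid). Metadata is not
#' written.
#'
#' @param cohort A [graft_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- tibble::as_tibble(cohort)
  out$major_mm <- sprintf("%.1f", out$major_mm)
  out$minor_mm <- sprintf("%.1f", out$minor_mm)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a cohort against study constraints
#'
#' Checks record-level study constraints on top of the per-measurement
#' invariants enforced at construction: adult age (the study excludes
#' patients under 18), actual graft diameter within the plausible 5-12 mm
#' surgical range, completeness (8 measurements: 2 readers x 2 sessions x 2
#' tendons), uniqueness of the patient/reader/session/tendon key, and
#' consistency of demographics within a patient. Violations are data, not
#' exceptions: the return value is a tibble with one row per violation.
#'
#' A missing actual graft diameter is accepted (prediction-only records) but
#' flagged with severity `"note"`; agreement analyses skip such records and
#' report the exclusion count. All other violations carry severity
#' `"error"`.
#'
#' @param cohort A [graft_cohort()].
#' @return Tibble with columns `patient_id`, `rule`, `severity`, `message`;
#'   zero rows iff every record satisfies all constraints and completeness.
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  add <- function(patient_id, rule, severity, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      patient_id = patient_id, rule = rule,
      severity = severity, message = message
    )
  }

  per_patient <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$patient_id),
    n_meas = dplyr::n(),
    n_key = dplyr::n_distinct(paste(.data$reader, .data$session, .data$tendon)),
    n_readers = dplyr::n_distinct(.data$reader),
    age = .data$age_years[1],
    n_age = dplyr::n_distinct(.data$age_years),
    n_sex = dplyr::n_distinct(.data$sex),
    n_side = dplyr::n_distinct(.data$side),
    n_actual = dplyr::n_distinct(.data$actual_graft_mm),
    actual = .data$actual_graft_mm[1],
    .groups = "drop"
  )

  for (i in seq_len(nrow(per_patient))) {
    p <- per_patient[i, ]
    if (p$n_meas != 8L || p$n_key != 8L || p$n_readers != 2L) {
      add(p$patient_id, "incomplete_measurements", "error",
          sprintf("expected 8 distinct reader x session x tendon measurements, found %d rows (%d distinct)",
                  p$n_meas, p$n_key))
    }
    if (is.na(p$age) || p$age < 18L) {
      add(p$patient_id, "age_below_18", "error",
          sprintf("age %s is below the adult inclusion threshold of 18 years",
                  ifelse(is.na(p$age), "missing", p$age)))
    }
    if (p$n_age > 1L || p$n_sex > 1L || p$n_side > 1L || p$n_actual > 1L) {
      add(p$patient_id, "inconsistent_demographics", "error",
          "demographic or actual-size fields differ across the patient's rows")
    }
    if (is.na(p$actual)) {
      add(p$patient_id, "missing_actual_graft", "note",
          "actual graft diameter missing; record usable for prediction only")
    } else if (p$actual < 5L || p$actual > 12L) {
      add(p$patient_id, "actual_graft_out_of_range", "error",
          sprintf("actual graft %d mm outside the plausible 5-12 mm range", p$actual))
    }
  }

  if (length(v) == 0) {
    return(tibble::tibble(patient_id = character(), rule = character(),
                          severity = character(), message = character()))
  }
  out <- dplyr::bind_rows(v)
  out[order(out$patient_id, out$rule), ]
}

#' Is a cohort free of validation errors?
#'
#' @param cohort A [graft_cohort()].
#' @return `TRUE` iff [validate_cohort()] reports no `"error"`-severity
#'   violations (notes, e.g. missing actual sizes, are allowed).
#' @export
cohort_is_valid <- function(cohort) {
  viol <- validate_cohort(cohort)
  !any(viol$severity == "error")
}
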