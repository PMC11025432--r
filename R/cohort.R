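#' Construct a validated MLTC cohort
#'
#' A cohort bundles a patient table and a diagnosis-event table. Patients
#' carry demographics (age at the index date, gender, ethnicity, IMD decile
#' of residence where 1 is least deprived), a de-registration flag and three
#' one-year binary outcomes (death from any cause, any emergency-department
#' attendance, any emergency hospital admission). Events carry one row per
#' patient-disease pair holding the age at the earliest recorded diagnosis.
#'
#' Validation enforces the MLTC inclusion rule (two or more distinct
#' long-term conditions per patient); patients with fewer are dropped with a
#' message, mirroring cohort construction from an EHR extract. Duplicate
#' patient-disease rows are collapsed to the earliest diagnosis age with a
#' warning. Diagnoses after the index date or diseases absent from the
#' accompanying cluster map are errors.
#'
#' @param patients Data frame with columns `patient_id`, `age_at_index`,
#'   `gender` (`"female"`/`"male"`), `ethnicity`, `imd_decile` (integer
#'   1-10), `deregistered` (logical or 0/1), and the three outcome columns
#'   `death`, `ed_attendance`, `emergency_admission` (logical or 0/1).
#' @param events Data frame with columns `patient_id`, `disease_id`,
#'   `age_at_diagnosis`.
#' @param map Optional [cluster_map()]; when supplied, every event's disease
#'   must appear in it.
#' @param index_date_label Free-text label for the index date the ages refer
#'   to.
#' @return A list of class `cohort` with elements `patients`, `events`
#'   (tibbles) and `index_date_label`.
#' @export
cohort <- function(patients, events, map = NULL, index_date_label = "index") {
  patients <- as_tibble(patients)
  events <- as_tibble(events)

  pat_cols <- c(
    "patient_id", "age_at_index", "gender", "ethnicity", "imd_decile",
    "deregistered", outcome_names()
  )
  ev_cols <- c("patient_id", "disease_id", "age_at_diagnosis")
  check_columns(patients, pat_cols, "patient table")
  check_columns(events, ev_cols, "event table")

  patients <- mutate(patients,
    patient_id = as.character(.data$patient_id),
    age_at_index = as.numeric(.data$age_at_index),
    gender = as.character(.data$gender),
    ethnicity = as.character(.data$ethnicity),
    imd_decile = as.integer(.data$imd_decile),
    deregistered = as.logical(.data$deregistered),
    across(all_of(outcome_names()), ~ as.integer(as.logical(.x)))
  )
  events <- mutate(events,
    patient_id = as.character(.data$patient_id),
    disease_id = as.character(.data$disease_id),
    age_at_diagnosis = as.numeric(.data$age_at_diagnosis)
  )

  if (anyDuplicated(patients$patient_id)) {
    abort("duplicate patient_id in patient table", class = "mltc_validation_error")
  }
  if (any(patients$age_at_index < 18)) {
    abort("age_at_index below 18: cohort is adults only",
          class = "mltc_validation_error")
  }
  bad_imd <- !is.na(patients$imd_decile) &
    (patients$imd_decile < 1 | patients$imd_decile > 10)
  if (any(bad_imd)) {
    abort("imd_decile outside 1-10", class = "mltc_validation_error")
  }

  if (!is.null(map)) {
    unknown <- setdiff(unique(events$disease_id), map$disease_id)
    if (length(unknown) > 0) {
      abort(paste0(
        "event disease_id(s) not in cluster map: ",
        paste(utils::head(unknown, 5), collapse = ", ")
      ), class = "mltc_referential_error")
    }
  }
  orphan <- setdiff(unique(events$patient_id), patients$patient_id)
  if (length(orphan) > 0) {
    abort(paste0("event patient_id(s) not in patient table: ",
                 paste(utils::head(orphan, 5), collapse = ", ")),
          class = "mltc_referential_error")
  }

  # collapse duplicate patient-disease rows to the earliest diagnosis
  n_raw <- nrow(events)
  events <- events |>
    group_by(.data$patient_id, .data$disease_id) |>
    summarise(age_at_diagnosis = min(.data$age_at_diagnosis), .groups = "drop")
  if (nrow(events) < n_raw) {
    warn(sprintf(
      "%d duplicate diagnosis row(s) collapsed to the earliest age",
      n_raw - nrow(events)
    ))
  }

  idx <- setNames(patients$age_at_index, patients$patient_id)
  late <- events$age_at_diagnosis > idx[events$patient_id] + 1e-9
  if (any(late)) {
    abort(paste0(
      "age_at_diagnosis after age_at_index for ", sum(late), " row(s), e.g. ",
      paste(utils::head(paste0(events$patient_id[late], "/",
                               events$disease_id[late]), 5), collapse = ", ")
    ), class = "mltc_validation_error")
  }
  if (any(events$age_at_diagnosis <= 0)) {
    abort("age_at_diagnosis must be positive", class = "mltc_validation_error")
  }

  # MLTC inclusion: >= 2 distinct diseases
  counts <- events |> count(.data$patient_id, name = "n_ltc")
  keep <- counts$patient_id[counts$n_ltc >= 2]
  dropped <- nrow(patients) - length(keep)
  if (dropped > 0) {
    inform(sprintf(
      "dropped %d patient(s) with fewer than 2 long-term conditions", dropped
    ))
    patients <- filter(patients, .data$patient_id %in% keep)
    events <- filter(events, .data$patient_id %in% keep)
  }
  if (nrow(patients) == 0) {
    abort("no patients with two or more long-term conditions",
          class = "mltc_validation_error")
  }

  structure(
    list(
      patients = arrange(patients, .data$patient_id),
      events = arrange(events, .data$patient_id, .data$disease_id),
      index_date_label = index_date_label
    ),
    class = "cohort"
  )
}

check_columns <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")),
          class = "mltc_format_error")
  }
  invisible(x)
}

#' Load a cohort from patient and event CSV files
#'
#' Reads `patients.csv` (schema: `patient_id,age_at_index,gender,ethnicity,`
#' `imd_decile,deregistered,death,ed_attendance,emergency_admission`, booleans
#' as 0/1) and `events.csv` (`patient_id,disease_id,age_at_diagnosis`), then
#' validates them with [cohort()] against `map`.
#'
#' @param patients_path,events_path CSV file paths.
#' @param map A [cluster_map()] the events must reference.
#' @param index_date_label Label stored on the cohort.
#' @return A validated `cohort`.
#' @export
load_cohort <- function(patients_path, events_path, map,
                        index_date_label = "index") {
  for (p in c(patients_path, events_path)) {
    if (!file.exists(p)) {
      abort(paste0("file not found: ", p), class = "mltc_format_error")
    }
  }
  patients <- readr::read_csv(patients_path, col_types = readr::cols(
    patient_id = readr::col_character(),
    age_at_index = readr::col_double(),
    gender = readr::col_character(),
    ethnicity = readr::col_character(),
    imd_decile = readr::col_integer(),
    deregistered = readr::col_integer(),
    death = readr::col_integer(),
    ed_attendance = readr::col_integer(),
    emergency_admission = readr::col_integer()
  ))
  events <- readr::read_csv(events_path, col_types = readr::cols(
    patient_id = readr::col_character(),
    disease_id = readr::col_character(),
    age_at_diagnosis = readr::col_double()
  ))
  cohort(patients, events, map = map, index_date_label = index_date_label)
}

#' Write a cohort to patient and event CSV files
#'
#' Inverse of [load_cohort()]: logical flags are written as 0/1.
#'
#' @param x A `cohort`.
#' @param patients_path,events_path Output CSV paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_cohort <- function(x, patients_path, events_path) {
  stopifnot(inherits(x, "cohort"))
  pat <- mutate(x$patients, deregistered = as.integer(.data$deregistered))
  readr::write_csv(pat, patients_path)
  readr::write_csv(x$events, events_path)
  invisible(c(patients_path, events_path))
}

#' Exclude patients who de-registered during follow-up
#'
#' Removes patients flagged as having left a contributing practice during the
#' one-year follow-up window, so that all retained patients have equal
#' follow-up time. The excluded count and fraction are reported via a message.
#'
#' @param x A `cohort`.
#' @return The sub-cohort with `deregistered == FALSE`.
#' @export
apply_followup_exclusion <- function(x) {
  stopifnot(inherits(x, "cohort"))
  n0 <- nrow(x$patients)
  keep <- !x$patients$deregistered
  n_excl <- sum(!keep)
  inform(sprintf(
    "follow-up exclusion: removed %d of %d patients (%.1f%%) who de-registered",
    n_excl, n0, 100 * n_excl / max(n0, 1)
  ))
  x$patients <- x$patients[keep, , drop = FALSE]
  x$events <- filter(x$events, .data$patient_id %in% x$patients$patient_id)
  x
}

#' @export
print.cohort <- function(x, ...) {
  nd <- x$events |> count(.data$patient_id) |> pull(n)
  cat(sprintf(
    "<cohort> %d patients, %d diagnosis events (median %d LTCs per patient)\n",
    nrow(x$patients), nrow(x$events), as.integer(median(nd))
  ))
  invisible(x)
}
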