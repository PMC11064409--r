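# Structured-EMR data model: five delimited tables (children, encounters,
# diagnoses, procedures, lab_orders), validation, readers/writers, and the
# derived temporal quantities (term status, postmenstrual age, hospitalization
# episodes) consumed by the criteria engine.
#
# Data dictionary (CSV headers; dates ISO-8601, timestamps
# "YYYY-MM-DD HH:MM:SS" in UTC, date-only timestamps span the whole day):
#   children:   child_id, mother_id, birth_date, gestational_age_days,
#               death_date (optional)
#   encounters: encounter_id, child_id, encounter_class {inpatient, emergency,
#               outpatient, icu, cticu, specialist_visit}, specialty (required
#               iff specialist_visit), start, end (optional),
#               discharge_disposition (optional)
#   diagnoses:  child_id, icd_code, date, encounter_id
#   procedures: child_id, code, name, date, status {completed, cancelled,
#               preliminary, final}, surgical (logical), cardiothoracic
#               (logical)
#   lab_orders: child_id, category {genetic_test, metabolic_test, imaging_ct,
#               imaging_mri, other}, date, status

ENCOUNTER_CLASSES <- c("inpatient", "emergency", "outpatient", "icu",
                       "cticu", "specialist_visit")
EMPTY_EPISODES <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                             end = as.POSIXct(character(), tz = "UTC"),
                             duration_hours = numeric(),
                             censored = logical(),
                             age_start_days = numeric())
ORDER_STATUSES <- c("completed", "cancelled", "preliminary", "final")
LAB_CATEGORIES <- c("genetic_test", "metabolic_test", "imaging_ct",
                    "imaging_mri", "other")

#' Derive term status from gestational age at birth
#'
#' Pre-term is defined as birth before 37 completed weeks of gestation
#' (259 days), the standard clinical cutoff.
#'
#' @param gestational_age_days integer days of gestation at birth; must lie
#'   in \[140, 315\].
#' @param cutoff_days pre-term cutoff (default 259 = 37 weeks).
#' @return Character vector: "pre_term" or "full_term".
#' @export
#' @examples
#' derive_term_status(c(280, 258, 259))
derive_term_status <- function(gestational_age_days, cutoff_days = 259) {
  ga <- as.numeric(gestational_age_days)
  if (any(is.na(ga) | ga < 140 | ga > 315)) {
    stop("gestational_age_days must lie in [140, 315]", call. = FALSE)
  }
  ifelse(ga < cutoff_days, "pre_term", "full_term")
}

#' Postmenstrual age at a date
#'
#' Gestational age at birth plus chronological age, in days. Used to filter
#' hospitalizations occurring before 35 weeks (245 days) postmenstrual age.
#'
#' @param gestational_age_days gestational age at birth in days.
#' @param birth_date birth date.
#' @param date calendar date at which to compute the postmenstrual age; must
#'   not precede the birth date.
#' @return Numeric days.
#' @export
#' @examples
#' postmenstrual_age(196, as.Date("2020-01-01"), as.Date("2020-02-19"))
postmenstrual_age <- function(gestational_age_days, birth_date, date) {
  age <- as.numeric(as.Date(date) - as.Date(birth_date))
  if (any(age < 0)) {
    stop("date precedes birth date", call. = FALSE)
  }
  as.numeric(gestational_age_days) + age
}

#' Derive hospitalization episodes from encounters
#'
#' Filters encounters to the requested class(es), merges overlapping or
#' contiguous stays into single episodes (a same-moment transfer is not a new
#' hospitalization), and computes durations in hours. Open-ended stays are
#' censored at the observation limit and flagged.
#'
#' @param encounters encounter table for one child.
#' @param birth_date the child's birth date.
#' @param observation_days observation window length in days (default 1095).
#' @param classes encounter classes to treat as stays (default "inpatient").
#' @return data.frame with columns start, end, duration_hours, censored,
#'   age_start_days; zero rows when no qualifying encounter exists.
#' @export
hospitalization_episodes <- function(encounters, birth_date,
                                     observation_days = 1095,
                                     classes = "inpatient") {
  birth0 <- as_utc_midnight(birth_date)
  limit <- birth0 + observation_days * 86400
  empty <- EMPTY_EPISODES
  if (is.null(encounters) || nrow(encounters) == 0L) return(empty)
  enc <- encounters[encounters$encounter_class %in% classes, , drop = FALSE]
  if (nrow(enc) == 0L) return(empty)
  start <- parse_event_time(enc$start, "start")
  end <- parse_event_time(enc$end, "end")
  keep <- start <= limit
  start <- start[keep]; end <- end[keep]
  if (!length(start)) return(empty)
  censored <- is.na(end) | end > limit
  end[is.na(end) | end > limit] <- limit
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]; censored <- censored[ord]
  ep_start <- start[1L]; ep_end <- end[1L]; ep_cens <- censored[1L]
  out <- list()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ep_end) {                 # overlap or zero gap: merge
      if (end[i] > ep_end) ep_end <- end[i]
      ep_cens <- ep_cens || censored[i]
    } else {
      out[[length(out) + 1L]] <- list(ep_start, ep_end, ep_cens)
      ep_start <- start[i]; ep_end <- end[i]; ep_cens <- censored[i]
    }
  }
  out[[length(out) + 1L]] <- list(ep_start, ep_end, ep_cens)
  starts <- as.POSIXct(vapply(out, function(e) as.numeric(e[[1L]]), 0),
                       tz = "UTC", origin = "1970-01-01")
  ends <- as.POSIXct(vapply(out, function(e) as.numeric(e[[2L]]), 0),
                     tz = "UTC", origin = "1970-01-01")
  data.frame(start = starts, end = ends,
             duration_hours = as.numeric(difftime(ends, starts,
                                                  units = "hours")),
             censored = vapply(out, function(e) e[[3L]], TRUE),
             age_start_days = age_in_days(birth_date, starts))
}

# Column templates -----------------------------------------------------------

empty_children_table <- function() {
  data.frame(child_id = character(), mother_id = character(),
             birth_date = as.Date(character()),
             gestational_age_days = integer(),
             death_date = as.Date(character()),
             stringsAsFactors = FALSE)
}

empty_encounters_table <- function() {
  data.frame(encounter_id = character(), child_id = character(),
             encounter_class = character(), specialty = character(),
             start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             discharge_disposition = character(),
             stringsAsFactors = FALSE)
}

empty_diagnoses_table <- function() {
  data.frame(child_id = character(), icd_code = character(),
             date = as.Date(character()), encounter_id = character(),
             stringsAsFactors = FALSE)
}

empty_procedures_table <- function() {
  data.frame(child_id = character(), code = character(), name = character(),
             date = as.Date(character()), status = character(),
             surgical = logical(), cardiothoracic = logical(),
             stringsAsFactors = FALSE)
}

empty_lab_orders_table <- function() {
  data.frame(child_id = character(), category = character(),
             date = as.Date(character()), status = character(),
             stringsAsFactors = FALSE)
}

#' An empty cohort
#' @param observation_days observation window in days.
#' @return An `emr_cohort` with zero children.
#' @export
empty_cohort <- function(observation_days = 1095) {
  cohort(empty_children_table(), empty_encounters_table(),
         empty_diagnoses_table(), empty_procedures_table(),
         empty_lab_orders_table(), observation_days = observation_days)
}

# Validation helpers ---------------------------------------------------------

check_columns <- function(df, expected, table) {
  missing <- setdiff(expected, names(df))
  unknown <- setdiff(names(df), expected)
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", table,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(unknown)) {
    stop(sprintf("%s: unknown column(s): %s", table,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  df[, expected, drop = FALSE]
}

check_enum <- function(x, allowed, table, column) {
  bad <- which(!is.na(x) & !(x %in% allowed))
  if (length(bad)) {
    stop(sprintf("%s: invalid %s '%s' in row %d", table, column,
                 x[bad[1L]], bad[1L]), call. = FALSE)
  }
}

check_child_ids <- function(x, known, table) {
  bad <- which(!(x %in% known))
  if (length(bad)) {
    stop(sprintf("%s: unknown child_id '%s' in row %d", table,
                 x[bad[1L]], bad[1L]), call. = FALSE)
  }
}

# Drop rows dated after the observation window (with a log line) and error on
# rows dated before birth. `age` is in completed days since birth.
censor_window <- function(df, age, observation_days, table) {
  if (!nrow(df)) return(df)
  if (any(age < 0)) {
    stop(sprintf("%s: event dated before birth in row %d", table,
                 which(age < 0)[1L]), call. = FALSE)
  }
  late <- age > observation_days
  if (any(late)) {
    message(sprintf("%s: dropping %d event(s) after the %d-day window",
                    table, sum(late), observation_days))
    df <- df[!late, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Assemble and validate a cohort
#'
#' Bundles the five EMR tables into a validated cohort object. Validation
#' enforces the data dictionary: column sets, enumerations, referential
#' integrity (every event's `child_id` exists; every diagnosis resolves to an
#' encounter of the same child), gestational ages within \[140, 315\] days,
#' death dates not before birth, encounter ends not before starts, and
#' specialty present exactly for specialist visits. Events dated after the
#' observation window are dropped with a log line; events before birth are an
#' error. Censoring is idempotent: re-validating a cohort drops nothing.
#'
#' @param children,encounters,diagnoses,procedures,lab_orders the five tables.
#' @param observation_days observation window in days (default 1095, i.e.
#'   three years of age).
#' @return An object of class `emr_cohort`.
#' @export
cohort <- function(children, encounters, diagnoses, procedures, lab_orders,
                   observation_days = 1095) {
  children <- check_columns(children, names(empty_children_table()),
                            "children")
  encounters <- check_columns(encounters, names(empty_encounters_table()),
                              "encounters")
  diagnoses <- check_columns(diagnoses, names(empty_diagnoses_table()),
                             "diagnoses")
  procedures <- check_columns(procedures, names(empty_procedures_table()),
                              "procedures")
  lab_orders <- check_columns(lab_orders, names(empty_lab_orders_table()),
                              "lab_orders")

  children$child_id <- as.character(children$child_id)
  children$mother_id <- as.character(children$mother_id)
  children$birth_date <- parse_date_col(children$birth_date, "children",
                                        "birth_date")
  children$gestational_age_days <- as.integer(children$gestational_age_days)
  children$death_date <- parse_date_col(children$death_date, "children",
                                        "death_date")
  if (anyDuplicated(children$child_id)) {
    stop("children: duplicate child_id", call. = FALSE)
  }
  if (nrow(children)) {
    derive_term_status(children$gestational_age_days)  # range check
    bad <- which(!is.na(children$death_date) &
                   children$death_date < children$birth_date)
    if (length(bad)) {
      stop(sprintf("children: death_date before birth_date in row %d",
                   bad[1L]), call. = FALSE)
    }
  }

  ids <- children$child_id
  birth_of <- stats::setNames(children$birth_date, ids)

  encounters$encounter_id <- as.character(encounters$encounter_id)
  encounters$child_id <- as.character(encounters$child_id)
  encounters$encounter_class <- as.character(encounters$encounter_class)
  encounters$specialty <- as.character(encounters$specialty)
  encounters$discharge_disposition <-
    as.character(encounters$discharge_disposition)
  encounters$start <- parse_event_time(encounters$start, "start")
  encounters$end <- parse_event_time(encounters$end, "end")
  check_enum(encounters$encounter_class, ENCOUNTER_CLASSES, "encounters",
             "encounter_class")
  check_child_ids(encounters$child_id, ids, "encounters")
  if (nrow(encounters)) {
    if (anyDuplicated(encounters$encounter_id)) {
      stop("encounters: duplicate encounter_id", call. = FALSE)
    }
    bad <- which(!is.na(encounters$end) & encounters$end < encounters$start)
    if (length(bad)) {
      stop(sprintf("encounters: end before start in row %d", bad[1L]),
           call. = FALSE)
    }
    is_spec <- encounters$encounter_class == "specialist_visit"
    has_spec <- !is.na(encounters$specialty) & nzchar(encounters$specialty)
    if (any(is_spec & !has_spec)) {
      stop(sprintf("encounters: specialist_visit without specialty in row %d",
                   which(is_spec & !has_spec)[1L]), call. = FALSE)
    }
    if (any(!is_spec & has_spec)) {
      stop(sprintf("encounters: specialty on non-specialist encounter in row %d",
                   which(!is_spec & has_spec)[1L]), call. = FALSE)
    }
    age <- age_in_days(birth_of[encounters$child_id], encounters$start)
    encounters <- censor_window(encounters, age, observation_days,
                                "encounters")
  }

  diagnoses$child_id <- as.character(diagnoses$child_id)
  diagnoses$icd_code <- as.character(diagnoses$icd_code)
  diagnoses$encounter_id <- as.character(diagnoses$encounter_id)
  diagnoses$date <- parse_date_col(diagnoses$date, "diagnoses", "date")
  check_child_ids(diagnoses$child_id, ids, "diagnoses")
  if (nrow(diagnoses)) {
    enc_child <- stats::setNames(encounters$child_id,
                                 encounters$encounter_id)
    owner <- enc_child[diagnoses$encounter_id]
    bad <- which(is.na(owner) | owner != diagnoses$child_id)
    if (length(bad)) {
      stop(sprintf(
        "diagnoses: encounter_id '%s' in row %d does not resolve to an encounter of the same child",
        diagnoses$encounter_id[bad[1L]], bad[1L]), call. = FALSE)
    }
    age <- age_in_days(birth_of[diagnoses$child_id], diagnoses$date)
    diagnoses <- censor_window(diagnoses, age, observation_days, "diagnoses")
  }

  procedures$child_id <- as.character(procedures$child_id)
  procedures$code <- as.character(procedures$code)
  procedures$name <- as.character(procedures$name)
  procedures$status <- as.character(procedures$status)
  procedures$date <- parse_date_col(procedures$date, "procedures", "date")
  procedures$surgical <- as.logical(procedures$surgical)
  procedures$cardiothoracic <- as.logical(procedures$cardiothoracic)
  check_enum(procedures$status, ORDER_STATUSES, "procedures", "status")
  check_child_ids(procedures$child_id, ids, "procedures")
  if (nrow(procedures)) {
    age <- age_in_days(birth_of[procedures$child_id], procedures$date)
    procedures <- censor_window(procedures, age, observation_days,
                                "procedures")
  }

  lab_orders$child_id <- as.character(lab_orders$child_id)
  lab_orders$category <- as.character(lab_orders$category)
  lab_orders$status <- as.character(lab_orders$status)
  lab_orders$date <- parse_date_col(lab_orders$date, "lab_orders", "date")
  check_enum(lab_orders$category, LAB_CATEGORIES, "lab_orders", "category")
  check_enum(lab_orders$status, ORDER_STATUSES, "lab_orders", "status")
  check_child_ids(lab_orders$child_id, ids, "lab_orders")
  if (nrow(lab_orders)) {
    age <- age_in_days(birth_of[lab_orders$child_id], lab_orders$date)
    lab_orders <- censor_window(lab_orders, age, observation_days,
                                "lab_orders")
  }

  structure(list(children = children, encounters = encounters,
                 diagnoses = diagnoses, procedures = procedures,
                 lab_orders = lab_orders,
                 observation_days = observation_days),
            class = "emr_cohort")
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat(sprintf(paste0("<emr_cohort: %d children, %d encounters, %d diagnoses,",
                     " %d procedures, %d lab orders; %d-day window>\n"),
              nrow(x$children), nrow(x$encounters), nrow(x$diagnoses),
              nrow(x$procedures), nrow(x$lab_orders), x$observation_days))
  invisible(x)
}

#' Read a cohort from a directory of delimited tables
#'
#' Expects `children.csv`, `encounters.csv`, `diagnoses.csv`,
#' `procedures.csv` and `lab_orders.csv` (plain or gzipped) conforming to the
#' data dictionary, and validates them via [cohort()].
#'
#' @param dir directory containing the five tables.
#' @param observation_days observation window in days.
#' @return An `emr_cohort`.
#' @export
read_cohort <- function(dir, observation_days = 1095) {
  read_table <- function(stem) {
    path <- file.path(dir, paste0(stem, ".csv"))
    if (!file.exists(path)) path <- paste0(path, ".gz")
    if (!file.exists(path)) {
      stop("missing table: ", stem, ".csv in ", dir, call. = FALSE)
    }
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = "")
  }
  ch <- read_table("children")
  en <- read_table("encounters")
  dx <- read_table("diagnoses")
  pr <- read_table("procedures")
  lo <- read_table("lab_orders")
  cohort(ch, en, dx, pr, lo, observation_days = observation_days)
}

#' Write a cohort to a directory of delimited tables
#'
#' Serializes the five tables as CSV with ISO-8601 dates and
#' "YYYY-MM-DD HH:MM:SS" UTC timestamps; missing values are written empty.
#' `read_cohort(write_cohort(x, dir))` reproduces `x` exactly.
#'
#' @param x an `emr_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "emr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (nm in names(df)) {
      if (inherits(df[[nm]], "POSIXct")) {
        df[[nm]] <- format(df[[nm]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
      } else if (inherits(df[[nm]], "Date")) {
        df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
      }
    }
    df
  }
  for (stem in c("children", "encounters", "diagnoses", "procedures",
                 "lab_orders")) {
    utils::write.csv(fmt(x[[stem]]), file.path(dir, paste0(stem, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}
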