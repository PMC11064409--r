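# Versioned criterion configuration: identifiers, tiers, scores and the
# numeric thresholds of the thirteen criteria. Shipped as machine-readable
# JSON so threshold changes are data, not code.

#' The thirteen criterion identifiers, in canonical order
#' @return Character vector of length 13.
#' @export
criterion_ids <- function() {
  c("nicu_stay", "hospitalizations", "multiple_specialists", "er_visits",
    "feeding_support", "respiratory_support", "imaging", "genetic_tests",
    "metabolic_tests", "death", "developmental_delay", "metabolic_icd",
    "heart_surgery")
}

#' Load the criterion configuration
#'
#' Reads tiers, scores and thresholds for the thirteen criteria. The default
#' configuration encodes the published rule set: five major criteria scoring
#' 3 (prolonged NICU stay, prolonged/multiple hospitalizations, in-hospital
#' death, recurrent metabolic diagnosis codes, heart surgery), feeding and
#' respiratory support scoring 2, and the remaining six minor criteria
#' scoring 1.
#'
#' @param path optional path to an alternative JSON configuration.
#' @return An object of class `criteria_spec` with elements `criteria`
#'   (data.frame of id, tier, score), `thresholds`, `observation_days`,
#'   `preterm_cutoff_days`, and `version`.
#' @export
default_criteria <- function(path = NULL) {
  path <- path %||% system.file("extdata", "criteria_config.json",
                                package = "pheindex")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  crit <- as.data.frame(cfg$criteria, stringsAsFactors = FALSE)
  if (!setequal(crit$id, criterion_ids()) || anyDuplicated(crit$id)) {
    stop("criterion configuration must define each of the 13 criteria once",
         call. = FALSE)
  }
  crit <- crit[match(criterion_ids(), crit$id), ]
  rownames(crit) <- NULL
  if (sum(crit$tier == "major") != 5L || sum(crit$tier == "minor") != 8L) {
    stop("criterion configuration must have 5 major and 8 minor criteria",
         call. = FALSE)
  }
  if (!all(crit$score %in% 1:3)) {
    stop("criterion scores must be 1, 2 or 3", call. = FALSE)
  }
  structure(list(
    criteria = crit,
    thresholds = cfg$thresholds,
    observation_days = cfg$observation_days,
    preterm_cutoff_days = cfg$preterm_cutoff_days,
    version = cfg$version
  ), class = "criteria_spec")
}

# Threshold lookup, optionally keyed by term status.
spec_threshold <- function(specs, name, term_status = NULL) {
  th <- specs$thresholds[[name]]
  if (is.null(th)) stop("unknown threshold: ", name, call. = FALSE)
  if (!is.null(term_status) && is.list(th)) th <- th[[term_status]]
  as.numeric(th)
}

# Criteria applicable to a term status (prolonged NICU stay applies to
# full-term newborns only).
applicable_criteria <- function(specs, term_status) {
  ids <- specs$criteria$id
  if (identical(term_status, "pre_term")) ids <- setdiff(ids, "nicu_stay")
  ids
}

#' Maximum attainable score
#'
#' Sum of the scores of all criteria applicable to a term status: 25 for
#' full-term children and 22 for pre-term children (where the NICU criterion
#' does not apply).
#'
#' @param specs a [default_criteria()] object.
#' @param term_status "full_term" or "pre_term".
#' @return Integer.
#' @export
max_score <- function(specs, term_status = c("full_term", "pre_term")) {
  term_status <- match.arg(term_status)
  ids <- applicable_criteria(specs, term_status)
  sum(specs$criteria$score[specs$criteria$id %in% ids])
}

#' @export
print.criteria_spec <- function(x, ...) {
  cat(sprintf("<criteria_spec v%s: %d criteria (%d major, %d minor)>\n",
              x$version, nrow(x$criteria),
              sum(x$criteria$tier == "major"),
              sum(x$criteria$tier == "minor")))
  print(x$criteria, row.names = FALSE)
  invisible(x)
}
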