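# Criteria engine: evaluates the thirteen criteria for one child or a whole
# cohort, recording met/not-met, the age (in days) at which each criterion
# first became true, and an evidence count.

#' Extract one child's evaluation bundle from a cohort
#'
#' Collects the child's row and event streams, derives term status, and
#' pre-censors events to the observation window (censoring is idempotent, so
#' bundles built from already-censored cohorts are unchanged).
#'
#' @param x an `emr_cohort`.
#' @param child_id the child to extract.
#' @return A list of class `child_bundle`.
#' @export
child_bundle <- function(x, child_id) {
  stopifnot(inherits(x, "emr_cohort"))
  i <- match(child_id, x$children$child_id)
  if (is.na(i)) stop("unknown child_id: ", child_id, call. = FALSE)
  build_bundle(
    x$children[i, ],
    x$encounters[x$encounters$child_id == child_id, , drop = FALSE],
    x$diagnoses[x$diagnoses$child_id == child_id, , drop = FALSE],
    x$procedures[x$procedures$child_id == child_id, , drop = FALSE],
    x$lab_orders[x$lab_orders$child_id == child_id, , drop = FALSE],
    x$observation_days
  )
}

build_bundle <- function(child_row, encounters, diagnoses, procedures,
                         lab_orders, observation_days) {
  birth <- child_row$birth_date
  keep_enc <- age_in_days(birth, encounters$start) <= observation_days
  keep_dx <- age_in_days(birth, diagnoses$date) <= observation_days
  keep_pr <- age_in_days(birth, procedures$date) <= observation_days
  keep_lo <- age_in_days(birth, lab_orders$date) <= observation_days
  structure(list(
    child_id = child_row$child_id,
    birth_date = birth,
    gestational_age_days = child_row$gestational_age_days,
    term_status = derive_term_status(child_row$gestational_age_days),
    death_date = child_row$death_date,
    encounters = encounters[keep_enc, , drop = FALSE],
    diagnoses = diagnoses[keep_dx, , drop = FALSE],
    procedures = procedures[keep_pr, , drop = FALSE],
    lab_orders = lab_orders[keep_lo, , drop = FALSE],
    observation_days = observation_days
  ), class = "child_bundle")
}

criterion_result <- function(id, met, first_met_age = NA_real_,
                             evidence_count = 0L) {
  list(id = id, met = isTRUE(met),
       first_met_age = if (isTRUE(met)) as.numeric(first_met_age)
                       else NA_real_,
       evidence_count = as.integer(evidence_count))
}

# Non-cancelled procedures of a bundle.
active_procedures <- function(bundle) {
  pr <- bundle$procedures
  pr[pr$status != "cancelled", , drop = FALSE]
}

# Ages (days) of surgery anchors: procedures flagged surgical plus
# cardiothoracic-ICU encounter starts.
surgery_ages <- function(bundle) {
  pr <- active_procedures(bundle)
  s1 <- age_in_days(bundle$birth_date, pr$date[pr$surgical %in% TRUE])
  ct <- bundle$encounters[bundle$encounters$encounter_class == "cticu", ,
                          drop = FALSE]
  s2 <- if (nrow(ct)) age_in_days(bundle$birth_date,
                                  parse_event_time(ct$start, "start"))
        else numeric(0)
  c(s1, s2)
}

#' Prolonged NICU stay (full-term only; major, score 3)
#'
#' Met when a full-term newborn has an ICU-class episode starting within 7
#' days of birth lasting at least 4 days. NICU admission is inferred from
#' early ICU encounters because de-identified extracts rarely carry an
#' explicit NICU flag. The criterion never applies to pre-term children,
#' whose NICU stays reflect prematurity itself.
#'
#' @param bundle a [child_bundle()].
#' @param specs a [default_criteria()] object.
#' @return A criterion result list (id, met, first_met_age, evidence_count).
#' @export
evaluate_nicu_stay <- function(bundle, specs = default_criteria()) {
  if (bundle$term_status == "pre_term") {
    return(criterion_result("nicu_stay", FALSE))
  }
  min_days <- spec_threshold(specs, "nicu_min_days")
  window <- spec_threshold(specs, "nicu_birth_window_days")
  ep <- hospitalization_episodes(bundle$encounters, bundle$birth_date,
                                 bundle$observation_days, classes = "icu")
  ok <- ep$age_start_days <= window & ep$duration_hours >= min_days * 24
  criterion_result("nicu_stay", any(ok),
                   first_met_age = if (any(ok))
                     min(ep$age_start_days[ok]) + min_days,
                   evidence_count = sum(ok))
}

#' Prolonged or multiple hospitalizations (major, score 3)
#'
#' Hospitalization = merged inpatient episode lasting at least 48 h. Episodes
#' admitted at postmenstrual age of 35 weeks (245 days) or less — including
#' the birth hospitalization of very pre-term children — are excluded. Met
#' when some eligible episode lasts at least 14 days, or when the count of
#' eligible episodes reaches 2 (full-term) or 3 (pre-term).
#'
#' @inheritParams evaluate_nicu_stay
#' @return A criterion result list.
#' @export
evaluate_hospitalizations <- function(bundle, specs = default_criteria()) {
  min_h <- spec_threshold(specs, "hosp_min_hours")
  long_d <- spec_threshold(specs, "hosp_prolonged_days")
  k <- spec_threshold(specs, "hosp_min_count", bundle$term_status)
  min_pma <- spec_threshold(specs, "hosp_min_pma_days")
  ep <- hospitalization_episodes(bundle$encounters, bundle$birth_date,
                                 bundle$observation_days)
  if (!nrow(ep)) return(criterion_result("hospitalizations", FALSE))
  pma <- bundle$gestational_age_days + ep$age_start_days
  ep <- ep[ep$duration_hours >= min_h & pma > min_pma, , drop = FALSE]
  if (!nrow(ep)) return(criterion_result("hospitalizations", FALSE))
  ages <- numeric(0)
  long_ok <- ep$duration_hours >= long_d * 24
  if (any(long_ok)) {
    ages <- c(ages, min(ep$age_start_days[long_ok]) + long_d)
  }
  if (nrow(ep) >= k) {
    ages <- c(ages, sort(ep$age_start_days)[k])
  }
  criterion_result("hospitalizations", length(ages) > 0,
                   first_met_age = if (length(ages)) min(ages),
                   evidence_count = nrow(ep))
}

#' Visits to multiple types of specialists (minor, score 1)
#'
#' Counts the number of distinct included specialty types visited (not the
#' number of visits); met at 3 types for full-term and 4 for pre-term
#' children. Excluded specialties (Pediatric Infectious Disease by default)
#' never count.
#'
#' @inheritParams evaluate_nicu_stay
#' @param taxonomy a [specialty_taxonomy()].
#' @return A criterion result list.
#' @export
evaluate_multiple_specialists <- function(bundle,
                                          taxonomy =
                                            default_specialty_taxonomy(),
                                          specs = default_criteria()) {
  k <- spec_threshold(specs, "specialist_types", bundle$term_status)
  enc <- bundle$encounters
  enc <- enc[enc$encounter_class == "specialist_visit", , drop = FALSE]
  if (nrow(enc)) {
    counted <- tolower(enc$specialty) %in% tolower(taxonomy$included) &
      !(tolower(enc$specialty) %in% tolower(taxonomy$excluded))
    enc <- enc[counted, , drop = FALSE]
  }
  if (!nrow(enc)) return(criterion_result("multiple_specialists", FALSE))
  age <- age_in_days(bundle$birth_date, parse_event_time(enc$start, "start"))
  ord <- order(age)
  first_seen <- !duplicated(tolower(enc$specialty)[ord])
  n_types <- sum(first_seen)
  met <- n_types >= k
  criterion_result("multiple_specialists", met,
                   first_met_age = if (met) age[ord][first_seen][k],
                   evidence_count = n_types)
}

#' Multiple emergency-room visits (minor, score 1)
#'
#' Met at 5 ER visits for full-term and 7 for pre-term children. Each
#' emergency-class encounter counts as one visit (no same-day collapsing).
#'
#' @inheritParams evaluate_nicu_stay
#' @return A criterion result list.
#' @export
evaluate_er_visits <- function(bundle, specs = default_criteria()) {
  k <- spec_threshold(specs, "er_visits", bundle$term_status)
  enc <- bundle$encounters
  enc <- enc[enc$encounter_class == "emergency", , drop = FALSE]
  n <- nrow(enc)
  if (!n) return(criterion_result("er_visits", FALSE))
  age <- sort(age_in_days(bundle$birth_date,
                          parse_event_time(enc$start, "start")))
  criterion_result("er_visits", n >= k,
                   first_met_age = if (n >= k) age[k],
                   evidence_count = n)
}

#' Feeding support (minor, score 2)
#'
#' Met when any diagnosis matches the feeding-support code set, or any
#' non-cancelled procedure name matches the feeding keyword rule
#' (nasogastric / gastrostomy feeding).
#'
#' @inheritParams evaluate_nicu_stay
#' @param codes feeding-support [codeset()].
#' @param rule feeding [keyword_rule()].
#' @return A criterion result list.
#' @export
evaluate_feeding_support <- function(bundle,
                                     codes = default_vocabulary()$feeding_codes,
                                     rule = feeding_keyword_rule()) {
  dx <- bundle$diagnoses
  dx_hit <- if (nrow(dx)) code_matches(dx$icd_code, codes) else logical(0)
  pr <- active_procedures(bundle)
  pr_hit <- if (nrow(pr)) keyword_match(pr$name, rule) else logical(0)
  ages <- c(age_in_days(bundle$birth_date, dx$date[dx_hit]),
            age_in_days(bundle$birth_date, pr$date[pr_hit]))
  criterion_result("feeding_support", length(ages) > 0,
                   first_met_age = if (length(ages)) min(ages),
                   evidence_count = length(ages))
}

#' Respiratory support outside the perioperative window (minor, score 2)
#'
#' Tracheostomy or ventilation (including CPAP), identified from procedure
#' names and diagnosis codes. A support event on day `d` qualifies only if it
#' is clear of every surgery day `s` (surgical procedures and
#' cardiothoracic-ICU admissions): `d <= s - 1` or `d >= s + 5`, i.e. routine
#' perioperative ventilation does not count. With no surgeries, any support
#' event qualifies. This is the one criterion that is not monotone under
#' added events: recording a new surgery can disqualify a previously
#' qualifying support event.
#'
#' @inheritParams evaluate_nicu_stay
#' @param codes respiratory-support diagnosis [codeset()].
#' @param rule respiratory [keyword_rule()].
#' @return A criterion result list.
#' @export
evaluate_respiratory_support <- function(bundle,
                                         specs = default_criteria(),
                                         codes =
                                           default_vocabulary()$respiratory_codes,
                                         rule = respiratory_keyword_rule()) {
  before <- spec_threshold(specs, "resp_days_before_surgery")
  after <- spec_threshold(specs, "resp_days_after_surgery")
  pr <- active_procedures(bundle)
  pr_hit <- if (nrow(pr)) keyword_match(pr$name, rule) else logical(0)
  dx <- bundle$diagnoses
  dx_hit <- if (nrow(dx)) code_matches(dx$icd_code, codes) else logical(0)
  days <- c(age_in_days(bundle$birth_date, pr$date[pr_hit]),
            age_in_days(bundle$birth_date, dx$date[dx_hit]))
  if (!length(days)) {
    return(criterion_result("respiratory_support", FALSE))
  }
  surg <- surgery_ages(bundle)
  ok <- vapply(days, function(d) {
    all(d <= surg - before | d >= surg + after)
  }, TRUE)
  criterion_result("respiratory_support", any(ok),
                   first_met_age = if (any(ok)) min(days[ok]),
                   evidence_count = sum(ok))
}

#' Order-based criteria: imaging, genetic tests, metabolic tests (minor, score 1)
#'
#' Met when at least one lab/procedure order of the category has status
#' completed, preliminary or final, regardless of result. Imaging covers CT
#' and MRI orders.
#'
#' @inheritParams evaluate_nicu_stay
#' @param category "imaging", "genetic_tests" or "metabolic_tests".
#' @return A criterion result list.
#' @export
evaluate_order_criterion <- function(bundle, category) {
  cats <- switch(category,
                 imaging = c("imaging_ct", "imaging_mri"),
                 genetic_tests = "genetic_test",
                 metabolic_tests = "metabolic_test",
                 stop("unknown order category: ", category, call. = FALSE))
  lo <- bundle$lab_orders
  hit <- lo$category %in% cats &
    lo$status %in% c("completed", "preliminary", "final")
  ages <- age_in_days(bundle$birth_date, lo$date[hit])
  criterion_result(category, length(ages) > 0,
                   first_met_age = if (length(ages)) min(ages),
                   evidence_count = length(ages))
}

#' In-hospital death (major, score 3)
#'
#' Met when any encounter's discharge disposition contains a configured death
#' term (expired, funeral home, morgue, organ harvest), or when the child
#' record carries a death date within the observation window.
#'
#' @inheritParams evaluate_nicu_stay
#' @param dispositions character vector of lower-case disposition terms.
#' @return A criterion result list.
#' @export
evaluate_death <- function(bundle,
                           dispositions =
                             default_vocabulary()$death_dispositions) {
  enc <- bundle$encounters
  ages <- numeric(0)
  if (nrow(enc)) {
    disp <- tolower(enc$discharge_disposition)
    hit <- rep(FALSE, nrow(enc))
    for (term in tolower(dispositions)) {
      hit <- hit | (!is.na(disp) & grepl(term, disp, fixed = TRUE))
    }
    if (any(hit)) {
      t_end <- parse_event_time(enc$end, "end")[hit]
      t_start <- parse_event_time(enc$start, "start")[hit]
      t <- ifelse(is.na(t_end), t_start, t_end)
      ages <- age_in_days(bundle$birth_date,
                          as.POSIXct(t, tz = "UTC", origin = "1970-01-01"))
    }
  }
  if (!is.na(bundle$death_date)) {
    a <- age_in_days(bundle$birth_date, bundle$death_date)
    if (a <= bundle$observation_days) ages <- c(ages, a)
  }
  ages <- pmin(ages, bundle$observation_days)
  criterion_result("death", length(ages) > 0,
                   first_met_age = if (length(ages)) min(ages),
                   evidence_count = length(ages))
}

#' Developmental delay (minor, score 1)
#'
#' Met on any developmental-pediatrics specialist visit, or on at least two
#' diagnosis records matching the developmental-delay code set on distinct
#' calendar dates (distinct dates guard against same-day duplicate coding).
#'
#' @inheritParams evaluate_nicu_stay
#' @param codes developmental-delay [codeset()].
#' @param dev_ped_label specialty label of developmental pediatricians.
#' @return A criterion result list.
#' @export
evaluate_developmental_delay <- function(bundle,
                                         codes =
                                           default_vocabulary()$developmental_delay_codes,
                                         dev_ped_label =
                                           "Developmental Pediatrics") {
  ages <- numeric(0)
  n_evidence <- 0L
  enc <- bundle$encounters
  vis <- enc$encounter_class == "specialist_visit" &
    !is.na(enc$specialty) &
    tolower(enc$specialty) == tolower(dev_ped_label)
  if (any(vis)) {
    a <- age_in_days(bundle$birth_date,
                     parse_event_time(enc$start[vis], "start"))
    ages <- c(ages, min(a))
    n_evidence <- n_evidence + sum(vis)
  }
  dx <- bundle$diagnoses
  hit <- if (nrow(dx)) code_matches(dx$icd_code, codes) else logical(0)
  if (any(hit)) {
    dates <- sort(unique(dx$date[hit]))
    n_evidence <- n_evidence + sum(hit)
    if (length(dates) >= 2L) {
      ages <- c(ages, age_in_days(bundle$birth_date, dates[2L]))
    }
  }
  criterion_result("developmental_delay", length(ages) > 0,
                   first_met_age = if (length(ages)) min(ages),
                   evidence_count = n_evidence)
}

#' Recurrent metabolic-disease diagnosis codes (major, score 3)
#'
#' Met when diagnoses matching the metabolic-disease code set occur in at
#' least two distinct encounters.
#'
#' @inheritParams evaluate_nicu_stay
#' @param codes metabolic-disease [codeset()].
#' @return A criterion result list.
#' @export
evaluate_metabolic_icd <- function(bundle,
                                   codes =
                                     default_vocabulary()$metabolic_codes) {
  dx <- bundle$diagnoses
  hit <- if (nrow(dx)) code_matches(dx$icd_code, codes) else logical(0)
  if (!any(hit)) return(criterion_result("metabolic_icd", FALSE))
  dxh <- dx[hit, , drop = FALSE]
  first_date <- vapply(split(dxh$date, dxh$encounter_id),
                       function(d) min(as.numeric(d)), 0)
  n_enc <- length(first_date)
  met <- n_enc >= 2L
  age2 <- if (met) {
    age_in_days(bundle$birth_date,
                as.Date(sort(first_date)[2L], origin = "1970-01-01"))
  }
  criterion_result("metabolic_icd", met, first_met_age = age2,
                   evidence_count = n_enc)
}

#' Heart surgery (major, score 3)
#'
#' Met on any cardiothoracic-ICU encounter or any non-cancelled procedure
#' flagged cardiothoracic.
#'
#' @inheritParams evaluate_nicu_stay
#' @return A criterion result list.
#' @export
evaluate_heart_surgery <- function(bundle) {
  enc <- bundle$encounters
  ct <- enc[enc$encounter_class == "cticu", , drop = FALSE]
  ages <- if (nrow(ct)) {
    age_in_days(bundle$birth_date, parse_event_time(ct$start, "start"))
  } else numeric(0)
  pr <- active_procedures(bundle)
  pr <- pr[pr$cardiothoracic %in% TRUE, , drop = FALSE]
  ages <- c(ages, age_in_days(bundle$birth_date, pr$date))
  criterion_result("heart_surgery", length(ages) > 0,
                   first_met_age = if (length(ages)) min(ages),
                   evidence_count = length(ages))
}

#' Evaluate all thirteen criteria for one child
#'
#' @param bundle a [child_bundle()].
#' @param specs a [default_criteria()] object.
#' @param vocab a [default_vocabulary()] bundle.
#' @return A `criteria_profile`: a 13-row data.frame (criterion, met,
#'   first_met_age, evidence_count) with `child_id` and `term_status`
#'   attributes.
#' @export
evaluate_all <- function(bundle, specs = default_criteria(),
                         vocab = default_vocabulary()) {
  res <- list(
    evaluate_nicu_stay(bundle, specs),
    evaluate_hospitalizations(bundle, specs),
    evaluate_multiple_specialists(bundle, vocab$taxonomy, specs),
    evaluate_er_visits(bundle, specs),
    evaluate_feeding_support(bundle, vocab$feeding_codes,
                             vocab$feeding_rule),
    evaluate_respiratory_support(bundle, specs, vocab$respiratory_codes,
                                 vocab$respiratory_rule),
    evaluate_order_criterion(bundle, "imaging"),
    evaluate_order_criterion(bundle, "genetic_tests"),
    evaluate_order_criterion(bundle, "metabolic_tests"),
    evaluate_death(bundle, vocab$death_dispositions),
    evaluate_developmental_delay(bundle, vocab$developmental_delay_codes,
                                 vocab$developmental_pediatrics_label),
    evaluate_metabolic_icd(bundle, vocab$metabolic_codes),
    evaluate_heart_surgery(bundle)
  )
  prof <- data.frame(
    criterion = vapply(res, `[[`, "", "id"),
    met = vapply(res, `[[`, TRUE, "met"),
    first_met_age = vapply(res, `[[`, 0, "first_met_age"),
    evidence_count = vapply(res, `[[`, 0L, "evidence_count"),
    stringsAsFactors = FALSE
  )
  stopifnot(identical(prof$criterion, criterion_ids()))
  attr(prof, "child_id") <- bundle$child_id
  attr(prof, "term_status") <- bundle$term_status
  class(prof) <- c("criteria_profile", "data.frame")
  prof
}

#' Evaluate all thirteen criteria for every child in a cohort
#'
#' @param x an `emr_cohort`.
#' @param specs a [default_criteria()] object.
#' @param vocab a [default_vocabulary()] bundle.
#' @return A `criteria_profiles` data.frame with one row per child:
#'   `child_id`, `term_status`, then `met_<criterion>` (logical) and
#'   `age_<criterion>` (days, `NA` when unmet) for each criterion.
#' @export
evaluate_cohort <- function(x, specs = default_criteria(),
                            vocab = default_vocabulary()) {
  stopifnot(inherits(x, "emr_cohort"))
  ids <- x$children$child_id
  n <- length(ids)
  cids <- criterion_ids()
  met <- matrix(FALSE, n, 13L, dimnames = list(NULL, cids))
  age <- matrix(NA_real_, n, 13L, dimnames = list(NULL, cids))
  if (n) {
    f <- function(df) split(seq_len(nrow(df)),
                            factor(df$child_id, levels = ids))
    idx_enc <- f(x$encounters)
    idx_dx <- f(x$diagnoses)
    idx_pr <- f(x$procedures)
    idx_lo <- f(x$lab_orders)
    ch <- x$children
    for (i in seq_len(n)) {
      b <- build_bundle(list(child_id = ch$child_id[i],
                             birth_date = ch$birth_date[i],
                             gestational_age_days =
                               ch$gestational_age_days[i],
                             death_date = ch$death_date[i]),
                        x$encounters[idx_enc[[i]], , drop = FALSE],
                        x$diagnoses[idx_dx[[i]], , drop = FALSE],
                        x$procedures[idx_pr[[i]], , drop = FALSE],
                        x$lab_orders[idx_lo[[i]], , drop = FALSE],
                        x$observation_days)
      prof <- evaluate_all(b, specs, vocab)
      met[i, ] <- prof$met
      age[i, ] <- prof$first_met_age
    }
  }
  out <- data.frame(child_id = ids,
                    term_status = if (n)
                      derive_term_status(x$children$gestational_age_days)
                    else character(0),
                    stringsAsFactors = FALSE)
  for (j in seq_along(cids)) out[[paste0("met_", cids[j])]] <- met[, j]
  for (j in seq_along(cids)) out[[paste0("age_", cids[j])]] <- age[, j]
  class(out) <- c("criteria_profiles", "data.frame")
  out
}

#' Met-flag matrix of a cohort profile table
#'
#' @param profiles a `criteria_profiles` data.frame from [evaluate_cohort()].
#' @return Logical matrix, one row per child, one column per criterion.
#' @export
met_matrix <- function(profiles) {
  cols <- paste0("met_", criterion_ids())
  stopifnot(all(cols %in% names(profiles)))
  m <- as.matrix(profiles[cols])
  colnames(m) <- criterion_ids()
  mode(m) <- "logical"
  m
}

#' Assemble a cohort profile table from a met-flag matrix
#'
#' Convenience constructor used when criterion flags come from an external
#' source (e.g. chart review, or the generator's latent intents) rather than
#' from [evaluate_cohort()].
#'
#' @param child_id character vector.
#' @param term_status "full_term"/"pre_term" vector.
#' @param met logical matrix with one column per criterion (by name).
#' @param age optional matrix of first-met ages.
#' @return A `criteria_profiles` data.frame.
#' @export
profiles_from_matrix <- function(child_id, term_status, met, age = NULL) {
  cids <- criterion_ids()
  stopifnot(all(cids %in% colnames(met)),
            nrow(met) == length(child_id))
  out <- data.frame(child_id = as.character(child_id),
                    term_status = as.character(term_status),
                    stringsAsFactors = FALSE)
  for (id in cids) out[[paste0("met_", id)]] <- as.logical(met[, id])
  for (id in cids) {
    out[[paste0("age_", id)]] <-
      if (is.null(age)) ifelse(out[[paste0("met_", id)]], 0, NA_real_)
      else as.numeric(age[, id])
  }
  class(out) <- c("criteria_profiles", "data.frame")
  out
}
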