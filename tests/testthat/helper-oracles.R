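# Independent brute-force oracles, written as plain loops over the raw tables
# with the published thresholds hard-coded. They deliberately share no code
# with the package implementation.

# Literal restatement of the positive-classification conditions.
oracle_classify <- function(met) {
  majors <- c("nicu_stay", "hospitalizations", "death", "metabolic_icd",
              "heart_surgery")
  n_major <- sum(met[majors])
  n_minor <- sum(met[setdiff(names(met), majors)])
  (n_major >= 2) ||
    (n_major >= 1 && n_minor >= 1) ||
    (n_minor >= 5) ||
    isTRUE(met[["death"]])
}

oracle_score <- function(met) {
  sc <- c(nicu_stay = 3, hospitalizations = 3, multiple_specialists = 1,
          er_visits = 1, feeding_support = 2, respiratory_support = 2,
          imaging = 1, genetic_tests = 1, metabolic_tests = 1, death = 3,
          developmental_delay = 1, metabolic_icd = 3, heart_surgery = 3)
  sum(sc[names(met)[met]])
}

# Merge [start, end] hour intervals with zero allowed gap.
oracle_merge <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ms <- c(); me <- c()
  for (i in seq_along(s)) {
    if (length(ms) && s[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], e[i])
    } else {
      ms <- c(ms, s[i]); me <- c(me, e[i])
    }
  }
  cbind(ms, me)
}

# Brute-force met flags for one child of a cohort.
oracle_child_met <- function(co, id) {
  ch <- co$children[co$children$child_id == id, ]
  birth <- ch$birth_date
  birth0 <- as.POSIXct(paste(birth, "00:00:00"), tz = "UTC")
  preterm <- ch$gestational_age_days < 259
  W <- 1095

  enc <- co$encounters[co$encounters$child_id == id, ]
  enc$start_h <- as.numeric(difftime(enc$start, birth0, units = "hours"))
  enc$end_h <- as.numeric(difftime(enc$end, birth0, units = "hours"))
  enc$end_h[is.na(enc$end_h) | enc$end_h > W * 24] <- W * 24
  enc <- enc[enc$start_h <= W * 24, ]
  dx <- co$diagnoses[co$diagnoses$child_id == id, ]
  dx <- dx[as.numeric(dx$date - birth) <= W, ]
  pr <- co$procedures[co$procedures$child_id == id, ]
  pr <- pr[as.numeric(pr$date - birth) <= W & pr$status != "cancelled", ]
  lab <- co$lab_orders[co$lab_orders$child_id == id, ]
  lab <- lab[as.numeric(lab$date - birth) <= W, ]

  met <- setNames(rep(FALSE, 13), criterion_ids())

  icu <- enc[enc$encounter_class == "icu", ]
  if (!preterm && nrow(icu)) {
    m <- oracle_merge(icu$start_h, icu$end_h)
    met["nicu_stay"] <- any(floor(m[, 1] / 24) <= 7 &
                              (m[, 2] - m[, 1]) >= 4 * 24)
  }

  inp <- enc[enc$encounter_class == "inpatient", ]
  if (nrow(inp)) {
    m <- oracle_merge(inp$start_h, inp$end_h)
    dur <- m[, 2] - m[, 1]
    pma <- ch$gestational_age_days + floor(m[, 1] / 24)
    elig <- dur >= 48 & pma > 245
    met["hospitalizations"] <- any(elig & dur >= 14 * 24) ||
      sum(elig) >= (if (preterm) 3 else 2)
  }

  sv <- enc[enc$encounter_class == "specialist_visit", ]
  incl <- tolower(TEST_VOCAB$taxonomy$included)
  types <- unique(tolower(sv$specialty))
  types <- types[types %in% incl]
  met["multiple_specialists"] <- length(types) >= (if (preterm) 4 else 3)

  met["er_visits"] <-
    sum(enc$encounter_class == "emergency") >= (if (preterm) 7 else 5)

  prefix_hit <- function(codes, set) {
    vapply(codes, function(cd) any(startsWith(toupper(cd), set)), TRUE,
           USE.NAMES = FALSE)
  }
  feed_dx <- any(prefix_hit(dx$icd_code, TEST_VOCAB$feeding_codes$codes))
  nm <- tolower(pr$name)
  feed_pr <- grepl("nasogastric", nm) |
    (grepl("gastrostomy", nm) & grepl("feed", nm)) |
    (grepl("gastrostomy", nm) & grepl("tube", nm))
  met["feeding_support"] <- isTRUE(feed_dx) || any(feed_pr)

  vent_days <- c(
    as.numeric(pr$date - birth)[grepl("tracheostomy|ventilat|cpap", nm)],
    as.numeric(dx$date - birth)[prefix_hit(dx$icd_code,
                                 TEST_VOCAB$respiratory_codes$codes)])
  surg_days <- c(as.numeric(pr$date - birth)[pr$surgical %in% TRUE],
                 floor(enc$start_h[enc$encounter_class == "cticu"] / 24))
  met["respiratory_support"] <- any(vapply(vent_days, function(d)
    all(d <= surg_days - 1 | d >= surg_days + 5), TRUE))

  ok_status <- lab$status %in% c("completed", "preliminary", "final")
  met["imaging"] <- any(ok_status &
                          lab$category %in% c("imaging_ct", "imaging_mri"))
  met["genetic_tests"] <- any(ok_status & lab$category == "genetic_test")
  met["metabolic_tests"] <- any(ok_status & lab$category == "metabolic_test")

  disp <- tolower(enc$discharge_disposition)
  met["death"] <- any(!is.na(disp) &
                        grepl("expired|funeral home|morgue|organ harvest",
                              disp)) ||
    (!is.na(ch$death_date) && as.numeric(ch$death_date - birth) <= W)

  dd_hits <- dx[prefix_hit(dx$icd_code,
                           TEST_VOCAB$developmental_delay_codes$codes), ]
  met["developmental_delay"] <-
    any(tolower(sv$specialty) == "developmental pediatrics") ||
    length(unique(dd_hits$date)) >= 2

  micd <- dx[prefix_hit(dx$icd_code, TEST_VOCAB$metabolic_codes$codes), ]
  met["metabolic_icd"] <- length(unique(micd$encounter_id)) >= 2

  met["heart_surgery"] <- any(enc$encounter_class == "cticu") ||
    any(pr$cardiothoracic %in% TRUE)

  met
}
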