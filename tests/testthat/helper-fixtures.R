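# Fixture builders: hand-assembled single-child cohorts for rule-level tests.
# All fixtures are generated in code; nothing is read from disk.

FIX_BIRTH <- as.Date("2020-01-01")

fix_enc <- function(class, day, dur_h = 24, specialty = NA_character_,
                    disposition = NA_character_, child = "K1",
                    id = NA_character_) {
  start <- as.POSIXct(paste(FIX_BIRTH + day, "08:00:00"), tz = "UTC")
  data.frame(encounter_id = id, child_id = child, encounter_class = class,
             specialty = specialty, start = start,
             end = start + dur_h * 3600,
             discharge_disposition = disposition, stringsAsFactors = FALSE)
}

fix_enc_open <- function(class, day, child = "K1", id = NA_character_) {
  e <- fix_enc(class, day, child = child, id = id)
  e$end <- as.POSIXct(NA, tz = "UTC")
  e
}

fix_dx <- function(code, day, enc_id, child = "K1") {
  data.frame(child_id = child, icd_code = code, date = FIX_BIRTH + day,
             encounter_id = enc_id, stringsAsFactors = FALSE)
}

fix_proc <- function(name, day, status = "completed", surgical = FALSE,
                     cardiothoracic = FALSE, child = "K1") {
  data.frame(child_id = child, code = "PROC", name = name,
             date = FIX_BIRTH + day, status = status, surgical = surgical,
             cardiothoracic = cardiothoracic, stringsAsFactors = FALSE)
}

fix_lab <- function(category, day, status = "completed", child = "K1") {
  data.frame(child_id = child, category = category, date = FIX_BIRTH + day,
             status = status, stringsAsFactors = FALSE)
}

# One-child cohort; event arguments are lists of rows from the fix_* builders.
fix_cohort <- function(ga = 280, encounters = list(), diagnoses = list(),
                       procedures = list(), lab_orders = list(),
                       death_day = NA) {
  ch <- data.frame(child_id = "K1", mother_id = "M1", birth_date = FIX_BIRTH,
                   gestational_age_days = ga,
                   death_date = if (is.na(death_day)) as.Date(NA)
                                else FIX_BIRTH + death_day,
                   stringsAsFactors = FALSE)
  enc <- if (length(encounters)) do.call(rbind, encounters)
         else pheindex:::empty_encounters_table()
  if (nrow(enc)) {
    blank <- is.na(enc$encounter_id)
    enc$encounter_id[blank] <- sprintf("E%03d", which(blank))
  }
  dx <- if (length(diagnoses)) do.call(rbind, diagnoses)
        else pheindex:::empty_diagnoses_table()
  pr <- if (length(procedures)) do.call(rbind, procedures)
        else pheindex:::empty_procedures_table()
  lo <- if (length(lab_orders)) do.call(rbind, lab_orders)
        else pheindex:::empty_lab_orders_table()
  cohort(ch, enc, dx, pr, lo)
}

fix_bundle <- function(...) child_bundle(fix_cohort(...), "K1")

# Shared heavyweight defaults, loaded once per test run.
TEST_SPECS <- default_criteria()
TEST_VOCAB <- default_vocabulary()
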