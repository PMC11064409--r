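# Synthetic EMR cohort generator. Children receive a term status, a latent
# disorder status, and a per-criterion intent vector; each intended criterion
# is emitted as a minimal event pattern the criteria engine provably detects,
# while non-intended criteria receive only sub-threshold decoy events, so the
# boundary behavior of every rule is exercised constantly. The latent truth
# table is returned separately and is never visible to the engine.

#' Default non-disordered criterion rates
#'
#' Per-criterion intent probabilities for children without the latent
#' disorder. Values are calibrated so that, with the default multipliers and
#' a 3% disorder prevalence, the population marginal frequencies land on
#' realistic targets for a birth cohort (about 4.2% multiple ER visits, 3.4%
#' developmental delay, 3.3% multiple specialists, 0.14% feeding support,
#' 0.09% recurrent metabolic codes; the remaining criteria are interpolated
#' between those anchors). The NICU rate applies to full-term children only.
#'
#' @return Named numeric vector over the 13 criteria.
#' @export
default_base_rates <- function() {
  c(nicu_stay            = 0.00945,
    hospitalizations     = 0.01575,
    multiple_specialists = 0.02727,
    er_visits            = 0.03962,
    feeding_support      = 0.000986,
    respiratory_support  = 0.00301,
    imaging              = 0.02500,
    genetic_tests        = 0.00764,
    metabolic_tests      = 0.00704,
    death                = 0.00248,
    developmental_delay  = 0.02810,
    metabolic_icd        = 0.000573,
    heart_surgery        = 0.00526)
}

#' Default disorder rate multipliers
#'
#' Factor by which each criterion's intent rate is multiplied for children
#' carrying the latent disorder. Criteria tied to diagnostic work-up and
#' severe disease (genetic testing, metabolic codes, feeding support) are the
#' most disorder-linked; ER utilization the least.
#'
#' @return Named numeric vector over the 13 criteria, all >= 1.
#' @export
default_disorder_multipliers <- function() {
  c(nicu_stay            = 10,
    hospitalizations     = 10,
    multiple_specialists = 8,
    er_visits            = 3,
    feeding_support      = 15,
    respiratory_support  = 12,
    imaging              = 5,
    genetic_tests        = 20,
    metabolic_tests      = 15,
    death                = 8,
    developmental_delay  = 8,
    metabolic_icd        = 20,
    heart_surgery        = 12)
}

#' Generator configuration
#'
#' @param n_children cohort size (>= 1).
#' @param preterm_fraction fraction of pre-term births (default 0.125).
#' @param disorder_prevalence latent disorder prevalence (default 0.03).
#' @param base_rates named per-criterion intent rates for non-disordered
#'   children; see [default_base_rates()].
#' @param disorder_rate_multipliers named multipliers (>= 1) applied for
#'   disordered children; the intent rate is `base * multiplier`, capped at 1.
#' @param co_occurrence_pairs list of `list(criterion_a, criterion_b,
#'   target_jaccard)` couplings, induced by marginal-preserving intent swaps
#'   within term-by-disorder strata (default: prolonged NICU stay and heart
#'   surgery at Jaccard 0.44 among full-term children).
#' @param documentation_flip_rates named per-criterion probabilities that the
#'   emitted record disagrees with the latent intent (default all zero);
#'   also consumed by [inject_documentation_noise()].
#' @param seed integer seed; generation is deterministic given the config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_children,
                             preterm_fraction = 0.125,
                             disorder_prevalence = 0.03,
                             base_rates = default_base_rates(),
                             disorder_rate_multipliers =
                               default_disorder_multipliers(),
                             co_occurrence_pairs =
                               list(list("nicu_stay", "heart_surgery", 0.44)),
                             documentation_flip_rates = NULL,
                             seed = 1L) {
  stopifnot(n_children >= 1, preterm_fraction >= 0, preterm_fraction <= 1,
            disorder_prevalence >= 0, disorder_prevalence <= 1)
  cids <- criterion_ids()
  rates <- default_base_rates()
  rates[names(base_rates)] <- base_rates
  mult <- default_disorder_multipliers()
  mult[names(disorder_rate_multipliers)] <- disorder_rate_multipliers
  flips <- stats::setNames(rep(0, 13L), cids)
  if (!is.null(documentation_flip_rates)) {
    flips[names(documentation_flip_rates)] <- documentation_flip_rates
  }
  stopifnot(all(names(rates) %in% cids), all(rates >= 0), all(rates <= 1),
            all(mult >= 1), all(flips >= 0), all(flips <= 1))
  for (p in co_occurrence_pairs) {
    stopifnot(length(p) == 3L, p[[1L]] %in% cids, p[[2L]] %in% cids,
              p[[3L]] >= 0, p[[3L]] <= 1)
  }
  structure(list(n_children = as.integer(n_children),
                 preterm_fraction = preterm_fraction,
                 disorder_prevalence = disorder_prevalence,
                 base_rates = rates[cids],
                 disorder_rate_multipliers = mult[cids],
                 co_occurrence_pairs = co_occurrence_pairs,
                 documentation_flip_rates = flips,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Implied population marginal rates of a generator configuration
#'
#' The expected met-fraction per criterion:
#' `base * (1 - p) + min(1, base * multiplier) * p` at disorder prevalence
#' `p`. For the NICU criterion the marginal is among full-term children.
#'
#' @param config a [generator_config()].
#' @return Named numeric vector over the 13 criteria.
#' @export
implied_marginal_rates <- function(config) {
  p <- config$disorder_prevalence
  r <- config$base_rates
  m <- config$disorder_rate_multipliers
  r * (1 - p) + pmin(1, r * m) * p
}

# Intent draws: Bernoulli per criterion, rate multiplied for disordered
# children; the NICU criterion is never intended for pre-term children.
draw_intents <- function(children, config) {
  n <- nrow(children)
  disorder <- children$has_disorder
  cids <- criterion_ids()
  I <- matrix(FALSE, n, 13L, dimnames = list(NULL, cids))
  for (id in cids) {
    r <- config$base_rates[[id]]
    prob <- ifelse(disorder,
                   pmin(1, r * config$disorder_rate_multipliers[[id]]), r)
    I[, id] <- stats::runif(n) < prob
  }
  I[children$term_status == "pre_term", "nicu_stay"] <- FALSE
  I
}

# Raise pairwise Jaccard towards configured targets by marginal-preserving
# swaps: within each term-by-disorder stratum, a child intending only a and a
# child intending only b are paired; the first gains b, the second loses it.
# Intersection grows, union shrinks, both criterion counts are unchanged.
apply_co_occurrence <- function(I, children, config) {
  for (pair in config$co_occurrence_pairs) {
    a <- pair[[1L]]; b <- pair[[2L]]; target <- pair[[3L]]
    ft_only <- "nicu_stay" %in% c(a, b)
    scope <- if (ft_only) children$term_status == "full_term"
             else rep(TRUE, nrow(I))
    for (term in unique(children$term_status[scope])) {
      for (dis in c(TRUE, FALSE)) {
        S <- which(scope & children$term_status == term &
                     children$has_disorder == dis)
        if (!length(S)) next
        ia <- I[S, a]; ib <- I[S, b]
        uni <- sum(ia | ib)
        if (!uni) next
        inter <- sum(ia & ib)
        k <- ceiling((target * uni - inter) / (1 + target))
        if (k <= 0) next
        aonly <- S[ia & !ib]; bonly <- S[!ia & ib]
        k <- min(k, length(aonly), length(bonly))
        if (!k) next
        gain <- if (length(aonly) == 1L) aonly else sample(aonly, k)
        lose <- if (length(bonly) == 1L) bonly else sample(bonly, k)
        I[gain[seq_len(k)], b] <- TRUE
        I[lose[seq_len(k)], b] <- FALSE
      }
    }
    rows <- which(scope)
    uni <- sum(I[rows, a] | I[rows, b])
    achieved <- if (uni) sum(I[rows, a] & I[rows, b]) / uni else NA_real_
    if (is.na(achieved) || abs(achieved - target) > 0.05) {
      warning(sprintf(
        "co-occurrence target %s/%s = %.2f not reached (achieved %.2f)",
        a, b, target, achieved), call. = FALSE)
    }
  }
  I
}

# Event emission ---------------------------------------------------------------
# Witness patterns are minimal rule-satisfying event sets; decoys are random
# sub-threshold patterns emitted for non-intended criteria.

emit_cohort <- function(children, intents, config) {
  n <- nrow(children)
  cid <- children$child_id
  ga <- children$gestational_age_days
  ft <- children$term_status == "full_term"
  birth0 <- as_utc_midnight(children$birth_date)

  enc_parts <- list(); dx_parts <- list(); pr_parts <- list()
  lab_parts <- list()
  carrier_count <- 0L
  new_carrier_ids <- function(k) {
    ids <- sprintf("X%07d", carrier_count + seq_len(k))
    carrier_count <<- carrier_count + k
    ids
  }

  add_enc <- function(i, class, day, dur_h, specialty = NA_character_,
                      disposition = NA_character_, eid = NA_character_) {
    if (!length(i)) return(invisible(NULL))
    start <- birth0[i] + day * 86400 + 8 * 3600
    enc_parts[[length(enc_parts) + 1L]] <<- data.frame(
      encounter_id = eid, child_id = cid[i], encounter_class = class,
      specialty = specialty, start = start, end = start + dur_h * 3600,
      discharge_disposition = disposition, stringsAsFactors = FALSE)
  }
  # a diagnosis needs an encounter of the same child: emit an outpatient
  # carrier visit per diagnosis date
  add_dx_visit <- function(i, code, day) {
    if (!length(i)) return(invisible(NULL))
    eid <- new_carrier_ids(length(i))
    add_enc(i, "outpatient", day, 1, eid = eid)
    dx_parts[[length(dx_parts) + 1L]] <<- data.frame(
      child_id = cid[i], icd_code = code,
      date = children$birth_date[i] + day, encounter_id = eid,
      stringsAsFactors = FALSE)
  }
  add_proc <- function(i, name, day, status = "completed", surgical = FALSE,
                       cardiothoracic = FALSE) {
    if (!length(i)) return(invisible(NULL))
    pr_parts[[length(pr_parts) + 1L]] <<- data.frame(
      child_id = cid[i], code = "PROC", name = name,
      date = children$birth_date[i] + day, status = status,
      surgical = surgical, cardiothoracic = cardiothoracic,
      stringsAsFactors = FALSE)
  }
  add_lab <- function(i, category, day, status = "completed") {
    if (!length(i)) return(invisible(NULL))
    lab_parts[[length(lab_parts) + 1L]] <<- data.frame(
      child_id = cid[i], category = category,
      date = children$birth_date[i] + day, status = status,
      stringsAsFactors = FALSE)
  }
  rint <- function(k, lo, hi) {
    if (!k) integer(0) else lo + floor(stats::runif(k) * (hi - lo + 1))
  }
  pick <- function(k, choices) choices[rint(k, 1L, length(choices))]

  # background realism: a sub-48 h birth hospitalization for most children,
  # sporadic well-child outpatient visits, and unrelated completed lab orders
  bg <- which(stats::runif(n) < 0.8)
  add_enc(bg, "inpatient", 0, rint(length(bg), 24, 47))
  nvis <- stats::rpois(n, 1)
  for (j in seq_len(max(c(nvis, 0L)))) {
    i <- which(nvis >= j)
    add_enc(i, "outpatient", rint(length(i), 0, 365), 1)
  }
  olab <- which(stats::runif(n) < 0.2)
  add_lab(olab, "other", rint(length(olab), 0, 365))

  # prolonged NICU stay: ICU episode starting within 7 days of birth, >= 4 d
  i <- which(intents[, "nicu_stay"])
  add_enc(i, "icu", rint(length(i), 0, 2),
          (4 + stats::rpois(length(i), 2)) * 24)
  d <- which(ft & !intents[, "nicu_stay"] & stats::runif(n) < 0.03)
  late <- stats::runif(length(d)) < 0.5
  add_enc(d[!late], "icu", rint(sum(!late), 0, 2),
          rint(sum(!late), 24, 90))                       # too short
  add_enc(d[late], "icu", rint(sum(late), 10, 20),
          rint(sum(late), 4, 8) * 24)                     # outside window
  d <- which(!ft & stats::runif(n) < 0.25)                # routine pre-term NICU
  add_enc(d, "icu", 0, rint(length(d), 7, 45) * 24)

  # hospitalizations: eligible stays must start after 245 d postmenstrual age
  hosp_base <- pmax(30, 247 - ga)
  i <- which(intents[, "hospitalizations"])
  prolonged <- stats::runif(length(i)) < 0.3
  ip <- i[prolonged]
  add_enc(ip, "inpatient", hosp_base[ip] + rint(length(ip), 0, 60),
          rint(length(ip), 14, 21) * 24)
  ic <- i[!prolonged]
  kc <- ifelse(ft[ic], 2L, 3L)
  for (j in 1:3) {
    ij <- ic[kc >= j]
    add_enc(ij, "inpatient",
            hosp_base[ij] + (j - 1L) * 45 + rint(length(ij), 0, 10),
            rint(length(ij), 55, 110))
  }
  d <- which(!intents[, "hospitalizations"] & stats::runif(n) < 0.05)
  shortstay <- stats::runif(length(d)) < 0.4
  add_enc(d[shortstay], "inpatient",
          hosp_base[d[shortstay]] + rint(sum(shortstay), 0, 30),
          rint(sum(shortstay), 30, 47))                   # under 48 h
  dsub <- d[!shortstay]                                   # threshold - 1 stays
  ks <- ifelse(ft[dsub], 1L, 2L)
  for (j in 1:2) {
    ij <- dsub[ks >= j]
    add_enc(ij, "inpatient",
            hosp_base[ij] + (j - 1L) * 45 + rint(length(ij), 0, 10),
            rint(length(ij), 55, 110))
  }

  # multiple specialists: threshold distinct included types, drawn as
  # consecutive taxonomy labels from a per-child random offset
  taxo <- default_specialty_taxonomy()
  i <- which(intents[, "multiple_specialists"])
  kk <- ifelse(ft[i], 3L, 4L)
  off <- rint(length(i), 0L, 19L)
  for (j in 1:4) {
    sel <- kk >= j
    if (!any(sel)) next
    add_enc(i[sel], "specialist_visit",
            60 + (j - 1L) * 40 + rint(sum(sel), 0, 10), 1,
            specialty = taxo$included[(off[sel] + j - 1L) %% 20L + 1L])
  }
  d <- which(!intents[, "multiple_specialists"] & stats::runif(n) < 0.08)
  kd <- pmin(ifelse(ft[d], 2L, 3L), 1L + rint(length(d), 0L, 2L))
  offd <- rint(length(d), 0L, 19L)
  for (j in 1:3) {
    ij <- which(kd >= j)
    add_enc(d[ij], "specialist_visit", 60 + (j - 1L) * 40 + rint(length(ij), 0, 10),
            1, specialty = taxo$included[(offd[ij] + j - 1L) %% 20L + 1L])
  }
  dpid <- d[stats::runif(length(d)) < 0.5]                # excluded specialty
  add_enc(dpid, "specialist_visit", rint(length(dpid), 30, 200), 1,
          specialty = taxo$excluded[1L])

  # multiple ER visits
  i <- which(intents[, "er_visits"])
  ke <- ifelse(ft[i], 5L, 7L)
  base_er <- rint(length(i), 10, 50)
  for (j in 1:7) {
    ij <- ke >= j
    add_enc(i[ij], "emergency",
            base_er[ij] + (j - 1L) * 30 + rint(sum(ij), 0, 10), 4)
  }
  d <- which(!intents[, "er_visits"] & stats::runif(n) < 0.10)
  kd <- 1L + rint(length(d), 0L, ifelse(ft[d], 3L, 5L))   # at most threshold-1
  base_er <- rint(length(d), 10, 50)
  for (j in 1:6) {
    ij <- kd >= j
    add_enc(d[ij], "emergency",
            base_er[ij] + (j - 1L) * 30 + rint(sum(ij), 0, 10), 4)
  }

  # feeding support: keyword procedure or feeding ICD code
  i <- which(intents[, "feeding_support"])
  viaproc <- stats::runif(length(i)) < 0.7
  ip <- i[viaproc]
  add_proc(ip, pick(length(ip), c("Gastrostomy tube placement",
                                  "Nasogastric tube feed insertion",
                                  "Gastrostomy feeding tube exchange")),
           rint(length(ip), 20, 200))
  ix <- i[!viaproc]
  add_dx_visit(ix, pick(length(ix), c("Z93.1", "R63.3", "P92.5")),
               rint(length(ix), 20, 200))
  d <- which(!intents[, "feeding_support"] & stats::runif(n) < 0.05)
  cancelled <- stats::runif(length(d)) < 0.5
  add_proc(d[cancelled], "Gastrostomy tube placement",
           rint(sum(cancelled), 20, 200), status = "cancelled")
  add_proc(d[!cancelled], "Gastrostomy revision",
           rint(sum(!cancelled), 20, 200))                # no feed/tube term

  # respiratory support clear of surgeries (witness day >= 200; all emitted
  # surgeries occur before day 85)
  i <- which(intents[, "respiratory_support"])
  viaproc <- stats::runif(length(i)) < 0.7
  ip <- i[viaproc]
  add_proc(ip, pick(length(ip), c("Mechanical ventilation",
                                  "CPAP initiation",
                                  "Tracheostomy placement")),
           200 + rint(length(ip), 0, 50))
  ix <- i[!viaproc]
  add_dx_visit(ix, pick(length(ix), c("Z99.1", "Z93.0")),
               200 + rint(length(ix), 0, 50))
  d <- which(!intents[, "respiratory_support"] & stats::runif(n) < 0.05)
  d0 <- rint(length(d), 100, 150)                         # perioperative pair
  add_proc(d, "Mechanical ventilation", d0)
  add_proc(d, "Exploratory laparotomy", d0, surgical = TRUE)

  # imaging / genetic tests / metabolic tests: completed-ish orders
  order_spec <- list(
    imaging = function(k) pick(k, c("imaging_ct", "imaging_mri")),
    genetic_tests = function(k) rep("genetic_test", k),
    metabolic_tests = function(k) rep("metabolic_test", k))
  for (id in names(order_spec)) {
    i <- which(intents[, id])
    add_lab(i, order_spec[[id]](length(i)), rint(length(i), 20, 300),
            pick(length(i), c("completed", "preliminary", "final")))
    d <- which(!intents[, id] & stats::runif(n) < 0.05)
    add_lab(d, order_spec[[id]](length(d)), rint(length(d), 20, 300),
            "cancelled")
  }

  # in-hospital death: terminal encounter with a death disposition, plus the
  # child-level death date; all other events occur before day 370
  death_day <- rep(NA_real_, n)
  i <- which(intents[, "death"])
  death_day[i] <- rint(length(i), 380, 500)
  add_enc(i, "inpatient", death_day[i] - 1, 24,
          disposition = pick(length(i), c("Expired",
                                          "To funeral home/morgue",
                                          "Organ harvest")))

  # developmental delay: developmental-pediatrics visit or two ICD dates
  i <- which(intents[, "developmental_delay"])
  viavisit <- stats::runif(length(i)) < 0.3
  iv <- i[viavisit]
  add_enc(iv, "specialist_visit", rint(length(iv), 150, 360), 1,
          specialty = "Developmental Pediatrics")
  ix <- i[!viavisit]
  ddcode <- pick(length(ix), c("F80.1", "F82.4", "F88.0", "R62.50"))
  dday <- rint(length(ix), 150, 300)
  add_dx_visit(ix, ddcode, dday)
  add_dx_visit(ix, ddcode, dday + 45)
  d <- which(!intents[, "developmental_delay"] & stats::runif(n) < 0.08)
  single <- stats::runif(length(d)) < 0.5
  add_dx_visit(d[single], pick(sum(single), c("F80.1", "R62.50")),
               rint(sum(single), 150, 300))
  dsame <- d[!single]                                     # same-day duplicate
  sday <- rint(length(dsame), 150, 300)
  if (length(dsame)) {
    eid <- new_carrier_ids(length(dsame))
    add_enc(dsame, "outpatient", sday, 1, eid = eid)
    code <- pick(length(dsame), c("F80.1", "R62.50"))
    dx_parts[[length(dx_parts) + 1L]] <- data.frame(
      child_id = rep(cid[dsame], 2L), icd_code = rep(code, 2L),
      date = rep(children$birth_date[dsame] + sday, 2L),
      encounter_id = rep(eid, 2L), stringsAsFactors = FALSE)
  }

  # recurrent metabolic ICD codes: same code in two distinct encounters
  i <- which(intents[, "metabolic_icd"])
  mcode <- pick(length(i), c("E70.0", "E71.311", "E72.19", "E74.21",
                             "E88.40"))
  mday <- rint(length(i), 60, 250)
  add_dx_visit(i, mcode, mday)
  add_dx_visit(i, mcode, mday + 30)
  d <- which(!intents[, "metabolic_icd"] & stats::runif(n) < 0.03)
  if (length(d)) {                                        # one encounter only
    sday <- rint(length(d), 60, 250)
    eid <- new_carrier_ids(length(d))
    add_enc(d, "outpatient", sday, 1, eid = eid)
    code <- pick(length(d), c("E70.0", "E74.21"))
    dx_parts[[length(dx_parts) + 1L]] <- data.frame(
      child_id = rep(cid[d], 2L), icd_code = rep(code, 2L),
      date = rep(children$birth_date[d] + sday, 2L),
      encounter_id = rep(eid, 2L), stringsAsFactors = FALSE)
  }

  # heart surgery: CTICU admission or cardiothoracic procedure
  i <- which(intents[, "heart_surgery"])
  viacticu <- stats::runif(length(i)) < 0.6
  ic <- i[viacticu]
  add_enc(ic, "cticu", rint(length(ic), 2, 6), rint(length(ic), 48, 120))
  ip <- i[!viacticu]
  add_proc(ip, pick(length(ip), c("Cardiothoracic surgery - VSD repair",
                                  "Arterial switch operation",
                                  "Norwood procedure stage 1")),
           rint(length(ip), 5, 60), surgical = TRUE, cardiothoracic = TRUE)
  d <- which(!intents[, "heart_surgery"] & stats::runif(n) < 0.04)
  add_proc(d, "Inguinal hernia repair", rint(length(d), 10, 80),
           surgical = TRUE)

  # assemble tables
  bind <- function(parts, template) {
    if (!length(parts)) return(template)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  encounters <- bind(enc_parts, empty_encounters_table())
  if (nrow(encounters)) {
    need <- is.na(encounters$encounter_id)
    encounters$encounter_id[need] <- sprintf("E%07d", seq_len(sum(need)))
  }
  children_out <- children[, c("child_id", "mother_id", "birth_date",
                               "gestational_age_days")]
  children_out$death_date <- children$birth_date + death_day
  list(children = children_out,
       encounters = encounters,
       diagnoses = bind(dx_parts, empty_diagnoses_table()),
       procedures = bind(pr_parts, empty_procedures_table()),
       lab_orders = bind(lab_parts, empty_lab_orders_table()))
}

#' Generate a synthetic EMR cohort
#'
#' Draws term status, latent disorder status and per-criterion intents for
#' each child, applies any configured co-occurrence couplings, and emits the
#' five EMR tables. At zero documentation noise the criteria engine recovers
#' every intended criterion exactly (witness events always satisfy the rule;
#' decoys never do), which is the contract the engine tests rely on.
#'
#' @param config a [generator_config()].
#' @return List with `cohort` (an `emr_cohort` carrying the config as an
#'   attribute) and `truth` (data.frame: child_id, has_disorder,
#'   `intent_<criterion>` flags).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_children
    preterm <- stats::runif(n) < config$preterm_fraction
    ga <- integer(n)
    ga[preterm] <- 175L + floor(stats::runif(sum(preterm)) * 84)   # 175..258
    ga[!preterm] <- 259L + floor(stats::runif(sum(!preterm)) * 36) # 259..294
    children <- data.frame(
      child_id = sprintf("C%06d", seq_len(n)),
      mother_id = sprintf("M%06d", seq_len(n)),
      birth_date = as.Date("2015-01-01") +
        floor(stats::runif(n) * 1461),
      gestational_age_days = ga,
      stringsAsFactors = FALSE)
    children$term_status <- derive_term_status(ga)
    children$has_disorder <- stats::runif(n) < config$disorder_prevalence
    intents <- draw_intents(children, config)
    intents <- apply_co_occurrence(intents, children, config)
    flips <- config$documentation_flip_rates
    observed <- intents
    if (any(flips > 0)) {
      observed <- flip_intents(intents, children, flips)
    }
    tabs <- emit_cohort(children, observed, config)
    co <- cohort(tabs$children, tabs$encounters, tabs$diagnoses,
                 tabs$procedures, tabs$lab_orders)
    attr(co, "generator_config") <- config
    truth <- data.frame(child_id = children$child_id,
                        has_disorder = children$has_disorder,
                        stringsAsFactors = FALSE)
    for (id in criterion_ids()) {
      truth[[paste0("intent_", id)]] <- intents[, id]
    }
    list(cohort = co, truth = truth)
  })
}

# Flip intents at per-criterion rates. The NICU criterion can only disagree
# for full-term children (the rule is structurally false for pre-term
# children), so its flips are drawn among full-term children only.
flip_intents <- function(intents, children, flip_rates) {
  observed <- intents
  ft <- children$term_status == "full_term"
  n <- nrow(intents)
  for (id in names(flip_rates)) {
    rate <- flip_rates[[id]]
    if (rate <= 0) next
    fl <- stats::runif(n) < rate
    if (id == "nicu_stay") fl <- fl & ft
    observed[, id] <- xor(intents[, id], fl)
  }
  observed[children$term_status == "pre_term", "nicu_stay"] <- FALSE
  observed
}

#' Inject documentation noise into a generated cohort
#'
#' Emulates incomplete EMR documentation: for each criterion, a configured
#' fraction of children has its record flipped relative to the latent truth —
#' witness events are dropped for flipped positives and spurious witnesses
#' added for flipped negatives — by re-emitting the event tables from the
#' flipped intent vector. The engine's extraction then disagrees with the
#' latent truth at approximately the configured per-criterion rate.
#'
#' @param x an `emr_cohort` produced by [generate_cohort()].
#' @param truth the matching truth table.
#' @param flip_rates named per-criterion flip probabilities.
#' @param seed integer seed for the flip and re-emission draws.
#' @param config the generator configuration; defaults to the one attached to
#'   `x`.
#' @return A new `emr_cohort`.
#' @export
inject_documentation_noise <- function(x, truth, flip_rates, seed = 1L,
                                       config = attr(x, "generator_config")) {
  stopifnot(inherits(x, "emr_cohort"))
  if (is.null(config)) {
    stop("cohort carries no generator_config; pass `config` explicitly",
         call. = FALSE)
  }
  flips <- stats::setNames(rep(0, 13L), criterion_ids())
  flips[names(flip_rates)] <- flip_rates
  stopifnot(all(flips >= 0), all(flips <= 1))
  if (all(flips == 0)) return(x)
  children <- x$children
  children <- children[, c("child_id", "mother_id", "birth_date",
                           "gestational_age_days")]
  children$term_status <- derive_term_status(children$gestational_age_days)
  stopifnot(identical(children$child_id, truth$child_id))
  children$has_disorder <- truth$has_disorder
  intents <- as.matrix(truth[paste0("intent_", criterion_ids())])
  colnames(intents) <- criterion_ids()
  with_seed(seed, {
    observed <- flip_intents(intents, children, flips)
    tabs <- emit_cohort(children, observed, config)
    co <- cohort(tabs$children, tabs$encounters, tabs$diagnoses,
                 tabs$procedures, tabs$lab_orders)
    attr(co, "generator_config") <- config
    attr(co, "observed_intents") <- observed
    co
  })
}

#' Latent truth intents as a cohort profile table
#'
#' Recasts the generator's truth table in the `criteria_profiles` layout so
#' it can serve as a gold standard in [per_criterion_accuracy()].
#'
#' @param truth truth table from [generate_cohort()].
#' @param children the matching children table (for term status).
#' @return A `criteria_profiles` data.frame.
#' @export
truth_as_profiles <- function(truth, children) {
  stopifnot(identical(children$child_id, truth$child_id))
  m <- as.matrix(truth[paste0("intent_", criterion_ids())])
  colnames(m) <- criterion_ids()
  profiles_from_matrix(truth$child_id,
                       derive_term_status(children$gestational_age_days), m)
}
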