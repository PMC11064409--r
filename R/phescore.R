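# Severity score and binary classification built from a criteria profile.
#
# The score is the sum of the per-criterion scores over met criteria. Summing
# the configured scores gives a ceiling of 25 for full-term children (22 for
# pre-term, where the NICU criterion does not apply); the implementation
# treats that arithmetic ceiling as authoritative and exposes it via
# max_score(). A child is classified positive when any of four conditions
# holds: (a) at least 2 major criteria, (b) at least 1 major and 1 minor,
# (c) at least 5 minor, or (d) the child is deceased. The a-b-c-d precedence
# is reporting-only; it never changes the binary outcome.

TRIGGER_LEVELS <- c("a_two_major", "b_major_plus_minor", "c_five_minor",
                    "d_deceased")

#' Severity score of one profile
#'
#' @param profile a `criteria_profile` from [evaluate_all()].
#' @param specs a [default_criteria()] object.
#' @return Integer score (0 to [max_score()]).
#' @export
compute_score <- function(profile, specs = default_criteria()) {
  stopifnot(inherits(profile, "criteria_profile"))
  sc <- specs$criteria$score[match(profile$criterion, specs$criteria$id)]
  as.integer(sum(sc[profile$met]))
}

#' Classify one profile
#'
#' @param profile a `criteria_profile` from [evaluate_all()].
#' @param specs a [default_criteria()] object.
#' @return One-row data.frame: child_id, term_status, score, n_major,
#'   n_minor, n_met, classification ("positive"/"negative"),
#'   triggering_condition (`NA` when negative).
#' @export
classify <- function(profile, specs = default_criteria()) {
  stopifnot(inherits(profile, "criteria_profile"))
  m <- matrix(profile$met, nrow = 1,
              dimnames = list(NULL, profile$criterion))
  out <- classify_matrix(m, attr(profile, "term_status") %||% NA_character_,
                         attr(profile, "child_id") %||% NA_character_,
                         specs)
  out
}

# Vectorized classification over a logical met matrix.
classify_matrix <- function(met, term_status, child_id, specs) {
  crit <- specs$criteria
  major_ids <- crit$id[crit$tier == "major"]
  minor_ids <- crit$id[crit$tier == "minor"]
  score <- as.integer(met[, crit$id, drop = FALSE] %*% crit$score)
  n_major <- rowSums(met[, major_ids, drop = FALSE])
  n_minor <- rowSums(met[, minor_ids, drop = FALSE])
  cond_a <- n_major >= 2
  cond_b <- n_major >= 1 & n_minor >= 1
  cond_c <- n_minor >= 5
  cond_d <- met[, "death"]
  positive <- cond_a | cond_b | cond_c | cond_d
  trig <- rep(NA_character_, nrow(met))
  trig[cond_d] <- "d_deceased"
  trig[cond_c] <- "c_five_minor"
  trig[cond_b] <- "b_major_plus_minor"
  trig[cond_a] <- "a_two_major"
  data.frame(child_id = as.character(child_id),
             term_status = as.character(term_status),
             score = score,
             n_major = as.integer(n_major),
             n_minor = as.integer(n_minor),
             n_met = as.integer(n_major + n_minor),
             classification = ifelse(positive, "positive", "negative"),
             triggering_condition = trig,
             stringsAsFactors = FALSE)
}

#' Classify every child in a cohort profile table
#'
#' @param profiles a `criteria_profiles` data.frame from [evaluate_cohort()]
#'   or [profiles_from_matrix()].
#' @param specs a [default_criteria()] object.
#' @param quiet suppress the summary log line.
#' @return A `phe_results` data.frame, one row per child (see [classify()]).
#' @export
classify_cohort <- function(profiles, specs = default_criteria(),
                            quiet = FALSE) {
  met <- met_matrix(profiles)
  out <- classify_matrix(met, profiles$term_status, profiles$child_id, specs)
  class(out) <- c("phe_results", "data.frame")
  if (!quiet && nrow(out)) {
    message(sprintf("classified %d children: %d positive (%.2f%%), %d negative",
                    nrow(out), sum(out$classification == "positive"),
                    100 * mean(out$classification == "positive"),
                    sum(out$classification == "negative")))
  }
  out
}

#' Write classification results
#'
#' Emits both a delimited table and JSON lines, including the per-criterion
#' met flags when the matching profile table is supplied.
#'
#' @param results a `phe_results` data.frame.
#' @param path output stem; writes `<path>.csv` and `<path>.jsonl`.
#' @param profiles optional `criteria_profiles` to append met flags.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, profiles = NULL) {
  out <- results
  if (!is.null(profiles)) {
    stopifnot(identical(profiles$child_id, results$child_id))
    out <- cbind(out, profiles[paste0("met_", criterion_ids())])
  }
  utils::write.csv(out, paste0(path, ".csv"), row.names = FALSE, na = "")
  con <- file(paste0(path, ".jsonl"), open = "wt")
  on.exit(close(con))
  jsonlite::stream_out(out, con, verbose = FALSE, na = "null")
  invisible(path)
}
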