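# Cohort-level descriptive analytics: per-criterion frequencies,
# term-stratified Jaccard co-occurrence matrices, time-to-first-criterion
# cumulative curves, and criteria-count / score distributions. Numerical
# tables are the contract; any plotting can be regenerated from them.

#' Per-criterion frequencies
#'
#' Count and percentage of children meeting each criterion. Percentages are
#' reported to two decimals.
#'
#' @param profiles a `criteria_profiles` data.frame.
#' @return data.frame (criterion, n, pct); zero rows for an empty cohort.
#' @export
criterion_frequencies <- function(profiles) {
  if (!nrow(profiles)) {
    return(data.frame(criterion = character(), n = integer(),
                      pct = numeric()))
  }
  met <- met_matrix(profiles)
  n <- colSums(met)
  data.frame(criterion = criterion_ids(),
             n = as.integer(n),
             pct = round(100 * n / nrow(met), 2),
             row.names = NULL)
}

#' Jaccard co-occurrence matrix of criteria
#'
#' For a term stratum, computes J(i, j) = |met_i intersect met_j| /
#' |met_i union met_j| over the children meeting each pair of criteria. The
#' pre-term stratum carries 12 criteria (the NICU criterion does not apply);
#' the full-term stratum carries all 13. Pairs with an empty union are
#' undefined and reported as `NA` rather than 0, which would fabricate
#' dissimilarity.
#'
#' @param profiles a `criteria_profiles` data.frame.
#' @param stratum "full_term" or "pre_term".
#' @return A symmetric numeric matrix of class `jaccard_matrix` with a
#'   `stratum` attribute; diagonal entries are 1 where the criterion has at
#'   least one positive child and `NA` otherwise.
#' @export
jaccard_matrix <- function(profiles, stratum = c("full_term", "pre_term")) {
  stratum <- match.arg(stratum)
  labels <- criterion_ids()
  if (stratum == "pre_term") labels <- setdiff(labels, "nicu_stay")
  sub <- profiles[profiles$term_status == stratum, , drop = FALSE]
  m <- met_matrix(sub)[, labels, drop = FALSE]
  storage.mode(m) <- "numeric"
  inter <- crossprod(m)                       # |A & B|
  counts <- diag(inter)
  uni <- outer(counts, counts, "+") - inter   # |A| + |B| - |A & B|
  J <- ifelse(uni > 0, inter / uni, NA_real_)
  dimnames(J) <- list(labels, labels)
  structure(J, class = c("jaccard_matrix", class(J)), stratum = stratum)
}

#' Time-to-first-criterion cumulative curves
#'
#' For each criterion, the fraction of children who met it whose first-met
#' age is at most t, over an ascending day grid. Normalization is among met
#' children only, so each curve is nondecreasing and reaches 1 at the end of
#' the observation window. Criteria met by no child are omitted (and named in
#' the `omitted` attribute).
#'
#' @param profiles a `criteria_profiles` data.frame.
#' @param grid ascending vector of ages in days, all at most 1095.
#' @return Long data.frame (criterion, t, fraction) with attribute `omitted`.
#' @export
time_to_criterion_curves <- function(profiles,
                                     grid = seq(0, 1095, by = 15)) {
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0) ||
      any(grid > 1095)) {
    stop("grid must be strictly ascending within [0, 1095]", call. = FALSE)
  }
  met <- met_matrix(profiles)
  out <- list()
  omitted <- character(0)
  for (id in criterion_ids()) {
    ages <- profiles[[paste0("age_", id)]][met[, id]]
    if (!length(ages)) {
      omitted <- c(omitted, id)
      next
    }
    frac <- vapply(grid, function(t) mean(ages <= t), 0)
    out[[id]] <- data.frame(criterion = id, t = grid, fraction = frac,
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(criterion = character(), t = numeric(), fraction = numeric())
  rownames(res) <- NULL
  attr(res, "omitted") <- omitted
  res
}

#' Criteria-count and score distributions
#'
#' Histogram of the number of criteria met and of the severity score, the
#' latter split by classification. Percentages sum to 100 up to rounding and
#' counts conserve the cohort size.
#'
#' @param results a `phe_results` data.frame from [classify_cohort()].
#' @return List with data.frames `counts` (n_criteria, n, pct) and `scores`
#'   (score, classification, n, pct).
#' @export
count_and_score_distributions <- function(results) {
  n_tot <- nrow(results)
  if (!n_tot) {
    return(list(
      counts = data.frame(n_criteria = integer(), n = integer(),
                          pct = numeric()),
      scores = data.frame(score = integer(), classification = character(),
                          n = integer(), pct = numeric())))
  }
  ct <- as.data.frame(table(n_criteria = results$n_met),
                      stringsAsFactors = FALSE)
  counts <- data.frame(n_criteria = as.integer(ct$n_criteria),
                       n = as.integer(ct$Freq),
                       pct = round(100 * ct$Freq / n_tot, 2))
  st <- as.data.frame(table(score = results$score,
                            classification = results$classification),
                      stringsAsFactors = FALSE)
  st <- st[st$Freq > 0, , drop = FALSE]
  scores <- data.frame(score = as.integer(st$score),
                       classification = st$classification,
                       n = as.integer(st$Freq),
                       pct = round(100 * st$Freq / n_tot, 2))
  scores <- scores[order(scores$score, scores$classification), ]
  rownames(scores) <- NULL
  list(counts = counts, scores = scores)
}
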