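# Diagnostic-validation computations: confusion summary with unknown-label
# exclusion, the standard diagnostic metrics, prevalence-adjusted PPV,
# per-criterion accuracy against a gold standard, and the stratified
# chart-review sampler.

#' Summarize a confusion matrix from counts
#'
#' Computes sensitivity, specificity, PPV, NPV and accuracy from the four
#' cell counts. Exact fractions are retained; the `*_pct` fields are rounded
#' to the nearest integer percent for reporting. Metrics with a zero
#' denominator are `NA` and listed in `$flags`.
#'
#' @param tp,fn,fp,tn confusion cell counts.
#' @param n_excluded_unknown children excluded for an "unknown" gold label.
#' @return An object of class `confusion_summary`.
#' @export
#' @examples
#' confusion_from_counts(tp = 85, fn = 9, fp = 3, tn = 91,
#'                       n_excluded_unknown = 12)
confusion_from_counts <- function(tp, fn, fp, tn, n_excluded_unknown = 0L) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  n <- tp + fn + fp + tn
  if (n == 0L) stop("no evaluable children", call. = FALSE)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  metrics <- list(sensitivity = frac(tp, tp + fn),
                  specificity = frac(tn, tn + fp),
                  ppv = frac(tp, tp + fp),
                  npv = frac(tn, tn + fn),
                  accuracy = frac(tp + tn, n))
  flags <- names(metrics)[vapply(metrics, is.na, TRUE)]
  out <- list(tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp),
              tn = as.integer(tn), n_evaluated = as.integer(n),
              n_excluded_unknown = as.integer(n_excluded_unknown),
              flags = flags)
  for (nm in names(metrics)) {
    out[[nm]] <- metrics[[nm]]
    out[[paste0(nm, "_pct")]] <- if (is.na(metrics[[nm]])) NA_real_
                                 else round(100 * metrics[[nm]])
  }
  structure(out, class = "confusion_summary")
}

#' Confusion summary of predictions against gold labels
#'
#' Gold labels are "has_disease", "no_disease" or "unknown"; children with an
#' unknown label are excluded before counting (and tallied in
#' `n_excluded_unknown`). Every gold child must have a prediction.
#'
#' @param pred data.frame with `child_id` and `classification`
#'   ("positive"/"negative"), e.g. a `phe_results` table.
#' @param gold data.frame with `child_id` and `status`.
#' @return A [confusion_from_counts()] object.
#' @export
confusion <- function(pred, gold) {
  stopifnot(all(c("child_id", "classification") %in% names(pred)),
            all(c("child_id", "status") %in% names(gold)))
  bad <- setdiff(gold$status, c("has_disease", "no_disease", "unknown"))
  if (length(bad)) {
    stop("unknown gold status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  i <- match(gold$child_id, pred$child_id)
  if (anyNA(i)) {
    stop("missing prediction for child_id: ",
         gold$child_id[which(is.na(i))[1L]], call. = FALSE)
  }
  p <- pred$classification[i]
  keep <- gold$status != "unknown"
  n_unknown <- sum(!keep)
  p <- p[keep]
  g <- gold$status[keep]
  confusion_from_counts(
    tp = sum(p == "positive" & g == "has_disease"),
    fn = sum(p == "negative" & g == "has_disease"),
    fp = sum(p == "positive" & g == "no_disease"),
    tn = sum(p == "negative" & g == "no_disease"),
    n_excluded_unknown = n_unknown
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary: n=%d evaluated, %d unknown excluded>\n",
              x$n_evaluated, x$n_excluded_unknown))
  cat(sprintf("  TP=%d FN=%d FP=%d TN=%d\n", x$tp, x$fn, x$fp, x$tn))
  fmt <- function(nm) {
    if (is.na(x[[nm]])) "undefined" else sprintf("%d%%", x[[paste0(nm, "_pct")]])
  }
  cat(sprintf("  sensitivity %s, specificity %s, PPV %s, NPV %s, accuracy %s\n",
              fmt("sensitivity"), fmt("specificity"), fmt("ppv"), fmt("npv"),
              fmt("accuracy")))
  if (length(x$flags)) {
    cat("  undefined (zero denominator): ",
        paste(x$flags, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Prevalence-adjusted positive predictive value
#'
#' Bayes re-computation of PPV at an assumed population prevalence:
#' `sens * p / (sens * p + (1 - spec) * (1 - p))`. A screening study with
#' balanced cases and controls overstates the PPV that would be seen at the
#' true population prevalence; this restates it.
#'
#' @param sensitivity fraction in (0, 1].
#' @param specificity fraction in (0, 1]; with specificity 1 there are no
#'   false positives and the adjusted PPV is exactly 1.
#' @param prevalence assumed population prevalence in (0, 1].
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' adjusted_ppv(0.90, 0.97, 0.03)  # 0.4813...
adjusted_ppv <- function(sensitivity, specificity, prevalence) {
  ok <- function(x) is.numeric(x) && all(x > 0 & x <= 1)
  if (!ok(sensitivity) || !ok(specificity) || !ok(prevalence)) {
    stop("sensitivity, specificity and prevalence must lie in (0, 1]",
         call. = FALSE)
  }
  num <- sensitivity * prevalence
  num / (num + (1 - specificity) * (1 - prevalence))
}

#' Per-criterion accuracy against a gold standard
#'
#' For each criterion, the fraction of children whose met flag agrees between
#' the algorithm and the gold profiles, as a percentage, plus the
#' cross-criterion mean.
#'
#' @param pred_profiles,gold_profiles `criteria_profiles` tables over the
#'   same children (any order).
#' @return An object of class `criterion_accuracy`: list with `table`
#'   (criterion, n, n_agree, accuracy_pct) and `mean_accuracy_pct`.
#' @export
per_criterion_accuracy <- function(pred_profiles, gold_profiles) {
  if (!setequal(pred_profiles$child_id, gold_profiles$child_id) ||
      nrow(pred_profiles) != nrow(gold_profiles)) {
    stop("pred and gold profiles must cover the same children",
         call. = FALSE)
  }
  gold_profiles <- gold_profiles[match(pred_profiles$child_id,
                                       gold_profiles$child_id), ,
                                 drop = FALSE]
  mp <- met_matrix(pred_profiles)
  mg <- met_matrix(gold_profiles)
  agree <- colSums(mp == mg)
  tab <- data.frame(criterion = criterion_ids(),
                    n = nrow(mp),
                    n_agree = as.integer(agree),
                    accuracy_pct = 100 * agree / nrow(mp),
                    row.names = NULL)
  structure(list(table = tab,
                 mean_accuracy_pct = mean(tab$accuracy_pct)),
            class = "criterion_accuracy")
}

#' @export
print.criterion_accuracy <- function(x, ...) {
  tab <- x$table
  tab$accuracy_pct <- round(tab$accuracy_pct, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("mean accuracy: %.1f%%\n", x$mean_accuracy_pct))
  invisible(x)
}

#' Stratified chart-review sampler
#'
#' Samples `n_pos` positive and `n_neg` negative children for manual review
#' such that the sampled scores span each class's observed score range:
#' within each class, scores are cut into up to ten quantile bins and one
#' child is drawn per bin in rotation; any remainder is filled uniformly at
#' random. Deterministic given the seed.
#'
#' @param results a `phe_results` data.frame.
#' @param n_pos,n_neg number of positives / negatives to sample.
#' @param seed integer seed.
#' @return Character vector of `n_pos + n_neg` child ids.
#' @export
sample_chart_review <- function(results, n_pos = 100L, n_neg = 100L,
                                seed = 1L) {
  sample_class <- function(cls, n_want) {
    sub <- results[results$classification == cls, , drop = FALSE]
    if (nrow(sub) < n_want) {
      stop(sprintf("%s stratum has only %d children (< %d requested)",
                   cls, nrow(sub), n_want), call. = FALSE)
    }
    if (length(unique(sub$score)) == 1L) {
      message(sprintf("%s stratum has a single score (%d): degenerate coverage",
                      cls, sub$score[1L]))
      return(sub$child_id[sample.int(nrow(sub), n_want)])
    }
    breaks <- unique(stats::quantile(sub$score, probs = seq(0, 1, 0.1),
                                     type = 1))
    bin <- cut(sub$score, breaks = breaks, include.lowest = TRUE)
    picked <- character(0)
    pools <- split(sub$child_id, bin)
    pools <- lapply(pools, function(p) p[sample.int(length(p))])  # shuffle
    depth <- 1L
    while (length(picked) < n_want) {
      layer <- unlist(lapply(pools, function(p)
        if (length(p) >= depth) p[depth] else NULL), use.names = FALSE)
      if (!length(layer)) break
      picked <- c(picked, layer[seq_len(min(length(layer),
                                            n_want - length(picked)))])
      depth <- depth + 1L
    }
    picked
  }
  with_seed(seed, {
    c(sample_class("positive", n_pos), sample_class("negative", n_neg))
  })
}
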