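#' F-score (harmonic mean of precision and sensitivity)
#'
#' @param precision,sensitivity Numeric vectors in [0, 1].
#' @return Numeric vector; 0 where both inputs are 0.
#' @export
f_score <- function(precision, sensitivity) {
  if (any(precision < 0 | precision > 1 | sensitivity < 0 | sensitivity > 1,
          na.rm = TRUE)) {
    stop("precision and sensitivity must lie in [0, 1]", call. = FALSE)
  }
  denom <- precision + sensitivity
  ifelse(denom > 0, 2 * precision * sensitivity / denom, 0)
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    if (fn > 0) {
      warning("nothing retrieved while relevant instances exist; precision set to 0")
    }
    0
  }
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = precision, sensitivity = sensitivity,
       f_score = f_score(precision, sensitivity))
}

#' Score age-related-abstract detection against gold annotations
#'
#' An abstract counts as a true positive when both the pipeline and the gold
#' reader deem it age-related. Among true positives, the fraction of
#' perfectly extracted ranges (exact low/high agreement) is also reported.
#'
#' @param predictions Data frame with columns `pmid`, `age_related`
#'   (logical), and for age-related predictions `low_years`, `high_years`.
#' @param gold Data frame with columns `pmid`, `is_age_related`, and for
#'   age-related records `low_years`, `high_years`.
#' @return List: `precision`, `sensitivity`, `f_score`, `perfect_range_fraction`,
#'   plus raw counts `tp`, `fp`, `fn`.
#' @export
evaluate_age_detection <- function(predictions, gold) {
  if (!setequal(predictions$pmid, gold$pmid)) {
    stop("prediction and gold PMID sets differ", call. = FALSE)
  }
  m <- match(gold$pmid, predictions$pmid)
  pred <- predictions[m, , drop = FALSE]
  tp_i <- which(pred$age_related & gold$is_age_related)
  fp <- sum(pred$age_related & !gold$is_age_related)
  fn <- sum(!pred$age_related & gold$is_age_related)
  scores <- prf(length(tp_i), fp, fn)
  perfect <- if (length(tp_i)) {
    mean(pred$low_years[tp_i] == gold$low_years[tp_i] &
           pred$high_years[tp_i] == gold$high_years[tp_i])
  } else {
    NA_real_
  }
  c(scores, list(perfect_range_fraction = perfect,
                 tp = length(tp_i), fp = fp, fn = fn))
}

#' Score relationship-type assignment against gold annotations
#'
#' Considers records the gold reader deemed age-related. `correct` and
#' `undetermined` are fractions of all evaluated records;
#' `incorrect_of_assigned` is the fraction of wrong assignments among
#' records where the pipeline assigned a (non-undetermined) type, `NA` when
#' nothing was assigned.
#'
#' @param predictions Data frame with columns `pmid`, `relationship`.
#' @param gold Data frame with columns `pmid`, `gold_relationship`.
#' @return List: `correct`, `undetermined`, `incorrect_of_assigned`, `n`.
#' @export
evaluate_relationship <- function(predictions, gold) {
  if (!setequal(predictions$pmid, gold$pmid)) {
    stop("prediction and gold PMID sets differ", call. = FALSE)
  }
  m <- match(gold$pmid, predictions$pmid)
  pred <- predictions$relationship[m]
  n <- length(pred)
  assigned <- pred != "UNDETERMINED"
  list(correct = mean(assigned & pred == gold$gold_relationship),
       undetermined = mean(!assigned),
       incorrect_of_assigned = if (any(assigned)) {
         mean(pred[assigned] != gold$gold_relationship[assigned])
       } else {
         NA_real_
       },
       n = n)
}

#' Summarise snippet-quality judgements
#'
#' Snippet generation is judged by a human reader comparing each generated
#' snippet with one written from the full abstract; each snippet is rated
#' `COMPLETE` (all important age-related information present),
#' `MISSING_INFO`, or `ERRONEOUS` (unrelated information included). This
#' summarises the judgement fractions.
#'
#' @param judgements Data frame with columns `instance_id`,
#'   `gold_snippet_quality` (one of the three ratings).
#' @return List: `complete`, `missing_info`, `erroneous`, `n`.
#' @export
evaluate_snippet <- function(judgements) {
  q <- judgements$gold_snippet_quality
  ok <- c("COMPLETE", "MISSING_INFO", "ERRONEOUS")
  bad <- setdiff(unique(q), ok)
  if (length(bad)) {
    stop("unknown snippet quality rating(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(complete = mean(q == "COMPLETE"),
       missing_info = mean(q == "MISSING_INFO"),
       erroneous = mean(q == "ERRONEOUS"),
       n = length(q))
}

#' Score phenotype mapping against gold annotations
#'
#' Per instance, predicted phenotype terms are compared with the gold
#' reader's terms. Terms in both are true positives; gold terms that were
#' missed are false negatives, except gold phenotypes absent from both
#' lexicons, which are treated as true negatives and excluded. Predicted
#' extras annotated as harmless (redundant or overly general but not
#' erroneous) are removed before false-positive counting in
#' `"HARMLESS_EXCLUDED"` mode, or counted as false positives in
#' `"HARMLESS_AS_FP"` mode; all other extras are always false positives.
#'
#' @param predicted Data frame with columns `instance_id`, `term_id`.
#' @param gold Data frame with columns `instance_id`, `term_id`,
#'   `is_harmless` (logical; harmless predicted extras), and optionally
#'   `in_lexicon` (logical, default `TRUE`; gold phenotypes absent from the
#'   lexicons). Rows with `is_harmless = TRUE` list tolerated extras, not
#'   required phenotypes.
#' @param mode `"HARMLESS_EXCLUDED"` or `"HARMLESS_AS_FP"`.
#' @return List: `precision`, `sensitivity`, `f_score`, `tp`, `fp`, `fn`.
#' @export
evaluate_mapping <- function(predicted, gold,
                             mode = c("HARMLESS_EXCLUDED", "HARMLESS_AS_FP")) {
  mode <- match.arg(mode)
  if (!"in_lexicon" %in% names(gold)) gold$in_lexicon <- TRUE
  ids <- unique(c(predicted$instance_id, gold$instance_id))
  tp <- fp <- fn <- 0L
  for (id in ids) {
    p <- unique(predicted$term_id[predicted$instance_id == id])
    g <- gold[gold$instance_id == id, , drop = FALSE]
    required <- unique(g$term_id[!g$is_harmless & g$in_lexicon])
    harmless <- unique(g$term_id[g$is_harmless])
    tp <- tp + length(intersect(p, required))
    fn <- fn + length(setdiff(required, p))
    extras <- setdiff(p, required)
    if (mode == "HARMLESS_EXCLUDED") {
      extras <- setdiff(extras, harmless)
    }
    fp <- fp + length(extras)
  }
  c(prf(tp, fp, fn), list(tp = tp, fp = fp, fn = fn))
}
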