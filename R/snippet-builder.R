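#' Patient/subject cue words used in snippet scoring
#' @return Character vector.
#' @export
subject_cues <- function() {
  c("patients", "patient", "subjects", "subject", "cases", "case",
    "men", "women", "children", "participants")
}

#' Build the evidence snippet for an age mention
#'
#' The snippet is composed of whole sentences only, at most
#' `max_sentences` of them, possibly non-consecutive. The sentence
#' containing the age mention is always included. Every other sentence is
#' scored: +3 if it lies in a CONCLUSION(S) section or is the final sentence
#' of an unstructured abstract (a concluding sentence); +2 if it contains a
#' patient/subject cue; +2 if it contains a cue word of the assigned
#' relationship type; +1 if it is adjacent to the age sentence. The top
#' `max_sentences - 1` sentences with positive score are added, ties broken
#' by earlier position.
#'
#' @param record Sentence-segmented `abstract_record`.
#' @param mention One row of [extract_age_mentions()] output.
#' @param rel Assigned relationship type (not `"UNDETERMINED"`).
#' @param cues Cue table used for the relationship-cue bonus.
#' @param max_sentences Hard cap on snippet length in sentences.
#' @return A list of class `snippet`: `pmid`, `sentence_indices`
#'   (increasing), `text` (sentences joined with single spaces).
#' @export
build_snippet <- function(record, mention, rel, cues = relation_cues(),
                          max_sentences = 3L) {
  stopifnot(inherits(record, "abstract_record"), !is.null(record$sentences))
  if (identical(rel, "UNDETERMINED")) {
    stop("cannot build a snippet for an UNDETERMINED relationship",
         call. = FALSE)
  }
  sent <- record$sentences
  si <- mention$sentence_index[1]
  others <- sent[sent$index != si, , drop = FALSE]
  chosen <- si
  if (nrow(others) && max_sentences > 1L) {
    structured <- any(!is.na(sent$section_label))
    rel_cues <- cues$cue[cues$type == rel]
    score <- vapply(seq_len(nrow(others)), function(i) {
      s <- others[i, ]
      sc <- 0
      concl_section <- !is.na(s$section_label) &&
        s$section_label %in% c("CONCLUSION", "CONCLUSIONS")
      final_unstructured <- !structured && s$index == max(sent$index)
      if (concl_section || final_unstructured) sc <- sc + 3
      if (any(vapply(subject_cues(), function(cue) {
        nrow(match_all(token_bound_pattern(cue), s$text)) > 0
      }, TRUE))) sc <- sc + 2
      if (length(rel_cues) && any(vapply(rel_cues, function(cue) {
        nrow(match_all(token_bound_pattern(cue), s$text)) > 0
      }, TRUE))) sc <- sc + 2
      if (abs(s$index - si) == 1L) sc <- sc + 1
      sc
    }, numeric(1))
    ord <- order(-score, others$index)
    take <- ord[score[ord] > 0]
    take <- utils::head(take, max_sentences - 1L)
    chosen <- sort(c(si, others$index[take]))
  }
  structure(list(pmid = record$pmid,
                 sentence_indices = as.integer(chosen),
                 text = paste(sent$text[match(chosen, sent$index)],
                              collapse = " ")),
            class = "snippet")
}

#' @export
print.snippet <- function(x, ...) {
  cat("<snippet> PMID", x$pmid, "sentences",
      paste(x$sentence_indices, collapse = ","), "\n")
  cat(" ", x$text, "\n")
  invisible(x)
}
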