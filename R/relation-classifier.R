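RELATIONSHIP_TYPES <- c("AGE_OF_ONSET", "AGE_OF_DIAGNOSIS",
                        "AGE_OF_OBSERVATION", "AGE_OF_OCCURRENCE",
                        "AGE_OF_EVALUATION")

#' Relationship cue table
#'
#' Cue words/phrases for the five age-phenotype relationship types. `level`
#' encodes precedence when cues of several types fire in the same window:
#' more specific clinical events (onset, diagnosis) outrank generic study
#' verbs (evaluation). Cues are matched case-insensitively on token
#' boundaries; multi-word cues tolerate any whitespace.
#'
#' @param path Optional TSV (columns `cue`, `type`, `level`) replacing the
#'   built-in table.
#' @return Data frame with columns `cue`, `type`, `level`.
#' @export
relation_cues <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("cue", "type", "level")
    if (!all(need %in% names(tab))) {
      stop("cue table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    bad <- setdiff(unique(tab$type), RELATIONSHIP_TYPES)
    if (length(bad)) {
      stop("unknown relationship type(s) in cue table: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    return(tab[, need])
  }
  mk <- function(type, level, cues) {
    data.frame(cue = cues, type = type, level = level,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("AGE_OF_ONSET", 5,
       c("onset", "first appeared", "developed", "began", "debut")),
    mk("AGE_OF_DIAGNOSIS", 4, c("diagnosed", "diagnosis", "detected")),
    mk("AGE_OF_OBSERVATION", 3,
       c("observed", "presented with", "presenting", "found to have",
         "seen in")),
    mk("AGE_OF_OCCURRENCE", 2,
       c("occurred", "occurrence", "incidence", "events")),
    mk("AGE_OF_EVALUATION", 1,
       c("evaluated", "assessed", "examined", "screened", "measured")))
}

# All cue matches in `text` (offsets 1-based into text).
find_cues <- function(text, cues) {
  out <- lapply(seq_len(nrow(cues)), function(i) {
    m <- match_all(token_bound_pattern(cues$cue[i]), text)
    if (!nrow(m)) return(NULL)
    m$cue <- cues$cue[i]
    m$type <- cues$type[i]
    m$level <- cues$level[i]
    m
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), cue = character(),
                      type = character(), level = integer()))
  }
  do.call(rbind, out)
}

#' Classify the age-phenotype relationship for an age mention
#'
#' Scans for relationship cues in three widening windows — the sentence
#' containing the mention, that sentence plus its neighbours, then the whole
#' abstract — and stops at the first window where any cue fires. Within a
#' window the firing cue with the highest precedence level determines the
#' type; ties are broken by proximity to the age mention, then by earlier
#' text position. Returns `"UNDETERMINED"` when no cue fires anywhere, so an
#' age-cue co-occurrence in the same local window is required, not mere
#' keyword co-occurrence in the abstract.
#'
#' @param record A sentence-segmented `abstract_record`.
#' @param mention One row of [extract_age_mentions()] output.
#' @param cues Cue table, see [relation_cues()].
#' @return A single relationship type string, or `"UNDETERMINED"`.
#' @export
classify_relationship <- function(record, mention, cues = relation_cues()) {
  stopifnot(inherits(record, "abstract_record"), !is.null(record$sentences))
  sent <- record$sentences
  si <- mention$sentence_index[1]
  windows <- list(si,
                  intersect(c(si - 1L, si, si + 1L), sent$index),
                  sent$index)
  hits <- find_cues(record$abstract, cues)
  if (!nrow(hits)) return("UNDETERMINED")
  # map each cue hit to its sentence
  hits$sentence_index <- vapply(hits$start, function(s) {
    idx <- sent$index[sent$start <= s & sent$end >= s]
    if (length(idx)) idx[1] else NA_integer_
  }, integer(1))
  for (w in windows) {
    inw <- hits[hits$sentence_index %in% w, , drop = FALSE]
    if (!nrow(inw)) next
    top <- inw[inw$level == max(inw$level), , drop = FALSE]
    dist <- abs(top$start - mention$start[1])
    top <- top[order(dist, top$start), , drop = FALSE]
    return(top$type[1])
  }
  "UNDETERMINED"
}
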