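#' Pipeline configuration
#'
#' Bundles every table and mode flag the pipeline uses. All behaviour-bearing
#' tables (age patterns, relationship cues, section labels, gendered terms)
#' are data, overridable here, never hard-coded in the stages.
#'
#' @param patterns Age-pattern table ([age_patterns()]).
#' @param cues Relationship-cue table ([relation_cues()]).
#' @param max_snippet_sentences Snippet cap in sentences.
#' @param legacy_mean_priority Prefer mean-age mentions over explicit
#'   ranges (replicates a known failure mode of early rule sets).
#' @param include_titles Also mine title text (prepended to the abstract).
#' @param include_redundant_hits Let redundant hits satisfy the population
#'   filter and phenotype queries.
#' @param allowed_semantic_types Concept-lexicon semantic-type allow-list.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(patterns = age_patterns(),
                            cues = relation_cues(),
                            max_snippet_sentences = 3L,
                            legacy_mean_priority = FALSE,
                            include_titles = FALSE,
                            include_redundant_hits = FALSE,
                            allowed_semantic_types = c("disease", "drug",
                                                       "finding")) {
  structure(list(patterns = patterns, cues = cues,
                 max_snippet_sentences = as.integer(max_snippet_sentences),
                 legacy_mean_priority = legacy_mean_priority,
                 include_titles = include_titles,
                 include_redundant_hits = include_redundant_hits,
                 allowed_semantic_types = allowed_semantic_types),
            class = "pipeline_config")
}

#' Run the full mining pipeline over a corpus
#'
#' Chains the four mining steps — age detection, relationship typing,
#' snippet generation, phenotype mapping — and populates the evidence
#' store, applying the population filter (candidates whose relationship
#' could not be determined, or for which no phenotype was found, are
#' dropped and counted).
#'
#' @param records List of `abstract_record`s from [read_medline()].
#' @param ontology A `disease_ontology`.
#' @param concepts A `concept_lexicon` (or `NULL`).
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `store` (an `apk_store`) and
#'   `report` (named counts: `records_in`, `age_related_records`,
#'   `candidates_total`, `relationship_assigned`, `snippets_built`,
#'   `instances_populated`, `dropped_undetermined`, `dropped_no_phenotype`,
#'   `multi_instance_abstracts`).
#' @export
run_pipeline <- function(records, ontology, concepts = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- c(records_in = length(records), age_related_records = 0L,
              candidates_total = 0L, relationship_assigned = 0L,
              snippets_built = 0L, instances_populated = 0L,
              dropped_undetermined = 0L, dropped_no_phenotype = 0L,
              multi_instance_abstracts = 0L)
  rows <- list()
  for (rec in records) {
    if (config$include_titles && nzchar(rec$title)) {
      rec <- new_abstract_record(rec$pmid, rec$title,
                                 paste(rec$title, rec$abstract),
                                 rec$pub_year, rec$pub_types)
    }
    rec <- segment_sentences(rec)
    mentions <- extract_age_mentions(rec, config$patterns)
    if (!nrow(mentions)) next
    report["age_related_records"] <- report["age_related_records"] + 1L
    cands <- select_age_candidates(mentions, config$legacy_mean_priority)
    report["candidates_total"] <- report["candidates_total"] + nrow(cands)
    n_inst <- 0L
    for (ci in seq_len(nrow(cands))) {
      cand <- cands[ci, , drop = FALSE]
      rel <- classify_relationship(rec, cand, config$cues)
      if (identical(rel, "UNDETERMINED")) {
        report["dropped_undetermined"] <- report["dropped_undetermined"] + 1L
        next
      }
      report["relationship_assigned"] <- report["relationship_assigned"] + 1L
      snip <- build_snippet(rec, cand, rel, config$cues,
                            config$max_snippet_sentences)
      report["snippets_built"] <- report["snippets_built"] + 1L
      hits <- flag_redundant(map_snippet(snip, ontology, concepts), ontology)
      if (!config$include_redundant_hits && nrow(hits)) {
        usable <- hits[!hits$is_redundant, , drop = FALSE]
      } else {
        usable <- hits
      }
      if (!nrow(usable)) {
        report["dropped_no_phenotype"] <- report["dropped_no_phenotype"] + 1L
        next
      }
      gender <- detect_gender(snip)
      inst <- assemble_instance(rec, cand, rel, snip, hits, gender,
                                ordinal = n_inst + 1L)
      n_inst <- n_inst + 1L
      rows[[length(rows) + 1L]] <- inst
    }
    report["instances_populated"] <- report["instances_populated"] + n_inst
    if (n_inst >= 2L) {
      report["multi_instance_abstracts"] <-
        report["multi_instance_abstracts"] + 1L
    }
  }
  structure(list(store = bind_store(rows), report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$report)) {
    cat(sprintf("  %-24s %d\n", nm, x$report[[nm]]))
  }
  invisible(x)
}
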