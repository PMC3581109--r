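#' Default synthetic disease pool
#'
#' A 14-term mini disease hierarchy: a root, two internal terms (cancer,
#' infectious disease) and ten leaf diseases with one synonym each, plus a
#' concept ID per term for the synthetic concept lexicon (filename-level
#' fixtures built from this pool are synthetic stand-ins, not excerpts of
#' any real vocabulary).
#'
#' @return Data frame: `term_id`, `name`, `synonym` (may be `NA`), `parent`
#'   (`NA` for the root), `concept_id`, `leaf`.
#' @export
default_disease_pool <- function() {
  d <- function(term_id, name, synonym, parent, concept_id, leaf) {
    data.frame(term_id = term_id, name = name, synonym = synonym,
               parent = parent, concept_id = concept_id, leaf = leaf,
               stringsAsFactors = FALSE)
  }
  rbind(
    d("DOID:0000001", "disease", NA, NA, "C0000001", FALSE),
    d("DOID:0000002", "cancer", "malignant neoplasm", "DOID:0000001",
      "C0000002", FALSE),
    d("DOID:0000003", "infectious disease", NA, "DOID:0000001", "C0000003",
      FALSE),
    d("DOID:0000011", "leukemia", "leukaemia", "DOID:0000002", "C0000011", TRUE),
    d("DOID:0000012", "lymphoma", NA, "DOID:0000002", "C0000012", TRUE),
    d("DOID:0000013", "melanoma", NA, "DOID:0000002", "C0000013", TRUE),
    d("DOID:0000014", "glioblastoma", "glioblastoma multiforme",
      "DOID:0000002", "C0000014", TRUE),
    d("DOID:0000015", "breast cancer", NA, "DOID:0000002", "C0000015", TRUE),
    d("DOID:0000021", "influenza", "flu", "DOID:0000003", "C0000021", TRUE),
    d("DOID:0000022", "tuberculosis", NA, "DOID:0000003", "C0000022", TRUE),
    d("DOID:0000023", "measles", NA, "DOID:0000003", "C0000023", TRUE),
    d("DOID:0000024", "gonorrhea", NA, "DOID:0000003", "C0000024", TRUE),
    d("DOID:0000025", "hepatitis", NA, "DOID:0000003", "C0000025", TRUE))
}

#' Render a disease pool as an OBO ontology
#'
#' @param pool A disease pool, see [default_disease_pool()].
#' @return Character vector of OBO lines.
#' @export
pool_to_obo <- function(pool = default_disease_pool()) {
  lines <- c("format-version: 1.2", "ontology: synthetic-disease-ontology", "")
  for (i in seq_len(nrow(pool))) {
    p <- pool[i, ]
    lines <- c(lines, "[Term]",
               paste0("id: ", p$term_id),
               paste0("name: ", p$name))
    if (!is.na(p$synonym)) {
      lines <- c(lines, sprintf('synonym: "%s" EXACT []', p$synonym))
    }
    if (!is.na(p$parent)) {
      lines <- c(lines, paste0("is_a: ", p$parent))
    }
    lines <- c(lines, paste0("xref: UMLS_CUI:", p$concept_id), "")
  }
  lines
}

#' Render a disease pool as a concept-subset lexicon
#'
#' Disease concepts for every pool term (names and synonyms), plus one drug
#' and one finding concept so the allow-list is exercised.
#'
#' @param pool A disease pool.
#' @return Character vector of TSV lines (with header).
#' @export
pool_to_concepts <- function(pool = default_disease_pool()) {
  rows <- c("concept_id\tsemantic_type\tstring")
  for (i in seq_len(nrow(pool))) {
    p <- pool[i, ]
    rows <- c(rows, paste(p$concept_id, "disease", p$name, sep = "\t"))
    if (!is.na(p$synonym)) {
      rows <- c(rows, paste(p$concept_id, "disease", p$synonym, sep = "\t"))
    }
  }
  c(rows,
    "C0000201\tdrug\taspirin",
    "C0000202\tfinding\tfever")
}

#' Specify a synthetic corpus
#'
#' The generator emulates the study conditions of a literature-mining run:
#' each age-related abstract embeds one sampled age (rendered through one of
#' the package's own extraction patterns), one relationship cue (or none),
#' one disease from the pool and gendered wording per the mix. Defaults:
#' 200 abstracts, all five relationship types plus a 20% no-cue fraction,
#' 10% inferred ranges, 10% non-age-related abstracts, 30% structured
#' abstracts, gender mix 40/30/30 male/female/unstated.
#'
#' @param n_abstracts Number of abstracts.
#' @param disease_pool Disease pool data frame.
#' @param age_means,age_sds Named per-leaf age profile parameters (years);
#'   defaults spread means over 10-80 with sd 5, truncated to [1, 95].
#' @param relationship_mix Named weights over the five types plus `none`
#'   (no cue planted); must sum to 1.
#' @param inferred_fraction Fraction of age-related abstracts with an
#'   open-ended (inferred) range.
#' @param gender_mix Named weights over `male`, `female`, `none`.
#' @param structured_fraction Fraction of structured abstracts.
#' @param nonage_fraction Fraction of abstracts with no age mention.
#' @param corruption Fraction of age-related abstracts whose age is written
#'   non-numerically (and hence, by design, not extractable).
#' @param seed Mandatory RNG seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_abstracts = 200L,
                         disease_pool = default_disease_pool(),
                         age_means = NULL, age_sds = NULL,
                         relationship_mix = c(AGE_OF_ONSET = 0.16,
                                              AGE_OF_DIAGNOSIS = 0.16,
                                              AGE_OF_OBSERVATION = 0.16,
                                              AGE_OF_OCCURRENCE = 0.16,
                                              AGE_OF_EVALUATION = 0.16,
                                              none = 0.2),
                         inferred_fraction = 0.1,
                         gender_mix = c(male = 0.4, female = 0.3, none = 0.3),
                         structured_fraction = 0.3,
                         nonage_fraction = 0.1,
                         corruption = 0,
                         seed = 1L) {
  leaves <- disease_pool$name[disease_pool$leaf]
  if (!length(leaves)) stop("disease pool has no leaf diseases", call. = FALSE)
  if (is.null(age_means)) {
    age_means <- stats::setNames(seq(10, 80, length.out = length(leaves)),
                                 leaves)
  }
  if (is.null(age_sds)) {
    age_sds <- stats::setNames(rep(5, length(leaves)), leaves)
  }
  stopifnot(abs(sum(relationship_mix) - 1) < 1e-8,
            abs(sum(gender_mix) - 1) < 1e-8,
            all(age_sds > 0),
            inferred_fraction >= 0, inferred_fraction <= 1,
            structured_fraction >= 0, structured_fraction <= 1,
            nonage_fraction >= 0, nonage_fraction <= 1,
            corruption >= 0, corruption <= 1)
  structure(list(n_abstracts = as.integer(n_abstracts),
                 disease_pool = disease_pool,
                 age_means = age_means, age_sds = age_sds,
                 relationship_mix = relationship_mix,
                 inferred_fraction = inferred_fraction,
                 gender_mix = gender_mix,
                 structured_fraction = structured_fraction,
                 nonage_fraction = nonage_fraction,
                 corruption = corruption,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

cue_phrase_point <- function(type) {
  switch(type,
         AGE_OF_ONSET = "developed",
         AGE_OF_DIAGNOSIS = "was diagnosed with",
         AGE_OF_OBSERVATION = "was found to have",
         AGE_OF_OCCURRENCE = "experienced events of",
         AGE_OF_EVALUATION = "was evaluated for",
         none = "had a history of")
}

cue_phrase_range <- function(type) {
  switch(type,
         AGE_OF_ONSET = "first appeared",
         AGE_OF_DIAGNOSIS = "was diagnosed",
         AGE_OF_OBSERVATION = "was observed",
         AGE_OF_OCCURRENCE = "occurred",
         AGE_OF_EVALUATION = "was assessed",
         none = "was common")
}

cap_first <- function(s) {
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

#' Generate a seeded synthetic corpus with gold annotations
#'
#' Produces a MEDLINE corpus, a matching mini ontology and concept lexicon,
#' and gold tables recording every planted value. Identical seeds give
#' byte-identical outputs.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Optional directory; when given, `corpus.medline`,
#'   `ontology.obo`, `concepts.tsv` and the gold TSVs are written there.
#' @return List: `medline`, `obo`, `concepts` (character line vectors) and
#'   `gold` (list of data frames: `age`, `relationship`, `phenotype`,
#'   `gender`).
#' @export
generate_corpus <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  pool <- spec$disease_pool
  leaves <- pool[pool$leaf, , drop = FALSE]
  with_seed(spec$seed, {
    n <- spec$n_abstracts
    gold_age <- vector("list", n)
    gold_rel <- vector("list", n)
    gold_phe <- vector("list", n)
    gold_gen <- vector("list", n)
    med <- vector("list", n)
    for (i in seq_len(n)) {
      pmid <- sprintf("9%06d", i)
      li <- sample.int(nrow(leaves), 1L)
      disease <- leaves$name[li]
      term_id <- leaves$term_id[li]
      year <- sample(1990:2011, 1L)
      age_related <- stats::runif(1) >= spec$nonage_fraction
      if (!age_related) {
        ab <- paste0("The molecular basis of ", disease,
                     " was reviewed in detail. ",
                     "Gene expression profiles were compared across tissues.")
        med[[i]] <- c(sprintf("PMID- %s", pmid),
                      sprintf("TI  - A study of %s.", disease),
                      sprintf("AB  - %s", ab),
                      sprintf("DP  - %d Jan", year),
                      "PT  - Journal Article", "")
        gold_age[[i]] <- data.frame(pmid = pmid, is_age_related = FALSE,
                                    low_years = NA_real_,
                                    high_years = NA_real_, inferred = NA,
                                    stringsAsFactors = FALSE)
        next
      }
      mu <- spec$age_means[[disease]]
      sdev <- spec$age_sds[[disease]]
      age <- round(min(95, max(1, stats::rnorm(1, mu, sdev))))
      rel <- sample(names(spec$relationship_mix), 1L,
                    prob = spec$relationship_mix)
      gender <- sample(names(spec$gender_mix), 1L, prob = spec$gender_mix)
      corrupted <- stats::runif(1) < spec$corruption
      inferred <- !corrupted && stats::runif(1) < spec$inferred_fraction
      use_range <- !inferred && !corrupted && stats::runif(1) < 0.5
      if (corrupted) {
        gnoun <- switch(gender, male = "man", female = "woman",
                        none = "patient")
        age_sentence <- sprintf("An adult %s %s %s.", gnoun,
                                cue_phrase_point(rel), disease)
        low <- age; high <- age; inf_flag <- FALSE
      } else if (inferred) {
        open_high <- stats::runif(1) < 0.5
        gword <- switch(gender, male = "men", female = "women",
                        none = "patients")
        age_sentence <- sprintf("%s %s in %s aged %d years or %s.",
                                cap_first(disease), cue_phrase_range(rel),
                                gword, age,
                                if (open_high) "more" else "less")
        if (open_high) { low <- age; high <- 120 } else { low <- 0; high <- age }
        inf_flag <- TRUE
      } else if (use_range) {
        lo <- max(0, age - sample(1:3, 1L))
        hi <- min(95, age + sample(1:3, 1L))
        gword <- switch(gender, male = "men", female = "women",
                        none = "patients")
        age_sentence <- sprintf("%s %s in %s aged %d to %d years.",
                                cap_first(disease), cue_phrase_range(rel),
                                gword, lo, hi)
        low <- lo; high <- hi; inf_flag <- FALSE
      } else {
        gnoun <- switch(gender, male = "man", female = "woman",
                        none = "patient")
        age_sentence <- sprintf("A %d-year-old %s %s %s.", age, gnoun,
                                cue_phrase_point(rel), disease)
        low <- age; high <- age; inf_flag <- FALSE
      }
      structured <- stats::runif(1) < spec$structured_fraction
      ab <- if (structured) {
        paste0("OBJECTIVE: We characterized the clinical profile of this ",
               "condition. METHODS: Medical records were reviewed ",
               "retrospectively. RESULTS: ", age_sentence,
               " CONCLUSIONS: These findings support age-specific clinical ",
               "management.")
      } else {
        paste0("The clinical burden of this condition remains poorly ",
               "understood. ", age_sentence,
               " These findings support age-specific clinical management.")
      }
      med[[i]] <- c(sprintf("PMID- %s", pmid),
                    sprintf("TI  - A study of %s.", disease),
                    sprintf("AB  - %s", ab),
                    sprintf("DP  - %d Jan", year),
                    "PT  - Journal Article", "")
      detectable <- !corrupted
      gold_age[[i]] <- data.frame(pmid = pmid, is_age_related = detectable,
                                  low_years = if (detectable) low else NA_real_,
                                  high_years = if (detectable) high else NA_real_,
                                  inferred = if (detectable) inf_flag else NA,
                                  stringsAsFactors = FALSE)
      gold_rel[[i]] <- data.frame(pmid = pmid,
                                  gold_relationship = if (rel == "none")
                                    "UNDETERMINED" else rel,
                                  stringsAsFactors = FALSE)
      gold_phe[[i]] <- data.frame(pmid = pmid, term_id = term_id,
                                  concept_id = leaves$concept_id[li],
                                  stringsAsFactors = FALSE)
      gold_gen[[i]] <- data.frame(pmid = pmid, gender = toupper(gender),
                                  stringsAsFactors = FALSE)
    }
    out <- list(medline = unlist(med),
                obo = pool_to_obo(pool),
                concepts = pool_to_concepts(pool),
                gold = list(age = do.call(rbind, gold_age),
                            relationship = do.call(rbind, gold_rel[
                              !vapply(gold_rel, is.null, TRUE)]),
                            phenotype = do.call(rbind, gold_phe[
                              !vapply(gold_phe, is.null, TRUE)]),
                            gender = do.call(rbind, gold_gen[
                              !vapply(gold_gen, is.null, TRUE)])))
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      writeLines(out$medline, file.path(outdir, "corpus.medline"))
      writeLines(out$obo, file.path(outdir, "ontology.obo"))
      writeLines(out$concepts, file.path(outdir, "concepts.tsv"))
      for (g in names(out$gold)) {
        utils::write.table(out$gold[[g]],
                           file.path(outdir, paste0("gold_", g, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    out
  })
}

#' Generate the planted two-group clustering fixture
#'
#' Builds an evidence store directly: two groups of five diseases whose
#' single-age instances are drawn from normal age profiles peaking near 20
#' (late teens/early twenties, as for sexually transmitted infections in
#' the literature) and near 60 (cancers and cardiovascular disease), so a
#' two-way cut of the dendrogram should recover the planted partition.
#'
#' @param seed RNG seed.
#' @param n_per_disease Instances per disease.
#' @param peaks Numeric length-2 vector of group peak ages.
#' @param sd Age standard deviation within a disease.
#' @return List: `store` (an `apk_store`), `partition` (named integer
#'   vector of planted group per disease), `peaks`.
#' @export
generate_two_group_store <- function(seed = 1L, n_per_disease = 30L,
                                     peaks = c(20, 60), sd = 3) {
  stopifnot(length(peaks) == 2L, sd > 0)
  diseases <- c(sprintf("DOID:1%03d", 1:5), sprintf("DOID:2%03d", 1:5))
  partition <- stats::setNames(rep(1:2, each = 5L), diseases)
  with_seed(seed, {
    rows <- list()
    k <- 0L
    for (d in diseases) {
      mu <- peaks[partition[[d]]]
      for (j in seq_len(n_per_disease)) {
        k <- k + 1L
        a <- round(min(110, max(0, stats::rnorm(1, mu, sd))))
        hits <- data.frame(source = "ONTOLOGY", id = d,
                           mapped_ontology_id = NA_character_,
                           matched_span = d, start = 1L, end = nchar(d),
                           is_redundant = FALSE, stringsAsFactors = FALSE)
        row <- data.frame(instance_id = sprintf("%07d_01", k),
                          pmid = sprintf("%07d", k),
                          low_years = a, high_years = a, inferred = FALSE,
                          age_class = assign_age_class(a, a),
                          relationship = sample(RELATIONSHIP_TYPES, 1L),
                          snippet_text = sprintf(
                            "Synthetic evidence for %s at age %d.", d, a),
                          gender = "NONE", pub_year = 2000L, curated = FALSE,
                          stringsAsFactors = FALSE)
        row$snippet_indices <- list(1L)
        row$hits <- list(hits)
        row$pub_types <- list("Journal Article")
        rows[[k]] <- row
      }
    }
    list(store = bind_store(rows), partition = partition, peaks = peaks)
  })
}
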