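STORE_SCHEMA_VERSION <- 1L

#' Construct an evidence-store table
#'
#' The knowledge-base unit is an evidence instance: one age range from one
#' abstract linked to phenotypes via a whole-sentence snippet and a typed
#' relationship. The population rule is enforced here: an instance must
#' carry a determined relationship and at least one phenotype hit.
#'
#' @param instances Data frame of instances (see [assemble_instance()]).
#' @return Object of class `apk_store` (a data frame).
#' @export
new_apk_store <- function(instances = NULL) {
  if (is.null(instances)) {
    instances <- data.frame(instance_id = character(), pmid = character(),
                            low_years = numeric(), high_years = numeric(),
                            inferred = logical(), age_class = character(),
                            relationship = character(),
                            snippet_text = character(),
                            gender = character(), pub_year = integer(),
                            curated = logical(), stringsAsFactors = FALSE)
    instances$snippet_indices <- list()
    instances$hits <- list()
    instances$pub_types <- list()
  }
  validate_store(instances)
  structure(instances, class = c("apk_store", "data.frame"))
}

validate_store <- function(x) {
  need <- c("instance_id", "pmid", "low_years", "high_years", "inferred",
            "age_class", "relationship", "snippet_text", "snippet_indices",
            "hits", "gender", "pub_year", "pub_types", "curated")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("store is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(x)) return(invisible(TRUE))
  bad_rel <- !(x$relationship %in% RELATIONSHIP_TYPES)
  if (any(bad_rel)) {
    stop("instance(s) with undetermined or unknown relationship: ",
         paste(x$instance_id[bad_rel], collapse = ", "), call. = FALSE)
  }
  no_hits <- vapply(x$hits, function(h) is.null(h) || nrow(h) == 0L, TRUE)
  if (any(no_hits)) {
    stop("instance(s) without phenotype hits: ",
         paste(x$instance_id[no_hits], collapse = ", "), call. = FALSE)
  }
  expect_class <- assign_age_class(x$low_years, x$high_years)
  bad_cls <- x$age_class != expect_class
  if (any(bad_cls)) {
    stop("instance(s) with inconsistent age class: ",
         paste(x$instance_id[bad_cls], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$instance_id)) {
    stop("duplicate instance_id in store", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.apk_store <- function(x, ...) {
  cat("<apk_store>", nrow(x), "evidence instance(s),",
      length(unique(x$pmid)), "abstract(s)\n")
  if (nrow(x)) {
    print(table(relationship = x$relationship))
  }
  invisible(x)
}

#' Assemble one evidence instance, or drop it
#'
#' Applies the population filter: instances for which no relationship could
#' be determined or no phenotype was found are not stored.
#'
#' @param record Sentence-segmented `abstract_record`.
#' @param mention One candidate row from [select_age_candidates()].
#' @param rel Relationship type or `"UNDETERMINED"`.
#' @param snippet A `snippet`.
#' @param hits Hits with redundancy flags, from [flag_redundant()].
#' @param gender `"MALE"`, `"FEMALE"` or `"NONE"`.
#' @param ordinal Instance ordinal within the abstract (for the ID).
#' @return A one-row instance data frame, or `NULL` when filtered out.
#' @export
assemble_instance <- function(record, mention, rel, snippet, hits, gender,
                              ordinal = 1L) {
  if (identical(rel, "UNDETERMINED") || is.null(hits) || nrow(hits) == 0L) {
    return(NULL)
  }
  out <- data.frame(
    instance_id = sprintf("%s_%02d", record$pmid, ordinal),
    pmid = record$pmid,
    low_years = mention$low_years[1], high_years = mention$high_years[1],
    inferred = mention$inferred[1],
    age_class = assign_age_class(mention$low_years[1], mention$high_years[1]),
    relationship = rel,
    snippet_text = snippet$text,
    gender = gender,
    pub_year = record$pub_year %||% NA_integer_,
    curated = FALSE,
    stringsAsFactors = FALSE)
  out$snippet_indices <- list(snippet$sentence_indices)
  out$hits <- list(hits)
  out$pub_types <- list(record$pub_types)
  out
}

# Bind one-row instance frames into a store.
bind_store <- function(rows) {
  if (!length(rows)) return(new_apk_store())
  new_apk_store(do.call(rbind, rows))
}

# Ontology terms an instance's hits stand for.
instance_terms <- function(hits, include_redundant = FALSE) {
  if (!include_redundant && nrow(hits)) {
    hits <- hits[!hits$is_redundant, , drop = FALSE]
  }
  t <- hit_ontology_term(hits)
  unique(t[!is.na(t)])
}

#' Query the evidence store
#'
#' Supports the three query modes — by age, by phenotype, or both — plus the
#' refinement filters, all conjunctive. An age query matches instances whose
#' range intersects the query interval (`contained = TRUE` switches to
#' strict containment); an age-class name queries with that class's
#' interval. A phenotype query matches instances carrying a hit on the query
#' term or any of its ontology descendants, so searching a high-level term
#' retrieves all of its subtypes. `wiki_preset = TRUE` applies the curated
#' subset rule: occurrence- and evaluation-typed evidence and inferred age
#' ranges are excluded.
#'
#' @param store An `apk_store`.
#' @param ontology A `disease_ontology`; required for phenotype queries.
#' @param age `NULL`, a numeric `c(low, high)` (or single age), or an age
#'   class name from [age_classes()].
#' @param phenotypes Character vector of ontology term IDs; conjunctive
#'   (an instance must match every one).
#' @param year_range Numeric `c(from, to)` on publication year.
#' @param pub_type Keep instances with this publication type.
#' @param curated Logical filter on curation status.
#' @param relationship Keep only these relationship types.
#' @param gender Keep only this gender value.
#' @param wiki_preset Apply the curated-subset exclusions.
#' @param contained Use strict containment for age matching.
#' @param include_redundant Let redundant hits satisfy phenotype queries.
#' @return An `apk_store` subset, rows ordered by relationship type then
#'   instance ID (results group naturally by relationship).
#' @export
query_store <- function(store, ontology = NULL, age = NULL, phenotypes = NULL,
                        year_range = NULL, pub_type = NULL, curated = NULL,
                        relationship = NULL, gender = NULL,
                        wiki_preset = FALSE, contained = FALSE,
                        include_redundant = FALSE) {
  stopifnot(inherits(store, "apk_store"))
  keep <- rep(TRUE, nrow(store))
  if (!is.null(age)) {
    if (is.character(age)) {
      cls <- age_classes()
      if (!age %in% cls$name) {
        stop("unknown age class: ", age, call. = FALSE)
      }
      iv <- c(cls$low[cls$name == age], cls$high[cls$name == age])
    } else {
      iv <- range(as.numeric(age))
    }
    keep <- keep & if (contained) {
      store$low_years >= iv[1] & store$high_years <= iv[2]
    } else {
      store$low_years <= iv[2] & store$high_years >= iv[1]
    }
  }
  if (!is.null(phenotypes)) {
    if (is.null(ontology)) {
      stop("phenotype queries require an ontology", call. = FALSE)
    }
    unknown <- setdiff(phenotypes, ontology$ids)
    if (length(unknown)) {
      stop("unknown phenotype term(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    inst_terms <- lapply(store$hits, instance_terms,
                         include_redundant = include_redundant)
    for (p in phenotypes) {
      fam <- c(p, term_descendants(ontology, p))
      keep <- keep & vapply(inst_terms, function(t) any(t %in% fam), TRUE)
    }
  }
  if (!is.null(year_range)) {
    keep <- keep & !is.na(store$pub_year) &
      store$pub_year >= year_range[1] & store$pub_year <= year_range[2]
  }
  if (!is.null(pub_type)) {
    keep <- keep & vapply(store$pub_types, function(p) pub_type %in% p, TRUE)
  }
  if (!is.null(curated)) keep <- keep & store$curated == curated
  if (!is.null(relationship)) keep <- keep & store$relationship %in% relationship
  if (!is.null(gender)) keep <- keep & store$gender == gender
  if (isTRUE(wiki_preset)) {
    keep <- keep & !(store$relationship %in%
                       c("AGE_OF_OCCURRENCE", "AGE_OF_EVALUATION")) &
      !store$inferred
  }
  out <- store[keep, , drop = FALSE]
  out <- out[order(match(out$relationship, RELATIONSHIP_TYPES),
                   out$instance_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("apk_store", "data.frame"))
}

#' Split query results by relationship type
#'
#' @param store An `apk_store` (typically a [query_store()] result).
#' @return Named list of `apk_store` subsets, one per relationship type
#'   present.
#' @export
split_by_relationship <- function(store) {
  stopifnot(inherits(store, "apk_store"))
  lapply(split(seq_len(nrow(store)), store$relationship, drop = TRUE),
         function(i) structure(store[i, , drop = FALSE],
                               class = c("apk_store", "data.frame")))
}

#' Persist an evidence store as JSON lines
#'
#' Line 1 is a schema header; each following line is one instance, ordered
#' by instance ID, so rewriting an unmodified store is byte-identical.
#'
#' @param store An `apk_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "apk_store"))
  store <- store[order(store$instance_id), , drop = FALSE]
  header <- jsonlite::toJSON(list(format = "apk-store",
                                  schema_version = STORE_SCHEMA_VERSION),
                             auto_unbox = TRUE)
  lines <- vapply(seq_len(nrow(store)), function(i) {
    rec <- list(
      instance_id = store$instance_id[i], pmid = store$pmid[i],
      low_years = store$low_years[i], high_years = store$high_years[i],
      inferred = store$inferred[i], age_class = store$age_class[i],
      relationship = store$relationship[i],
      snippet_text = store$snippet_text[i],
      snippet_indices = store$snippet_indices[[i]],
      hits = store$hits[[i]],
      gender = store$gender[i],
      pub_year = store$pub_year[i],
      pub_types = store$pub_types[[i]],
      curated = store$curated[i])
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' Read an evidence store written by [write_store()]
#'
#' Validates the schema header and every instance on load (population
#' filter included); a truncated or corrupt file fails without a partial
#' load.
#'
#' @param path Store file path.
#' @return An `apk_store`.
#' @export
read_store <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty store file: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) stop("corrupt store header in ",
                                              path, call. = FALSE))
  if (!identical(header$format, "apk-store")) {
    stop("not an apk-store file: ", path, call. = FALSE)
  }
  if (!identical(as.integer(header$schema_version), STORE_SCHEMA_VERSION)) {
    stop("store schema version ", header$schema_version,
         " does not match supported version ", STORE_SCHEMA_VERSION,
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- lapply(seq_along(body), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(body[i]),
                    error = function(e) stop("corrupt store record at line ",
                                             i + 1L, " in ", path,
                                             call. = FALSE))
    out <- data.frame(instance_id = rec$instance_id, pmid = rec$pmid,
                      low_years = rec$low_years, high_years = rec$high_years,
                      inferred = rec$inferred, age_class = rec$age_class,
                      relationship = rec$relationship,
                      snippet_text = rec$snippet_text,
                      gender = rec$gender,
                      pub_year = if (is.null(rec$pub_year)) NA_integer_ else
                        as.integer(rec$pub_year),
                      curated = rec$curated, stringsAsFactors = FALSE)
    hits <- as.data.frame(rec$hits, stringsAsFactors = FALSE)
    if (nrow(hits)) {
      if (!"mapped_ontology_id" %in% names(hits)) {
        hits$mapped_ontology_id <- NA_character_
      }
      # an all-null JSON column deserialises as logical NA
      hits$mapped_ontology_id <- as.character(hits$mapped_ontology_id)
      hits$start <- as.integer(hits$start)
      hits$end <- as.integer(hits$end)
    }
    out$snippet_indices <- list(as.integer(rec$snippet_indices))
    out$hits <- list(hits)
    out$pub_types <- list(as.character(unlist(rec$pub_types)))
    out
  })
  bind_store(rows)
}
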