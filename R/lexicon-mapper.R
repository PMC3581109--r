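#' Normalise a term string for perfect-match search
#'
#' Lowercases, collapses internal whitespace to single spaces, and strips
#' surrounding (not internal) punctuation. No stemming, no fuzzy matching:
#' mapping is perfect-match only. The function is idempotent.
#'
#' @param s Character vector.
#' @return Normalised character vector.
#' @export
normalize_term <- function(s) {
  s <- tolower(s)
  s <- gsub("\\s+", " ", s)
  s <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", s)
  s
}

#' Load a disease ontology from an OBO 1.2 file
#'
#' Reads `[Term]` stanzas honouring the `id`, `name`, `synonym`, `is_a` and
#' `xref` tags (obsolete terms are skipped). Builds a normalised
#' string-to-term lookup over names and synonyms, a parent map for ancestor
#' queries, and an xref index from external concept IDs (with and without
#' their source prefix) to term IDs.
#'
#' @param path OBO file path, or use `text` for in-memory content.
#' @param text Optional character scalar/vector with OBO content.
#' @return Object of class `disease_ontology`.
#' @export
read_obo <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    readLines(path, warn = FALSE)
  }
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      if (cur$id %in% names(terms)) {
        stop("duplicate term id in ontology: ", cur$id, call. = FALSE)
      }
      terms[[cur$id]] <<- cur
    }
  }
  for (line in lines) {
    line <- trimws(sub("!.*$", "", line))
    if (line == "[Term]") {
      flush(); cur <- list(synonyms = character(), parents = character(),
                           xrefs = character()); in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(line)) next
    if (grepl("^id:", line)) {
      cur$id <- trimws(sub("^id:", "", line))
    } else if (grepl("^name:", line)) {
      cur$name <- trimws(sub("^name:", "", line))
    } else if (grepl("^synonym:", line)) {
      syn <- regmatches(line, regexpr('"[^"]*"', line))
      if (length(syn)) {
        cur$synonyms <- c(cur$synonyms, gsub('"', "", syn))
      }
    } else if (grepl("^is_a:", line)) {
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", line)))
    } else if (grepl("^xref:", line)) {
      cur$xrefs <- c(cur$xrefs, trimws(sub("^xref:", "", line)))
    } else if (grepl("^is_obsolete:\\s*true", line)) {
      cur$obsolete <- TRUE
    }
  }
  flush()
  if (!length(terms)) {
    warning("ontology contains no terms")
  }
  ids <- names(terms)
  parents <- lapply(terms, `[[`, "parents")
  missing <- setdiff(unlist(parents), ids)
  if (length(missing)) {
    stop("is_a parent(s) not defined in ontology: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_acyclic(parents)
  # normalised string -> term ids (a string may name several terms)
  str_rows <- do.call(rbind, lapply(terms, function(t) {
    strings <- unique(c(t$name, t$synonyms))
    strings <- strings[nzchar(strings)]
    if (!length(strings)) return(NULL)
    data.frame(string = strings, norm = normalize_term(strings),
               term_id = t$id, stringsAsFactors = FALSE)
  }))
  rownames(str_rows) <- NULL
  xref_rows <- do.call(rbind, lapply(terms, function(t) {
    if (!length(t$xrefs)) return(NULL)
    data.frame(xref = t$xrefs, bare = sub("^[A-Za-z_]+:", "", t$xrefs),
               term_id = t$id, stringsAsFactors = FALSE)
  }))
  structure(list(terms = terms, ids = ids, parents = parents,
                 strings = str_rows, xrefs = xref_rows),
            class = "disease_ontology")
}

# DFS cycle check over the is_a graph; errors naming one cycle.
check_acyclic <- function(parents) {
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    st <- state[[id]] %||% 0L
    if (st == 1L) {
      cyc <- c(stack[which(stack == id):length(stack)], id)
      stop("cycle in is_a hierarchy: ", paste(cyc, collapse = " -> "),
           call. = FALSE)
    }
    if (st == 2L) return(invisible())
    state[[id]] <- 1L
    for (p in parents[[id]]) visit(p, c(stack, id))
    state[[id]] <- 2L
  }
  for (id in names(parents)) visit(id, character())
  invisible(TRUE)
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat("<disease_ontology>", length(x$ids), "terms,",
      if (is.null(x$strings)) 0L else nrow(x$strings), "strings,",
      if (is.null(x$xrefs)) 0L else nrow(x$xrefs), "xrefs\n")
  invisible(x)
}

#' Ancestors of an ontology term
#'
#' Transitive closure over `is_a`, excluding the term itself.
#'
#' @param ontology A `disease_ontology`.
#' @param term_id Term identifier.
#' @return Character vector of ancestor term IDs.
#' @export
term_ancestors <- function(ontology, term_id) {
  if (!term_id %in% ontology$ids) {
    stop("unknown ontology term: ", term_id, call. = FALSE)
  }
  out <- character()
  frontier <- ontology$parents[[term_id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(ontology$parents[frontier])), out)
  }
  out
}

#' Descendants of an ontology term
#'
#' Transitive closure over inverted `is_a`, excluding the term itself.
#'
#' @inheritParams term_ancestors
#' @return Character vector of descendant term IDs.
#' @export
term_descendants <- function(ontology, term_id) {
  if (!term_id %in% ontology$ids) {
    stop("unknown ontology term: ", term_id, call. = FALSE)
  }
  has_anc <- vapply(ontology$ids, function(id) {
    term_id %in% term_ancestors(ontology, id)
  }, TRUE)
  ontology$ids[has_anc]
}

#' Look up ontology terms by string
#'
#' @param ontology A `disease_ontology`.
#' @param s String; normalised before lookup.
#' @return Character vector of matching term IDs (empty when none).
#' @export
lookup_term <- function(ontology, s) {
  if (is.null(ontology$strings)) return(character())
  unique(ontology$strings$term_id[ontology$strings$norm == normalize_term(s)])
}

#' Load a concept-subset lexicon from TSV
#'
#' The lexicon is a neutral stand-in for a licensed concept vocabulary:
#' three tab-separated columns `concept_id`, `semantic_type`, `string` (with
#' header). Rows whose semantic type is outside the allow-list are dropped
#' and counted; rows with an empty string are rejected with their line
#' number; duplicate (concept_id, string) pairs collapse to one.
#'
#' @param path TSV path, or use `text`.
#' @param text Optional character content.
#' @param allowed_types Semantic-type allow-list.
#' @return Object of class `concept_lexicon` (a data frame with columns
#'   `concept_id`, `semantic_type`, `string`, `norm`); attribute
#'   `n_dropped` counts rows outside the allow-list.
#' @export
read_concept_subset <- function(path = NULL, text = NULL,
                                allowed_types = c("disease", "drug", "finding")) {
  tab <- if (!is.null(text)) {
    utils::read.delim(text = paste(text, collapse = "\n"),
                      stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("concept_id", "semantic_type", "string")
  if (!all(need %in% names(tab))) {
    stop("concept subset must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, need]
  empty <- !nzchar(trimws(tab$string)) | is.na(tab$string)
  if (any(empty)) {
    warning("rejected ", sum(empty), " row(s) with empty string at line(s): ",
            paste(which(empty) + 1L, collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  outside <- !(tab$semantic_type %in% allowed_types)
  n_dropped <- sum(outside)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) outside the semantic-type allow-list dropped")
  }
  tab <- tab[!outside, , drop = FALSE]
  tab <- tab[!duplicated(tab[, c("concept_id", "string")]), , drop = FALSE]
  tab$norm <- normalize_term(tab$string)
  rownames(tab) <- NULL
  structure(tab, class = c("concept_lexicon", "data.frame"),
            n_dropped = n_dropped)
}

empty_hits <- function() {
  data.frame(source = character(), id = character(),
             mapped_ontology_id = character(), matched_span = character(),
             start = integer(), end = integer(), is_redundant = logical(),
             stringsAsFactors = FALSE)
}

#' Map a snippet to ontology and concept-lexicon terms
#'
#' Perfect-match search: every normalised lexicon string is sought in the
#' snippet text on token boundaries (whitespace runs flexible, case
#' ignored); all occurrences of all strings are reported, so nested matches
#' such as "carcinoma" inside "squamous cell carcinoma" co-occur and are
#' later flagged as redundant rather than suppressed. The ontology is
#' searched first, then the concept subset; a disease-type concept hit whose
#' concept ID is cross-referenced by an ontology term also carries that
#' term in `mapped_ontology_id`.
#'
#' @param snippet A `snippet` object or character scalar of snippet text.
#' @param ontology A `disease_ontology`, or `NULL` to skip.
#' @param concepts A `concept_lexicon`, or `NULL` to skip.
#' @return Data frame of hits: `source` (`ONTOLOGY`/`CONCEPT_SUBSET`), `id`,
#'   `mapped_ontology_id`, `matched_span`, `start`, `end` (1-based inclusive
#'   offsets into the snippet text), `is_redundant` (all `NA`; see
#'   [flag_redundant()]).
#' @export
map_snippet <- function(snippet, ontology = NULL, concepts = NULL) {
  text <- if (inherits(snippet, "snippet")) snippet$text else snippet
  stopifnot(is.character(text), length(text) == 1L)
  rows <- list()
  scan <- function(strings, ids, source, mapped) {
    for (i in seq_along(strings)) {
      if (!nzchar(strings[i])) next
      m <- match_all(token_bound_pattern(strings[i]), text)
      if (!nrow(m)) next
      rows[[length(rows) + 1L]] <<- data.frame(
        source = source, id = ids[i],
        mapped_ontology_id = mapped[i],
        matched_span = substring(text, m$start, m$end),
        start = m$start, end = m$end, is_redundant = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(ontology) && !is.null(ontology$strings)) {
    s <- ontology$strings
    scan(s$norm, s$term_id, "ONTOLOGY", rep(NA_character_, nrow(s)))
  }
  if (!is.null(concepts) && nrow(concepts)) {
    mapped <- rep(NA_character_, nrow(concepts))
    if (!is.null(ontology) && !is.null(ontology$xrefs)) {
      is_dis <- concepts$semantic_type == "disease"
      idx <- match(concepts$concept_id,
                   c(ontology$xrefs$xref, ontology$xrefs$bare))
      term <- c(ontology$xrefs$term_id, ontology$xrefs$term_id)[idx]
      mapped[is_dis & !is.na(term)] <- term[is_dis & !is.na(term)]
    }
    scan(concepts$norm, concepts$concept_id, "CONCEPT_SUBSET", mapped)
  }
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("source", "id", "start", "end")]), ]
  out <- out[order(out$start, out$end, out$source, out$id), ]
  rownames(out) <- NULL
  out
}

# Resolve the ontology term a hit stands for (its own id, or the mapped one).
hit_ontology_term <- function(hits) {
  ifelse(hits$source == "ONTOLOGY", hits$id, hits$mapped_ontology_id)
}

#' Flag harmless redundant hits
#'
#' A hit is dominated by another when its matched span is a proper substring
#' of the other's span at overlapping offsets (e.g. "carcinoma" inside
#' "squamous cell carcinoma"), or when its ontology term is a strict
#' ancestor of the other's ontology term. Hits are visited from longest span
#' to shortest and flagged redundant iff dominated by an already-kept
#' (non-redundant) hit, so removing a redundant hit never changes the
#' non-redundant set. Redundant hits add harmless redundancy, never
#' erroneous mapping, and are retained but flagged.
#'
#' @param hits Hits from [map_snippet()] for one snippet.
#' @param ontology A `disease_ontology` (used for ancestor tests); optional.
#' @return `hits` with `is_redundant` filled in, duplicates dropped.
#' @export
flag_redundant <- function(hits, ontology = NULL) {
  if (!nrow(hits)) {
    hits$is_redundant <- logical(0)
    return(hits)
  }
  hits <- hits[!duplicated(hits[, c("source", "id", "start", "end")]), ]
  n <- nrow(hits)
  terms <- hit_ontology_term(hits)
  anc <- lapply(terms, function(t) {
    if (is.na(t) || is.null(ontology)) character() else term_ancestors(ontology, t)
  })
  dominated_by <- function(i, j) {
    nested <- hits$start[j] <= hits$start[i] && hits$end[i] <= hits$end[j] &&
      (hits$end[i] - hits$start[i]) < (hits$end[j] - hits$start[j])
    ancestor <- !is.na(terms[i]) && !is.na(terms[j]) && terms[i] %in% anc[[j]]
    nested || ancestor
  }
  ord <- order(-(hits$end - hits$start), hits$start, hits$source, hits$id)
  red <- logical(n)
  kept <- integer()
  for (i in ord) {
    if (any(vapply(kept, function(j) dominated_by(i, j), TRUE))) {
      red[i] <- TRUE
    } else {
      kept <- c(kept, i)
    }
  }
  hits$is_redundant <- red
  rownames(hits) <- NULL
  hits
}

#' Gendered-term lists used by gender assignment
#' @return Named list with elements `male` and `female`.
#' @export
gender_terms <- function() {
  list(male = c("man", "men", "male", "males", "boy", "boys"),
       female = c("woman", "women", "female", "females", "girl", "girls"))
}

#' Detect the gender mentioned in a snippet
#'
#' Gender is assigned only when terms of exactly one gendered list occur in
#' the snippet (token-boundary matching, so "human" never matches "man");
#' both or neither yield `"NONE"`.
#'
#' @param snippet A `snippet` or character scalar.
#' @return `"MALE"`, `"FEMALE"` or `"NONE"`.
#' @export
detect_gender <- function(snippet) {
  text <- if (inherits(snippet, "snippet")) snippet$text else snippet
  terms <- gender_terms()
  found <- vapply(terms, function(lst) {
    any(vapply(lst, function(t) {
      nrow(match_all(token_bound_pattern(t), text)) > 0
    }, TRUE))
  }, TRUE)
  if (sum(found) != 1L) "NONE" else toupper(names(terms)[found])
}
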