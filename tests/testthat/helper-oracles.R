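# Independent brute-force oracles used by property tests. These deliberately
# avoid the implementation's code paths (no token_bound_pattern, no
# age_classes() containment shortcut).

# Parse + segment a one-off abstract.
make_record <- function(ab, pmid = "1", title = "T.", dp = "2000 Jan",
                        pt = "Journal Article") {
  txt <- c(paste0("PMID- ", pmid), paste0("TI  - ", title),
           paste0("AB  - ", ab), paste0("DP  - ", dp), paste0("PT  - ", pt))
  segment_sentences(read_medline(text = txt)[[1]])
}

# Most specific age class by exhaustive interval scan (independent table).
oracle_age_class <- function(low, high) {
  classes <- list(
    INFANT_NEWBORN = c(0, 1 / 12), INFANT = c(0, 2),
    PRESCHOOL_CHILD = c(2, 6), CHILD = c(2, 12), ADOLESCENT = c(12, 18),
    YOUNG_ADULT = c(18, 24), ADULT = c(18, 120), MIDDLE_AGED = c(45, 64),
    AGED = c(64, 120), AGED_80_OVER = c(80, 120), PERSON_ALL = c(0, 120))
  best <- NULL
  best_width <- Inf
  for (nm in names(classes)) {
    iv <- classes[[nm]]
    if (iv[1] <= low && iv[2] >= high) {
      w <- iv[2] - iv[1]
      if (w < best_width) {   # ties: first listed (earlier/younger) wins
        best <- nm
        best_width <- w
      }
    }
  }
  best
}

# Every perfect-match occurrence of every lexicon string in `text`:
# position-by-position scan with whitespace collapsing and explicit
# alphanumeric boundary checks. Returns data.frame(string, start, end).
oracle_scan <- function(text, strings) {
  tl <- tolower(text)
  n <- nchar(tl)
  chars <- strsplit(tl, "")[[1]]
  is_alnum <- grepl("[a-z0-9]", chars)
  squish <- function(s) gsub("\\s+", " ", s)
  out <- list()
  for (s in unique(strings)) {
    sc <- squish(tolower(s))
    L <- nchar(sc)
    if (L == 0) next
    for (i in seq_len(n)) {
      if (chars[i] != substr(sc, 1, 1)) next
      if (i > 1 && is_alnum[i - 1] && grepl("^[a-z0-9]", sc)) next
      # find the minimal end j whose squished window equals sc
      for (j in i:(min(n, i + L + 6L))) {
        win <- squish(substr(tl, i, j))
        if (nchar(win) > L) break
        if (win == sc) {
          if (j < n && is_alnum[j + 1] && grepl("[a-z0-9]$", sc)) break
          out[[length(out) + 1L]] <- data.frame(
            string = s, start = i, end = j, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(string = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$string), , drop = FALSE]
}

# Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# A tiny ontology echoing the carcinoma worked example.
carcinoma_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: DOID:4", "name: disease", "",
    "[Term]", "id: DOID:305", "name: carcinoma", "is_a: DOID:4",
    "xref: UMLS_CUI:C0007097", "",
    "[Term]", "id: DOID:0050866", "name: squamous cell carcinoma",
    'synonym: "SCC" EXACT []', "is_a: DOID:305",
    "xref: UMLS_CUI:C0007137", "",
    "[Term]", "id: DOID:8469", "name: influenza", 'synonym: "flu" EXACT []',
    "is_a: DOID:4", "")
}

carcinoma_concepts <- function() {
  c("concept_id\tsemantic_type\tstring",
    "C0007137\tdisease\tsquamous cell carcinoma",
    "C0007097\tdisease\tcarcinoma",
    "C0004057\tdrug\taspirin",
    "C0015967\tfinding\tfever")
}

# Build a small in-memory store with controlled fields for query tests.
make_instance <- function(id, pmid, low, high, inferred = FALSE,
                          rel = "AGE_OF_DIAGNOSIS", term = "DOID:0050866",
                          gender = "NONE", pub_year = 2000L,
                          pub_types = "Journal Article", curated = FALSE,
                          extra_terms = character(),
                          redundant_terms = character()) {
  mk_hit <- function(t, red) {
    data.frame(source = "ONTOLOGY", id = t, mapped_ontology_id = NA_character_,
               matched_span = t, start = 1L, end = nchar(t),
               is_redundant = red, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(list(mk_hit(term, FALSE)),
                           lapply(extra_terms, mk_hit, red = FALSE),
                           lapply(redundant_terms, mk_hit, red = TRUE)))
  row <- data.frame(instance_id = id, pmid = pmid, low_years = low,
                    high_years = high, inferred = inferred,
                    age_class = assign_age_class(low, high),
                    relationship = rel, snippet_text = "Synthetic snippet.",
                    gender = gender, pub_year = pub_year, curated = curated,
                    stringsAsFactors = FALSE)
  row$snippet_indices <- list(1L)
  row$hits <- list(hits)
  row$pub_types <- list(pub_types)
  row
}

make_store <- function(rows) new_apk_store(do.call(rbind, rows))
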