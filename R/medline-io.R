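#' Default structured-abstract section labels
#'
#' Uppercase section headings recognised when splitting a structured abstract
#' into labelled sections. A heading is a run of at most four uppercase words
#' immediately followed by a colon at the start of the abstract or of a
#' sentence.
#'
#' @return Character vector of recognised labels.
#' @export
section_labels <- function() {
  c("OBJECTIVE", "OBJECTIVES", "BACKGROUND", "METHOD", "METHODS",
    "RESULTS", "CONCLUSION", "CONCLUSIONS", "PATIENTS",
    "PATIENTS AND METHODS", "MATERIALS AND METHODS", "DESIGN",
    "SETTING", "PURPOSE", "AIM", "AIMS")
}

#' Abbreviations that never end a sentence
#'
#' Lowercased tokens (final period stripped) exempted from sentence splitting.
#' Single letters are exempt too (initials), handled separately.
#'
#' @return Character vector.
#' @export
abbreviations <- function() {
  c("e.g", "i.e", "vs", "dr", "mr", "mrs", "ms", "prof", "fig", "figs",
    "no", "nos", "approx", "al", "cf", "ca", "st", "etc", "resp")
}

new_abstract_record <- function(pmid, title, abstract, pub_year = NA_integer_,
                                pub_types = character()) {
  sections <- detect_sections(abstract)
  rec <- list(pmid = pmid, title = title, abstract = abstract,
              sections = sections, pub_year = pub_year,
              pub_types = pub_types, sentences = NULL)
  class(rec) <- "abstract_record"
  rec
}

#' @export
print.abstract_record <- function(x, ...) {
  cat("<abstract_record> PMID", x$pmid,
      if (!is.na(x$pub_year)) paste0("(", x$pub_year, ")"), "\n")
  cat("  title:   ", substr(x$title, 1, 70), "\n")
  cat("  abstract:", nchar(x$abstract), "chars,",
      nrow(x$sections), "section(s)",
      if (!is.null(x$sentences)) paste0(", ", nrow(x$sentences), " sentence(s)"),
      "\n")
  invisible(x)
}

# Locate structured-abstract section headings and return 1-based inclusive
# character spans of each section body within `abstract`.
detect_sections <- function(abstract, labels = section_labels()) {
  none <- data.frame(label = NA_character_,
                     start = 1L, end = nchar(abstract),
                     stringsAsFactors = FALSE)
  if (!nzchar(abstract)) {
    return(none[0, ])
  }
  alt <- paste(vapply(labels, regex_escape, ""), collapse = "|")
  pat <- paste0("(?:^|(?<=[.?!:])\\s)(", alt, "):\\s*")
  m <- gregexpr(pat, abstract, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(none)
  }
  cap_start <- attr(m, "capture.start")[, 1]
  cap_len <- attr(m, "capture.length")[, 1]
  hdr_start <- as.integer(m)
  hdr_end <- hdr_start + attr(m, "match.length") - 1L
  n <- length(m)
  body_start <- hdr_end + 1L
  body_end <- c(hdr_start[-1] - 1L, nchar(abstract))
  out <- data.frame(label = substring(abstract, cap_start, cap_start + cap_len - 1L),
                    start = body_start, end = body_end,
                    stringsAsFactors = FALSE)
  # Text before the first recognised heading is an unlabelled section.
  if (hdr_start[1] > 1L && grepl("[^[:space:]]", substr(abstract, 1, hdr_start[1] - 1L))) {
    out <- rbind(data.frame(label = NA_character_, start = 1L,
                            end = hdr_start[1] - 1L, stringsAsFactors = FALSE),
                 out)
  }
  out
}

#' Parse MEDLINE flat-file records
#'
#' Reads tag-dash field syntax (`PMID- `, `TI  - `, `AB  - `, `DP  - `,
#' `PT  - `) with indented continuation lines. Records lacking a PMID or an
#' AB field are dropped with a message giving the count; the pipeline mines
#' abstracts only.
#'
#' @param path Path to a MEDLINE file, or a character vector of lines when
#'   `text` is used instead.
#' @param text Optional character scalar/vector with MEDLINE content.
#' @return List of `abstract_record` objects, with attribute `n_dropped`
#'   (records without an abstract).
#' @export
read_medline <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    readLines(path, warn = FALSE)
  }
  records <- list()
  fields <- NULL   # list of c(tag, value)
  open_tag <- NA_integer_
  dropped <- 0L

  flush_record <- function() {
    if (is.null(fields) || length(fields) == 0L) return(invisible())
    tags <- vapply(fields, `[[`, "", 1L)
    vals <- vapply(fields, `[[`, "", 2L)
    pmid <- vals[tags == "PMID"][1]
    ab <- vals[tags == "AB"][1]
    if (is.na(pmid) || !nzchar(trimws(pmid)) || is.na(ab)) {
      dropped <<- dropped + 1L
      return(invisible())
    }
    pmid <- trimws(pmid)
    dp <- vals[tags == "DP"][1]
    year <- NA_integer_
    if (!is.na(dp)) {
      y <- regmatches(dp, regexpr("\\b(1[0-9]{3}|2[0-9]{3})\\b", dp))
      if (length(y)) year <- as.integer(y)
    }
    ti <- vals[tags == "TI"][1]
    rec <- new_abstract_record(pmid = pmid,
                               title = if (is.na(ti)) "" else ti,
                               abstract = ab,
                               pub_year = year,
                               pub_types = unname(vals[tags == "PT"]))
    records[[length(records) + 1L]] <<- rec
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) {
      flush_record()
      fields <- NULL
      open_tag <- NA_integer_
      next
    }
    if (grepl("^[A-Z][A-Z0-9]{0,3}\\s*-", line)) {
      tag <- sub("^([A-Z][A-Z0-9]{0,3})\\s*-.*$", "\\1", line)
      value <- sub("^[A-Z][A-Z0-9]{0,3}\\s*-\\s?", "", line)
      if (tag == "PMID" && !is.null(fields) &&
          any(vapply(fields, `[[`, "", 1L) == "PMID")) {
        flush_record()
        fields <- NULL
      }
      fields <- c(fields %||% list(), list(c(tag, value)))
      open_tag <- length(fields)
    } else if (grepl("^\\s+\\S", line)) {
      if (is.na(open_tag)) {
        stop("malformed MEDLINE field line outside any record at line ", i,
             call. = FALSE)
      }
      fields[[open_tag]][2] <- paste(fields[[open_tag]][2], trimws(line))
    } else {
      stop("malformed MEDLINE field line at line ", i, ": ",
           substr(line, 1, 40), call. = FALSE)
    }
  }
  flush_record()

  pmids <- vapply(records, `[[`, "", "pmid")
  dup <- unique(pmids[duplicated(pmids)])
  if (length(dup)) {
    stop("duplicate PMID(s) in corpus: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (dropped > 0L) {
    message(dropped, " record(s) without an abstract were dropped")
  }
  attr(records, "n_dropped") <- dropped
  records
}

#' Write abstract records back to MEDLINE flat-file format
#'
#' Emits one field per line (no line wrapping); `read_medline()` on the
#' output reconstructs identical records.
#'
#' @param records List of `abstract_record` objects.
#' @param path Output path; when `NULL` the lines are returned invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_medline <- function(records, path = NULL) {
  fmt <- function(tag, value) {
    sprintf("%-4s- %s", tag, value)
  }
  blocks <- lapply(records, function(r) {
    out <- c(fmt("PMID", r$pmid))
    if (nzchar(r$title)) out <- c(out, fmt("TI", r$title))
    out <- c(out, fmt("AB", r$abstract))
    if (!is.na(r$pub_year)) out <- c(out, fmt("DP", r$pub_year))
    for (pt in r$pub_types) out <- c(out, fmt("PT", pt))
    c(out, "")
  })
  lines <- unlist(blocks)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Segment an abstract into sentences
#'
#' Rule-based splitter: a sentence ends at `.`, `?` or `!` followed by
#' whitespace and an uppercase letter, digit or opening bracket/quote, unless
#' the period terminates a known abbreviation or a single-letter initial.
#' Periods inside decimal numbers never split (they are not followed by
#' whitespace). Sentences never cross structured-abstract section
#' boundaries; each carries the label of its containing section.
#'
#' @param record An `abstract_record`.
#' @param abbrev Abbreviation exception list, see [abbreviations()].
#' @return The record with `$sentences`: a data frame with columns `index`
#'   (1-based), `text`, `section_label`, `start`, `end` (1-based inclusive
#'   character offsets into `$abstract`).
#' @export
segment_sentences <- function(record, abbrev = abbreviations()) {
  stopifnot(inherits(record, "abstract_record"))
  if (!nzchar(record$abstract)) {
    stop("abstract text is empty for PMID ", record$pmid, call. = FALSE)
  }
  abstract <- record$abstract
  sent <- list()
  for (s in seq_len(nrow(record$sections))) {
    sec <- record$sections[s, ]
    body <- substr(abstract, sec$start, sec$end)
    spans <- split_sentences_in(body, abbrev)
    if (nrow(spans)) {
      spans$start <- spans$start + sec$start - 1L
      spans$end <- spans$end + sec$start - 1L
      spans$section_label <- sec$label
      sent[[length(sent) + 1L]] <- spans
    }
  }
  sentences <- do.call(rbind, sent)
  sentences <- sentences[order(sentences$start), , drop = FALSE]
  sentences$index <- seq_len(nrow(sentences))
  sentences$text <- substring(abstract, sentences$start, sentences$end)
  rownames(sentences) <- NULL
  record$sentences <- sentences[, c("index", "text", "section_label",
                                    "start", "end")]
  record
}

# Split one section body into sentence spans (1-based inclusive, local).
split_sentences_in <- function(body, abbrev) {
  n <- nchar(body)
  if (!grepl("[^[:space:]]", body)) {
    return(data.frame(start = integer(), end = integer()))
  }
  cand <- match_all("[.?!](?=\\s+[\"'(\\[]?[A-Z0-9])", body,
                    ignore_case = FALSE)
  keep <- logical(nrow(cand))
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      pos <- cand$start[i]
      if (substr(body, pos, pos) != ".") {
        keep[i] <- TRUE
        next
      }
      before <- substr(body, max(1L, pos - 12L), pos - 1L)
      tok <- regmatches(before, regexpr("[A-Za-z][A-Za-z.]*$", before))
      tok <- if (length(tok)) tolower(tok) else ""
      single_initial <- grepl("^[A-Za-z]$", tok)
      keep[i] <- !(tok %in% abbrev || single_initial)
    }
  }
  ends <- cand$start[keep]
  bounds <- c(0L, ends, n)
  starts <- integer()
  stops <- integer()
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i] + 1L
    b <- bounds[i + 1L]
    # trim leading/trailing whitespace from the span
    seg <- substr(body, a, b)
    lead <- regexpr("[^[:space:]]", seg)
    if (lead == -1L) next
    trail <- regexpr("[[:space:]]*$", seg)
    starts <- c(starts, a + as.integer(lead) - 1L)
    stops <- c(stops, a + as.integer(trail) - 2L)
  }
  data.frame(start = starts, end = stops)
}
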