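NUM <- "(\\d{1,3}(?:\\.\\d+)?)"

#' Age-mention pattern table
#'
#' Regular-expression patterns for numeric age and age-range mentions. Every
#' pattern contains an age-anchoring cue word (year/yr/month/week/day/age/
#' aged/old) so bare numbers and durations never match; spelled-out numbers
#' ("two to five years old") are deliberately not parsed. `role` is one of
#' `range`, `open_low` (upper bound stated, lower inferred as 0), `open_high`
#' (lower bound stated, upper inferred as 120), `point`, or `mean`
#' (mean/median age of a study group). On overlapping matches the higher
#' `priority` wins, then the longer match.
#'
#' @param path Optional TSV (columns `name`, `regex`, `role`, `unit`,
#'   `priority`) replacing the built-in table.
#' @return Data frame with columns `name`, `regex`, `role`, `unit`,
#'   `priority`.
#' @export
age_patterns <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "regex", "role", "unit", "priority")
    if (!all(need %in% names(tab))) {
      stop("pattern table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    return(tab[, need])
  }
  yr <- "(?:years?|yrs?)"
  p <- function(name, regex, role, unit = "years", priority) {
    data.frame(name = name, regex = regex, role = role, unit = unit,
               priority = priority, stringsAsFactors = FALSE)
  }
  rbind(
    p("years_or_less",
      paste0(NUM, "\\s*", yr, "(?:\\s+old)?\\s+or\\s+(?:less|younger|under)"),
      "open_low", priority = 50),
    p("years_or_more",
      paste0(NUM, "\\s*", yr, "(?:\\s+old)?\\s+or\\s+(?:more|older|over|above)"),
      "open_high", priority = 50),
    p("under_n_years",
      paste0("(?:under|less\\s+than|younger\\s+than|below|up\\s+to|<)\\s*",
             "(?:the\\s+age\\s+of\\s+)?", NUM, "\\s*", yr,
             "(?:\\s+(?:of\\s+age|old))?"),
      "open_low", priority = 45),
    p("over_n_years",
      paste0("(?:over|more\\s+than|older\\s+than|above|at\\s+least|>)\\s*",
             "(?:the\\s+age\\s+of\\s+)?", NUM, "\\s*", yr,
             "(?:\\s+(?:of\\s+age|old))?"),
      "open_high", priority = 45),
    p("between_n_and_m",
      paste0("between\\s+", NUM, "\\s+and\\s+", NUM, "\\s*", yr,
             "(?:\\s+(?:of\\s+age|old))?"),
      "range", priority = 40),
    p("n_to_m_years",
      paste0(NUM, "\\s+to\\s+", NUM, "\\s*", yr, "(?:\\s+(?:of\\s+age|old))?"),
      "range", priority = 40),
    p("aged_n_to_m",
      paste0("aged?\\s+", NUM, "\\s*(?:-|to)\\s*", NUM,
             "(?:\\s*", yr, ")?"),
      "range", priority = 40),
    p("n_to_m_hyphen_years",
      paste0(NUM, "\\s*-\\s*", NUM, "\\s*", yr,
             "(?:\\s+(?:of\\s+age|old))?"),
      "range", priority = 39),
    p("n_years_old",
      paste0(NUM, "[-\\s](?:year|yr)s?[-\\s]old"),
      "point", priority = 30),
    p("n_months_old",
      paste0(NUM, "[-\\s]months?[-\\s](?:old|of\\s+age)"),
      "point", unit = "months", priority = 30),
    p("n_weeks_old",
      paste0(NUM, "[-\\s]weeks?[-\\s](?:old|of\\s+age)"),
      "point", unit = "weeks", priority = 30),
    p("n_days_old",
      paste0(NUM, "[-\\s]days?[-\\s](?:old|of\\s+age)"),
      "point", unit = "days", priority = 30),
    p("n_years_of_age",
      paste0(NUM, "\\s*", yr, "\\s+of\\s+age"),
      "point", priority = 30),
    p("mean_age_n",
      paste0("(?:mean|median|average)\\s+age(?:\\s+of)?(?:\\s+was|\\s+is)?\\s+",
             NUM),
      "mean", priority = 25),
    p("aged_n",
      paste0("aged?\\s+", NUM, "(?:\\s*", yr, ")?(?:\\s+old)?"),
      "point", priority = 20),
    p("at_age_n",
      paste0("at\\s+(?:the\\s+)?age\\s+(?:of\\s+)?", NUM),
      "point", priority = 20)
  )
}

MAX_AGE <- 120

unit_to_years <- function(x, unit) {
  switch(unit,
         years = x,
         months = x / 12,
         weeks = x / 52,
         days = x / 365,
         stop("unknown age unit: ", unit, call. = FALSE))
}

#' Extract numeric age mentions from a segmented abstract
#'
#' Applies the pattern table to the abstract body. Overlapping matches are
#' resolved by pattern priority, then match length, then position, so
#' "aged 30 years or less" yields the inferred range [0, 30] rather than the
#' point mention "aged 30 years". Bounds are converted to years (1 month =
#' 1/12 year, 1 week = 1/52, 1 day = 1/365) and clamped to [0, 120].
#'
#' @param record A sentence-segmented `abstract_record`.
#' @param patterns Pattern table, see [age_patterns()].
#' @return Data frame with one row per mention: `raw_span`, `start`, `end`
#'   (1-based inclusive offsets into the abstract), `sentence_index`,
#'   `low_years`, `high_years`, `inferred`, `role`, `pattern`.
#' @export
extract_age_mentions <- function(record, patterns = age_patterns()) {
  stopifnot(inherits(record, "abstract_record"))
  if (is.null(record$sentences)) {
    stop("record must be sentence-segmented first (see segment_sentences)",
         call. = FALSE)
  }
  text <- record$abstract
  rows <- list()
  for (i in seq_len(nrow(patterns))) {
    pat <- patterns[i, ]
    m <- gregexpr(pat$regex, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    for (k in seq_along(m)) {
      nums <- as.numeric(substring(text, cs[k, ], cs[k, ] + cl[k, ] - 1L))
      nums <- nums[!is.na(nums)]
      if (!length(nums)) next
      vals <- unit_to_years(nums, pat$unit)
      bounds <- switch(pat$role,
                       range = c(min(vals), max(vals), FALSE),
                       open_low = c(0, vals[1], TRUE),
                       open_high = c(vals[1], MAX_AGE, TRUE),
                       point = c(vals[1], vals[1], FALSE),
                       mean = c(vals[1], vals[1], FALSE))
      low <- max(0, min(bounds[1], MAX_AGE))
      high <- max(0, min(bounds[2], MAX_AGE))
      if (low > high) next
      rows[[length(rows) + 1L]] <- data.frame(
        raw_span = substring(text, m[k], m[k] + attr(m, "match.length")[k] - 1L),
        start = as.integer(m[k]),
        end = as.integer(m[k]) + attr(m, "match.length")[k] - 1L,
        low_years = low, high_years = high,
        inferred = as.logical(bounds[3]),
        role = pat$role, pattern = pat$name,
        priority = pat$priority,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(raw_span = character(), start = integer(),
                      end = integer(), sentence_index = integer(),
                      low_years = numeric(), high_years = numeric(),
                      inferred = logical(), role = character(),
                      pattern = character(), stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  all <- do.call(rbind, rows)
  # overlap resolution: priority desc, length desc, position asc
  all <- all[order(-all$priority, -(all$end - all$start), all$start), ]
  kept <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    overlaps <- kept & (all$start <= all$end[i]) & (all$end >= all$start[i])
    if (!any(overlaps)) kept[i] <- TRUE
  }
  out <- all[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  sent <- record$sentences
  out$sentence_index <- vapply(out$start, function(s) {
    idx <- sent$index[sent$start <= s & sent$end >= s]
    if (length(idx)) idx[1] else sent$index[which.max(sent$start[sent$start <= s])]
  }, integer(1))
  rownames(out) <- NULL
  out[, c("raw_span", "start", "end", "sentence_index", "low_years",
          "high_years", "inferred", "role", "pattern")]
}

#' Merge mentions into candidate instance ranges
#'
#' Mentions with identical normalised ranges are merged (one candidate
#' instance per distinct range). By default an explicit range mention
#' suppresses mean/median-age mentions occurring in the same abstract, so a
#' stated full range is preferred over a group mean;
#' `legacy_mean_priority = TRUE` reverts to preferring the mean.
#'
#' @param mentions Output of [extract_age_mentions()].
#' @param legacy_mean_priority Prefer mean-age mentions over explicit ranges.
#' @return Subset of `mentions`, one row per distinct normalised range
#'   (earliest mention kept as representative).
#' @export
select_age_candidates <- function(mentions, legacy_mean_priority = FALSE) {
  if (!nrow(mentions)) return(mentions)
  has_mean <- any(mentions$role == "mean")
  has_range <- any(mentions$role %in% c("range", "open_low", "open_high"))
  if (has_mean && has_range) {
    if (legacy_mean_priority) {
      mentions <- mentions[!(mentions$role %in% c("range", "open_low", "open_high")), ]
    } else {
      mentions <- mentions[mentions$role != "mean", ]
    }
  }
  mentions <- mentions[order(mentions$start), ]
  out <- mentions[!duplicated(paste(mentions$low_years, mentions$high_years,
                                    mentions$inferred)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Age-ontology classes
#'
#' The eleven age classes with their year intervals: infant newborn
#' [0, 1/12], infant [0, 2], preschool child [2, 6], child [2, 12],
#' adolescent [12, 18], young adult [18, 24], adult [18, 120], middle aged
#' [45, 64], aged [64, 120], 80 and over [80, 120], and the root class
#' covering [0, 120].
#'
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
age_classes <- function() {
  data.frame(
    name = c("INFANT_NEWBORN", "INFANT", "PRESCHOOL_CHILD", "CHILD",
             "ADOLESCENT", "YOUNG_ADULT", "ADULT", "MIDDLE_AGED", "AGED",
             "AGED_80_OVER", "PERSON_ALL"),
    low = c(0, 0, 2, 2, 12, 18, 18, 45, 64, 80, 0),
    high = c(1 / 12, 2, 6, 12, 18, 24, 120, 64, 120, 120, 120),
    stringsAsFactors = FALSE)
}

#' Assign the most specific age class containing a range
#'
#' Returns, for each range, the class with the smallest interval width among
#' all classes whose interval contains `[low, high]`; the root class
#' (`PERSON_ALL`) when no other class contains it. Width ties (possible only
#' for point ages on shared class boundaries, e.g. age 18) are broken by
#' table order, i.e. the earlier, younger-starting class wins.
#'
#' @param low,high Numeric vectors of range bounds in years.
#' @return Character vector of class names.
#' @export
assign_age_class <- function(low, high) {
  stopifnot(length(low) == length(high), all(low <= high),
            all(low >= 0), all(high <= MAX_AGE))
  cls <- age_classes()
  width <- cls$high - cls$low
  vapply(seq_along(low), function(i) {
    contains <- cls$low <= low[i] & cls$high >= high[i]
    cand <- which(contains)
    cls$name[cand[which.min(width[cand])]]
  }, character(1))
}
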