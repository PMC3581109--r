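#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so fixtures never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Escape a literal string for use inside a PCRE pattern.
regex_escape <- function(x) {
  gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)
}

# Perfect-match pattern for a lexicon string: literal characters, internal
# whitespace runs made flexible, guarded by non-alphanumeric boundaries.
token_bound_pattern <- function(s) {
  core <- gsub("\\s+", "\\\\s+", regex_escape(s))
  paste0("(?<![A-Za-z0-9])", core, "(?![A-Za-z0-9])")
}

# All match start/end (inclusive) positions of `pattern` in `text`.
match_all <- function(pattern, text, ignore_case = TRUE) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
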