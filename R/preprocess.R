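# Lightweight caption-oriented preprocessing: token spans, a rule-based
# part-of-speech labeller (only the noun/verb distinction matters here — the
# pipeline uses it to drop organism-name candidates used as verbs), a
# sentence splitter that protects genus abbreviations ("S. typhimurium"),
# and Schwartz–Hearst long-form/short-form abbreviation pairing.

TOKEN_RE <- "[\\p{L}\\p{N}](?:[\\p{L}\\p{N}'’-]*[\\p{L}\\p{N}])?|[^\\p{L}\\p{N}\\s]"

#' Token spans of a text
#'
#' Tokens are maximal alphanumeric runs (hyphens and apostrophes allowed
#' inside, so "wild-type" is one token) plus punctuation singletons.
#'
#' @param text Input text.
#' @return Data frame with 0-based half-open code-point columns
#'   `start`, `end` and the `surface` column; spans are ordered and
#'   non-overlapping.
#' @export
token_spans <- function(text) {
  text <- enc2utf8(text)
  if (!nzchar(text))
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE))
  m <- gregexpr(TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE))
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = start1 - 1L, end = start1 - 1L + len,
             surface = vapply(seq_along(start1), function(i)
               substr(text, start1[i], start1[i] + len[i] - 1L), character(1)),
             stringsAsFactors = FALSE)
}

AUX_VERBS <- c("is", "are", "was", "were", "be", "been", "being", "am",
               "has", "have", "had", "do", "does", "did",
               "can", "could", "may", "might", "must", "shall", "should",
               "will", "would")

CLOSED_VERBS <- c("show", "shows", "showed", "shown", "indicate", "indicates",
                  "indicated", "represent", "represents", "represented",
                  "denote", "denotes", "denoted", "see", "note", "compare",
                  "reveal", "reveals", "revealed", "demonstrate",
                  "demonstrates", "demonstrated")

#' Tokenize with rule-based part-of-speech labels
#'
#' A deliberately small tagger: auxiliaries and a closed list of
#' reporting verbs are `verb`; an `-ed`/`-ing` form directly after an
#' auxiliary is `verb` ("were expressed"); punctuation and numbers are
#' `other`; everything else (including capitalized biomedical tokens)
#' defaults to `noun`.  That is exactly the coverage the identification
#' pipeline needs for its verb filter; the tagger is replaceable.
#'
#' @param text Input text.
#' @return Data frame of `start`, `end`, `surface`, `pos_label`
#'   (`noun`/`verb`/`other`).
#' @export
tokenize_with_pos <- function(text) {
  tok <- token_spans(text)
  n <- nrow(tok)
  pos <- character(n)
  prev_aux <- FALSE
  for (i in seq_len(n)) {
    w <- tok$surface[[i]]
    lw <- tolower(w)
    if (grepl("^[^\\p{L}\\p{N}]", w, perl = TRUE) || grepl("^\\p{N}+$", w, perl = TRUE)) {
      pos[[i]] <- "other"
    } else if (lw %in% AUX_VERBS || lw %in% CLOSED_VERBS) {
      pos[[i]] <- "verb"
    } else if (prev_aux && grepl("(ed|ing)$", lw) && nchar(lw) > 4) {
      pos[[i]] <- "verb"
    } else {
      pos[[i]] <- "noun"
    }
    prev_aux <- lw %in% AUX_VERBS
  }
  tok$pos_label <- pos
  tok
}

protected_abbrevs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "protected_abbrev.txt", package = "captaxa")
      cache <<- if (nzchar(path)) tolower(trimws(readLines(path, encoding = "UTF-8")))
                else character(0)
      cache <<- cache[nzchar(cache) & !startsWith(cache, "#")]
    }
    cache
  }
})

#' Split text into sentence spans
#'
#' Boundaries are sentence-final `.`, `!` or `?` followed by whitespace.  No
#' boundary is placed after a single capital letter (genus abbreviations such
#' as "S. typhimurium"), after a protected abbreviation (packaged list:
#' "subsp", "et al", "fig", ...), or when the following character is
#' lowercase.
#'
#' @param text Input text.
#' @return Data frame of 0-based half-open `start`/`end` spans partitioning
#'   the non-whitespace text, in order.
#' @export
split_sentences <- function(text) {
  text <- enc2utf8(text)
  empty <- data.frame(start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(trimws(text))) return(empty)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  prot <- protected_abbrevs()
  boundaries <- integer(0)  # positions AFTER which a new sentence starts (0-based, exclusive end)
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[[j + 1L]] %in% c(".", "!", "?", "\"", "'", ")")) j <- j + 1L
      if (j < n && grepl("\\s", chars[[j + 1L]])) {
        k <- j + 1L
        while (k <= n && grepl("\\s", chars[[k]])) k <- k + 1L
        nxt <- if (k <= n) chars[[k]] else ""
        ok <- nzchar(nxt) && grepl("[\\p{Lu}\\p{N}\"'(\\[]", nxt, perl = TRUE)
        if (ok && ch == ".") {
          # word immediately before the period
          e <- i - 1L
          while (e >= 1L && grepl("[\\p{L}\\p{N}.-]", chars[[e]], perl = TRUE)) e <- e - 1L
          word <- paste(chars[seq.int(e + 1L, i - 1L)[seq_len(max(0L, i - 1L - e))]],
                        collapse = "")
          if (grepl("^\\p{Lu}$", word, perl = TRUE)) ok <- FALSE
          if (tolower(sub("\\.$", "", word)) %in% prot) ok <- FALSE
        }
        if (ok) boundaries <- c(boundaries, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cut_starts <- c(0L, boundaries)
  cut_ends <- c(boundaries, n)
  spans <- lapply(seq_along(cut_starts), function(ix) {
    s <- cut_starts[[ix]]; e <- cut_ends[[ix]]
    while (s < e && grepl("\\s", chars[[s + 1L]])) s <- s + 1L
    while (e > s && grepl("\\s", chars[[e]])) e <- e - 1L
    if (e > s) c(s, e) else NULL
  })
  spans <- Filter(Negate(is.null), spans)
  if (length(spans) == 0) return(empty)
  data.frame(start = vapply(spans, `[[`, integer(1), 1),
             end = vapply(spans, `[[`, integer(1), 2),
             stringsAsFactors = FALSE)
}

# --------------------------------------------------------------------------
# Schwartz–Hearst abbreviation pairing

is_valid_short_form <- function(sf) {
  nc <- nchar(sf)
  if (nc < 2 || nc > 10) return(FALSE)
  if (length(strsplit(trimws(sf), "\\s+")[[1]]) > 2) return(FALSE)
  if (!grepl("\\p{L}", sf, perl = TRUE)) return(FALSE)
  grepl("^[\\p{L}\\p{N}]", sf, perl = TRUE)
}

# canonical right-to-left character alignment; returns the long form substring
# (word-aligned at the first short-form character) or NULL
find_best_long_form <- function(long, short) {
  l <- strsplit(tolower(long), "")[[1]]
  s <- strsplit(tolower(short), "")[[1]]
  li <- length(l); si <- length(s)
  while (si > 0) {
    c <- s[[si]]
    if (!grepl("[\\p{L}\\p{N}]", c, perl = TRUE)) { si <- si - 1L; next }
    while (li > 0 &&
           (l[[li]] != c ||
            (si == 1L && li > 1L && grepl("[\\p{L}\\p{N}]", l[[li - 1L]], perl = TRUE)))) {
      li <- li - 1L
    }
    if (li == 0) return(NULL)
    si <- si - 1L; li <- li - 1L
  }
  # long form starts at the word containing position li + 1
  start <- li + 1L
  substr(long, start, nchar(long))
}

sh_constraints_ok <- function(long, short) {
  lw <- length(strsplit(trimws(long), "\\s+")[[1]])
  nchar(short) < nchar(long) &&
    lw <= min(nchar(short) + 5L, 2L * nchar(short)) &&
    !grepl("[()]", long)
}

abbrev_pair <- function(long, long_start, short, short_start) {
  structure(list(
    long_form = long, long_start = as.integer(long_start),
    long_end = as.integer(long_start + ncp(long)),
    short_form = short, short_start = as.integer(short_start),
    short_end = as.integer(short_start + ncp(short))
  ), class = "abbrev_pair")
}

# genus-style pairs: "<Genus> ... <Epithet> (G. epithet)"; these exceed the
# canonical 10-character short-form cap but are the dominant organism
# abbreviation pattern, so they get a dedicated rule
genus_pair <- function(before, before_start, inner, inner_start) {
  m <- regmatches(inner, regexec("^(\\p{Lu})\\.\\s+([\\p{L}\\p{N}-]+)$", inner, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  cap <- m[[2]]; epithet <- tolower(m[[3]])
  words <- token_spans(before)
  words <- words[grepl("^\\p{L}", words$surface, perl = TRUE), , drop = FALSE]
  if (nrow(words) == 0) return(NULL)
  gi <- which(substr(words$surface, 1, 1) == cap)
  if (length(gi) == 0) return(NULL)
  ei <- which(tolower(words$surface) == epithet)
  for (g in rev(gi)) {
    e_ok <- ei[ei >= g]
    if (length(e_ok) == 0) next
    e <- max(e_ok)
    long <- slice_cp(before, words$start[[g]], words$end[[e]])
    return(abbrev_pair(long, before_start + words$start[[g]],
                       inner, inner_start))
  }
  NULL
}

#' Detect full-name/abbreviation pairs in a sentence
#'
#' Schwartz–Hearst character alignment over parenthesized patterns, in both
#' the `long form (SF)` and `SF (long form)` orders, with the canonical
#' constraints (short form 2–10 characters, at most two words, at least one
#' letter; long form at most `min(|SF|+5, 2|SF|)` words).  A dedicated rule
#' additionally pairs genus-abbreviated organism names such as
#' `Salmonella ... Typhimurium (S. typhimurium)`, which the canonical length
#' cap would reject.
#'
#' @param sentence A single sentence.
#' @return List of `abbrev_pair` records with long/short surfaces and their
#'   0-based spans within `sentence`.
#' @export
detect_abbreviations <- function(sentence) {
  sentence <- enc2utf8(sentence)
  out <- list()
  m <- gregexpr("\\(([^()]+)\\)", sentence, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts1 <- as.integer(m)
  lens <- attr(m, "match.length")
  for (k in seq_along(starts1)) {
    open1 <- starts1[[k]]
    inner <- substr(sentence, open1 + 1L, open1 + lens[[k]] - 2L)
    inner_trim <- trimws(inner)
    inner_start0 <- open1 - 1L + 1L + (ncp(inner) - ncp(sub("^\\s+", "", inner)))
    before <- substr(sentence, 1, open1 - 1L)
    before_start0 <- 0L
    gp <- genus_pair(before, before_start0, inner_trim, inner_start0)
    if (!is.null(gp)) { out[[length(out) + 1L]] <- gp; next }
    if (is_valid_short_form(inner_trim)) {
      # long (SHORT): candidate long form = trailing words before '('
      words <- token_spans(before)
      if (nrow(words) == 0) next
      max_words <- min(nchar(inner_trim) + 5L, 2L * nchar(inner_trim))
      take <- min(max_words, nrow(words))
      cand_start <- words$start[[nrow(words) - take + 1L]]
      cand <- trimws(slice_cp(before, cand_start, words$end[[nrow(words)]]))
      lf <- find_best_long_form(cand, inner_trim)
      if (!is.null(lf) && sh_constraints_ok(lf, inner_trim)) {
        # lf is a suffix of cand (alignment never extends past it)
        lf_start <- cand_start + ncp(cand) - ncp(lf)
        out[[length(out) + 1L]] <-
          abbrev_pair(lf, lf_start, inner_trim, inner_start0)
      }
    } else {
      # SHORT (long form): token immediately before '(' is the short form
      words <- token_spans(before)
      words <- words[grepl("^[\\p{L}\\p{N}]", words$surface, perl = TRUE), , drop = FALSE]
      if (nrow(words) == 0) next
      sf <- words$surface[[nrow(words)]]
      if (!is_valid_short_form(sf)) next
      lf <- find_best_long_form(inner_trim, sf)
      if (!is.null(lf) && sh_constraints_ok(lf, sf)) {
        lf_start <- inner_start0 + ncp(inner_trim) - ncp(lf)
        out[[length(out) + 1L]] <-
          abbrev_pair(lf, lf_start, sf, words$start[[nrow(words)]])
      }
    }
  }
  out
}
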