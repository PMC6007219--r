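# Taxonomy lexicon: NCBI taxonomy ID <-> surface names, with generated base
# forms.  Loaded from a TSV of `taxon_id<TAB>name<TAB>name_class` rows.

NAME_CLASSES <- c("scientific", "common", "strain", "abbreviation", "general")

irregular_plurals <- c(
  larvae = "larva", mice = "mouse", fungi = "fungus", algae = "alga",
  pupae = "pupa", nuclei = "nucleus", genera = "genus", species = "species"
)

base_form_word <- function(w) {
  lw <- tolower(w)
  if (!is.na(irregular_plurals[lw])) return(unname(irregular_plurals[lw]))
  n <- nchar(lw)
  if (n > 4 && endsWith(lw, "ies")) return(sub("ies$", "y", lw))
  if (n > 3 && grepl("(s|x|z|ch|sh)es$", lw)) return(sub("es$", "", lw))
  if (n > 3 && endsWith(lw, "s") && !grepl("(ss|us|is)$", lw))
    return(sub("s$", "", lw))
  lw
}

#' Base (lemmatized) form of an organism term
#'
#' Lowercases the term and strips the plural from its final word using a small
#' rule table with irregulars ("larvae" -> "larva", "mice" -> "mouse").
#' Multi-word names are lowercased whole with only the last word de-pluralized.
#'
#' @param term Character vector of terms.
#' @return Character vector of base forms.
#' @export
base_form <- function(term) {
  vapply(term, function(x) {
    x <- tolower(enc2utf8(x))
    words <- strsplit(x, " ", fixed = TRUE)[[1]]
    if (length(words) == 0) return(x)
    words[length(words)] <- base_form_word(words[length(words)])
    paste(words, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

new_lexicon <- function(entries = list()) {
  lex <- structure(list(entries = entries, name_index = list(),
                        lc_index = list()), class = "taxa_lexicon")
  rebuild_name_index(lex)
}

rebuild_name_index <- function(lex) {
  idx <- list()
  for (e in lex$entries) {
    keys <- unique(c(e$names$surface, e$base_forms))
    for (k in keys) idx[[k]] <- sort(unique(c(idx[[k]], e$taxon_id)))
  }
  lex$name_index <- idx
  lc <- list()
  for (k in names(idx)) {
    lk <- tolower(k)
    lc[[lk]] <- sort(unique(c(lc[[lk]], idx[[k]])))
  }
  lex$lc_index <- lc
  lex
}

#' Load a taxonomy lexicon from TSV text
#'
#' Rows are `taxon_id<TAB>name<TAB>name_class` (UTF-8, no header; `#` starts a
#' comment line).  Duplicate (id, name) rows collapse; a name occurring under
#' several IDs is indexed under all of them and is thereby ambiguous.
#'
#' @param tsv_text TSV content as a single string, a character vector of
#'   lines, or a file path to an existing file.
#' @return A `taxa_lexicon`: `entries` keyed by taxonomy ID, plus a
#'   `name_index` mapping every surface form (and, after
#'   [expand_base_forms()], every base form) to its ID set.
#' @export
load_lexicon <- function(tsv_text) {
  lines <- if (length(tsv_text) == 1 && !grepl("[\t\n]", tsv_text) &&
               file.exists(tsv_text)) {
    readLines(tsv_text, encoding = "UTF-8")
  } else {
    unlist(strsplit(enc2utf8(tsv_text), "\n", fixed = TRUE))
  }
  entries <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop("lexicon row ", i, ": expected 3 tab-separated columns, got ",
           length(parts))
    id <- suppressWarnings(as.integer(parts[[1]]))
    if (is.na(id))
      stop("lexicon row ", i, ": non-integer taxonomy ID '", parts[[1]], "'")
    surface <- enc2utf8(parts[[2]])
    cls <- parts[[3]]
    key <- as.character(id)
    if (is.null(entries[[key]]))
      entries[[key]] <- list(taxon_id = id,
                             names = data.frame(surface = character(),
                                                name_class = character(),
                                                stringsAsFactors = FALSE),
                             base_forms = character())
    nm <- entries[[key]]$names
    if (!any(nm$surface == surface & nm$name_class == cls)) {
      entries[[key]]$names <- rbind(
        nm, data.frame(surface = surface, name_class = cls,
                       stringsAsFactors = FALSE))
    }
  }
  new_lexicon(entries)
}

#' Add generated base forms to every lexicon entry
#'
#' For each registered name its base form ([base_form()]) is added to the
#' entry's `base_forms` and indexed; the original names are untouched.
#'
#' @param lex A `taxa_lexicon`.
#' @return The expanded lexicon.
#' @export
expand_base_forms <- function(lex) {
  stopifnot(inherits(lex, "taxa_lexicon"))
  for (key in names(lex$entries)) {
    bf <- base_form(lex$entries[[key]]$names$surface)
    lex$entries[[key]]$base_forms <-
      sort(unique(c(lex$entries[[key]]$base_forms, bf)))
  }
  rebuild_name_index(lex)
}

#' Look up a surface form in the lexicon
#'
#' Exact lookup first; names of five or more code points also match
#' case-insensitively; finally the base form of the query is tried.
#'
#' @param lex A `taxa_lexicon`.
#' @param surface The term to look up.
#' @return Integer vector of candidate taxonomy IDs (possibly empty).
#' @export
lexicon_lookup <- function(lex, surface) {
  surface <- enc2utf8(surface)
  hit <- lex$name_index[[surface]]
  if (!is.null(hit)) return(hit)
  if (ncp(surface) >= 5) {
    hit <- lex$lc_index[[tolower(surface)]]
    if (!is.null(hit)) return(hit)
  }
  bf <- base_form(surface)
  if (!identical(bf, surface)) {
    hit <- lex$lc_index[[bf]]
    if (!is.null(hit)) return(hit)
  }
  integer(0)
}

#' Scientific name of a taxonomy ID
#' @param lex A `taxa_lexicon`.
#' @param taxon_id Integer ID.
#' @return The first name of class `"scientific"`, or `NA_character_`.
#' @export
scientific_name <- function(lex, taxon_id) {
  e <- lex$entries[[as.character(taxon_id)]]
  if (is.null(e)) return(NA_character_)
  sci <- e$names$surface[e$names$name_class == "scientific"]
  if (length(sci) == 0) NA_character_ else sci[[1]]
}

#' @export
print.taxa_lexicon <- function(x, ...) {
  cat(sprintf("<taxa_lexicon: %d taxa, %d indexed surface forms>\n",
              length(x$entries), length(x$name_index)))
  invisible(x)
}

#' Load a common-term table
#'
#' TSV rows of `term<TAB>comma-separated candidate IDs`.  The packaged default
#' carries the three context-dependent common terms observed in the Bio-ID
#' training corpus: larva (7227, 7955, 6239), embryo (10090, 7955, 6239,
#' 9031), seedling (3915, 3702).
#'
#' @param path Path to the TSV; default is the packaged table.
#' @return Named list mapping base-form term to an ordered integer ID vector.
#' @export
load_common_terms <- function(path = system.file("extdata",
                                                 "common_terms.tsv",
                                                 package = "captaxa")) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    stopifnot(length(parts) == 2)
    out[[tolower(parts[[1]])]] <-
      as.integer(trimws(strsplit(parts[[2]], ",", fixed = TRUE)[[1]]))
  }
  out
}
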