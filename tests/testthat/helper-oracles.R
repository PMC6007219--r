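# Shared helpers: independent oracle matchers and small fixture builders.
# The oracles deliberately avoid the trie — they enumerate the flat name set —
# and reuse only the published selection policy (captaxa:::select_matches) so
# that candidate *finding* is checked by an independent route.

ncp_h <- function(x) nchar(x, type = "chars")

slice_h <- function(text, start, end) substr(text, start + 1L, end)

# flat-set exact matcher: every indexed name, checked by direct substring
# equality at token boundaries
naive_exact_scan <- function(lex, text) {
  tok <- token_spans(text)
  if (nrow(tok) == 0) return(list())
  end_set <- logical(ncp_h(text)); end_set[tok$end] <- TRUE
  cands <- list()
  for (key in names(lex$name_index)) {
    klen <- ncp_h(key)
    if (klen == 0) next
    ci <- klen >= 5
    pat <- if (ci) tolower(key) else key
    hay <- if (ci) tolower(text) else text
    for (s in tok$start) {
      e <- s + klen
      if (e > ncp_h(text) || !end_set[e]) next
      if (identical(slice_h(hay, s, e), pat)) {
        cands[[length(cands) + 1L]] <- list(start = s, end = e, name = key,
                                            ids = lex$name_index[[key]],
                                            cost = 0L)
      }
    }
  }
  captaxa:::select_matches(cands)
}

# sliding-window bounded-Levenshtein matcher over the flat name set, with the
# same gates as the scanner: names >= 10 code points, case-insensitive,
# boundary characters anchored
naive_approx_scan <- function(lex, text, budget) {
  tok <- token_spans(text)
  if (nrow(tok) == 0) return(list())
  n <- ncp_h(text)
  end_set <- logical(n); end_set[tok$end] <- TRUE
  hay <- tolower(text)
  cands <- list()
  for (key in names(lex$name_index)) {
    klen <- ncp_h(key)
    if (klen == 0) next
    ci <- klen >= 5
    pat <- if (ci) tolower(key) else key
    h <- if (ci) hay else text
    for (s in tok$start) {
      # exact
      if (s + klen <= n && end_set[s + klen] &&
          identical(slice_h(h, s, s + klen), pat)) {
        cands[[length(cands) + 1L]] <- list(start = s, end = s + klen,
                                            name = key,
                                            ids = lex$name_index[[key]],
                                            cost = 0L)
      }
      if (budget == 0 || klen < 10 || !ci) next
      for (e in tok$end[tok$end > s & tok$end <= min(n, s + klen + budget)]) {
        win <- slice_h(hay, s, e)
        if (substr(win, 1, 1) != substr(pat, 1, 1)) next
        if (substr(win, ncp_h(win), ncp_h(win)) != substr(pat, klen, klen)) next
        cost <- utils::adist(pat, win)[1, 1]
        if (cost <= budget && cost > 0) {
          cands[[length(cands) + 1L]] <- list(start = s, end = e, name = key,
                                              ids = lex$name_index[[key]],
                                              cost = as.integer(cost))
        }
      }
    }
  }
  captaxa:::select_matches(cands)
}

match_df <- function(matches) {
  if (length(matches) == 0)
    return(data.frame(start = integer(), end = integer(), cost = integer(),
                      ids = character()))
  data.frame(start = vapply(matches, `[[`, integer(1), "start"),
             end = vapply(matches, `[[`, integer(1), "end"),
             cost = vapply(matches, `[[`, integer(1), "edit_cost"),
             ids = vapply(matches, function(m)
               paste(m$candidate_ids, collapse = ","), character(1)))
}

oracle_df <- function(matches) match_df(matches)

# random lexicon of synthetic names (letters only, so token boundaries are
# predictable), ids >= 10^7
random_lexicon <- function(n_names, seed) {
  set.seed(seed)
  mk_word <- function() paste(sample(letters, sample(3:9, 1), TRUE), collapse = "")
  rows <- vapply(seq_len(n_names), function(i) {
    nm <- paste(replicate(sample(1:2, 1), mk_word()), collapse = " ")
    sprintf("%d\t%s\tgeneral", 10000000L + i, nm)
  }, character(1))
  load_lexicon(paste(rows, collapse = "\n"))
}

random_text_from <- function(lex, n_tokens, seed) {
  set.seed(seed)
  names_pool <- names(lex$name_index)
  fillers <- c("the", "in", "of", "with", "sample", "figure", "panel",
               "cells", "after", "before", "control")
  words <- vapply(seq_len(n_tokens), function(i) {
    if (stats::runif(1) < 0.3) sample(names_pool, 1) else sample(fillers, 1)
  }, character(1))
  paste(words, collapse = " ")
}

corrupt_name <- function(name, n_edits, seed) {
  set.seed(seed)
  chars <- strsplit(name, "")[[1]]
  # interior substitutions only, keeping the anchor characters intact
  idx <- sample(2:(length(chars) - 1L), min(n_edits, length(chars) - 2L))
  for (i in idx) chars[i] <- if (chars[i] == "q") "z" else "q"
  paste(chars, collapse = "")
}

fig1_caption <- function(offset = 0L) {
  bioc_passage(offset,
    "Quantification of MRSA strain USA300 survival in human blood.",
    section_label = "fig_caption")
}

simple_collection <- function() {
  p <- bioc_passage(0, "MRSA infection", "fig_caption",
                    annotations = list(
                      span_annotation(0, 4, "MRSA", taxon_id = 1280)))
  bioc_collection("test", list(bioc_document("doc1", list(p))))
}
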