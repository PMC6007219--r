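# Multistage organism identification: process the full text section by
# section (Introduction first, then abstract, then the rest) to accumulate
# per-article meta-information — pre-linked taxonomy-ID counts, extra
# matchable terms from full-name/abbreviation pairs, a blacklist of
# non-organism pairs — then tag figure captions against lexicon + meta-info,
# apply the verb filter, and resolve context-dependent common terms.

#' Empty per-article meta-information store
#'
#' @return A `meta_info` object: `counts` (named integer vector, taxonomy ID
#'   -> number of successful links so far), `first_pos` (earliest
#'   document-global link offset per ID), `extra_terms` (surface -> ID map
#'   learned from abbreviation pairs), `blacklist` (short forms of rejected
#'   pairs) and `blacklist_pairs`.
#' @export
meta_info <- function() {
  structure(list(counts = integer(0), first_pos = integer(0),
                 extra_terms = integer(0), blacklist = character(0),
                 blacklist_pairs = list()),
            class = "meta_info")
}

#' @export
print.meta_info <- function(x, ...) {
  cat(sprintf("<meta_info: %d pre-linked ID(s), %d extra term(s), %d blacklisted pair(s)>\n",
              length(x$counts), length(x$extra_terms), length(x$blacklist_pairs)))
  if (length(x$counts)) {
    cat("  pre-linked counts: ",
        paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "), "\n")
  }
  invisible(x)
}

meta_count_link <- function(meta, id, pos) {
  key <- as.character(id)
  meta$counts[key] <- if (is.na(meta$counts[key])) 1L else meta$counts[[key]] + 1L
  if (is.na(meta$first_pos[key])) meta$first_pos[key] <- as.integer(pos)
  meta
}

meta_counts_for <- function(meta, ids) {
  v <- meta$counts[as.character(ids)]
  v[is.na(v)] <- 0L
  stats::setNames(as.integer(v), as.character(ids))
}

meta_first_pos_for <- function(meta, ids) {
  v <- meta$first_pos[as.character(ids)]
  v[is.na(v)] <- .Machine$integer.max
  stats::setNames(as.integer(v), as.character(ids))
}

is_caption_label <- function(label) grepl("fig|caption", tolower(label))

section_rank <- function(label) {
  l <- tolower(trimws(label))
  if (l %in% c("introduction", "background") || startsWith(l, "intro")) 1L
  else if (l == "abstract" || startsWith(l, "abstract")) 2L
  else 3L
}

#' Order a document's sections for full-text processing
#'
#' Introduction (or background) passages first, then the abstract, then the
#' remaining non-caption passages in document order; figure-caption passages
#' are excluded (they are tagged separately).  Section labels are matched
#' case-insensitively.
#'
#' @param doc A [bioc_document()].
#' @return List of passages in processing order.
#' @export
order_sections <- function(doc) {
  stopifnot(inherits(doc, "bioc_document"))
  ps <- Filter(function(p) !is_caption_label(p$section_label), doc$passages)
  if (length(ps) == 0) return(list())
  ranks <- vapply(ps, function(p) section_rank(p$section_label), integer(1))
  ps[order(ranks, seq_along(ps))]
}

# scan text with the lexicon graph plus the meta-info's extra terms;
# blacklisted short forms never produce matches
scan_with_meta <- function(graph, text, meta, max_mismatch = 3L) {
  matches <- scan_text(graph, text, max_mismatch = max_mismatch)
  if (length(meta$extra_terms)) {
    ids <- unname(meta$extra_terms)
    surfs <- names(meta$extra_terms)
    entries <- list()
    for (i in seq_along(ids)) {
      key <- as.character(ids[[i]])
      if (is.null(entries[[key]]))
        entries[[key]] <- list(taxon_id = ids[[i]],
                               names = data.frame(surface = character(),
                                                  name_class = character(),
                                                  stringsAsFactors = FALSE),
                               base_forms = character(0))
      entries[[key]]$names <- rbind(entries[[key]]$names,
        data.frame(surface = surfs[[i]], name_class = "abbreviation",
                   stringsAsFactors = FALSE))
    }
    extra_graph <- build_match_graph(new_lexicon(entries))
    matches <- select_matches(lapply(
      c(matches, scan_text(extra_graph, text, max_mismatch = 0L)),
      function(m) list(start = m$start, end = m$end, name = m$matched_name,
                       ids = m$candidate_ids, cost = m$edit_cost)))
  }
  if (length(meta$blacklist)) {
    matches <- Filter(function(m) !(m$matched_name %in% meta$blacklist),
                      matches)
  }
  matches
}

match_overlaps_verb <- function(m, tokens) {
  any(tokens$pos_label == "verb" &
        tokens$start < m$end & tokens$end > m$start)
}

#' Build the per-article meta-information from full text
#'
#' Processes the document's sections in [order_sections()] order.  In each
#' section, full-name/abbreviation pairs are detected per sentence: when the
#' base form of the long form is in the lexicon with a unique ID, both forms
#' become extra matchable terms for that ID; otherwise the pair is
#' blacklisted.  The section text is then scanned (lexicon graph plus extra
#' terms); every unambiguous, non-verb match counts as a successful link, and
#' ambiguous matches are resolved against the counts accumulated so far
#' (majority rule) before counting — unresolvable ones do not count.
#'
#' @param doc A [bioc_document()] carrying full-text passages.
#' @param lex The `taxa_lexicon`.
#' @param graph Matching graph from [build_match_graph()].
#' @param max_mismatch Edit budget forwarded to [scan_text()].
#' @return A `meta_info` object.
#' @export
build_meta_info <- function(doc, lex, graph, max_mismatch = 3L) {
  meta <- meta_info()
  for (p in order_sections(doc)) {
    sents <- split_sentences(p$text)
    for (si in seq_len(nrow(sents))) {
      sent <- slice_cp(p$text, sents$start[[si]], sents$end[[si]])
      for (pair in detect_abbreviations(sent)) {
        ids <- lexicon_lookup(lex, pair$long_form)
        if (length(ids) == 0)
          ids <- lex$lc_index[[base_form(pair$long_form)]]
        if (length(ids) == 1) {
          meta$extra_terms[pair$long_form] <- ids
          if (!(pair$short_form %in% meta$blacklist))
            meta$extra_terms[pair$short_form] <- ids
        } else {
          meta$blacklist <- unique(c(meta$blacklist, pair$short_form))
          meta$blacklist_pairs[[length(meta$blacklist_pairs) + 1L]] <-
            c(long = pair$long_form, short = pair$short_form)
          meta$extra_terms <-
            meta$extra_terms[names(meta$extra_terms) != pair$short_form]
        }
      }
    }
    tokens <- tokenize_with_pos(p$text)
    for (m in scan_with_meta(graph, p$text, meta, max_mismatch)) {
      if (match_overlaps_verb(m, tokens)) next
      pos <- p$offset + m$start
      if (length(m$candidate_ids) == 1) {
        meta <- meta_count_link(meta, m$candidate_ids, pos)
      } else {
        cnt <- meta_counts_for(meta, m$candidate_ids)
        mx <- max(cnt)
        if (mx > 0 && sum(cnt == mx) == 1) {
          meta <- meta_count_link(meta, as.integer(names(cnt)[cnt == mx]), pos)
        }
      }
    }
  }
  meta
}

new_mention <- function(start, end, surface, candidate_ids,
                        resolved_id = NULL, status = "ambiguous",
                        reason = NULL, type_only_label = NULL,
                        matched_name = NULL, edit_cost = 0L) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 surface = surface,
                 candidate_ids = sort(unique(as.integer(candidate_ids))),
                 resolved_id = if (is.null(resolved_id)) NULL else as.integer(resolved_id),
                 status = status, reason = reason,
                 type_only_label = type_only_label,
                 matched_name = matched_name,
                 edit_cost = as.integer(edit_cost)),
            class = "taxa_mention")
}

#' @export
print.taxa_mention <- function(x, ...) {
  tail <- switch(x$status,
    resolved = paste0("-> ", x$resolved_id),
    type_only = paste0("type-only '", x$type_only_label, "'"),
    dropped = paste0("dropped (", x$reason, ")"),
    paste0("ambiguous {", paste(x$candidate_ids, collapse = ","), "}"))
  cat(sprintf("<mention [%d,%d) '%s' %s>\n", x$start, x$end, x$surface, tail))
  invisible(x)
}

#' Resolve a context-dependent common term
#'
#' Looks the (base-formed) term up in the common-term table, lists its
#' candidate IDs and selects the one with the most pre-linked occurrences in
#' the article's meta-info.  When no candidate has been pre-linked at all the
#' mention stays a type-only organism annotation.
#'
#' @param term The common term as it appeared (e.g. "embryos").
#' @param meta The article's `meta_info`.
#' @param common Common-term table from [load_common_terms()].
#' @param start,end Optional span for the returned mention.
#' @return A `taxa_mention`, status `resolved` or `type_only`.
#' @export
resolve_common_term <- function(term, meta, common, start = 0L, end = ncp(term)) {
  bf <- base_form(term)
  cands <- common[[bf]]
  if (is.null(cands))
    stop("'", term, "' (base form '", bf, "') is not in the common-term table")
  cnt <- meta_counts_for(meta, cands)
  if (all(cnt == 0)) {
    return(new_mention(start, end, term, cands, status = "type_only",
                       type_only_label = "organism", matched_name = bf))
  }
  mx <- max(cnt)
  best <- cands[cnt == mx]
  if (length(best) > 1) {
    fp <- meta_first_pos_for(meta, best)
    best <- best[order(fp, match(best, cands))]
  }
  new_mention(start, end, term, cands, resolved_id = best[[1]],
              status = "resolved", matched_name = bf)
}

#' Tag a figure caption
#'
#' Scans the caption with the lexicon graph plus the article's extra terms,
#' drops matches overlapping verb-labelled tokens (`reason = "pos_filter"`),
#' routes common terms ("embryo", "larva", "seedling" after base-forming)
#' through [resolve_common_term()] — with an adjacency override: an organism
#' mention within the two tokens before the common term that is itself one of
#' the term's candidates wins over the majority count — and leaves remaining
#' multi-candidate mentions `ambiguous` for the disambiguation step.
#'
#' @param passage A caption [bioc_passage()].
#' @param meta The article's `meta_info` (may be `meta_info()` when no full
#'   text is available; the caption is then tagged from the lexicon alone).
#' @param graph Matching graph.
#' @param common Common-term table.
#' @param max_mismatch Edit budget forwarded to [scan_text()].
#' @return List of `taxa_mention`s in span order (spans are passage-local,
#'   0-based code points).
#' @export
tag_caption <- function(passage, meta, graph, common, max_mismatch = 3L) {
  stopifnot(inherits(passage, "bioc_passage"))
  text <- passage$text
  tokens <- tokenize_with_pos(text)
  mentions <- list()

  # common terms are token-level, found independently of the lexicon graph
  common_tok <- which(vapply(tokens$surface, function(w)
    !is.null(common[[base_form(w)]]), logical(1)))
  common_spans <- tokens[common_tok, , drop = FALSE]

  for (m in scan_with_meta(graph, text, meta, max_mismatch)) {
    # a lexicon match that IS a common-term token is routed to the table
    if (any(common_spans$start == m$start & common_spans$end == m$end)) next
    if (match_overlaps_verb(m, tokens)) {
      mentions[[length(mentions) + 1L]] <-
        new_mention(m$start, m$end, slice_cp(text, m$start, m$end),
                    m$candidate_ids, status = "dropped", reason = "pos_filter",
                    matched_name = m$matched_name, edit_cost = m$edit_cost)
      next
    }
    surf <- slice_cp(text, m$start, m$end)
    if (length(m$candidate_ids) == 1) {
      mentions[[length(mentions) + 1L]] <-
        new_mention(m$start, m$end, surf, m$candidate_ids,
                    resolved_id = m$candidate_ids, status = "resolved",
                    matched_name = m$matched_name, edit_cost = m$edit_cost)
    } else {
      mentions[[length(mentions) + 1L]] <-
        new_mention(m$start, m$end, surf, m$candidate_ids,
                    status = "ambiguous", matched_name = m$matched_name,
                    edit_cost = m$edit_cost)
    }
  }

  for (ci in seq_len(nrow(common_spans))) {
    tok_i <- common_tok[[ci]]
    term <- common_spans$surface[[ci]]
    cands <- common[[base_form(term)]]
    cm <- NULL
    # adjacency override: "zebrafish embryos" — a resolved organism mention
    # within the two preceding tokens whose ID is a candidate wins
    if (tok_i > 1) {
      lo <- tokens$start[[max(1L, tok_i - 2L)]]
      for (mm in mentions) {
        if (mm$status == "resolved" && mm$end <= common_spans$start[[ci]] &&
            mm$end > lo - 1L && mm$start >= lo && mm$resolved_id %in% cands) {
          cm <- new_mention(common_spans$start[[ci]], common_spans$end[[ci]],
                            term, cands, resolved_id = mm$resolved_id,
                            status = "resolved", matched_name = base_form(term))
        }
      }
    }
    if (is.null(cm))
      cm <- resolve_common_term(term, meta, common,
                                start = common_spans$start[[ci]],
                                end = common_spans$end[[ci]])
    mentions[[length(mentions) + 1L]] <- cm
  }

  mentions[order(vapply(mentions, `[[`, integer(1), "start"))]
}
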