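# Character word-graph (trie) over the lexicon's names, with exact and
# bounded-edit-distance scanning anchored at token boundaries.
#
# Matching policy (documented, configurable at scan time):
#  * names of >= 5 code points match case-insensitively, shorter names
#    (abbreviations like "LV") match verbatim;
#  * approximate matching (Levenshtein distance <= max_mismatch, default 3)
#    applies only to names of >= 10 code points;
#  * matches must start and end at token boundaries;
#  * at one start position exact beats approximate, then lower edit cost,
#    then the longer match; overlaps are resolved longest-first.

CI_MIN_LEN <- 5L
APPROX_MIN_LEN <- 10L

trie_node <- function() new.env(parent = emptyenv())

trie_insert <- function(root, key_chars, ids, name) {
  node <- root
  for (ch in key_chars) {
    nxt <- node[[ch]]
    if (is.null(nxt)) {
      nxt <- trie_node()
      assign(ch, nxt, envir = node)
    }
    node <- nxt
  }
  node$.ids <- sort(unique(c(node$.ids, ids)))
  if (is.null(node$.name)) node$.name <- name
  invisible(root)
}

#' Build the character word-graph of a lexicon
#'
#' Every name and base form in the lexicon's index becomes an accepting path
#' in a character trie; the accepting vertex carries the taxonomy-ID set of
#' that name.  The accepted language equals the indexed name set exactly,
#' which is the contract ([scan_text()] is tested for equivalence against a
#' naive flat-set matcher).
#'
#' @param lex A `taxa_lexicon`.
#' @return A `taxa_match_graph`.
#' @export
build_match_graph <- function(lex) {
  stopifnot(inherits(lex, "taxa_lexicon"))
  ci <- trie_node(); cs <- trie_node()
  n <- 0L; max_ci <- 0L
  for (key in names(lex$name_index)) {
    ids <- lex$name_index[[key]]
    klen <- ncp(key)
    if (klen == 0) next
    n <- n + 1L
    if (klen >= CI_MIN_LEN) {
      lk <- tolower(key)
      trie_insert(ci, strsplit(lk, "")[[1]], ids, key)
      max_ci <- max(max_ci, ncp(lk))
    } else {
      trie_insert(cs, strsplit(key, "")[[1]], ids, key)
    }
  }
  structure(list(ci = ci, cs = cs, n_names = n, max_len_ci = max_ci),
            class = "taxa_match_graph")
}

#' @export
print.taxa_match_graph <- function(x, ...) {
  cat(sprintf("<taxa_match_graph: %d name(s)>\n", x$n_names))
  invisible(x)
}

raw_match <- function(start, end, matched_name, candidate_ids, edit_cost) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 matched_name = matched_name,
                 candidate_ids = sort(unique(as.integer(candidate_ids))),
                 edit_cost = as.integer(edit_cost)),
            class = "raw_match")
}

# exact walk from each start position; accept where an accepting node is
# reached at a token end
trie_exact_scan <- function(root, chars, starts0, end_set) {
  out <- list()
  nchars <- length(chars)
  for (s in starts0) {
    node <- root
    j <- s
    while (j < nchars) {
      node <- node[[chars[[j + 1L]]]]
      if (is.null(node)) break
      j <- j + 1L
      if (!is.null(node$.ids) && end_set[[j]]) {
        out[[length(out) + 1L]] <-
          list(start = s, end = j, name = node$.name, ids = node$.ids, cost = 0L)
      }
    }
  }
  out
}

# bounded-Levenshtein search over the trie, anchored at one start position;
# classic per-node DP row, pruned when the row minimum exceeds the budget
trie_approx_from <- function(root, chars, s, budget, end_set, max_window) {
  m <- min(length(chars) - s, max_window)
  if (m <= 0) return(list())
  window <- chars[(s + 1L):(s + m)]
  out <- list()
  recurse <- function(node, depth, row) {
    if (!is.null(node$.ids) && depth >= APPROX_MIN_LEN) {
      # anchor rule: the window must agree with the name at its first and
      # last character, so edits never swallow adjacent short words
      lname <- tolower(node$.name)
      first_ok <- window[[1L]] == substr(lname, 1L, 1L)
      last_ch <- substr(lname, ncp(lname), ncp(lname))
      for (j in seq_len(m)) {
        if (first_ok && row[[j + 1L]] <= budget && end_set[[s + j]] &&
            window[[j]] == last_ch) {
          out[[length(out) + 1L]] <<-
            list(start = s, end = s + j, name = node$.name,
                 ids = node$.ids, cost = row[[j + 1L]])
        }
      }
    }
    for (ch in ls(node, all.names = TRUE)) {
      if (ch == ".ids" || ch == ".name") next
      child <- node[[ch]]
      if (!is.environment(child)) next
      newrow <- integer(m + 1L)
      newrow[[1L]] <- depth + 1L
      for (j in seq_len(m)) {
        cost_sub <- row[[j]] + (window[[j]] != ch)
        newrow[[j + 1L]] <- min(row[[j + 1L]] + 1L, newrow[[j]] + 1L, cost_sub)
      }
      if (min(newrow) <= budget) recurse(child, depth + 1L, newrow)
    }
  }
  recurse(root, 0L, 0:m)
  out
}

#' Scan text for lexicon matches
#'
#' Finds all maximal organism-name matches in `text`, anchored at token
#' boundaries, allowing up to `max_mismatch` character edits (Levenshtein) for
#' dictionary names of at least ten code points.
#'
#' @param graph A `taxa_match_graph` from [build_match_graph()].
#' @param text Text to scan.
#' @param max_mismatch Edit budget, 0..3 (default 3).
#' @return List of `raw_match` records ordered by span start, each with
#'   `start`/`end` (0-based code-point span), `matched_name`, `candidate_ids`
#'   and `edit_cost`.
#' @export
scan_text <- function(graph, text, max_mismatch = 3L) {
  stopifnot(inherits(graph, "taxa_match_graph"), max_mismatch <= 3L)
  text <- enc2utf8(text)
  n <- ncp(text)
  if (n == 0) return(list())
  chars <- strsplit(text, "")[[1]]
  lchars <- vapply(chars, tolower, character(1), USE.NAMES = FALSE)
  tok <- token_spans(text)
  if (nrow(tok) == 0) return(list())
  start_set <- tok$start
  end_set <- logical(n)
  end_set[tok$end] <- TRUE   # tok$end is half-open, so usable as 1-based flag

  cands <- trie_exact_scan(graph$cs, chars, start_set, end_set)
  cands <- c(cands, trie_exact_scan(graph$ci, lchars, start_set, end_set))
  if (max_mismatch > 0L && graph$max_len_ci >= APPROX_MIN_LEN) {
    maxw <- graph$max_len_ci + max_mismatch
    for (s in start_set) {
      cands <- c(cands,
                 trie_approx_from(graph$ci, lchars, s, as.integer(max_mismatch),
                                  end_set, maxw))
    }
  }
  select_matches(cands)
}

# Shared selection policy (also applied to the naive oracle in tests):
# collapse duplicates by span, keep the best candidate per start position
# (lowest cost, then longest), then greedy longest-first overlap resolution.
select_matches <- function(cands) {
  if (length(cands) == 0) return(list())
  key <- vapply(cands, function(x) paste(x$start, x$end), character(1))
  merged <- lapply(split(cands, key), function(grp) {
    costs <- vapply(grp, `[[`, integer(1), "cost")
    best <- min(costs)
    ids <- sort(unique(unlist(lapply(grp[costs == best], `[[`, "ids"))))
    g1 <- grp[costs == best][[1]]
    list(start = g1$start, end = g1$end, name = g1$name, ids = ids, cost = best)
  })
  starts <- vapply(merged, `[[`, integer(1), "start")
  ends <- vapply(merged, `[[`, integer(1), "end")
  costs <- vapply(merged, `[[`, integer(1), "cost")
  # one candidate per start: exact before approximate, then longest
  keep <- unlist(lapply(split(seq_along(merged), starts), function(ix) {
    ix[order(costs[ix], -ends[ix])][1L]
  }), use.names = FALSE)
  merged <- merged[keep]
  starts <- starts[keep]; ends <- ends[keep]; costs <- costs[keep]
  lens <- ends - starts
  ord <- order(-lens, costs, starts)
  chosen <- list()
  occupied_start <- integer(0); occupied_end <- integer(0)
  for (i in ord) {
    s <- starts[[i]]; e <- ends[[i]]
    if (any(s < occupied_end & e > occupied_start)) next
    chosen[[length(chosen) + 1L]] <- merged[[i]]
    occupied_start <- c(occupied_start, s)
    occupied_end <- c(occupied_end, e)
  }
  chosen <- chosen[order(vapply(chosen, `[[`, integer(1), "start"))]
  lapply(chosen, function(x)
    raw_match(x$start, x$end, x$name, x$ids, x$cost))
}
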