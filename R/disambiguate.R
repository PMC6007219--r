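# Disambiguation of ambiguous organism mentions: the majority rule over the
# article's pre-linked ID counts, and the candidate-count threshold filter of
# the three run configurations (2 / 10 / infinite).

#' Majority-rule resolution of an ambiguous mention
#'
#' A single-candidate mention resolves immediately.  Otherwise the candidate
#' with the most pre-linked occurrences in the article's meta-info wins; ties
#' at a positive count break by earliest first-link position, then smallest
#' taxonomy ID.  When every candidate has count zero the mention stays
#' ambiguous.
#'
#' @param mention A `taxa_mention`.
#' @param meta The article's `meta_info`.
#' @return The mention, possibly resolved.
#' @export
majority_resolve <- function(mention, meta) {
  stopifnot(inherits(mention, "taxa_mention"))
  if (!mention$status %in% c("ambiguous")) return(mention)
  cands <- mention$candidate_ids
  if (length(cands) == 1) {
    mention$resolved_id <- cands
    mention$status <- "resolved"
    return(mention)
  }
  cnt <- meta_counts_for(meta, cands)
  if (all(cnt == 0)) return(mention)
  mx <- max(cnt)
  best <- cands[cnt == mx]
  if (length(best) > 1) {
    fp <- meta_first_pos_for(meta, best)
    best <- best[order(fp, best)]
  }
  mention$resolved_id <- best[[1]]
  mention$status <- "resolved"
  mention
}

#' Threshold filter over still-ambiguous mentions
#'
#' Drops (reason `"threshold"`) any mention that is still ambiguous after
#' disambiguation and has more candidate IDs than `threshold`.  Resolved,
#' type-only and already-dropped mentions pass through; `threshold = Inf`
#' drops nothing.  The kept set is monotone in the threshold.
#'
#' @param mentions List of `taxa_mention`s.
#' @param threshold Positive count or `Inf`.
#' @return The mention list with over-ambiguous mentions marked dropped.
#' @export
apply_threshold_filter <- function(mentions, threshold) {
  stopifnot(is.numeric(threshold), threshold > 0)
  lapply(mentions, function(m) {
    if (m$status == "ambiguous" && length(m$candidate_ids) > threshold) {
      m$status <- "dropped"
      m$reason <- "threshold"
    }
    m
  })
}
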