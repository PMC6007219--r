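# Bio-ID scoring protocol: mention-level micro-PRF under strict and overlap
# span criteria, and caption-level normalization micro-PRF over unique ID
# sets.  Counts are pooled over all captions before rates are computed
# (micro-averaging); zero denominators give rate 0.

new_prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 precision = p, recall = r, f1 = f), class = "taxa_prf")
}

#' @export
print.taxa_prf <- function(x, ...) {
  cat(sprintf("P=%.3f R=%.3f F=%.3f  (tp=%d fp=%d fn=%d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

spans_of <- function(anns) {
  data.frame(start = vapply(anns, `[[`, integer(1), "start"),
             end = vapply(anns, `[[`, integer(1), "end"))
}

#' Mention-level micro-PRF
#'
#' `pred` and `gold` are parallel lists (one element per caption) of
#' annotation lists; each annotation needs `start`/`end` spans.  Matching is
#' one-to-one and greedy in span order: under `strict` a prediction matches an
#' unmatched gold annotation with the identical half-open span, under
#' `overlap` one sharing at least one code point.
#'
#' @param pred,gold Per-caption lists of annotations ([span_annotation()] or
#'   any list with `start`/`end`).
#' @param mode `"strict"` or `"overlap"`.
#' @return A `taxa_prf` with pooled counts.
#' @export
score_mentions <- function(pred, gold, mode = c("strict", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(length(pred) == length(gold))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (ci in seq_along(pred)) {
    ps <- spans_of(pred[[ci]]); gs <- spans_of(gold[[ci]])
    if (any(ps$end <= ps$start) || any(gs$end <= gs$start))
      stop("inconsistent span (end <= start) in caption ", ci)
    ps <- ps[order(ps$start, ps$end), , drop = FALSE]
    gs <- gs[order(gs$start, gs$end), , drop = FALSE]
    used <- logical(nrow(gs))
    for (i in seq_len(nrow(ps))) {
      hit <- if (mode == "strict") {
        which(!used & gs$start == ps$start[[i]] & gs$end == ps$end[[i]])
      } else {
        which(!used & gs$start < ps$end[[i]] & gs$end > ps$start[[i]])
      }
      if (length(hit)) {
        used[hit[[1]]] <- TRUE
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(!used)
  }
  new_prf(tp, fp, fn)
}

#' Caption-level normalization micro-PRF
#'
#' For each caption the predicted set of unique taxonomy IDs is compared with
#' the gold set; tp/fp/fn counts are pooled across captions.  Type-only
#' annotations carry no ID and so never enter these sets.
#'
#' @param pred,gold Parallel lists of integer ID vectors (one per caption);
#'   duplicates within a caption are ignored.
#' @return A `taxa_prf`.
#' @export
score_normalization <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (ci in seq_along(pred)) {
    p <- unique(as.integer(pred[[ci]])); g <- unique(as.integer(gold[[ci]]))
    tp <- tp + length(intersect(p, g))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  new_prf(tp, fp, fn)
}

caption_passages <- function(doc) {
  Filter(function(p) is_caption_label(p$section_label), doc$passages)
}

organism_anns <- function(p) {
  Filter(function(a) !is.null(a$taxon_id) || !is.null(a$type_only_label),
         p$annotations)
}

caption_id_set <- function(p) {
  ids <- unlist(lapply(p$annotations, function(a) a$taxon_id))
  unique(as.integer(ids))
}

#' Score a predicted collection against a gold collection
#'
#' Aligns captions by document ID and passage offset (an error lists orphan
#' document IDs present on one side only) and reports strict, overlap and
#' normalization micro-PRF.
#'
#' @param gold,pred [bioc_collection()]s sharing document IDs.
#' @return Named list of `taxa_prf`: `strict`, `overlap`, `normalization`.
#' @export
score_collections <- function(gold, pred) {
  gids <- vapply(gold$documents, `[[`, character(1), "doc_id")
  pids <- vapply(pred$documents, `[[`, character(1), "doc_id")
  orphans <- c(setdiff(gids, pids), setdiff(pids, gids))
  if (length(orphans))
    stop("document IDs present in only one collection: ",
         paste(orphans, collapse = ", "))
  pred_anns <- list(); gold_anns <- list()
  pred_ids <- list(); gold_ids <- list()
  for (did in gids) {
    gdoc <- gold$documents[[which(gids == did)]]
    pdoc <- pred$documents[[which(pids == did)]]
    gcaps <- caption_passages(gdoc); pcaps <- caption_passages(pdoc)
    goff <- vapply(gcaps, `[[`, integer(1), "offset")
    poff <- vapply(pcaps, `[[`, integer(1), "offset")
    for (i in seq_along(gcaps)) {
      j <- which(poff == goff[[i]])
      panns <- if (length(j)) organism_anns(pcaps[[j[[1]]]]) else list()
      gold_anns[[length(gold_anns) + 1L]] <- organism_anns(gcaps[[i]])
      pred_anns[[length(pred_anns) + 1L]] <- panns
      gold_ids[[length(gold_ids) + 1L]] <- caption_id_set(gcaps[[i]])
      pred_ids[[length(pred_ids) + 1L]] <-
        if (length(j)) caption_id_set(pcaps[[j[[1]]]]) else integer(0)
    }
  }
  list(strict = score_mentions(pred_anns, gold_anns, "strict"),
       overlap = score_mentions(pred_anns, gold_anns, "overlap"),
       normalization = score_normalization(pred_ids, gold_ids))
}
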