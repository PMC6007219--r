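# End-to-end tagging pipeline wiring the modules into the three run
# configurations: run1 = majority rule + threshold 2, run2 = CNN + threshold
# 10, run3 = CNN + infinite threshold.

#' Run configuration
#'
#' @param preset `"run1"` (majority disambiguation, candidate threshold 2),
#'   `"run2"` (CNN, threshold 10) or `"run3"` (CNN, infinite threshold);
#'   individual parameters override the preset.
#' @param disambiguator `"majority"` or `"model"`.
#' @param threshold Maximum number of candidate IDs an unresolved mention may
#'   keep; `Inf` disables the filter.
#' @param max_mismatch Edit budget for the matcher (default 3).
#' @param seed RNG seed for anything stochastic downstream.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = c("run1", "run2", "run3"),
                       disambiguator = NULL, threshold = NULL,
                       max_mismatch = 3L, seed = 42L) {
  preset <- match.arg(preset)
  def <- switch(preset,
                run1 = list(disambiguator = "majority", threshold = 2),
                run2 = list(disambiguator = "model", threshold = 10),
                run3 = list(disambiguator = "model", threshold = Inf))
  if (is.null(disambiguator)) disambiguator <- def$disambiguator
  if (is.null(threshold)) threshold <- def$threshold
  disambiguator <- match.arg(disambiguator, c("majority", "model"))
  structure(list(preset = preset, disambiguator = disambiguator,
                 threshold = threshold, max_mismatch = as.integer(max_mismatch),
                 seed = as.integer(seed)),
            class = "run_config")
}

mention_to_annotation <- function(m, passage, ann_id) {
  if (m$status == "resolved") {
    span_annotation(passage$offset + m$start, passage$offset + m$end,
                    m$surface, taxon_id = m$resolved_id, id = ann_id)
  } else {
    span_annotation(passage$offset + m$start, passage$offset + m$end,
                    m$surface, type_only_label = m$type_only_label, id = ann_id)
  }
}

#' Tag every figure caption in a collection
#'
#' For each document, meta-information is built from the matching full-text
#' document (matched by document ID in `fulltext`); captions are then tagged,
#' disambiguated per the run configuration, threshold-filtered, and the
#' surviving mentions written back as organism annotations.  Mentions that
#' survive the filter but remain unresolved are emitted as type-only organism
#' annotations (recognized but unlinked).
#'
#' @param captions A [bioc_collection()] whose caption passages are tagged.
#' @param fulltext Optional [bioc_collection()] of full-text documents; when
#'   a document has no full text the caption is tagged in degraded mode with
#'   an empty meta-info.
#' @param lex The `taxa_lexicon`.
#' @param graph Matching graph (built from `lex` when `NULL`).
#' @param common Common-term table.
#' @param config A [run_config()].
#' @param model A trained `taxa_cnn`; required when
#'   `config$disambiguator == "model"`.
#' @return List with `collection` (annotated copy of `captions`), `log`
#'   (per-stage drop counts: `pos_filter`, `threshold`, `model_reject`) and
#'   `mentions` (per caption, for inspection).
#' @export
tag_collection <- function(captions, fulltext = NULL, lex, graph = NULL,
                           common = load_common_terms(),
                           config = run_config("run1"), model = NULL) {
  stopifnot(inherits(captions, "bioc_collection"))
  if (is.null(graph)) graph <- build_match_graph(lex)
  if (config$disambiguator == "model" && is.null(model))
    stop("disambiguator 'model' requires a trained model")
  ft_ids <- if (is.null(fulltext)) character(0)
            else vapply(fulltext$documents, `[[`, character(1), "doc_id")
  drops <- c(pos_filter = 0L, threshold = 0L, model_reject = 0L)
  all_mentions <- list()
  ann_counter <- 0L
  out_docs <- lapply(captions$documents, function(d) {
    fi <- which(ft_ids == d$doc_id)
    meta <- if (length(fi)) {
      build_meta_info(fulltext$documents[[fi[[1]]]], lex, graph,
                      max_mismatch = config$max_mismatch)
    } else {
      meta_info()
    }
    d$passages <- lapply(d$passages, function(p) {
      if (!is_caption_label(p$section_label)) return(p)
      mentions <- tag_caption(p, meta, graph, common,
                              max_mismatch = config$max_mismatch)
      if (config$disambiguator == "majority") {
        mentions <- lapply(mentions, majority_resolve, meta = meta)
        mentions <- apply_threshold_filter(mentions, config$threshold)
      } else {
        mentions <- apply_threshold_filter(mentions, config$threshold)
        mentions <- lapply(mentions, function(m) {
          if (m$status %in% c("dropped", "type_only")) return(m)
          model_resolve(m, mention_context(p$text, m$start, m$end), model, lex)
        })
      }
      for (m in mentions) {
        if (m$status == "dropped") drops[[m$reason]] <<- drops[[m$reason]] + 1L
      }
      all_mentions[[length(all_mentions) + 1L]] <<-
        list(doc_id = d$doc_id, offset = p$offset, mentions = mentions)
      keep <- Filter(function(m) m$status %in% c("resolved", "type_only"),
                     mentions)
      p$annotations <- lapply(seq_along(keep), function(i) {
        ann_counter <<- ann_counter + 1L
        mention_to_annotation(keep[[i]], p, as.character(ann_counter))
      })
      p
    })
    d
  })
  list(collection = bioc_collection(captions$source_id, out_docs),
       log = as.list(drops), mentions = all_mentions)
}

#' Build meta-info for every document of a full-text collection
#'
#' @param fulltext A [bioc_collection()].
#' @param lex,graph Lexicon and matching graph.
#' @param max_mismatch Edit budget.
#' @return Named list of `meta_info` keyed by document ID.
#' @export
build_all_meta <- function(fulltext, lex, graph = NULL, max_mismatch = 3L) {
  if (is.null(graph)) graph <- build_match_graph(lex)
  metas <- lapply(fulltext$documents, build_meta_info, lex = lex,
                  graph = graph, max_mismatch = max_mismatch)
  names(metas) <- vapply(fulltext$documents, `[[`, character(1), "doc_id")
  metas
}

#' Train a disambiguation model from a caption collection
#'
#' Convenience wrapper: builds per-article meta-info, extracts the training
#' set ([build_disambiguation_dataset()]) and trains the CNN.
#'
#' @param captions,fulltext Collections as in [tag_collection()].
#' @param lex The lexicon.
#' @param cfg A [taxa_cnn_config()].
#' @param common Common-term table.
#' @param embeddings Optional embedding table.
#' @param file Optional path; when given the model is saved there with
#'   [save_model()].
#' @return The trained `taxa_cnn`.
#' @export
train_pipeline <- function(captions, fulltext = NULL, lex,
                           cfg = taxa_cnn_config(),
                           common = load_common_terms(),
                           embeddings = NULL, file = NULL) {
  graph <- build_match_graph(lex)
  metas <- if (is.null(fulltext)) list()
           else build_all_meta(fulltext, lex, graph)
  data <- build_disambiguation_dataset(captions, metas, lex, graph, common)
  if (length(data) == 0)
    stop("no linked or ambiguous mentions extractable: nothing to train on")
  model <- train_disambiguator(data, cfg, embeddings = embeddings)
  if (!is.null(file)) save_model(model, file)
  model
}

#' Save / load a disambiguation model
#'
#' The checkpoint is a single self-describing file embedding the
#' configuration and all parameter arrays; `load_model(save_model(m, f))`
#' restores bit-identical scores.
#'
#' @param model A `taxa_cnn`.
#' @param file Path.
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, file) {
  stopifnot(inherits(model, "taxa_cnn"))
  saveRDS(model, file)
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) {
  model <- readRDS(file)
  stopifnot(inherits(model, "taxa_cnn"))
  model
}
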