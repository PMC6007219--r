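# Deterministic mini-lexicon and synthetic BioC article generator: every
# pipeline path (standard names, strains, abbreviations defined in the
# Introduction, ambiguous names backed by full-text majority, common terms,
# character noise) is exercisable without any corpus download.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The packaged fixture lexicon
#'
#' A small deterministic lexicon covering the taxa whose IDs appear in the
#' motivating corpus examples — human (9606), MRSA/S. aureus (1280), the
#' USA300 strain (367830), zebrafish (7955), mouse (10090), C. elegans
#' (6239), chicken (9031), Drosophila melanogaster (7227), S. typhimurium
#' (90371), Trypanosoma brucei (5691), Lentivirus (11646), the Arabidopsis
#' entries (3701/3702/3915) — plus clearly synthetic padding entries with
#' IDs >= 10^7.  Base forms are pre-expanded.
#'
#' @return A `taxa_lexicon`.
#' @export
make_fixture_lexicon <- function() {
  expand_base_forms(load_lexicon(
    system.file("extdata", "fixture_lexicon.tsv", package = "captaxa")))
}

#' Specification for the synthetic corpus generator
#'
#' @param seed RNG seed; identical specs generate byte-identical collections.
#' @param n_articles,captions_per_article Corpus shape.
#' @param ambiguity_rate Per-caption probability of an ambiguous mention
#'   ("Arabidopsis", majority-resolvable from planted full-text links).
#' @param abbreviation_rate Per-article probability that the Introduction
#'   defines a full-name/abbreviation pair later used in a caption.
#' @param common_term_rate Per-caption probability of a common-term mention
#'   ("embryos"/"larvae"/"seedlings") when the article's organism admits one.
#' @param noise_rate Per-character corruption probability applied to caption
#'   mention surfaces (0 = clean).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_articles = 4L, captions_per_article = 3L,
                         ambiguity_rate = 0.25, abbreviation_rate = 0.3,
                         common_term_rate = 0.2, noise_rate = 0) {
  rates <- c(ambiguity_rate, abbreviation_rate, common_term_rate, noise_rate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            n_articles >= 1, captions_per_article >= 1)
  structure(list(seed = as.integer(seed), n_articles = as.integer(n_articles),
                 captions_per_article = as.integer(captions_per_article),
                 ambiguity_rate = ambiguity_rate,
                 abbreviation_rate = abbreviation_rate,
                 common_term_rate = common_term_rate,
                 noise_rate = noise_rate),
            class = "fixture_spec")
}

# organisms safe as article "home" taxa: unambiguous in the fixture lexicon
FIXTURE_ORGANISMS <- list(
  list(id = 6239L,  body = "Caenorhabditis elegans",  cap = "C. elegans",   common = "embryos"),
  list(id = 7955L,  body = "Danio rerio",             cap = "zebrafish",    common = "embryos"),
  list(id = 10090L, body = "Mus musculus",            cap = "mouse",        common = "embryos"),
  list(id = 7227L,  body = "Drosophila melanogaster", cap = "Drosophila melanogaster", common = "larvae"),
  list(id = 9031L,  body = "Gallus gallus",           cap = "chicken",      common = "embryos"),
  list(id = 9606L,  body = "Homo sapiens",            cap = "human",        common = NA),
  list(id = 5691L,  body = "Trypanosoma brucei",      cap = "Trypanosoma brucei", common = NA)
)

ST_LONG <- "Salmonella enterica subsp. enterica serovar Typhimurium"
ST_SHORT <- "S. typhimurium"
ST_ID <- 90371L
AMBIG_SURFACE <- "Arabidopsis"
AMBIG_SUPPORT <- "Arabidopsis thaliana"
AMBIG_ID <- 3702L

corrupt_chars <- function(text, noise_rate) {
  # every character consumes one uniform draw regardless of noise_rate, so a
  # fixed seed yields nested corruption sets across noise levels
  chars <- strsplit(text, "")[[1]]
  u <- stats::runif(length(chars))
  hit <- u < noise_rate
  chars[hit] <- ifelse(tolower(chars[hit]) == "x", "y", "x")
  paste(chars, collapse = "")
}

# one caption sentence carrying one mention; returns text plus the mention's
# span within it
caption_sentence <- function(kind, org, noise_rate) {
  switch(kind,
    standard = {
      surf <- corrupt_chars(org$cap, noise_rate)
      pre <- "Quantification of "
      list(text = paste0(pre, surf, " samples after treatment."),
           start = ncp(pre), surface = surf, id = org$id, kind = kind)
    },
    common = {
      pre <- "Representative images of "
      list(text = paste0(pre, org$common, " at the indicated stages."),
           start = ncp(pre), surface = org$common, id = org$id, kind = kind)
    },
    ambiguous = {
      pre <- "Expression levels in "
      list(text = paste0(pre, AMBIG_SURFACE, " leaf tissue."),
           start = ncp(pre), surface = AMBIG_SURFACE, id = AMBIG_ID, kind = kind)
    },
    abbrev = {
      pre <- "Survival of "
      list(text = paste0(pre, ST_SHORT, " inside macrophages."),
           start = ncp(pre), surface = ST_SHORT, id = ST_ID, kind = kind)
    })
}

#' Generate a synthetic annotated collection
#'
#' Each article carries an Introduction (which may define an
#' abbreviation pair), a results section repeatedly mentioning the article's
#' home organism (the planted pre-link majority), and figure-caption passages
#' whose mentions follow the spec's rates; captions carry gold annotations
#' whose spans always slice to their surfaces.  The accompanying ground-truth
#' report lists the expected meta-info counts and the per-caption gold ID
#' sets.
#'
#' @param spec A [fixture_spec()].
#' @param lex Lexicon used only to sanity-check that planted names resolve;
#'   defaults to [make_fixture_lexicon()].
#' @return List with `collection` (a [bioc_collection()]; full-text and
#'   caption passages per document, gold annotations on captions) and `truth`
#'   (per-document expected counts and caption ID sets, plus mention tallies).
#' @export
generate_synthetic_collection <- function(spec = fixture_spec(),
                                          lex = make_fixture_lexicon()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    docs <- list()
    truth_docs <- list()
    n_mentions <- 0L; n_ambiguous <- 0L
    for (ai in seq_len(spec$n_articles)) {
      org <- FIXTURE_ORGANISMS[[1L + (ai - 1L) %% length(FIXTURE_ORGANISMS)]]
      doc_id <- sprintf("synth-%03d", ai)
      has_abbrev <- stats::runif(1) < spec$abbreviation_rate
      n_links <- sample(2:4, 1)

      counts <- stats::setNames(n_links, as.character(org$id))
      intro <- paste0("We study ", org$body, " as a model system in this work.")
      if (has_abbrev) {
        intro <- paste0(intro, " ", ST_LONG, " (", ST_SHORT,
                        ") was used for infection assays.")
        # the long form and its parenthesized short form each count one link
        counts[as.character(ST_ID)] <- sum(counts[as.character(ST_ID)], 2L,
                                           na.rm = TRUE)
      }
      body_sents <- rep(paste0("Samples from ", org$body,
                               " were collected in triplicate."), n_links - 1L)

      caption_plans <- list()
      need_ambig_support <- FALSE
      for (ci in seq_len(spec$captions_per_article)) {
        kinds <- "standard"
        if (!is.na(org$common) && stats::runif(1) < spec$common_term_rate)
          kinds <- c(kinds, "common")
        if (stats::runif(1) < spec$ambiguity_rate) {
          kinds <- c(kinds, "ambiguous")
          need_ambig_support <- TRUE
        }
        if (has_abbrev && ci == 1L) kinds <- c(kinds, "abbrev")
        caption_plans[[ci]] <- kinds
      }
      if (need_ambig_support && org$id != AMBIG_ID) {
        body_sents <- c(body_sents,
                        rep(paste0(AMBIG_SUPPORT,
                                   " plants were grown for two weeks."), 2L))
        counts[as.character(AMBIG_ID)] <-
          sum(counts[as.character(AMBIG_ID)], 2L, na.rm = TRUE)
      }

      offset <- 0L
      passages <- list()
      add_passage <- function(text, label, anns = list()) {
        p <- bioc_passage(offset, text, section_label = label,
                          annotations = anns)
        passages[[length(passages) + 1L]] <<- p
        offset <<- offset + ncp(text) + 1L
        p
      }
      add_passage(intro, "introduction")
      if (length(body_sents))
        add_passage(paste(body_sents, collapse = " "), "results")

      truth_caps <- list()
      for (ci in seq_along(caption_plans)) {
        parts <- lapply(caption_plans[[ci]], caption_sentence, org = org,
                        noise_rate = spec$noise_rate)
        text <- ""
        anns <- list()
        cap_offset <- offset
        for (pt in parts) {
          base <- ncp(text) + if (nzchar(text)) 1L else 0L
          text <- if (nzchar(text)) paste(text, pt$text) else pt$text
          s <- cap_offset + base + pt$start
          anns[[length(anns) + 1L]] <-
            span_annotation(s, s + ncp(pt$surface), pt$surface,
                            taxon_id = pt$id)
          n_mentions <- n_mentions + 1L
          if (pt$kind == "ambiguous") n_ambiguous <- n_ambiguous + 1L
        }
        add_passage(text, "fig_caption", anns)
        truth_caps[[ci]] <- list(
          offset = cap_offset,
          ids = sort(unique(vapply(anns, `[[`, integer(1), "taxon_id"))))
      }
      docs[[length(docs) + 1L]] <- bioc_document(doc_id, passages)
      truth_docs[[doc_id]] <- list(expected_counts = counts,
                                   captions = truth_caps)
    }
    list(collection = bioc_collection("captaxa-synthetic", docs),
         truth = list(docs = truth_docs, n_mentions = n_mentions,
                      n_ambiguous = n_ambiguous))
  })
}

#' Write the fixture bundle to a directory
#'
#' Writes the fixture lexicon TSV, the common-term TSV, and a synthetic BioC
#' collection with its gold annotations plus the ground-truth report.
#'
#' @param out_dir Output directory (created if missing).
#' @param spec A [fixture_spec()].
#' @return Invisibly, the paths written.
#' @export
write_fixture_bundle <- function(out_dir, spec = fixture_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    lexicon = file.path(out_dir, "lexicon.tsv"),
    common = file.path(out_dir, "common_terms.tsv"),
    collection = file.path(out_dir, "collection.xml"),
    truth = file.path(out_dir, "truth.json"))
  file.copy(system.file("extdata", "fixture_lexicon.tsv", package = "captaxa"),
            paths[["lexicon"]], overwrite = TRUE)
  file.copy(system.file("extdata", "common_terms.tsv", package = "captaxa"),
            paths[["common"]], overwrite = TRUE)
  gen <- generate_synthetic_collection(spec)
  write_collection(gen$collection, paths[["collection"]])
  jsonlite::write_json(gen$truth, paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
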