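# Small configurations keep these tests fast; the architecture is identical
# at every size.
small_cfg <- function(...) {
  taxa_cnn_config(word_dim = 16L, position_dim = 4L, filter_count = 8L,
                  hidden_dim = 16L, max_context_length = 20L, ...)
}

# separable synthetic set: two organisms with disjoint context vocabularies
separable_set <- function(n_per = 10L) {
  mk <- function(w1, w2, ent, lab)
    disamb_example(c(w1, "ORG", w2), -1:1, ent, lab)
  data <- list()
  for (i in seq_len(n_per)) {
    f <- sprintf("fin%d", i %% 3)
    r <- sprintf("fur%d", i %% 3)
    data <- c(data,
              list(mk(f, "swim", "Danio rerio", "yes"),
                   mk(f, "swim", "Mus musculus", "no"),
                   mk(r, "run", "Mus musculus", "yes"),
                   mk(r, "run", "Danio rerio", "no")))
  }
  data
}

train_acc <- function(model, data) {
  mean(vapply(data, function(ex) {
    (score_candidate(model, ex)[["yes"]] >= 0.5) == (ex$label == "yes")
  }, logical(1)))
}

test_that("the default configuration carries the stated hyperparameters", {
  cfg <- taxa_cnn_config()
  expect_identical(cfg$learning_rate, 0.01)
  expect_identical(cfg$kernel_width, 2L)
  expect_identical(cfg$epochs, 50L)
  expect_identical(cfg$decision_cutoff, 0.5)
})

test_that("training on a separable set reaches accuracy 1.0 within 50 epochs", {
  data <- separable_set()
  model <- train_disambiguator(data, small_cfg(seed = 7L, epochs = 50L))
  expect_identical(train_acc(model, data), 1)
  expect_lt(model$epoch_loss[[length(model$epoch_loss)]], model$epoch_loss[[1]])

  # the gold candidate's P(yes) exceeds every alternative's on each context
  yes <- Filter(function(ex) ex$label == "yes", data)
  for (ex in yes[1:4]) {
    alt <- disamb_example(ex$words, ex$distances,
                          setdiff(c("Danio rerio", "Mus musculus"),
                                  ex$entity_name))
    expect_gt(score_candidate(model, ex)[["yes"]],
              score_candidate(model, alt)[["yes"]])
  }
})

test_that("training is deterministic given the seed; epochs 0 is the init", {
  data <- separable_set(4L)
  m1 <- train_disambiguator(data, small_cfg(seed = 3L, epochs = 5L))
  m2 <- train_disambiguator(data, small_cfg(seed = 3L, epochs = 5L))
  expect_identical(m1, m2)
  expect_identical(score_candidate(m1, data[[1]]), score_candidate(m2, data[[1]]))
  m3 <- train_disambiguator(data, small_cfg(seed = 4L, epochs = 5L))
  expect_false(identical(m1$W_conv, m3$W_conv))

  init <- train_disambiguator(data, small_cfg(seed = 3L, epochs = 0L))
  expect_length(init$epoch_loss, 0)
  # same seed: epoch-0 model equals the initialization of the trained one
  expect_identical(init$E_pos[1:5, ],
                   train_disambiguator(data, small_cfg(seed = 3L, epochs = 0L))$E_pos[1:5, ])

  expect_error(train_disambiguator(list(), small_cfg()), "empty")
})

test_that("scores are a two-class distribution and OOV words map to OOV", {
  data <- separable_set(3L)
  model <- train_disambiguator(data, small_cfg(seed = 1L, epochs = 2L))
  p <- score_candidate(model, data[[1]])
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_named(p, c("yes", "no"))

  unseen <- disamb_example(c("zzzz", "qqqq", "wwww"), -1:1, "Danio rerio")
  as_oov <- disamb_example(c("OOV", "OOV", "OOV"), -1:1, "Danio rerio")
  expect_identical(score_candidate(model, unseen), score_candidate(model, as_oov))
})

test_that("the context encoding matches the signed-distance scheme", {
  txt <- "Mice infected with wild S. typhimurium or its isogenic mutant."
  s <- regexpr("S. typhimurium", txt, fixed = TRUE)[[1]] - 1L
  ctx <- mention_context(txt, s, s + nchar("S. typhimurium"))
  i0 <- which(ctx$distances == 0L)
  expect_identical(ctx$words[i0], "S. typhimurium")
  expect_identical(ctx$words[(i0 - 1L):(i0 + 2L)],
                   c("wild", "S. typhimurium", "or", "its"))
  expect_identical(ctx$distances[(i0 - 1L):(i0 + 2L)], c(-1L, 0L, 1L, 2L))
})

test_that("dataset construction yields one yes and per-alternative no examples", {
  lex <- make_fixture_lexicon()
  graph <- build_match_graph(lex)
  # four captions, each with the ambiguous two-candidate surface plus full
  # text pre-linking one of them
  caps <- lapply(1:4, function(i)
    bioc_passage(100L * i, "Expression levels in Arabidopsis leaf tissue.",
                 "fig_caption"))
  doc <- bioc_document("d1", c(list(
    bioc_passage(0, "Arabidopsis thaliana plants were grown.", "introduction")),
    caps))
  col <- bioc_collection("t", list(doc))
  metas <- list(d1 = build_meta_info(doc, lex, graph))
  data <- build_disambiguation_dataset(col, metas, lex, graph)
  labs <- vapply(data, `[[`, character(1), "label")
  expect_identical(sum(labs == "yes"), 4L)
  expect_identical(sum(labs == "no"), 4L)
  ents <- vapply(data, `[[`, character(1), "entity_name")
  expect_setequal(unique(ents[labs == "yes"]), "Arabidopsis thaliana")
  expect_setequal(unique(ents[labs == "no"]), "Arabidopsis")

  none <- build_disambiguation_dataset(
    bioc_collection("e", list(bioc_document("x", list(
      bioc_passage(0, "Nothing to see.", "fig_caption"))))),
    list(), lex, graph)
  expect_length(none, 0)
})

test_that("model_resolve applies argmax, cutoff, and the tie rule", {
  data <- separable_set()
  model <- train_disambiguator(data, small_cfg(seed = 7L, epochs = 50L))
  lex <- make_fixture_lexicon()
  ctx <- list(words = c("fin1", "ORG", "swim"), distances = -1:1)
  m <- captaxa:::new_mention(0L, 3L, "ORG", c(7955L, 10090L))
  res <- model_resolve(m, ctx, model, lex)
  expect_identical(res$status, "resolved")
  expect_identical(res$resolved_id, 7955L)

  # a single candidate can still be rejected when P(yes) < cutoff
  wrong_ctx <- list(words = c("fur1", "ORG", "run"), distances = -1:1)
  single <- captaxa:::new_mention(0L, 3L, "ORG", 7955L)
  res2 <- model_resolve(single, wrong_ctx, model, lex)
  expect_identical(res2$status, "dropped")
  expect_identical(res2$reason, "model_reject")

  # exact score tie: both candidates share the entity representation
  tie_lex <- expand_base_forms(load_lexicon(
    "10000005\tSynthorg gammaensis\tscientific\n10000006\tSynthorg gammaensis\tscientific"))
  tie <- captaxa:::new_mention(0L, 3L, "ORG", c(10000006L, 10000005L))
  res3 <- model_resolve(tie, ctx, model, tie_lex)
  if (res3$status == "resolved") expect_identical(res3$resolved_id, 10000005L)
})

test_that("models survive a save/load round trip and score identically", {
  data <- separable_set(3L)
  model <- train_disambiguator(data, small_cfg(seed = 2L, epochs = 3L))
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(score_candidate(back, data[[1]]),
                   score_candidate(model, data[[1]]))
  unlink(f)
})

test_that("word2vec text embeddings load and set the model dimension", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("3 4",
               "swim 0.1 0.2 0.3 0.4",
               "run -0.1 -0.2 -0.3 -0.4",
               "fin1 0.5 0.5 0.5 0.5"), f)
  emb <- load_word_embeddings(f)
  expect_identical(emb$words, c("swim", "run", "fin1"))
  expect_identical(dim(emb$vectors), c(3L, 4L))
  model <- train_disambiguator(separable_set(2L),
                               small_cfg(seed = 1L, epochs = 1L),
                               embeddings = emb)
  expect_identical(model$word_dim, 4L)
  expect_identical(unname(model$cfg$word_dim), 16L)  # config untouched
  unlink(f)
})

test_that("a planted context rule beats majority when counts are uninformative", {
  data <- separable_set()
  model <- train_disambiguator(data, small_cfg(seed = 7L, epochs = 50L))
  lex <- make_fixture_lexicon()
  # held-out captions follow the planted rule; pre-link counts are equal, so
  # the majority rule degenerates to its tie-break
  meta <- meta_info()
  meta$counts <- c("7955" = 2L, "10090" = 2L)
  meta$first_pos <- c("7955" = 5L, "10090" = 5L)
  held <- list(list(ctx = list(words = c("fin2", "ORG", "swim"), distances = -1:1),
                    gold = 7955L),
               list(ctx = list(words = c("fur2", "ORG", "run"), distances = -1:1),
                    gold = 10090L),
               list(ctx = list(words = c("fin0", "ORG", "swim"), distances = -1:1),
                    gold = 7955L),
               list(ctx = list(words = c("fur0", "ORG", "run"), distances = -1:1),
                    gold = 10090L))
  model_hits <- 0L; majority_hits <- 0L
  for (h in held) {
    m <- captaxa:::new_mention(0L, 3L, "ORG", c(7955L, 10090L))
    r1 <- model_resolve(m, h$ctx, model, lex)
    if (r1$status == "resolved" && r1$resolved_id == h$gold)
      model_hits <- model_hits + 1L
    r2 <- majority_resolve(m, meta)
    if (r2$status == "resolved" && identical(r2$resolved_id, h$gold))
      majority_hits <- majority_hits + 1L
  }
  expect_gt(model_hits, majority_hits)
})
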