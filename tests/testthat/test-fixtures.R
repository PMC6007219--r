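test_that("the fixture lexicon is deterministic and covers the printed IDs", {
  lex <- make_fixture_lexicon()
  expect_identical(lexicon_lookup(lex, "human"), 9606L)
  expect_identical(lexicon_lookup(lex, "MRSA"), 1280L)
  expect_identical(lexicon_lookup(lex, "USA300"), 367830L)
  expect_identical(lexicon_lookup(lex, "zebrafish"), 7955L)
  expect_identical(lexicon_lookup(lex, "mouse"), 10090L)
  expect_identical(lexicon_lookup(lex, "C. elegans"), 6239L)
  expect_identical(lexicon_lookup(lex, "chicken"), 9031L)
  expect_identical(lexicon_lookup(lex, "Drosophila melanogaster"), 7227L)
  expect_identical(
    lexicon_lookup(lex, "Salmonella enterica subsp. enterica serovar Typhimurium"),
    90371L)
  expect_identical(lexicon_lookup(lex, "Trypanosoma brucei"), 5691L)
  expect_identical(lexicon_lookup(lex, "Lentivirus"), 11646L)
  expect_identical(lexicon_lookup(lex, "Arabidopsis"), c(3701L, 3702L))
  expect_identical(make_fixture_lexicon(), lex)
  # padding entries never use real-looking IDs
  ids <- as.integer(names(lex$entries))
  known <- c(9606L, 1280L, 367830L, 7955L, 10090L, 6239L, 9031L, 7227L,
             90371L, 5691L, 11646L, 3701L, 3702L, 3915L)
  expect_true(all(ids %in% known | ids >= 10000000L))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- fixture_spec(seed = 17, n_articles = 3)
  a <- generate_synthetic_collection(spec)
  b <- generate_synthetic_collection(spec)
  expect_identical(write_collection(a$collection), write_collection(b$collection))
  expect_identical(a$truth, b$truth)
  c <- generate_synthetic_collection(fixture_spec(seed = 18, n_articles = 3))
  expect_false(identical(write_collection(a$collection),
                         write_collection(c$collection)))
})

test_that("gold spans slice to their surfaces across seeds", {
  for (seed in 1:20) {
    gen <- generate_synthetic_collection(fixture_spec(seed = seed,
                                                      n_articles = 2))
    for (d in gen$collection$documents) {
      for (p in d$passages) {
        for (a in p$annotations) {
          expect_identical(substr(p$text, a$start - p$offset + 1,
                                  a$end - p$offset), a$surface,
                           label = paste(seed, d$doc_id))
        }
      }
    }
  }
})

test_that("the realized ambiguity fraction tracks the requested rate", {
  spec <- fixture_spec(seed = 1234, n_articles = 25, captions_per_article = 3,
                       ambiguity_rate = 0.3, common_term_rate = 0.2)
  gen <- generate_synthetic_collection(spec)
  expect_gte(gen$truth$n_mentions, 75L)
  frac <- gen$truth$n_ambiguous / gen$truth$n_mentions
  # n_mentions > ambiguity draws, so the realized fraction is below the
  # per-caption rate; bound it within the binomial tolerance band of the
  # per-caption draw count
  n_caps <- spec$n_articles * spec$captions_per_article
  expect_lt(abs(gen$truth$n_ambiguous / n_caps - 0.3), 0.1)
  expect_true(frac > 0 && frac < 0.3 + 0.1)
})

test_that("invalid fixture specifications are rejected by name", {
  expect_error(fixture_spec(ambiguity_rate = 1.5))
  expect_error(fixture_spec(n_articles = 0))
})

test_that("planted meta-info counts match the generator's report", {
  lex <- make_fixture_lexicon()
  graph <- build_match_graph(lex)
  gen <- generate_synthetic_collection(fixture_spec(seed = 29, n_articles = 4))
  for (d in gen$collection$documents) {
    meta <- build_meta_info(d, lex, graph)
    want <- gen$truth$docs[[d$doc_id]]$expected_counts
    expect_identical(meta$counts[order(names(meta$counts))],
                     want[order(names(want))], label = d$doc_id)
  }
})

test_that("noise-free resolvable collections close the loop at F = 1", {
  lex <- make_fixture_lexicon()
  gen <- generate_synthetic_collection(
    fixture_spec(seed = 41, n_articles = 5, captions_per_article = 3,
                 noise_rate = 0), lex)
  res <- tag_collection(gen$collection, fulltext = gen$collection, lex = lex,
                        config = run_config("run1"))
  sc <- score_collections(gen$collection, res$collection)
  expect_identical(sc$normalization$f1, 1)
  expect_identical(sc$strict$f1, 1)
  # and the predicted per-caption ID sets equal the ground-truth report
  for (d in res$collection$documents) {
    truth_caps <- gen$truth$docs[[d$doc_id]]$captions
    caps <- Filter(function(p) grepl("fig", p$section_label), d$passages)
    for (i in seq_along(caps)) {
      got <- sort(unique(unlist(lapply(caps[[i]]$annotations, `[[`, "taxon_id"))))
      expect_identical(got, truth_caps[[i]]$ids, label = d$doc_id)
    }
  }
})

test_that("normalization F never improves as character noise increases", {
  lex <- make_fixture_lexicon()
  f_at <- function(seed, noise) {
    gen <- generate_synthetic_collection(
      fixture_spec(seed = seed, n_articles = 3, captions_per_article = 2,
                   noise_rate = noise), lex)
    res <- tag_collection(gen$collection, fulltext = gen$collection, lex = lex,
                          config = run_config("run1"))
    score_collections(gen$collection, res$collection)$normalization$f1
  }
  for (seed in c(2, 9, 23)) {
    fs <- vapply(c(0, 0.15, 0.5), function(nr) f_at(seed, nr), numeric(1))
    expect_true(all(diff(fs) <= 0), label = paste("seed", seed,
                                                  paste(round(fs, 3), collapse = ">=")))
    expect_identical(fs[[1]], 1)
  }
})

test_that("the fixture bundle writes a re-readable corpus", {
  dir <- tempfile("bundle")
  paths <- write_fixture_bundle(dir, fixture_spec(seed = 2, n_articles = 2))
  expect_true(all(file.exists(paths)))
  col <- read_collection(paths[["collection"]])
  expect_length(col$documents, 2)
  lex <- expand_base_forms(load_lexicon(paths[["lexicon"]]))
  expect_identical(lexicon_lookup(lex, "human"), 9606L)
  unlink(dir, recursive = TRUE)
})
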