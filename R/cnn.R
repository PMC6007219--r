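# Convolutional yes/no scorer for organism-ID disambiguation.
#
# Architecture (the minimal one consistent with the stated facts — window 2,
# learning rate 0.01, word dim 200 with pre-trained embeddings, position
# representations, an OOV token):
#   * each context token is the concatenation of its word embedding and the
#     embedding of its signed distance to the target mention (the mention is
#     the single unit at distance 0);
#   * one convolution of width `kernel_width` + ReLU + max-pooling over the
#     context gives the context vector;
#   * the candidate entity (its scientific name) is the mean of its word
#     embeddings;
#   * [context; entity] -> one ReLU hidden layer -> affine -> 2-way softmax.
#     The hidden layer is load-bearing: with a purely affine combination the
#     score difference between two candidate IDs for the same mention is a
#     constant independent of the context, so context-dependent
#     disambiguation would be unlearnable;
#   * plain SGD, cross-entropy, per-example updates, seeded shuffling.

#' Configuration for the disambiguation model
#'
#' @param learning_rate SGD step size (default 0.01).
#' @param kernel_width Convolution window in tokens (default 2).
#' @param word_dim Word-embedding dimension; 50 by default so the test suite
#'   never needs the 200-dimensional pre-trained PubMed vectors — loading a
#'   word2vec file via `embeddings` switches to that file's dimension.
#' @param position_dim Position-embedding dimension (default 5).
#' @param filter_count Number of convolution filters (default 64).
#' @param hidden_dim Width of the ReLU hidden layer combining the context and
#'   entity channels (default 32).
#' @param max_context_length Maximum context window in tokens, centered on
#'   the mention (default 100); distances are clamped to this radius.
#' @param epochs Training epochs (default 50).
#' @param seed RNG seed controlling initialization and shuffling.
#' @param decision_cutoff Minimum P(yes) for [model_resolve()] to keep a
#'   candidate (default 0.5).
#' @return A `taxa_cnn_config` list.
#' @export
taxa_cnn_config <- function(learning_rate = 0.01, kernel_width = 2L,
                            word_dim = 50L, position_dim = 5L,
                            filter_count = 64L, hidden_dim = 32L,
                            max_context_length = 100L,
                            epochs = 50L, seed = 42L, decision_cutoff = 0.5) {
  stopifnot(learning_rate > 0, kernel_width >= 1, word_dim >= 1,
            position_dim >= 1, filter_count >= 1, hidden_dim >= 1,
            max_context_length >= 1,
            epochs >= 0, decision_cutoff > 0, decision_cutoff < 1)
  structure(list(learning_rate = learning_rate,
                 kernel_width = as.integer(kernel_width),
                 word_dim = as.integer(word_dim),
                 position_dim = as.integer(position_dim),
                 filter_count = as.integer(filter_count),
                 hidden_dim = as.integer(hidden_dim),
                 max_context_length = as.integer(max_context_length),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 decision_cutoff = decision_cutoff),
            class = "taxa_cnn_config")
}

#' Construct a disambiguation training/scoring example
#'
#' @param words Context words left to right, with the mention surface as one
#'   unit.
#' @param distances Signed token distances to the mention; exactly one zero,
#'   strictly increasing.
#' @param entity_name The candidate ID's scientific name.
#' @param label `"yes"`, `"no"`, or `NA` for scoring-only examples.
#' @return A `disamb_example`.
#' @export
disamb_example <- function(words, distances, entity_name, label = NA_character_) {
  stopifnot(length(words) == length(distances),
            sum(distances == 0L) == 1L,
            all(diff(distances) > 0))
  structure(list(words = as.character(words),
                 distances = as.integer(distances),
                 entity_name = entity_name, label = label),
            class = "disamb_example")
}

example_words <- function(ex) tolower(ex$words)

entity_tokens <- function(name) {
  tok <- token_spans(tolower(name))
  tok$surface[grepl("^[\\p{L}\\p{N}]", tok$surface, perl = TRUE)]
}

# the customary +/-0.25 uniform range for embedding tables; smaller scales
# leave the hidden layer in its near-linear regime and training plateaus
init_mat <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -0.25, 0.25), nrow = nr, ncol = nc)
}

#' Train the convolutional disambiguator
#'
#' Deterministic given `cfg$seed`; the vocabulary is built from the training
#' examples (context words and entity-name words, lowercased) plus the
#' reserved `OOV` token that represents unseen words at scoring time.  With
#' `epochs = 0` the returned model is exactly its random initialization.
#'
#' @param data Non-empty list of labelled [disamb_example()]s.
#' @param cfg A [taxa_cnn_config()].
#' @param embeddings Optional word-embedding table from
#'   [load_word_embeddings()]; overrides `cfg$word_dim` and initializes known
#'   words from the table.
#' @return A `taxa_cnn` model; `$epoch_loss` holds the monitored mean
#'   training loss per epoch.
#' @export
train_disambiguator <- function(data, cfg = taxa_cnn_config(),
                                embeddings = NULL) {
  if (length(data) == 0) stop("empty training data")
  labs <- vapply(data, `[[`, character(1), "label")
  stopifnot(all(labs %in% c("yes", "no")))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  words <- unique(unlist(c(lapply(data, example_words),
                           lapply(data, function(ex) entity_tokens(ex$entity_name)))))
  vocab <- c("OOV", sort(setdiff(words, "OOV")))
  dw <- if (is.null(embeddings)) cfg$word_dim else ncol(embeddings$vectors)
  E_word <- init_mat(length(vocab), dw)
  if (!is.null(embeddings)) {
    hit <- match(vocab, embeddings$words)
    known <- which(!is.na(hit))
    E_word[known, ] <- embeddings$vectors[hit[known], , drop = FALSE]
  }
  R <- cfg$max_context_length
  E_pos <- init_mat(2L * R + 1L, cfg$position_dim)
  D <- dw + cfg$position_dim
  W_conv <- init_mat(cfg$filter_count, cfg$kernel_width * D)
  b_conv <- stats::runif(cfg$filter_count, -0.05, 0.05)
  nin <- cfg$filter_count + dw
  # He-style scale so the hidden layer trains in few epochs at lr 0.01
  W_hid <- matrix(stats::rnorm(cfg$hidden_dim * nin, 0, sqrt(2 / nin)),
                  cfg$hidden_dim, nin)
  b_hid <- numeric(cfg$hidden_dim)
  W_out <- matrix(stats::rnorm(2L * cfg$hidden_dim, 0,
                               sqrt(2 / cfg$hidden_dim)), 2L, cfg$hidden_dim)
  b_out <- numeric(2L)

  model <- structure(list(vocab = vocab, E_word = E_word, E_pos = E_pos,
                          W_conv = W_conv, b_conv = b_conv,
                          W_hid = W_hid, b_hid = b_hid,
                          W_out = W_out, b_out = b_out,
                          word_dim = dw, cfg = cfg,
                          epoch_loss = numeric(0)),
                     class = "taxa_cnn")
  if (cfg$epochs == 0L) return(model)

  env <- list2env(model[c("E_word", "E_pos", "W_conv", "b_conv",
                          "W_hid", "b_hid", "W_out", "b_out")])
  lr <- cfg$learning_rate
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(data))
    total <- 0
    for (i in ord) {
      ex <- data[[i]]
      fw <- cnn_forward(env, model, ex)
      y <- if (ex$label == "yes") 1L else 2L
      total <- total - log(max(fw$p[[y]], 1e-12))
      cnn_backward(env, model, ex, fw, y, lr)
    }
    model$epoch_loss <- c(model$epoch_loss, total / length(data))
  }
  model$E_word <- env$E_word; model$E_pos <- env$E_pos
  model$W_conv <- env$W_conv; model$b_conv <- env$b_conv
  model$W_hid <- env$W_hid; model$b_hid <- env$b_hid
  model$W_out <- env$W_out; model$b_out <- env$b_out
  model
}

example_indices <- function(model, ex) {
  wi <- match(example_words(ex), model$vocab)
  wi[is.na(wi)] <- 1L
  R <- model$cfg$max_context_length
  pidx <- pmin(pmax(ex$distances, -R), R) + R + 1L
  et <- entity_tokens(ex$entity_name)
  ei <- match(et, model$vocab)
  ei[is.na(ei)] <- 1L
  if (length(ei) == 0) ei <- 1L
  list(wi = wi, pidx = pidx, ei = ei)
}

cnn_forward <- function(env, model, ex) {
  idx <- example_indices(model, ex)
  k <- model$cfg$kernel_width
  X <- cbind(env$E_word[idx$wi, , drop = FALSE],
             env$E_pos[idx$pidx, , drop = FALSE])
  n <- nrow(X)
  if (n < k) {  # pad with zero rows so at least one window exists
    X <- rbind(X, matrix(0, k - n, ncol(X)))
    n <- k
  }
  m <- n - k + 1L
  Z <- matrix(0, m, k * ncol(X))
  for (j in seq_len(m))
    Z[j, ] <- as.numeric(t(X[j:(j + k - 1L), , drop = FALSE]))
  A <- Z %*% t(env$W_conv) + matrix(env$b_conv, m, length(env$b_conv),
                                    byrow = TRUE)
  Arelu <- pmax(A, 0)
  amax <- max.col(t(Arelu), ties.method = "first")
  h <- Arelu[cbind(amax, seq_along(amax))]
  e <- colMeans(env$E_word[idx$ei, , drop = FALSE])
  he <- c(h, e)
  a_hid <- as.numeric(env$W_hid %*% he + env$b_hid)
  u <- pmax(a_hid, 0)
  logits <- as.numeric(env$W_out %*% u + env$b_out)
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  list(idx = idx, X = X, Z = Z, A = A, amax = amax, h = h, e = e,
       he = he, a_hid = a_hid, u = u, p = p, m = m)
}

cnn_backward <- function(env, model, ex, fw, y, lr) {
  k <- model$cfg$kernel_width
  dw <- model$word_dim
  Fn <- model$cfg$filter_count
  dlogit <- fw$p
  dlogit[y] <- dlogit[y] - 1
  du <- as.numeric(t(env$W_out) %*% dlogit)
  env$W_out <- env$W_out - lr * (dlogit %o% fw$u)
  env$b_out <- env$b_out - lr * dlogit
  da <- du * (fw$a_hid > 0)
  dhe <- as.numeric(t(env$W_hid) %*% da)
  env$W_hid <- env$W_hid - lr * (da %o% fw$he)
  env$b_hid <- env$b_hid - lr * da
  dh <- dhe[seq_len(Fn)]
  de <- dhe[Fn + seq_len(dw)]
  # entity channel: mean of word embeddings
  ei <- fw$idx$ei
  g <- de / length(ei)
  for (ii in ei) env$E_word[ii, ] <- env$E_word[ii, ] - lr * g
  # conv: gradient flows only through each filter's argmax window
  D <- ncol(fw$X)
  dZrow <- vector("list", fw$m)
  for (f in seq_len(Fn)) {
    j <- fw$amax[[f]]
    if (fw$A[j, f] <= 0) next
    gf <- dh[[f]]
    if (gf == 0) next
    env$b_conv[[f]] <- env$b_conv[[f]] - lr * gf
    zrow <- fw$Z[j, ]
    dzr <- gf * env$W_conv[f, ]
    env$W_conv[f, ] <- env$W_conv[f, ] - lr * gf * zrow
    if (is.null(dZrow[[j]])) dZrow[[j]] <- dzr else dZrow[[j]] <- dZrow[[j]] + dzr
  }
  n_real <- length(fw$idx$wi)
  for (j in seq_len(fw$m)) {
    if (is.null(dZrow[[j]])) next
    dz <- matrix(dZrow[[j]], k, D, byrow = TRUE)  # rows are window positions
    for (t in seq_len(k)) {
      row <- j + t - 1L
      if (row > n_real) next  # padding row
      env$E_word[fw$idx$wi[[row]], ] <-
        env$E_word[fw$idx$wi[[row]], ] - lr * dz[t, seq_len(dw)]
      env$E_pos[fw$idx$pidx[[row]], ] <-
        env$E_pos[fw$idx$pidx[[row]], ] - lr * dz[t, dw + seq_len(D - dw)]
    }
  }
  invisible(NULL)
}

#' Score a candidate with the disambiguation model
#'
#' @param model A trained (or initialized) `taxa_cnn`.
#' @param ex A [disamb_example()]; out-of-vocabulary words map to the `OOV`
#'   token.
#' @return Named numeric vector `c(yes = ..., no = ...)` summing to 1.
#' @export
score_candidate <- function(model, ex) {
  stopifnot(inherits(model, "taxa_cnn"), inherits(ex, "disamb_example"))
  env <- list2env(model[c("E_word", "E_pos", "W_conv", "b_conv",
                          "W_hid", "b_hid", "W_out", "b_out")])
  p <- cnn_forward(env, model, ex)$p
  c(yes = p[[1]], no = p[[2]])
}

#' @export
print.taxa_cnn <- function(x, ...) {
  cat(sprintf(
    "<taxa_cnn: vocab %d, word dim %d, %d filter(s) of width %d, %d epoch(s) trained>\n",
    length(x$vocab), x$word_dim, x$cfg$filter_count, x$cfg$kernel_width,
    length(x$epoch_loss)))
  if (length(x$epoch_loss))
    cat(sprintf("  final mean training loss: %.4f\n",
                x$epoch_loss[[length(x$epoch_loss)]]))
  invisible(x)
}

#' @export
predict.taxa_cnn <- function(object, newdata, ...) {
  if (inherits(newdata, "disamb_example")) newdata <- list(newdata)
  t(vapply(newdata, function(ex) score_candidate(object, ex), numeric(2)))
}

#' Load word embeddings in word2vec text format
#'
#' First line `count dim`, then one `word v1 ... vd` row per word.
#'
#' @param path File path.
#' @return List with `words` (character) and `vectors` (matrix, one row per
#'   word).
#' @export
load_word_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
  stopifnot(length(header) == 2)
  n <- header[[1]]; d <- header[[2]]
  words <- character(n); vecs <- matrix(0, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]]
    stopifnot(length(parts) == d + 1L)
    words[[i]] <- parts[[1]]
    vecs[i, ] <- as.numeric(parts[-1])
  }
  list(words = words, vectors = vecs)
}

# --------------------------------------------------------------------------
# Dataset construction and model-based resolution

#' Context encoding of a mention within a caption
#'
#' The mention is one context unit at distance 0; surrounding tokens carry
#' their signed distances ("... wild/-1, S. typhimurium/0, or/1, its/2 ...").
#'
#' @param text Caption text.
#' @param start,end Mention span (0-based code points).
#' @return List with `words` and `distances`.
#' @export
mention_context <- function(text, start, end) {
  tok <- token_spans(text)
  before <- tok[tok$end <= start, , drop = FALSE]
  after <- tok[tok$start >= end, , drop = FALSE]
  words <- c(before$surface, slice_cp(text, start, end), after$surface)
  dists <- c(seq_len(nrow(before)) - nrow(before) - 1L, 0L, seq_len(nrow(after)))
  list(words = words, distances = dists)
}

#' Build the disambiguation training set from a tagged collection
#'
#' Captions are tagged ([tag_caption()]) and majority-resolved against each
#' article's meta-info; every resolved mention contributes one `yes` example
#' for its ID and one `no` example per alternative candidate, with the
#' caption context encoded as signed distances and the candidate's
#' scientific-class name as the entity channel.  Candidates without a
#' scientific name in the lexicon are skipped with a warning.
#'
#' @param collection A [bioc_collection()] of captions.
#' @param metas Named list of `meta_info` keyed by document ID (missing
#'   entries mean no full text; an empty meta-info is used).
#' @param lex The `taxa_lexicon`.
#' @param graph Matching graph.
#' @param common Common-term table.
#' @return List of labelled [disamb_example()]s.
#' @export
build_disambiguation_dataset <- function(collection, metas, lex, graph,
                                         common = load_common_terms()) {
  out <- list()
  for (d in collection$documents) {
    meta <- metas[[d$doc_id]]
    if (is.null(meta)) meta <- meta_info()
    for (p in Filter(function(p) is_caption_label(p$section_label), d$passages)) {
      mentions <- tag_caption(p, meta, graph, common)
      mentions <- lapply(mentions, majority_resolve, meta = meta)
      for (m in mentions) {
        if (m$status != "resolved") next
        ctx <- mention_context(p$text, m$start, m$end)
        for (cand in m$candidate_ids) {
          sci <- scientific_name(lex, cand)
          if (is.na(sci)) {
            warning("no scientific name for taxon ", cand, "; example skipped")
            next
          }
          out[[length(out) + 1L]] <- disamb_example(
            ctx$words, ctx$distances, sci,
            label = if (cand == m$resolved_id) "yes" else "no")
        }
      }
    }
  }
  out
}

#' Model-based resolution of a mention
#'
#' Every candidate (including a lone one) is scored; the mention resolves to
#' the candidate with the highest P(yes) provided it reaches the decision
#' cutoff, with score ties broken by the smaller taxonomy ID; otherwise the
#' mention is dropped with reason `"model_reject"`.
#'
#' @param mention A `taxa_mention` with at least one candidate.
#' @param context Context encoding from [mention_context()].
#' @param model A trained `taxa_cnn`.
#' @param lex The `taxa_lexicon` (entity names).
#' @return The mention, resolved or dropped.
#' @export
model_resolve <- function(mention, context, model, lex) {
  stopifnot(inherits(mention, "taxa_mention"))
  if (mention$status %in% c("dropped", "type_only")) return(mention)
  cands <- mention$candidate_ids
  scores <- vapply(cands, function(cand) {
    sci <- scientific_name(lex, cand)
    if (is.na(sci)) sci <- mention$surface
    ex <- disamb_example(context$words, context$distances, sci)
    score_candidate(model, ex)[["yes"]]
  }, numeric(1))
  best <- which(scores == max(scores))
  pick <- best[order(cands[best])][[1]]
  if (scores[[pick]] >= model$cfg$decision_cutoff) {
    mention$resolved_id <- cands[[pick]]
    mention$status <- "resolved"
  } else {
    mention$status <- "dropped"
    mention$reason <- "model_reject"
    mention$resolved_id <- NULL
  }
  mention
}
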