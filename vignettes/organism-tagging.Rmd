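---
title: "Recognizing and normalizing organism terms in figure captions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing and normalizing organism terms in figure captions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captaxa)
```

## The problem

Captions name organisms through common English names, strain labels and
ad-hoc abbreviations far more often than through Latin binomials, and the
same surface form can denote different taxa in different articles. Linking a
caption mention to an NCBI Taxonomy ID therefore needs evidence from outside
the caption. `captaxa` implements a multistage pipeline that reads the
article's full text before its captions, accumulating *meta-information*:
counts of successfully linked IDs, their first link positions, extra
matchable terms learned from abbreviation definitions, and a blacklist of
non-organism abbreviation pairs.

## Matching model and its knobs

The lexicon (TSV of `taxon_id`, name, name class) is indexed as a character
word-graph whose accepted language is exactly the name set plus generated
base forms (lowercased, de-pluralized with an irregular table, so
"embryos" → "embryo" and "larvae" → "larva"). Scanning policy, all
configurable:

* **Token anchoring.** Matches start and end at token boundaries, so "rat"
  never fires inside "strategy".
* **Case.** Names of ≥ 5 code points match case-insensitively; shorter ones
  (abbreviations like "LV", "SIN") must match verbatim. Rationale: short
  abbreviations are exactly where case carries signal.
* **Approximate matching.** Up to `max_mismatch = 3` Levenshtein edits, but
  only for names of ≥ 10 code points, and only when the matched window
  agrees with the name at its first and last character. The three-edit
  budget tolerates strain/scientific-name variants ("Salmonela
  typhimurium"); the length gate keeps three edits from making short names
  match almost anything; the boundary anchor keeps edits from swallowing
  adjacent short words ("of C. elegans" as a 3-edit match of "C. elegans" —
  an artifact we observed and closed during development). Treating the
  stated "mismatch of three characters" as full edit distance (not
  substitutions only) is an interpretation; both the budget and the gates
  are parameters.
* **Selection.** At one start position exact beats approximate, then lower
  edit cost, then the longer name; overlaps resolve longest-first; output is
  deterministic.

## Identification and disambiguation

Sections are processed Introduction (or Background) first, then Abstract,
then everything else in document order — captions are excluded and tagged
separately. In each section, Schwartz–Hearst pairing (canonical constraints:
short form 2–10 characters, ≤ 2 words; long form ≤ min(|SF|+5, 2|SF|)
words) runs per sentence, extended with a genus rule for pairs like
"Salmonella … Typhimurium (S. typhimurium)" that the canonical length cap
would reject. A pair whose long-form base form resolves to a unique lexicon
ID contributes both surfaces as extra matchable terms; any other pair is
blacklisted, and blacklisted short forms never produce mentions. Unambiguous
matches increment their ID's pre-link count; ambiguous full-text matches are
resolved against the counts accumulated *so far* (this build-time use of the
majority rule is a documented choice — the alternative of skipping them
entirely loses the order-sensitivity benefit of processing the Introduction
first) and do not count when unresolvable.

Caption mentions overlapping a verb-labelled token are dropped
(`pos_filter`). The part-of-speech labeller is deliberately tiny — closed
auxiliary/reporting-verb lists plus an "-ed/-ing after auxiliary" rule —
because the pipeline only consumes the verb/non-verb distinction; it is
replaceable behind `tokenize_with_pos()`.

The majority rule resolves an ambiguous mention to the candidate with most
pre-linked occurrences; ties break by earliest first-link position, then
smallest ID; an all-zero count profile leaves the mention ambiguous, after
which the run threshold (2 / 10 / ∞ in the three presets) drops mentions
with too many surviving candidates. Common terms ("embryo", "larva",
"seedling") route through a fixed candidate table and the same majority
logic, with one override: an adjacent organism mention within two tokens
before the term ("zebrafish embryos") wins outright. When nothing is
pre-linked, the term is emitted as a type-only organism annotation rather
than guessed. The candidate table is closed by default but user-overridable.

## The neural scorer

The CNN formulates disambiguation as binary classification over (mention
context, candidate) pairs. Each context token is the concatenation of a word
embedding and an embedding of its signed distance to the mention (the
mention itself is the single unit at distance 0); one convolution of width 2
with ReLU and max-pooling summarizes the context; the candidate is the mean
word embedding of its scientific name; the two channels pass through one
ReLU hidden layer to a 2-way softmax, trained by plain SGD at learning rate
0.01 with an `OOV` token for unseen words. Stated facts fixed the window
(2), the learning rate (0.01), the 200-dimensional pre-trained-embedding
pathway and the OOV token; everything else is our choice, kept small and
explicit in `taxa_cnn_config()`: position dimension 5, 64 filters, hidden
width 32, context radius 100, 50 epochs, decision cutoff 0.5, default word
dimension 50 with seeded random initialization (±0.25 uniform — the
customary embedding range; smaller scales demonstrably plateau) so tests
never download embeddings; loading a word2vec text file switches to its
dimension.

The hidden layer is a deliberate deviation from the most minimal
"concatenate and classify" reading: with a purely affine combination the
difference in P(yes) between two candidates for the same mention is a
constant independent of context, so context-dependent disambiguation is
unlearnable in principle. We verified this empirically (training stalls at
chance) before adding the layer. Whether "window size 2" meant kernel width
or context radius is unstated; we treat it as kernel width, configurable.

Training examples come from the pipeline's own resolved mentions: one *yes*
per resolved ID, one *no* per alternative candidate, skipping candidates
without a scientific-class name (with a warning). In the model-based runs
every surviving mention — including single-candidate ones — is scored and
may be rejected (`model_reject`), which is what makes those runs
precision-oriented.

## Evaluation protocol

Mention-level micro-PRF under strict (identical half-open spans) and overlap
(≥ 1 shared code point) criteria with one-to-one greedy matching in span
order (multi-overlap resolution is not defined by the protocol; greedy
one-to-one is our documented choice), and caption-level normalization
micro-PRF over unique ID sets. Type-only annotations participate at mention
level but carry no ID and are excluded from normalization. Zero denominators
give rate 0.

## Offsets, units, and span repair

All offsets are 0-based, half-open, in Unicode code points — one canonical
unit, because observed corpus span errors stem from byte/UTF-16 confusion
around characters like "α". `repair_annotation_spans()` re-anchors any
annotation whose declared span does not slice to its surface, searching
± 10 code points (span errors from the cited characters shift offsets by a
few units only); unrepairable annotations are flagged, never dropped. The
source corpora's actual unit is unknowable from the text alone, so repair is
unit-agnostic by design.

## What the synthetic generator does and does not establish

`generate_synthetic_collection()` emulates the *shape* of a caption corpus:
articles with an Introduction that may define an abbreviation pair, a
results section planting a pre-link majority for the article's home
organism, and caption passages exercising the standard-name, strain,
abbreviation, ambiguity, and common-term paths at configurable rates, plus
per-character corruption noise. Defaults (4 articles × 3 captions,
ambiguity 0.25, abbreviation 0.3, common terms 0.2, noise 0) are our
choices of a small but path-covering corpus; sentence templates are
hand-written caption-like frames, not natural prose. Padding taxa use IDs
≥ 10⁷ so no invented surface is attached to a real-looking taxonomy entry.
Noise consumes one uniform draw per character regardless of the rate, so
corruption sets are nested across noise levels under a fixed seed and the
degradation-monotonicity check is exact rather than statistical.

A green end-to-end test (normalization F = 1 on clean generated corpora)
establishes that the pipeline's stages compose correctly and invert the
generator's stated world; it does not establish corpus-level accuracy — the
official benchmark requires a gated download and its headline figures are
out of scope here.

## Known limitations

* Life-cycle-stage names (PCF/BCF of *Trypanosoma brucei*) are not
  recognized; the "BCF" abbreviation also genuinely fails canonical
  Schwartz–Hearst alignment ('C' has no source letter in "the bloodstream
  form"). Semantic interpretation of such nouns is explicitly out of scope.
* The part-of-speech rules cover caption-style English only.
* Blacklisting suppresses a short form article-wide even when it is also a
  lexicon name ("LV") — a precision-oriented trade-off inherited from the
  pairing rule.
* The trie is a plain trie; suffix sharing would shrink memory but the
  contract is accepted-language equivalence, not topology.
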