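---
title: "From GO annotations to function paragraphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GO annotations to function paragraphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goprose)
library(dplyr)
```

## The problem

A protein's function is most often recorded as a set of Gene Ontology
(GO) terms — controlled-vocabulary identifiers spread over three
namespaces: biological process (BP), cellular component (CC) and
molecular function (MF). Each term carries a free-text definition
("Binding to a transfer RNA."), but a bag of term definitions is not what
a biologist wants to read. Curated databases instead write short prose
paragraphs: a general *Function* description, a *Subunit structure*
paragraph about interactions and stoichiometry, and a *Pathway* line
placing the protein in its metabolic context.

goprose implements the full pipeline for learning that mapping: it turns
a protein's GO annotation into a concatenated description document, trains
an encoder–decoder summarizer to rewrite the document as one of the three
section paragraphs, attaches a beam-probability confidence score to each
generated paragraph, and evaluates generated text against references with
embedding-based and optimal-transport mover metrics. Because the
summarizer also works on *predicted* GO terms, the package includes the
protein-centric Fmax score to quantify prediction quality alongside
summary quality.

## Dataset construction

**Documents.** `build_documents()` joins the definitions of a protein's
GO terms with single spaces, in ascending GO-id order by default
(namespace-grouped order is available). The order is a free choice — no
canonical concatenation order exists — and we default to GO-id order
because it is deterministic and reproducible. Definitions are
sentence-terminated (a `.` is appended when missing) because the
sentence-mover metrics downstream need sentence boundaries, and internal
whitespace is normalized to single spaces. Documents are truncated to
`max_tokens` whitespace words (default 1024, the model input budget);
`token_count` counts whitespace-delimited words, so punctuation stays
attached to its word. Subword re-tokenization is a backend concern: the
corpus layer stays model-agnostic.

**Redundancy reduction.** Proteins with near-identical annotations would
leak between training and test splits. The pairwise annotation overlap is
`|A ∩ B| / min(|A|, |B|)` — the shared fraction measured against either
protein and the larger value kept — and proteins with overlap ≥ 0.90 are
clustered. The clustering rule is single-linkage connected components of
the ≥-threshold graph: it is the unique parameter-free rule guaranteeing
that *every* between-cluster pair falls below the threshold, which is the
property the deduplication exists to provide. A greedy leader-clustering
variant is available behind `method = "leader"` for comparison. One
representative per cluster is drawn uniformly with a recorded seed.
The all-pairs scan uses an inverted index (GO id → proteins) so only
pairs sharing a term are examined; it is O(n²) worst-case and meant for
desk-scale corpora.

**Sections and splits.** Each of the three sections gets its own dataset,
because most entries carry only a subset of the three paragraphs; a
protein with all three appears in all three datasets. We cluster once on
the full annotation table and then assemble sections. Splits are
80/10/10 by a seeded uniform shuffle with floor arithmetic (train
`⌊0.8n⌋`, validation `⌊0.1n⌋`, remainder to test); each section dataset
holds one row per protein, so no protein straddles splits within a
section. We split each section independently; whether common proteins
should share split assignments across sections is left open, and
accession-keyed records make either policy easy to impose.

## The summarizer

The summarizer is a *contract*, not a fixed network: a tokenizer, a
proper conditional next-token distribution given (input, prefix), and
trainable parameters. Anything exposing those three closures plugs into
training, beam search, confidence scoring and evaluation unchanged — an
adapter over a large pretrained encoder–decoder checkpoint fits the same
surface.

The reference backend shipped in the package, `bow_seq2seq_backend()`, is
deliberately compact so that it trains on a single CPU in seconds:

* encoder: `h = tanh(W x + b)` over the normalized bag-of-words histogram
  `x` of the input document;
* decoder: `logits(t) = U h + A[prev_t, ] + c`, a content term plus a
  learned previous-token (bigram) table.

All parameters train jointly by Adam on token-level cross-entropy between
the predicted and reference summaries, with gradients derived by hand
(the model is one hidden layer deep, so backpropagation is a few matrix
products). We chose this architecture over a miniature transformer
because no automatic-differentiation framework is part of the package's
dependency set, a hand-written multi-head-attention backward pass is a
serious correctness risk, and the templated synthetic corpus (below) is
expressible by exactly this decomposition: the input bag determines
*which* clauses appear, the bigram table determines local word order.
What the simplification costs is long-range word-order sensitivity within
the input — acceptable for a reference backend whose role is to make the
pipeline's learning contract testable, not to reach production quality.

The default training configuration mirrors the full-scale recipe:
100 epochs, Adam at learning rate 1e-4, batch size 4, input cap 1024
tokens, target cap 256 tokens, early stopping on validation
cross-entropy (patience 5; the stopping metric is our choice — only the
existence of early stopping is given). Test-scale runs use fewer epochs,
a target cap of 64 and a larger learning rate, stated where they are
used. One integer seed drives initialization and shuffling;
single-threaded execution makes training bit-reproducible, which is a
tested contract.

**Beam search.** Generation is length-bounded beam search (default width
4). A hypothesis's probability is the raw product of its next-token
probabilities, accumulated in log space; no length normalization is
applied by default because the confidence score consumes plain
probabilities, but a length-penalty exponent is available for ranking.
`<eos>` is forbidden at the first step so every hypothesis contains at
least one word.

**Confidence.** The confidence of the top hypothesis is its probability
divided by the total probability of the `N` final beam hypotheses
(`N = 4` by default). With equal probabilities this is `1/N`; a dominant
hypothesis approaches 1. The ratio is computed from log-probabilities
with a max-shift, so beams whose raw probabilities underflow (hundreds of
tokens) are scored exactly, and the value is invariant to any constant
shift of all log-probabilities.

## Evaluation metrics

**Embedding scores.** `embedding_cosine()` compares candidate and
reference as vectors under a pluggable embedder; the primary score is the
mean over a panel of three embedders (`average_embedding_score()`),
mirroring the practice of averaging several pretrained sentence
embedders. The package ships a deterministic hash embedder — each word
maps to a unit vector drawn from a generator seeded by a hash of the word
itself, a text to the mean of its word vectors — so the whole evaluation
stack runs offline. In high dimension unrelated texts embed nearly
orthogonally while shared vocabulary pulls the cosine up, which is the
property the tests rely on. Adapters over real pretrained embedders
implement the same `embed()`/`embed_words()` surface.

**Mover similarities.** WMS treats documents as count-weighted bags of
word embeddings; SMS as length-weighted bags of sentence embeddings
(sentence vector = mean of word vectors); S+WMS as the union of both bags
with combined weights renormalized. Bags are normalized to unit mass, the
ground cost is the Euclidean distance between embeddings, and the
distance is the optimal value of the exact transportation problem, solved
in-package by the transportation simplex (north-west-corner start, MODI
pivoting, infinitesimal supply perturbation against degeneracy). The
solver is exact, which the test suite verifies against permutation brute
force (uniform equal-size bags) and a 0.05-step simplex-grid search
(unequal bags), plus metric-axiom checks on random triples. Similarity is
`exp(−distance)`: the sources describing these metrics report
similarities in (0, 1] while defining a minimum transport *cost*, and the
negative-exponential is the standard bridge between the two; raw
distances are exposed alongside. Sentence segmentation splits after
sentence-final punctuation followed by whitespace and an uppercase
letter; a text with no usable sentence falls back to one sentence with a
warning. No stop-word removal is applied by default (a `stopwords` hook
exists).

**Win rates and score classes.** `win_fraction()` is the fraction of
paired entries where one system's score strictly exceeds the other's;
ties are non-wins. Score reports band entries into high `[0.8, 1.0]`,
moderate `[0.5, 0.8)` and low `[0, 0.5)` classes of the average embedding
score, the bands used for confidence-versus-accuracy summaries.

**Fmax.** For scored GO predictions, `compute_fmax()` follows the CAFA
protein-centric convention: at each threshold, precision is averaged over
proteins with at least one prediction at or above the threshold, recall
over all truth-bearing proteins, and Fmax is the maximal harmonic mean
over a 0.01-step threshold grid.

## Robustness protocols

The deletion protocol selects targets with exactly 8 terms of the probed
category, at least one term in each other category and 10–24 terms in
total, then removes k = 1…7 category terms uniformly at random — terms of
the other categories are never touched — in 3 seeded trials per (target,
k). The addition protocol selects targets with exactly 5 category terms,
7–15 total, whose original document stays within 512 words (added
definitions must still fit the input budget), and adds 1–10 terms drawn
from vocabulary terms not annotated to the target ("irrelevant" is
defined as not-annotated; an exclusion hook allows stricter notions).
Scores are averaged over trials and then over targets; deletion curves
are keyed by *remaining* category terms, addition curves by terms
*added*. Trial seeds are derived per (target, k, trial), so curves are
reproducible and no randomness is shared across cells.

## The synthetic world

Everything above is testable offline because `make_vocabulary()` /
`make_proteins()` generate a self-contained GO world: templated term
definitions built from namespace-specific concept banks (distinct terms
get distinct concepts, hence distinct definitions), annotation sets with
controlled overlap structure (redundancy groups share a base set and
differ by at most one private term, giving pairwise overlap `m/(m+1)` ≥
the requested fraction on disjoint vocabulary slices), and reference
paragraphs derived from the annotation by a fixed compositional rule —
one clause per term, in ascending GO-id order, phrased by namespace.
Function paragraphs use every term, Subunit paragraphs the CC/MF terms,
Pathway paragraphs one short sentence, reproducing the real sections'
length ordering (Pathway < Subunit < Function). Section presence is a
seeded Bernoulli draw whose default availabilities (Function 1.00,
Subunit 0.64, Pathway 0.15) mirror the relative sizes of the three
full-scale section datasets.

Because references are compositional in the annotation, identical
annotations yield identical references and the document→paragraph mapping
is learnable by a small model — that is precisely what makes the
end-to-end learning property testable on a CPU. The trade-off is
deliberate: the world has no linguistic variation, no synonymy, no DAG
structure, and definition lengths far below the real 3–7,836-word range.
Passing tests therefore demonstrate that the pipeline's machinery —
dataset construction, training dynamics, decoding, scoring — behaves as
specified; they say nothing about summary quality on natural corpora,
which depends on a large pretrained backend plugged into the same
contract.

The test suite and the acceptance script train on a world of 500 proteins
over 120 terms (≈ 400 training / 50 validation / 50 test Function
records, dimension-32 backend, 40 epochs at learning rate 0.02, target
cap 64), sizes at which the whole pipeline runs in well under a minute
while leaving the learning signal unmistakable: the fine-tuned backend
beats an untrained copy on essentially every held-out record, and
deleting BP terms from full annotation down to one remaining term drops
the mean embedding score by ≈ 0.3.

```{r tiny-run, eval = FALSE}
spec <- fixture_spec(
  n_terms = c(BP = 40, CC = 40, MF = 40), n_proteins = 500,
  redundancy_groups = list(c(4, 0.9), c(4, 0.9), c(4, 0.9)),
  perturbation_targets = 12, seed = 1
)
vocab <- make_vocabulary(spec)
world <- make_proteins(spec, vocab)
clusters <- cluster_by_overlap(world$annotations) |>
  select_representatives(seed = 1)
reps <- dplyr::semi_join(
  world$annotations,
  dplyr::filter(clusters, is_representative),
  by = "accession"
)
records <- assemble_section(reps, vocab, world$references, "Function") |>
  split_dataset(seed = 1)
```

## Numerical choices and degenerate inputs

* Beam probabilities live in log space end to end; `exp` happens only
  inside the confidence ratio after a max-shift.
* The transport solver perturbs supplies by ~1e-13 to keep the basis a
  spanning tree; the squared-distance expansion used for ground costs is
  clamped so identical atoms cost exactly zero (the metric identity
  axiom is tested, not assumed).
* The Fmax threshold grid is rounded to 9 decimals to protect
  `score >= threshold` comparisons from `seq()` floating-point noise.
* Empty annotation sets, empty beams, non-positive probabilities,
  zero-norm embeddings, invalid GO accessions and malformed OBO stanzas
  are rejected with informative errors; obsolete OBO terms are skipped
  with a count; proteins lacking a section paragraph are silently
  excluded from that section's dataset (by design, not an error).
* `split_dataset()` requires n ≥ 3 so every part is non-empty.

## Known limitations

* The reference backend has no word-order sensitivity within the input
  document and no attention; it is a pipeline-verification model.
* The transportation simplex is dense; bags beyond a few hundred atoms
  per side (very long documents) would be slow.
* Redundancy clustering is quadratic in the number of proteins sharing
  terms; full-database scale would need blocking or sketching.
* GO DAG semantics (ancestor closure, term obsolescence remapping,
  semantic similarity) are intentionally out of scope.
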