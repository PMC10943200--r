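# goprose

Turning a protein's Gene Ontology (GO) annotations into readable prose.

Curated protein databases describe function twice: as a set of GO term
identifiers, and as short human-written paragraphs — a general
**Function** description, a **Subunit structure** paragraph, and a
**Pathway** line. goprose implements the complete pipeline for learning
the mapping from the first representation to the second:

1. **GO corpus** — read GO vocabularies (OBO 1.2) and protein
   annotations (GAF 2.x or simple TSV), and concatenate each protein's
   term definitions into a single document, capped at 1024 words.
2. **Redundancy reduction** — cluster proteins whose annotations overlap
   by ≥ 90 % (overlap = `|A ∩ B| / min(|A|, |B|)`, i.e. the shared
   fraction against either protein with the larger value kept;
   single-linkage components) and keep one seeded representative per
   cluster, so near-duplicates never straddle training and test data.
3. **Datasets** — per-section paired records (document, reference
   paragraph) with seeded 80/10/10 splits
   (`⌊0.8n⌋ / ⌊0.1n⌋ /` remainder).
4. **Summarizer** — a trainable encoder–decoder contract (tokenizer +
   conditional next-token distribution + parameters) with a compact
   CPU-trainable reference backend, Adam on token-level cross-entropy,
   early stopping, and width-4 beam-search generation.
5. **Confidence** — each generated paragraph is scored by
   `Prob(top) / Σⱼ Prob(j)` over the `N = 4` final beam hypotheses,
   computed stably in log space.
6. **Evaluation** — per-embedder cosine similarity and its 3-embedder
   average; Word/Sentence Mover's Similarity (WMS, SMS, S+WMS) via an
   exact in-package optimal-transport solver, reported as
   `exp(−cost)`; strict win rates between systems; high/moderate/low
   score classes (`[0.8, 1]`, `[0.5, 0.8)`, `[0, 0.5)`); and
   protein-centric Fmax for scored GO predictions.
7. **Robustness** — the GO-deletion and GO-addition protocols
   (seeded term removal/addition with trial averaging) producing
   score-versus-k curves.
8. **Synthetic world** — a generator for templated GO vocabularies,
   overlap-controlled annotation sets and rule-derived reference
   paragraphs, so every stage above runs and is tested fully offline.

Everything is tibble-in / tibble-out and pipe-friendly; fitted models
support `tidy()`, `glance()` and `autoplot()`, and a command-line
interface (`inst/scripts/goprose`) exposes the stages as composable
subcommands with JSON run manifests.

## Worked example

A fully synthetic end-to-end run — generate a GO world, deduplicate,
assemble the Function dataset, train, generate and score:

```r
library(goprose)
library(dplyr)

spec <- fixture_spec(
  n_terms = c(BP = 40, CC = 40, MF = 40), n_proteins = 500,
  redundancy_groups = list(c(4, 0.9), c(4, 0.9), c(4, 0.9)),
  perturbation_targets = 12, seed = 1
)
vocab <- make_vocabulary(spec)
world <- make_proteins(spec, vocab)

clusters <- cluster_by_overlap(world$annotations) |>
  select_representatives(seed = 1)
reps <- semi_join(world$annotations,
                  filter(clusters, is_representative), by = "accession")

records <- assemble_section(reps, vocab, world$references, "Function")
split <- split_dataset(records, seed = 1)
table(split$split)
#>      train validation       test
#>        399         49         51

train <- filter(split, split == "train")
tok <- word_tokenizer(c(train$input_text, train$target_text))
fit <- train_summarizer(
  bow_seq2seq_backend(tok, dim = 32, seed = 1),
  train, filter(split, split == "validation"),
  training_config(epochs = 40, learning_rate = 0.02,
                  max_target_tokens = 64, early_stopping_patience = 10,
                  seed = 1)
)
glance(fit)
#>   epochs best_epoch train_loss best_val_loss n_params learning_rate batch_size
#> 1     32         22      0.755         0.865    19568          0.02          4

test <- filter(split, split == "test")
generate_summaries(fit, test[1:3, ], max_tokens = 64)
#>   accession summary                                        logprob confidence
#> 1 SYN00163  involved in gamma folding regulation. involv…   -31.6      0.314
#> 2 SYN00143  binds the kappa nucleolus structure. located…   -28.4      0.318
#> 3 SYN00019  involved in the omega chaperone target. invo…   -28.6      0.321
```

Each row is the top beam hypothesis for one protein with its total
log-probability and its confidence — the share of the 4-hypothesis
beam's probability mass it carries (0.25 would mean a four-way tie; ~0.32
means mild dominance). Scoring those summaries against the reference
paragraphs:

```r
entries <- bind_cols(test[1:3, c("accession", "target_text")],
                     generate_summaries(fit, test[1:3, ],
                                        max_tokens = 64)[, c("summary", "confidence")])
glance(score_report(entries))
#>   n mean_embedding_score mean_wms mean_sms mean_swms mean_confidence n_high n_moderate n_low
#> 1 3                0.753    0.515    0.673     0.589           0.318      1          2     0
```

`mean_embedding_score` is the 3-embedder cosine average in [-1, 1];
the mover similarities are `exp(−transport cost)` in (0, 1]; the class
counts band entries at 0.8 and 0.5. Training for longer and on more
proteins pushes the embedding score up; an untrained backend scores near
0 on every record.

## Scope

goprose provides the machinery: corpus construction, deduplication,
splits, the training/decoding/scoring stack, robustness protocols, and
offline test fixtures. It does not bundle pretrained model or embedder
weights — large backends and real sentence embedders plug into the same
backend/embedder contracts — and it does not implement GO DAG semantics
(ancestor closure, term remapping) or retrieve data from the web.
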