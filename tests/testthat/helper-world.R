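# Shared fixtures: a small synthetic GO world, deterministic stub
# embedders, a brute-force union-find clustering oracle, and a cached
# trained summarizer reused by the slower end-to-end tests.

small_world <- function(seed = 11L, n_proteins = 40L,
                        redundancy_groups = list(),
                        perturbation_targets = 0L,
                        section_availability = c(Function = 1.0,
                                                 Subunit = 0.64,
                                                 Pathway = 0.15)) {
  spec <- fixture_spec(
    n_terms = c(BP = 15L, CC = 15L, MF = 15L),
    n_proteins = n_proteins,
    terms_per_protein = c(3L, 8L),
    redundancy_groups = redundancy_groups,
    section_availability = section_availability,
    perturbation_targets = perturbation_targets,
    seed = seed
  )
  vocab <- make_vocabulary(spec)
  world <- make_proteins(spec, vocab)
  list(spec = spec, vocab = vocab,
       annotations = world$annotations, references = world$references)
}

# An embedder that maps whole texts to fixed vectors via a lookup table;
# used for hand-computed cosine oracles.
table_embedder <- function(vectors, name = "table") {
  dim <- length(vectors[[1]])
  list(
    name = name,
    dim = dim,
    embed = function(text) {
      v <- vectors[[text]]
      if (is.null(v)) stop("no vector for text: ", text)
      v
    },
    embed_words = function(words) {
      vapply(words, function(w) vectors[[w]], numeric(dim))
    }
  )
}

# Independent clustering oracle: all-pairs overlap matrix + union-find.
oracle_clusters <- function(annotations, threshold = 0.9) {
  sets <- split(annotations$go_id, annotations$accession)
  n <- length(sets)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ov <- length(intersect(sets[[i]], sets[[j]])) /
          min(length(unique(sets[[i]])), length(unique(sets[[j]])))
        if (ov >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  setNames(match(roots, unique(roots)), names(sets))
}

# Brute-force optimal transport for uniform equal-size bags: by
# Birkhoff-von Neumann the optimum is attained at a permutation.
oracle_ot_uniform <- function(cost) {
  n <- nrow(cost)
  perms <- permutations_of(seq_len(n))
  min(vapply(perms, function(p) mean(cost[cbind(seq_len(n), p)]), numeric(1)))
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# Grid brute force for small unequal bags: enumerate transport plans whose
# entries lie on a step-0.05 simplex grid and satisfy the marginals.
oracle_ot_grid <- function(cost, a, b, step = 0.05) {
  m <- nrow(cost); n <- ncol(cost)
  units <- round(1 / step)
  au <- round(a * units); bu <- round(b * units)
  stopifnot(sum(au) == units, sum(bu) == units)
  best <- Inf
  # enumerate row-wise compositions recursively
  recurse <- function(row, remaining_cols, plan) {
    if (row > m) {
      if (all(remaining_cols == 0)) {
        val <- sum(plan * cost) / units
        if (val < best) best <<- val
      }
      return(invisible())
    }
    comps <- compositions_of(au[row], n, cap = remaining_cols)
    for (cmp in comps) {
      plan[row, ] <- cmp
      recurse(row + 1L, remaining_cols - cmp, plan)
    }
  }
  recurse(1L, bu, matrix(0L, m, n))
  best
}

compositions_of <- function(total, k, cap) {
  if (k == 1L) {
    if (total <= cap[1]) return(list(total)) else return(list())
  }
  out <- list()
  for (first in 0:min(total, cap[1])) {
    for (rest in compositions_of(total - first, k - 1L, cap[-1])) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# Cached trained summarizer on the standard training world, shared by the
# end-to-end tests so the model is fitted once per test run.
.trained_cache <- new.env(parent = emptyenv())

training_world <- function() {
  if (is.null(.trained_cache$world)) {
    spec <- fixture_spec(
      n_terms = c(BP = 40L, CC = 40L, MF = 40L),
      n_proteins = 500L,
      terms_per_protein = c(4L, 8L),
      redundancy_groups = list(c(4, 0.9), c(4, 0.9), c(4, 0.9)),
      section_availability = c(Function = 1.0, Subunit = 0.64, Pathway = 0.15),
      perturbation_targets = 12L,
      seed = 2024L
    )
    vocab <- make_vocabulary(spec)
    world <- make_proteins(spec, vocab)
    .trained_cache$world <- list(spec = spec, vocab = vocab,
                                 annotations = world$annotations,
                                 references = world$references)
  }
  .trained_cache$world
}

trained_model <- function() {
  if (is.null(.trained_cache$fit)) {
    w <- training_world()
    # cluster, keep representatives, assemble the Function dataset, split
    clusters <- cluster_by_overlap(w$annotations, threshold = 0.9)
    clusters <- select_representatives(clusters, seed = 5L)
    reps <- dplyr::filter(
      w$annotations,
      accession %in% clusters$accession[clusters$is_representative]
    )
    records <- assemble_section(reps, w$vocab, w$references, "Function")
    split <- split_dataset(records, seed = 5L)
    train <- dplyr::filter(split, split == "train")
    validation <- dplyr::filter(split, split == "validation")
    test <- dplyr::filter(split, split == "test")
    tok <- word_tokenizer(c(train$input_text, train$target_text))
    backend <- bow_seq2seq_backend(tok, dim = 32L, seed = 5L)
    config <- training_config(
      epochs = 40L, learning_rate = 0.02, batch_size = 4L,
      max_input_tokens = 1024L, max_target_tokens = 64L,
      early_stopping_patience = 10L, seed = 5L
    )
    fit <- train_summarizer(backend, train, validation, config)
    untrained <- bow_seq2seq_backend(tok, dim = 32L, seed = 99L)
    .trained_cache$fit <- list(fit = fit, untrained = untrained,
                               train = train, validation = validation,
                               test = test, tokenizer = tok)
  }
  .trained_cache$fit
}
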