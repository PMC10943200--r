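# A hand-specified mock backend over vocabulary (<pad>, <bos>, <eos>,
# <unk>, "a", "b") with a two-step branching next-token distribution and a
# forced <eos> at step 3; small enough to enumerate every hypothesis.
mock_backend <- function() {
  vocab <- c("<pad>", "<bos>", "<eos>", "<unk>", "a", "b")
  dist <- function(prefix) {
    p <- rep(0, 6)
    n <- length(prefix)
    if (n == 0) {
      p[5] <- 0.6; p[6] <- 0.4
    } else if (n == 1) {
      if (prefix[1] == 5) { p[5] <- 0.7; p[6] <- 0.3 }
      else { p[5] <- 0.2; p[6] <- 0.8 }
    } else {
      p[3] <- 1
    }
    log(p)
  }
  list(
    tokenizer = structure(list(vocab = vocab,
                               index = setNames(seq_along(vocab), vocab)),
                          class = "word_tokenizer"),
    encode_input = function(ids) list(),
    logprobs = function(state, prefix) dist(prefix)
  )
}

# All complete hypotheses of the mock backend with their probabilities.
mock_enumeration <- function() {
  seqs <- list(c(5, 5, 3), c(5, 6, 3), c(6, 5, 3), c(6, 6, 3))
  probs <- c(0.6 * 0.7, 0.6 * 0.3, 0.4 * 0.2, 0.4 * 0.8)
  list(seqs = seqs, probs = probs)
}

test_that("training_config defaults match the fine-tuning recipe", {
  cfg <- training_config()
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$max_input_tokens, 1024L)
  expect_equal(cfg$max_target_tokens, 256L)
})

test_that("beam search matches exhaustive enumeration on the mock backend", {
  be <- mock_backend()
  oracle <- mock_enumeration()
  res <- beam_search(be, integer(), beam_width = 4L, max_tokens = 5L)
  expect_equal(res$n, 4L)
  ord <- order(oracle$probs, decreasing = TRUE)
  expect_equal(res$logprobs, log(oracle$probs[ord]), tolerance = 1e-12)
  expect_equal(res$token_ids, oracle$seqs[ord])
  # width 2: the two highest-product paths
  res2 <- beam_search(be, integer(), beam_width = 2L, max_tokens = 5L)
  expect_equal(exp(res2$logprobs), sort(oracle$probs, decreasing = TRUE)[1:2])
})

test_that("beam width 1 equals greedy decoding", {
  be <- mock_backend()
  res <- beam_search(be, integer(), beam_width = 1L, max_tokens = 5L)
  expect_equal(res$token_ids[[1]], c(5, 5, 3)) # argmax path a, a, <eos>
  expect_equal(res$hypotheses[1], "a a")
})

test_that("beam probabilities are non-increasing and lengths bounded", {
  be <- mock_backend()
  res <- beam_search(be, integer(), beam_width = 3L, max_tokens = 2L)
  expect_true(all(diff(res$logprobs) <= 1e-12))
  expect_true(all(lengths(res$token_ids) <= 2L))
})

test_that("an invalid backend distribution is rejected", {
  be <- mock_backend()
  be$logprobs <- function(state, prefix) log(c(0.5, 0, 0, 0, 0.4, 0.4))
  expect_error(beam_search(be, integer(), beam_width = 2L), "distribution")
})

test_that("training reduces the loss on a learnable templated corpus", {
  w <- small_world(seed = 61L, n_proteins = 80L)
  recs <- assemble_section(w$annotations, w$vocab, w$references, "Function")
  split <- split_dataset(recs, seed = 6L)
  train <- split[split$split == "train", ]
  val <- split[split$split == "validation", ]
  tok <- word_tokenizer(c(train$input_text, train$target_text))
  backend <- bow_seq2seq_backend(tok, dim = 24L, seed = 6L)
  cfg <- training_config(epochs = 12L, learning_rate = 0.02,
                         max_target_tokens = 64L,
                         early_stopping_patience = 12L, seed = 6L)
  fit <- train_summarizer(backend, train, val, cfg)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_lt(tail(fit$history$val_loss, 1), fit$history$val_loss[1])
  # loss trace bookkeeping
  expect_equal(tidy(fit)$loss[tidy(fit)$dataset == "train"],
               fit$history$train_loss)
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
})

test_that("training is deterministic given seed and config", {
  w <- small_world(seed = 62L, n_proteins = 24L)
  recs <- assemble_section(w$annotations, w$vocab, w$references, "Function")
  split <- split_dataset(recs, seed = 1L)
  train <- split[split$split == "train", ]
  val <- split[split$split == "validation", ]
  tok <- word_tokenizer(c(train$input_text, train$target_text))
  cfg <- training_config(epochs = 4L, learning_rate = 0.01,
                         max_target_tokens = 64L, seed = 9L)
  fit1 <- train_summarizer(bow_seq2seq_backend(tok, seed = 9L),
                           train, val, cfg)
  fit2 <- train_summarizer(bow_seq2seq_backend(tok, seed = 9L),
                           train, val, cfg)
  expect_identical(fit1$history, fit2$history)
})

test_that("early stopping halts after the patience window", {
  w <- small_world(seed = 63L, n_proteins = 20L)
  recs <- assemble_section(w$annotations, w$vocab, w$references, "Function")
  split <- split_dataset(recs, seed = 2L)
  train <- split[split$split == "train", ]
  val <- split[split$split == "validation", ]
  tok <- word_tokenizer(c(train$input_text, train$target_text))
  # learning rate 0 freezes the parameters: validation loss can only
  # improve once (first epoch), so training stops after 1 + patience epochs
  cfg <- training_config(epochs = 50L, learning_rate = 1e-12,
                         max_target_tokens = 64L,
                         early_stopping_patience = 3L, seed = 2L)
  fit <- train_summarizer(bow_seq2seq_backend(tok, seed = 2L),
                          train, val, cfg)
  expect_lte(nrow(fit$history), 4L)
})

test_that("empty datasets are rejected", {
  tok <- word_tokenizer("a b c")
  be <- bow_seq2seq_backend(tok)
  empty <- tibble::tibble(input_text = character(), target_text = character())
  full <- tibble::tibble(input_text = "a b", target_text = "c")
  expect_error(train_summarizer(be, empty, full), "non-empty")
  expect_error(train_summarizer(be, full, empty), "non-empty")
})

test_that("generated hypotheses respect the target token cap", {
  mdl <- trained_model()
  doc <- mdl$test[1, ]
  res <- beam_search(mdl$fit$backend,
                     tokenize(mdl$tokenizer, doc$input_text),
                     beam_width = 4L, max_tokens = 8L)
  expect_true(all(lengths(res$token_ids) <= 8L))
  expect_equal(res$n, 4L)
  expect_true(all(diff(res$logprobs) <= 1e-12))
})

test_that("model checkpoints round-trip through save/load", {
  mdl <- trained_model()
  dir <- withr::local_tempdir()
  save_summarizer(mdl$fit, dir)
  back <- load_summarizer(dir)
  expect_equal(back$backend$tokenizer$vocab, mdl$tokenizer$vocab)
  expect_equal(back$history$val_loss, mdl$fit$history$val_loss,
               tolerance = 1e-9)
  doc <- mdl$test[1:2, ]
  expect_equal(generate_summaries(back, doc, max_tokens = 32L),
               generate_summaries(mdl$fit, doc, max_tokens = 32L))
})
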