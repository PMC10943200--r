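#' Training configuration for the summarizer
#'
#' Defaults follow the fine-tuning recipe used for the full-scale model:
#' 100 epochs of Adam at learning rate 1e-4 on batches of 4, inputs capped
#' at 1024 tokens and targets at 256, with early stopping on validation
#' cross-entropy.
#'
#' @param epochs maximum training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size sequences per gradient step.
#' @param max_input_tokens input token cap.
#' @param max_target_tokens target token cap.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @param seed integer seed driving parameter init and shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 100L,
                            learning_rate = 1e-4,
                            batch_size = 4L,
                            max_input_tokens = 1024L,
                            max_target_tokens = 256L,
                            early_stopping_patience = 5L,
                            seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            max_input_tokens >= 1, max_target_tokens >= 1,
            early_stopping_patience >= 1)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_input_tokens = as.integer(max_input_tokens),
         max_target_tokens = as.integer(max_target_tokens),
         early_stopping_patience = as.integer(early_stopping_patience),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' A compact trainable encoder-decoder backend
#'
#' The package's reference summarizer backend, small enough to train on a
#' CPU in seconds: the encoder maps the input document to a latent vector
#' through a one-hidden-layer network over its normalized bag-of-words
#' histogram, and the decoder produces a next-token distribution from that
#' latent vector plus a learned previous-token (bigram) table,
#'
#'   `h = tanh(W x + b)`;  `logits(t) = U h + A[prev_t, ] + c`.
#'
#' All parameters are trained jointly by Adam on token-level cross-entropy.
#' The backend fulfils the generic summarizer contract — a tokenizer, a
#' proper conditional next-token distribution, and trainable parameters —
#' so beam search, confidence scoring and evaluation are architecture
#' agnostic; an adapter over a large pretrained encoder-decoder can expose
#' the same three closures (`encode_input`, `logprobs`, `n_params`).
#'
#' @param tokenizer a [word_tokenizer()] over the training corpus.
#' @param dim latent dimension (default 32).
#' @param seed seed for parameter initialization.
#' @param init_sd standard deviation of the Gaussian initializer.
#' @return An object of class `c("bow_seq2seq", "summarizer_backend")` with
#'   elements `tokenizer`, `par` (parameter environment), `encode_input(ids)`
#'   and `logprobs(state, prefix_ids)`.
#' @export
bow_seq2seq_backend <- function(tokenizer, dim = 32L, seed = 1L,
                                init_sd = 0.05) {
  V <- length(tokenizer$vocab)
  par <- new.env(parent = emptyenv())
  with_seed(derive_seed(seed, "init"), {
    par$W <- matrix(rnorm(dim * V, sd = init_sd), dim, V)
    par$b <- rnorm(dim, sd = init_sd)
    par$U <- matrix(rnorm(V * dim, sd = init_sd), V, dim)
    par$A <- matrix(rnorm(V * V, sd = init_sd), V, V)
    par$c <- rnorm(V, sd = init_sd)
  })
  backend <- list(
    tokenizer = tokenizer,
    dim = as.integer(dim),
    seed = as.integer(seed),
    par = par
  )
  backend$encode_input <- function(input_ids) {
    x <- bow_vector(input_ids, V)
    list(x = x, h = tanh(drop(par$W %*% x) + par$b))
  }
  backend$logprobs <- function(state, prefix_ids) {
    prev <- if (length(prefix_ids) == 0L) TOK_BOS else prefix_ids[length(prefix_ids)]
    logits <- drop(par$U %*% state$h) + par$A[prev, ] + par$c
    logits - logsumexp(logits)
  }
  backend$n_params <- function() dim * V + dim + V * dim + V * V + V
  structure(backend, class = c("bow_seq2seq", "summarizer_backend"))
}

# Normalized bag-of-words histogram over the vocabulary (special tokens
# contribute nothing).
bow_vector <- function(ids, V) {
  x <- numeric(V)
  ids <- ids[ids > TOK_UNK]
  if (length(ids) > 0L) {
    tab <- tabulate(ids, nbins = V)
    x <- tab / sum(tab)
  }
  x
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.summarizer_backend <- function(x, ...) {
  cat("<", class(x)[1], "> vocab ", length(x$tokenizer$vocab),
      ", latent dim ", x$dim, ", ", format(x$n_params(), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# Validate that a backend-emitted vector is a proper log-probability
# distribution over the vocabulary.
check_logprob_vector <- function(lp, V) {
  if (length(lp) != V || anyNA(lp) || any(!is.finite(lp) & lp > -Inf)) {
    abort("Backend emitted an invalid next-token distribution.")
  }
  total <- logsumexp(lp)
  if (abs(total) > 1e-6) {
    abort(paste0("Backend next-token distribution does not sum to 1 (log mass ",
                 format(total), ")."))
  }
  invisible(lp)
}
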