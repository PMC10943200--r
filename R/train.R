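#' Train a summarizer backend
#'
#' Fine-tunes the backend's parameters by Adam on token-level cross-entropy
#' between predicted and reference summaries, with early stopping on
#' validation loss. Inputs are truncated to `config$max_input_tokens` words
#' and targets to `config$max_target_tokens`; every target sequence is
#' framed as `<bos> ... <eos>` and the model is scored on predicting each
#' target token and the terminator.
#'
#' Training is deterministic given (`data`, `config`): one integer seed
#' drives initialization and per-epoch shuffling, and execution is single
#' threaded.
#'
#' @param backend a trainable backend, e.g. [bow_seq2seq_backend()].
#' @param train,validation tibbles with `input_text` and `target_text`.
#' @param config a [training_config()].
#' @return An object of class `goprose_fit`: the trained `backend` (best
#'   validation parameters restored), a `history` tibble of per-epoch
#'   train/validation loss, `config`, `best_epoch`.
#' @export
train_summarizer <- function(backend, train, validation, config = training_config()) {
  if (nrow(train) == 0L || nrow(validation) == 0L) {
    abort("train_summarizer() requires non-empty train and validation sets.")
  }
  tok <- backend$tokenizer
  enc <- function(df) {
    list(
      x = lapply(df$input_text, function(s)
        bow_vector(tokenize(tok, s, config$max_input_tokens),
                   length(tok$vocab))),
      y = lapply(df$target_text, function(s)
        c(tokenize(tok, s, config$max_target_tokens - 1L), TOK_EOS))
    )
  }
  tr <- enc(train)
  va <- enc(validation)
  par <- backend$par
  opt <- adam_state(par, config$learning_rate)
  n <- length(tr$x)
  history <- vector("list", config$epochs)
  best <- list(loss = Inf, epoch = 0L, par = NULL)
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, "shuffle", epoch), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    epoch_tokens <- 0L
    for (batch in batches) {
      g <- zero_grads(par)
      batch_loss <- 0
      batch_tokens <- 0L
      for (i in batch) {
        res <- seq_loss_grad(par, tr$x[[i]], tr$y[[i]], g)
        batch_loss <- batch_loss + res$loss
        batch_tokens <- batch_tokens + res$tokens
      }
      if (!is.finite(batch_loss)) {
        abort(paste0("Non-finite training loss at epoch ", epoch,
                     "; lower the learning rate."))
      }
      scale_grads(g, 1 / batch_tokens)
      adam_step(par, g, opt)
      epoch_loss <- epoch_loss + batch_loss
      epoch_tokens <- epoch_tokens + batch_tokens
    }
    train_loss <- epoch_loss / epoch_tokens
    val_loss <- dataset_loss(par, va)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss
    )
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, epoch = epoch, par = snapshot_params(par))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stopping_patience) break
    }
  }
  if (!is.null(best$par)) restore_params(par, best$par)
  structure(
    list(
      backend = backend,
      history = dplyr::bind_rows(history),
      config = config,
      best_epoch = best$epoch,
      best_val_loss = best$loss
    ),
    class = "goprose_fit"
  )
}

# Cross-entropy loss and (optionally) gradients for one sequence.
# x: bag-of-words input vector; y: target ids ending in <eos>.
# Accumulates gradients of summed token CE into environment g when given.
seq_loss_grad <- function(par, x, y, g = NULL) {
  h <- tanh(drop(par$W %*% x) + par$b)
  Tn <- length(y)
  prev <- c(TOK_BOS, y[-Tn])
  base <- drop(par$U %*% h) + par$c
  logits <- par$A[prev, , drop = FALSE] +
    matrix(base, Tn, length(base), byrow = TRUE)
  m <- apply(logits, 1L, max)
  Z <- log(rowSums(exp(logits - m))) + m
  loss <- sum(Z - logits[cbind(seq_len(Tn), y)])
  if (!is.null(g)) {
    P <- exp(logits - Z)
    P[cbind(seq_len(Tn), y)] <- P[cbind(seq_len(Tn), y)] - 1
    dbase <- colSums(P)
    g$U <- g$U + outer(dbase, h)
    g$c <- g$c + dbase
    dA <- rowsum(P, prev)
    rows <- as.integer(rownames(dA))
    g$A[rows, ] <- g$A[rows, , drop = FALSE] + dA
    dh <- drop(crossprod(par$U, dbase))
    dpre <- dh * (1 - h^2)
    g$W <- g$W + outer(dpre, x)
    g$b <- g$b + dpre
  }
  list(loss = loss, tokens = Tn)
}

# Mean per-token cross entropy over an encoded dataset.
dataset_loss <- function(par, data) {
  total <- 0
  tokens <- 0L
  for (i in seq_along(data$x)) {
    res <- seq_loss_grad(par, data$x[[i]], data$y[[i]])
    total <- total + res$loss
    tokens <- tokens + res$tokens
  }
  total / tokens
}

PARAM_NAMES <- c("W", "b", "U", "A", "c")

zero_grads <- function(par) {
  g <- new.env(parent = emptyenv())
  for (nm in PARAM_NAMES) g[[nm]] <- par[[nm]] * 0
  g
}

scale_grads <- function(g, s) {
  for (nm in PARAM_NAMES) g[[nm]] <- g[[nm]] * s
  invisible(g)
}

adam_state <- function(par, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$t <- 0L
  for (nm in PARAM_NAMES) {
    st[[paste0("m_", nm)]] <- par[[nm]] * 0
    st[[paste0("v_", nm)]] <- par[[nm]] * 0
  }
  st
}

adam_step <- function(par, g, st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (nm in PARAM_NAMES) {
    m <- st$beta1 * st[[paste0("m_", nm)]] + (1 - st$beta1) * g[[nm]]
    v <- st$beta2 * st[[paste0("v_", nm)]] + (1 - st$beta2) * g[[nm]]^2
    st[[paste0("m_", nm)]] <- m
    st[[paste0("v_", nm)]] <- v
    par[[nm]] <- par[[nm]] - st$lr * (m / bc1) / (sqrt(v / bc2) + st$eps)
  }
  invisible(par)
}

snapshot_params <- function(par) {
  setNames(lapply(PARAM_NAMES, function(nm) par[[nm]]), PARAM_NAMES)
}

restore_params <- function(par, snap) {
  for (nm in PARAM_NAMES) par[[nm]] <- snap[[nm]]
  invisible(par)
}

#' Write the training log as CSV
#'
#' Columns `epoch`, `train_loss`, `val_loss`.
#'
#' @param fit a `goprose_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(fit, path) {
  utils::write.csv(as.data.frame(fit$history), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.goprose_fit <- function(x, ...) {
  cat("<goprose_fit> ", nrow(x$history), " epoch(s), best validation loss ",
      format(round(x$best_val_loss, 4)), " at epoch ", x$best_epoch, "\n",
      sep = "")
  invisible(x)
}
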