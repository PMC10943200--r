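#' Beam-search decoding
#'
#' Length-bounded beam search over a backend's conditional next-token
#' distributions. At each step every live hypothesis is expanded over the
#' vocabulary and the `beam_width` highest-scoring hypotheses are kept;
#' a hypothesis that emits `<eos>` is frozen. The search stops when all
#' beams are finished or `max_tokens` tokens have been generated, and the
#' `beam_width` hypotheses alive at termination are returned ordered by
#' probability.
#'
#' Hypothesis scores are raw sums of token log-probabilities (so
#' `Prob(j) = exp(score)` is the plain product of next-token
#' probabilities), the form consumed by [confidence_score()]. An optional
#' length penalty divides the score by `length^length_penalty` for ranking,
#' off by default.
#'
#' @param backend a summarizer backend (anything providing `encode_input`,
#'   `logprobs` closures and a `tokenizer`).
#' @param input_ids integer token ids of the input document.
#' @param beam_width number of hypotheses, default 4.
#' @param max_tokens maximum generated tokens per hypothesis, default 256.
#' @param min_tokens minimum tokens before `<eos>` is allowed, default 1.
#' @param length_penalty exponent for length-normalized ranking; 0 disables.
#' @return An object of class `beam_result`: list with `hypotheses`
#'   (character), `token_ids` (list), `logprobs` (numeric, non-increasing),
#'   `n`.
#' @export
beam_search <- function(backend, input_ids, beam_width = 4L,
                        max_tokens = 256L, min_tokens = 1L,
                        length_penalty = 0) {
  stopifnot(beam_width >= 1L, max_tokens >= 1L)
  V <- length(backend$tokenizer$vocab)
  state <- backend$encode_input(input_ids)
  beams <- list(list(ids = integer(), logp = 0, done = FALSE))
  for (step in seq_len(max_tokens)) {
    if (all(vapply(beams, `[[`, logical(1), "done"))) break
    cand_ids <- list()
    cand_logp <- numeric()
    cand_done <- logical()
    for (b in beams) {
      if (b$done) {
        cand_ids <- c(cand_ids, list(b$ids))
        cand_logp <- c(cand_logp, b$logp)
        cand_done <- c(cand_done, TRUE)
        next
      }
      lp <- backend$logprobs(state, b$ids)
      check_logprob_vector(lp, V)
      if (step <= min_tokens) lp[TOK_EOS] <- -Inf
      lp[c(TOK_PAD, TOK_BOS)] <- -Inf
      keep <- utils::head(order(lp, decreasing = TRUE), beam_width)
      for (tok in keep) {
        cand_ids <- c(cand_ids, list(c(b$ids, tok)))
        cand_logp <- c(cand_logp, b$logp + lp[tok])
        cand_done <- c(cand_done, tok == TOK_EOS)
      }
    }
    rank_score <- if (length_penalty > 0) {
      cand_logp / (vapply(cand_ids, length, integer(1))^length_penalty)
    } else {
      cand_logp
    }
    top <- utils::head(order(rank_score, decreasing = TRUE), beam_width)
    beams <- lapply(top, function(k) {
      list(ids = cand_ids[[k]], logp = cand_logp[k], done = cand_done[k])
    })
  }
  ord <- order(vapply(beams, `[[`, numeric(1), "logp"), decreasing = TRUE)
  beams <- beams[ord]
  structure(
    list(
      hypotheses = vapply(beams, function(b)
        detokenize(backend$tokenizer, b$ids), character(1)),
      token_ids = lapply(beams, `[[`, "ids"),
      logprobs = vapply(beams, `[[`, numeric(1), "logp"),
      n = length(beams)
    ),
    class = "beam_result"
  )
}

#' Summarize GO documents with a trained model
#'
#' Runs beam search on each document and returns the top hypothesis with
#' its beam-probability confidence score.
#'
#' @param fit a `goprose_fit` (or a bare backend).
#' @param documents tibble with `accession` and `text` (or `input_text`).
#' @param beam_width beam width, default 4 (the confidence score's N).
#' @param max_tokens generation cap, default 256.
#' @param ... passed to [beam_search()].
#' @return tibble with `accession`, `summary`, `logprob`, `confidence`.
#' @export
generate_summaries <- function(fit, documents, beam_width = 4L,
                               max_tokens = 256L, ...) {
  backend <- if (inherits(fit, "goprose_fit")) fit$backend else fit
  text_col <- if ("text" %in% names(documents)) "text" else "input_text"
  purrr::map2_dfr(documents$accession, documents[[text_col]], function(acc, txt) {
    beam <- beam_search(
      backend,
      tokenize(backend$tokenizer, txt),
      beam_width = beam_width, max_tokens = max_tokens, ...
    )
    tibble::tibble(
      accession = acc,
      summary = beam$hypotheses[1],
      logprob = beam$logprobs[1],
      confidence = confidence_score(beam)
    )
  })
}

#' @export
print.beam_result <- function(x, ...) {
  cat("<beam_result> ", x$n, " hypothesis(es); top log-probability ",
      format(round(x$logprobs[1], 3)), "\n", sep = "")
  invisible(x)
}

#' Tidy a beam result
#'
#' @param x a `beam_result`.
#' @param ... unused.
#' @return tibble with `rank`, `hypothesis`, `logprob`, `prob`,
#'   `confidence` (each hypothesis's share of the beam's probability mass).
#' @export
tidy.beam_result <- function(x, ...) {
  shares <- exp(x$logprobs - logsumexp(x$logprobs))
  tibble::tibble(
    rank = seq_len(x$n),
    hypothesis = x$hypotheses,
    logprob = x$logprobs,
    prob = exp(x$logprobs),
    confidence = shares
  )
}
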