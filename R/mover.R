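#' Mover distances and similarities between paragraphs
#'
#' Earth-mover comparisons of a candidate and a reference paragraph under
#' an embedder, in three flavours:
#'
#' * `WMS` (word mover): each document is a bag of its words, weighted by
#'   count, each word represented by its embedding.
#' * `SMS` (sentence mover): a bag of sentences, each embedded as the mean
#'   of its word vectors and weighted by its length in words.
#' * `S+WMS`: the union of both bags with the combined weights
#'   renormalized.
#'
#' Each bag is normalized to total mass 1; the ground cost between atoms is
#' the Euclidean distance between embeddings, the distance is the optimal
#' value of the exact transportation problem ([solve_transport()]), and the
#' similarity is `exp(-distance)`, which maps identical documents to 1 and
#' decays towards 0 with increasing transport cost.
#'
#' @param candidate,reference non-empty texts.
#' @param embedder a text embedder (see [hash_embedder()]).
#' @param mode `"WMS"`, `"SMS"`, or `"S+WMS"`.
#' @param stopwords optional character vector of words excluded from word
#'   bags (none by default).
#' @return `mover_distance()` the transport cost (`>= 0`);
#'   `mover_similarity()` `exp(-distance)`, in `(0, 1]`.
#' @export
mover_similarity <- function(candidate, reference, embedder,
                             mode = c("WMS", "SMS", "S+WMS"),
                             stopwords = NULL) {
  exp(-mover_distance(candidate, reference, embedder, mode, stopwords))
}

#' @rdname mover_similarity
#' @export
mover_distance <- function(candidate, reference, embedder,
                           mode = c("WMS", "SMS", "S+WMS"),
                           stopwords = NULL) {
  mode <- match.arg(mode)
  if (!nzchar(trimws(candidate)) || !nzchar(trimws(reference))) {
    abort("Mover metrics require two non-empty texts.")
  }
  ba <- text_bag(candidate, embedder, mode, stopwords)
  bb <- text_bag(reference, embedder, mode, stopwords)
  cost <- euclidean_cost(ba$points, bb$points)
  solve_transport(cost, ba$weights, bb$weights)$cost
}

# Weighted embedding bag of a text: points is a dim x k matrix, weights sum
# to 1.
text_bag <- function(text, embedder, mode, stopwords = NULL) {
  bags <- list()
  if (mode %in% c("WMS", "S+WMS")) {
    words <- text_words(text)
    if (!is.null(stopwords)) words <- words[!words %in% tolower(stopwords)]
    if (length(words) == 0L) {
      abort(paste0("No words left to embed in text: '", text, "'"))
    }
    tab <- table(words)
    bags$word <- list(
      points = embedder$embed_words(names(tab)),
      weights = as.numeric(tab) / sum(tab)
    )
  }
  if (mode %in% c("SMS", "S+WMS")) {
    sents <- split_sentences(text)
    lens <- count_words(sents)
    bags$sentence <- list(
      points = vapply(sents, embedder$embed, numeric(embedder$dim)),
      weights = lens / sum(lens)
    )
  }
  if (length(bags) == 1L) {
    bag <- bags[[1]]
  } else {
    bag <- list(
      points = cbind(bags$word$points, bags$sentence$points),
      weights = c(bags$word$weights, bags$sentence$weights) / 2
    )
  }
  bag$points <- matrix(bag$points, nrow = embedder$dim)
  bag
}

#' Split a paragraph into sentences
#'
#' Deterministic rule: split after sentence-final punctuation (`.`, `!`,
#' `?`) followed by whitespace and an uppercase letter. A text that yields
#' no usable sentence (e.g. only whitespace) falls back to a single
#' sentence with a warning; a text without terminal punctuation is simply
#' one sentence.
#'
#' @param text a single string.
#' @return character vector of sentences.
#' @export
split_sentences <- function(text) {
  sents <- strsplit(text, "(?<=[.!?])\\s+(?=[A-Z])", perl = TRUE)[[1]]
  sents <- trimws(sents)
  sents <- sents[nzchar(sents)]
  if (length(sents) == 0L) {
    warn("Text could not be segmented; treating it as one sentence.")
    return(trimws(text))
  }
  sents
}

euclidean_cost <- function(p, q) {
  pn <- colSums(p^2)
  qn <- colSums(q^2)
  d2 <- outer(pn, qn, `+`) - 2 * crossprod(p, q)
  # the expansion leaves O(eps) noise where atoms coincide; identical
  # atoms must cost exactly zero for the metric identity axiom
  d2[d2 < 1e-10] <- 0
  sqrt(d2)
}
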