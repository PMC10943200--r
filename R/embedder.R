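#' Text embedders
#'
#' Evaluation metrics consume an *embedder*: a deterministic map from text
#' to a fixed-dimension real vector (and from individual words to vectors,
#' for the mover metrics). The package ships a self-contained hash embedder
#' for fully offline use; adapters over pretrained sentence-embedding
#' models can implement the same contract (`name`, `dim`, `embed(text)`,
#' `embed_words(words)`).
#'
#' The hash embedder assigns every word a unit vector drawn from a
#' generator seeded by a hash of the word itself (mixed with the embedder
#' seed), and embeds a text as the mean of its word vectors. It is
#' deterministic across sessions and vocabulary-free; in high dimension,
#' unrelated texts embed nearly orthogonally while shared words pull the
#' cosine up, which is the property the evaluation suite needs.
#'
#' @param dim embedding dimension (default 256).
#' @param seed integer seed mixed into the per-word hash.
#' @param name embedder label used in reports.
#' @return An object of class `c("hash_embedder", "text_embedder")`.
#' @export
hash_embedder <- function(dim = 256L, seed = 1L, name = paste0("hash", seed)) {
  force(dim); force(seed); force(name)
  cache <- new.env(parent = emptyenv())
  word_vec <- function(w) {
    v <- cache[[w]]
    if (is.null(v)) {
      v <- with_seed(derive_seed(seed, "word", w), rnorm(dim))
      v <- v / sqrt(sum(v^2))
      cache[[w]] <- v
    }
    v
  }
  emb <- list(
    name = name,
    dim = as.integer(dim),
    embed_words = function(words) {
      out <- vapply(tolower(words), word_vec, numeric(dim))
      matrix(out, nrow = dim, dimnames = list(NULL, words))
    },
    embed = function(text) {
      words <- text_words(text)
      if (length(words) == 0L) {
        abort(paste0("Cannot embed empty text: '", text, "'"))
      }
      v <- vapply(words, word_vec, numeric(dim))
      rowMeans(matrix(v, nrow = dim))
    }
  )
  structure(emb, class = c("hash_embedder", "text_embedder"))
}

#' The default evaluation embedder set
#'
#' Three independent hash embedders, mirroring the three-embedder averaging
#' used by the evaluation protocol.
#'
#' @param dim embedding dimension.
#' @param seed base seed; the three embedders use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return list of three embedders.
#' @export
default_embedders <- function(dim = 256L, seed = 1L) {
  lapply(0:2, function(k) {
    hash_embedder(dim = dim, seed = seed + k, name = paste0("hash", seed + k))
  })
}

text_words <- function(text) {
  words <- strsplit(tolower(text), "\\s+")[[1]]
  words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", words)
  words[nzchar(words)]
}

#' Cosine similarity between two texts under an embedder
#'
#' @param candidate,reference non-empty texts.
#' @param embedder a text embedder.
#' @return cosine similarity in `[-1, 1]`.
#' @export
embedding_cosine <- function(candidate, reference, embedder) {
  if (!nzchar(trimws(candidate)) || !nzchar(trimws(reference))) {
    abort("embedding_cosine() requires two non-empty texts.")
  }
  u <- embedder$embed(candidate)
  v <- embedder$embed(reference)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort(paste0("Zero-norm embedding for text: '",
                 if (nu == 0) candidate else reference, "'"))
  }
  sum(u * v) / (nu * nv)
}

#' Average embedding score across an embedder panel
#'
#' The arithmetic mean of per-embedder cosine similarities — the package's
#' primary summary-quality score, averaged over three embedders by default.
#'
#' @param candidate,reference texts.
#' @param embedders non-empty list of embedders, e.g. [default_embedders()].
#' @return mean cosine similarity.
#' @export
average_embedding_score <- function(candidate, reference,
                                    embedders = default_embedders()) {
  if (length(embedders) == 0L) {
    abort("average_embedding_score() needs at least one embedder.")
  }
  mean(vapply(embedders, function(e)
    embedding_cosine(candidate, reference, e), numeric(1)))
}
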