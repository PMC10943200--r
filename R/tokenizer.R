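# Special token ids shared by every backend: padding, beginning/end of
# sequence, unknown word.
TOK_PAD <- 1L
TOK_BOS <- 2L
TOK_EOS <- 3L
TOK_UNK <- 4L
SPECIAL_TOKENS <- c("<pad>", "<bos>", "<eos>", "<unk>")

#' Build a word-level tokenizer
#'
#' Lowercases, splits on whitespace, and assigns integer ids to every word
#' seen in the training texts, after four reserved special tokens
#' (`<pad>`, `<bos>`, `<eos>`, `<unk>`). Ordering is by descending frequency
#' with alphabetical ties, so the vocabulary is a pure function of the
#' input corpus.
#'
#' @param texts character vector of training texts.
#' @param max_vocab optional cap on vocabulary size (most frequent kept).
#' @return An object of class `word_tokenizer` with `$vocab` (character
#'   vector, index = id), usable with [tokenize()] and [detokenize()].
#' @export
word_tokenizer <- function(texts, max_vocab = Inf) {
  words <- unlist(strsplit(tolower(texts), "\\s+"), use.names = FALSE)
  words <- words[nzchar(words)]
  freq <- sort(table(words), decreasing = TRUE)
  ord <- order(-as.integer(freq), names(freq))
  vocab_words <- names(freq)[ord]
  if (is.finite(max_vocab)) {
    vocab_words <- utils::head(vocab_words, max_vocab)
  }
  vocab <- c(SPECIAL_TOKENS, vocab_words)
  structure(
    list(vocab = vocab,
         index = setNames(seq_along(vocab), vocab)),
    class = "word_tokenizer"
  )
}

#' Encode text to token ids / decode ids back to text
#'
#' @param tokenizer a [word_tokenizer()].
#' @param text a single string.
#' @param max_tokens optional cap; longer sequences are truncated.
#' @return `tokenize()` an integer vector of ids (`<unk>` for out-of-vocab
#'   words); `detokenize()` a single string with special tokens dropped.
#' @export
tokenize <- function(tokenizer, text, max_tokens = Inf) {
  words <- strsplit(tolower(text), "\\s+")[[1]]
  words <- words[nzchar(words)]
  ids <- unname(tokenizer$index[words])
  ids[is.na(ids)] <- TOK_UNK
  if (length(ids) > max_tokens) ids <- ids[seq_len(max_tokens)]
  as.integer(ids)
}

#' @rdname tokenize
#' @param ids integer vector of token ids.
#' @export
detokenize <- function(tokenizer, ids) {
  ids <- ids[!ids %in% c(TOK_PAD, TOK_BOS, TOK_EOS)]
  paste(tokenizer$vocab[ids], collapse = " ")
}
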