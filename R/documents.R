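#' Build concatenated GO-description documents
#'
#' For each protein, joins the free-text definitions of its annotated GO
#' terms into one document — the summarizer's input. Definitions are joined
#' with a single space in a deterministic order, sentence-terminated (a `.`
#' is appended to any definition lacking terminal punctuation), and the
#' joined text is truncated to at most `max_tokens` whitespace-delimited
#' words.
#'
#' @param annotations long tibble with columns `accession`, `go_id`.
#' @param terms terms tibble as returned by [read_obo()].
#' @param max_tokens word cap on the document (default 1024, the model input
#'   budget).
#' @param order `"go_id"` (ascending GO accession, the default) or
#'   `"namespace"` (grouped BP, CC, MF, ascending id within each).
#' @param missing `"strict"` errors on GO ids absent from `terms`;
#'   `"lenient"` skips them and reports the skipped ids in a warning.
#' @return A tibble with one row per protein: `accession`, `text`,
#'   `token_count` (words after truncation), `truncated`.
#' @examples
#' terms <- tibble::tibble(
#'   go_id = c("GO:0000001", "GO:0000002"),
#'   namespace = c("MF", "MF"),
#'   name = c("tRNA binding", "endonuclease"),
#'   definition = c("Binding to a transfer RNA.", "Has endonuclease activity.")
#' )
#' anns <- tibble::tibble(accession = "P1", go_id = c("GO:0000001", "GO:0000002"))
#' build_documents(anns, terms)
#' @export
build_documents <- function(annotations, terms,
                            max_tokens = 1024L,
                            order = c("go_id", "namespace"),
                            missing = c("strict", "lenient")) {
  order <- match.arg(order)
  missing <- match.arg(missing)
  stopifnot(max_tokens >= 1L)
  if (nrow(annotations) == 0L) {
    abort("Cannot build documents from an empty annotation table.")
  }
  absent <- setdiff(unique(annotations$go_id), terms$go_id)
  if (length(absent) > 0L) {
    if (missing == "strict") {
      abort(paste0("GO id(s) missing from the vocabulary: ",
                   paste(absent, collapse = ", ")))
    }
    warn(paste0("Skipping GO id(s) missing from the vocabulary: ",
                paste(absent, collapse = ", ")))
    annotations <- dplyr::filter(annotations, !.data$go_id %in% absent)
    if (nrow(annotations) == 0L) {
      abort("All GO ids were missing from the vocabulary.")
    }
  }
  ann <- annotations |>
    dplyr::distinct(.data$accession, .data$go_id) |>
    dplyr::left_join(
      dplyr::select(terms, "go_id", "namespace", "definition"),
      by = "go_id"
    )
  ann <- if (order == "namespace") {
    dplyr::arrange(ann, .data$accession,
                   match(.data$namespace, GO_NAMESPACES), .data$go_id)
  } else {
    dplyr::arrange(ann, .data$accession, .data$go_id)
  }
  ann |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      text = paste(normalize_definition(.data$definition), collapse = " "),
      .groups = "drop"
    ) |>
    dplyr::mutate(truncate_words(.data$text, max_tokens))
}

# Collapse internal whitespace and guarantee sentence-terminal punctuation,
# so documents segment cleanly for the sentence-mover metrics.
normalize_definition <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  needs_dot <- !grepl("[.!?]$", x)
  x[needs_dot] <- paste0(x[needs_dot], ".")
  x
}

# Truncate each text to `max_tokens` whitespace words; returns a tibble of
# text / token_count / truncated suitable for mutate() splicing.
truncate_words <- function(text, max_tokens) {
  words <- strsplit(text, " ", fixed = TRUE)
  n <- lengths(words)
  truncated <- n > max_tokens
  text[truncated] <- vapply(
    words[truncated],
    function(w) paste(w[seq_len(max_tokens)], collapse = " "),
    character(1)
  )
  tibble::tibble(
    text = text,
    token_count = pmin(n, max_tokens),
    truncated = truncated
  )
}

#' Count whitespace-delimited words
#'
#' @param text character vector.
#' @return integer vector of word counts (0 for empty strings).
#' @export
count_words <- function(text) {
  n <- lengths(strsplit(text, "\\s+"))
  n[!nzchar(trimws(text))] <- 0L
  n
}

#' Write / read GO documents as JSONL
#'
#' One JSON object per line with fields `accession`, `text`, `token_count`,
#' `truncated`.
#'
#' @param documents tibble from [build_documents()].
#' @param path file path.
#' @return `write_documents_jsonl()` returns `path` invisibly;
#'   `read_documents_jsonl()` returns the documents tibble.
#' @export
write_documents_jsonl <- function(documents, path) {
  write_jsonl(documents, path)
}

#' @rdname write_documents_jsonl
#' @export
read_documents_jsonl <- function(path) {
  out <- read_jsonl(path)
  out$token_count <- as.integer(out$token_count)
  out
}

write_jsonl <- function(df, path) {
  lines <- vapply(
    seq_len(nrow(df)),
    function(i) jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  dplyr::bind_rows(lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
}
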