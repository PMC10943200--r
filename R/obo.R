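#' Read GO terms from an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas of a Gene Ontology OBO 1.2 file into a tibble of
#' term definitions. Only the fields the summarization pipeline needs are
#' read: `id`, `name`, `namespace`, `def` and `is_obsolete`. The ontology
#' graph (`is_a`, `relationship`) is deliberately ignored; the pipeline uses
#' term descriptions, not the DAG.
#'
#' The quoted definition string is unescaped and the trailing dbxref bracket
#' list (`[...]`) is stripped, so `GO:0000049` yields the plain text
#' `"Binding to a transfer RNA."`.
#'
#' @param path path to an OBO 1.2 file, or a character vector of its lines.
#' @return A tibble with columns `go_id`, `namespace` (one of `"BP"`, `"CC"`,
#'   `"MF"`), `name`, and `definition`, one row per non-obsolete term.
#'   Obsolete terms are skipped; their count is reported with a message.
#' @seealso [write_obo()] for the matching writer, [build_documents()] for
#'   the downstream consumer.
#' @export
read_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  # split into stanzas at headers like [Term] / [Typedef]
  header_idx <- grep("^\\[", lines)
  if (length(header_idx) == 0L) {
    return(empty_terms())
  }
  bounds <- c(header_idx, length(lines) + 1L)
  stanzas <- lapply(seq_along(header_idx), function(i) {
    lines[header_idx[i]:(bounds[i + 1L] - 1L)]
  })
  stanzas <- stanzas[vapply(stanzas, function(s) s[1] == "[Term]", logical(1))]
  n_obsolete <- 0L
  rows <- vector("list", length(stanzas))
  for (i in seq_along(stanzas)) {
    s <- stanzas[[i]]
    get_field <- function(key) {
      hit <- grep(paste0("^", key, ":"), s, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      trimws(sub(paste0("^", key, ":\\s*"), "", hit[1]))
    }
    if (identical(get_field("is_obsolete"), "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- get_field("id")
    ns <- get_field("namespace")
    if (is.na(id) || is.na(ns)) {
      abort(paste0(
        "Malformed [Term] stanza (", if (is.na(id)) "missing id" else id,
        "): both 'id' and 'namespace' are required."
      ))
    }
    if (!ns %in% names(OBO_NAMESPACES)) {
      abort(paste0("Unknown namespace '", ns, "' in stanza ", id, "."))
    }
    rows[[i]] <- tibble::tibble(
      go_id = id,
      namespace = unname(OBO_NAMESPACES[[ns]]),
      name = get_field("name") %||% NA_character_,
      definition = parse_obo_def(get_field("def"))
    )
  }
  if (n_obsolete > 0L) {
    inform(paste0("Skipped ", n_obsolete, " obsolete term(s)."))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty_terms() else out
}

empty_terms <- function() {
  tibble::tibble(
    go_id = character(), namespace = character(),
    name = character(), definition = character()
  )
}

# Extract the quoted string of a `def:` value, unescape \" and \\, and drop
# the trailing dbxref bracket list.
parse_obo_def <- function(x) {
  if (is.na(x)) return(NA_character_)
  m <- regmatches(x, regexpr('^"(\\\\.|[^"\\\\])*"', x))
  if (length(m) == 0L) return(trimws(x))
  inner <- substr(m, 2L, nchar(m) - 1L)
  inner <- gsub('\\\\(["\\\\])', "\\1", inner)
  trimws(inner)
}

#' Write GO terms to a minimal OBO 1.2 file
#'
#' Emits one `[Term]` stanza per row with `id`, `name`, `namespace`, and a
#' quoted `def` line, producing a file that [read_obo()] round-trips
#' losslessly. Used mainly by the synthetic fixture generator so the reader
#' is exercised on disk.
#'
#' @param terms tibble with columns `go_id`, `namespace`, `name`,
#'   `definition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(terms, path) {
  ns_long <- names(OBO_NAMESPACES)[match(terms$namespace, OBO_NAMESPACES)]
  esc <- gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", terms$definition))
  stanzas <- paste0(
    "[Term]\n",
    "id: ", terms$go_id, "\n",
    "name: ", terms$name, "\n",
    "namespace: ", ns_long, "\n",
    "def: \"", esc, "\" []\n"
  )
  writeLines(c("format-version: 1.2", "", stanzas), path)
  invisible(path)
}
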