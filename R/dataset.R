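#' Assemble a per-section paired dataset
#'
#' Pairs each representative protein's GO document with its reference
#' paragraph for one UniProt section (Function, Subunit or Pathway).
#' Proteins lacking a non-empty paragraph for the requested section are
#' simply excluded — UniProt entries often carry only a subset of the three
#' descriptions, which is why each section gets its own dataset.
#'
#' @param annotations long tibble with `accession`, `go_id`, already reduced
#'   to cluster representatives.
#' @param terms terms tibble ([read_obo()]).
#' @param references tibble with columns `accession`, `section`, `paragraph`.
#' @param section one of `"Function"`, `"Subunit"`, `"Pathway"`.
#' @param max_tokens input document word cap (default 1024).
#' @param ... passed on to [build_documents()].
#' @return A tibble of section records: `accession`, `section`,
#'   `input_text`, `target_text`, `token_count`, `truncated`.
#' @export
assemble_section <- function(annotations, terms, references, section,
                             max_tokens = 1024L, ...) {
  section <- match.arg(section, GO_SECTIONS)
  refs <- references |>
    dplyr::filter(.data$section == !!section, nzchar(trimws(.data$paragraph))) |>
    dplyr::distinct(.data$accession, .keep_all = TRUE)
  keep <- annotations |>
    dplyr::filter(.data$accession %in% refs$accession)
  if (nrow(keep) == 0L) {
    return(tibble::tibble(
      accession = character(), section = character(),
      input_text = character(), target_text = character(),
      token_count = integer(), truncated = logical()
    ))
  }
  build_documents(keep, terms, max_tokens = max_tokens, ...) |>
    dplyr::inner_join(dplyr::select(refs, "accession", "paragraph"),
                      by = "accession") |>
    dplyr::transmute(
      accession = .data$accession,
      section = !!section,
      input_text = .data$text,
      target_text = .data$paragraph,
      token_count = .data$token_count,
      truncated = .data$truncated
    )
}

#' Split-size arithmetic for an 80/10/10 split
#'
#' Train and validation take `floor(0.8 n)` and `floor(0.1 n)` records; the
#' remainder goes to test. This reproduces, e.g., 97,600 -> 78,080/9,760/9,760
#' and 14,600 -> 11,680/1,460/1,460.
#'
#' @param n number of records.
#' @param fractions length-3 numeric, must sum to 1.
#' @return named integer vector `c(train, validation, test)`.
#' @export
split_sizes <- function(n, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  c(train = n_train, validation = n_val, test = n - n_train - n_val)
}

#' Split section records into train / validation / test
#'
#' Shuffles the records with a seeded generator and partitions them
#' 80/10/10 by [split_sizes()]. Records are keyed by row, and each section
#' dataset holds one row per protein, so a protein never straddles splits
#' within a section.
#'
#' @param records tibble of section records ([assemble_section()]); any
#'   tibble works, rows are the unit.
#' @param seed integer seed for the shuffle.
#' @param fractions split fractions, default `c(0.8, 0.1, 0.1)`.
#' @return The input tibble, reordered to the shuffle order, with a `split`
#'   factor column (`train`/`validation`/`test`).
#' @export
split_dataset <- function(records, seed = 1L, fractions = c(0.8, 0.1, 0.1)) {
  n <- nrow(records)
  if (n < 3L) {
    abort("split_dataset() needs at least 3 records to populate all parts.")
  }
  sizes <- split_sizes(n, fractions)
  perm <- with_seed(seed, sample.int(n))
  out <- records[perm, , drop = FALSE]
  out$split <- factor(
    rep(c("train", "validation", "test"), times = sizes),
    levels = c("train", "validation", "test")
  )
  out
}

#' Write / read a split dataset as JSONL files
#'
#' One file per split named `<stem>-<split>.jsonl`, each line an object with
#' `accession`, `section`, `input_text`, `target_text`. Line order is the
#' split order.
#'
#' @param records split tibble from [split_dataset()].
#' @param dir output directory.
#' @param stem file-name stem (default the section of the first record).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset_jsonl <- function(records, dir, stem = NULL) {
  stem <- stem %||% tolower(as.character(records$section[1]))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (part in levels(records$split)) {
    path <- file.path(dir, paste0(stem, "-", part, ".jsonl"))
    write_jsonl(
      records[records$split == part,
              c("accession", "section", "input_text", "target_text")],
      path
    )
    paths[part] <- path
  }
  invisible(paths)
}

#' @rdname write_dataset_jsonl
#' @param path a single JSONL file to read back.
#' @export
read_dataset_jsonl <- function(path) {
  read_jsonl(path)
}

#' Read reference paragraphs
#'
#' Accepts the TSV layout `accession<TAB>section<TAB>paragraph` (no header)
#' or JSONL with the same fields.
#'
#' @param path input file.
#' @param format `"tsv"` or `"jsonl"`.
#' @return tibble with `accession`, `section`, `paragraph`.
#' @export
read_references <- function(path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    out <- read_jsonl(path)
  } else {
    df <- utils::read.delim(path, header = FALSE, quote = "",
                            col.names = c("accession", "section", "paragraph"),
                            stringsAsFactors = FALSE)
    out <- tibble::as_tibble(df)
  }
  bad <- setdiff(unique(out$section), GO_SECTIONS)
  if (length(bad) > 0L) {
    abort(paste0("Unknown section label(s): ", paste(bad, collapse = ", ")))
  }
  out
}

#' Write reference paragraphs as TSV
#'
#' @param references tibble with `accession`, `section`, `paragraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_references <- function(references, path) {
  writeLines(
    paste(references$accession, references$section, references$paragraph,
          sep = "\t"),
    path
  )
  invisible(path)
}
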