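#' Read protein GO annotations
#'
#' Reads protein-to-GO-term annotations from either a GAF 2.x gene
#' association file (tab-separated; accession in column 2, GO id in column 5;
#' `!` comment lines ignored) or a simple two-column TSV dialect
#' (`accession<TAB>comma-separated GO ids`). Rows sharing an accession are
#' merged and duplicate GO ids collapse, so the result is one row per
#' (accession, GO id) pair.
#'
#' @param path path to the annotation file, or a character vector of lines.
#' @param dialect `"gaf"` or `"tsv"`.
#' @return A tibble in long format with columns `accession` and `go_id`;
#'   the package's standard annotation-set representation. Proteins with no
#'   valid GO id are dropped with a warning.
#' @export
read_annotations <- function(path, dialect = c("gaf", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble::tibble(accession = character(), go_id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "gaf") {
    acc <- vapply(fields, function(f) if (length(f) >= 5L) f[2] else NA_character_, character(1))
    ids <- vapply(fields, function(f) if (length(f) >= 5L) f[5] else NA_character_, character(1))
    bad_row <- is.na(acc) | is.na(ids)
    if (any(bad_row)) {
      abort(paste0("GAF row(s) with fewer than 5 columns at line(s) ",
                   paste(line_no[bad_row], collapse = ", "), "."))
    }
    long <- tibble::tibble(accession = acc, go_id = ids, line = line_no)
  } else {
    acc <- vapply(fields, `[`, character(1), 1L)
    ids <- lapply(fields, function(f) {
      if (length(f) < 2L) character() else trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
    })
    long <- tibble::tibble(
      accession = rep(acc, lengths(ids)),
      go_id = unlist(ids, use.names = FALSE) %||% character(),
      line = rep(line_no, lengths(ids))
    )
    dropped <- acc[lengths(ids) == 0L]
    if (length(dropped) > 0L) {
      warn(paste0("Dropped accession(s) with no GO ids: ",
                  paste(unique(dropped), collapse = ", ")))
    }
  }
  bad <- !is_go_id(long$go_id)
  if (any(bad)) {
    abort(paste0(
      "Invalid GO id(s): ",
      paste0("'", long$go_id[bad], "' (line ", long$line[bad], ")", collapse = ", ")
    ))
  }
  dplyr::distinct(long, .data$accession, .data$go_id)
}

#' Write annotations in the simple TSV dialect
#'
#' One line per protein: `accession<TAB>GO:...,GO:...` with ids sorted
#' ascending. Round-trips through [read_annotations()] with
#' `dialect = "tsv"`.
#'
#' @param annotations long tibble with `accession`, `go_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  by_acc <- annotations |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(ids = paste(sort(unique(.data$go_id)), collapse = ","), .groups = "drop")
  writeLines(paste0(by_acc$accession, "\t", by_acc$ids), path)
  invisible(path)
}

#' Write annotations as a minimal GAF 2.2 file
#'
#' Emits the 17-column GAF layout with only the columns the reader consumes
#' populated meaningfully (DB, accession, symbol, GO id, evidence, aspect);
#' the rest are placeholders. Used by the fixture generator so
#' [read_annotations()] is exercised against an on-disk GAF.
#'
#' @param annotations long tibble with `accession`, `go_id`.
#' @param terms optional terms tibble (for the aspect column); aspect falls
#'   back to `"P"` when missing.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, terms = NULL) {
  aspect <- rep("P", nrow(annotations))
  if (!is.null(terms)) {
    ns <- terms$namespace[match(annotations$go_id, terms$go_id)]
    aspect <- dplyr::recode(ns, BP = "P", CC = "C", MF = "F", .default = "P")
  }
  rows <- paste(
    "SYNDB", annotations$accession, annotations$accession, "",
    annotations$go_id, "SYN:0000000", "IEA", "", aspect,
    "", "", "protein", "taxon:0000", "20220211", "SYNDB", "", "",
    sep = "\t"
  )
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

# Split a long annotation tibble into a named list of GO id character sets.
annotation_sets <- function(annotations) {
  split(annotations$go_id, annotations$accession)
}
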