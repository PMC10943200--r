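#' Fraction of paired wins
#'
#' The fraction of paired entries where system A's score strictly exceeds
#' system B's; ties count as non-wins. This is the head-to-head statistic
#' used to compare a fine-tuned summarizer against an untrained or baseline
#' one.
#'
#' @param scores_a,scores_b equal-length numeric vectors, paired by entry.
#' @return fraction in `[0, 1]`.
#' @export
win_fraction <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    abort("win_fraction() requires equal-length paired score vectors.")
  }
  mean(scores_a > scores_b)
}

#' Per-entry evaluation report
#'
#' Scores each generated summary against its reference: per-embedder
#' cosine, their average, the three mover similarities under the first
#' embedder, and the score class (high `[0.8, 1.0]`, moderate `[0.5, 0.8)`,
#' low `[0, 0.5)`). Any columns already present in `entries` (for example
#' `confidence` from [generate_summaries()]) are carried through.
#'
#' @param entries tibble with `accession`, `summary` (candidate) and
#'   `target_text` or `reference` columns.
#' @param embedders embedder panel, default [default_embedders()].
#' @param mover_modes mover metrics to compute, default all three; set to
#'   `character()` to skip the transport solves.
#' @return An object of class `c("score_report", "tbl_df")`: one row per
#'   entry with the score columns appended.
#' @export
score_report <- function(entries, embedders = default_embedders(),
                         mover_modes = c("WMS", "SMS", "S+WMS")) {
  ref_col <- if ("reference" %in% names(entries)) "reference" else "target_text"
  stopifnot(ref_col %in% names(entries), "summary" %in% names(entries))
  rows <- purrr::map2_dfr(entries$summary, entries[[ref_col]], function(cand, ref) {
    cand_ok <- nzchar(trimws(cand))
    cos <- if (cand_ok) {
      vapply(embedders, function(e) embedding_cosine(cand, ref, e), numeric(1))
    } else {
      rep(0, length(embedders))
    }
    out <- setNames(as.list(cos), paste0("cosine_", vapply(embedders, `[[`, character(1), "name")))
    out$embedding_score <- mean(cos)
    for (mode in mover_modes) {
      col <- paste0("similarity_", tolower(gsub("\\+", "", mode)))
      out[[col]] <- if (cand_ok) {
        mover_similarity(cand, ref, embedders[[1]], mode)
      } else {
        0
      }
    }
    tibble::as_tibble(out)
  })
  out <- dplyr::bind_cols(entries, rows)
  out$score_class <- score_class(out$embedding_score)
  class(out) <- c("score_report", class(out))
  out
}

#' Summarize a score report
#'
#' @param x a `score_report`.
#' @param ... unused.
#' @return One-row tibble with the number of entries, mean embedding score,
#'   mean mover similarities (where computed), mean confidence (if
#'   present), and the high/moderate/low class counts.
#' @export
glance.score_report <- function(x, ...) {
  out <- tibble::tibble(
    n = nrow(x),
    mean_embedding_score = mean(x$embedding_score)
  )
  for (col in intersect(c("similarity_wms", "similarity_sms", "similarity_swms",
                          "confidence"), names(x))) {
    out[[paste0("mean_", sub("^similarity_", "", col))]] <- mean(x[[col]])
  }
  counts <- table(x$score_class)
  out$n_high <- as.integer(counts[["high"]])
  out$n_moderate <- as.integer(counts[["moderate"]])
  out$n_low <- as.integer(counts[["low"]])
  out
}

#' Write a score report as TSV
#'
#' Numeric columns are written with 4 decimal places.
#'
#' @param report a `score_report` (or any tibble).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  df <- as.data.frame(report)
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- formatC(df[[col]], format = "f", digits = 4)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
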