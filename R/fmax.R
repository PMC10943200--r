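#' Protein-centric Fmax for GO term predictions
#'
#' The standard protein-function evaluation score: for every decision
#' threshold `t`, precision is averaged over the proteins with at least one
#' prediction scoring `>= t`, recall is averaged over all proteins carrying
#' ground-truth terms, and Fmax is the maximum over thresholds of the
#' harmonic mean of the two. Fmax ranges from 0 to 1, with 1 for perfect
#' agreement with the ground-truth GO terms.
#'
#' @param predictions tibble with `accession`, `go_id`, `score` in `[0, 1]`.
#' @param truth tibble with `accession`, `go_id` (the ground-truth
#'   annotations); every protein appearing here counts towards recall.
#' @param thresholds decision-threshold grid, default `seq(0.01, 1, 0.01)`.
#' @return list with `fmax`, `threshold` (the argmax), and `curve`
#'   (tibble of `threshold`, `precision`, `recall`, `f1`).
#' @export
compute_fmax <- function(predictions, truth,
                         thresholds = seq(0.01, 1, by = 0.01)) {
  if (nrow(truth) == 0L) {
    abort("compute_fmax() requires non-empty ground truth.")
  }
  stopifnot(all(predictions$score >= 0 & predictions$score <= 1))
  # guard against accumulated floating-point noise in seq()-built grids
  thresholds <- round(thresholds, 9)
  truth_sets <- annotation_sets(truth)
  pred_by_acc <- split(predictions[c("go_id", "score")], predictions$accession)
  n_truth <- length(truth_sets)
  curve <- purrr::map_dfr(thresholds, function(t) {
    prec <- c(); rec <- numeric(n_truth)
    for (k in seq_along(truth_sets)) {
      acc <- names(truth_sets)[k]
      tset <- unique(truth_sets[[k]])
      p <- pred_by_acc[[acc]]
      hit <- if (is.null(p)) character() else unique(p$go_id[p$score >= t])
      if (length(hit) > 0L) {
        prec <- c(prec, length(intersect(hit, tset)) / length(hit))
      }
      rec[k] <- length(intersect(hit, tset)) / length(tset)
    }
    precision <- if (length(prec) > 0L) mean(prec) else NA_real_
    recall <- mean(rec)
    f1 <- if (!is.na(precision) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      0
    }
    tibble::tibble(threshold = t, precision = precision, recall = recall, f1 = f1)
  })
  best <- which.max(curve$f1)
  list(fmax = curve$f1[best], threshold = curve$threshold[best], curve = curve)
}

#' Read GO predictions from TSV
#'
#' Layout: `accession<TAB>GO id<TAB>score`, no header.
#'
#' @param path input path.
#' @return tibble with `accession`, `go_id`, `score`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("accession", "go_id", "score"),
                          stringsAsFactors = FALSE)
  bad <- !is_go_id(df$go_id)
  if (any(bad)) {
    abort(paste0("Invalid GO id(s) in predictions: ",
                 paste(unique(df$go_id[bad]), collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Write GO predictions as TSV
#'
#' @param predictions tibble with `accession`, `go_id`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  writeLines(
    paste(predictions$accession, predictions$go_id,
          formatC(predictions$score, format = "f", digits = 4), sep = "\t"),
    path
  )
  invisible(path)
}
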