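#' Configuration for GO deletion / addition robustness experiments
#'
#' Defaults follow the robustness protocols of the full-scale study. For
#' deletion: targets carry exactly 8 terms of the probed category, at least
#' one term in each other category, and 10-24 terms in total; 1-7 category
#' terms are removed. For addition: exactly 5 category terms, 7-15 in
#' total, targets whose original document exceeds 512 words are dropped
#' (room must remain for the added descriptions), and 1-10 irrelevant terms
#' are added. Each (target, k) cell is perturbed in 3 independent seeded
#' trials.
#'
#' @param mode `"deletion"` or `"addition"`.
#' @param category the probed GO namespace: `"BP"`, `"CC"` or `"MF"`.
#' @param exact_category_count required category term count (8 deletion / 5
#'   addition when `NULL`).
#' @param total_range length-2 integer range of total term counts
#'   (`c(10, 24)` deletion / `c(7, 15)` addition when `NULL`).
#' @param k_range length-2 range of removed/added counts (`c(1, 7)` /
#'   `c(1, 10)` when `NULL`).
#' @param max_doc_tokens_for_addition document word cap for addition
#'   targets (default 512).
#' @param trials perturbation trials per (target, k), default 3.
#' @param seed base seed; trial seeds are derived per (target, k, trial).
#' @return list of class `perturbation_config`.
#' @export
perturbation_config <- function(mode = c("deletion", "addition"),
                                category = c("BP", "CC", "MF"),
                                exact_category_count = NULL,
                                total_range = NULL,
                                k_range = NULL,
                                max_doc_tokens_for_addition = 512L,
                                trials = 3L,
                                seed = 1L) {
  mode <- match.arg(mode)
  category <- match.arg(category)
  exact_category_count <- exact_category_count %||%
    if (mode == "deletion") 8L else 5L
  total_range <- total_range %||%
    if (mode == "deletion") c(10L, 24L) else c(7L, 15L)
  k_range <- k_range %||% if (mode == "deletion") c(1L, 7L) else c(1L, 10L)
  stopifnot(trials >= 1L, length(total_range) == 2L, length(k_range) == 2L)
  if (mode == "deletion" && k_range[2] >= exact_category_count) {
    abort("Deletion k_range must leave at least one category term.")
  }
  structure(
    list(mode = mode, category = category,
         exact_category_count = as.integer(exact_category_count),
         total_range = as.integer(total_range),
         k_range = as.integer(k_range),
         max_doc_tokens_for_addition = as.integer(max_doc_tokens_for_addition),
         trials = as.integer(trials), seed = as.integer(seed)),
    class = "perturbation_config"
  )
}

#' Select perturbation target proteins
#'
#' Applies the target filter of the configured protocol: exact category
#' term count, at least one term in each other category, total term count
#' within range, and (addition mode only) an original document of at most
#' `max_doc_tokens_for_addition` words.
#'
#' @param annotations long tibble with `accession`, `go_id`.
#' @param terms terms tibble (provides each term's namespace and, for
#'   addition mode, the definitions used to measure document length).
#' @param cfg a [perturbation_config()].
#' @return the accessions satisfying the filter (character vector; possibly
#'   empty).
#' @export
select_targets <- function(annotations, terms, cfg) {
  ann <- dplyr::left_join(
    annotations,
    dplyr::select(terms, "go_id", "namespace"),
    by = "go_id"
  )
  if (anyNA(ann$namespace)) {
    abort("select_targets(): some GO ids are missing from the vocabulary.")
  }
  other <- setdiff(GO_NAMESPACES, cfg$category)
  per_acc <- ann |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      n_cat = sum(.data$namespace == cfg$category),
      n_other_min = min(vapply(other, function(ns)
        sum(.data$namespace == ns), numeric(1))),
      n_total = dplyr::n(),
      .groups = "drop"
    )
  hits <- per_acc |>
    dplyr::filter(
      .data$n_cat == cfg$exact_category_count,
      .data$n_other_min >= 1L,
      .data$n_total >= cfg$total_range[1],
      .data$n_total <= cfg$total_range[2]
    ) |>
    dplyr::pull("accession")
  if (cfg$mode == "addition" && length(hits) > 0L) {
    docs <- build_documents(
      dplyr::filter(annotations, .data$accession %in% hits),
      terms, max_tokens = .Machine$integer.max
    )
    hits <- docs$accession[docs$token_count <= cfg$max_doc_tokens_for_addition]
  }
  hits
}

#' Perturb one protein's annotation set
#'
#' Deletion removes `k` uniformly chosen terms of the probed category only
#' (terms of the other categories are retained throughout); addition
#' inserts `k` uniformly chosen terms from a pool of irrelevant GO ids
#' (ids not annotated to the protein). The draw is seeded and reproducible
#' per (`annotation`, `k`, `trial_seed`).
#'
#' @param go_ids character vector of the protein's GO ids.
#' @param terms terms tibble (for namespaces).
#' @param cfg a [perturbation_config()].
#' @param k number of terms to remove / add (`k = 0` returns the input).
#' @param trial_seed integer seed for this trial.
#' @param pool for addition mode: candidate GO ids, disjoint from `go_ids`.
#' @return perturbed character vector of GO ids.
#' @export
perturb_annotation <- function(go_ids, terms, cfg, k, trial_seed,
                               pool = NULL) {
  stopifnot(k >= 0L)
  if (k == 0L) return(go_ids)
  if (cfg$mode == "deletion") {
    ns <- terms$namespace[match(go_ids, terms$go_id)]
    cat_ids <- go_ids[ns == cfg$category]
    if (k >= length(cat_ids)) {
      abort(paste0("Cannot remove ", k, " of ", length(cat_ids),
                   " category terms: at least one must remain."))
    }
    drop <- with_seed(trial_seed, sample(cat_ids, k))
    setdiff(go_ids, drop)
  } else {
    pool <- setdiff(pool, go_ids)
    if (length(pool) < k) {
      abort(paste0("Addition pool has ", length(pool),
                   " terms; cannot add ", k, "."))
    }
    add <- with_seed(trial_seed, sample(pool, k))
    c(go_ids, add)
  }
}

#' Run a perturbation score curve
#'
#' For each perturbation size `k`, each target is perturbed in
#' `cfg$trials` independent seeded trials; each perturbed annotation is
#' rebuilt into a document, summarized, and scored against the target's
#' reference paragraph with the average embedding score. Scores are
#' averaged over trials, then over targets. The unperturbed baseline
#' (`k = 0`) is always included.
#'
#' Deletion curves are keyed by the number of *remaining* category terms;
#' addition curves by the number of terms *added*.
#'
#' @param targets accessions to perturb (from [select_targets()]).
#' @param annotations long annotation tibble covering the targets.
#' @param terms terms tibble.
#' @param references tibble with `accession`, `reference` — the paragraph
#'   each summary is scored against.
#' @param cfg a [perturbation_config()].
#' @param fit trained summarizer ([train_summarizer()]) or backend; may be
#'   `NULL` when a custom `scorer` needs no generated summary.
#' @param embedders embedder panel for the average embedding score.
#' @param scorer optional function `(summary, reference, document) ->
#'   numeric` replacing the embedding score (used for instrumentation and
#'   testing; `document` is the perturbed document text).
#' @param max_doc_tokens document word cap, default 1024.
#' @param ... passed to [generate_summaries()] (e.g. `max_tokens`,
#'   `beam_width`).
#' @return An object of class `c("perturbation_curve", "tbl_df")`:
#'   columns `mode`, `category`, `k`, `x` (remaining or added terms),
#'   `mean_score`, `n_targets`, `trials`, `seed`.
#' @export
run_perturbation_curve <- function(targets, annotations, terms, references,
                                   cfg, fit, embedders = default_embedders(),
                                   scorer = NULL, max_doc_tokens = 1024L,
                                   ...) {
  if (length(targets) == 0L) abort("No perturbation targets supplied.")
  sets <- annotation_sets(
    dplyr::filter(annotations, .data$accession %in% targets)
  )
  refs <- setNames(references$reference, references$accession)
  if (!all(targets %in% names(refs))) {
    abort("Every target needs a reference paragraph.")
  }
  score_fn <- scorer %||% function(cand, ref, doc) {
    if (!nzchar(trimws(cand))) return(0)
    average_embedding_score(cand, ref, embedders)
  }
  if (is.null(fit) && is.null(scorer)) {
    abort("Either a trained summarizer or a scorer must be supplied.")
  }
  # "irrelevant" terms: vocabulary terms not annotated to the target
  # protein (perturb_annotation removes the target's own ids from the pool)
  pool <- terms$go_id
  ks <- c(0L, seq(cfg$k_range[1], cfg$k_range[2]))
  rows <- purrr::map_dfr(ks, function(k) {
    target_means <- vapply(targets, function(acc) {
      n_trials <- if (k == 0L) 1L else cfg$trials
      trial_scores <- vapply(seq_len(n_trials), function(trial) {
        ids <- perturb_annotation(
          sets[[acc]], terms, cfg, k,
          trial_seed = derive_seed(cfg$seed, acc, k, trial),
          pool = pool
        )
        doc <- build_documents(
          tibble::tibble(accession = acc, go_id = ids),
          terms, max_tokens = max_doc_tokens
        )
        cand <- if (is.null(fit)) "" else {
          generate_summaries(fit, doc, ...)$summary[1]
        }
        score_fn(cand, refs[[acc]], doc$text[1])
      }, numeric(1))
      mean(trial_scores)
    }, numeric(1))
    x <- if (cfg$mode == "deletion") cfg$exact_category_count - k else k
    tibble::tibble(
      mode = cfg$mode, category = cfg$category, k = k, x = x,
      mean_score = mean(target_means),
      n_targets = length(targets), trials = cfg$trials, seed = cfg$seed
    )
  })
  class(rows) <- c("perturbation_curve", class(rows))
  rows
}

#' Write a perturbation curve as TSV
#'
#' @param curve a `perturbation_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_perturbation_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  df$mean_score <- formatC(df$mean_score, format = "f", digits = 4)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
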