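# A vocabulary where every namespace has single-word concept definitions of
# known length, so document word counts are easy to reason about.
perturb_vocab <- function(n_per_ns = 12L) {
  purrr::map_dfr(c("BP", "CC", "MF"), function(ns) {
    offset <- match(ns, c("BP", "CC", "MF")) * 100L
    tibble::tibble(
      go_id = sprintf("GO:%07d", offset + seq_len(n_per_ns)),
      namespace = ns,
      name = paste0(tolower(ns), seq_len(n_per_ns)),
      definition = paste0("Definition of ", tolower(ns), " term ",
                          seq_len(n_per_ns), ".")
    )
  })
}

ann_of <- function(acc, ids) tibble::tibble(accession = acc, go_id = ids)

test_that("select_targets applies the deletion filter exactly", {
  vocab <- perturb_vocab()
  bp <- vocab$go_id[vocab$namespace == "BP"]
  cc <- vocab$go_id[vocab$namespace == "CC"]
  mf <- vocab$go_id[vocab$namespace == "MF"]
  ann <- dplyr::bind_rows(
    ann_of("OK1", c(bp[1:8], cc[1], mf[1])),          # 8 BP, total 10
    ann_of("OK2", c(bp[1:8], cc[1:4], mf[1:4])),      # 8 BP, total 16
    ann_of("NO_CC", c(bp[1:8], mf[1:2])),             # zero CC
    ann_of("SEVEN", c(bp[1:7], cc[1:2], mf[1])),      # 7 BP only
    ann_of("SPARSE", c(bp[1:8], cc[1]))               # no MF, total 9
  )
  cfg <- perturbation_config(mode = "deletion", category = "BP")
  expect_setequal(select_targets(ann, vocab, cfg), c("OK1", "OK2"))
  # independent re-count on a generated pool
  w <- small_world(seed = 91L, n_proteins = 150L, perturbation_targets = 10L)
  got <- select_targets(w$annotations, w$vocab, cfg)
  sets <- split(w$annotations$go_id, w$annotations$accession)
  ns_of <- setNames(w$vocab$namespace, w$vocab$go_id)
  manual <- names(Filter(function(ids) {
    ns <- ns_of[ids]
    sum(ns == "BP") == 8 && sum(ns == "CC") >= 1 && sum(ns == "MF") >= 1 &&
      length(ids) >= 10 && length(ids) <= 24
  }, sets))
  expect_setequal(got, manual)
  expect_gte(length(got), 10L)
})

test_that("addition mode drops targets with over-long documents", {
  vocab <- perturb_vocab()
  bp <- vocab$go_id[vocab$namespace == "BP"]
  cc <- vocab$go_id[vocab$namespace == "CC"]
  mf <- vocab$go_id[vocab$namespace == "MF"]
  ann <- dplyr::bind_rows(
    ann_of("SHORT", c(bp[1:5], cc[1], mf[1])),
    ann_of("LONG", c(bp[6:10], cc[2], mf[2]))
  )
  # every definition is 5 words: SHORT's document is 35 words; give LONG a
  # low cap so its 35-word document exceeds it
  cfg <- perturbation_config(mode = "addition", category = "BP",
                             max_doc_tokens_for_addition = 600L)
  expect_setequal(select_targets(ann, vocab, cfg), c("SHORT", "LONG"))
  cfg_small <- perturbation_config(mode = "addition", category = "BP",
                                   max_doc_tokens_for_addition = 30L)
  expect_length(select_targets(ann, vocab, cfg_small), 0L)
})

test_that("deletion removes only category terms and preserves counts", {
  vocab <- perturb_vocab()
  bp <- vocab$go_id[vocab$namespace == "BP"]
  cc <- vocab$go_id[vocab$namespace == "CC"]
  mf <- vocab$go_id[vocab$namespace == "MF"]
  ids <- c(bp[1:8], cc[1:2], mf[1:2])
  cfg <- perturbation_config(mode = "deletion", category = "BP")
  expect_identical(perturb_annotation(ids, vocab, cfg, 0L, 1L), ids)
  out <- perturb_annotation(ids, vocab, cfg, 7L, trial_seed = 42L)
  expect_length(out, 5L)
  expect_equal(sum(out %in% bp), 1L)
  expect_true(all(c(cc[1:2], mf[1:2]) %in% out))
  # determinism per seed; different seeds vary
  expect_identical(perturb_annotation(ids, vocab, cfg, 3L, 7L),
                   perturb_annotation(ids, vocab, cfg, 3L, 7L))
  draws <- unique(lapply(1:10, function(s)
    sort(perturb_annotation(ids, vocab, cfg, 3L, s))))
  expect_gt(length(draws), 1L)
  expect_error(perturb_annotation(ids, vocab, cfg, 8L, 1L), "at least one")
})

test_that("addition draws from the pool and respects its size", {
  vocab <- perturb_vocab()
  ids <- vocab$go_id[c(1:5, 13, 25)]
  pool <- setdiff(vocab$go_id, ids)
  cfg <- perturbation_config(mode = "addition", category = "BP")
  out <- perturb_annotation(ids, vocab, cfg, 3L, 5L, pool = pool)
  expect_length(out, length(ids) + 3L)
  expect_true(all(ids %in% out))
  expect_true(all(setdiff(out, ids) %in% pool))
  expect_error(
    perturb_annotation(ids, vocab, cfg, 5L, 1L, pool = pool[1:2]),
    "pool"
  )
})

test_that("the curve plumbing averages a transparent stub scorer", {
  vocab <- perturb_vocab()
  bp <- vocab$go_id[vocab$namespace == "BP"]
  cc <- vocab$go_id[vocab$namespace == "CC"]
  mf <- vocab$go_id[vocab$namespace == "MF"]
  ann <- dplyr::bind_rows(
    ann_of("T1", c(bp[1:8], cc[1], mf[1])),
    ann_of("T2", c(bp[2:9], cc[2], mf[2]))
  )
  refs <- tibble::tibble(accession = c("T1", "T2"), reference = "unused ref.")
  cfg <- perturbation_config(mode = "deletion", category = "BP", trials = 1L,
                             seed = 3L)
  # stub: document word count; every definition has 5 words, so removing k
  # BP terms gives exactly (10 - k) * 5 words
  curve <- run_perturbation_curve(
    c("T1", "T2"), ann, vocab, refs, cfg, fit = NULL,
    scorer = function(cand, ref, doc) count_words(doc)
  )
  expect_s3_class(curve, "perturbation_curve")
  expect_equal(curve$k, 0:7)
  expect_equal(curve$x, 8 - (0:7))
  expect_equal(curve$mean_score, (10 - curve$k) * 5)
  # monotone stub: remaining category fraction forces a decreasing curve
  bp_defs <- vocab$definition[vocab$namespace == "BP"]
  frac <- run_perturbation_curve(
    c("T1", "T2"), ann, vocab, refs, cfg, fit = NULL,
    scorer = function(cand, ref, doc) {
      mean(vapply(bp_defs, grepl, logical(1), x = doc, fixed = TRUE))
    }
  )
  expect_true(all(diff(frac$mean_score) < 0))
  # identical seeds reproduce identical curves
  curve2 <- run_perturbation_curve(
    c("T1", "T2"), ann, vocab, refs, cfg, fit = NULL,
    scorer = function(cand, ref, doc) count_words(doc)
  )
  expect_identical(curve, curve2)
})
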