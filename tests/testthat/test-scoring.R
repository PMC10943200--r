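test_that("confidence score normalizes the top beam probability", {
  expect_equal(confidence_score(rep(0.25, 4), log = FALSE), 0.25)
  expect_equal(confidence_score(c(0.4, 0.3, 0.2, 0.1), log = FALSE), 0.4)
  # independent arithmetic oracle on log inputs
  lp <- c(-1, -1, -2, -3)
  oracle <- exp(-1) / (2 * exp(-1) + exp(-2) + exp(-3))
  expect_equal(confidence_score(lp), oracle)
  expect_equal(round(oracle, 4), 0.3995)
})

test_that("confidence is shift-invariant and handles underflowing beams", {
  lp <- c(-2.5, -3.1, -7.0, -9.2)
  for (shift in c(-1000, -100, 0, 50)) {
    expect_equal(confidence_score(lp + shift), confidence_score(lp))
  }
  # raw probabilities would underflow to 0 here; log space must not
  expect_gt(confidence_score(c(-1e4, -1e4 - 1)), 0.5)
})

test_that("per-hypothesis confidences sum to one across the beam", {
  res <- structure(
    list(hypotheses = letters[1:4], token_ids = list(1, 2, 3, 4),
         logprobs = c(-1.1, -2.3, -2.9, -5.0), n = 4L),
    class = "beam_result"
  )
  td <- tidy(res)
  expect_equal(sum(td$confidence), 1)
  expect_equal(td$confidence[1], confidence_score(res))
  expect_gte(confidence_score(res), 1 / 4)
})

test_that("confidence rejects degenerate inputs", {
  expect_error(confidence_score(numeric()), "Empty beam")
  expect_error(confidence_score(c(0.5, 0), log = FALSE), "positive")
  expect_error(confidence_score(c(0.5, -0.1), log = FALSE), "positive")
})

test_that("embedding cosine matches hand-computed vectors", {
  vecs <- list(x = c(1, 0, 0), y = c(0.6, 0.8, 0), z = c(0, 1, 0))
  e <- table_embedder(vecs)
  expect_equal(embedding_cosine("x", "y", e), 0.6)
  expect_equal(embedding_cosine("x", "z", e), 0)
  expect_equal(embedding_cosine("x", "x", e), 1)
  expect_error(embedding_cosine("", "x", e), "non-empty")
  e0 <- table_embedder(list(w = c(0, 0, 0), x = c(1, 0, 0)))
  expect_error(embedding_cosine("w", "x", e0), "Zero-norm")
})

test_that("average embedding score is the mean over the embedder panel", {
  vecs <- list(cand = c(1, 0), ref = c(1, 0))
  e1 <- table_embedder(list(cand = c(1, 0, 0), ref = c(0.6, 0.8, 0)))   # 0.6
  e2 <- table_embedder(list(cand = c(1, 0, 0), ref = c(0, 1, 0)))       # 0.0
  e3 <- table_embedder(list(cand = c(0.6, 0.8, 0), ref = c(1, 0, 0)))   # 0.6
  expect_equal(average_embedding_score("cand", "ref", list(e1, e2, e3)), 0.4)
  emb <- default_embedders()
  expect_length(emb, 3L)
  txt <- "binds the alpha kinase target."
  expect_equal(average_embedding_score(txt, txt, emb), 1)
  expect_error(average_embedding_score("a", "b", list()), "at least one")
})

test_that("identical documents have mover similarity one in every mode", {
  e <- make_test_embedder(seed = 2L, dim = 64L)
  txt <- "Binds the alpha kinase target. Located in the beta nucleus structure."
  for (mode in c("WMS", "SMS", "S+WMS")) {
    expect_equal(mover_similarity(txt, txt, e, mode), 1, tolerance = 1e-9)
  }
})

test_that("single-word documents reduce to exp(-distance)", {
  e <- make_test_embedder(seed = 3L, dim = 32L)
  va <- e$embed("kinase")
  vb <- e$embed("nucleus")
  d <- sqrt(sum((va - vb)^2))
  expect_equal(mover_similarity("kinase", "nucleus", e, "WMS"), exp(-d),
               tolerance = 1e-9)
})

test_that("two-word uniform bags pick the better of the two pairings", {
  e <- make_test_embedder(seed = 4L, dim = 32L)
  words_a <- c("kinase", "nucleus")
  words_b <- c("helicase", "vesicle")
  pa <- e$embed_words(words_a)
  pb <- e$embed_words(words_b)
  cost <- outer(1:2, 1:2, Vectorize(function(i, j)
    sqrt(sum((pa[, i] - pb[, j])^2))))
  oracle <- min(mean(c(cost[1, 1], cost[2, 2])),
                mean(c(cost[1, 2], cost[2, 1])))
  got <- mover_distance("kinase nucleus", "helicase vesicle", e, "WMS")
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("exact transport matches permutation brute force on uniform bags", {
  set.seed(77)
  for (n in 2:5) {
    cost <- matrix(runif(n * n), n, n)
    got <- solve_transport(cost, rep(1 / n, n), rep(1 / n, n))$cost
    expect_equal(got, oracle_ot_uniform(cost), tolerance = 1e-8)
  }
})

test_that("exact transport matches simplex-grid search on unequal bags", {
  masses <- list(`2` = c(0.6, 0.4), `3` = c(0.5, 0.3, 0.2))
  demands <- list(`2` = c(0.55, 0.45), `3` = c(0.45, 0.3, 0.25))
  set.seed(78)
  for (rep in 1:5) {
    m <- sample(2:3, 1); n <- sample(2:3, 1)
    cost <- matrix(runif(m * n), m, n)
    a <- masses[[as.character(m)]]
    b <- demands[[as.character(n)]]
    got <- solve_transport(cost, a, b)$cost
    grid <- oracle_ot_grid(cost, a, b, step = 0.05)
    # the grid contains the exact optimum's support pattern at step 0.05
    expect_lte(got, grid + 1e-8)
    expect_gte(got, grid - 0.05 * max(cost))
  }
})

test_that("transport plans satisfy the marginals", {
  set.seed(79)
  cost <- matrix(runif(12), 3, 4)
  a <- c(0.2, 0.5, 0.3)
  b <- c(0.1, 0.2, 0.3, 0.4)
  res <- solve_transport(cost, a, b)
  expect_equal(rowSums(res$plan), a, tolerance = 1e-6)
  expect_equal(colSums(res$plan), b, tolerance = 1e-6)
  expect_true(all(res$plan > -1e-12))
})

test_that("mover distance behaves like a metric on random paragraphs", {
  e <- make_test_embedder(seed = 5L, dim = 32L)
  words <- c("kinase", "nucleus", "helicase", "vesicle", "ligase",
             "membrane", "signaling", "transport")
  make_text <- function() paste(sample(words, 4, replace = TRUE), collapse = " ")
  set.seed(80)
  for (i in 1:20) {
    x <- make_text(); y <- make_text(); z <- make_text()
    dxy <- mover_distance(x, y, e, "WMS")
    dyx <- mover_distance(y, x, e, "WMS")
    expect_equal(dxy, dyx, tolerance = 1e-8)
    dxz <- mover_distance(x, z, e, "WMS")
    dyz <- mover_distance(y, z, e, "WMS")
    expect_lte(dxz, dxy + dyz + 1e-8)
    expect_equal(mover_distance(x, x, e, "WMS"), 0, tolerance = 1e-9)
  }
})

test_that("win_fraction counts strict wins only", {
  expect_equal(win_fraction(c(2, 3, 4, 1), c(1, 2, 3, 2)), 0.75)
  expect_equal(win_fraction(c(1, 1), c(1, 1)), 0)
  expect_equal(win_fraction(c(1, 1) + 1e-9, c(1, 1)), 1)
  expect_error(win_fraction(1:3, 1:2), "equal-length")
})

test_that("Fmax matches hand enumeration and the exhaustive oracle", {
  truth <- tibble::tibble(
    accession = "P1",
    go_id = sprintf("GO:%07d", 1:5)
  )
  preds <- tibble::tibble(
    accession = "P1",
    go_id = c("GO:0000001", "GO:0009999"),
    score = c(0.9, 0.9)
  )
  res <- compute_fmax(preds, truth)
  expect_equal(res$fmax, 2 * (0.5 * 0.2) / 0.7, tolerance = 1e-9)

  # perfect prediction
  perfect <- dplyr::mutate(truth, score = 1.0)
  expect_equal(compute_fmax(perfect, truth)$fmax, 1.0)
  # fully disjoint prediction
  wrong <- tibble::tibble(accession = "P1",
                          go_id = sprintf("GO:%07d", 6:8), score = 0.9)
  expect_equal(compute_fmax(wrong, truth)$fmax, 0)
  expect_error(compute_fmax(preds, truth[0, ]), "non-empty")
})

test_that("Fmax agrees with exhaustive threshold enumeration", {
  # independent oracle: loop over every distinct score value as a
  # threshold, computing protein-averaged precision/recall from scratch
  oracle_fmax <- function(preds, truth) {
    truth_sets <- split(truth$go_id, truth$accession)
    best <- 0
    for (t in sort(unique(preds$score))) {
      precs <- c(); recs <- c()
      for (acc in names(truth_sets)) {
        p <- preds[preds$accession == acc & preds$score >= t, ]
        if (nrow(p) > 0) {
          precs <- c(precs, sum(p$go_id %in% truth_sets[[acc]]) / nrow(p))
        }
        recs <- c(recs, sum(truth_sets[[acc]] %in% p$go_id) /
                    length(truth_sets[[acc]]))
      }
      if (length(precs) > 0) {
        prec <- mean(precs); rec <- mean(recs)
        if (prec + rec > 0) best <- max(best, 2 * prec * rec / (prec + rec))
      }
    }
    best
  }
  set.seed(81)
  ids <- sprintf("GO:%07d", 1:12)
  for (rep in 1:4) {
    accs <- paste0("P", seq_len(sample(3:5, 1)))
    truth <- purrr::map_dfr(accs, function(a)
      tibble::tibble(accession = a, go_id = sample(ids, sample(2:5, 1))))
    preds <- purrr::map_dfr(accs, function(a) {
      n <- sample(2:6, 1)
      tibble::tibble(accession = a, go_id = sample(ids, n),
                     score = round(runif(n, 0.05, 1), 2))
    })
    # scores are multiples of 0.01, so the default grid covers every
    # distinct score value the oracle enumerates
    got <- compute_fmax(preds, truth)$fmax
    expect_equal(got, oracle_fmax(preds, truth), tolerance = 1e-9)
  }
})

test_that("score_report composes per-entry metrics with class bands", {
  mdl <- trained_model()
  entries <- dplyr::bind_cols(
    mdl$test[1:6, c("accession", "target_text")],
    summary = generate_summaries(mdl$fit, mdl$test[1:6, ],
                                 max_tokens = 48L)$summary
  )
  report <- score_report(entries)
  expect_s3_class(report, "score_report")
  expect_equal(nrow(report), 6L)
  expect_true(all(c("embedding_score", "similarity_wms", "similarity_sms",
                    "similarity_swms", "score_class") %in% names(report)))
  expect_true(all(report$embedding_score >= -1 & report$embedding_score <= 1))
  expect_true(all(report$similarity_wms > 0 & report$similarity_wms <= 1))
  g <- glance(report)
  expect_equal(g$n, 6L)
  expect_equal(g$n_high + g$n_moderate + g$n_low, 6L)
  # class boundaries: high is [0.8, 1.0], moderate [0.5, 0.8), low [0, 0.5)
  expect_equal(as.character(score_class(c(0.8, 0.799, 0.5, 0.499, 1.0))),
               c("high", "moderate", "moderate", "low", "high"))
})
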