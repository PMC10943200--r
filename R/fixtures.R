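# Namespace-specific concept banks for the synthetic GO world. Concepts are
# paired adjective + noun phrases so thousands of distinct term definitions
# can be composed from a compact bank.
FIXTURE_NOUNS <- list(
  MF = c("kinase", "phosphatase", "helicase", "ligase", "protease",
         "isomerase", "reductase", "oxidase", "transferase", "hydrolase",
         "receptor", "channel", "transporter", "chaperone", "polymerase",
         "nuclease", "synthase", "carboxylase", "dehydrogenase", "esterase"),
  BP = c("glycolysis", "translation", "transcription", "replication",
         "autophagy", "apoptosis", "mitosis", "meiosis", "secretion",
         "endocytosis", "signaling", "differentiation", "morphogenesis",
         "homeostasis", "biosynthesis", "catabolism", "transport",
         "repair", "splicing", "folding"),
  CC = c("nucleus", "nucleolus", "cytoplasm", "mitochondrion", "ribosome",
         "membrane", "vesicle", "lysosome", "peroxisome", "cytoskeleton",
         "centrosome", "chromatin", "spliceosome", "proteasome", "endosome",
         "vacuole", "flagellum", "axoneme", "lamellipodium", "nucleoid")
)
FIXTURE_ADJECTIVES <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "theta", "kappa",
  "lambda", "sigma", "omega", "primary", "secondary", "auxiliary", "distal",
  "proximal", "apical", "basal", "cortical", "luminal"
)

#' Specification for a synthetic GO world
#'
#' Declares the shape of a fully synthetic fixture: a GO vocabulary with
#' templated free-text definitions, protein annotation sets with controlled
#' overlap structure, and rule-derived reference paragraphs for the three
#' UniProt-style sections. The entire fixture is a pure function of the
#' spec and its seed, so every pipeline stage is testable offline.
#'
#' @param n_terms named integer vector of terms per namespace,
#'   e.g. `c(BP = 10, CC = 10, MF = 10)`.
#' @param n_proteins number of proteins (redundancy-group members count
#'   towards this total).
#' @param terms_per_protein length-2 range of annotation set sizes.
#' @param redundancy_groups list of `c(size, overlap)` pairs; each group's
#'   members share at least the given pairwise GO-term overlap and groups
#'   use disjoint term slices, so they cluster apart.
#' @param section_availability named fractions of proteins carrying each
#'   reference section. The defaults (Function 1.00, Subunit 0.64, Pathway
#'   0.15) mirror the relative sizes of the three full-scale section
#'   datasets (97,600 : 62,340 : 14,600).
#' @param perturbation_targets number of extra engineered proteins
#'   satisfying the BP-deletion target filter (8 BP + 2 CC + 2 MF terms).
#' @param seed integer seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = c(BP = 10L, CC = 10L, MF = 10L),
                         n_proteins = 50L,
                         terms_per_protein = c(3L, 8L),
                         redundancy_groups = list(),
                         section_availability = c(Function = 1.0,
                                                  Subunit = 0.64,
                                                  Pathway = 0.15),
                         perturbation_targets = 0L,
                         seed = 1L) {
  stopifnot(all(n_terms >= 1L), n_proteins >= 1L,
            all(section_availability >= 0 & section_availability <= 1),
            all(GO_NAMESPACES %in% names(n_terms)),
            all(GO_SECTIONS %in% names(section_availability)))
  structure(
    list(n_terms = n_terms, n_proteins = as.integer(n_proteins),
         terms_per_protein = as.integer(terms_per_protein),
         redundancy_groups = redundancy_groups,
         section_availability = section_availability,
         perturbation_targets = as.integer(perturbation_targets),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate the synthetic GO vocabulary
#'
#' Each term receives a sequential accession, a namespace, a unique concept
#' phrase, and a 1-3 sentence definition composed from namespace-specific
#' templates (e.g. "Binding to a transfer RNA."-style phrasing for MF
#' terms). Distinct terms are guaranteed distinct definitions because each
#' consumes a distinct concept.
#'
#' @param spec a [fixture_spec()].
#' @return terms tibble (`go_id`, `namespace`, `name`, `definition`) plus a
#'   `concept` column used by the reference-paragraph rule.
#' @export
make_vocabulary <- function(spec) {
  with_seed(derive_seed(spec$seed, "vocab"), {
    # accessions are assigned to namespaces in shuffled order, as in the
    # real ontology, so GO-id order and namespace-grouped order differ
    labels <- sample(rep(GO_NAMESPACES, times = spec$n_terms[GO_NAMESPACES]))
    rows <- list()
    for (ns in GO_NAMESPACES) {
      n <- spec$n_terms[[ns]]
      pool <- as.vector(outer(FIXTURE_ADJECTIVES, FIXTURE_NOUNS[[ns]],
                              paste))
      if (n > length(pool)) {
        abort(paste0("Concept bank too small for ", n, " ", ns, " terms."))
      }
      concepts <- sample(pool, n)
      rows[[ns]] <- tibble::tibble(
        go_id = sprintf("GO:%07d", which(labels == ns)),
        namespace = ns,
        name = paste(ns, "term for", concepts),
        definition = fixture_definition(ns, concepts),
        concept = concepts
      )
    }
    dplyr::arrange(dplyr::bind_rows(rows), .data$go_id)
  })
}

# Templated 1-3 sentence definitions; the concept phrase appears verbatim so
# the mapping from document to reference clause is learnable.
fixture_definition <- function(ns, concepts) {
  extra <- sample(c("", " This activity is essential for cell viability.",
                    " It operates under tight regulatory control."),
                  length(concepts), replace = TRUE)
  lead <- switch(
    ns,
    MF = paste0("Binding to a ", concepts,
                " target. Catalysis associated with ", concepts,
                " activity."),
    BP = paste0("Any process that modulates ", concepts,
                " in the cell. The process contributes to ", concepts,
                " progression."),
    CC = paste0("A cellular component associated with the ", concepts,
                " structure.")
  )
  paste0(lead, extra)
}

#' Generate synthetic proteins: annotations and reference paragraphs
#'
#' Annotation sets are drawn per the spec. Redundancy groups are built on
#' disjoint vocabulary slices: members of one group share a common base set
#' and differ by at most one private term when that keeps the pairwise
#' overlap at or above the requested fraction (members are identical
#' otherwise), so within-group overlaps meet the constraint and
#' between-group overlaps are zero.
#'
#' Reference paragraphs are derived from the annotation by a fixed
#' compositional rule — one clause per term, in ascending GO id order — so
#' identical annotations yield identical references and a small model can
#' learn the mapping. Function paragraphs use every term, Subunit
#' paragraphs the CC/MF terms, and Pathway paragraphs are a single short
#' sentence from the first BP term, mirroring the real sections' length
#' ordering (Pathway < Subunit < Function). Section presence is a seeded
#' Bernoulli draw at the configured availability.
#'
#' @param spec a [fixture_spec()].
#' @param vocab terms tibble from [make_vocabulary()].
#' @return list with `annotations` (long tibble `accession`, `go_id`) and
#'   `references` (tibble `accession`, `section`, `paragraph`).
#' @export
make_proteins <- function(spec, vocab) {
  with_seed(derive_seed(spec$seed, "proteins"), {
    group_sizes <- vapply(spec$redundancy_groups, function(g)
      as.integer(g[[1]]), integer(1))
    if (sum(group_sizes) > spec$n_proteins) {
      abort("Redundancy groups exceed n_proteins.")
    }
    all_ids <- sample(vocab$go_id) # shuffled; groups take disjoint slices
    sets <- list()
    cursor <- 1L
    for (gi in seq_along(spec$redundancy_groups)) {
      g <- spec$redundancy_groups[[gi]]
      size <- as.integer(g[[1]]); ov <- as.numeric(g[[2]])
      remaining <- length(all_ids) - cursor + 1L
      # members sharing a base of m terms plus one private term each have
      # pairwise overlap m/(m+1); when the vocabulary cannot support the
      # base size that requires, members are identical copies instead
      ideal <- if (ov >= 1) Inf else
        max(spec$terms_per_protein[1], ceiling(ov / (1 - ov)))
      distinct_ok <- is.finite(ideal) && ideal + size <= remaining
      base_m <- if (distinct_ok) ideal else
        min(max(spec$terms_per_protein), remaining)
      need <- base_m + if (distinct_ok) size else 0L
      if (need > remaining || base_m < 1L) {
        abort("Vocabulary too small for the requested redundancy groups.")
      }
      slice <- all_ids[cursor:(cursor + need - 1L)]
      cursor <- cursor + need
      base <- slice[seq_len(base_m)]
      for (k in seq_len(size)) {
        sets[[length(sets) + 1L]] <-
          if (distinct_ok) c(base, slice[base_m + k]) else base
      }
    }
    n_rest <- spec$n_proteins - sum(group_sizes)
    for (k in seq_len(n_rest)) {
      m <- sample(seq(spec$terms_per_protein[1], spec$terms_per_protein[2]), 1L)
      sets[[length(sets) + 1L]] <- sample(vocab$go_id, m)
    }
    if (spec$perturbation_targets > 0L) {
      by_ns <- split(vocab$go_id, vocab$namespace)
      if (length(by_ns$BP) < 8L || length(by_ns$CC) < 2L || length(by_ns$MF) < 2L) {
        abort("Vocabulary too small for perturbation targets (needs 8 BP, 2 CC, 2 MF).")
      }
      for (k in seq_len(spec$perturbation_targets)) {
        sets[[length(sets) + 1L]] <- c(
          sample(by_ns$BP, 8L), sample(by_ns$CC, 2L), sample(by_ns$MF, 2L)
        )
      }
    }
    accs <- sprintf("SYN%05d", seq_along(sets))
    annotations <- tibble::tibble(
      accession = rep(accs, lengths(sets)),
      go_id = unlist(sets, use.names = FALSE)
    )
    references <- purrr::map2_dfr(accs, sets, function(acc, ids)
      fixture_references(acc, ids, vocab))
    avail <- spec$section_availability
    keep <- purrr::map_lgl(seq_len(nrow(references)), function(i) {
      p <- avail[[as.character(references$section[i])]]
      if (p >= 1) TRUE else runif(1) < p
    })
    list(annotations = annotations, references = references[keep, ])
  })
}

# Rule-derived ground-truth paragraphs: one clause per term in ascending
# GO id order, phrased by namespace.
fixture_references <- function(acc, ids, vocab) {
  ids <- sort(unique(ids))
  idx <- match(ids, vocab$go_id)
  ns <- vocab$namespace[idx]
  concept <- vocab$concept[idx]
  clause <- dplyr::case_when(
    ns == "MF" ~ paste0("Binds the ", concept, " target."),
    ns == "BP" ~ paste0("Involved in ", concept, " regulation."),
    ns == "CC" ~ paste0("Located in the ", concept, " structure.")
  )
  fun <- paste(clause, collapse = " ")
  sub_idx <- ns %in% c("CC", "MF")
  subunit <- if (any(sub_idx)) {
    paste(paste0("Associates with the ", concept[sub_idx], " machinery."),
          collapse = " ")
  } else {
    ""
  }
  bp_first <- which(ns == "BP")[1]
  pathway <- if (!is.na(bp_first)) {
    paste0("Pathway: ", concept[bp_first], " route.")
  } else {
    ""
  }
  out <- tibble::tibble(
    accession = acc,
    section = GO_SECTIONS,
    paragraph = c(fun, subunit, pathway)
  )
  out[nzchar(out$paragraph), ]
}

#' Generate synthetic GO predictions for Fmax evaluation
#'
#' Emulates a GO term predictor's scored output: each true term is
#' predicted with a high seeded score, except that a `corruption` fraction
#' of true terms is replaced by random off-target terms, and a few spurious
#' low-scoring terms are appended. Useful for exercising [compute_fmax()]
#' without a real predictor; the output is synthetic, not a reference
#' prediction set.
#'
#' @param annotations long tibble of true annotations.
#' @param vocab terms tibble.
#' @param corruption fraction of true terms replaced (default 0.3).
#' @param seed integer seed.
#' @return predictions tibble (`accession`, `go_id`, `score`).
#' @export
make_predictions <- function(annotations, vocab, corruption = 0.3, seed = 1L) {
  with_seed(derive_seed(seed, "predictions"), {
    purrr::map_dfr(split(annotations$go_id, annotations$accession),
                   function(ids) {
      swap <- runif(length(ids)) < corruption
      pred <- ids
      pred[swap] <- sample(setdiff(vocab$go_id, ids), sum(swap))
      spurious <- sample(setdiff(vocab$go_id, pred),
                         min(2L, length(setdiff(vocab$go_id, pred))))
      tibble::tibble(
        go_id = c(pred, spurious),
        score = c(round(runif(length(pred), 0.6, 1), 4),
                  round(runif(length(spurious), 0.05, 0.4), 4))
      )
    }, .id = "accession") |>
      dplyr::select("accession", "go_id", "score")
  })
}

#' Deterministic test embedder
#'
#' A convenience alias for the seeded [hash_embedder()]: word vectors from
#' a seeded hash, text vector the mean of word vectors, no external data.
#'
#' @param seed embedder seed.
#' @param dim embedding dimension.
#' @return a text embedder.
#' @export
make_test_embedder <- function(seed = 1L, dim = 256L) {
  hash_embedder(dim = dim, seed = seed)
}

#' Write a complete fixture world to disk
#'
#' Emits the vocabulary as OBO 1.2, annotations as both GAF 2.2 and simple
#' TSV, and references as TSV, exercising every on-disk reader.
#'
#' @param world list from [make_proteins()] plus its vocabulary.
#' @param vocab terms tibble.
#' @param dir output directory.
#' @return named character vector of paths, invisibly.
#' @export
write_fixture_world <- function(world, vocab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    obo = file.path(dir, "terms.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    tsv = file.path(dir, "annotations.tsv"),
    references = file.path(dir, "references.tsv")
  )
  write_obo(vocab, paths["obo"])
  write_gaf(world$annotations, paths["gaf"], terms = vocab)
  write_annotations_tsv(world$annotations, paths["tsv"])
  write_references(world$references, paths["references"])
  invisible(paths)
}
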