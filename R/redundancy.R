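#' GO-annotation overlap between two proteins
#'
#' The fraction of shared GO terms, taking either protein's annotation size
#' as the denominator and keeping the larger value — equivalently
#' `|A n B| / min(|A|, |B|)`. Two proteins annotated with `{g1,g2,g3}` and
#' `{g1,g2,g3,g4}` overlap 100% (3/3 beats 3/4).
#'
#' @param a,b character vectors of GO ids (duplicates ignored).
#' @return overlap fraction in `[0, 1]`.
#' @export
go_overlap <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("go_overlap() requires two non-empty annotation sets.")
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Cluster proteins by GO-annotation overlap
#'
#' Groups proteins whose annotations are largely identical, so that one
#' representative per group can stand in for all of them when assembling a
#' non-redundant dataset. Two proteins are linked when their [go_overlap()]
#' is at least `threshold` (default 0.90, i.e. "90% or more identical");
#' clusters are the connected components of that graph (single linkage), so
#' every between-cluster pair falls below the threshold. A greedy
#' leader-clustering alternative is available for comparison.
#'
#' The all-pairs scan is pruned with an inverted index (GO id -> proteins):
#' only pairs sharing at least one term are examined. This is O(n^2) in the
#' worst case and intended for desk-scale datasets.
#'
#' @param annotations long tibble with `accession`, `go_id`; every protein
#'   must have at least one annotation.
#' @param threshold overlap threshold in `(0, 1]`; pairs with overlap
#'   `>= threshold` are clustered together.
#' @param method `"components"` (single-linkage connected components, the
#'   default) or `"leader"` (greedy: each protein joins the first leader it
#'   overlaps with, in accession order).
#' @return A tibble with columns `accession` and `cluster` (integer id).
#' @export
cluster_by_overlap <- function(annotations, threshold = 0.90,
                               method = c("components", "leader")) {
  method <- match.arg(method)
  stopifnot(threshold > 0, threshold <= 1)
  sets <- annotation_sets(annotations)
  accs <- names(sets)
  n <- length(accs)
  if (n == 0L) {
    return(tibble::tibble(accession = character(), cluster = integer()))
  }
  pairs <- candidate_pairs(sets)
  hit <- logical(nrow(pairs))
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      hit[k] <- go_overlap(sets[[pairs$i[k]]], sets[[pairs$j[k]]]) >= threshold
    }
  }
  edges <- pairs[hit, , drop = FALSE]
  cluster <- if (method == "components") {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges) > 0L) {
      g <- igraph::add_edges(g, rbind(edges$i, edges$j))
    }
    as.integer(igraph::components(g)$membership)
  } else {
    leader_clusters(n, edges)
  }
  tibble::tibble(accession = accs, cluster = cluster)
}

# Candidate pairs sharing >= 1 GO id, via an inverted index.
candidate_pairs <- function(sets) {
  idx <- rep(seq_along(sets), lengths(sets))
  by_term <- split(idx, unlist(sets, use.names = FALSE))
  pair_mat <- lapply(by_term, function(members) {
    if (length(members) < 2L) return(NULL)
    t(utils::combn(sort(members), 2L))
  })
  pair_mat <- do.call(rbind, pair_mat)
  if (is.null(pair_mat)) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  dplyr::distinct(tibble::tibble(i = pair_mat[, 1], j = pair_mat[, 2]))
}

# Greedy leader clustering: scan proteins in order; attach to the first
# existing leader the protein links to, else start a new cluster.
leader_clusters <- function(n, edges) {
  linked <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    linked[[i]] <- c(linked[[i]], j)
    linked[[j]] <- c(linked[[j]], i)
  }
  cluster <- rep(NA_integer_, n)
  leaders <- integer()
  for (v in seq_len(n)) {
    hit <- leaders[leaders %in% linked[[v]]]
    if (length(hit) > 0L) {
      cluster[v] <- cluster[hit[1]]
    } else {
      cluster[v] <- length(leaders) + 1L
      leaders <- c(leaders, v)
    }
  }
  cluster
}

#' Pick one representative protein per cluster
#'
#' Draws one member uniformly at random from each cluster with a seeded
#' generator, so the choice is reproducible. Singleton clusters contribute
#' their sole member.
#'
#' @param clusters tibble from [cluster_by_overlap()].
#' @param seed integer seed for the draw.
#' @return The input tibble with a logical `is_representative` column added.
#' @export
select_representatives <- function(clusters, seed = 1L) {
  if (nrow(clusters) == 0L) {
    return(dplyr::mutate(clusters, is_representative = logical()))
  }
  members <- split(clusters$accession, clusters$cluster)
  reps <- with_seed(seed, {
    vapply(members, function(a) a[[sample.int(length(a), 1L)]], character(1))
  })
  dplyr::mutate(clusters, is_representative = .data$accession %in% reps)
}

#' Write a cluster report TSV
#'
#' Columns: `accession`, `cluster_id`, `is_representative`.
#'
#' @param clusters tibble from [select_representatives()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- data.frame(
    accession = clusters$accession,
    cluster_id = clusters$cluster,
    is_representative = clusters$is_representative
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
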