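#' Exact optimal transport between two weighted point sets
#'
#' Solves the classical transportation problem
#' `min sum_ij P_ij C_ij` s.t. `rowSums(P) = a`, `colSums(P) = b`,
#' `P >= 0` exactly with the transportation simplex (north-west-corner
#' start, MODI pivoting). Degeneracy is handled by an infinitesimal
#' perturbation of the supplies. Intended for the bag sizes arising from
#' paragraphs (tens of atoms per side).
#'
#' @param cost `m x n` cost matrix.
#' @param a supply weights (length m, positive, summing to the demand total).
#' @param b demand weights (length n, positive).
#' @return list with `cost` (the optimal transport cost) and `plan`
#'   (the `m x n` optimal plan).
#' @export
solve_transport <- function(cost, a, b) {
  cost <- as.matrix(cost)
  m <- nrow(cost); n <- ncol(cost)
  stopifnot(length(a) == m, length(b) == n, all(a > 0), all(b > 0))
  if (abs(sum(a) - sum(b)) > 1e-9 * max(sum(a), sum(b))) {
    abort("solve_transport(): supplies and demands must balance.")
  }
  scale <- sum(a)
  eps <- 1e-13 / max(m, 1)
  a2 <- a / scale + eps
  b2 <- b / scale
  b2[n] <- b2[n] + m * eps

  # North-west corner initial basic feasible solution
  plan <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  ra <- a2; rb <- b2
  i <- 1L; j <- 1L
  while (i <= m && j <= n) {
    q <- min(ra[i], rb[j])
    plan[i, j] <- q
    basis[i, j] <- TRUE
    ra[i] <- ra[i] - q
    rb[j] <- rb[j] - q
    if (i == m && j == n) break
    if (ra[i] <= rb[j] && i < m) i <- i + 1L else j <- j + 1L
  }

  tol <- 1e-10 * (max(abs(cost)) + 1)
  max_iter <- 20L * (m + n)^2
  for (iter in seq_len(max_iter)) {
    duals <- transport_duals(cost, basis)
    red <- cost - outer(duals$u, duals$v, `+`)
    red[basis] <- 0
    enter <- arrayInd(which.min(red), dim(red))
    if (red[enter] >= -tol) break
    cyc <- transport_cycle(basis, enter[1], enter[2])
    minus <- cyc[seq(2L, nrow(cyc), by = 2L), , drop = FALSE]
    vals <- plan[minus]
    theta <- min(vals)
    leave <- minus[which.min(vals), , drop = FALSE]
    sign <- rep_len(c(1, -1), nrow(cyc))
    plan[cyc] <- plan[cyc] + sign * theta
    basis[enter] <- TRUE
    basis[leave] <- FALSE
    plan[leave] <- 0
  }
  plan <- plan * scale
  list(cost = sum(plan * cost), plan = plan)
}

# Dual potentials u, v with u[1] = 0, solved by sweeping the basis tree.
transport_duals <- function(cost, basis) {
  m <- nrow(basis); n <- ncol(basis)
  u <- rep(NA_real_, m); v <- rep(NA_real_, n)
  u[1] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) {
      cols <- which(basis[i, ])
      if (!is.na(u[i])) {
        new <- cols[is.na(v[cols])]
        if (length(new) > 0L) { v[new] <- cost[i, new] - u[i]; changed <- TRUE }
      }
    }
    for (j in seq_len(n)) {
      rows <- which(basis[, j])
      if (!is.na(v[j])) {
        new <- rows[is.na(u[rows])]
        if (length(new) > 0L) { u[new] <- cost[new, j] - v[j]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  if (anyNA(u) || anyNA(v)) {
    abort("Degenerate transport basis: disconnected spanning tree.")
  }
  list(u = u, v = v)
}

# The unique alternating cycle created by adding cell (i0, j0) to the basis
# tree, returned as a 2-column (row, col) matrix starting at the entering
# cell; odd positions gain mass, even positions lose it.
transport_cycle <- function(basis, i0, j0) {
  m <- nrow(basis); n <- ncol(basis)
  # nodes: rows 1..m, cols m+1..m+n; BFS from row i0 to col j0 over basis edges
  parent <- rep(NA_integer_, m + n)
  visited <- rep(FALSE, m + n)
  queue <- i0
  visited[i0] <- TRUE
  while (length(queue) > 0L) {
    node <- queue[1]; queue <- queue[-1]
    if (node == m + j0) break
    nbrs <- if (node <= m) m + which(basis[node, ]) else which(basis[, node - m])
    nbrs <- nbrs[!visited[nbrs]]
    for (nb in nbrs) {
      visited[nb] <- TRUE
      parent[nb] <- node
      queue <- c(queue, nb)
    }
  }
  if (!visited[m + j0]) {
    abort("Transport pivot failed: no cycle found (corrupt basis).")
  }
  path <- m + j0
  while (path[1] != i0) path <- c(parent[path[1]], path)
  # path: i0, col, row, ..., col j0 (alternating); convert edges to cells
  cells <- matrix(NA_integer_, 0, 2)
  for (k in seq_len(length(path) - 1L)) {
    r <- min(path[k], path[k + 1L])
    c <- max(path[k], path[k + 1L]) - m
    cells <- rbind(cells, c(r, c))
  }
  rbind(c(i0, j0), cells[rev(seq_len(nrow(cells))), , drop = FALSE])
}
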