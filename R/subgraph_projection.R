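#' Unweighted bipartite projection onto one side
#'
#' Two nodes of the projected side are connected iff they share at least
#' one neighbor on the opposite side; equivalently the projection is the
#' off-diagonal support of the Gram matrix A A^T (piRNA side) or A^T A
#' (disease side).
#'
#' @param A_pd binary incidence matrix (piRNAs x diseases).
#' @param side `"piRNA"` or `"disease"`.
#' @return binary symmetric adjacency with zero diagonal.
#' @export
bipartite_projection <- function(A_pd, side = c("piRNA", "disease")) {
  side <- match_side(side)
  A_pd <- as.matrix(A_pd)
  gram <- if (side == "piRNA") tcrossprod(A_pd) else crossprod(A_pd)
  adj <- (gram > 0) * 1
  diag(adj) <- 0
  adj
}

#' PageRank centrality by power iteration
#'
#' Uniform teleportation (1 - alpha)/N; the rank mass of dangling
#' (isolated) nodes is redistributed uniformly. Iteration stops when the
#' L1 change falls below `tol`.
#'
#' @param adjacency square (here: symmetric binary) adjacency matrix.
#' @param alpha damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning and `converged = FALSE`.
#' @return a `pagerank_scores` object: `scores` (sums to 1), `alpha`,
#'   `iterations`, `converged`.
#' @export
pagerank <- function(adjacency, alpha = 0.85, tol = 1e-12, max_iter = 1000L) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  stopifnot(n == ncol(adjacency), alpha > 0, alpha < 1)
  out_deg <- colSums(adjacency)
  dangling <- out_deg == 0
  # column-stochastic transition; dangling columns handled separately
  P <- adjacency
  nz <- which(!dangling)
  P[, nz] <- sweep(P[, nz, drop = FALSE], 2L, out_deg[nz], `/`)
  r <- rep(1 / n, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r_new <- alpha * (P %*% r + sum(r[dangling]) / n) + (1 - alpha) / n
    r_new <- as.vector(r_new)
    if (sum(abs(r_new - r)) < tol) {
      r <- r_new
      converged <- TRUE
      break
    }
    r <- r_new
  }
  if (!converged) {
    warning("PageRank did not converge in ", max_iter, " iterations")
  }
  names(r) <- rownames(adjacency)
  structure(
    list(scores = r, alpha = alpha, iterations = iter, converged = converged),
    class = "pagerank_scores"
  )
}

#' Size of the median-centrality subsample
#'
#' k = floor(C_pd / ((d_max - d_min) * mu)), clamped to
#' \[1, side_size\]. When the opposite side has uniform degree
#' (d_max == d_min) the formula degenerates and the whole side is kept.
#'
#' @param C_pd number of known associations.
#' @param d_max,d_min maximum/minimum degree of the opposite side.
#' @param mu dilution factor (> 0); larger values keep fewer nodes.
#' @param side_size number of nodes on the projected side.
#' @return integer k in \[1, side_size\].
#' @export
compute_k <- function(C_pd, d_max, d_min, mu, side_size) {
  stopifnot(mu > 0, side_size >= 1L)
  if (d_max == d_min) return(as.integer(side_size))
  k <- floor(C_pd / ((d_max - d_min) * mu))
  as.integer(min(max(k, 1), side_size))
}

#' Induced subgraph on the k nodes with PageRank nearest the median
#'
#' Nodes are ordered by |PR - median(PR)| ascending with ties broken by
#' node index; the first k are retained and the adjacency restricted to
#' them (non-retained rows/columns zeroed, original indexing preserved).
#'
#' @param adjacency binary symmetric adjacency.
#' @param scores a [pagerank()] result (or a bare numeric vector).
#' @param k number of nodes to retain.
#' @return a `projection_subgraph`: `adjacency`, `selected` (indices),
#'   `median_pr`, plus the scores object.
#' @export
median_centrality_subsample <- function(adjacency, scores, k) {
  pr <- if (inherits(scores, "pagerank_scores")) scores$scores else scores
  n <- nrow(adjacency)
  stopifnot(length(pr) == n, k >= 1L, k <= n)
  med <- stats::median(pr)
  ord <- order(abs(pr - med), seq_len(n))
  selected <- sort(ord[seq_len(k)])
  adj <- matrix(0, n, n, dimnames = dimnames(adjacency))
  adj[selected, selected] <- adjacency[selected, selected]
  structure(
    list(adjacency = adj, selected = selected, median_pr = med,
         scores = pr, k = as.integer(k)),
    class = "projection_subgraph"
  )
}

#' Build the intra-side projection subgraph for one side
#'
#' Composes [bipartite_projection()], [pagerank()] on the projected graph,
#' [compute_k()] from the opposite side's degrees, and
#' [median_centrality_subsample()]. Deterministic given inputs.
#'
#' @param assoc an [association_table()] (or a bare incidence matrix).
#' @param side which side to project onto.
#' @param mu dilution factor; the defaults used downstream are 100 for the
#'   piRNA side and 1 for the disease side.
#' @param alpha PageRank damping.
#' @param mode `"induced"` (select median-central nodes of the projected
#'   graph, the default) or `"intermediary"` (restrict the projection to
#'   paths through median-central nodes of the opposite side).
#' @return a `projection_subgraph` with provenance fields `side`, `mu`,
#'   `alpha`, `mode`.
#' @export
build_projection_subgraph <- function(assoc, side = c("piRNA", "disease"),
                                      mu = if (match.arg(side) == "piRNA") 100 else 1,
                                      alpha = 0.85,
                                      mode = c("induced", "intermediary")) {
  side <- match_side(side)
  mode <- match.arg(mode)
  A_pd <- if (inherits(assoc, "association_table")) assoc$A_pd else as.matrix(assoc)
  C_pd <- sum(A_pd)
  opp_deg <- if (side == "piRNA") colSums(A_pd) else rowSums(A_pd)
  side_size <- if (side == "piRNA") nrow(A_pd) else ncol(A_pd)
  if (mode == "induced") {
    proj <- bipartite_projection(A_pd, side)
    k <- compute_k(C_pd, max(opp_deg), min(opp_deg), mu, side_size)
    pr <- pagerank(proj, alpha)
    sub <- median_centrality_subsample(proj, pr, k)
  } else {
    # project only through opposite-side nodes with centrality near the
    # median of the opposite side's projected graph
    opp_side <- if (side == "piRNA") "disease" else "piRNA"
    opp_size <- if (side == "piRNA") ncol(A_pd) else nrow(A_pd)
    opp_proj <- bipartite_projection(A_pd, opp_side)
    k <- compute_k(C_pd, max(opp_deg), min(opp_deg), mu, opp_size)
    pr <- pagerank(opp_proj, alpha)
    opp_sub <- median_centrality_subsample(opp_proj, pr, k)
    A_restricted <- if (side == "piRNA") {
      A_pd[, opp_sub$selected, drop = FALSE]
    } else {
      A_pd[opp_sub$selected, , drop = FALSE]
    }
    proj <- bipartite_projection(A_restricted, side)
    sub <- list(adjacency = proj, selected = seq_len(side_size),
                median_pr = opp_sub$median_pr, scores = pr$scores,
                k = opp_sub$k)
    class(sub) <- "projection_subgraph"
  }
  sub$side <- side
  sub$mu <- mu
  sub$alpha <- alpha
  sub$mode <- mode
  sub
}
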