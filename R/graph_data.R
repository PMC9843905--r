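#' Construct an association table
#'
#' The central container for a bipartite piRNA-disease association graph.
#' Node ids are kept in first-seen order; edges are stored as a two-column
#' integer matrix of (piRNA index, disease index) pairs, 1-based, with the
#' binary incidence matrix `A_pd` derived from them.
#'
#' @param piRNA_ids character vector of unique piRNA identifiers.
#' @param disease_ids character vector of unique disease identifiers.
#' @param edges two-column integer matrix of (piRNA index, disease index)
#'   pairs; duplicates are collapsed.
#' @return an object of class `association_table` with elements
#'   `piRNA_ids`, `disease_ids`, `edges`, `A_pd`.
#' @export
association_table <- function(piRNA_ids, disease_ids, edges) {
  piRNA_ids <- as.character(piRNA_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(piRNA_ids)) stop("duplicate piRNA ids")
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids")
  n <- length(piRNA_ids)
  m <- length(disease_ids)
  if (n < 1L || m < 1L) stop("association table needs at least one node per side")
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("piRNA", "disease")))
  if (nrow(edges) == 0L) stop("association table needs at least one edge")
  if (any(edges[, 1L] < 1L | edges[, 1L] > n) ||
      any(edges[, 2L] < 1L | edges[, 2L] > m)) {
    stop("edge references an index outside the id maps")
  }
  edges <- edges[!duplicated(edges), , drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  A <- matrix(0, n, m, dimnames = list(piRNA_ids, disease_ids))
  A[edges] <- 1
  structure(
    list(piRNA_ids = piRNA_ids, disease_ids = disease_ids,
         edges = edges, A_pd = A),
    class = "association_table"
  )
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("association_table: %d piRNAs x %d diseases, %d edges\n",
              length(x$piRNA_ids), length(x$disease_ids), nrow(x$edges)))
  invisible(x)
}

#' Load a piRNA-disease association edge list
#'
#' Reads a two-column, tab-separated edge list (piRNA id, disease id).
#' Ids are deduplicated in first-seen order and duplicated rows collapse to
#' a single edge.
#'
#' @param path path to the TSV file.
#' @param has_header logical; set `TRUE` when the first row is a header.
#' @return an [association_table()].
#' @export
load_associations <- function(path, has_header = FALSE) {
  if (!file.exists(path)) stop("association file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (has_header && length(lines) >= 1L) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty association file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed association row at line %d (expected 2 tab-separated fields)",
                 bad[1L] + as.integer(has_header)))
  }
  p <- vapply(parts, `[[`, "", 1L)
  d <- vapply(parts, `[[`, "", 2L)
  piRNA_ids <- unique(p)
  disease_ids <- unique(d)
  association_table(piRNA_ids, disease_ids,
                    cbind(match(p, piRNA_ids), match(d, disease_ids)))
}

#' Write an association table back to edge-list TSV
#'
#' The canonical serialization: one `piRNA_id <TAB> disease_id` row per
#' edge, sorted by (piRNA index, disease index), with a header.
#'
#' @param assoc an [association_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  stopifnot(inherits(assoc, "association_table"))
  df <- data.frame(piRNA_id = assoc$piRNA_ids[assoc$edges[, 1L]],
                   disease_id = assoc$disease_ids[assoc$edges[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

match_side <- function(side) {
  match.arg(side, c("piRNA", "disease"))
}

#' Degree distribution of one side of the bipartite graph
#'
#' For the chosen side, computes N_k (number of nodes of degree k) and
#' P_k = N_k / N, where N is the node count of that side. Degrees are row
#' sums (piRNA side) or column sums (disease side) of the incidence matrix.
#'
#' @param assoc an [association_table()].
#' @param side `"piRNA"` or `"disease"`.
#' @return a `degree_distribution` object with `side`, `degrees` (per
#'   node), `counts` (named by k) and `probabilities` (named by k).
#' @export
degree_distribution <- function(assoc, side = c("piRNA", "disease")) {
  stopifnot(inherits(assoc, "association_table"))
  side <- match_side(side)
  deg <- if (side == "piRNA") rowSums(assoc$A_pd) else colSums(assoc$A_pd)
  tab <- table(deg)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(
    list(side = side, degrees = deg, counts = counts,
         probabilities = counts / length(deg)),
    class = "degree_distribution"
  )
}

#' Remove low-degree nodes from one side
#'
#' Single-pass filter: nodes on `side` whose degree is below `min_degree`
#' are dropped together with their incident edges; the opposite side is
#' untouched even if edge removal lowers its degrees (no iterative
#' re-filtering). Id maps are re-indexed densely.
#'
#' @param assoc an [association_table()].
#' @param min_degree keep nodes with degree >= `min_degree` (default 2,
#'   i.e. drop degree-1 nodes).
#' @param side which side to filter; default `"piRNA"`.
#' @return a filtered [association_table()].
#' @export
filter_low_degree <- function(assoc, min_degree = 2L, side = "piRNA") {
  stopifnot(inherits(assoc, "association_table"), min_degree >= 1L)
  side <- match_side(side)
  deg <- if (side == "piRNA") rowSums(assoc$A_pd) else colSums(assoc$A_pd)
  keep <- which(deg >= min_degree)
  if (length(keep) == 0L) stop("filtering removed every ", side, " node")
  edges <- assoc$edges
  col <- if (side == "piRNA") 1L else 2L
  sel <- edges[, col] %in% keep
  edges <- edges[sel, , drop = FALSE]
  remap <- integer(if (side == "piRNA") length(assoc$piRNA_ids) else length(assoc$disease_ids))
  remap[keep] <- seq_along(keep)
  edges[, col] <- remap[edges[, col]]
  if (side == "piRNA") {
    association_table(assoc$piRNA_ids[keep], assoc$disease_ids, edges)
  } else {
    association_table(assoc$piRNA_ids, assoc$disease_ids[keep], edges)
  }
}

#' Binary incidence matrix of the association table
#'
#' @param assoc an [association_table()].
#' @return the N x M binary matrix whose (i, j) entry is 1 iff piRNA i is
#'   associated with disease j.
#' @export
build_bipartite_matrix <- function(assoc) {
  stopifnot(inherits(assoc, "association_table"))
  assoc$A_pd
}
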