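#' Binary k-mer presence/absence profile of piRNA sequences
#'
#' Sequences are uppercased and U is merged with T before extraction, so
#' RNA and DNA spellings of the same molecule yield identical profiles.
#' Columns are every k-mer over {A, C, G, T} in lexicographic order;
#' entries record presence only, not counts.
#'
#' @param sequences named character vector of sequences (alphabet ACGT/ACGU).
#' @param k word size; default 3.
#' @return a `kmer_profile` object: `k` and the binary N x 4^k `matrix`
#'   with sequence ids as row names.
#' @export
kmer_profile <- function(sequences, k = 3L) {
  stopifnot(k >= 1L, length(sequences) >= 1L)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  seqs <- chartr("Uu", "Tt", toupper(sequences))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("sequence '", names(sequences)[which(bad)[1L]],
         "' contains a character outside the ACGT/ACGU alphabet")
  }
  alphabet <- c("A", "C", "G", "T")
  words <- alphabet
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      words <- as.vector(t(outer(words, alphabet, paste0)))
    }
  }
  words <- sort(words)
  mat <- matrix(0L, length(seqs), length(words),
                dimnames = list(names(sequences), words))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) next  # all-zero row; caught downstream by Jaccard guard
    kmers <- unique(substring(s, 1:(n - k + 1L), k:n))
    mat[i, kmers] <- 1L
  }
  structure(list(k = as.integer(k), matrix = mat), class = "kmer_profile")
}

#' Jaccard similarity over binary profiles
#'
#' S(i, j) = |x_i AND x_j| / |x_i OR x_j| over binary rows; the diagonal is 1.
#'
#' @param profile a [kmer_profile()] or a binary matrix (rows = entities).
#' @return symmetric similarity matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
jaccard_similarity <- function(profile) {
  x <- if (inherits(profile, "kmer_profile")) profile$matrix else profile
  x <- (x != 0) * 1
  if (any(rowSums(x) == 0)) {
    stop("undefined Jaccard similarity: profile has an all-zero row ",
         "(sequence shorter than k?)")
  }
  inter <- tcrossprod(x)
  sizes <- rowSums(x)
  union <- outer(sizes, sizes, `+`) - inter
  s <- inter / union
  diag(s) <- 1
  dimnames(s) <- list(rownames(x), rownames(x))
  s
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' S(i, j) = exp(-gamma * ||A(i) - A(j)||^2), where A(i) is node i's
#' interaction-profile row and the bandwidth gamma is the raw bandwidth
#' divided by the mean squared profile norm of the side being compared.
#'
#' @param profiles matrix with one interaction profile per row (rows of
#'   the incidence matrix for piRNAs, columns for diseases).
#' @param raw_bandwidth the unnormalized bandwidth, default 1.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
gip_similarity <- function(profiles, raw_bandwidth = 1) {
  profiles <- as.matrix(profiles)
  stopifnot(raw_bandwidth > 0)
  sq_norms <- rowSums(profiles^2)
  denom <- mean(sq_norms)
  if (denom <= 0) stop("GIP bandwidth undefined: all interaction profiles are zero")
  gamma <- raw_bandwidth / denom
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(sq_norms, sq_norms, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numeric round-off
  s <- exp(-gamma * d2)
  diag(s) <- 1
  dimnames(s) <- list(rownames(profiles), rownames(profiles))
  s
}

integrate_with_gip <- function(primary, gip) {
  if (!all(dim(primary) == dim(gip))) {
    stop("similarity matrices must have identical shapes")
  }
  out <- ifelse(primary != 0, primary, 0.5 * gip)
  diag(out) <- 1
  dimnames(out) <- dimnames(primary)
  out
}

#' Integrated piRNA similarity
#'
#' Keeps the sequence-based Jaccard similarity wherever it is nonzero and
#' falls back to half the GIP kernel similarity where it is zero; the
#' diagonal stays 1.
#'
#' @param S_J Jaccard similarity matrix.
#' @param S_PG GIP similarity matrix of the same shape.
#' @return integrated similarity matrix S_P.
#' @export
integrate_piRNA_similarity <- function(S_J, S_PG) {
  integrate_with_gip(S_J, S_PG)
}

#' Integrated disease similarity
#'
#' Same fallback rule as [integrate_piRNA_similarity()], with the semantic
#' similarity as the primary matrix.
#'
#' @param S_semantic semantic similarity matrix.
#' @param S_DG GIP similarity matrix of the same shape.
#' @return integrated similarity matrix S_D.
#' @export
integrate_disease_similarity <- function(S_semantic, S_DG) {
  integrate_with_gip(S_semantic, S_DG)
}

#' Build a disease DAG from MeSH-style tree numbers or explicit edges
#'
#' With `tree_numbers`, every dot-delimited prefix of a tree number
#' becomes an ancestor term (e.g. `C04.588` contributes terms `C04` and
#' `C04.588`); a disease with several tree numbers gets the union of the
#' chains. With `parent_edges` (a child/parent table) the DAG is taken as
#' given and checked for cycles.
#'
#' @param tree_numbers data frame or TSV path with columns
#'   (disease_id, tree_number).
#' @param parent_edges data frame or TSV path with columns (child, parent);
#'   disease ids are DAG nodes directly.
#' @param decay per-hop semantic decay in (0, 1\]; default 0.5.
#' @return a `disease_dag`: `terms`, `children` (term -> child terms),
#'   `anchors` (disease id -> its own term nodes), `ancestors`
#'   (disease id -> full term set T(d)), `decay`.
#' @export
build_disease_dag <- function(tree_numbers = NULL, parent_edges = NULL,
                              decay = 0.5) {
  stopifnot(decay > 0, decay <= 1)
  if (is.null(tree_numbers) == is.null(parent_edges)) {
    stop("provide exactly one of tree_numbers or parent_edges")
  }
  read_two_col <- function(x, names) {
    if (is.character(x) && length(x) == 1L) {
      x <- utils::read.table(x, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    }
    x <- as.data.frame(x)
    if (ncol(x) < 2L) stop("expected two columns: ", paste(names, collapse = ", "))
    stats::setNames(x[, 1:2], names)
  }
  if (!is.null(tree_numbers)) {
    tn <- read_two_col(tree_numbers, c("disease_id", "tree_number"))
    edge_child <- character(0)
    edge_parent <- character(0)
    anchors <- split(as.character(tn$tree_number), as.character(tn$disease_id))
    for (t in unique(as.character(tn$tree_number))) {
      parts <- strsplit(t, ".", fixed = TRUE)[[1L]]
      if (length(parts) > 1L) {
        chain <- vapply(seq_along(parts),
                        function(i) paste(parts[1:i], collapse = "."), "")
        edge_child <- c(edge_child, chain[-1L])
        edge_parent <- c(edge_parent, chain[-length(chain)])
      }
    }
    edges <- unique(data.frame(child = edge_child, parent = edge_parent,
                               stringsAsFactors = FALSE))
    terms <- unique(c(unlist(anchors, use.names = FALSE),
                      edges$child, edges$parent))
  } else {
    edges <- unique(read_two_col(parent_edges, c("child", "parent")))
    terms <- unique(c(edges$child, edges$parent))
    anchors <- stats::setNames(as.list(terms), terms)
  }
  parents_of <- split(edges$parent, factor(edges$child, levels = terms))
  # cycle check by Kahn-style peeling on the child -> parent relation
  indeg <- vapply(parents_of, length, 1L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  children_of <- split(edges$child, factor(edges$parent, levels = terms))
  remaining <- indeg
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children_of[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) stop("cycle detected in disease DAG edge table")
  ancestors <- lapply(anchors, function(start) {
    out <- character(0)
    frontier <- unique(start)
    while (length(frontier)) {
      out <- c(out, frontier)
      frontier <- unique(unlist(parents_of[frontier], use.names = FALSE))
      frontier <- setdiff(frontier, out)
    }
    unique(out)
  })
  structure(
    list(terms = terms, children = children_of, parents = parents_of,
         anchors = anchors, ancestors = ancestors, decay = decay),
    class = "disease_dag"
  )
}

#' Semantic contribution of each ancestor term to a disease
#'
#' The disease's own term(s) contribute 1; every other term t in T(d)
#' contributes decay * max contribution of its children within T(d), i.e.
#' the decayed best path down to the disease.
#'
#' @param dag a [build_disease_dag()] object.
#' @param d disease id.
#' @return named numeric vector over T(d).
#' @export
semantic_contribution <- function(dag, d) {
  stopifnot(inherits(dag, "disease_dag"))
  Td <- dag$ancestors[[d]]
  if (is.null(Td)) stop("unknown disease id: ", d)
  contrib <- stats::setNames(rep(NA_real_, length(Td)), Td)
  anchor <- dag$anchors[[d]]
  eval_term <- function(t) {
    if (!is.na(contrib[[t]])) return(contrib[[t]])
    if (t %in% anchor) {
      contrib[[t]] <<- 1
      return(1)
    }
    kids <- intersect(dag$children[[t]], Td)
    if (!length(kids)) {
      contrib[[t]] <<- 0
      return(0)
    }
    val <- dag$decay * max(vapply(kids, eval_term, 0))
    contrib[[t]] <<- val
    val
  }
  for (t in Td) eval_term(t)
  contrib
}

#' Semantic value DV(d): total contribution over T(d)
#'
#' @inheritParams semantic_contribution
#' @return a positive scalar, at least 1.
#' @export
semantic_value <- function(dag, d) {
  sum(semantic_contribution(dag, d))
}

#' Semantic similarity between two diseases on the DAG
#'
#' Shared-ancestor contributions relative to the total semantic values:
#' sum over t in T(i) n T(j) of (D_i(t) + D_j(t)), divided by
#' DV(i) + DV(j). Symmetric, 1 on the diagonal, 0 for disjoint ancestries.
#'
#' @param dag a [build_disease_dag()] object.
#' @param i,j disease ids.
#' @return similarity in \[0, 1\].
#' @export
semantic_similarity <- function(dag, i, j) {
  ci <- semantic_contribution(dag, i)
  cj <- semantic_contribution(dag, j)
  shared <- intersect(names(ci), names(cj))
  (sum(ci[shared]) + sum(cj[shared])) / (sum(ci) + sum(cj))
}

#' Pairwise semantic similarity matrix for a set of diseases
#'
#' @param dag a [build_disease_dag()] object.
#' @param disease_ids diseases to score; defaults to every disease with an
#'   anchor term in the DAG.
#' @return symmetric matrix of [semantic_similarity()] values.
#' @export
semantic_similarity_matrix <- function(dag, disease_ids = names(dag$anchors)) {
  contribs <- lapply(disease_ids, function(d) semantic_contribution(dag, d))
  dv <- vapply(contribs, sum, 0)
  m <- length(disease_ids)
  s <- diag(1, m)
  if (m > 1L) {
    for (a in 1:(m - 1L)) {
      for (b in (a + 1L):m) {
        shared <- intersect(names(contribs[[a]]), names(contribs[[b]]))
        val <- (sum(contribs[[a]][shared]) + sum(contribs[[b]][shared])) /
          (dv[[a]] + dv[[b]])
        s[a, b] <- s[b, a] <- val
      }
    }
  }
  dimnames(s) <- list(disease_ids, disease_ids)
  s
}

#' Read piRNA sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
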