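#' Specification for a synthetic piRNA-disease benchmark fixture
#'
#' The defaults describe the planted-structure benchmark used throughout
#' the tests: 120 piRNAs and 12 diseases in 3 aligned community/group
#' blocks, roughly 400 associations concentrated within blocks, skewed
#' disease degrees, 26-31 nt sequences carrying a community motif, and a
#' toy disease hierarchy whose subtrees match the disease groups.
#'
#' @param n_piRNA,m_disease node counts.
#' @param density background edge probability per cell when no blocks are
#'   planted.
#' @param skew disease-degree skew exponent (0 = uniform; larger = more
#'   weight on top-ranked diseases within each group).
#' @param n_blocks number of planted (piRNA community, disease group)
#'   blocks; 0 disables planting.
#' @param p_in,p_out within-/cross-block edge probabilities.
#' @param length_range sequence length bounds, default c(26, 31).
#' @param motif_length length of the community motif inserted into
#'   sequences, default 12.
#' @param dag_depth,dag_branching toy disease hierarchy shape.
#' @param seed mandatory integer seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_piRNA = 120L, m_disease = 12L, density = 0.05,
                         skew = 0.5, n_blocks = 3L, p_in = 0.9, p_out = 0.02,
                         length_range = c(26L, 31L), motif_length = 12L,
                         dag_depth = 2L, dag_branching = 4L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_piRNA >= 1, m_disease >= 1, density >= 0, density <= 1,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            length_range[1] <= length_range[2])
  structure(
    list(n_piRNA = as.integer(n_piRNA), m_disease = as.integer(m_disease),
         density = density, skew = skew, n_blocks = as.integer(n_blocks),
         p_in = p_in, p_out = p_out, length_range = as.integer(length_range),
         motif_length = as.integer(motif_length),
         dag_depth = as.integer(dag_depth),
         dag_branching = as.integer(dag_branching), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

block_of <- function(i, n, n_blocks) {
  ((i - 1L) * n_blocks) %/% n + 1L
}

#' Generate a skewed bipartite association graph
#'
#' Disease attractiveness follows a Zipf-like weight rank^(-skew); with
#' planted blocks, a cell's edge probability is `p_in` within its block
#' and `p_out` across, both modulated by the disease weight; without
#' blocks the probability is 1 - (1 - density)^(m * w_d), so density 1
#' yields the complete bipartite graph. Every node is topped up to
#' degree >= 1.
#'
#' @param spec a [fixture_spec()].
#' @return an [association_table()] with ids `p0001...` / `d01...`.
#' @export
generate_bipartite <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_piRNA; m <- spec$m_disease
  with_seed(derive_seed(spec$seed, "bipartite"), {
    # per-disease weight, ranked within the whole side, mean 1
    w <- (seq_len(m))^(-spec$skew)
    w <- w * m / sum(w)
    P <- matrix(0, n, m)
    if (spec$n_blocks > 0L) {
      pb <- block_of(seq_len(n), n, spec$n_blocks)
      db <- block_of(seq_len(m), m, spec$n_blocks)
      base <- ifelse(outer(pb, db, `==`), spec$p_in, spec$p_out)
      P <- 1 - (1 - base)^rep(w, each = n)
      P <- pmin(P, 1)
    } else {
      P <- matrix(rep(1 - (1 - spec$density)^(m * w), each = n), n, m)
    }
    A <- (matrix(stats::runif(n * m), n, m) < P) * 1
    # guarantee degree >= 1 on both sides
    for (i in which(rowSums(A) == 0)) A[i, sample.int(m, 1L)] <- 1
    for (j in which(colSums(A) == 0)) A[sample.int(n, 1L), j] <- 1
    piRNA_ids <- sprintf("p%04d", seq_len(n))
    disease_ids <- sprintf("d%02d", seq_len(m))
    association_table(piRNA_ids, disease_ids, which(A == 1, arr.ind = TRUE))
  })
}

#' Generate piRNA-like random sequences
#'
#' Uniform random RNA letters of lengths drawn from `length_range`; when
#' community assignments are given, each community's motif is inserted at
#' a random offset so within-community k-mer similarity exceeds
#' between-community similarity.
#'
#' @param n number of sequences.
#' @param length_range integer bounds, default c(26, 31).
#' @param communities optional integer community label per sequence.
#' @param motifs optional character vector of per-community motifs;
#'   auto-generated distinct random motifs when `NULL`.
#' @param motif_length length of auto-generated motifs.
#' @param seed integer seed.
#' @return named character vector (ids `p0001`, ...).
#' @export
generate_sequences <- function(n, length_range = c(26L, 31L),
                               communities = NULL, motifs = NULL,
                               motif_length = 12L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  alphabet <- c("A", "C", "G", "U")
  with_seed(derive_seed(seed, "sequences"), {
    if (!is.null(communities) && is.null(motifs)) {
      motifs <- vapply(seq_len(max(communities)), function(b) {
        paste(sample(alphabet, motif_length, replace = TRUE), collapse = "")
      }, "")
    }
    if (!is.null(motifs) && any(nchar(motifs) > length_range[1])) {
      stop("motif longer than the minimum sequence length")
    }
    len_choices <- seq(length_range[1], length_range[2])
    lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(alphabet, lens[i], replace = TRUE)
      if (!is.null(communities)) {
        motif <- strsplit(motifs[communities[i]], "")[[1L]]
        off <- sample.int(lens[i] - length(motif) + 1L, 1L)
        s[off:(off + length(motif) - 1L)] <- motif
      }
      paste(s, collapse = "")
    }, "")
    names(seqs) <- sprintf("p%04d", seq_len(n))
    seqs
  })
}

#' Generate a toy disease hierarchy as tree numbers
#'
#' Leaves of a uniform `branching`-ary tree of the given depth under a
#' shared root term `R`; diseases are assigned to leaves in order, so
#' consecutive diseases are siblings sharing long prefixes while distant
#' diseases share only the root.
#'
#' @param m number of diseases (must not exceed `branching^depth`).
#' @param depth tree depth below the root, default 2.
#' @param branching children per internal node, default 4.
#' @param seed integer seed (kept for interface uniformity; the
#'   assignment is deterministic).
#' @return data frame (disease_id, tree_number).
#' @export
generate_toy_dag <- function(m, depth = 2L, branching = 4L, seed = 0L) {
  if (m > branching^depth) {
    stop("infeasible shape: ", m, " diseases but only ", branching^depth,
         " leaves at depth ", depth)
  }
  paths <- as.matrix(do.call(expand.grid,
                             rev(replicate(depth, seq_len(branching),
                                           simplify = FALSE))))
  paths <- paths[, rev(seq_len(depth)), drop = FALSE]  # first level varies slowest
  leaves <- apply(paths, 1L, function(p) paste(c("R", p), collapse = "."))
  data.frame(disease_id = sprintf("d%02d", seq_len(m)),
             tree_number = leaves[seq_len(m)],
             stringsAsFactors = FALSE)
}

#' Generate and optionally write a complete synthetic fixture
#'
#' Produces the three standard inputs (association edge TSV, FASTA,
#' tree-number TSV) plus a manifest; piRNA communities and disease groups
#' are aligned so the planted signal is visible to both the topology and
#' the feature pathway.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; created if needed.
#' @return list with `assoc`, `sequences`, `tree_numbers`, `spec`, and
#'   (when written) `paths`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  assoc <- generate_bipartite(spec)
  communities <- if (spec$n_blocks > 0L) {
    block_of(seq_len(spec$n_piRNA), spec$n_piRNA, spec$n_blocks)
  } else NULL
  seqs <- generate_sequences(spec$n_piRNA, spec$length_range,
                             communities = communities,
                             motif_length = spec$motif_length,
                             seed = spec$seed)
  tn <- generate_toy_dag(spec$m_disease, spec$dag_depth, spec$dag_branching,
                         spec$seed)
  out <- list(assoc = assoc, sequences = seqs, tree_numbers = tn, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(edges = file.path(dir, "associations.tsv"),
                  fasta = file.path(dir, "sequences.fasta"),
                  tree = file.path(dir, "tree_numbers.tsv"),
                  manifest = file.path(dir, "manifest.yaml"))
    df <- data.frame(assoc$piRNA_ids[assoc$edges[, 1L]],
                     assoc$disease_ids[assoc$edges[, 2L]])
    utils::write.table(df, paths$edges, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_fasta(seqs, paths$fasta)
    utils::write.table(tn, paths$tree, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    yaml::write_yaml(unclass(spec), paths$manifest)
    out$paths <- paths
  }
  out
}
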