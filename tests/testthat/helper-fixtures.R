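# shared in-code fixtures; everything is generated at test time

# small random association table with a reproducible edge set
random_assoc <- function(n = 20, m = 5, n_edges = 30, seed = 42) {
  with_seed(seed, {
    cells <- sample(n * m, n_edges)
    edges <- cbind((cells - 1L) %% n + 1L, (cells - 1L) %/% n + 1L)
    # top up empty rows/columns so the table is valid
    A <- matrix(0, n, m); A[edges] <- 1
    for (i in which(rowSums(A) == 0)) A[i, sample(m, 1)] <- 1
    for (j in which(colSums(A) == 0)) A[sample(n, 1), j] <- 1
    association_table(paste0("p", seq_len(n)), paste0("d", seq_len(m)),
                      which(A == 1, arr.ind = TRUE))
  })
}

# random binary profile matrix
random_profiles <- function(n = 10, d = 6, seed = 1) {
  with_seed(seed, matrix(rbinom(n * d, 1, 0.4), n, d))
}

# the standard planted-structure benchmark spec used across tests
benchmark_spec <- function(seed) fixture_spec(seed = seed)

# tiny trained model on a toy graph, reused by predictor tests
toy_trained_model <- function(epochs = 50, seed = 5) {
  n <- 6; m <- 3
  A_pd <- matrix(0, n, m)
  A_pd[cbind(c(1, 2, 3, 4, 5, 6, 1, 4), c(1, 1, 2, 2, 3, 3, 2, 3))] <- 1
  A_pp <- bipartite_projection(A_pd, "piRNA")
  A_dd <- bipartite_projection(A_pd, "disease")
  adj <- assemble_adjacency(A_pp, A_dd, A_pd)
  nir <- with_seed(seed, matrix(rnorm((n + m) * 4), n + m, 4))
  pairs <- rbind(which(A_pd == 1, arr.ind = TRUE),
                 which(A_pd == 0, arr.ind = TRUE))
  labels <- c(rep(1, sum(A_pd)), rep(0, sum(A_pd == 0)))
  cfg <- model_config(h1 = 8, h2 = 8, f1 = 8, f2 = 4, dropout = 0,
                      epochs = epochs, seed = seed)
  list(model = train_pda_gcn(adj, nir, pairs, labels, cfg),
       adj = adj, nir = nir, pairs = pairs, labels = labels,
       A_pd = A_pd, n = n, m = m)
}
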