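test_that("heterogeneous adjacency has the block layout and normalized operator", {
  A_pd <- matrix(0, 2, 2)
  adj0 <- assemble_adjacency(matrix(0, 2, 2), matrix(0, 2, 2),
                             rbind(c(1, 0), c(0, 1)))
  expect_equal(adj0$A[1:2, 3:4], rbind(c(1, 0), c(0, 1)))
  expect_equal(adj0$A, t(adj0$A))

  # all-zero blocks: A = 0, G = I
  adjz <- assemble_adjacency(matrix(0, 2, 2), matrix(0, 3, 3),
                             matrix(0, 2, 3))
  expect_equal(adjz$G, diag(5))

  # dense hand-computed oracle on a 6 + 3 node fixture
  with_seed(37, {
    A_pd <- matrix(rbinom(18, 1, 0.4), 6, 3)
  })
  A_pp <- bipartite_projection(A_pd, "piRNA")
  A_dd <- bipartite_projection(A_pd, "disease")
  adj <- assemble_adjacency(A_pp, A_dd, A_pd)
  A <- rbind(cbind(A_pp, A_pd), cbind(t(A_pd), A_dd))
  Ap <- A + diag(9)
  Dm <- diag(1 / sqrt(rowSums(Ap)))
  expect_equal(adj$G, Dm %*% Ap %*% Dm, tolerance = 1e-12)
  expect_error(assemble_adjacency(A_pp, A_dd, t(A_pd)), "conform")
})

test_that("the normalized operator has spectral radius at most 1", {
  for (s in c(1, 2, 3)) {
    fx <- generate_fixture(fixture_spec(n_piRNA = 30, m_disease = 8,
                                        dag_branching = 3, seed = s))
    A_pd <- fx$assoc$A_pd
    adj <- assemble_adjacency(bipartite_projection(A_pd, "piRNA"),
                              bipartite_projection(A_pd, "disease"), A_pd)
    expect_lte(max(abs(eigen(adj$G, only.values = TRUE)$values)), 1 + 1e-10)
  }
})

test_that("the leakage guard fires when a held-out edge is in the adjacency", {
  A_pd <- rbind(c(1, 1), c(1, 0))
  expect_error(
    assemble_adjacency(matrix(0, 2, 2), matrix(0, 2, 2), A_pd,
                       holdout_pairs = cbind(1, 2)),
    "leakage")
  expect_silent(
    assemble_adjacency(matrix(0, 2, 2), matrix(0, 2, 2), A_pd,
                       holdout_pairs = cbind(2, 2)))
})

test_that("GCN forward propagation matches a dense matrix-chain oracle", {
  # identity propagation
  H0 <- matrix(abs(rnorm(12)), 4, 3)
  w <- list(W0 = diag(3), W1 = diag(3))
  H2 <- gcn_forward(diag(4), H0, w)
  expect_equal(unname(H2), unname(H0), ignore_attr = TRUE)

  with_seed(41, {
    A_pd <- matrix(rbinom(18, 1, 0.5), 6, 3)
    H0r <- matrix(rnorm(9 * 4), 9, 4)
    wr <- list(W0 = matrix(rnorm(4 * 5), 4, 5), W1 = matrix(rnorm(5 * 2), 5, 2))
  })
  adj <- assemble_adjacency(bipartite_projection(A_pd, "piRNA"),
                            bipartite_projection(A_pd, "disease"), A_pd)
  H2r <- gcn_forward(adj, H0r, wr)
  step1 <- pmax(adj$G %*% H0r %*% wr$W0, 0)
  step2 <- adj$G %*% step1 %*% wr$W1
  expect_equal(unname(H2r), unname(step2), ignore_attr = TRUE)

  # permuting node order permutes embeddings identically (within one side)
  perm <- c(3, 1, 2, 6, 5, 4)
  adj_p <- assemble_adjacency(
    bipartite_projection(A_pd[perm, ], "piRNA"),
    bipartite_projection(A_pd[perm, ], "disease"), A_pd[perm, ])
  H2p <- gcn_forward(adj_p, H0r[c(perm, 7:9), ], wr)
  expect_equal(unname(H2p[1:6, ]), unname(H2r[perm, ]), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("the link predictor is a plain feed-forward map of pair embeddings", {
  with_seed(43, H2 <- matrix(rnorm(8 * 6), 8, 6))
  wz <- list(F1 = matrix(0, 12, 4), b1 = rep(0, 4),
             F2 = matrix(0, 4, 3), b2 = rep(0, 3),
             F3 = matrix(0, 3, 1), b3 = 0)
  p <- predict_links(H2, rbind(c(1, 1), c(5, 2)), wz, n_piRNA = 5)
  expect_equal(p, c(0.5, 0.5))  # sigmoid(0) everywhere with zero weights

  with_seed(44, wr <- list(F1 = matrix(rnorm(48), 12, 4), b1 = rnorm(4),
                           F2 = matrix(rnorm(12), 4, 3), b2 = rnorm(3),
                           F3 = matrix(rnorm(3), 3, 1), b3 = 0.3))
  pairs <- rbind(c(2, 1), c(2, 1), c(4, 3))
  pr <- predict_links(H2, pairs, wr, n_piRNA = 5)
  expect_equal(pr[1], pr[2])  # duplicated pair, identical output
  # manual layer-by-layer evaluation
  x <- c(H2[4, ], H2[5 + 3, ])
  a1 <- pmax(x %*% wr$F1 + wr$b1, 0)
  a2 <- pmax(a1 %*% wr$F2 + wr$b2, 0)
  expect_equal(pr[3], as.vector(1 / (1 + exp(-(a2 %*% wr$F3 + 0.3)))))
  expect_true(all(pr > 0 & pr < 1))
  expect_error(predict_links(H2, cbind(6, 1), wr, n_piRNA = 5), "range")
})

test_that("dual loss matches direct substitution and finite differences", {
  # perfect prediction limit
  y <- c(1, 1, 0, 0)
  expect_lt(dual_loss(y, c(0.9999, 0.9999, 1e-4, 1e-4)), 1e-3)

  # flat 0.5 scores on a balanced batch
  parts <- dual_loss(y, rep(0.5, 4), w = 0.1, components = TRUE)
  expect_equal(parts$ss, 0.5)
  expect_equal(parts$ce, -log(0.5))

  expect_warning(dual_loss(c(1, 1), c(0.6, 0.7)), "single-class")

  # finite-difference oracle for the gradient wrt the logit
  with_seed(51, {
    y6 <- c(1, 0, 1, 0, 0, 1)
    logit <- rnorm(6)
  })
  p <- 1 / (1 + exp(-logit))
  g <- pdalink:::dual_loss_grad_logit(y6, p, 0.1)
  eps <- 1e-6
  for (i in 1:6) {
    lp <- logit; lp[i] <- lp[i] + eps
    lm <- logit; lm[i] <- lm[i] - eps
    fd <- (dual_loss(y6, 1 / (1 + exp(-lp)), 0.1) -
           dual_loss(y6, 1 / (1 + exp(-lm)), 0.1)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-6)
  }
})

test_that("training is deterministic, loss decreases, and lr 0 is a null step", {
  t1 <- toy_trained_model(epochs = 60, seed = 5)
  t2 <- toy_trained_model(epochs = 60, seed = 5)
  expect_identical(t1$model$loss_trace, t2$model$loss_trace)
  expect_identical(t1$model$weights, t2$model$weights)
  expect_lt(tail(t1$model$loss_trace, 1), t1$model$loss_trace[1])
  expect_true(all(is.finite(t1$model$loss_trace)))

  cfg0 <- model_config(h1 = 8, h2 = 8, f1 = 8, f2 = 4, dropout = 0,
                       epochs = 10, learning_rate = 0, seed = 5)
  m0 <- train_pda_gcn(t1$adj, t1$nir, t1$pairs, t1$labels, cfg0)
  expect_equal(max(abs(m0$loss_trace - m0$loss_trace[1])), 0)
  w_init <- pdalink:::init_gcn_weights(ncol(t1$nir), cfg0)
  expect_equal(m0$weights, w_init)
})

test_that("end-to-end predictions are invariant under consistent relabeling", {
  t1 <- toy_trained_model(epochs = 40, seed = 9)
  n <- t1$n
  with_seed(10, perm <- sample(n))
  A_pd_p <- t1$A_pd[perm, ]
  adj_p <- assemble_adjacency(bipartite_projection(A_pd_p, "piRNA"),
                              bipartite_projection(A_pd_p, "disease"), A_pd_p)
  nir_p <- t1$nir
  nir_p[1:n, ] <- t1$nir[perm, ]
  pairs_p <- t1$pairs
  pairs_p[, 1] <- match(pairs_p[, 1], perm)
  cfg <- model_config(h1 = 8, h2 = 8, f1 = 8, f2 = 4, dropout = 0,
                      epochs = 40, seed = 9)
  m_p <- train_pda_gcn(adj_p, nir_p, pairs_p, t1$labels, cfg)
  # same weight init (seeded) + equivariant graph ops => same predictions
  expect_equal(predict(m_p, pairs_p), predict(t1$model, t1$pairs),
               tolerance = 1e-8)
})

test_that("training on a planted-structure graph separates held-out links", {
  fx <- generate_fixture(benchmark_spec(61))
  assoc <- fx$assoc
  SJ <- jaccard_similarity(kmer_profile(fx$sequences[assoc$piRNA_ids]))
  dag <- build_disease_dag(tree_numbers = fx$tree_numbers)
  Ss <- semantic_similarity_matrix(dag, assoc$disease_ids)
  neg <- sample_negatives(assoc, 1, seed = 62)
  splits <- make_cv_splits(assoc$edges, neg, 5, seed = 63)
  cfg <- model_config(epochs = 500, seed = 64)
  fold <- splits$folds[[1]]
  res <- pdalink:::run_fold(assoc, SJ, Ss, fold, splits, cfg, list(),
                            fold_seed = 65)
  expect_gt(res$metrics$auc, 0.9)
})
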