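test_that("negative sampling avoids positives and respects the ratio", {
  assoc <- association_table(c("p1", "p2"), c("d1", "d2"),
                             rbind(c(1, 1), c(2, 2)))
  neg <- sample_negatives(assoc, 1, seed = 1)
  expect_equal(nrow(neg), 2)
  expect_setequal(paste(neg[, 1], neg[, 2]), c("1 2", "2 1"))

  expect_identical(sample_negatives(assoc, 1, seed = 7),
                   sample_negatives(assoc, 1, seed = 7))

  big <- random_assoc(n = 40, m = 10, n_edges = 50, seed = 2)
  neg5 <- sample_negatives(big, 5, seed = 3)
  expect_equal(nrow(neg5), 5 * nrow(big$edges))
  expect_equal(anyDuplicated(neg5), 0)
  overlap <- intersect(paste(neg5[, 1], neg5[, 2]),
                       paste(big$edges[, 1], big$edges[, 2]))
  expect_length(overlap, 0)
  expect_error(sample_negatives(assoc, 10, seed = 1), "not enough")
})

test_that("cross-validation folds partition positives and negatives", {
  assoc <- random_assoc(n = 20, m = 5, n_edges = 30, seed = 4)
  pos <- assoc$edges[1:10, ]
  neg <- sample_negatives(assoc, 1, seed = 5)[1:10, ]
  plan <- make_cv_splits(pos, neg, 5, seed = 6)
  test_sets <- lapply(plan$folds, `[[`, "test_pos")
  expect_equal(sort(unlist(test_sets)), 1:10)
  expect_equal(vapply(test_sets, length, 1L), rep(2L, 5))
  for (f in plan$folds) {
    expect_length(intersect(f$test_pos, f$train_pos), 0)
    expect_setequal(c(f$test_pos, f$train_pos), 1:10)
    # class balance within one sample of the global 1:1 ratio
    expect_lte(abs(length(f$test_pos) - length(f$test_neg)), 1)
  }
  expect_error(make_cv_splits(pos[1:3, ], neg, 5, seed = 1), "fewer positives")
})

test_that("metrics match the worked confusion matrix and pair-counting AUC", {
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$auc, 0.75)

  sep <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$auc, 1)
  expect_equal(sep$aupr, 1)

  ties <- compute_metrics(c(0, 1, 0, 1), rep(0.4, 4))
  expect_equal(ties$auc, 0.5)
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)), "single-class")
})

test_that("rank AUC equals the Mann-Whitney pair-counting oracle", {
  with_seed(71, {
    for (rep in 1:5) {
      n <- sample(20:200, 1)
      y <- rbinom(n, 1, 0.4)
      if (sum(y) == 0 || sum(y) == n) next
      s <- round(runif(n), 2)  # coarse grid forces ties
      pairs_won <- 0
      for (i in which(y == 1)) for (j in which(y == 0)) {
        pairs_won <- pairs_won + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
      }
      oracle <- pairs_won / (sum(y == 1) * sum(y == 0))
      expect_equal(compute_metrics(y, s)$auc, oracle)
    }
  })
})

test_that("ranking metrics are invariant to strictly monotone score transforms", {
  with_seed(73, {
    y <- rbinom(60, 1, 0.5)
    s <- runif(60)
  })
  base <- compute_metrics(y, s)
  trans <- compute_metrics(y, qlogis(s / 2 + 0.25))
  expect_equal(trans$auc, base$auc)
  expect_equal(trans$aupr, base$aupr)
})

test_that("cross-validation runs clean on a small fixture and audits leak-free", {
  fx <- generate_fixture(fixture_spec(n_piRNA = 30, m_disease = 8,
                                      dag_branching = 3, seed = 81))
  assoc <- fx$assoc
  neg <- sample_negatives(assoc, 1, seed = 82)
  splits <- make_cv_splits(assoc$edges, neg, 3, seed = 83)
  cfg <- model_config(h1 = 16, h2 = 16, f1 = 16, f2 = 8, epochs = 60,
                      seed = 84)
  rep <- run_cross_validation(
    assoc, fx$sequences, build_disease_dag(tree_numbers = fx$tree_numbers),
    cfg, splits, mode_flags = list(encoder_epochs = 40, d0 = 8),
    keep_models = TRUE)
  expect_equal(nrow(rep$table), 4)  # 3 folds + mean
  expect_true(all(rep$table$auc >= 0 & rep$table$auc <= 1))
  mean_row <- rep$table[4, ]
  expect_equal(mean_row$auc, mean(rep$table$auc[1:3]))
  expect_true(audit_leakage(rep))
  # no test positive in any fold's training incidence, GIP input included
  for (f in seq_len(3)) {
    det <- rep$folds[[f]]
    expect_true(all(det$A_train[det$holdout] == 0))
  }
})

test_that("link embeddings export one identifiable row per pair", {
  t1 <- toy_trained_model(epochs = 30, seed = 13)
  pairs <- rbind(c(1, 1), c(2, 2), c(1, 1))
  df <- export_link_embeddings(t1$model, pairs, c(1, 0, 1))
  expect_equal(nrow(df), 3)
  expect_equal(ncol(df), 3 + 2 * 8)  # ids + label + concat embedding
  expect_equal(unlist(df[1, -(1:3)]), unlist(df[3, -(1:3)]))

  f <- withr::local_tempfile(fileext = ".tsv")
  export_link_embeddings(t1$model, pairs, c(1, 0, 1), f)
  back <- utils::read.delim(f)
  expect_equal(as.matrix(back[, -(1:3)]), as.matrix(df[, -(1:3)]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("candidate ranking excludes knowns and matches score-then-sort", {
  t1 <- toy_trained_model(epochs = 30, seed = 14)
  assoc <- association_table(paste0("p", 1:t1$n), paste0("d", 1:t1$m),
                             which(t1$A_pd == 1, arr.ind = TRUE))
  rk <- rank_candidates(t1$model, assoc, "d1", exclude_known = TRUE)
  known <- assoc$piRNA_ids[assoc$A_pd[, 1] == 1]
  expect_length(intersect(rk$piRNA_id, known), 0)

  all_rk <- rank_candidates(t1$model, assoc, "d1", exclude_known = FALSE)
  scores <- predict(t1$model, cbind(1:t1$n, 1))
  ord <- order(-scores, assoc$piRNA_ids)
  expect_equal(all_rk$piRNA_id, assoc$piRNA_ids[ord])
  expect_equal(all_rk$score, scores[ord])
  # top-k is a prefix of top-(k+1)
  expect_equal(all_rk$piRNA_id[1:3], all_rk$piRNA_id[1:4][1:3])
  expect_error(rank_candidates(t1$model, assoc, "nope"), "unknown disease")
})
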