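#' Sample negative (unlabeled) piRNA-disease pairs
#'
#' Uniform draw without replacement from the cells of the incidence
#' matrix that are not known positives.
#'
#' @param assoc an [association_table()].
#' @param ratio negatives per positive (1, 5, 10, ...), default 1.
#' @param seed integer seed; the draw is reproducible.
#' @return two-column matrix of (piRNA index, disease index) pairs.
#' @export
sample_negatives <- function(assoc, ratio = 1, seed) {
  stopifnot(inherits(assoc, "association_table"))
  if (missing(seed)) stop("a seed is mandatory")
  n <- length(assoc$piRNA_ids); m <- length(assoc$disease_ids)
  n_pos <- nrow(assoc$edges)
  needed <- round(n_pos * ratio)
  free <- which(assoc$A_pd == 0)  # column-major linear indices
  if (length(free) < needed) {
    stop("not enough unlabeled pairs: need ", needed, ", have ", length(free))
  }
  chosen <- with_seed(seed, sample(free, needed))
  cbind(piRNA = as.integer((chosen - 1L) %% n + 1L),
        disease = as.integer((chosen - 1L) %/% n + 1L))
}

#' Build a k-fold cross-validation split plan
#'
#' Positives and negatives are shuffled and partitioned independently
#' into `k_folds` near-equal parts; fold f tests part f of each and
#' trains on the rest, so train and test negatives are disjoint.
#'
#' @param positives two-column matrix of positive pairs.
#' @param negatives two-column matrix of sampled negative pairs.
#' @param k_folds number of folds, default 5.
#' @param seed integer seed.
#' @return a `split_plan`: `folds` (each with `test_pos`, `test_neg`,
#'   `train_pos`, `train_neg` row-index vectors), `positives`,
#'   `negatives`, `k_folds`, `seed`.
#' @export
make_cv_splits <- function(positives, negatives, k_folds = 5L, seed) {
  stopifnot(k_folds >= 2L)
  if (missing(seed)) stop("a seed is mandatory")
  n_pos <- nrow(positives); n_neg <- nrow(negatives)
  if (n_pos < k_folds) stop("fewer positives than folds")
  assign_folds <- function(n, s) {
    perm <- with_seed(s, sample.int(n))
    rep_len(seq_len(k_folds), n)[order(perm)]
  }
  fold_pos <- assign_folds(n_pos, derive_seed(seed, "fold_pos"))
  fold_neg <- assign_folds(n_neg, derive_seed(seed, "fold_neg"))
  folds <- lapply(seq_len(k_folds), function(f) {
    list(test_pos = which(fold_pos == f), test_neg = which(fold_neg == f),
         train_pos = which(fold_pos != f), train_neg = which(fold_neg != f))
  })
  structure(
    list(folds = folds, positives = positives, negatives = negatives,
         k_folds = as.integer(k_folds), seed = seed),
    class = "split_plan"
  )
}

#' Classification and ranking metrics for one set of scores
#'
#' AUC by the rank (Mann-Whitney) statistic with ties averaged; AUPR by
#' step-wise integration of the precision-recall curve (average
#' precision, no interpolation); accuracy, precision, recall and F1 from
#' the confusion matrix at `threshold`.
#'
#' @param labels binary labels with both classes present.
#' @param scores numeric scores.
#' @param threshold classification threshold, default 0.5.
#' @return one-row data frame: accuracy, precision, recall, f1, auc,
#'   aupr, threshold.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as.numeric(labels)
  stopifnot(length(y) == length(scores), all(y %in% c(0, 1)))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("metrics undefined for single-class labels")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # average precision over positives in score-descending order; ties are
  # broken by original index for determinism
  ord <- order(-scores, seq_along(scores))
  ys <- y[ord]
  cum_tp <- cumsum(ys)
  prec_at <- cum_tp / seq_along(ys)
  aupr <- sum(prec_at[ys == 1]) / n_pos
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  data.frame(accuracy = (tp + tn) / length(y), precision = precision,
             recall = recall, f1 = f1, auc = auc, aupr = aupr,
             threshold = threshold)
}

binarize_similarity <- function(S, threshold = NULL) {
  S <- as.matrix(S)
  off <- S[row(S) != col(S)]
  if (is.null(threshold)) threshold <- mean(off)
  adj <- (S > threshold) * 1
  diag(adj) <- 0
  adj <- 1 * ((adj + t(adj)) > 0)
  adj
}

#' Per-fold pipeline: rebuild, train and score one CV fold
#'
#' Everything derived from associations (GIP profiles, projection or
#' similarity subgraphs, residual scaling, the A_pd adjacency block) is
#' rebuilt from the fold's training positives only; test edges are zeroed
#' everywhere upstream of training.
#'
#' @keywords internal
run_fold <- function(assoc, S_J, S_sem, fold, splits, config, mode_flags,
                     fold_seed) {
  n <- length(assoc$piRNA_ids); m <- length(assoc$disease_ids)
  pos <- splits$positives; neg <- splits$negatives
  A_train <- matrix(0, n, m, dimnames = dimnames(assoc$A_pd))
  A_train[pos[fold$train_pos, , drop = FALSE]] <- 1
  holdout <- pos[fold$test_pos, , drop = FALSE]

  S_PG <- gip_similarity(A_train)
  S_DG <- gip_similarity(t(A_train))
  S_P <- integrate_piRNA_similarity(S_J, S_PG)
  S_D <- integrate_disease_similarity(S_sem, S_DG)

  subgraph <- mode_flags$subgraph %||% "projection"
  # permissive variant: build the intra-side subgraphs from ALL known
  # edges instead of the training fold only (leaks structure; off by
  # default and excluded from the leakage audit's guarantees)
  A_proj <- if (isTRUE(mode_flags$static_subgraphs)) assoc$A_pd else A_train
  if (subgraph == "projection") {
    A_pp <- build_projection_subgraph(A_proj, "piRNA",
                                      mu = mode_flags$mu_p %||% 100)$adjacency
    A_dd <- build_projection_subgraph(A_proj, "disease",
                                      mu = mode_flags$mu_d %||% 1)$adjacency
  } else if (subgraph == "similarity") {
    A_pp <- binarize_similarity(S_P)
    A_dd <- binarize_similarity(S_D)
  } else if (subgraph == "rs_similarity") {
    Rp <- residual_profile(S_P, A_train, "piRNA",
                           mode_flags$delta_scale_p %||% 10)
    Rd <- residual_profile(S_D, A_train, "disease",
                           mode_flags$delta_scale_d %||% 10)
    Sp2 <- residual_scale(S_P, Rp); Sp2 <- (Sp2 + t(Sp2)) / 2
    Sd2 <- residual_scale(S_D, Rd); Sd2 <- (Sd2 + t(Sd2)) / 2
    A_pp <- binarize_similarity(Sp2)
    A_dd <- binarize_similarity(Sd2)
  } else stop("unknown subgraph mode: ", subgraph)

  nir <- node_initial_representation(
    S_P, S_D, A_train,
    delta_scale_p = mode_flags$delta_scale_p %||% 10,
    delta_scale_d = mode_flags$delta_scale_d %||% 10,
    d0 = mode_flags$d0 %||% 64L,
    seed = derive_seed(fold_seed, "nir"),
    mode = mode_flags$nir %||% "augmented",
    mu_mode = mode_flags$mu_mode %||% "raw_degree_mean",
    epochs = mode_flags$encoder_epochs %||% 200L
  )
  adjacency <- assemble_adjacency(A_pp, A_dd, A_train,
                                  holdout_pairs = holdout)
  train_pairs <- rbind(pos[fold$train_pos, , drop = FALSE],
                       neg[fold$train_neg, , drop = FALSE])
  train_labels <- c(rep(1, length(fold$train_pos)),
                    rep(0, length(fold$train_neg)))
  fold_config <- config
  fold_config$seed <- derive_seed(fold_seed, "train")
  model <- train_pda_gcn(adjacency, nir, train_pairs, train_labels,
                         fold_config)
  test_pairs <- rbind(pos[fold$test_pos, , drop = FALSE],
                      neg[fold$test_neg, , drop = FALSE])
  test_labels <- c(rep(1, length(fold$test_pos)),
                   rep(0, length(fold$test_neg)))
  scores <- predict(model, test_pairs)
  list(model = model, metrics = compute_metrics(test_labels, scores),
       scores = scores, test_pairs = test_pairs, test_labels = test_labels,
       A_train = A_train, holdout = holdout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated evaluation of the link predictor
#'
#' Runs the full per-fold pipeline of [run_fold()] over every fold of a
#' [make_cv_splits()] plan and aggregates the metric table (one row per
#' fold plus an arithmetic-mean row).
#'
#' @param assoc an [association_table()].
#' @param sequences named character vector of piRNA sequences (ignored
#'   when `S_J` is supplied).
#' @param dag a [build_disease_dag()] (ignored when `S_sem` is supplied).
#' @param config a [model_config()].
#' @param splits a [make_cv_splits()] plan.
#' @param mode_flags list of ablation/config switches: `subgraph`
#'   (`"projection"`, `"similarity"`, `"rs_similarity"`), `nir`
#'   (`"augmented"`, `"raw_similarity"`, `"constant"`), `mu_mode`
#'   (residual centering, see [residual_profile()]), `static_subgraphs`
#'   (`TRUE` builds intra-side subgraphs from all known edges — the
#'   permissive, leak-prone variant), `mu_p`, `mu_d`, `delta_scale_p`,
#'   `delta_scale_d`, `d0`, `encoder_epochs`, `kmer_k`.
#' @param S_J,S_sem precomputed piRNA Jaccard / disease semantic
#'   similarity matrices (optional shortcuts).
#' @param keep_models retain per-fold models (default keeps the last
#'   fold's model only).
#' @return an `eval_report`: `table` (folds + mean row), `folds`
#'   (per-fold details for auditing), `config`, `mode_flags`.
#' @export
run_cross_validation <- function(assoc, sequences = NULL, dag = NULL,
                                 config, splits, mode_flags = list(),
                                 S_J = NULL, S_sem = NULL,
                                 keep_models = FALSE) {
  stopifnot(inherits(assoc, "association_table"),
            inherits(splits, "split_plan"))
  n <- length(assoc$piRNA_ids); m <- length(assoc$disease_ids)
  if (is.null(S_J)) {
    if (is.null(sequences)) stop("need sequences or a precomputed S_J")
    S_J <- jaccard_similarity(kmer_profile(sequences[assoc$piRNA_ids],
                                           mode_flags$kmer_k %||% 3L))
  }
  if (is.null(S_sem)) {
    if (is.null(dag)) stop("need a disease DAG or a precomputed S_sem")
    S_sem <- semantic_similarity_matrix(dag, assoc$disease_ids)
  }
  stopifnot(nrow(S_J) == n, nrow(S_sem) == m)
  fold_rows <- list()
  fold_details <- list()
  for (f in seq_along(splits$folds)) {
    fold_seed <- derive_seed(splits$seed, paste0("fold", f))
    res <- run_fold(assoc, S_J, S_sem, splits$folds[[f]], splits, config,
                    mode_flags, fold_seed)
    fold_rows[[f]] <- cbind(fold = f, res$metrics)
    if (!keep_models && f < length(splits$folds)) res$model <- NULL
    fold_details[[f]] <- res
  }
  tab <- do.call(rbind, fold_rows)
  mean_row <- cbind(fold = NA,
                    as.data.frame(t(colMeans(tab[, -1, drop = FALSE]))))
  tab <- rbind(tab, mean_row)
  structure(
    list(table = tab, folds = fold_details, config = config,
         mode_flags = mode_flags, splits = splits),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("cross-validation report (last row = mean):\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Audit a cross-validation report for train/test leakage
#'
#' Checks, for every fold, that no test positive pair is present in the
#' training incidence matrix (which also feeds the GIP profiles and the
#' projection subgraphs).
#'
#' @param report an `eval_report` from [run_cross_validation()].
#' @return `TRUE` invisibly if clean; otherwise an error.
#' @export
audit_leakage <- function(report) {
  for (f in seq_along(report$folds)) {
    det <- report$folds[[f]]
    if (any(det$A_train[det$holdout] != 0)) {
      stop("leakage detected in fold ", f)
    }
  }
  invisible(TRUE)
}

#' Export link embeddings for external 2D projection
#'
#' One row per pair: the ids, the label, and the link embedding (the
#' concatenated or Hadamard node embedding used by the predictor).
#'
#' @param model a trained `pda_model`.
#' @param pairs two-column (piRNA index, disease index) matrix.
#' @param labels binary labels for `pairs`.
#' @param path optional TSV output path.
#' @param piRNA_ids,disease_ids id vectors used to label rows.
#' @return the embedding data frame, invisibly when written to `path`.
#' @export
export_link_embeddings <- function(model, pairs, labels, path = NULL,
                                   piRNA_ids = NULL, disease_ids = NULL) {
  stopifnot(inherits(model, "pda_model"))
  pairs <- matrix(as.integer(as.matrix(pairs)[, 1:2]), ncol = 2L)
  emb <- link_features(model$embeddings, pairs, model$n_piRNA,
                       model$config$link_op)
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  pid <- if (is.null(piRNA_ids)) pairs[, 1L] else piRNA_ids[pairs[, 1L]]
  did <- if (is.null(disease_ids)) pairs[, 2L] else disease_ids[pairs[, 2L]]
  df <- data.frame(piRNA_id = pid, disease_id = did,
                   label = as.numeric(labels), emb, check.names = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Rank candidate piRNAs for one disease
#'
#' Scores every piRNA against the disease and sorts descending, breaking
#' score ties by piRNA id for determinism; known training positives can
#' be excluded.
#'
#' @param model a trained `pda_model`.
#' @param assoc the [association_table()] the model was trained on (id
#'   maps and known edges).
#' @param disease_id disease to query.
#' @param exclude_known drop known associated piRNAs, default `TRUE`.
#' @return data frame (piRNA_id, score) in rank order.
#' @export
rank_candidates <- function(model, assoc, disease_id, exclude_known = TRUE) {
  j <- match(disease_id, assoc$disease_ids)
  if (is.na(j)) stop("unknown disease id: ", disease_id)
  n <- length(assoc$piRNA_ids)
  pairs <- cbind(seq_len(n), j)
  scores <- predict(model, pairs)
  keep <- rep(TRUE, n)
  if (exclude_known) keep <- assoc$A_pd[, j] == 0
  df <- data.frame(piRNA_id = assoc$piRNA_ids[keep], score = scores[keep])
  df[order(-df$score, df$piRNA_id), , drop = FALSE]
}
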