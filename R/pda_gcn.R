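#' Model hyper-parameters for the GCN link predictor
#'
#' @param h1,h2 GCN layer widths (default 64 each).
#' @param f1,f2 hidden widths of the fully-connected predictor (the input
#'   width is fixed by the link operator, 2*h2 for concatenation).
#' @param dropout dropout rate in \[0, 1), default 0.2.
#' @param learning_rate Adam step size, default 0.002.
#' @param epochs training epochs, default 12000 (use far fewer for small
#'   synthetic benchmarks).
#' @param loss_weight sensitivity ratio w of the dual loss, in (0, 1);
#'   candidate set {0.1, 0.01}, default 0.1.
#' @param seed mandatory integer seed.
#' @param link_op `"concat"` (default) or `"hadamard"` link embedding.
#' @param activation2 second GCN layer activation, `"linear"` (default)
#'   or `"relu"`.
#' @return a `model_config` list.
#' @export
model_config <- function(h1 = 64L, h2 = 64L, f1 = 64L, f2 = 32L,
                         dropout = 0.2, learning_rate = 0.002,
                         epochs = 12000L, loss_weight = 0.1, seed,
                         link_op = c("concat", "hadamard"),
                         activation2 = c("linear", "relu")) {
  link_op <- match.arg(link_op)
  activation2 <- match.arg(activation2)
  stopifnot(dropout >= 0, dropout < 1, epochs >= 1,
            loss_weight > 0, loss_weight < 1, learning_rate >= 0)
  if (missing(seed)) stop("a seed is mandatory")
  structure(
    list(h1 = as.integer(h1), h2 = as.integer(h2),
         f1 = as.integer(f1), f2 = as.integer(f2),
         dropout = dropout, learning_rate = learning_rate,
         epochs = as.integer(epochs), loss_weight = loss_weight,
         seed = as.integer(seed), link_op = link_op,
         activation2 = activation2),
    class = "model_config"
  )
}

#' Assemble the heterogeneous adjacency and its normalized operator
#'
#' Lays out the (N + M) x (N + M) block matrix \[A_pp, A_pd; t(A_pd),
#' A_dd\] and computes the symmetric normalization
#' G = D^(-1/2) (A + I) D^(-1/2).
#'
#' @param A_pp binary symmetric piRNA-piRNA adjacency (or a
#'   `projection_subgraph`).
#' @param A_dd binary symmetric disease-disease adjacency (or a
#'   `projection_subgraph`).
#' @param A_pd_train binary incidence block; must contain only
#'   training-fold positive edges.
#' @param holdout_pairs optional two-column matrix of held-out
#'   (piRNA, disease) index pairs; assembly aborts if any of them is
#'   present in `A_pd_train` (leakage guard).
#' @return a `hetero_adjacency`: `A`, `G`, `n_piRNA`, `n_disease`.
#' @export
assemble_adjacency <- function(A_pp, A_dd, A_pd_train, holdout_pairs = NULL) {
  if (inherits(A_pp, "projection_subgraph")) A_pp <- A_pp$adjacency
  if (inherits(A_dd, "projection_subgraph")) A_dd <- A_dd$adjacency
  A_pd_train <- as.matrix(A_pd_train)
  n <- nrow(A_pd_train); m <- ncol(A_pd_train)
  if (!all(dim(A_pp) == n) || !all(dim(A_dd) == m)) {
    stop("block shapes do not conform: A_pp must be NxN, A_dd MxM")
  }
  if (!is.null(holdout_pairs)) {
    hp <- as.matrix(holdout_pairs)[, 1:2, drop = FALSE]
    if (nrow(hp) > 0 && any(A_pd_train[hp] != 0)) {
      stop("leakage: a held-out association is present in the training adjacency")
    }
  }
  A <- rbind(cbind(A_pp, A_pd_train), cbind(t(A_pd_train), A_dd))
  if (max(abs(A - t(A))) > 0) stop("assembled adjacency is not symmetric")
  d <- rowSums(A) + 1  # A' = A + I always has positive degree
  inv_sqrt <- 1 / sqrt(d)
  G <- (A + diag(n + m)) * outer(inv_sqrt, inv_sqrt)
  structure(list(A = A, G = G, n_piRNA = n, n_disease = m),
            class = "hetero_adjacency")
}

init_gcn_weights <- function(d0, config) {
  in_fc <- if (config$link_op == "concat") 2L * config$h2 else config$h2
  with_seed(config$seed, list(
    W0 = glorot_matrix(d0, config$h1),
    W1 = glorot_matrix(config$h1, config$h2),
    F1 = glorot_matrix(in_fc, config$f1), b1 = rep(0, config$f1),
    F2 = glorot_matrix(config$f1, config$f2), b2 = rep(0, config$f2),
    F3 = glorot_matrix(config$f2, 1L), b3 = 0
  ))
}

#' Two-layer graph convolution forward pass
#'
#' H1 = relu(G H0 W0); H2 = act2(G H1 W1) with a linear second layer by
#' default. Dropout (inverted scaling) is applied to H1 only while
#' `training` is `TRUE`.
#'
#' @param G normalized operator from [assemble_adjacency()].
#' @param H0 node initial representation matrix.
#' @param weights list with `W0`, `W1` (e.g. from a trained model).
#' @param dropout dropout rate used when `training`.
#' @param training logical; `FALSE` (default) gives a deterministic pass.
#' @param activation2 second-layer activation.
#' @return node embedding matrix H2 with the layer-1 activations attached
#'   as attribute `"H1"`.
#' @export
gcn_forward <- function(G, H0, weights, dropout = 0, training = FALSE,
                        activation2 = "linear") {
  if (inherits(G, "hetero_adjacency")) G <- G$G
  H1 <- relu(G %*% H0 %*% weights$W0)
  H1d <- H1
  if (training && dropout > 0) {
    mask <- (matrix(stats::runif(length(H1)), nrow(H1)) >= dropout) /
      (1 - dropout)
    H1d <- H1 * mask
  }
  Z2 <- G %*% H1d %*% weights$W1
  H2 <- if (activation2 == "relu") relu(Z2) else Z2
  if (any(!is.finite(H2))) stop("non-finite activations in GCN layer 2")
  attr(H2, "H1") <- H1
  H2
}

link_features <- function(H2, pairs, n_piRNA, link_op = "concat") {
  zi <- H2[pairs[, 1L], , drop = FALSE]
  zj <- H2[n_piRNA + pairs[, 2L], , drop = FALSE]
  if (link_op == "concat") cbind(zi, zj) else zi * zj
}

fc_forward <- function(X, w) {
  Z1 <- add_bias(X %*% w$F1, w$b1); A1 <- relu(Z1)
  Z2 <- add_bias(A1 %*% w$F2, w$b2); A2 <- relu(Z2)
  logit <- as.vector(A2 %*% w$F3 + w$b3)
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, logit = logit,
       p = sigmoid(logit))
}

#' Score candidate links with the fully-connected predictor
#'
#' The link embedding of pair (i, j) is the concatenation (or Hadamard
#' product) of piRNA embedding row i and disease embedding row N + j,
#' passed through two ReLU layers and a sigmoid output.
#'
#' @param H2 node embedding matrix ((N + M) rows).
#' @param pairs two-column matrix of (piRNA index, disease index).
#' @param weights weight list containing `F1`, `b1`, `F2`, `b2`, `F3`,
#'   `b3`.
#' @param n_piRNA number of piRNA rows in `H2`.
#' @param link_op `"concat"` or `"hadamard"`.
#' @return vector of probabilities in (0, 1).
#' @export
predict_links <- function(H2, pairs, weights, n_piRNA, link_op = "concat") {
  pairs <- matrix(as.integer(as.matrix(pairs)[, 1:2]), ncol = 2L)
  n_total <- nrow(H2)
  if (any(pairs[, 1L] < 1L | pairs[, 1L] > n_piRNA) ||
      any(pairs[, 2L] < 1L | pairs[, 2L] > n_total - n_piRNA)) {
    stop("link index out of range")
  }
  fc_forward(link_features(H2, pairs, n_piRNA, link_op), weights)$p
}

#' Dual loss: cross-entropy plus sensitivity-specificity error
#'
#' The total loss is mean binary cross-entropy plus a differentiable
#' sensitivity-specificity term w * (1 - sp) + (1 - w) * (1 - se), with
#' soft rates se = mean predicted score over positives and
#' sp = mean (1 - score) over negatives. The weight w trades specificity
#' against sensitivity. With a single-class batch the
#' sensitivity-specificity term is skipped with a warning.
#'
#' @param y binary labels.
#' @param y_hat predicted probabilities in (0, 1).
#' @param w sensitivity ratio in (0, 1), default 0.1.
#' @param components return the two parts separately.
#' @return scalar loss, or a list with `ce`, `ss`, `total`.
#' @export
dual_loss <- function(y, y_hat, w = 0.1, components = FALSE) {
  stopifnot(length(y) == length(y_hat), all(y %in% c(0, 1)))
  eps <- 1e-12
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  ce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("single-class batch: sensitivity-specificity term skipped")
    ss <- 0
  } else {
    se_soft <- sum(p[y == 1]) / n_pos
    sp_soft <- sum(1 - p[y == 0]) / n_neg
    ss <- w * (1 - sp_soft) + (1 - w) * (1 - se_soft)
  }
  if (components) list(ce = ce, ss = ss, total = ce + ss) else ce + ss
}

# gradient of the dual loss with respect to the logit, for full-batch
# backprop: d(mean BCE)/dlogit = (p - y)/n; the soft-rate term contributes
# w/n_neg * dp on negatives and -(1 - w)/n_pos * dp on positives.
dual_loss_grad_logit <- function(y, p, w) {
  n <- length(y)
  g <- (p - y) / n
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos > 0 && n_neg > 0) {
    dp <- numeric(n)
    dp[y == 1] <- -(1 - w) / n_pos
    dp[y == 0] <- w / n_neg
    g <- g + dp * p * (1 - p)
  }
  g
}

#' Train the GCN encoder and link predictor end to end
#'
#' Full-batch joint training of the two GCN layers and the three-layer
#' fully-connected predictor with Adam under the dual loss. Dropout is
#' applied to the GCN hidden layer and both FC hidden layers. Fully
#' deterministic for a fixed config seed.
#'
#' @param adjacency a [assemble_adjacency()] result.
#' @param NIR node feature matrix (or an `augmented_features` object).
#' @param pairs two-column (piRNA index, disease index) training pairs.
#' @param labels binary labels for `pairs`.
#' @param config a [model_config()].
#' @return a `pda_model`: `weights`, `embeddings` (H2, eval mode),
#'   `loss_trace`, `config`, `n_piRNA`, `n_disease`.
#' @export
train_pda_gcn <- function(adjacency, NIR, pairs, labels, config) {
  stopifnot(inherits(adjacency, "hetero_adjacency"),
            inherits(config, "model_config"))
  if (inherits(NIR, "augmented_features")) NIR <- NIR$NIR
  G <- adjacency$G
  n_p <- adjacency$n_piRNA
  pairs <- matrix(as.integer(as.matrix(pairs)[, 1:2]), ncol = 2L)
  y <- as.numeric(labels)
  stopifnot(nrow(pairs) == length(y), nrow(NIR) == nrow(G))
  w <- init_gcn_weights(ncol(NIR), config)
  state <- adam_init(w)
  GH0 <- G %*% NIR
  drop <- config$dropout
  idx_p <- pairs[, 1L]
  idx_d <- n_p + pairs[, 2L]
  act2 <- config$activation2
  trace <- numeric(config$epochs)
  rng_seed <- derive_seed(config$seed, "dropout")
  with_seed(rng_seed, {
    for (ep in seq_len(config$epochs)) {
      # ---- forward ----
      H1 <- relu(GH0 %*% w$W0)
      if (drop > 0) {
        mask1 <- (matrix(stats::runif(length(H1)), nrow(H1)) >= drop) / (1 - drop)
        H1d <- H1 * mask1
      } else H1d <- H1
      GH1 <- G %*% H1d
      Z2 <- GH1 %*% w$W1
      H2 <- if (act2 == "relu") relu(Z2) else Z2
      X <- if (config$link_op == "concat") {
        cbind(H2[idx_p, , drop = FALSE], H2[idx_d, , drop = FALSE])
      } else {
        H2[idx_p, , drop = FALSE] * H2[idx_d, , drop = FALSE]
      }
      ZF1 <- add_bias(X %*% w$F1, w$b1); AF1 <- relu(ZF1)
      if (drop > 0) {
        mf1 <- (matrix(stats::runif(length(AF1)), nrow(AF1)) >= drop) / (1 - drop)
        AF1d <- AF1 * mf1
      } else AF1d <- AF1
      ZF2 <- add_bias(AF1d %*% w$F2, w$b2); AF2 <- relu(ZF2)
      if (drop > 0) {
        mf2 <- (matrix(stats::runif(length(AF2)), nrow(AF2)) >= drop) / (1 - drop)
        AF2d <- AF2 * mf2
      } else AF2d <- AF2
      logit <- as.vector(AF2d %*% w$F3 + w$b3)
      p <- sigmoid(logit)
      loss <- dual_loss(y, p, config$loss_weight)
      if (!is.finite(loss)) {
        stop("training failure: non-finite loss at epoch ", ep)
      }
      trace[ep] <- loss
      # ---- backward ----
      dlogit <- dual_loss_grad_logit(y, p, config$loss_weight)
      dF3 <- crossprod(AF2d, dlogit); db3 <- sum(dlogit)
      dAF2d <- outer(dlogit, as.vector(w$F3))
      dAF2 <- if (drop > 0) dAF2d * mf2 else dAF2d
      dZF2 <- dAF2 * (ZF2 > 0)
      dF2 <- crossprod(AF1d, dZF2); db2 <- colSums(dZF2)
      dAF1d <- tcrossprod(dZF2, w$F2)
      dAF1 <- if (drop > 0) dAF1d * mf1 else dAF1d
      dZF1 <- dAF1 * (ZF1 > 0)
      dF1 <- crossprod(X, dZF1); db1 <- colSums(dZF1)
      dX <- tcrossprod(dZF1, w$F1)
      h2w <- ncol(H2)
      dH2 <- matrix(0, nrow(H2), h2w)
      if (config$link_op == "concat") {
        contrib_p <- dX[, seq_len(h2w), drop = FALSE]
        contrib_d <- dX[, h2w + seq_len(h2w), drop = FALSE]
      } else {
        contrib_p <- dX * H2[idx_d, , drop = FALSE]
        contrib_d <- dX * H2[idx_p, , drop = FALSE]
      }
      # piRNA and disease slots are disjoint index ranges
      agg_p <- rowsum(contrib_p, idx_p)
      dH2[as.integer(rownames(agg_p)), ] <- agg_p
      agg_d <- rowsum(contrib_d, idx_d)
      dH2[as.integer(rownames(agg_d)), ] <- agg_d
      dZ2 <- if (act2 == "relu") dH2 * (Z2 > 0) else dH2
      dW1 <- crossprod(GH1, dZ2)
      dH1d <- (G %*% dZ2) %*% t(w$W1)  # G symmetric
      dH1 <- if (drop > 0) dH1d * mask1 else dH1d
      dZ1 <- dH1 * (H1 > 0)
      dW0 <- crossprod(GH0, dZ1)
      grads <- list(W0 = dW0, W1 = dW1, F1 = dF1, b1 = db1,
                    F2 = dF2, b2 = db2, F3 = dF3, b3 = db3)
      upd <- adam_step(w, grads, state, config$learning_rate)
      w <- upd$params
      state <- upd$state
    }
  })
  H2 <- gcn_forward(G, NIR, w, training = FALSE, activation2 = act2)
  structure(
    list(weights = w, embeddings = H2, loss_trace = trace, config = config,
         n_piRNA = n_p, n_disease = adjacency$n_disease),
    class = "pda_model"
  )
}

#' @export
predict.pda_model <- function(object, pairs, ...) {
  predict_links(object$embeddings, pairs, object$weights, object$n_piRNA,
                object$config$link_op)
}

#' @export
print.pda_model <- function(x, ...) {
  cat(sprintf("pda_model: %d piRNAs + %d diseases, %d epochs, final loss %.4g\n",
              x$n_piRNA, x$n_disease, length(x$loss_trace),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}
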