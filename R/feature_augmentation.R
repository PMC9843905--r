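#' Residual profile of a similarity matrix against association degrees
#'
#' For node i, delta_i is the ratio of its association degree (row sum of
#' the incidence matrix for piRNAs, column sum for diseases) to the mass
#' of its similarity row. The residual is the absolute deviation of
#' log(delta_i + 1) from its centering constant, stretched by a scaling
#' factor: R_i = |log(delta_i + 1) - mu_bar| * delta_scale.
#'
#' @param S square similarity matrix for one side.
#' @param A_pd binary incidence matrix aligned with `S`'s side.
#' @param side `"piRNA"` (rows of `A_pd`) or `"disease"` (columns).
#' @param delta_scale scaling factor; candidate set {0.1, 10, 100},
#'   default 10.
#' @param mu_mode centering constant: `"raw_degree_mean"` (default, the
#'   mean association degree) or `"log_ratio_mean"` (the mean of
#'   log(delta + 1) over nodes, an alternative that centers the residual
#'   in the transformed scale but collapses near-average rows to zero).
#' @return a `residual_profile`: `side`, `delta`, `mu_bar`, `delta_scale`,
#'   `R` (non-negative, one entry per node).
#' @export
residual_profile <- function(S, A_pd, side = c("piRNA", "disease"),
                             delta_scale = 10,
                             mu_mode = c("raw_degree_mean", "log_ratio_mean")) {
  side <- match_side(side)
  mu_mode <- match.arg(mu_mode)
  S <- as.matrix(S)
  deg <- if (side == "piRNA") rowSums(A_pd) else colSums(A_pd)
  if (length(deg) != nrow(S)) {
    stop("similarity matrix and incidence matrix are misaligned for side ", side)
  }
  smass <- rowSums(S)
  if (any(smass <= 0)) stop("similarity matrix has a non-positive row sum")
  delta <- deg / smass
  lg <- log(delta + 1)
  mu_bar <- if (mu_mode == "log_ratio_mean") mean(lg) else mean(deg)
  structure(
    list(side = side, delta = delta, mu_bar = mu_bar,
         delta_scale = delta_scale, R = abs(lg - mu_bar) * delta_scale),
    class = "residual_profile"
  )
}

#' Row-wise residual scaling of a similarity matrix
#'
#' Row i of the output is R_i times row i of `S` (diag(R) S).
#'
#' @param S square similarity matrix.
#' @param R a [residual_profile()] or a bare non-negative vector, one
#'   entry per row of `S`.
#' @return the scaled matrix S'.
#' @export
residual_scale <- function(S, R) {
  r <- if (inherits(R, "residual_profile")) R$R else R
  S <- as.matrix(S)
  stopifnot(length(r) == nrow(S))
  S * r  # column vector recycling multiplies row i by r[i]
}

ae_forward <- function(X, p, activation) {
  act <- if (activation == "relu") relu else identity
  Z1 <- add_bias(X %*% p$We1, p$be1); A1 <- act(Z1)
  Zc <- add_bias(A1 %*% p$We2, p$be2)          # code layer, linear
  Z3 <- add_bias(Zc %*% p$Wd1, p$bd1); A3 <- act(Z3)
  Xh <- add_bias(A3 %*% p$Wd2, p$bd2)
  list(Z1 = Z1, A1 = A1, Zc = Zc, Z3 = Z3, A3 = A3, Xh = Xh)
}

#' Train a denoising autoencoder on a feature matrix
#'
#' Symmetric architecture input -> hidden -> code -> hidden -> input with
#' a linear code layer and linear output, trained full-batch with Adam to
#' minimize mean squared reconstruction error. Deterministic for a fixed
#' seed.
#'
#' @param X numeric matrix, one row per node.
#' @param latent_dim code width d0 (capped at the input width).
#' @param hidden_dim hidden width; default `min(256, ncol(X))`.
#' @param epochs training epochs, default 200.
#' @param seed mandatory integer seed for weight initialization.
#' @param learning_rate Adam step size, default 0.01.
#' @param activation hidden activation, `"relu"` (default) or `"linear"`.
#' @return an `autoencoder`: weights, `loss_trace`, `latent_dim`, spec.
#' @export
train_denoising_encoder <- function(X, latent_dim, hidden_dim = NULL,
                                    epochs = 200L, seed,
                                    learning_rate = 0.01,
                                    activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  d_in <- ncol(X)
  latent_dim <- min(latent_dim, d_in)
  if (is.null(hidden_dim)) hidden_dim <- min(256L, d_in)
  hidden_dim <- max(hidden_dim, latent_dim)
  if (missing(seed)) stop("a seed is mandatory for encoder training")
  p <- with_seed(seed, list(
    We1 = glorot_matrix(d_in, hidden_dim), be1 = rep(0, hidden_dim),
    We2 = glorot_matrix(hidden_dim, latent_dim), be2 = rep(0, latent_dim),
    Wd1 = glorot_matrix(latent_dim, hidden_dim), bd1 = rep(0, hidden_dim),
    Wd2 = glorot_matrix(hidden_dim, d_in), bd2 = rep(0, d_in)
  ))
  state <- adam_init(p)
  n_entries <- length(X)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    f <- ae_forward(X, p, activation)
    err <- f$Xh - X
    loss <- mean(err^2)
    if (!is.finite(loss)) {
      stop("autoencoder training failed: non-finite loss at epoch ", ep)
    }
    trace[ep] <- loss
    dXh <- 2 * err / n_entries
    dWd2 <- crossprod(f$A3, dXh); dbd2 <- colSums(dXh)
    dA3 <- tcrossprod(dXh, p$Wd2)
    dZ3 <- if (activation == "relu") dA3 * (f$Z3 > 0) else dA3
    dWd1 <- crossprod(f$Zc, dZ3); dbd1 <- colSums(dZ3)
    dZc <- dZ3 %*% t(p$Wd1)
    dWe2 <- crossprod(f$A1, dZc); dbe2 <- colSums(dZc)
    dA1 <- dZc %*% t(p$We2)
    dZ1 <- if (activation == "relu") dA1 * (f$Z1 > 0) else dA1
    dWe1 <- crossprod(X, dZ1); dbe1 <- colSums(dZ1)
    grads <- list(We1 = dWe1, be1 = dbe1, We2 = dWe2, be2 = dbe2,
                  Wd1 = dWd1, bd1 = dbd1, Wd2 = dWd2, bd2 = dbd2)
    upd <- adam_step(p, grads, state, learning_rate)
    p <- upd$params
    state <- upd$state
  }
  structure(
    list(weights = p, activation = activation, latent_dim = latent_dim,
         hidden_dim = hidden_dim, input_dim = d_in, seed = seed,
         epochs = epochs, learning_rate = learning_rate,
         loss_trace = trace),
    class = "autoencoder"
  )
}

#' Encode rows through a trained autoencoder
#'
#' @param encoder an [train_denoising_encoder()] result.
#' @param X matrix with `encoder$input_dim` columns.
#' @return code matrix with `encoder$latent_dim` columns.
#' @export
encode_features <- function(encoder, X) {
  stopifnot(inherits(encoder, "autoencoder"))
  f <- ae_forward(as.matrix(X), encoder$weights, encoder$activation)
  f$Zc
}

reconstruction_error <- function(encoder, X) {
  f <- ae_forward(as.matrix(X), encoder$weights, encoder$activation)
  mean((f$Xh - X)^2)
}

#' Node initial representations from augmented similarity profiles
#'
#' Default mode: each side's integrated similarity matrix is residual
#' scaled ([residual_profile()] + [residual_scale()]) and compressed by a
#' per-side denoising autoencoder; the encoded rows are stacked piRNAs
#' first into an (N + M) x d0 feature matrix. Both sides share the code
#' width, which is capped at the narrower input.
#'
#' @param S_P integrated piRNA similarity (N x N).
#' @param S_D integrated disease similarity (M x M).
#' @param A_pd binary incidence matrix (N x M).
#' @param delta_scale_p,delta_scale_d residual scaling factors per side.
#' @param d0 target feature width, default 64 (auto-shrunk to the
#'   narrower similarity input).
#' @param seed mandatory integer seed.
#' @param mode `"augmented"` (default), `"raw_similarity"` (skip residual
#'   scaling, encode the similarity directly) or `"constant"` (all-ones
#'   single column).
#' @param mu_mode centering constant for the residual (see
#'   [residual_profile()]).
#' @param epochs autoencoder epochs per side.
#' @return an `augmented_features` object: `NIR`, `S_prime_p`,
#'   `S_prime_d`, `encoders`, `mode`, `d0`.
#' @export
node_initial_representation <- function(S_P, S_D, A_pd,
                                        delta_scale_p = 10,
                                        delta_scale_d = 10,
                                        d0 = 64L, seed,
                                        mode = c("augmented", "raw_similarity",
                                                 "constant"),
                                        mu_mode = "raw_degree_mean",
                                        epochs = 200L) {
  mode <- match.arg(mode)
  n <- nrow(A_pd); m <- ncol(A_pd)
  stopifnot(nrow(S_P) == n, nrow(S_D) == m)
  if (mode == "constant") {
    nir <- matrix(1, n + m, 1L)
    rownames(nir) <- c(rownames(A_pd), colnames(A_pd))
    return(structure(list(NIR = nir, S_prime_p = NULL, S_prime_d = NULL,
                          encoders = NULL, mode = mode, d0 = 1L),
                     class = "augmented_features"))
  }
  if (missing(seed)) stop("a seed is mandatory")
  if (mode == "augmented") {
    Rp <- residual_profile(S_P, A_pd, "piRNA", delta_scale_p, mu_mode)
    Rd <- residual_profile(S_D, A_pd, "disease", delta_scale_d, mu_mode)
    Xp <- residual_scale(S_P, Rp)
    Xd <- residual_scale(S_D, Rd)
  } else {
    Xp <- as.matrix(S_P)
    Xd <- as.matrix(S_D)
  }
  # residual scaling sets the relative row weights; the global magnitude
  # is arbitrary, so normalize to unit RMS to keep the autoencoder
  # optimization well conditioned regardless of delta_scale
  norm_rms <- function(X) {
    r <- sqrt(mean(X^2))
    if (r > 0) X / r else X
  }
  Xp_in <- norm_rms(Xp)
  Xd_in <- norm_rms(Xd)
  d0 <- min(d0, ncol(Xp), ncol(Xd))
  enc_p <- train_denoising_encoder(Xp_in, d0, epochs = epochs,
                                   seed = derive_seed(seed, "encoder_piRNA"))
  enc_d <- train_denoising_encoder(Xd_in, d0, epochs = epochs,
                                   seed = derive_seed(seed, "encoder_disease"))
  nir <- rbind(encode_features(enc_p, Xp_in), encode_features(enc_d, Xd_in))
  if (any(!is.finite(nir))) stop("non-finite node representations")
  rownames(nir) <- c(rownames(A_pd), colnames(A_pd))
  structure(
    list(NIR = nir, S_prime_p = Xp, S_prime_d = Xd,
         encoders = list(piRNA = enc_p, disease = enc_d),
         mode = mode, d0 = as.integer(d0)),
    class = "augmented_features"
  )
}
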