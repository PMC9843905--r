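# Small shared numerics: seeded RNG scopes, deterministic seed substreams,
# weight initialization and an Adam optimizer used by both the denoising
# autoencoder and the GCN trainer.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals
#' never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Named-substream scheme: the stage name is hashed into an offset so that
#' adding a pipeline stage never perturbs the randomness of earlier
#' stages. The result is always a valid 32-bit integer seed.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(global_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(global_seed)) %% 2147483647 * 69069 + h) %% 2147483647)
}

# fan-in/fan-out scaled uniform initialization
glorot_matrix <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / (1 - beta1^state$t)
    v_hat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(params = params, state = state)
}

relu <- function(x) {
  x * (x > 0)
}

# add a bias row-vector to every row without sweep()'s aperm overhead
add_bias <- function(Z, b) {
  Z + rep(b, each = nrow(Z))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
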