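# R-level surface of the model core. The numerics live in src/capsnet.cpp;
# these wrappers fix layouts, validate shapes, and expose each building block
# (embedding lookup, LSTM cell, BiLSTM encoder, squashing, dynamic routing,
# capsule transform, full forward pass) for direct use and testing.

#' Embedding lookup
#'
#' Row `t` of the result is the embedding-table row indexed by `ids[t]`
#' (0-based ids; row 0 is the padding embedding, frozen at zero during
#' training).
#'
#' @param ids integer vector of 0-based token ids.
#' @param We embedding table, `|V| x k`.
#' @return `length(ids) x k` matrix.
#' @export
embed_tokens <- function(ids, We) {
  if (any(ids < 0L | ids >= nrow(We))) stop("token id out of range")
  We[ids + 1L, , drop = FALSE]
}

#' Capsule squashing nonlinearity
#'
#' Maps a pre-activation vector to the same direction with norm strictly below
#' 1: `(||s||^2 / (1 + ||s||^2)) * s / ||s||` in the standard form, so a unit
#' vector keeps its direction at norm 0.5 and the zero vector maps to itself.
#' The `norm1` variant uses `||s|| / (1 + ||s||^2)` as the length factor.
#'
#' @param s numeric vector.
#' @param variant `"standard"` (default) or `"norm1"`.
#' @return Squashed vector of the same dimension.
#' @export
squash <- function(s, variant = "standard") {
  as.numeric(cpp_squash(as.numeric(s), match_variant(variant)))
}

#' One LSTM cell step
#'
#' Computes the gated update for a single time step: sigmoid forget, input and
#' output gates and a tanh candidate, each acting on the concatenation
#' `[h_prev, x]`; the cell state is `f * C_prev + i * c_tilde` and the hidden
#' state `o * tanh(C)`.
#'
#' @param x input vector at this step.
#' @param state list with `h` and `C`, the previous hidden and cell state.
#' @param params list with gate weights `W_i`, `W_f`, `W_c`, `W_o` (each
#'   `h x (h + k)`, acting on `[h_prev, x]`) and biases `b_i`, `b_f`, `b_c`,
#'   `b_o`.
#' @return list with the new `h` and `C` and the gate activations `gates`.
#' @export
lstm_cell_step <- function(x, state, params) {
  h <- length(state$h)
  dims <- vapply(params[c("W_i", "W_f", "W_c", "W_o")], function(W)
    all(dim(W) == c(h, h + length(x))), logical(1))
  if (!all(dims)) stop("gate weight dimensions inconsistent with state/input")
  W <- rbind(params$W_i, params$W_f, params$W_c, params$W_o)
  b <- c(params$b_i, params$b_f, params$b_c, params$b_o)
  out <- cpp_lstm_cell_step(as.numeric(x), as.numeric(state$h),
                            as.numeric(state$C), W, b)
  list(h = as.numeric(out$h), C = as.numeric(out$C),
       gates = lapply(out$gates, as.numeric))
}

#' Bidirectional LSTM encoder
#'
#' Runs one LSTM over the rows of `X` in order and a second over the reversed
#' order, both from zero initial states, and concatenates their hidden states
#' per position.
#'
#' @param X `L x k` matrix of embedded tokens.
#' @param p_fwd,p_bwd gate parameter lists as in [lstm_cell_step()].
#' @return `L x 2h` matrix; columns `1:h` are the forward hidden states.
#' @export
bilstm_forward <- function(X, p_fwd, p_bwd) {
  pack <- function(p) list(W = rbind(p$W_i, p$W_f, p$W_c, p$W_o),
                           b = c(p$b_i, p$b_f, p$b_c, p$b_o))
  f <- pack(p_fwd); b <- pack(p_bwd)
  cpp_bilstm_forward(X, f$W, f$b, b$W, b$b)
}

#' Dynamic routing between capsule layers
#'
#' Iterates, `r` times: couplings from a softmax over the routing logits; each
#' output capsule as the coupling-weighted sum of its prediction vectors;
#' squashing; and (except after the final iteration) a logit update by the
#' agreement between output capsule and prediction vector.
#'
#' @param u_hat prediction vectors, array `n_in x n_out x d_out`
#'   (`u_hat[i, j, ]` predicts output capsule `j` from input capsule `i`).
#' @param r number of routing iterations (>= 1, default 3).
#' @param softmax_axis `"output"` (couplings sum to 1 over output capsules for
#'   each input, the capsule-network convention and default) or `"input"`.
#' @param squash_variant see [squash()].
#' @return list with `a` (`n_out x d_out` output capsules), `c` (final
#'   couplings, `n_in x n_out`), `b` (final logits), `s` (pre-activations,
#'   `n_out x d_out`), and `c_history` (`n_in x n_out x r` couplings at every
#'   iteration).
#' @export
dynamic_routing <- function(u_hat, r = 3L, softmax_axis = "output",
                            squash_variant = "standard") {
  stopifnot(length(dim(u_hat)) == 3)
  if (r < 1) stop("routing iterations must be >= 1")
  U <- aperm(u_hat, c(3, 2, 1))    # -> d_out x n_out x n_in
  out <- cpp_dynamic_routing(U, as.integer(r), match_axis(softmax_axis),
                             match_variant(squash_variant))
  list(a = t(out$a), c = out$c, b = out$b, s = t(out$s),
       c_history = out$c_history)
}

#' Capsule layer: transform then route
#'
#' Forms prediction vectors `u_hat[i, j] = W[i, j, , ] %*% v[i, ]` and applies
#' [dynamic_routing()].
#'
#' @param v input capsules, `n_in x d_in`.
#' @param W transform tensor, array `n_in x n_out x d_out x d_in`.
#' @param r routing iterations.
#' @param softmax_axis,squash_variant as in [dynamic_routing()].
#' @return As [dynamic_routing()], plus `u_hat` (`n_in x n_out x d_out`).
#' @export
capsule_forward <- function(v, W, r = 3L, softmax_axis = "output",
                            squash_variant = "standard") {
  stopifnot(length(dim(W)) == 4, nrow(v) == dim(W)[1], ncol(v) == dim(W)[4])
  n_in <- dim(W)[1]; n_out <- dim(W)[2]; d_out <- dim(W)[3]; d_in <- dim(W)[4]
  # pack to the compiled layout: slice i has row j*d_out + q = W[i, j, q, ]
  Wcap <- array(0, c(n_out * d_out, d_in, n_in))
  for (i in seq_len(n_in))
    for (j in seq_len(n_out))
      Wcap[(j - 1L) * d_out + seq_len(d_out), , i] <- W[i, j, , ]
  out <- cpp_capsule_forward(t(v), Wcap, n_out, d_out, as.integer(r),
                             match_axis(softmax_axis), match_variant(squash_variant))
  list(a = t(out$a), c = out$c, b = out$b, s = t(out$s),
       u_hat = aperm(out$u_hat, c(3, 2, 1)), c_history = out$c_history)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights (forget-gate biases at +1, a standard recurrent
#' initialization), a zero-frozen padding embedding row, and a capsule
#' transform tensor only when the capsule layer is enabled.
#'
#' @param rcfg resolved model configuration from `resolve_model_cfg()`.
#' @param seed integer seed; all randomness derives from it.
#' @return Named list of parameter arrays.
#' @export
init_params <- function(rcfg, seed = 1L) {
  set.seed(seed)
  glorot <- function(nr, nc, fan_in = nc, fan_out = nr) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  k <- rcfg$embed_dim; h <- rcfg$hidden
  We <- matrix(rnorm(rcfg$vocab_size * k, 0, 0.1), rcfg$vocab_size, k)
  We[1, ] <- 0
  lstm_w <- function() {
    W <- glorot(4 * h, h + k, fan_in = h + k, fan_out = h)
    b <- numeric(4 * h)
    b[(h + 1):(2 * h)] <- 1      # forget gate bias
    list(W = W, b = b)
  }
  fw <- lstm_w(); bw <- lstm_w()
  f_in <- if (rcfg$use_capsule) rcfg$n_out * rcfg$d_out else 2L * h
  d1 <- rcfg$dense[1]; d2 <- rcfg$dense[2]
  p <- list(We = We,
            Wlf = fw$W, blf = fw$b, Wlb = bw$W, blb = bw$b,
            W1 = glorot(d1, f_in), b1 = numeric(d1),
            W2 = glorot(d2, d1), b2 = numeric(d2),
            W3 = glorot(1, d2), b3 = numeric(1))
  if (rcfg$use_capsule) {
    # Glorot scale shrunk by sqrt(n_out / n_in): each pre-activation capsule
    # sums n_in coupling-weighted predictions (couplings ~ 1/n_out), so an
    # unscaled init lands deep in the squash saturation zone and starves the
    # encoder of gradient
    lim <- sqrt(6 / (rcfg$d_in + rcfg$d_out)) * sqrt(rcfg$n_out / rcfg$n_in)
    p$Wcap <- array(runif(rcfg$n_out * rcfg$d_out * rcfg$d_in * rcfg$n_in, -lim, lim),
                    c(rcfg$n_out * rcfg$d_out, rcfg$d_in, rcfg$n_in))
  }
  p
}

#' Count learnable parameters
#' @param params parameter list from [init_params()] or a trained model.
#' @return Total number of scalar parameters.
#' @export
count_params <- function(params) {
  if (inherits(params, "capstf_model")) params <- params$params
  sum(vapply(params, length, numeric(1)))
}

#' Full forward pass
#'
#' Embeds, encodes with the BiLSTM, reshapes the encoder output into input
#' capsules, routes to the output capsules, flattens, and applies the dense
#' head with a sigmoid output. With `use_capsule = FALSE` the capsule stage is
#' replaced by mask-aware mean pooling of the encoder outputs.
#'
#' @param ids `L x n` integer matrix of 0-based token ids (one column per
#'   sequence), or a single `capstf_tokens`.
#' @param lengths integer vector of true (unpadded) lengths.
#' @param params parameter list.
#' @param rcfg resolved model configuration.
#' @return list with `p_tf` (probabilities in (0, 1)) and `features` (the
#'   `n x f` flattened capsule outputs, or the pooled representation under the
#'   ablation).
#' @export
model_forward <- function(ids, lengths, params, rcfg) {
  if (inherits(ids, "capstf_tokens")) {
    lengths <- sum(ids$mask)
    ids <- matrix(ids$ids, ncol = 1)
  }
  out <- cpp_forward(ids, as.integer(lengths), params, rcfg)
  list(p_tf = as.numeric(out$p), features = t(out$features))
}
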