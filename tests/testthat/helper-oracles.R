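# Independent reference implementations used to validate the compiled model
# core. Deliberately written as plain scalar/element loops, sharing no code
# with the package internals.

oracle_squash <- function(s, variant = "standard") {
  n2 <- sum(s^2)
  if (n2 < 1e-300) return(s * 0)
  n <- sqrt(n2)
  if (variant == "standard") (n2 / (1 + n2)) * s / n else (n / (1 + n2)) * s / n
}

# Explicit-loop dynamic routing. u_hat: array n_in x n_out x d_out.
oracle_routing <- function(u_hat, r, softmax_axis = "output",
                           squash_variant = "standard") {
  I <- dim(u_hat)[1]; J <- dim(u_hat)[2]; d <- dim(u_hat)[3]
  b <- matrix(0, I, J)
  c_hist <- array(NA_real_, c(I, J, r))
  a <- s <- matrix(0, J, d)
  cc <- matrix(0, I, J)
  for (t in seq_len(r)) {
    for (i in seq_len(I)) {
      # softmax along the requested axis, one row/column at a time
      if (softmax_axis == "output")
        cc[i, ] <- exp(b[i, ] - max(b[i, ])) / sum(exp(b[i, ] - max(b[i, ])))
    }
    if (softmax_axis == "input")
      for (j in seq_len(J))
        cc[, j] <- exp(b[, j] - max(b[, j])) / sum(exp(b[, j] - max(b[, j])))
    c_hist[, , t] <- cc
    for (j in seq_len(J)) {
      sj <- numeric(d)
      for (i in seq_len(I)) sj <- sj + cc[i, j] * u_hat[i, j, ]
      s[j, ] <- sj
      a[j, ] <- oracle_squash(sj, squash_variant)
    }
    if (t < r)
      for (i in seq_len(I))
        for (j in seq_len(J))
          b[i, j] <- b[i, j] + sum(a[j, ] * u_hat[i, j, ])
  }
  list(a = a, c = cc, b = b, s = s, c_history = c_hist)
}

# Scalar-loop LSTM cell (gate-by-gate, element-by-element).
oracle_lstm_step <- function(x, h0, C0, p) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- length(h0)
  inp <- c(h0, x)
  f <- i <- ct <- o <- Cn <- Hn <- numeric(h)
  for (q in seq_len(h)) {
    f[q] <- sig(sum(p$W_f[q, ] * inp) + p$b_f[q])
    i[q] <- sig(sum(p$W_i[q, ] * inp) + p$b_i[q])
    ct[q] <- tanh(sum(p$W_c[q, ] * inp) + p$b_c[q])
    o[q] <- sig(sum(p$W_o[q, ] * inp) + p$b_o[q])
    Cn[q] <- f[q] * C0[q] + i[q] * ct[q]
    Hn[q] <- o[q] * tanh(Cn[q])
  }
  list(h = Hn, C = Cn, gates = list(i = i, f = f, c = ct, o = o))
}

# Sequential BiLSTM built only on the scalar-step oracle.
oracle_bilstm <- function(X, p_fwd, p_bwd) {
  L <- nrow(X); h <- length(p_fwd$b_f)
  O <- matrix(0, L, 2 * h)
  st <- list(h = numeric(h), C = numeric(h))
  for (t in seq_len(L)) {
    st <- oracle_lstm_step(X[t, ], st$h, st$C, p_fwd)
    O[t, 1:h] <- st$h
  }
  st <- list(h = numeric(h), C = numeric(h))
  for (t in rev(seq_len(L))) {
    st <- oracle_lstm_step(X[t, ], st$h, st$C, p_bwd)
    O[t, (h + 1):(2 * h)] <- st$h
  }
  O
}

# Brute-force AUC over all positive-negative pairs (ties count 1/2).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Direct-arithmetic metrics from a per-sample recount.
oracle_metrics <- function(labels, preds) {
  TP <- sum(labels == 1 & preds == 1); TN <- sum(labels == 0 & preds == 0)
  FP <- sum(labels == 0 & preds == 1); FN <- sum(labels == 1 & preds == 0)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  list(Sn = TP / (TP + FN), Sp = TN / (TN + FP),
       Acc = (TP + TN) / (TP + TN + FP + FN),
       MCC = if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den))
}

# Random gate-parameter set in the list layout lstm_cell_step() expects.
random_gate_params <- function(h, k, scale = 0.5) {
  list(W_i = matrix(rnorm(h * (h + k), 0, scale), h),
       W_f = matrix(rnorm(h * (h + k), 0, scale), h),
       W_c = matrix(rnorm(h * (h + k), 0, scale), h),
       W_o = matrix(rnorm(h * (h + k), 0, scale), h),
       b_i = rnorm(h, 0, scale), b_f = rnorm(h, 0, scale),
       b_c = rnorm(h, 0, scale), b_o = rnorm(h, 0, scale))
}
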