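# One configuration object drives preprocessing, the model and training.
# Every value the original description leaves open is an explicit key here.

#' Default configuration
#'
#' Returns the full nested configuration with any overrides applied
#' (recursively, via [utils::modifyList()]). Keys:
#'
#' * `window$position` — `"upstream"`, `"centre"` or `"downstream"`; `window$length` — residues per model input (default 500).
#' * `token$unit` — `"residue"` (closed 22-token vocabulary, default) or `"kmer3"`.
#' * `model$embed_dim` — embedding width (20); `model$hidden` — LSTM hidden size per direction (64);
#'   `model$d_in` — input-capsule width (`2 * hidden`, i.e. one capsule per position);
#'   `model$n_out`/`model$d_out` — output capsule count/width (8 x 16, flattened to 128 features);
#'   `model$routing_iters` — dynamic-routing iterations (3);
#'   `model$softmax_axis` — `"output"` (couplings normalized over output capsules, default) or `"input"`;
#'   `model$squash_variant` — `"standard"` or `"norm1"`;
#'   `model$use_capsule` — `FALSE` swaps the capsule layer for masked mean pooling (ablation);
#'   `model$dense` — hidden sizes of the dense head (c(64, 16)).
#' * `train$epochs`, `train$batch_size`, `train$learning_rate`, `train$patience`
#'   (early stopping on a validation slice), `train$val_fraction`, `train$clip`
#'   (global gradient-norm ceiling), `train$seed`.
#'
#' @param ... named overrides, e.g. `capstf_config(window = list(position = "centre"))`.
#' @return A nested list of class `capstf_config`.
#' @export
capstf_config <- function(...) {
  cfg <- list(
    window = list(position = "upstream", length = 500L),
    token = list(unit = "residue"),
    model = list(embed_dim = 20L, hidden = 64L, d_in = NULL,
                 n_out = 8L, d_out = 16L, routing_iters = 3L,
                 softmax_axis = "output", squash_variant = "standard",
                 use_capsule = TRUE, dense = c(64L, 16L)),
    train = list(epochs = 40L, batch_size = 32L, learning_rate = 3e-4,
                 patience = 15L, val_fraction = 0.1, clip = 5, seed = 1L)
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) && is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = c("capstf_config", "list"))
}

# Resolve derived model sizes for a given vocabulary; validates consistency.
resolve_model_cfg <- function(cfg, vocab_size) {
  m <- cfg$model
  L <- as.integer(cfg$window$length)
  h <- as.integer(m$hidden)
  d_in <- if (is.null(m$d_in)) 2L * h else as.integer(m$d_in)
  total <- L * 2L * h
  if (total %% d_in != 0)
    stop("L * 2 * hidden must be divisible by d_in")
  list(embed_dim = as.integer(m$embed_dim), hidden = h, L = L,
       d_in = d_in, n_in = as.integer(total %/% d_in),
       n_out = as.integer(m$n_out), d_out = as.integer(m$d_out),
       routing_iters = as.integer(m$routing_iters),
       softmax_axis = match_axis(m$softmax_axis),
       squash_variant = match_variant(m$squash_variant),
       use_capsule = isTRUE(m$use_capsule),
       dense = as.integer(m$dense),
       vocab_size = as.integer(vocab_size))
}

match_axis <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  switch(match.arg(x, c("output", "input")), output = 0L, input = 1L)
}

match_variant <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  switch(match.arg(x, c("standard", "norm1")), standard = 0L, norm1 = 1L)
}

#' Print every configuration default as YAML
#' @param cfg a [capstf_config()].
#' @export
config_yaml <- function(cfg = capstf_config()) {
  yaml::as.yaml(unclass(cfg))
}

# Apply "a.b.c=value" CLI overrides onto a nested config.
apply_config_sets <- function(cfg, sets) {
  for (s in sets) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("--set expects key=value, got: ", s)
    path <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    value <- utils::type.convert(kv[2], as.is = TRUE)
    cfg <- assign_path(cfg, path, value)
  }
  cfg
}

assign_path <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path]] <- value
    return(x)
  }
  x[[path[1]]] <- assign_path(x[[path[1]]] %||% list(), path[-1], value)
  x
}
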