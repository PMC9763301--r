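# Training loop, prediction, and checkpointing.

#' Train the capsule TF classifier
#'
#' Minimizes binary cross-entropy with Adam over mini-batches. A stratified
#' validation slice (`train$val_fraction` of the records) drives early
#' stopping: training halts once the validation loss has not improved for
#' `train$patience` consecutive epochs, and the best-validation parameters are
#' kept. Every stochastic component (initialization, shuffling, the
#' validation split) derives from `train$seed`, so a repeated run is
#' bit-identical.
#'
#' @param train_ds a labeled `capstf_dataset` containing both classes.
#' @param config a [capstf_config()].
#' @param vocab optional pre-built vocabulary; built from `config$token$unit`
#'   (and, for `kmer3`, the training sequences) when omitted.
#' @return A `capstf_model`: list with `params`, `config`, `vocab` and a
#'   per-epoch `history` data.frame (train loss, validation loss/accuracy).
#' @export
train_capstf <- function(train_ds, config = capstf_config(), vocab = NULL) {
  if (any(is.na(train_ds$label)))
    stop("training dataset must be fully labeled")
  if (length(unique(train_ds$label)) < 2)
    stop("training dataset contains a single class; both classes are required")
  if (is.null(vocab))
    vocab <- build_vocabulary(config$token$unit, corpus = train_ds$sequence)
  rcfg <- resolve_model_cfg(config, length(vocab$token_to_id))
  tr <- config$train
  seed <- as.integer(tr$seed)

  tok <- tokenize_dataset(train_ds, vocab, rcfg$L, config$window$position)
  y <- as.numeric(train_ds$label)
  n <- length(y)

  set.seed(seed)
  params <- init_params(rcfg, seed = seed)

  # stratified validation slice (0-based indices for the compiled loop)
  n_val <- floor(tr$val_fraction * n)
  val_idx <- integer(0)
  if (n_val >= 2) {
    pos <- which(y == 1); neg <- which(y == 0)
    v_pos <- sample(pos, max(1, round(n_val * length(pos) / n)))
    v_neg <- sample(neg, max(1, round(n_val * length(neg) / n)))
    val_idx <- sort(c(v_pos, v_neg))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  perms <- vapply(seq_len(tr$epochs),
                  function(e) sample(train_idx) - 1L,
                  integer(length(train_idx)))

  fit <- cpp_train(tok$ids, tok$lengths, y, params, rcfg,
                   perms, as.integer(val_idx - 1L),
                   tr$learning_rate, as.integer(tr$batch_size),
                   as.integer(tr$patience), as.numeric(tr$clip))
  if (!is.finite(fit$train_loss[[length(fit$train_loss)]]))
    stop("training produced a non-finite loss")
  history <- data.frame(epoch = seq_along(unlist(fit$train_loss)),
                        train_loss = unlist(fit$train_loss),
                        val_loss = unlist(fit$val_loss),
                        val_acc = unlist(fit$val_acc))
  structure(list(params = fit$params, final_params = fit$final_params,
                 config = config, rcfg = rcfg, vocab = vocab,
                 history = history, best_epoch = fit$best_epoch,
                 n_train = length(train_idx), n_val = length(val_idx)),
            class = "capstf_model")
}

#' @export
print.capstf_model <- function(x, ...) {
  cat(sprintf(paste0("<capstf_model> %s | hidden=%d, capsules %dx%d (routing r=%d), ",
                     "%s params | trained %d epochs (best %d)\n"),
              if (x$rcfg$use_capsule) "capsule" else "non-capsule (ablation)",
              x$rcfg$hidden, x$rcfg$n_out, x$rcfg$d_out, x$rcfg$routing_iters,
              format(count_params(x$params), big.mark = ","),
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Predict TF probabilities for a dataset
#'
#' Deterministic inference with the model's own vocabulary and windowing
#' configuration. The predicted class is 1 (TF) iff `p_tf >= 0.5`.
#'
#' @param object a trained `capstf_model`.
#' @param ds a `capstf_dataset` (labels optional and ignored).
#' @param ... unused.
#' @return data.frame with `id`, `p_tf` and `label_hat`, in input order.
#' @export
predict.capstf_model <- function(object, ds, ...) {
  if (nrow(ds) == 0)
    return(data.frame(id = character(0), p_tf = numeric(0),
                      label_hat = integer(0)))
  tok <- tokenize_dataset(ds, object$vocab, object$rcfg$L,
                          object$config$window$position)
  out <- cpp_forward(tok$ids, tok$lengths, object$params, object$rcfg)
  data.frame(id = ds$id, p_tf = as.numeric(out$p),
             label_hat = as.integer(out$p >= 0.5))
}

#' Save a trained model checkpoint
#'
#' One file holding every parameter tensor plus the full configuration and
#' vocabulary, so inference is reproducible from the file alone.
#'
#' @param model a `capstf_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "capstf_model"))
  obj <- unclass(model)
  obj$capstf_version <- as.character(packageVersion("capstf"))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path path written by [save_model()].
#' @return A `capstf_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  required <- c("params", "config", "rcfg", "vocab")
  if (!is.list(obj) || !all(required %in% names(obj)))
    stop("not a capstf model checkpoint: ", path)
  structure(obj[setdiff(names(obj), "capstf_version")], class = "capstf_model")
}
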