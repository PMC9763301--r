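# Capsule-derived sequence representations: the flattened output capsules as a
# learned feature matrix, and their 2-D PCA projection for visual comparison
# of class separation.

#' Extract capsule features for a dataset
#'
#' Runs the trained model forward and returns, per record, the flattened
#' output capsules (the representation the dense head classifies). Refuses to
#' run on an ablated (non-capsule) model, whose pooled representation is not a
#' capsule feature.
#'
#' @param ds a `capstf_dataset`.
#' @param model a trained `capstf_model` with the capsule layer enabled.
#' @return `nrow(ds) x (n_out * d_out)` matrix, row names = record ids.
#' @export
extract_capsule_features <- function(ds, model) {
  stopifnot(inherits(model, "capstf_model"))
  if (!model$rcfg$use_capsule)
    stop("model was trained without the capsule layer; capsule features are undefined")
  tok <- tokenize_dataset(ds, model$vocab, model$rcfg$L,
                          model$config$window$position)
  out <- cpp_forward(tok$ids, tok$lengths, model$params, model$rcfg)
  X <- t(out$features)
  rownames(X) <- ds$id
  X
}

#' Project features onto the top principal components
#'
#' Mean-centred PCA (no scaling) via the singular value decomposition. Signs
#' follow a fixed convention: within each component, the loading of largest
#' magnitude is made positive, so the projection is deterministic.
#'
#' @param X numeric feature matrix, observations in rows (`n >= 2`).
#' @param n_components number of components to keep (default 2).
#' @return list with `coords` (`n x n_components`) and `explained_variance`
#'   (proportion of total variance per kept component).
#' @export
pca_project <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA requires at least 2 observations")
  if (all(apply(X, 2, stats::var) < .Machine$double.eps))
    stop("feature matrix has zero variance")
  n_components <- min(n_components, ncol(X), nrow(X) - 1L)
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  rot <- fit$rotation[, seq_len(n_components), drop = FALSE]
  coords <- fit$x[, seq_len(n_components), drop = FALSE]
  for (cmp in seq_len(n_components)) {
    peak <- which.max(abs(rot[, cmp]))
    if (rot[peak, cmp] < 0) {
      rot[, cmp] <- -rot[, cmp]
      coords[, cmp] <- -coords[, cmp]
    }
  }
  ev <- fit$sdev^2
  list(coords = coords,
       explained_variance = ev[seq_len(n_components)] / sum(ev))
}

#' Scatter plot of a 2-D feature projection, coloured by class
#'
#' @param coords `n x 2` matrix from [pca_project()].
#' @param labels binary 0/1 class vector (1 = TF).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_feature_pca <- function(coords, labels, title = "Capsule feature PCA") {
  df <- data.frame(PC1 = coords[, 1], PC2 = coords[, 2],
                   class = factor(ifelse(labels == 1, "TF", "non-TF"),
                                  levels = c("TF", "non-TF")))
  ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2, colour = class)) +
    ggplot2::geom_point(alpha = 0.75, size = 1.6) +
    ggplot2::scale_colour_manual(values = c("TF" = "#2166ac", "non-TF" = "#ef8a62")) +
    ggplot2::labs(title = title, colour = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("PC1", "PC2", "class"))
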