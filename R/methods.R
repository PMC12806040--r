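# S3 methods for fitted scscc objects.

#' @export
print.scscc <- function(x, ...) {
  cat("Contrastive clustering fit (scscc)\n")
  cat(sprintf("  cells: %d   embedding dim: %d   K: %d   objective: %s\n",
              nrow(x$embedding), ncol(x$embedding), x$K, x$objective))
  cat(sprintf("  stopped at epoch %d (%s); consensus ARI max: %.3f\n",
              x$stop_epoch, x$stop_reason, x$ari_max))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.scscc <- function(object, ...) {
  structure(list(fit = object), class = "summary.scscc")
}

#' @export
print.summary.scscc <- function(x, ...) {
  f <- x$fit
  print(f)
  tl <- f$trainlog
  done <- tl[stats::complete.cases(tl[, c("L_sw", "L_ins", "L")]), ]
  if (nrow(done)) {
    last <- done[nrow(done), ]
    cat(sprintf("  final losses: L=%.4f  L_sw=%.4f  L_ins=%.4f\n",
                last$L, last$L_sw, last$L_ins))
  }
  cat(sprintf("  kappa: %g   pretrain epochs: %d of %d total\n",
              f$kappa, f$config$train$pretrain_epochs,
              f$config$train$total_epochs))
  m <- f$metrics
  cat(sprintf("  metrics: ARI=%.3f  NMI=%.3f  SC=%.3f  DBi=%.3f\n",
              m["ARI"], m["NMI"], m["SC"], m["DBi"]))
  cat("  (ARI/NMI are NaN unless ground-truth labels were supplied)\n")
  invisible(x)
}

#' Prototype matrix of a fit
#'
#' @param object an `scscc` fit.
#' @param ... unused.
#' @return the K x t prototype matrix.
#' @export
coef.scscc <- function(object, ...) object$model$C

#' Cluster labels of a fit
#'
#' @param object an `scscc` fit.
#' @param ... unused.
#' @return integer label vector in `1..K`.
#' @export
labels.scscc <- function(object, ...) object$labels

#' Predict on new cells
#'
#' Applies the fitted preprocessing (stored median library size, gene subset,
#' per-gene centering/scaling) to new raw counts and pushes them through the
#' trained encoder. `type = "label"` assigns each new cell to the nearest
#' K-means centroid of the fit; `type = "prob"` returns soft prototype
#' assignments.
#'
#' @param object an `scscc` fit.
#' @param newdata cells x genes count matrix containing the fit's genes, or a
#'   preprocessed matrix with exactly those columns if the fit was built with
#'   `preprocess = FALSE`.
#' @param type "embedding" (default), "label", or "prob".
#' @param ... unused.
#' @return matrix of embeddings/probabilities, or an integer label vector.
#' @export
predict.scscc <- function(object, newdata,
                          type = c("embedding", "label", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  prep <- object$preprocessing
  if (!is.null(prep$s_mid)) {
    if (is.null(colnames(newdata)) ||
        !all(prep$genes %in% colnames(newdata))) {
      stop("newdata must contain all genes used by the fit")
    }
    s <- rowSums(newdata)
    if (any(s <= 0)) stop("newdata contains cell(s) with zero total count")
    ln <- log1p((prep$s_mid / s) * newdata[, prep$genes, drop = FALSE])
    X <- sweep(sweep(ln, 2, prep$gene_center), 2, prep$gene_scale, "/")
  } else {
    if (ncol(newdata) != object$model$dims$n_in) {
      stop("newdata must have ", object$model$dims$n_in, " columns")
    }
    X <- newdata
  }
  Z <- extract_embeddings(object$model, X)
  switch(type,
    embedding = Z,
    label = {
      d2 <- sapply(seq_len(nrow(object$centers)), function(j) {
        rowSums(sweep(Z, 2, object$centers[j, ])^2)
      })
      max.col(-as.matrix(d2), ties.method = "first")
    },
    prob = {
      H <- project(object$model, Z)
      soft_assign(prototype_logits(object$model, H),
                  object$config$loss$tau_s)
    }
  )
}

#' Plot the learned embedding
#'
#' Scatter of the first two principal components of the embedding, colored by
#' cluster label.
#'
#' @param x an `scscc` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scscc <- function(x, ...) {
  pc <- stats::prcomp(x$embedding, rank. = 2)$x
  cols <- grDevices::hcl.colors(x$K, "Dark 3")[x$labels]
  graphics::plot(pc, col = cols, pch = 19, cex = 0.6,
                 xlab = "PC1 of embedding", ylab = "PC2 of embedding", ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Serializes a fitted object (or bare model state) with its configuration;
#' loading round-trips bit-exactly.
#'
#' @param object an `scscc` fit or `scscc_model` state.
#' @param path file path.
#' @return `path` invisibly (save); the restored object (load).
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
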