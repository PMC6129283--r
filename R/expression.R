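# Expression preprocessing, PCA embedding and the observed similarity matrix D.

#' Validate a genes x samples expression matrix
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param nonnegative Require all values >= 0 (TPM-like input)?
#' @return The matrix, invisibly.
#' @export
validate_expression <- function(expr, nonnegative = FALSE) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicated sample ids")
  if (any(!is.finite(expr))) stop("expression matrix contains non-finite values")
  if (nonnegative && any(expr < 0)) {
    stop("expression matrix contains negative values")
  }
  invisible(expr)
}

#' Log-transform an expression matrix
#'
#' Applies `log2(x + pseudocount)` elementwise. The log transform is the
#' conventional variance-stabilisation for TPM-scale data ahead of PCA; it
#' keeps a handful of very highly expressed genes from dominating the first
#' component. With `log_transform = FALSE` the input is returned unchanged,
#' reproducing a raw-scale analysis.
#'
#' @param expr Non-negative numeric matrix, genes x samples.
#' @param log_transform Apply the transform? Default `TRUE`.
#' @param pseudocount Added before taking logs; default 1 so zero stays zero.
#' @return Transformed matrix of the same shape.
#' @export
preprocess_expression <- function(expr, log_transform = TRUE, pseudocount = 1) {
  validate_expression(expr, nonnegative = log_transform)
  if (!log_transform) return(expr)
  log2(expr + pseudocount)
}

#' PCA embedding of samples
#'
#' Projects samples onto the top principal axes of the gene-centered
#' expression matrix. The embedding is made deterministic across platforms by
#' fixing each component's sign so that its largest-magnitude gene loading is
#' positive.
#'
#' @param expr Numeric matrix, genes x samples (typically log2(TPM + 1)).
#' @param n_pcs Number of components to retain; default 4.
#' @param center Center each gene before decomposition? Default `TRUE`.
#' @return An object of class `pc_embedding`: list with `scores` (samples x
#'   n_pcs matrix), `explained_variance` (fraction per retained component) and
#'   `explained_variance_all` (fractions for every component).
#' @export
pca_embed <- function(expr, n_pcs = 4, center = TRUE) {
  validate_expression(expr)
  n <- ncol(expr)
  if (n < 2L) stop("PCA needs at least 2 samples")
  max_pcs <- min(n - 1L, nrow(expr))
  if (n_pcs < 1L || n_pcs > max_pcs) {
    stop("n_pcs must be between 1 and min(n_samples - 1, n_genes) = ", max_pcs)
  }
  fit <- stats::prcomp(t(expr), center = center, scale. = FALSE)
  if (all(fit$sdev < 1e-12)) {
    stop("expression matrix has no variance across samples")
  }
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- fit$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- colnames(expr)
  structure(
    list(scores = scores,
         explained_variance = ev[seq_len(n_pcs)],
         explained_variance_all = ev),
    class = "pc_embedding"
  )
}

#' @export
print.pc_embedding <- function(x, ...) {
  cat("PC embedding:", nrow(x$scores), "samples x", ncol(x$scores), "PCs;",
      sprintf("%.1f%% variance explained\n", 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Observed sample-similarity matrix D from a PC embedding
#'
#' Correlates every pair of samples' principal-component coordinate vectors.
#' With the default Spearman correlation, ties are resolved by average ranks
#' and the matrix is invariant to any strictly monotone transform applied to
#' a sample's score vector. Samples whose score vector is constant have
#' undefined correlations; those entries are set to `NA` with a warning and
#' are excluded pairwise downstream.
#'
#' @param embedding A `pc_embedding` from [pca_embed()] (needs >= 2 PCs), or a
#'   samples x coordinates numeric matrix.
#' @param cor Correlation type, `"spearman"` (default) or `"pearson"`.
#' @return Symmetric numeric matrix with unit diagonal and sample dimnames.
#' @export
observed_similarity_matrix <- function(embedding, cor = c("spearman", "pearson")) {
  cor <- match.arg(cor)
  scores <- if (inherits(embedding, "pc_embedding")) embedding$scores else embedding
  if (!is.matrix(scores) || ncol(scores) < 2L) {
    stop("need at least 2 PC coordinates per sample to correlate")
  }
  const <- apply(scores, 1L, function(r) max(r) - min(r) == 0)
  D <- suppressWarnings(stats::cor(t(scores), method = cor))
  if (any(const)) {
    warning(sum(const), " sample(s) with constant PC scores; ",
            "their similarities are NA")
    D[const, ] <- NA_real_
    D[, const] <- NA_real_
  }
  diag(D) <- 1
  dimnames(D) <- list(rownames(scores), rownames(scores))
  attr(D, "cor") <- cor
  D
}
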