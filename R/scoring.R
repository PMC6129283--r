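# Per-sample ontology scores: correlation of matched columns of the observed
# (expression-derived) and expected (ontology-derived) similarity matrices.

#' Align an observed and an expected similarity matrix
#'
#' Restricts both matrices to the samples they share, in the order of the
#' observed matrix, and reports how many samples were dropped from each side.
#' Alignment is always explicit: [ontology_score()] refuses mismatched sample
#' orders rather than silently reordering.
#'
#' @param D Observed similarity matrix (samples x samples, dimnames set).
#' @param O Expected similarity matrix (samples x samples, dimnames set).
#' @return List with elements `D` and `O`, identically ordered.
#' @export
align_similarity <- function(D, O) {
  shared <- intersect(colnames(D), colnames(O))
  if (length(shared) < 3L) {
    stop("fewer than 3 samples shared between D and O")
  }
  drop_d <- setdiff(colnames(D), shared)
  drop_o <- setdiff(colnames(O), shared)
  if (length(drop_d) > 0L || length(drop_o) > 0L) {
    warning("dropping ", length(drop_d), " sample(s) only in D and ",
            length(drop_o), " only in O")
  }
  list(D = D[shared, shared, drop = FALSE],
       O = O[shared, shared, drop = FALSE])
}

#' Per-sample ontology scores
#'
#' For each sample k, the ontology score u_k is the correlation between the
#' sample's observed similarities to all samples (column k of `D`) and its
#' expected, ontology-derived similarities (column k of `O`). A high score
#' means the expression-based neighbourhood of the sample ranks other samples
#' the way the ontology predicts.
#'
#' Entries where either column is undefined are excluded pairwise. If fewer
#' than 3 comparable pairs remain, or either column is constant over them, the
#' score is `NA` (a constant expected column carries no ranking information).
#' `include_self = TRUE` uses the full columns, diagonal included; excluding
#' the self pair drops one uninformative tied maximum (both diagonals are 1).
#'
#' @param D Observed similarity matrix.
#' @param O Expected similarity matrix; must cover the same samples in the
#'   same order as `D` (use [align_similarity()] first if not).
#' @param cor Correlation used for the score: `"spearman"` (default, average
#'   ranks for ties) or `"pearson"`.
#' @param include_self Include the self-similarity pair (1, 1)? Default `TRUE`.
#' @return Data frame of class `ontology_scores` with columns `sample_id`,
#'   `score` and `n_pairs`; attributes record `cor` and `include_self`.
#' @export
ontology_score <- function(D, O, cor = c("spearman", "pearson"),
                           include_self = TRUE) {
  cor <- match.arg(cor)
  if (is.null(colnames(D)) || is.null(colnames(O)) ||
      !identical(colnames(D), colnames(O))) {
    stop("D and O must cover the same samples in the same order; ",
         "use align_similarity() to reconcile them")
  }
  n <- ncol(D)
  scores <- rep(NA_real_, n)
  n_pairs <- integer(n)
  for (k in seq_len(n)) {
    x <- D[, k]
    y <- O[, k]
    if (!include_self) {
      x <- x[-k]
      y <- y[-k]
    }
    ok <- is.finite(x) & is.finite(y)
    n_pairs[k] <- sum(ok)
    if (n_pairs[k] < 3L) next
    x <- x[ok]
    y <- y[ok]
    if (max(x) - min(x) == 0 || max(y) - min(y) == 0) next
    scores[k] <- stats::cor(x, y, method = cor)
  }
  structure(
    data.frame(sample_id = colnames(D), score = scores, n_pairs = n_pairs,
               stringsAsFactors = FALSE),
    class = c("ontology_scores", "data.frame"),
    cor = cor,
    include_self = include_self
  )
}

#' Full scoring pipeline: expression + ontology mapping to per-sample scores
#'
#' Convenience composition of [preprocess_expression()], [pca_embed()],
#' [observed_similarity_matrix()], [expected_similarity_matrix()],
#' [align_similarity()] and [ontology_score()]. Defaults follow the reference
#' scheme: cosine term similarity for O, Spearman correlation for both D and
#' the score, first 4 PCs, log2(x + 1) preprocessing.
#'
#' @param expr Genes x samples expression matrix (TPM or normalized counts).
#' @param graph An `ontology` object.
#' @param mapping Sample mapping data frame (`sample_id`, `term_id`, ...).
#' @param measure Term similarity for O: `"cosine"` (default) or `"jaccard"`.
#' @param cor Correlation for D and the score: `"spearman"` (default) or
#'   `"pearson"`.
#' @param n_pcs Number of principal components; default 4.
#' @param log_transform,pseudocount See [preprocess_expression()].
#' @param include_self See [ontology_score()].
#' @return An `ontology_scores` data frame (see [ontology_score()]).
#' @export
score_expression <- function(expr, graph, mapping,
                             measure = c("cosine", "jaccard"),
                             cor = c("spearman", "pearson"),
                             n_pcs = 4, log_transform = TRUE, pseudocount = 1,
                             include_self = TRUE) {
  measure <- match.arg(measure)
  cor <- match.arg(cor)
  O <- expected_similarity_matrix(graph, mapping, measure = measure)
  pre <- preprocess_expression(expr, log_transform = log_transform,
                               pseudocount = pseudocount)
  emb <- pca_embed(pre, n_pcs = n_pcs)
  D <- observed_similarity_matrix(emb, cor = cor)
  al <- align_similarity(D, O)
  ontology_score(al$D, al$O, cor = cor, include_self = include_self)
}

#' Summarise ontology scores by group, batch or both
#'
#' @param u An `ontology_scores` data frame (or any data frame with
#'   `sample_id` and `score`).
#' @param mapping Sample mapping carrying the requested label column(s).
#' @param by `"group"`, `"batch"` or `"group_batch"`.
#' @return Data frame with one row per level: `n`, `n_na`, `mean`, `median`,
#'   `q25`, `q75` of the defined scores.
#' @export
group_scores <- function(u, mapping, by = c("group", "batch", "group_batch")) {
  by <- match.arg(by)
  cols <- if (by == "group_batch") c("group", "batch") else by
  missing_cols <- setdiff(cols, names(mapping))
  if (length(missing_cols) > 0L) {
    stop("mapping lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- merge(u, mapping, by = "sample_id", all.x = TRUE)
  bad <- m$sample_id[Reduce(`|`, lapply(cols, function(cc) is.na(m[[cc]])))]
  if (length(bad) > 0L) {
    stop("samples without a ", paste(cols, collapse = "/"), " label: ",
         paste(bad, collapse = ", "))
  }
  level <- do.call(paste, c(unname(m[cols]), sep = ":"))
  parts <- split(m$score, level)
  out <- data.frame(
    level = names(parts),
    n = vapply(parts, length, integer(1)),
    n_na = vapply(parts, function(s) sum(is.na(s)), integer(1)),
    mean = vapply(parts, function(s) mean(s, na.rm = TRUE), numeric(1)),
    median = vapply(parts, function(s) stats::median(s, na.rm = TRUE), numeric(1)),
    q25 = vapply(parts, function(s)
      unname(stats::quantile(s, 0.25, na.rm = TRUE, names = FALSE)), numeric(1)),
    q75 = vapply(parts, function(s)
      unname(stats::quantile(s, 0.75, na.rm = TRUE, names = FALSE)), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Compare two groups of ontology scores
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test on the score values: exact
#' for small tie-free samples, normal approximation with tie correction
#' otherwise (the behaviour of [stats::wilcox.test()]).
#'
#' @param u_a,u_b Numeric vectors of scores; `NA`s dropped; each needs >= 3
#'   defined values.
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_score_groups <- function(u_a, u_b) {
  a <- u_a[is.finite(u_a)]
  b <- u_b[is.finite(u_b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 defined scores")
  }
  if (max(c(a, b)) - min(c(a, b)) == 0) {
    warning("all scores tied across both groups; p = 1")
    res <- list(statistic = c(W = length(a) * length(b) / 2), p.value = 1,
                method = "Wilcoxon rank sum test (degenerate: all values tied)",
                alternative = "two.sided",
                data.name = "u_a and u_b")
    class(res) <- "htest"
    return(res)
  }
  suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
}
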