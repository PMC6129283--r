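# Reference models: randomized ontology mappings and a fixed two-valued
# ontology. Both replace the expected matrix O while the observed matrix D is
# held fixed, so any score difference is attributable to the ontology.

#' Randomize a sample-to-term mapping
#'
#' Assigns every sample a term drawn uniformly at random, with replacement,
#' from the ontology's non-obsolete terms. Group and batch labels are
#' preserved. With `observed_only = TRUE` the draw is restricted to terms that
#' occur in the original mapping, a harder null that keeps the term frequency
#' support.
#'
#' @param graph An `ontology` object with at least 2 non-obsolete terms.
#' @param mapping Sample mapping data frame.
#' @param seed Integer seed; the same seed reproduces the same mapping.
#' @param observed_only Restrict the candidate terms to those in `mapping`?
#' @return A mapping data frame with the same samples and randomized `term_id`.
#' @export
randomize_mapping <- function(graph, mapping, seed, observed_only = FALSE) {
  terms <- if (observed_only) {
    intersect(unique(mapping$term_id), .valid_terms(graph))
  } else {
    .valid_terms(graph)
  }
  if (length(terms) < 2L) {
    stop("need at least 2 non-obsolete candidate terms to randomize")
  }
  out <- mapping
  set.seed(seed)
  out$term_id <- sample(terms, nrow(mapping), replace = TRUE)
  out
}

#' Fixed two-valued expected similarity matrix
#'
#' A deliberately coarse ontology stand-in: samples sharing a group label get
#' similarity `same` (default 1.0), all other pairs get `other` (default
#' 0.25). Comparing scores under this matrix with scores under the real
#' ontology shows how much the graded between-type similarities contribute.
#'
#' @param mapping Sample mapping with a `group` column.
#' @param same Similarity for same-group pairs; default 1.0.
#' @param other Similarity for different-group pairs; default 0.25.
#' @return Symmetric matrix, unit diagonal, sample dimnames.
#' @export
fixed_similarity_matrix <- function(mapping, same = 1.0, other = 0.25) {
  if (!("group" %in% names(mapping)) || any(is.na(mapping$group))) {
    stop("fixed_similarity_matrix needs a complete group column in the mapping")
  }
  if (!(other >= 0 && other <= same && same <= 1)) {
    stop("need 0 <= other <= same <= 1")
  }
  g <- as.character(mapping$group)
  O <- ifelse(outer(g, g, `==`), same, other)
  diag(O) <- 1
  dimnames(O) <- list(mapping$sample_id, mapping$sample_id)
  attr(O, "measure") <- "fixed"
  O
}

#' Randomization experiment: true vs randomized vs fixed ontology
#'
#' Computes the observed similarity matrix D once, then rescores the samples
#' under (a) the true mapping, (b) `n_reps` independently randomized mappings
#' (replicate i uses `seed + i`, so any subset of replicates is reproducible),
#' and (c) the fixed `same`/`other` two-valued matrix. Rank-sum tests compare
#' the true scores against the pooled randomized scores and against the fixed
#' scores.
#'
#' @param expr Genes x samples expression matrix.
#' @param graph An `ontology` object.
#' @param mapping Sample mapping (needs `group` for the fixed matrix).
#' @param n_reps Number of randomized mappings; default 100.
#' @param seed Base seed for the replicate stream.
#' @param measure,cor,n_pcs,log_transform,include_self Scoring configuration,
#'   see [score_expression()].
#' @param fixed_same,fixed_other Values for [fixed_similarity_matrix()].
#' @param observed_only Passed to [randomize_mapping()].
#' @return List of class `randomization_experiment`: `scores_true`,
#'   `scores_fixed` (numeric vectors), `replicates` (per-replicate summary
#'   data frame), `scores_randomized` (samples x replicates matrix) and
#'   `tests` (data frame of rank-sum contrasts).
#' @export
randomization_experiment <- function(expr, graph, mapping, n_reps = 100,
                                     seed = 1,
                                     measure = c("cosine", "jaccard"),
                                     cor = c("spearman", "pearson"),
                                     n_pcs = 4, log_transform = TRUE,
                                     include_self = TRUE,
                                     fixed_same = 1.0, fixed_other = 0.25,
                                     observed_only = FALSE) {
  measure <- match.arg(measure)
  cor <- match.arg(cor)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  mapping <- validate_mapping(mapping, graph)

  pre <- preprocess_expression(expr, log_transform = log_transform)
  emb <- pca_embed(pre, n_pcs = n_pcs)
  D <- observed_similarity_matrix(emb, cor = cor)

  score_against <- function(O) {
    al <- align_similarity(D, O)
    ontology_score(al$D, al$O, cor = cor, include_self = include_self)$score
  }

  O_true <- expected_similarity_matrix(graph, mapping, measure = measure)
  u_true <- score_against(O_true)
  u_fixed <- score_against(fixed_similarity_matrix(mapping, fixed_same, fixed_other))

  u_rand <- matrix(NA_real_, nrow = nrow(mapping), ncol = n_reps,
                   dimnames = list(mapping$sample_id, NULL))
  for (i in seq_len(n_reps)) {
    m_i <- randomize_mapping(graph, mapping, seed = seed + i,
                             observed_only = observed_only)
    O_i <- expected_similarity_matrix(graph, m_i, measure = measure)
    u_rand[, i] <- score_against(O_i)
  }

  replicates <- data.frame(
    replicate = seq_len(n_reps),
    n = colSums(!is.na(u_rand)),
    mean = colMeans(u_rand, na.rm = TRUE),
    median = apply(u_rand, 2L, stats::median, na.rm = TRUE),
    sd = apply(u_rand, 2L, stats::sd, na.rm = TRUE)
  )

  t_rand <- compare_score_groups(u_true, as.vector(u_rand))
  t_fixed <- compare_score_groups(u_true, u_fixed)
  tests <- data.frame(
    contrast = c("true_vs_randomized", "true_vs_fixed"),
    statistic = c(unname(t_rand$statistic), unname(t_fixed$statistic)),
    p_value = c(t_rand$p.value, t_fixed$p.value)
  )

  structure(
    list(scores_true = stats::setNames(u_true, mapping$sample_id),
         scores_fixed = stats::setNames(u_fixed, mapping$sample_id),
         scores_randomized = u_rand,
         replicates = replicates,
         tests = tests,
         seed = seed),
    class = "randomization_experiment"
  )
}

#' @export
print.randomization_experiment <- function(x, ...) {
  cat("randomization experiment:", ncol(x$scores_randomized), "replicates\n")
  cat(sprintf("  mean score  true: %.4f  fixed: %.4f  randomized: %.4f\n",
              mean(x$scores_true, na.rm = TRUE),
              mean(x$scores_fixed, na.rm = TRUE),
              mean(x$scores_randomized, na.rm = TRUE)))
  print(x$tests)
  invisible(x)
}
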