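# Synthetic data: toy ontologies and expression matrices whose similarity
# structure is ontology-consistent, so the whole pipeline is testable without
# external downloads.

#' Build a complete branching-tree toy ontology
#'
#' Generates a rooted tree of terms with `branching` children per internal
#' node and `depth` levels below the root. Term ids are deterministic
#' (`TOY:0000001` is the root, numbered breadth-first), so identical calls
#' yield identical graphs.
#'
#' @param depth Number of levels below the root; >= 1.
#' @param branching Children per internal node; >= 2.
#' @return An `ontology` object (see [parse_obo()]).
#' @export
make_toy_ontology <- function(depth = 3, branching = 2) {
  if (depth < 1L) stop("depth must be >= 1")
  if (branching < 2L) stop("branching must be >= 2")
  n_terms <- sum(branching^(0:depth))
  ids <- sprintf("TOY:%07d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  labels <- character(n_terms)
  names(labels) <- ids
  labels[1] <- "root"
  parents[[1]] <- character(0)
  # breadth-first numbering: children of node i are at
  # branching * (i - 1) + 2, ..., branching * i + 1
  for (i in seq_len(n_terms)) {
    first_child <- branching * (i - 1L) + 2L
    if (first_child > n_terms) break
    for (k in seq_len(branching)) {
      ch <- first_child + k - 1L
      parents[[ch]] <- ids[i]
      labels[ch] <- sprintf("%s.%d", labels[i], k)
    }
  }
  structure(
    list(terms = ids, names = labels, parents = parents,
         obsolete = character(0)),
    class = "ontology"
  )
}

#' Leaf terms of an ontology
#'
#' Terms with no non-obsolete children over is_a edges.
#'
#' @param graph An `ontology` object.
#' @return Character vector of leaf term ids.
#' @export
ontology_leaves <- function(graph) {
  with_children <- unique(unlist(graph$parents[.valid_terms(graph)]))
  setdiff(.valid_terms(graph), with_children)
}

#' Simulate an expression matrix with ontology-consistent structure
#'
#' Group mean profiles diffuse down the ontology tree by Brownian drift: the
#' root profile is drawn i.i.d. standard normal per gene, each child's mean
#' profile is its parent's plus an independent `N(0, tau^2)` increment per
#' gene, and each sample is its leaf's mean plus `N(0, epsilon^2)` noise.
#' Under this model the expected expression distance between two groups grows
#' with their path distance in the tree, which is exactly the monotone
#' relation between ontology distance and expression distance that the
#' ontology score assumes. Values are shifted by a global constant so the
#' matrix is non-negative (a shift, unlike truncation, leaves the drift
#' covariance intact).
#'
#' @param graph A toy `ontology` from [make_toy_ontology()] (any is_a tree
#'   with a single root works).
#' @param n_per_group Samples per selected leaf term; default 15.
#' @param n_genes Number of genes; default 500.
#' @param tau Per-edge drift standard deviation; default 1.
#' @param epsilon Within-group noise standard deviation; default 0.1.
#' @param n_groups Number of leaf terms to use; default all leaves.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with `expr` (genes x samples matrix, non-negative) and
#'   `mapping` (data frame `sample_id`, `term_id`, `group`; group = leaf id).
#' @export
simulate_expression <- function(graph, n_per_group = 15, n_genes = 500,
                                tau = 1, epsilon = 0.1, n_groups = NULL,
                                seed = 1) {
  if (tau <= 0 || epsilon <= 0) stop("tau and epsilon must be > 0")
  leaves <- ontology_leaves(graph)
  if (is.null(n_groups)) n_groups <- length(leaves)
  if (n_groups < 2L || n_groups > length(leaves)) {
    stop("n_groups must be between 2 and the number of leaves (",
         length(leaves), ")")
  }
  groups <- leaves[seq_len(n_groups)]
  set.seed(seed)
  # means diffuse root -> leaves; graph$terms is in breadth-first order for
  # toy trees, but walk explicitly so any single-root is_a tree works
  roots <- graph$terms[lengths(graph$parents[graph$terms]) == 0L]
  if (length(roots) != 1L) stop("simulate_expression needs a single-root tree")
  children <- .children_map(graph)
  means <- matrix(NA_real_, n_genes, length(graph$terms),
                  dimnames = list(NULL, graph$terms))
  means[, roots] <- stats::rnorm(n_genes)
  queue <- roots
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    for (ch in children[[t]]) {
      means[, ch] <- means[, t] + stats::rnorm(n_genes, sd = tau)
      queue <- c(queue, ch)
    }
  }
  n <- n_groups * n_per_group
  sample_ids <- sprintf("S%04d", seq_len(n))
  expr <- matrix(NA_real_, n_genes, n,
                 dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                 sample_ids))
  term_of <- rep(groups, each = n_per_group)
  for (j in seq_len(n)) {
    expr[, j] <- means[, term_of[j]] + stats::rnorm(n_genes, sd = epsilon)
  }
  expr <- expr - min(expr)  # global shift to non-negative
  mapping <- data.frame(sample_id = sample_ids, term_id = term_of,
                        group = term_of, stringsAsFactors = FALSE)
  list(expr = expr, mapping = mapping)
}

#' Desk-scale end-to-end benchmark
#'
#' One call reproducing the three experiment designs on synthetic data: the
#' true-vs-randomized-vs-fixed ontology comparison, the contamination
#' fraction and noise intensity sweeps, and the before/noisy/adjusted scoring
#' loop for each requested adjuster.
#'
#' @param depth,branching Toy ontology shape; defaults 3 and 2 (8 leaves).
#' @param n_per_group,n_genes,tau,epsilon,n_groups Generator settings, see
#'   [simulate_expression()].
#' @param n_reps Randomized-mapping replicates; default 100.
#' @param fractions Contamination fractions for the fraction sweep.
#' @param mus Noise means for the intensity sweep.
#' @param noise_fraction Contaminated fraction for the intensity sweep and the
#'   adjustment loop; default 0.5.
#' @param mu,sigma Noise parameters for the fraction sweep and adjustment
#'   loop; defaults 10 and 1.
#' @param adjusters Adjuster names to benchmark; default
#'   `c("identity", "location_scale")`.
#' @param seed Master seed for generation, randomization, and noise.
#' @param measure,cor,n_pcs,include_self Scoring configuration.
#' @return List of class `ontoscore_benchmark` with elements `randomization`
#'   (a [randomization_experiment()] result), `fraction_sweep`,
#'   `intensity_sweep` (summary data frames) and `adjustment` (named list of
#'   [adjust_and_rescore()] results).
#' @export
end_to_end_benchmark <- function(depth = 3, branching = 2, n_per_group = 15,
                                 n_genes = 500, tau = 1, epsilon = 0.1,
                                 n_groups = NULL, n_reps = 100,
                                 fractions = seq(0, 0.5, by = 0.1),
                                 mus = c(0, 10, 20, 30),
                                 noise_fraction = 0.5, mu = 10, sigma = 1,
                                 adjusters = c("identity", "location_scale"),
                                 seed = 1, measure = "cosine",
                                 cor = "spearman", n_pcs = 4,
                                 include_self = TRUE) {
  graph <- make_toy_ontology(depth, branching)
  sim <- simulate_expression(graph, n_per_group = n_per_group,
                             n_genes = n_genes, tau = tau, epsilon = epsilon,
                             n_groups = n_groups, seed = seed)
  expr <- sim$expr
  mapping <- sim$mapping

  rand <- randomization_experiment(expr, graph, mapping, n_reps = n_reps,
                                   seed = seed, measure = measure, cor = cor,
                                   n_pcs = n_pcs, include_self = include_self)
  fsweep <- noise_fraction_sweep(expr, graph, mapping, fractions = fractions,
                                 mu = mu, sigma = sigma, seed = seed,
                                 measure = measure, cor = cor, n_pcs = n_pcs,
                                 include_self = include_self)
  isweep <- noise_intensity_sweep(expr, graph, mapping, mus = mus,
                                  sigma = sigma, fraction = noise_fraction,
                                  seed = seed, measure = measure, cor = cor,
                                  n_pcs = n_pcs, include_self = include_self)

  lexpr <- preprocess_expression(expr)
  noisy <- add_gaussian_noise(lexpr, fraction = noise_fraction, mu = mu,
                              sigma = sigma, seed = seed,
                              group = stats::setNames(mapping$group,
                                                      mapping$sample_id))
  adjustment <- lapply(stats::setNames(adjusters, adjusters), function(a) {
    adjust_and_rescore(lexpr, noisy$expr, noisy$batch, graph, mapping,
                       adjuster = a, measure = measure, cor = cor,
                       n_pcs = n_pcs, log_transform = FALSE,
                       include_self = include_self)
  })

  structure(
    list(randomization = rand, fraction_sweep = fsweep,
         intensity_sweep = isweep, adjustment = adjustment,
         graph = graph, mapping = mapping, seed = seed),
    class = "ontoscore_benchmark"
  )
}

#' @export
print.ontoscore_benchmark <- function(x, ...) {
  cat("== randomization (true vs null ontologies) ==\n")
  print(x$randomization)
  cat("\n== contamination fraction sweep ==\n")
  print(x$fraction_sweep, row.names = FALSE)
  cat("\n== noise intensity sweep ==\n")
  print(x$intensity_sweep, row.names = FALSE)
  cat("\n== adjust-and-rescore (median scores) ==\n")
  for (a in names(x$adjustment)) {
    d <- x$adjustment[[a]]
    cat(sprintf("  %-15s original %.3f  noisy %.3f  adjusted %.3f\n", a,
                stats::median(d$original, na.rm = TRUE),
                stats::median(d$noisy, na.rm = TRUE),
                stats::median(d$adjusted, na.rm = TRUE)))
  }
  invisible(x)
}
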