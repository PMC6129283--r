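# Shared fixtures: tiny OBO texts, a random-DAG generator and a literal
# brute-force similarity oracle used to cross-check the set-based code.

write_obo_text <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

# chain: c is_a b is_a a
chain_obo <- function() {
  write_obo_text(c(
    "[Term]", "id: X:a", "name: a", "",
    "[Term]", "id: X:b", "name: b", "is_a: X:a ! a", "",
    "[Term]", "id: X:c", "name: c", "is_a: X:b ! b"
  ))
}

# diamond: d is_a b, d is_a c, b is_a a, c is_a a
diamond_obo <- function() {
  write_obo_text(c(
    "[Term]", "id: X:a", "name: a", "",
    "[Term]", "id: X:b", "name: b", "is_a: X:a", "",
    "[Term]", "id: X:c", "name: c", "is_a: X:a", "",
    "[Term]", "id: X:d", "name: d", "is_a: X:b", "is_a: X:c"
  ))
}

# siblings a, b under root r
siblings_obo <- function() {
  write_obo_text(c(
    "[Term]", "id: X:r", "name: r", "",
    "[Term]", "id: X:a", "name: a", "is_a: X:r", "",
    "[Term]", "id: X:b", "name: b", "is_a: X:r"
  ))
}

# random DAG: term i (i >= 2) draws 1-2 parents among terms 1..i-1, which is
# acyclic by construction
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  ids <- sprintf("R:%03d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[1]] <- character(0)
  for (i in 2:n_terms) {
    k <- sample(1:min(2L, i - 1L), 1)
    parents[[i]] <- ids[sample.int(i - 1L, k)]
  }
  structure(list(terms = ids,
                 names = stats::setNames(ids, ids),
                 parents = parents,
                 obsolete = character(0)),
            class = "ontology")
}

# literal oracle: materialize full |CL|-length binary indicator vectors of the
# reflexive-transitive ancestor closure and apply the similarity definitions
# verbatim; independent of the package's set-based path
brute_force_similarity <- function(graph, t_i, t_j, measure) {
  closure <- function(t) {
    out <- character(0)
    stack <- t
    while (length(stack) > 0) {
      x <- stack[[1]]
      stack <- stack[-1]
      if (x %in% out) next
      out <- c(out, x)
      stack <- c(stack, graph$parents[[x]])
    }
    out
  }
  v_i <- as.numeric(graph$terms %in% closure(t_i))
  v_j <- as.numeric(graph$terms %in% closure(t_j))
  if (measure == "cosine") {
    sum(v_i * v_j) / (sqrt(sum(v_i^2)) * sqrt(sum(v_j^2)))
  } else {
    sum(v_i == 1 & v_j == 1) / sum(v_i == 1 | v_j == 1)
  }
}

# small ontology-consistent dataset reused across test files
toy_dataset <- function(seed = 1, n_per_group = 15, n_genes = 500,
                        tau = 1, epsilon = 0.1, depth = 3, branching = 2) {
  graph <- make_toy_ontology(depth, branching)
  sim <- simulate_expression(graph, n_per_group = n_per_group,
                             n_genes = n_genes, tau = tau, epsilon = epsilon,
                             seed = seed)
  list(graph = graph, expr = sim$expr, mapping = sim$mapping)
}
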