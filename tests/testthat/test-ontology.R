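# Ontology parsing, ancestor sets and term similarities.

test_that("parse_obo builds the is_a graph and handles obsolete terms", {
  path <- write_obo_text(c(
    "[Term]", "id: X:a", "name: a", "",
    "[Term]", "id: X:b", "name: b", "is_a: X:a ! a", "",
    "[Term]", "id: X:c", "name: c", "is_obsolete: true"
  ))
  g <- parse_obo(path)
  expect_setequal(g$terms, c("X:a", "X:b"))
  expect_equal(g$parents[["X:b"]], "X:a")
  expect_length(g$parents[["X:a"]], 0)

  g2 <- parse_obo(path, keep_obsolete = TRUE)
  expect_true("X:c" %in% g2$terms)
  expect_true("X:c" %in% g2$obsolete)
  expect_length(g2$parents[["X:c"]], 0)
})

test_that("parse_obo errors on cycles and unreadable files", {
  cyc <- write_obo_text(c(
    "[Term]", "id: X:a", "is_a: X:b", "",
    "[Term]", "id: X:b", "is_a: X:a"
  ))
  expect_error(parse_obo(cyc), "cycle")
  expect_error(parse_obo(tempfile()), "cannot read")
})

test_that("parse_obo ignores non-is_a relationships", {
  path <- write_obo_text(c(
    "[Term]", "id: X:a", "",
    "[Term]", "id: X:b", "is_a: X:a", "relationship: part_of X:a"
  ))
  g <- parse_obo(path)
  expect_equal(g$parents[["X:b"]], "X:a")
})

test_that("ancestor sets are the reflexive transitive is_a closure", {
  g <- parse_obo(chain_obo())
  expect_equal(ancestors(g, "X:a"), "X:a")
  expect_equal(ancestors(g, "X:c"), c("X:a", "X:b", "X:c"))

  d <- parse_obo(diamond_obo())
  expect_equal(ancestors(d, "X:d"), c("X:a", "X:b", "X:c", "X:d"))

  expect_error(ancestors(g, "X:zzz"), "unknown term")
})

test_that("term similarities match hand-derived toy values", {
  s <- parse_obo(siblings_obo())
  # A(a) = {a, r}, A(b) = {b, r}
  expect_equal(term_similarity(s, "X:a", "X:b", "jaccard"), 1 / 3)
  expect_equal(term_similarity(s, "X:a", "X:b", "cosine"), 1 / 2)

  g <- parse_obo(chain_obo())
  # A(b) = {a, b}, A(c) = {a, b, c}
  expect_equal(term_similarity(g, "X:b", "X:c", "jaccard"), 2 / 3)
  expect_equal(term_similarity(g, "X:b", "X:c", "cosine"), 2 / sqrt(6))

  for (m in c("jaccard", "cosine")) {
    expect_equal(term_similarity(g, "X:b", "X:b", m), 1.0)
  }
})

test_that("obsolete or unknown terms are rejected by term_similarity", {
  path <- write_obo_text(c(
    "[Term]", "id: X:a", "",
    "[Term]", "id: X:b", "is_a: X:a", "",
    "[Term]", "id: X:c", "is_obsolete: true"
  ))
  g <- parse_obo(path, keep_obsolete = TRUE)
  expect_error(term_similarity(g, "X:a", "X:c"), "obsolete")
  expect_error(term_similarity(g, "X:a", "X:nope"), "unknown")
})

test_that("similarity properties hold on random DAGs", {
  for (seed in 1:10) {
    g <- random_dag(sample(5:30, 1), seed = seed)
    pair <- sample(g$terms, 2)
    jac <- term_similarity(g, pair[1], pair[2], "jaccard")
    cos <- term_similarity(g, pair[1], pair[2], "cosine")
    expect_gte(cos, jac)  # holds for any two binary indicator vectors
    expect_true(jac >= 0 && cos <= 1)
    expect_equal(term_similarity(g, pair[2], pair[1], "jaccard"), jac)
    expect_equal(term_similarity(g, pair[2], pair[1], "cosine"), cos)
    identical_sets <- setequal(ancestors(g, pair[1]), ancestors(g, pair[2]))
    expect_equal(jac == 1, identical_sets)
    expect_equal(abs(cos - 1) < 1e-12, identical_sets)
  }
})

test_that("set-based similarities agree with the indicator-vector brute force", {
  worst <- 0
  for (seed in 1:100) {
    g <- random_dag(sample(5:50, 1), seed = 1000 + seed)
    pair <- sample(g$terms, 2)
    for (m in c("jaccard", "cosine")) {
      a <- term_similarity(g, pair[1], pair[2], m)
      b <- brute_force_similarity(g, pair[1], pair[2], m)
      worst <- max(worst, abs(a - b))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("expected similarity matrix broadcasts term similarities", {
  s <- parse_obo(siblings_obo())
  mapping <- data.frame(sample_id = c("s1", "s2", "s3"),
                        term_id = c("X:a", "X:a", "X:b"))
  O <- expected_similarity_matrix(s, mapping, measure = "cosine")
  expect_equal(dim(O), c(3, 3))
  expect_equal(unname(diag(O)), rep(1, 3))
  expect_equal(unname(O["s1", "s2"]), 1.0)   # same term
  expect_equal(unname(O["s1", "s3"]), 0.5)   # siblings, cosine
  expect_equal(O, t(O), ignore_attr = TRUE)
})

test_that("expected similarity matrix is permutation-equivariant", {
  td <- toy_dataset(seed = 3, n_per_group = 3, n_genes = 20)
  O <- expected_similarity_matrix(td$graph, td$mapping)
  perm <- sample(nrow(td$mapping))
  O_p <- expected_similarity_matrix(td$graph, td$mapping[perm, ])
  expect_equal(O_p, O[perm, perm], ignore_attr = TRUE)
})

test_that("mapping validation rejects unknown and obsolete terms", {
  g <- parse_obo(siblings_obo())
  expect_error(
    expected_similarity_matrix(g, data.frame(sample_id = "s1", term_id = "X:q")),
    "absent"
  )
  expect_error(
    validate_mapping(data.frame(sample_id = c("s1", "s1"),
                                term_id = c("X:a", "X:b")), g),
    "duplicated"
  )
})

test_that("similarity converts to distance elementwise", {
  m <- matrix(c(1, 0.25, 0.25, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  d <- similarity_to_distance(m)
  expect_equal(unname(d["a", "b"]), 0.75)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_identical(d, t(d))
  expect_error(similarity_to_distance(m * 2), "\\[0, 1\\]")
})
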