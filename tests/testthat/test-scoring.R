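# Per-sample ontology scores, alignment, group summaries, rank-sum tests.

# small non-trivial expected matrix over 5 samples
mk_O <- function() {
  ids <- sprintf("s%d", 1:5)
  O <- outer(1:5, 1:5, function(i, j) 1 - abs(i - j) / 8)
  dimnames(O) <- list(ids, ids)
  diag(O) <- 1
  O
}

test_that("score is 1 when observed equals expected, -1 under reversal", {
  O <- mk_O()
  u <- ontology_score(O, O, cor = "spearman")
  expect_equal(u$score, rep(1, 5))
  # strictly decreasing transform of each column reverses every rank
  D_rev <- 1 - O
  dimnames(D_rev) <- dimnames(O)
  u_rev <- ontology_score(D_rev, O, cor = "spearman")
  expect_equal(u_rev$score, rep(-1, 5))
})

test_that("constant expected columns give NA scores", {
  ids <- sprintf("s%d", 1:4)
  O <- matrix(1, 4, 4, dimnames = list(ids, ids))  # all samples same term
  set.seed(1)
  D <- stats::cor(matrix(rnorm(16), 4, 4))
  dimnames(D) <- list(ids, ids)
  u <- ontology_score(D, O, include_self = FALSE)
  expect_true(all(is.na(u$score)))
})

test_that("include_self adds exactly the tied (1, 1) pair", {
  O <- mk_O()
  set.seed(2)
  D <- O + matrix(rnorm(25, sd = 0.01), 5, 5)
  D <- (D + t(D)) / 2
  diag(D) <- 1
  dimnames(D) <- dimnames(O)
  u_with <- ontology_score(D, O, include_self = TRUE)
  u_without <- ontology_score(D, O, include_self = FALSE)
  expect_equal(u_with$n_pairs, u_without$n_pairs + 1L)
  # both modes agree closely when D tracks O
  expect_true(all(abs(u_with$score - u_without$score) < 0.2))
})

test_that("sample-order mismatches are refused, alignment fixes them", {
  O <- mk_O()
  D <- O[c(2, 1, 3, 4, 5), c(2, 1, 3, 4, 5)]
  expect_error(ontology_score(D, O), "same order")
  al <- align_similarity(D, O)
  expect_identical(colnames(al$D), colnames(al$O))
  expect_equal(ontology_score(al$D, al$O)$score, rep(1, 5))
})

test_that("alignment drops extra samples with a warning, errors below 3", {
  O <- mk_O()
  D <- rbind(cbind(O, s6 = 0.5), s6 = c(rep(0.5, 5), 1))
  dimnames(D) <- list(c(rownames(O), "s6"), c(colnames(O), "s6"))
  expect_warning(al <- align_similarity(D, O), "dropping")
  expect_equal(colnames(al$D), colnames(O))
  O2 <- O[1:2, 1:2]
  expect_error(align_similarity(O2, mk_O()[3:5, 3:5]), "fewer than 3")
})

test_that("spearman scores are invariant to positive affine transforms of D", {
  td <- toy_dataset(seed = 5, n_per_group = 4, n_genes = 100)
  O <- expected_similarity_matrix(td$graph, td$mapping)
  emb <- pca_embed(preprocess_expression(td$expr), n_pcs = 4)
  D <- observed_similarity_matrix(emb)
  u1 <- ontology_score(D, O)
  u2 <- ontology_score(0.5 * D + 0.2, O)
  expect_equal(u1$score, u2$score)
})

test_that("ontology-consistent data scores high, permuted labels near zero", {
  td <- toy_dataset(seed = 9)
  emb <- pca_embed(preprocess_expression(td$expr), n_pcs = 4)
  D <- observed_similarity_matrix(emb)
  O <- expected_similarity_matrix(td$graph, td$mapping)
  u <- ontology_score(D, O)
  expect_gt(median(u$score, na.rm = TRUE), 0.9)

  meds <- vapply(1:20, function(i) {
    set.seed(100 + i)
    perm <- td$mapping
    perm$term_id <- sample(perm$term_id)
    O_p <- expected_similarity_matrix(td$graph, perm)
    median(ontology_score(D, O_p)$score, na.rm = TRUE)
  }, numeric(1))
  expect_lt(max(abs(meds)), 0.35)
  expect_lt(abs(mean(meds)), 0.1)
})

test_that("group summaries aggregate scores per level", {
  u <- structure(data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                            score = c(0.2, 0.4, 0.5, NA),
                            n_pairs = rep(4L, 4)),
                 class = c("ontology_scores", "data.frame"))
  mapping <- data.frame(sample_id = sprintf("s%d", 1:4),
                        term_id = "t",
                        group = c("g1", "g1", "g2", "g2"),
                        batch = c("b1", "b2", "b1", "b2"))
  gs <- group_scores(u, mapping, by = "group")
  expect_equal(gs$mean[gs$level == "g1"], 0.3)
  expect_equal(gs$n, c(2L, 2L))
  expect_equal(gs$n_na[gs$level == "g2"], 1L)
  gb <- group_scores(u, mapping, by = "group_batch")
  expect_equal(nrow(gb), 4)
  expect_error(group_scores(u, mapping[, c("sample_id", "term_id")], by = "group"),
               "lacks")
})

test_that("rank-sum comparison matches the enumerated exact p-value", {
  res <- compare_score_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1)  # 2 / choose(6, 3) two-sided
  # symmetric in its arguments
  expect_equal(compare_score_groups(c(4, 5, 6), c(1, 2, 3))$p.value, 0.1)
  # exchangeable groups: p = 1
  expect_equal(compare_score_groups(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_warning(res0 <- compare_score_groups(rep(1, 3), rep(1, 4)), "tied")
  expect_equal(res0$p.value, 1)
  expect_error(compare_score_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})
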