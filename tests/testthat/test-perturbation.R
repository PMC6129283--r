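# Gaussian noise injection, sweeps and the adjust-and-rescore loop.

test_that("noise injection selects the exact rounded count and is seeded", {
  set.seed(3)
  expr <- matrix(rexp(50 * 100), 50, 100,
                 dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:100)))
  res <- add_gaussian_noise(expr, fraction = 0.5, seed = 1)
  expect_equal(sum(res$batch == "noisy"), 50)
  # fraction 0 is the identity
  res0 <- add_gaussian_noise(expr, fraction = 0, seed = 1)
  expect_identical(res0$expr, expr)
  expect_true(all(res0$batch == "clean"))
  # clean samples are bit-identical, reproducible from the seed
  clean <- names(res$batch)[res$batch == "clean"]
  expect_identical(res$expr[, clean], expr[, clean])
  res_again <- add_gaussian_noise(expr, fraction = 0.5, seed = 1)
  expect_identical(res$expr, res_again$expr)
  expect_error(add_gaussian_noise(expr, fraction = 1.5), "\\[0, 1\\]")
})

test_that("rounding is half away from zero and stratification keeps totals", {
  expr <- matrix(rexp(10 * 30), 10, 30,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:30)))
  group <- setNames(rep(c("a", "b", "c"), each = 10), colnames(expr))
  # 0.25 * 30 = 7.5 -> 8, spread 3/3/2 over the three groups
  res <- add_gaussian_noise(expr, fraction = 0.25, seed = 2, group = group)
  expect_equal(sum(res$batch == "noisy"), 8)
  per_group <- table(group[names(res$batch)[res$batch == "noisy"]])
  expect_true(all(per_group >= 2))  # every group holds both batches
})

test_that("injected noise has the requested mean", {
  expr <- matrix(0, 200, 100,
                 dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:100)))
  res <- add_gaussian_noise(expr, fraction = 0.5, mu = 10, sigma = 1, seed = 4)
  diffs <- res$expr[, res$batch == "noisy"] - 0
  expect_gte(length(diffs), 1e4)
  expect_lt(abs(mean(diffs) - 10), 0.1)
  expect_lt(abs(sd(as.vector(diffs)) - 1), 0.05)
})

test_that("fraction sweep reproduces unperturbed scores at fraction 0", {
  td <- toy_dataset(seed = 8, n_per_group = 6, n_genes = 200)
  sw <- noise_fraction_sweep(td$expr, td$graph, td$mapping,
                             fractions = c(0, 0.3), seed = 5)
  expect_equal(nrow(sw), 2)
  expect_named(sw, c("fraction", "n", "n_na", "mean", "median", "q25", "q75"))
  u0 <- score_expression(td$expr, td$graph, td$mapping)
  expect_equal(sw$median[sw$fraction == 0], median(u0$score, na.rm = TRUE))
  expect_lt(sw$median[sw$fraction == 0.3], sw$median[sw$fraction == 0])
})

test_that("noise degrades the score at moderate contamination", {
  td <- toy_dataset(seed = 12, n_per_group = 5, n_genes = 150)
  lexpr <- preprocess_expression(td$expr)
  grp <- setNames(td$mapping$group, td$mapping$sample_id)
  u0 <- median(score_expression(td$expr, td$graph, td$mapping)$score, na.rm = TRUE)
  worse <- vapply(1:20, function(s) {
    nz <- add_gaussian_noise(lexpr, fraction = 0.2, mu = 5, sigma = 1,
                             seed = s, group = grp)
    u <- score_expression(nz$expr, td$graph, td$mapping, log_transform = FALSE)
    median(u$score, na.rm = TRUE) <= u0
  }, logical(1))
  expect_true(all(worse))
})

test_that("intensity sweep drops fast then plateaus", {
  td <- toy_dataset(seed = 10, n_per_group = 8, n_genes = 300)
  sw <- noise_intensity_sweep(td$expr, td$graph, td$mapping,
                              mus = c(0, 10, 20, 30), seed = 6)
  drop_early <- sw$median[sw$mu == 0] - sw$median[sw$mu == 10]
  drop_late <- sw$median[sw$mu == 20] - sw$median[sw$mu == 30]
  expect_gt(drop_early, drop_late)
  expect_lt(abs(drop_late), 0.15)  # plateau beyond mu = 10
})

test_that("adjust_and_rescore matches its identity and oracle contracts", {
  td <- toy_dataset(seed = 13, n_per_group = 6, n_genes = 200)
  lexpr <- preprocess_expression(td$expr)
  grp <- setNames(td$mapping$group, td$mapping$sample_id)
  nz <- add_gaussian_noise(lexpr, fraction = 0.5, mu = 10, sigma = 1,
                           seed = 7, group = grp)
  res_id <- adjust_and_rescore(lexpr, nz$expr, nz$batch, td$graph, td$mapping,
                               adjuster = "identity")
  expect_equal(res_id$adjusted, res_id$noisy)
  res_or <- adjust_and_rescore(lexpr, nz$expr, nz$batch, td$graph, td$mapping,
                               adjuster = oracle_adjuster(lexpr))
  expect_equal(res_or$adjusted, res_or$original)
  # roster-changing adjusters violate the contract
  bad <- function(expr, batch, group = NULL) expr[, -1]
  expect_error(adjust_and_rescore(lexpr, nz$expr, nz$batch, td$graph,
                                  td$mapping, adjuster = bad),
               "contract")
})
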