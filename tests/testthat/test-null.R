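# Expression ranking, matched sampling, empirical p-values, BH adjustment,
# and the per-stratum permutation null.

test_that("genes are ranked by descending mean with id tie-break", {
  m <- fixture_matrix(c(10, 10,
                        5, 5,
                        1, 1), c("g1", "g2", "g3"), c("t1", "t2"))
  expect_equal(expression_ranks(m)$gene, c("g1", "g2", "g3"))

  tie <- fixture_matrix(c(5, 5,
                          5, 5,
                          1, 1), c("gB", "gA", "gC"), c("t1", "t2"))
  rk <- expression_ranks(tie)
  expect_equal(rk$gene[rk$rank == 1], "gA")
  expect_equal(rk$gene[rk$rank == 2], "gB")

  # 6-gene fixture against a hand sort
  set.seed(3)
  m6 <- matrix(runif(18, 0, 10), nrow = 6,
               dimnames = list(paste0("g", 1:6), paste0("t", 1:3)))
  rk6 <- expression_ranks(m6)
  expect_equal(rk6$gene, names(sort(rowMeans(m6), decreasing = TRUE)))
  expect_equal(rk6$rank, 1:6)
})

test_that("matched sampling honours the rank window and distinctness", {
  grouped <- random_stratum(30, 5, seed = 9)
  ranks <- expression_ranks(grouped[["FC.1"]])
  deg <- ranks$gene[15]
  set.seed(1)
  for (i in 1:50) {
    g <- sample_matched_set(ranks, deg, window = 5)
    expect_true(abs(ranks$rank[ranks$gene == g] - 15) <= 5)
  }

  deg3 <- ranks$gene[c(5, 15, 25)]
  set.seed(2)
  picks <- sample_matched_set(ranks, deg3, window = 5)
  expect_equal(length(unique(picks)), 3L)
  expect_false(any(picks %in% deg3))
})

test_that("with an unbounded window the draw is uniform over eligible genes", {
  grouped <- random_stratum(30, 5, seed = 10)
  ranks <- expression_ranks(grouped[["FC.1"]])
  deg <- ranks$gene[1]
  eligible <- setdiff(ranks$gene, deg)
  set.seed(4)
  draws <- vapply(1:10000, function(i) sample_matched_set(ranks, deg, window = 50),
                  character(1))
  counts <- table(factor(draws, levels = eligible))
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("empirical p-values follow the add-one estimator", {
  expect_equal(empirical_p(10, rep(0, 9)), 1 / 10)
  expect_equal(empirical_p(0, c(0, 1, 2)), 1.0)
  expect_equal(empirical_p(5, c(3, 5, 7)), 0.75)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.001, 1.0)), c(0.002, 1.0))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(5)
  for (i in 1:20) {
    p <- pmax(runif(sample(2:30, 1)), 1e-8)
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("the stratum null is reproducible and internally consistent", {
  cfg <- simulation_config(
    n_genes = 80, n_deg = 15,
    strata_counts = tibble::tibble(region = c("FC", "SC"), stage = c(1, 2),
                                   n = c(10, 12))
  )
  sim <- simulate_grouped_expression(cfg, seed = 31)
  a <- connectedness_null(sim$grouped, sim$truth$deg_genes, B = 200, seed = 7)
  b <- connectedness_null(sim$grouped, sim$truth$deg_genes, B = 200, seed = 7)
  expect_identical(a$nulls, b$nulls)
  expect_identical(a$summary, b$summary)

  # p recomputes from the stored null vector; length equals B
  for (key in names(a$nulls)) {
    expect_equal(length(a$nulls[[key]]), 200L)
    row <- a$summary[a$summary$stratum == key, ]
    expect_equal(row$p, empirical_p(row$observed, a$nulls[[key]]))
  }

  sig <- significance_test(sim$grouped, sim$truth$deg_genes, B = 200, seed = 7)
  expect_true(all(sig$summary$q >= sig$summary$p))
  none <- significance_test(sim$grouped, sim$truth$deg_genes, B = 200,
                            seed = 7, alpha = 0)
  expect_equal(sum(none$summary$significant), 0L)
})

test_that("a module planted in one stratum is flagged there and only there", {
  genes <- sprintf("G%04d", 1:12)
  cfg <- simulation_config(
    n_genes = 100, n_deg = 12,
    strata_counts = tibble::tibble(region = c("FC", "FC"), stage = c(1, 3),
                                   n = c(12, 12)),
    planted_modules = list(list(genes = genes, strata = "FC.1",
                                loading = 0.5,
                                noise_sd = module_noise_for_r(0.95, 0.5))),
    seed = 17
  )
  sim <- simulate_grouped_expression(cfg)
  res <- significance_test(sim$grouped, sim$truth$deg_genes, B = 300, seed = 19)
  expect_true(res$summary$significant[res$summary$stratum == "FC.1"])
  expect_false(res$summary$significant[res$summary$stratum == "FC.3"])
})
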