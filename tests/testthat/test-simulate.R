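# Synthetic-data generator: stratum layout, planted structure, dosage study,
# interaction track, and reproducibility.

test_that("canonical stratum layout gives 16 groups totalling 398 specimens", {
  counts <- brainspan_strata_counts()
  expect_equal(nrow(counts), 16L)
  expect_equal(sum(counts$n), 398L)

  sim <- simulate_grouped_expression(simulation_config(n_genes = 50, n_deg = 10,
                                                       seed = 3))
  layout <- tidy(sim$grouped)
  expect_equal(nrow(layout), 16L)
  expect_equal(sum(layout$n_samples), 398L)
  expect_equal(layout$n_samples[layout$stratum == "FC.1"], 18L)
  expect_equal(layout$n_samples[layout$stratum == "TP.1"], 10L)
})

test_that("a noiseless common-factor module is perfectly correlated in its stratum", {
  genes <- sprintf("G%04d", 1:10)
  cfg <- simulation_config(
    n_genes = 20, n_deg = 10,
    strata_counts = tibble::tibble(region = "FC", stage = 1, n = 10),
    planted_modules = list(list(genes = genes, strata = "FC.1",
                                loading = 1, noise_sd = 0)),
    seed = 5
  )
  sim <- simulate_grouped_expression(cfg)
  cors <- pairwise_correlations(sim$grouped[["FC.1"]], genes)
  offdiag <- abs(cors[upper.tri(cors)])
  expect_equal(length(offdiag), 45L)
  expect_true(all(offdiag > 1 - 1e-9))
})

test_that("structureless data produce no more co-expression than the null tail", {
  # Oracle (brute-force Monte-Carlo, frozen): for two independent log-normal
  # genes with log-sd 0.5 at n = 20 tissues, P(|r| >= 0.9) was estimated as
  # 1.9e-6 from 2e7 simulated pairs, i.e. an expected 0.038 passing pairs
  # among choose(200, 2) = 19900.
  expected_pairs <- 1.9e-6 * choose(200, 2)
  cfg0 <- simulation_config(
    n_genes = 200, n_deg = 20,
    strata_counts = tibble::tibble(region = "FC", stage = 1, n = 20)
  )
  counts <- vapply(1:100, function(s) {
    sim <- simulate_grouped_expression(cfg0, seed = 1000 + s)
    cors <- pairwise_correlations(sim$grouped[["FC.1"]])
    sum(abs(cors[upper.tri(cors)]) >= 0.9, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(counts), 2 * expected_pairs)
})

test_that("query genes and rank-matched genes have indistinguishable expression", {
  cfg <- simulation_config(
    n_genes = 500, n_deg = 100,
    strata_counts = tibble::tibble(region = "FC", stage = 1, n = 20)
  )
  ks_p <- vapply(1:50, function(s) {
    sim <- simulate_grouped_expression(cfg, seed = 2000 + s)
    mat <- sim$grouped[["FC.1"]]
    ranks <- expression_ranks(mat)
    # clustered query ranks occasionally widen the window; expected here
    matched <- suppressWarnings(sample_matched_set(ranks, sim$truth$deg_genes,
                                                   window = 5))
    mu <- rowMeans(mat)
    suppressWarnings(stats::ks.test(mu[sim$truth$deg_genes], mu[matched]))$p.value
  }, numeric(1))
  expect_gt(median(ks_p), 0.01)
})

test_that("within-module correlation rises with the loading/noise ratio", {
  genes <- sprintf("G%04d", 1:10)
  mean_abs_r <- vapply(c(0.5, 1, 3), function(ratio) {
    cfg <- simulation_config(
      n_genes = 30, n_deg = 10,
      strata_counts = tibble::tibble(region = "SC", stage = 2, n = 30),
      planted_modules = list(list(genes = genes, strata = "SC.2",
                                  loading = 0.5, noise_sd = 0.5 / ratio)),
      seed = 11
    )
    sim <- simulate_grouped_expression(cfg)
    cors <- pairwise_correlations(sim$grouped[["SC.2"]], genes)
    mean(abs(cors[upper.tri(cors)]))
  }, numeric(1))
  expect_true(all(diff(mean_abs_r) > 0))
})

test_that("strata with fewer than 3 specimens are rejected", {
  cfg <- simulation_config(strata_counts = tibble::tibble(region = "FC",
                                                          stage = 1, n = 2))
  expect_error(simulate_grouped_expression(cfg), "3 specimens")
})

test_that("deletion study lays out the expected chromosome partition", {
  study <- simulate_deg_study(simulation_config(seed = 4))
  ann <- study$annotation
  iv <- simulation_config()$deletion_interval
  inside <- ann$start < iv$end & ann$end > iv$start
  expect_equal(sum(inside), 47L)
  expect_equal(sum(!inside), 311L)
  # non-overlapping coordinates, 0-based half-open
  by_pos <- ann[order(ann$start), ]
  expect_true(all(by_pos$start < by_pos$end))
  expect_true(all(diff(by_pos$start) >= 0))
  expect_true(all(utils::head(by_pos$end, -1) <= utils::tail(by_pos$start, -1)))
  expect_equal(length(study$truth$flanking_genes), 6L)
})

test_that("deletion effect is recovered in the mean and vanishes at zero", {
  lfc_means <- vapply(1:100, function(s) {
    study <- simulate_deg_study(simulation_config(seed = 100 + s))
    mean(study$deg_table$log2fc[study$deg_table$gene_id %in%
                                  study$truth$deletion_genes])
  }, numeric(1))
  expect_lt(abs(mean(lfc_means) - (-1)), 0.02)

  null_study <- simulate_deg_study(simulation_config(deletion_log2fc = 0,
                                                     seed = 9))
  del <- null_study$deg_table$gene_id %in% null_study$truth$deletion_genes
  expect_lt(abs(mean(null_study$deg_table$log2fc[del])), 0.05)
})

test_that("interaction track plants exactly one super-threshold region", {
  track <- simulate_interaction_track(region_value = 0.5, seed = 2)
  regions <- find_interacting_regions(track, 0.4)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$end - regions$start, 3e6)  # 3 bins of 1 Mb

  boundary <- simulate_interaction_track(region_value = 0.4, seed = 2)
  expect_equal(nrow(find_interacting_regions(boundary, 0.4)), 0L)
})

test_that("a fixed seed reproduces the compendium bit for bit", {
  cfg <- simulation_config(n_genes = 40, n_deg = 10,
                           strata_counts = tibble::tibble(region = "TP",
                                                          stage = 4, n = 5),
                           seed = 21)
  a <- simulate_grouped_expression(cfg)
  b <- simulate_grouped_expression(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$meta, b$meta)
})
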