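# Dosage and positional statistics: contingency counts, chi-squared tests,
# interaction-region calling and the deletion dosage profile.

test_that("region counts partition a toy annotated chromosome correctly", {
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    chrom = "chr22",
    start = c(100, 200, 300, 1000, 2000, 3000),
    end = c(150, 250, 350, 1050, 2050, 3050),
    strand = "+"
  )
  deg <- tibble::tibble(
    gene_id = ann$gene_id, chrom = ann$chrom, start = ann$start, end = ann$end,
    log2fc = c(-1, -1, 0.2, 0.1, -2, 0.3),
    p = c(0.001, 0.2, 0.01, 0.5, 0.04, 0.9)
  )
  iv <- list(chrom = "chr22", start = 0, end = 500)
  tab <- region_counts(deg, ann, iv, rule = list(metric = "p", alpha = 0.05))
  # inside: g1 (sig), g2 (not), g3 (sig); outside: g5 (sig), g4/g6 (not)
  expect_equal(unname(unclass(tab)), matrix(c(2L, 1L, 1L, 2L), 2, byrow = TRUE))
  # conservation: cells sum to the chromosome universe
  expect_equal(sum(tab), 6L)

  no_overlap <- region_counts(deg, ann, list(chrom = "chr22",
                                             start = 5000, end = 6000))
  expect_equal(unname(unclass(no_overlap)[1L, ]), c(0L, 0L))
  expect_error(region_counts(deg, ann, list(chrom = "chrX", start = 0, end = 1)),
               "empty universe")
})

test_that("chi-squared on 2x2 tables matches hand computation and conventions", {
  flat <- chi2_2x2(contingency_2x2(5, 5, 5, 5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # textbook Pearson statistic without continuity correction
  tab <- contingency_2x2(10, 10, 10, 30)
  obs <- matrix(c(10, 10, 10, 30), 2, byrow = TRUE)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  hand <- sum((obs - expected)^2 / expected)
  got <- chi2_2x2(tab, continuity = FALSE)
  expect_equal(got$statistic, hand, tolerance = 1e-12)
  expect_equal(got$p_value, stats::pchisq(hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # correction only shrinks the statistic; transpose invariance
  expect_lte(chi2_2x2(tab, continuity = TRUE)$statistic, got$statistic)
  expect_equal(chi2_2x2(t(unclass(tab)))$statistic, chi2_2x2(tab)$statistic)

  expect_error(chi2_2x2(contingency_2x2(0, 0, 5, 5)), "exact test")
})

test_that("interacting regions are maximal strict-threshold runs", {
  flat_track <- tibble::tibble(chrom = "chr6", start = (0:9) * 1e6,
                               end = (1:10) * 1e6, correlation = 0.1)
  expect_equal(nrow(find_interacting_regions(flat_track)), 0L)

  track <- flat_track
  track$correlation[4:6] <- 0.5
  hits <- find_interacting_regions(track)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3e6)
  expect_equal(hits$end, 6e6)
  expect_equal(hits$n_bins, 3L)

  boundary <- flat_track
  boundary$correlation[5] <- 0.4
  expect_equal(nrow(find_interacting_regions(boundary)), 0L)  # strict >
})

test_that("DEG enrichment is detected in a dense region and calibrated otherwise", {
  iv <- list(start = 39e6, end = 43e6)
  region <- tibble::tibble(chrom = "chr6", start = iv$start, end = iv$end)

  p_enriched <- vapply(1:50, function(s) {
    pos <- simulate_positional_degs(interval = iv, p_sig_inside = 0.5,
                                    p_sig_outside = 0.1, seed = 300 + s)
    interaction_enrichment(pos$deg_table, pos$annotation, region)$p_value
  }, numeric(1))
  expect_lt(median(p_enriched), 0.05)

  hit_uniform <- vapply(1:50, function(s) {
    pos <- simulate_positional_degs(interval = iv, p_sig_inside = 0.1,
                                    p_sig_outside = 0.1, seed = 600 + s)
    interaction_enrichment(pos$deg_table, pos$annotation, region)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(hit_uniform), 0.1)

  empty <- tibble::tibble(chrom = "chr6", start = 168e6, end = 169.9e6)
  pos <- simulate_positional_degs(interval = iv, seed = 1)
  pos$annotation <- pos$annotation[pos$annotation$start < 160e6, ]
  pos$deg_table <- pos$deg_table[pos$deg_table$start < 160e6, ]
  expect_warning(out <- interaction_enrichment(pos$deg_table, pos$annotation,
                                               empty), "no annotated genes")
  expect_equal(nrow(out), 0L)
})

test_that("dosage profile recovers planted fold changes exactly and invariantly", {
  genes <- paste0("g", 1:5)
  ctrl <- matrix(rep(c(2, 4, 6, 8, 10), 3), nrow = 5,
                 dimnames = list(genes, paste0("c", 1:3)))
  # identical conditions -> all zero
  prof0 <- deletion_dosage_profile(ctrl, ctrl, genes[1:3], genes[4:5])
  expect_true(all(prof0$log2fc == 0))

  # exact halving without noise -> exactly -1
  case <- ctrl * 0.5
  colnames(case) <- paste0("k", 1:3)
  prof <- deletion_dosage_profile(case, ctrl, genes[1:3], genes[4:5])
  expect_equal(prof$log2fc[prof$group == "interval"], rep(-1, 3))

  # scaling every sample by a constant leaves log2FC unchanged
  prof_scaled <- deletion_dosage_profile(case * 7, ctrl * 7, genes[1:3], genes[4:5])
  expect_equal(prof_scaled$log2fc, prof$log2fc, tolerance = 1e-12)

  # absent gene is skipped with a warning
  expect_warning(
    part <- deletion_dosage_profile(case, ctrl, c(genes[1:3], "missing")),
    "missing"
  )
  expect_equal(nrow(part), 3L)

  expect_error(deletion_dosage_profile(case[, 1, drop = FALSE], ctrl, genes),
               ">= 2 samples")
})
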