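# Connectivity ranking, top-fraction selection, cross-stratum rank
# correlations, and expansion to background genes.

# helper: a coexpression_network from a hand-set correlation matrix
net_from_cors <- function(cors, tau = 0.9, stratum = NULL) {
  build_network(cors, tau = tau, stratum = stratum)
}

hand_cors <- function(pairs, genes) {
  m <- diag(length(genes))
  dimnames(m) <- list(genes, genes)
  for (p in pairs) m[p[1], p[2]] <- m[p[2], p[1]] <- 1
  m
}

test_that("stage totals sum the per-region degrees", {
  genes <- c("g1", "g2", "g3", "g4")
  # g1's degree by region: 2, 0, 1, 3
  nets <- list(
    net_from_cors(hand_cors(list(c("g1", "g2"), c("g1", "g3")), genes)),
    net_from_cors(hand_cors(list(c("g2", "g3")), genes)),
    net_from_cors(hand_cors(list(c("g1", "g4")), genes)),
    net_from_cors(hand_cors(list(c("g1", "g2"), c("g1", "g3"), c("g1", "g4")), genes))
  )
  total <- rank_by_connectivity(nets, scope = "stage_total")
  expect_equal(total$connections[total$gene == "g1"], 6L)
  per_region <- vapply(nets, function(nw) nw$degree[["g1"]], integer(1))
  expect_equal(sum(per_region), 6L)
})

test_that("tied connection counts rank by gene id", {
  genes <- c("gB", "gA", "gC")
  nets <- net_from_cors(hand_cors(list(c("gB", "gA")), genes))
  rk <- rank_by_connectivity(nets)
  expect_equal(rk$gene[1:2], c("gA", "gB"))  # both degree 1, id order
})

test_that("ranking equals a brute-force sort of recomputed degrees", {
  grouped <- random_stratum(5, 8, seed = 12)
  m <- grouped[["FC.1"]]
  net <- build_network(pairwise_correlations(m), 0.5)
  rk <- rank_by_connectivity(net)
  oracle <- brute_network(m, rownames(m), 0.5)
  ord <- order(-oracle$degree, names(oracle$degree))
  expect_equal(rk$gene, names(oracle$degree)[ord])
  expect_equal(rk$connections, unname(oracle$degree[ord]))
})

test_that("top-fraction selection takes floor(fraction * n) from the top", {
  ranking <- tibble::tibble(gene = sprintf("g%03d", 1:736),
                            connections = 736:1, rank = 1:736)
  expect_equal(length(top_fraction(ranking, 0.1)), 73L)
  small <- ranking[1:10, ]
  expect_equal(top_fraction(small, 0.1), "g001")
  expect_equal(length(top_fraction(small, 1.0)), 10L)
  expect_equal(top_fraction(small[0, ], 0.5), character())
})

test_that("rank correlations behave at the extremes and match the oracle", {
  r1 <- tibble::tibble(gene = paste0("g", 1:6), connections = c(10, 8, 6, 4, 2, 1))
  r2 <- r1  # identical ranking
  r3 <- tibble::tibble(gene = paste0("g", 1:6), connections = c(1, 2, 4, 6, 8, 10))
  m <- rank_correlation_matrix(list(a = r1, b = r2, c = r3))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["a", "b"], 1.0)
  expect_equal(m["a", "c"], -1.0)
  expect_equal(m, t(m))

  # two-strata fixture vs brute Spearman on the degree vectors
  set.seed(14)
  d1 <- sample(0:20, 6); d2 <- sample(0:20, 6)
  ra <- tibble::tibble(gene = paste0("g", 1:6), connections = d1)
  rb <- tibble::tibble(gene = paste0("g", 1:6), connections = d2)
  m2 <- rank_correlation_matrix(list(x = ra, y = rb))
  expect_equal(m2["x", "y"], brute_spearman(d1, d2), tolerance = 1e-10)

  # relabeling strata permutes the matrix consistently
  m3 <- rank_correlation_matrix(list(y = rb, x = ra))
  expect_equal(m3["x", "y"], m2["x", "y"])

  disjoint <- tibble::tibble(gene = paste0("h", 1:6), connections = d2)
  expect_error(rank_correlation_matrix(list(ra, disjoint)), "fewer than 2 genes")
})

test_that("expansion ranks background genes by connections to the top set", {
  # one stratum where the top query genes and some background genes share a
  # common factor; a lone planted background gene is the strongest connector
  set.seed(15)
  n_t <- 20
  f <- rnorm(n_t)
  deg_genes <- paste0("D", 1:5)
  bg_in <- "B001"  # planted inside the module
  bg_out <- paste0("B", sprintf("%03d", 2:40))
  rows <- rbind(
    t(sapply(seq_along(deg_genes), function(i) exp(0.5 * f + rnorm(n_t, 0, 0.1)))),
    exp(0.5 * f + rnorm(n_t, 0, 0.05)),
    matrix(exp(rnorm(39 * n_t, 0, 0.5)), nrow = 39)
  )
  dimnames(rows) <- list(c(deg_genes, bg_in, bg_out), paste0("t", 1:n_t))
  grouped <- make_grouped(list(FC.1 = rows))

  res <- expand_to_nondeg(grouped, deg_genes, tau = 0.9, n_select = 3)
  expect_equal(res$ranking$gene[1L], bg_in)
  expect_true(all(res$selected %in% res$ranking$gene[res$ranking$connections > 0]))
  expect_equal(sort(res$combined), sort(union(res$selected, deg_genes)))

  # nothing crosses the threshold -> empty selection
  res_hi <- expand_to_nondeg(grouped, deg_genes, tau = 0.99999, n_select = 3)
  expect_equal(length(res_hi$selected), 0L)
  expect_equal(sort(res_hi$combined), sort(deg_genes))
})
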