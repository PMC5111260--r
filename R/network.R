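# Correlation-threshold co-expression networks within one stratum.

#' Pairwise Pearson correlations among a gene set
#'
#' Correlations are computed across the tissues of one stratum, on the
#' expression scale given (optionally log2(x + 1)).  Pairs involving a
#' zero-variance gene are undefined and returned as `NA`.
#'
#' @param matrix Gene-by-sample matrix for one stratum.
#' @param genes Genes to correlate (default: all rows).
#' @param transform `"identity"` (raw values) or `"log2"` for log2(x + 1).
#' @return Symmetric correlation matrix with `NA` diagonal-off entries for
#'   undefined pairs and `NA` on the diagonal of zero-variance genes.
#' @export
pairwise_correlations <- function(matrix, genes = rownames(matrix),
                                  transform = c("identity", "log2")) {
  check_expression_matrix(matrix)
  transform <- match.arg(transform)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) {
    stop(sprintf("gene(s) absent from matrix: %s",
                 paste(head(missing, 3L), collapse = ", ")), call. = FALSE)
  }
  if (ncol(matrix) < 3L) {
    stop("need >= 3 tissues in a stratum to compute correlations", call. = FALSE)
  }
  x <- t(matrix[genes, , drop = FALSE])
  if (transform == "log2") x <- log2(x + 1)
  suppressWarnings(cor(x))  # zero-variance columns yield NA, by design
}

#' Build a co-expression network by thresholding correlations
#'
#' Gene pairs with `|R| >= tau` (both signs) become edges; undefined pairs
#' (zero-variance genes) contribute none.  Connectedness is the edge count.
#'
#' @param correlations Symmetric correlation matrix from
#'   [pairwise_correlations()].
#' @param tau Absolute-correlation threshold in (0, 1]; default 0.9.
#' @param stratum Optional stratum key recorded on the result.
#' @return A `coexpression_network` object with fields `nodes`, `edges`
#'   (tibble `gene_a`, `gene_b`, `r`), `connectedness` and `degree`.
#' @export
build_network <- function(correlations, tau = 0.9, stratum = NULL) {
  check_scalar_in(tau, "tau", 0, 1, lo_open = TRUE)
  stopifnot(is.matrix(correlations), nrow(correlations) == ncol(correlations))
  nodes <- rownames(correlations) %||% paste0("V", seq_len(nrow(correlations)))
  hit <- which(abs(correlations) >= tau & upper.tri(correlations), arr.ind = TRUE)
  edges <- tibble::tibble(
    gene_a = nodes[hit[, 1L]],
    gene_b = nodes[hit[, 2L]],
    r = correlations[hit]
  )
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  degree <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(c(edges$gene_a, edges$gene_b))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(
    list(stratum = stratum, tau = tau, nodes = nodes, edges = edges,
         connectedness = nrow(edges), degree = degree),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network%s> %d nodes, %d edges (|R| >= %s)\n",
              if (is.null(x$stratum)) "" else paste0(" ", x$stratum),
              length(x$nodes), x$connectedness, format(x$tau)))
  invisible(x)
}

#' @export
tidy.coexpression_network <- function(x, ...) {
  out <- x$edges
  out$stratum <- x$stratum %||% NA_character_
  out
}

#' @export
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum %||% NA_character_,
    n_nodes = length(x$nodes),
    connectedness = x$connectedness,
    max_degree = if (length(x$degree)) max(x$degree) else 0L,
    density = if (length(x$nodes) > 1L) {
      x$connectedness / choose(length(x$nodes), 2)
    } else 0
  )
}

#' Sweep the correlation threshold
#'
#' For each threshold in `tau_grid`, builds the network and summarises the
#' degree distribution with the R-squared of a least-squares line on
#' log(degree) versus log(frequency) over nonzero degrees — the usual quick
#' check that a threshold produces power-law-like connectivity.
#'
#' @param matrix Stratum matrix.
#' @param genes Gene set.
#' @param tau_grid Thresholds in (0, 1].
#' @param transform Expression transform, as in [pairwise_correlations()].
#' @return Tibble with `tau`, `connectedness`, `powerlaw_r2` (`NA` when fewer
#'   than 3 distinct nonzero degrees).
#' @export
threshold_sweep <- function(matrix, genes = rownames(matrix),
                            tau_grid = seq(0.5, 0.95, by = 0.05),
                            transform = c("identity", "log2")) {
  lapply(tau_grid, function(tau) check_scalar_in(tau, "tau_grid", 0, 1, lo_open = TRUE))
  cors <- pairwise_correlations(matrix, genes, transform = transform)
  purrr::map_dfr(tau_grid, function(tau) {
    net <- build_network(cors, tau = tau)
    tibble::tibble(tau = tau,
                   connectedness = net$connectedness,
                   powerlaw_r2 = degree_loglog_r2(net$degree))
  })
}

# R^2 of log-frequency vs log-degree over nonzero degrees
degree_loglog_r2 <- function(degree) {
  d <- degree[degree > 0]
  if (!length(d)) return(NA_real_)
  tab <- table(d)
  if (length(tab) < 3L) return(NA_real_)
  x <- log(as.numeric(names(tab)))
  y <- log(as.numeric(tab))
  summary(stats::lm(y ~ x))$r.squared
}

#' Write a network edge list as TSV
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(tidy(network), path)
  invisible(path)
}
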