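# Connectivity ranking, cross-stratum rank correlation, and network
# expansion to top-connected background genes.

#' Rank genes by number of network connections
#'
#' Given one network (per-stratum scope) or several networks over a shared
#' node universe (e.g. the four regions of one stage, giving a stage-total
#' scope), sums each gene's degree across the networks and ranks descending;
#' ties are broken by lexicographic gene id so the order is deterministic.
#'
#' @param networks A `coexpression_network` or a list of them.
#' @param scope Label recorded on the result (`"stratum"` or `"stage_total"`;
#'   purely descriptive).
#' @return A `connectivity_ranking` tibble: `gene`, `connections`, `rank`.
#' @export
rank_by_connectivity <- function(networks, scope = NULL) {
  if (inherits(networks, "coexpression_network")) networks <- list(networks)
  stopifnot(length(networks) >= 1L,
            all(vapply(networks, inherits, logical(1), "coexpression_network")))
  nodes <- networks[[1L]]$nodes
  for (nw in networks[-1L]) {
    if (!setequal(nw$nodes, nodes)) {
      stop("networks must share a node universe", call. = FALSE)
    }
  }
  total <- Reduce(`+`, lapply(networks, function(nw) nw$degree[nodes]))
  ord <- order(-total, nodes)
  out <- tibble::tibble(
    gene = nodes[ord],
    connections = as.integer(unname(total[ord])),
    rank = seq_along(ord)
  )
  attr(out, "scope") <- scope %||% if (length(networks) > 1L) "stage_total" else "stratum"
  class(out) <- c("connectivity_ranking", class(out))
  out
}

#' Select the top fraction of a connectivity ranking
#'
#' Takes `floor(fraction * n)` genes from the top of the ranking (strict
#' count; rank order breaks ties).
#'
#' @param ranking A `connectivity_ranking` (or any tibble with `gene`, `rank`).
#' @param fraction Fraction in (0, 1]; default 0.1.
#' @return Character vector of selected gene ids.
#' @export
top_fraction <- function(ranking, fraction = 0.1) {
  check_scalar_in(fraction, "fraction", 0, 1, lo_open = TRUE)
  n <- nrow(ranking)
  if (!n) return(character())
  k <- floor(fraction * n)
  head(ranking$gene, k)
}

#' Correlation of connectivity ranking orders across strata
#'
#' Computes Pearson correlation between the connectivity rank vectors of each
#' pair of strata over their common gene set (Spearman's rho in the absence of
#' ties; tied connection counts receive average ranks).
#'
#' @param rankings Named list of `connectivity_ranking` objects.
#' @return Symmetric correlation matrix with unit diagonal, dimnames from
#'   `names(rankings)`.
#' @export
rank_correlation_matrix <- function(rankings) {
  stopifnot(is.list(rankings), length(rankings) >= 2L)
  if (is.null(names(rankings))) names(rankings) <- paste0("S", seq_along(rankings))
  common <- Reduce(intersect, lapply(rankings, `[[`, "gene"))
  if (length(common) < 2L) {
    stop("rankings share fewer than 2 genes; cannot correlate ranking orders",
         call. = FALSE)
  }
  rk <- vapply(rankings, function(r) {
    conn <- r$connections[match(common, r$gene)]
    rank(-conn)  # 1 = most connected; ties get average ranks
  }, numeric(length(common)))
  # a stratum where every gene has the same connectivity (e.g. an empty
  # network) has no ranking order: its correlations are undefined (NA)
  m <- suppressWarnings(cor(rk))
  diag(m) <- 1
  dimnames(m) <- list(names(rankings), names(rankings))
  m
}

#' Expand a network to top-connected background genes
#'
#' For every background (non-query) gene, counts its `|R| >= tau` correlations
#' to the top query genes, summed over the requested strata, then selects the
#' most-connected background genes — either a fixed count (default 300) or a
#' fraction of the genes with at least one connection.
#'
#' @param grouped A `grouped_expression`.
#' @param top_deg Top query gene set.
#' @param nondeg_universe Background genes (must be disjoint from `top_deg`;
#'   default: all other genes in the matrix).
#' @param tau Correlation threshold (default 0.9).
#' @param strata Stratum keys to sum over (default all).
#' @param n_select Number of background genes to select (connectors only).
#' @param fraction If non-`NULL`, select `floor(fraction * n_connectors)`
#'   instead of `n_select`.
#' @param transform Expression transform, as in [pairwise_correlations()].
#' @return List with `ranking` (tibble `gene`, `connections`), `selected`
#'   (character), and `combined` (union of `selected` and `top_deg`).
#' @export
expand_to_nondeg <- function(grouped, top_deg, nondeg_universe = NULL,
                             tau = 0.9, strata = names(grouped),
                             n_select = 300L, fraction = NULL,
                             transform = c("identity", "log2")) {
  stopifnot(inherits(grouped, "grouped_expression"))
  check_scalar_in(tau, "tau", 0, 1, lo_open = TRUE)
  transform <- match.arg(transform)
  top_deg <- as.character(top_deg)
  all_genes <- rownames(grouped[[1L]])
  nondeg_universe <- nondeg_universe %||% setdiff(all_genes, top_deg)
  if (length(intersect(nondeg_universe, top_deg))) {
    stop("`nondeg_universe` and `top_deg` must be disjoint", call. = FALSE)
  }

  counts <- setNames(integer(length(nondeg_universe)), nondeg_universe)
  for (key in strata) {
    mat <- grouped[[key]]
    x <- t(mat[nondeg_universe, , drop = FALSE])
    y <- t(mat[top_deg, , drop = FALSE])
    if (transform == "log2") { x <- log2(x + 1); y <- log2(y + 1) }
    r <- suppressWarnings(cor(x, y))
    hit <- abs(r) >= tau
    hit[is.na(hit)] <- FALSE
    counts <- counts + rowSums(hit)
  }
  ord <- order(-counts, nondeg_universe)
  ranking <- tibble::tibble(
    gene = nondeg_universe[ord],
    connections = as.integer(unname(counts[ord]))
  )
  connectors <- ranking$gene[ranking$connections > 0L]
  k <- if (!is.null(fraction)) {
    check_scalar_in(fraction, "fraction", 0, 1, lo_open = TRUE)
    floor(fraction * length(connectors))
  } else {
    min(check_count(n_select, "n_select", min = 0L), length(connectors))
  }
  selected <- head(connectors, k)
  list(ranking = ranking,
       selected = selected,
       combined = union(selected, top_deg))
}
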