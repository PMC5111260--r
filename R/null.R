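# Expression-rank-matched permutation null for network connectedness.

#' Rank genes by mean expression within a stratum
#'
#' Rank 1 is the highest mean expression across the stratum's tissues; ties
#' are broken by lexicographic gene id so the ranking is stable.
#'
#' @param matrix Stratum gene-by-sample matrix.
#' @return Tibble with `gene`, `mean_expr`, `rank`, sorted by rank.
#' @export
expression_ranks <- function(matrix) {
  check_expression_matrix(matrix)
  mu <- rowMeans(matrix)
  ord <- order(-mu, rownames(matrix))
  tibble::tibble(
    gene = rownames(matrix)[ord],
    mean_expr = unname(mu[ord]),
    rank = seq_along(ord)
  )
}

#' Draw one expression-matched gene per query gene
#'
#' For each query (DEG) gene, samples uniformly one non-query gene whose
#' within-stratum expression rank is within `window` positions of the query
#' gene's rank.  Selected genes are mutually distinct (sampling without
#' replacement); a query gene whose window is exhausted is matched to the
#' nearest eligible gene, with a warning.
#'
#' @param ranks Tibble from [expression_ranks()].
#' @param deg_genes Query gene ids (must appear in `ranks`).
#' @param window Rank window half-width (default 5 positions).
#' @return Character vector of matched genes, one per query gene, in the order
#'   of `deg_genes`.
#' @export
sample_matched_set <- function(ranks, deg_genes, window = 5L) {
  window <- check_count(window, "window")
  deg_genes <- as.character(deg_genes)
  pos <- match(deg_genes, ranks$gene)
  if (anyNA(pos)) {
    stop(sprintf("query gene(s) absent from ranking: %s",
                 paste(head(deg_genes[is.na(pos)], 3L), collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(ranks)
  is_deg <- ranks$gene %in% deg_genes
  used <- logical(n)
  out <- character(length(pos))
  for (i in seq_along(pos)) {
    w <- window
    repeat {
      lo <- max(1L, pos[i] - w); hi <- min(n, pos[i] + w)
      cand <- which(!is_deg[lo:hi] & !used[lo:hi]) + lo - 1L
      if (length(cand)) break
      if (w >= n) stop("no eligible matched gene available", call. = FALSE)
      w <- w + 1L
    }
    if (w > window) {
      warning(sprintf("rank window widened to %d for query gene '%s'",
                      w, deg_genes[i]))
    }
    pick <- cand[sample.int(length(cand), 1L)]
    used[pick] <- TRUE
    out[i] <- ranks$gene[pick]
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a family of tests.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must all lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Permutation null for query-set connectedness, per stratum
#'
#' Within each stratum, builds the observed `tau`-network on the query genes,
#' then repeats the construction `B` times on random gene sets matched to the
#' query genes' expression ranks (window of `window` positions, recomputed per
#' stratum), yielding an empirical one-tailed (larger) p-value per stratum
#' with the add-one estimator `(1 + #\{null >= obs\}) / (B + 1)`.
#'
#' The random stream is forked per stratum from `seed` by a stable hash of the
#' stratum key, so results do not depend on stratum evaluation order.
#'
#' @param grouped A `grouped_expression`.
#' @param deg_genes Query gene set (screen all-zero genes first with
#'   [drop_zero_expression_genes()]).
#' @param tau Correlation threshold (default 0.9).
#' @param B Null iterations (default 10000).
#' @param window Rank-matching window (default 5).
#' @param seed Integer seed.
#' @param transform Expression transform, as in [pairwise_correlations()].
#' @return A `connectedness_null` object; `tidy()` gives the per-stratum
#'   summary, `x$nulls` the raw null vectors.
#' @export
connectedness_null <- function(grouped, deg_genes, tau = 0.9, B = 10000L,
                               window = 5L, seed = 1L,
                               transform = c("identity", "log2")) {
  stopifnot(inherits(grouped, "grouped_expression"))
  check_scalar_in(tau, "tau", 0, 1, lo_open = TRUE)
  B <- check_count(B, "B")
  window <- check_count(window, "window")
  transform <- match.arg(transform)
  deg_genes <- as.character(deg_genes)

  res <- lapply(names(grouped), function(key) {
    stratum_null(grouped[[key]], key, deg_genes, tau, B, window,
                 fork_seed(seed, key), transform)
  })
  summary <- dplyr::bind_rows(lapply(res, `[[`, "row"))
  nulls <- lapply(res, `[[`, "null")
  names(nulls) <- names(grouped)
  structure(
    list(summary = summary, nulls = nulls, tau = tau, B = B,
         window = window, seed = seed),
    class = "connectedness_null"
  )
}

stratum_null <- function(mat, key, deg_genes, tau, B, window, seed, transform) {
  present <- intersect(deg_genes, rownames(mat))
  if (length(present) < 2L) {
    stop(sprintf("stratum %s holds fewer than 2 query genes", key), call. = FALSE)
  }
  ranks <- expression_ranks(mat)
  n <- nrow(ranks)
  pos <- match(present, ranks$gene)           # 1-based rank positions
  is_deg <- ranks$gene %in% present

  # materialise correlations only for genes reachable by the matching windows
  # (window + one widening step per collision) plus the query genes
  reach <- window + length(present)
  needed <- logical(n)
  for (p in pos) {
    needed[max(1L, p - reach):min(n, p + reach)] <- TRUE
  }
  needed[pos] <- TRUE
  need_genes <- ranks$gene[needed]
  cors <- pairwise_correlations(mat, need_genes, transform = transform)
  adj <- abs(cors) >= tau
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE

  adj_row <- rep(-1L, n)
  adj_row[which(needed)] <- match(ranks$gene[needed], need_genes) - 1L

  obs_rows <- adj_row[pos] + 1L
  observed <- sum(adj[obs_rows, obs_rows, drop = FALSE]) / 2L

  set.seed(seed)
  null <- cpp_null_connectedness(adj, adj_row, pos - 1L, is_deg, window, B)

  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  list(
    row = tibble::tibble(
      stratum = key,
      region = parts[1L],
      stage = as.integer(parts[2L]),
      n_samples = ncol(mat),
      n_deg = length(present),
      observed = as.integer(observed),
      null_mean = mean(null),
      null_sd = sd(null),
      p = empirical_p(observed, null)
    ),
    null = null
  )
}

#' Flag strata whose query-set connectedness exceeds the matched null
#'
#' Runs [connectedness_null()], adjusts the per-stratum one-tailed p-values
#' across strata with Benjamini-Hochberg, and flags strata with `q < alpha`.
#'
#' @inheritParams connectedness_null
#' @param alpha FDR level (default 0.05).
#' @return A `connectedness_null` object whose summary carries `q` and
#'   `significant` columns.
#' @export
significance_test <- function(grouped, deg_genes, tau = 0.9, B = 10000L,
                              window = 5L, seed = 1L, alpha = 0.05,
                              transform = c("identity", "log2")) {
  check_scalar_in(alpha, "alpha", 0, 1)
  res <- connectedness_null(grouped, deg_genes, tau = tau, B = B,
                            window = window, seed = seed, transform = transform)
  res$summary$q <- bh_adjust(res$summary$p)
  res$summary$significant <- res$summary$q < alpha
  res$alpha <- alpha
  res
}

#' @export
print.connectedness_null <- function(x, ...) {
  cat(sprintf("<connectedness_null> %d strata, B = %d, |R| >= %s, window %d\n",
              nrow(x$summary), x$B, format(x$tau), x$window))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
tidy.connectedness_null <- function(x, ...) x$summary

#' @export
glance.connectedness_null <- function(x, ...) {
  tibble::tibble(
    n_strata = nrow(x$summary),
    B = x$B,
    tau = x$tau,
    window = x$window,
    min_p = min(x$summary$p),
    n_significant = if ("significant" %in% names(x$summary)) {
      sum(x$summary$significant)
    } else NA_integer_
  )
}

#' Write a connectedness-null summary as TSV
#' @param result A `connectedness_null`.
#' @param path Output path.
#' @export
write_null_summary <- function(result, path) {
  readr::write_tsv(result$summary, path)
  invisible(path)
}
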