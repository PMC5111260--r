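# Independent brute-force oracles, deliberately naive, used to cross-check
# the package implementations on small inputs.

# Pearson correlation from the raw sum formula
brute_cor <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# O(n^2) recount of edges and degrees straight from expression values
brute_network <- function(mat, genes, tau) {
  k <- length(genes)
  edges <- 0L
  degree <- setNames(integer(k), genes)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- brute_cor(mat[genes[i], ], mat[genes[j], ])
      if (!is.na(r) && abs(r) >= tau) {
        edges <- edges + 1L
        degree[i] <- degree[i] + 1L
        degree[j] <- degree[j] + 1L
      }
    }
  }
  list(connectedness = edges, degree = degree)
}

# hand ranks (1 = largest, ties averaged), then brute Pearson on the ranks
brute_spearman <- function(x, y) {
  rx <- rank(-x); ry <- rank(-y)
  brute_cor(rx, ry)
}

# Benjamini-Hochberg step-up, written from the definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1L):1L) if (m > 1L) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1L])
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# naive UPGMA agglomeration on a distance matrix; returns merge heights sorted
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}
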