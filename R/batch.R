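# Sample batching by UPGMA on correlation distance, plus a simple
# location/scale batch adjustment.

#' Cluster samples into batches by UPGMA on correlation distance
#'
#' Computes the distance `1 - Pearson R` between sample expression profiles,
#' agglomerates with average linkage (UPGMA), and cuts the tree into `k`
#' clusters.  Samples are processed in lexicographic id order so the result
#' does not depend on column order.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param k Number of batches (default 2).
#' @return A `batch_assignment`: list with `batches` (named integer vector)
#'   and `tree` (an `hclust`).
#' @export
upgma_batches <- function(matrix, k = 2L) {
  check_expression_matrix(matrix)
  k <- check_count(k, "k")
  if (ncol(matrix) < k) stop("fewer samples than requested batches", call. = FALSE)
  matrix <- matrix[, order(colnames(matrix)), drop = FALSE]
  sds <- apply(matrix, 2L, sd)
  if (any(sds == 0)) {
    stop(sprintf("constant expression vector for sample '%s': correlation undefined",
                 colnames(matrix)[sds == 0][1L]), call. = FALSE)
  }
  d <- as.dist(1 - cor(matrix))
  tree <- hclust(d, method = "average")
  batches <- cutree(tree, k = k)
  structure(list(batches = batches, tree = tree), class = "batch_assignment")
}

#' @export
print.batch_assignment <- function(x, ...) {
  cat(sprintf("<batch_assignment> %d samples in %d batch(es): %s\n",
              length(x$batches), length(unique(x$batches)),
              paste(table(x$batches), collapse = " + ")))
  invisible(x)
}

#' @export
tidy.batch_assignment <- function(x, ...) {
  tibble::tibble(sample_id = names(x$batches), batch = unname(x$batches))
}

#' Export a batch dendrogram in Newick format
#' @param assignment A `batch_assignment`.
#' @param path Output path.
#' @export
write_dendrogram <- function(assignment, path) {
  ape::write.tree(ape::as.phylo(assignment$tree), file = path)
  invisible(path)
}

#' Location/scale batch adjustment
#'
#' Per gene: standardize within each batch (subtract the batch mean, divide by
#' the batch standard deviation) and restore the pooled mean and standard
#' deviation, removing additive and multiplicative batch differences.  Genes
#' with zero variance within a batch are recentred to the pooled mean only.
#'
#' @param matrix Gene-by-sample matrix.
#' @param assignment A `batch_assignment` (or a named batch vector covering
#'   every sample); each batch needs >= 2 samples.
#' @return Adjusted matrix of the same dimensions.  Note that values may
#'   become negative: the adjustment lives on the measurement scale, not the
#'   non-negative FPKM scale.
#' @export
location_scale_adjust <- function(matrix, assignment) {
  check_expression_matrix(matrix)
  batches <- if (inherits(assignment, "batch_assignment")) {
    assignment$batches
  } else {
    assignment
  }
  if (!all(colnames(matrix) %in% names(batches))) {
    stop("every sample needs a batch label", call. = FALSE)
  }
  batches <- batches[colnames(matrix)]
  if (any(table(batches) < 2L)) {
    stop("each batch needs >= 2 samples", call. = FALSE)
  }
  pooled_mean <- rowMeans(matrix)
  pooled_sd <- apply(matrix, 1L, sd)
  out <- matrix
  for (b in unique(batches)) {
    cols <- which(batches == b)
    sub <- matrix[, cols, drop = FALSE]
    bm <- rowMeans(sub)
    bs <- apply(sub, 1L, sd)
    z <- (sub - bm) / ifelse(bs > 0, bs, 1)
    out[, cols] <- z * ifelse(bs > 0, pooled_sd, 1) + pooled_mean
  }
  out
}
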