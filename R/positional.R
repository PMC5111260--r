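# Positional / dosage statistics: interval-vs-rest contingency tests,
# interaction-track region calling, and deletion dosage profiles.

#' Build a 2x2 interval-membership by significance contingency table
#'
#' @param in_sig,in_not,out_sig,out_not Non-negative counts: genes inside the
#'   interval that are / are not significant, and likewise outside.
#' @return A `contingency_2x2` (2x2 integer matrix with informative dimnames).
#' @export
contingency_2x2 <- function(in_sig, in_not, out_sig, out_not) {
  counts <- c(in_sig, in_not, out_sig, out_not)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("contingency table is empty", call. = FALSE)
  m <- matrix(as.integer(counts), nrow = 2L, byrow = TRUE,
              dimnames = list(region = c("inside", "outside"),
                              status = c("significant", "not_significant")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

# default significance rule: nominal p < alpha; metric may be "p" or "q"
sig_rule <- function(metric = c("p", "q"), alpha = 0.05) {
  metric <- match.arg(metric)
  check_scalar_in(alpha, "alpha", 0, 1)
  function(deg_table) deg_table[[metric]] < alpha
}

#' Count genes by interval membership and significance
#'
#' Partitions the genes of the interval's chromosome by any-overlap membership
#' in the interval (0-based half-open) and by a pluggable significance rule,
#' producing the 2x2 table used for the dosage-region enrichment test.
#'
#' @param deg_table Per-gene differential-expression tibble (see
#'   [read_deg_table()]); genes of the chromosome absent from it count as not
#'   significant.
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`); its genes on the interval's chromosome form the universe.
#' @param interval `list(chrom, start, end)`.
#' @param rule Either a function `deg_table -> logical`, or a list
#'   `list(metric = "p"|"q", alpha = )`; default nominal `p < 0.05`.
#' @return A `contingency_2x2`.
#' @export
region_counts <- function(deg_table, annotation, interval,
                          rule = list(metric = "p", alpha = 0.05)) {
  deg_table <- validate_deg_table(deg_table)
  universe <- annotation[annotation$chrom == interval$chrom, ]
  if (!nrow(universe)) {
    stop(sprintf("no annotated genes on %s: empty universe", interval$chrom),
         call. = FALSE)
  }
  rule_fn <- if (is.function(rule)) rule else sig_rule(rule$metric, rule$alpha)
  sig_genes <- deg_table$gene_id[rule_fn(deg_table)]
  inside <- universe$start < interval$end & universe$end > interval$start
  sig <- universe$gene_id %in% sig_genes
  contingency_2x2(sum(inside & sig), sum(inside & !sig),
                  sum(!inside & sig), sum(!inside & !sig))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' One degree of freedom, with the Yates continuity correction on by default
#' (the convention of standard statistical environments for 2x2 tables).
#'
#' @param table A `contingency_2x2` (or any 2x2 matrix of counts).
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return Tibble with `statistic`, `df`, `p_value`, `continuity`.
#' @export
chi2_2x2 <- function(table, continuity = TRUE) {
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal in 2x2 table; use an exact test instead", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(m, correct = continuity))
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    continuity = continuity
  )
}

#' Find high-interaction regions in a binned correlation track
#'
#' Returns maximal runs of adjacent bins whose mean interaction correlation is
#' strictly greater than `cutoff`, merged into intervals.  Runs are broken
#' where consecutive passing bins are not contiguous in coordinates.
#'
#' @param track Tibble with `chrom`, `start`, `end`, `correlation` (sorted,
#'   non-overlapping bins).
#' @param cutoff Strict threshold (default 0.4).
#' @return Tibble of intervals: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_correlation`.
#' @export
find_interacting_regions <- function(track, cutoff = 0.4) {
  stopifnot(all(c("chrom", "start", "end", "correlation") %in% names(track)))
  check_scalar_in(cutoff, "cutoff", 0, 1)
  track <- dplyr::arrange(track, .data$chrom, .data$start)
  for (idx in split(seq_len(nrow(track)), track$chrom)) {
    s <- track$start[idx]; e <- track$end[idx]
    if (length(idx) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("track bins must be non-overlapping", call. = FALSE)
    }
  }
  pass <- track$correlation > cutoff
  if (!any(pass)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_bins = integer(),
                          mean_correlation = numeric()))
  }
  new_run <- pass & (!dplyr::lag(pass, default = FALSE) |
                       track$chrom != dplyr::lag(track$chrom, default = "") |
                       track$start != dplyr::lag(track$end, default = -1))
  run_id <- cumsum(new_run)
  run_id[!pass] <- NA_integer_
  hits <- track[pass, ]
  hits$run <- run_id[pass]
  dplyr::summarise(
    dplyr::group_by(hits, .data$run),
    chrom = .data$chrom[1L],
    start = min(.data$start),
    end = max(.data$end),
    n_bins = dplyr::n(),
    mean_correlation = mean(.data$correlation),
    .groups = "drop"
  )[, c("chrom", "start", "end", "n_bins", "mean_correlation")]
}

#' Test DEG enrichment inside high-interaction regions
#'
#' For each interval (as from [find_interacting_regions()]), builds the 2x2
#' membership-by-significance table against the rest of the interval's
#' chromosome and applies the chi-squared test.  Intervals containing no
#' annotated genes are skipped with a warning.
#'
#' @inheritParams region_counts
#' @param intervals Tibble of intervals (`chrom`, `start`, `end`).
#' @param continuity Yates correction flag, passed to [chi2_2x2()].
#' @return Tibble: one row per tested interval with counts, `statistic`,
#'   `p_value`.
#' @export
interaction_enrichment <- function(deg_table, annotation, intervals,
                                   rule = list(metric = "p", alpha = 0.05),
                                   continuity = TRUE) {
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- list(chrom = intervals$chrom[i], start = intervals$start[i],
               end = intervals$end[i])
    universe <- annotation[annotation$chrom == iv$chrom, ]
    n_inside <- sum(universe$start < iv$end & universe$end > iv$start)
    if (n_inside == 0L) {
      warning(sprintf("interval %s:%s-%s contains no annotated genes; skipped",
                      iv$chrom, format(iv$start, scientific = FALSE),
                      format(iv$end, scientific = FALSE)))
      return(NULL)
    }
    tab <- region_counts(deg_table, annotation, iv, rule)
    ht <- chi2_2x2(tab, continuity = continuity)
    tibble::tibble(
      chrom = iv$chrom, start = iv$start, end = iv$end,
      in_sig = tab[1L, 1L], in_not = tab[1L, 2L],
      out_sig = tab[2L, 1L], out_not = tab[2L, 2L],
      statistic = ht$statistic, p_value = ht$p_value
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-gene dosage profile across a deletion interval
#'
#' Computes each gene's case/control mean-expression ratio and log2 fold
#' change, for genes inside the deletion interval and for flanking genes, and
#' summarises each group by its median log2 fold change.  A hemizygous
#' deletion is expected near log2FC = -1 inside the interval and near 0 in the
#' flanks.
#'
#' @param case,control Gene-by-sample matrices for the two conditions (>= 2
#'   samples each).
#' @param interval_genes,flanking_genes Gene id vectors; genes absent from
#'   either matrix are skipped with a warning.
#' @return A `dosage_profile` tibble (`gene`, `group`, `mean_case`,
#'   `mean_control`, `ratio`, `log2fc`); `glance()` returns the group medians.
#' @export
deletion_dosage_profile <- function(case, control, interval_genes,
                                    flanking_genes = character()) {
  check_expression_matrix(case, "case")
  check_expression_matrix(control, "control")
  if (ncol(case) < 2L || ncol(control) < 2L) {
    stop("both conditions need >= 2 samples", call. = FALSE)
  }
  genes <- c(interval_genes, flanking_genes)
  group <- rep(c("interval", "flanking"),
               c(length(interval_genes), length(flanking_genes)))
  present <- genes %in% rownames(case) & genes %in% rownames(control)
  if (any(!present)) {
    warning(sprintf("gene(s) absent from expression matrices, skipped: %s",
                    paste(head(genes[!present], 3L), collapse = ", ")))
  }
  genes <- genes[present]; group <- group[present]
  mean_case <- rowMeans(case[genes, , drop = FALSE])
  mean_control <- rowMeans(control[genes, , drop = FALSE])
  out <- tibble::tibble(
    gene = genes,
    group = group,
    mean_case = unname(mean_case),
    mean_control = unname(mean_control),
    ratio = unname(mean_case / mean_control),
    log2fc = log2(unname(mean_case / mean_control))
  )
  class(out) <- c("dosage_profile", class(out))
  out
}

#' @export
glance.dosage_profile <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$group),
                   n_genes = dplyr::n(),
                   median_log2fc = median(.data$log2fc),
                   .groups = "drop")
}
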