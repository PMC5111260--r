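# Synthetic-data generator: a region-by-stage expression compendium with
# planted co-expression modules, a hemizygous-deletion case/control study,
# and a binned interaction-correlation track, each with ground-truth labels.

#' Specimen counts of the developmental brain compendium
#'
#' The canonical 16-stratum layout: four super-regions by four developmental
#' stages, 398 specimens in total.
#'
#' @return Tibble with columns `region`, `stage`, `n`.
#' @export
brainspan_strata_counts <- function() {
  tibble::tibble(
    region = rep(c("FC", "SC", "SM", "TP"), each = 4L),
    stage = rep(1:4, times = 4L),
    n = c(18L, 38L, 37L, 19L,
          13L, 34L, 32L, 18L,
          14L, 36L, 32L, 19L,
          10L, 28L, 32L, 18L)
  )
}

#' Configuration for the synthetic-data generator
#'
#' The baseline expression level of every gene is log-normal
#' (`exp(N(expression_logmean, expression_logsd))`), giving heavy-tailed
#' FPKM-like marginals; within a stratum each gene varies across tissues by an
#' independent log-normal factor with log-sd `sample_logsd`.  A planted module
#' replaces that independent variation with
#' `exp(loading * factor + N(0, noise_sd))`, where `factor` is one standard
#' normal draw per tissue, so the within-module log-scale correlation is
#' `loading^2 / (loading^2 + noise_sd^2)`.  Query ("DEG") baselines are drawn
#' from the same distribution as every other gene, so expression-rank matching
#' against non-query genes is meaningful.  The deletion study applies the
#' hemizygous effect as a shift of `deletion_log2fc` in log2 space (default -1,
#' i.e. half dosage), never by zeroing counts.
#'
#' @param n_genes Number of genes in the compendium.
#' @param n_deg Number of query (differentially expressed) genes; planted
#'   module members are always part of this set.
#' @param strata_counts Tibble (`region`, `stage`, `n`) of specimen counts;
#'   defaults to [brainspan_strata_counts()].
#' @param planted_modules List of modules, each a list with elements `genes`
#'   (gene ids), `strata` (stratum keys such as `"FC.1"`), `loading` (scalar or
#'   per-gene vector) and `noise_sd`.
#' @param expression_logmean,expression_logsd Log-normal baseline parameters.
#' @param sample_logsd Within-gene across-tissue log-sd for unstructured genes.
#' @param deletion_interval `list(chrom, start, end)` of the hemizygous
#'   deletion (0-based half-open).
#' @param n_deletion_genes,n_background_genes Genes inside the interval and on
#'   the rest of its chromosome.
#' @param deletion_log2fc Planted dosage effect in log2 units (default -1).
#' @param deletion_jitter_sd Gene-to-gene jitter of the planted effect.
#' @param n_case,n_control Specimens per condition in the deletion study.
#' @param study_logsd Residual within-condition log-sd of the (conceptually
#'   batch-corrected) study expression values.
#' @param seed Integer seed; all `simulate_*()` functions are reproducible
#'   given the config seed.
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(n_genes = 500L,
                              n_deg = 50L,
                              strata_counts = brainspan_strata_counts(),
                              planted_modules = list(),
                              expression_logmean = 1,
                              expression_logsd = 1,
                              sample_logsd = 0.5,
                              deletion_interval = list(chrom = "chr22",
                                                       start = 18e6, end = 21.5e6),
                              n_deletion_genes = 47L,
                              n_background_genes = 311L,
                              deletion_log2fc = -1,
                              deletion_jitter_sd = 0.05,
                              n_case = 10L,
                              n_control = 9L,
                              study_logsd = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_deg = check_count(n_deg, "n_deg"),
    strata_counts = tibble::as_tibble(strata_counts),
    planted_modules = planted_modules,
    expression_logmean = expression_logmean,
    expression_logsd = check_scalar_in(expression_logsd, "expression_logsd", 0, Inf),
    sample_logsd = check_scalar_in(sample_logsd, "sample_logsd", 0, Inf),
    deletion_interval = deletion_interval,
    n_deletion_genes = check_count(n_deletion_genes, "n_deletion_genes"),
    n_background_genes = check_count(n_background_genes, "n_background_genes"),
    deletion_log2fc = deletion_log2fc,
    deletion_jitter_sd = check_scalar_in(deletion_jitter_sd, "deletion_jitter_sd", 0, Inf),
    n_case = check_count(n_case, "n_case", min = 2L),
    n_control = check_count(n_control, "n_control", min = 2L),
    study_logsd = check_scalar_in(study_logsd, "study_logsd", 0, Inf),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!all(c("region", "stage", "n") %in% names(cfg$strata_counts))) {
    abort_field("strata_counts", "needs columns region, stage, n")
  }
  if (any(cfg$strata_counts$n < 1)) abort_field("strata_counts", "counts must be positive")
  bad_region <- setdiff(cfg$strata_counts$region, REGIONS)
  if (length(bad_region)) {
    abort_field("strata_counts", paste("unknown region", bad_region[1L]))
  }
  if (cfg$n_deg > cfg$n_genes) abort_field("n_deg", "cannot exceed n_genes")

  genes <- gene_universe(cfg$n_genes)
  keys <- stratum_key(cfg$strata_counts$region, cfg$strata_counts$stage)
  cfg$planted_modules <- lapply(seq_along(planted_modules), function(i) {
    m <- planted_modules[[i]]
    if (is.null(m$genes) || is.null(m$strata)) {
      abort_field("planted_modules", "each module needs `genes` and `strata`")
    }
    m$genes <- as.character(m$genes)
    if (!all(m$genes %in% genes)) {
      abort_field("planted_modules", "module genes outside the gene universe")
    }
    if (!all(m$strata %in% keys)) {
      abort_field("planted_modules", "active strata not among strata_counts keys")
    }
    m$loading <- rep_len(m$loading %||% 1, length(m$genes))
    m$noise_sd <- m$noise_sd %||% 0.25
    check_scalar_in(m$noise_sd, "planted_modules$noise_sd", 0, Inf)
    m$id <- paste0("M", i)
    m
  })
  n_module_genes <- length(unique(unlist(lapply(cfg$planted_modules, `[[`, "genes"))))
  if (n_module_genes > cfg$n_deg) {
    abort_field("planted_modules", "more module genes than n_deg")
  }
  structure(cfg, class = "simulation_config")
}

gene_universe <- function(n) sprintf("G%04d", seq_len(n))

#' Noise level giving a target within-module log-scale correlation
#'
#' Inverts `r = loading^2 / (loading^2 + noise^2)`.
#'
#' @param r Target correlation in (0, 1).
#' @param loading Factor loading.
#' @return The `noise_sd` to plant.
#' @export
module_noise_for_r <- function(r, loading = 1) {
  check_scalar_in(r, "r", 0, 1, lo_open = TRUE, hi_open = TRUE)
  loading * sqrt(1 / r - 1)
}

#' Simulate a stratified expression compendium
#'
#' Generates the full gene-by-sample matrix plus per-sample metadata (tissue
#' code and age drawn inside the corresponding stage window), stratifies it
#' with [group_samples()], and returns ground-truth labels for recovery tests.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return List with elements `grouped` (a `grouped_expression`), `matrix`,
#'   `meta`, and `truth` (list: `deg_genes`, `module_membership`, `hub_genes`).
#' @export
simulate_grouped_expression <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(config$strata_counts$n < 3L)) {
    stop("strata with < 3 specimens are rejected: correlations are degenerate",
         call. = FALSE)
  }
  set.seed(seed %||% config$seed)
  genes <- gene_universe(config$n_genes)
  counts <- config$strata_counts
  counts <- counts[order(match(counts$region, REGIONS), counts$stage), ]

  baseline <- rlnorm(config$n_genes, config$expression_logmean, config$expression_logsd)
  names(baseline) <- genes

  blocks <- vector("list", nrow(counts))
  meta_blocks <- vector("list", nrow(counts))
  sample_counter <- 0L
  for (i in seq_len(nrow(counts))) {
    region <- counts$region[i]; stage <- counts$stage[i]; n <- counts$n[i]
    key <- stratum_key(region, stage)
    logx <- matrix(rnorm(config$n_genes * n, 0, config$sample_logsd),
                   nrow = config$n_genes)
    for (m in config$planted_modules) {
      if (!key %in% m$strata) next
      f <- rnorm(n)
      idx <- match(m$genes, genes)
      logx[idx, ] <- outer(m$loading, f) +
        matrix(rnorm(length(idx) * n, 0, m$noise_sd), nrow = length(idx))
    }
    x <- baseline * exp(logx)
    ids <- sprintf("S%04d", sample_counter + seq_len(n))
    sample_counter <- sample_counter + n
    dimnames(x) <- list(genes, ids)
    blocks[[i]] <- x
    codes <- REGION_MAP[[region]]
    age <- switch(as.character(stage),
      `1` = sprintf("%.1f pcw", round(runif(n, 8, 12), 1)),
      `2` = sprintf("%.1f pcw", round(runif(n, 13, 26), 1)),
      `3` = sprintf("%.1f mon", round(runif(n, 4, 132), 1)),
      `4` = sprintf("%.1f yrs", round(runif(n, 13, 23), 1))
    )
    meta_blocks[[i]] <- tibble::tibble(
      sample_id = ids,
      region = rep_len(codes, n),
      age = age
    )
  }
  mat <- do.call(cbind, blocks)
  meta <- dplyr::bind_rows(meta_blocks)

  membership <- dplyr::bind_rows(lapply(config$planted_modules, function(m) {
    tibble::tibble(gene = m$genes, module = m$id)
  }))
  if (!nrow(membership)) membership <- tibble::tibble(gene = character(), module = character())
  hub_genes <- vapply(config$planted_modules, function(m) {
    m$genes[which.max(m$loading)]
  }, character(1))
  names(hub_genes) <- vapply(config$planted_modules, `[[`, character(1), "id")

  module_genes <- unique(membership$gene)
  filler <- setdiff(genes, module_genes)
  deg_genes <- c(module_genes, filler[seq_len(config$n_deg - length(module_genes))])

  grouped <- suppressMessages(group_samples(mat, meta))
  list(
    grouped = grouped,
    matrix = mat,
    meta = meta,
    truth = list(deg_genes = sort(deg_genes),
                 module_membership = membership,
                 hub_genes = hub_genes)
  )
}

#' Simulate a case/control deletion study
#'
#' Lays non-overlapping genes across the deletion interval and the rest of its
#' chromosome (0-based half-open BED-style coordinates), plants a hemizygous
#' expression shift of `deletion_log2fc` (with per-gene jitter) on the
#' interval genes, and produces a differential-expression table plus
#' case/control expression matrices consistent with it.  Background genes
#' carry no effect and uniform p-values.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `deg_table`, `annotation`, `case`, `control`, and `truth`
#'   (list: `deletion_genes`, `flanking_genes`, `planted_log2fc`).
#' @export
simulate_deg_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed %||% config$seed)
  iv <- config$deletion_interval
  n_del <- config$n_deletion_genes
  n_bg <- config$n_background_genes

  width <- iv$end - iv$start
  spacing <- floor(width / n_del)
  gene_len <- min(20000, floor(spacing * 0.6))
  if (gene_len < 1) {
    stop("deletion interval too small to hold n_deletion_genes non-overlapping genes",
         call. = FALSE)
  }
  del_start <- iv$start + (seq_len(n_del) - 1L) * spacing
  del <- tibble::tibble(
    gene_id = sprintf("DEL%03d", seq_len(n_del)),
    chrom = iv$chrom, start = del_start, end = del_start + gene_len, strand = "+"
  )
  if (any(del$end[-n_del] > del$start[-1L]) || any(del$end > iv$end)) {
    stop("overlapping gene coordinates inside the deletion interval", call. = FALSE)
  }
  n_left <- floor(n_bg / 2); n_right <- n_bg - n_left
  left_width <- min(iv$start, 10e6)
  left_start <- iv$start - left_width + (seq_len(n_left) - 1L) * floor(left_width / n_left)
  right_start <- iv$end + 50000 + (seq_len(n_right) - 1L) * floor(25e6 / n_right)
  bg_len <- 20000
  bg <- tibble::tibble(
    gene_id = sprintf("BG%03d", seq_len(n_bg)),
    chrom = iv$chrom,
    start = c(left_start, right_start),
    end = c(left_start, right_start) + bg_len,
    strand = "+"
  )
  annotation <- dplyr::arrange(dplyr::bind_rows(del, bg), .data$start)

  planted <- setNames(numeric(nrow(annotation)), annotation$gene_id)
  planted[del$gene_id] <- config$deletion_log2fc +
    rnorm(n_del, 0, config$deletion_jitter_sd)

  p <- setNames(numeric(nrow(annotation)), annotation$gene_id)
  p[del$gene_id] <- 10^runif(n_del, -12, -5)
  p[bg$gene_id] <- pmax(runif(n_bg), 1e-12)

  deg_table <- tibble::tibble(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    start = annotation$start,
    end = annotation$end,
    log2fc = unname(planted[annotation$gene_id]),
    p = unname(p[annotation$gene_id])
  )
  deg_table$q <- p.adjust(deg_table$p, method = "BH")
  deg_table$direction <- ifelse(deg_table$log2fc >= 0, "up", "down")

  # expression consistent with the planted effects
  base <- rlnorm(nrow(annotation), config$expression_logmean, config$expression_logsd)
  names(base) <- annotation$gene_id
  noise <- function(n) matrix(rnorm(nrow(annotation) * n, 0, config$study_logsd),
                              nrow = nrow(annotation))
  control <- base * exp(noise(config$n_control))
  case <- base * 2^planted[annotation$gene_id] * exp(noise(config$n_case))
  dimnames(control) <- list(annotation$gene_id,
                            sprintf("CTRL%02d", seq_len(config$n_control)))
  dimnames(case) <- list(annotation$gene_id,
                         sprintf("CASE%02d", seq_len(config$n_case)))

  left_flank <- utils::tail(bg$gene_id[bg$end <= iv$start], 3L)
  right_flank <- utils::head(bg$gene_id[bg$start >= iv$end], 3L)
  list(
    deg_table = deg_table,
    annotation = annotation,
    case = case,
    control = control,
    truth = list(deletion_genes = del$gene_id,
                 flanking_genes = c(left_flank, right_flank),
                 planted_log2fc = planted)
  )
}

#' Simulate a binned interaction-correlation track
#'
#' Background bins fluctuate around a low mean; one contiguous run of bins is
#' planted at a high interaction-correlation value, emulating a genomic region
#' in strong physical contact with a query locus.
#'
#' @param chrom Chromosome label.
#' @param n_bins Number of bins.
#' @param bin_size Bin width in bp.
#' @param background Background mean correlation (default 0.1).
#' @param background_sd Background jitter (values are kept below 0.35).
#' @param region_start_bin First bin (1-based) of the planted region.
#' @param region_n_bins Length of the planted region in bins.
#' @param region_value Planted correlation value (default 0.5).
#' @param seed Integer seed.
#' @return Tibble with columns `chrom`, `start`, `end`, `correlation`.
#' @export
simulate_interaction_track <- function(chrom = "chr6", n_bins = 100L,
                                       bin_size = 1e6, background = 0.1,
                                       background_sd = 0.02,
                                       region_start_bin = 40L,
                                       region_n_bins = 3L,
                                       region_value = 0.5,
                                       seed = 1L) {
  check_count(n_bins, "n_bins")
  check_scalar_in(bin_size, "bin_size", 0, Inf, lo_open = TRUE)
  check_count(region_start_bin, "region_start_bin")
  check_count(region_n_bins, "region_n_bins")
  if (region_start_bin + region_n_bins - 1L > n_bins) {
    abort_field("region_start_bin", "planted region extends past the track")
  }
  set.seed(seed)
  value <- pmin(pmax(rnorm(n_bins, background, background_sd), 0), 0.35)
  idx <- region_start_bin + seq_len(region_n_bins) - 1L
  value[idx] <- region_value
  tibble::tibble(
    chrom = chrom,
    start = (seq_len(n_bins) - 1) * bin_size,
    end = seq_len(n_bins) * bin_size,
    correlation = value
  )
}

#' Simulate a positional DEG study along one chromosome
#'
#' Places genes uniformly along a chromosome and draws their significance
#' status with a higher probability inside a designated interval, emulating a
#' genomic region enriched for differentially expressed genes (for example, a
#' region in physical contact with a deleted locus).
#'
#' @param chrom Chromosome label.
#' @param n_genes Genes laid uniformly along the chromosome.
#' @param chrom_size Chromosome length in bp.
#' @param interval `list(start, end)` of the enriched region.
#' @param p_sig_inside,p_sig_outside Probability that a gene is significant
#'   (p drawn below 0.05) inside/outside the region.
#' @param seed Integer seed.
#' @return List with `deg_table` and `annotation` tibbles.
#' @export
simulate_positional_degs <- function(chrom = "chr6", n_genes = 400L,
                                     chrom_size = 170e6,
                                     interval = list(start = 39e6, end = 43e6),
                                     p_sig_inside = 0.5,
                                     p_sig_outside = 0.1,
                                     seed = 1L) {
  check_count(n_genes, "n_genes")
  set.seed(seed)
  start <- sort(sample.int(chrom_size - 30000L, n_genes))
  annotation <- tibble::tibble(
    gene_id = sprintf("C%s_%04d", sub("^chr", "", chrom), seq_len(n_genes)),
    chrom = chrom, start = start, end = start + 20000L, strand = "+"
  )
  inside <- annotation$start < interval$end & annotation$end > interval$start
  p_sig <- ifelse(inside, p_sig_inside, p_sig_outside)
  sig <- runif(n_genes) < p_sig
  p <- ifelse(sig, runif(n_genes, 1e-6, 0.05), runif(n_genes, 0.05, 1))
  deg_table <- tibble::tibble(
    gene_id = annotation$gene_id, chrom = chrom,
    start = annotation$start, end = annotation$end,
    log2fc = rnorm(n_genes, 0, 0.5), p = p
  )
  deg_table$q <- p.adjust(deg_table$p, "BH")
  deg_table$direction <- ifelse(deg_table$log2fc >= 0, "up", "down")
  list(deg_table = deg_table, annotation = annotation)
}

#' Write a simulated compendium to disk
#'
#' Emits the expression matrix and metadata as TSV and the ground truth as
#' JSON, in the formats the readers in this package expect.
#'
#' @param sim Result of [simulate_grouped_expression()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$matrix, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$meta[c("sample_id", "region", "age")],
                   file.path(dir, "metadata.tsv"))
  truth <- list(
    deg_genes = sim$truth$deg_genes,
    module_membership = sim$truth$module_membership,
    hub_genes = as.list(sim$truth$hub_genes)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
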