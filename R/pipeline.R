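# End-to-end orchestration: filter -> stratify -> networks -> matched null ->
# hubs -> expansion -> positional statistics, with artifacts on disk.

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis, validated at load time:
#' the correlation threshold `tau` (default 0.9), null iterations `B` (default
#' 10000), rank-matching `window` (default 5 positions), hub `top_fraction`
#' (default 0.1), background selection size `n_nondeg` (default 300), FDR
#' level `alpha` (default 0.05), mean-expression `expr_cutoff` (default 1,
#' `>=` unless `cutoff_strict`), and interaction-track `interaction_cutoff`
#' (default 0.4, strict `>`).
#'
#' @param simulation `NULL`, or a [simulation_config()] (or argument list for
#'   one) to run on synthetic data.
#' @param expression,metadata,annotation,deg_table,track Input file paths
#'   (TSV/BED), used when `simulation` is `NULL`.  `annotation`, `deg_table`
#'   and `track` are optional.
#' @param deletion_interval `list(chrom, start, end)` for the dosage
#'   contingency test (optional).
#' @param tau,B,window,top_fraction,n_nondeg,alpha,expr_cutoff,cutoff_strict,interaction_cutoff
#'   Analysis constants (see above).
#' @param transform Expression scale for correlations (`"identity"` or
#'   `"log2"`).
#' @param seed Integer seed for every random draw.
#' @param out_dir Output directory for artifacts.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            expression = NULL, metadata = NULL,
                            annotation = NULL, deg_table = NULL, track = NULL,
                            deletion_interval = NULL,
                            tau = 0.9, B = 10000L, window = 5L,
                            top_fraction = 0.1, n_nondeg = 300L,
                            alpha = 0.05, expr_cutoff = 1,
                            cutoff_strict = FALSE,
                            interaction_cutoff = 0.4,
                            transform = c("identity", "log2"),
                            seed = 1L, out_dir = tempfile("stratanet")) {
  if (is.null(simulation) && (is.null(expression) || is.null(metadata))) {
    stop("provide either `simulation` or `expression` + `metadata` paths",
         call. = FALSE)
  }
  if (!is.null(simulation) && !inherits(simulation, "simulation_config")) {
    simulation <- do.call(simulation_config, as.list(simulation))
  }
  cfg <- list(
    simulation = simulation,
    expression = expression, metadata = metadata, annotation = annotation,
    deg_table = deg_table, track = track,
    deletion_interval = deletion_interval %||%
      simulation$deletion_interval,
    tau = check_scalar_in(tau, "tau", 0, 1, lo_open = TRUE),
    B = check_count(B, "B"),
    window = check_count(window, "window"),
    top_fraction = check_scalar_in(top_fraction, "top_fraction", 0, 1, lo_open = TRUE),
    n_nondeg = check_count(n_nondeg, "n_nondeg", min = 0L),
    alpha = check_scalar_in(alpha, "alpha", 0, 1),
    expr_cutoff = check_scalar_in(expr_cutoff, "expr_cutoff", 0, Inf),
    cutoff_strict = isTRUE(cutoff_strict),
    interaction_cutoff = check_scalar_in(interaction_cutoff, "interaction_cutoff", 0, 1),
    transform = match.arg(transform),
    seed = check_count(seed, "seed", min = 0L),
    out_dir = out_dir
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis
#'
#' Sequences the pipeline: mean-expression filter, stratification, per-stratum
#' query networks, rank-matched permutation null with BH correction, hub
#' ranking (per stage and overall), top-fraction selection, expansion to
#' top-connected background genes, and — when a DEG table, annotation, track
#' or case/control study is available — the positional contingency, trans
#' interaction-enrichment and dosage statistics.  All tables are written under
#' `config$out_dir` along with a machine-readable `report.json`; the run is
#' deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly (class `pipeline_report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  # --- inputs -------------------------------------------------------------
  study <- NULL; track <- NULL; annotation <- NULL; deg_table <- NULL
  if (!is.null(config$simulation)) {
    message("simulating compendium and deletion study")
    sim <- simulate_grouped_expression(config$simulation)
    study <- simulate_deg_study(config$simulation,
                                seed = fork_seed(config$seed, "deg_study"))
    track <- simulate_interaction_track(seed = fork_seed(config$seed, "track"))
    mat <- sim$matrix; meta <- sim$meta
    deg_genes <- sim$truth$deg_genes
    annotation <- study$annotation
    deg_table <- study$deg_table
  } else {
    mat <- read_expression(config$expression)
    meta <- read_metadata(config$metadata)
    if (!is.null(config$annotation)) annotation <- read_annotation(config$annotation)
    if (!is.null(config$deg_table)) deg_table <- read_deg_table(config$deg_table)
    if (!is.null(config$track)) track <- readr::read_tsv(config$track, show_col_types = FALSE)
    if (is.null(deg_table)) stop("a DEG table is required for real-data runs", call. = FALSE)
    deg_genes <- intersect(deg_table$gene_id, rownames(mat))
  }
  message(sprintf("expression: %d genes x %d samples", nrow(mat), ncol(mat)))

  # --- filter + stratify --------------------------------------------------
  mat <- filter_by_mean_expression(mat, config$expr_cutoff,
                                   strict = config$cutoff_strict)
  message(sprintf("mean-expression filter: %d genes retained", nrow(mat)))
  grouped <- group_samples(mat, meta)
  strata_tbl <- tidy(grouped)
  readr::write_tsv(strata_tbl, out("strata.tsv"))
  message(sprintf("stratified into %d groups (%d samples)",
                  nrow(strata_tbl), sum(strata_tbl$n_samples)))

  deg_genes <- intersect(deg_genes, rownames(mat))
  deg_genes <- drop_zero_expression_genes(grouped, deg_genes)
  message(sprintf("query set: %d genes after zero-expression screen",
                  length(deg_genes)))

  # --- networks + null ----------------------------------------------------
  networks <- lapply(names(grouped), function(key) {
    cors <- pairwise_correlations(grouped[[key]], deg_genes,
                                  transform = config$transform)
    build_network(cors, tau = config$tau, stratum = key)
  })
  names(networks) <- names(grouped)
  edges <- dplyr::bind_rows(lapply(networks, tidy))
  readr::write_tsv(edges, out("edges.tsv"))

  nullres <- significance_test(grouped, deg_genes, tau = config$tau,
                               B = config$B, window = config$window,
                               seed = config$seed, alpha = config$alpha,
                               transform = config$transform)
  write_null_summary(nullres, out("null_results.tsv"))
  message(sprintf("connectedness null: %d/%d strata significant at q < %s",
                  sum(nullres$summary$significant), nrow(nullres$summary),
                  format(config$alpha)))

  # --- hubs + expansion ---------------------------------------------------
  stages <- sort(unique(strata_tbl$stage))
  stage_rankings <- lapply(stages, function(s) {
    keys <- strata_tbl$stratum[strata_tbl$stage == s]
    rank_by_connectivity(networks[keys], scope = "stage_total")
  })
  names(stage_rankings) <- paste0("stage", stages)
  overall <- rank_by_connectivity(networks, scope = "overall_total")
  readr::write_tsv(
    dplyr::bind_rows(c(stage_rankings, list(overall = overall)), .id = "scope"),
    out("connectivity_rankings.tsv")
  )
  top_deg <- top_fraction(overall, config$top_fraction)

  stratum_rankings <- lapply(networks, rank_by_connectivity)
  rank_cor <- rank_correlation_matrix(stratum_rankings)
  readr::write_tsv(tibble::as_tibble(rank_cor, rownames = "stratum"),
                   out("rank_correlation.tsv"))

  expansion <- expand_to_nondeg(grouped, top_deg,
                                nondeg_universe = setdiff(rownames(mat), deg_genes),
                                tau = config$tau, n_select = config$n_nondeg,
                                transform = config$transform)
  writeLines(expansion$combined, out("combined_genes.txt"))
  message(sprintf("hub expansion: %d top query + %d background = %d genes",
                  length(top_deg), length(expansion$selected),
                  length(expansion$combined)))

  # --- positional statistics ----------------------------------------------
  contingency <- NULL; trans <- NULL; dosage <- NULL
  if (!is.null(deg_table) && !is.null(annotation) &&
      !is.null(config$deletion_interval)) {
    tab <- region_counts(deg_table, annotation, config$deletion_interval)
    ht <- chi2_2x2(tab)
    contingency <- tibble::tibble(
      in_sig = tab[1, 1], in_not = tab[1, 2],
      out_sig = tab[2, 1], out_not = tab[2, 2],
      statistic = ht$statistic, p_value = ht$p_value
    )
    readr::write_tsv(contingency, out("deletion_contingency.tsv"))
  }
  if (!is.null(track) && !is.null(deg_table)) {
    regions <- find_interacting_regions(track, config$interaction_cutoff)
    if (!is.null(config$simulation) && nrow(regions)) {
      # the simulated track lives on its own chromosome; test enrichment with
      # a positional study simulated on that chromosome
      pos <- simulate_positional_degs(
        chrom = regions$chrom[1L],
        interval = list(start = regions$start[1L], end = regions$end[1L]),
        seed = fork_seed(config$seed, "positional")
      )
      trans <- interaction_enrichment(pos$deg_table, pos$annotation, regions)
    } else if (nrow(regions)) {
      trans <- interaction_enrichment(deg_table, annotation, regions)
    }
    if (!is.null(trans)) readr::write_tsv(trans, out("interaction_enrichment.tsv"))
  }
  if (!is.null(study)) {
    dosage <- deletion_dosage_profile(study$case, study$control,
                                      study$truth$deletion_genes,
                                      study$truth$flanking_genes)
    readr::write_tsv(tibble::as_tibble(dosage), out("dosage_profile.tsv"))
  }

  # --- report -------------------------------------------------------------
  report <- list(
    provenance = list(
      package = "stratanet",
      version = as.character(utils::packageVersion("stratanet")),
      seed = config$seed,
      tau = config$tau, B = config$B, window = config$window,
      alpha = config$alpha
    ),
    strata = strata_tbl,
    n_query_genes = length(deg_genes),
    null = nullres$summary,
    significant_strata = nullres$summary$stratum[nullres$summary$significant],
    top_query_genes = top_deg,
    n_combined = length(expansion$combined),
    contingency = contingency,
    interaction = trans,
    dosage_summary = if (!is.null(dosage)) glance(dosage) else NULL
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d strata, %d query genes, %d significant stratum(s)\n",
              nrow(x$strata), x$n_query_genes, length(x$significant_strata)))
  if (length(x$significant_strata)) {
    cat("  significant:", paste(x$significant_strata, collapse = ", "), "\n")
  }
  cat(sprintf("  combined hub set: %d genes\n", x$n_combined))
  invisible(x)
}
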