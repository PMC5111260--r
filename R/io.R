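# Reading, validation and stratification of expression compendia.

# Tissue-code vocabulary of the developmental brain compendium, grouped into
# the four neuroanatomical super-regions used throughout the analysis.
REGION_MAP <- list(
  FC = c("DFC", "MFC", "OFC", "VFC"),
  SC = c("STR", "MD", "AMY", "HIP"),
  SM = c("A1C", "M1C", "S1C", "V1C"),
  TP = c("ITC", "STC", "IPC")
)

REGIONS <- names(REGION_MAP)
STAGES <- 1:4

#' Tissue codes recognised by [group_samples()]
#'
#' @return Named character vector mapping each of the 15 tissue codes to its
#'   super-region (`FC`, `SC`, `SM`, `TP`).
#' @export
tissue_regions <- function() {
  codes <- unlist(REGION_MAP, use.names = FALSE)
  setNames(rep(REGIONS, lengths(REGION_MAP)), codes)
}

stratum_key <- function(region, stage) paste(region, stage, sep = ".")

#' All (region, stage) stratum keys in canonical order
#' @return Character vector of 16 keys, e.g. `"FC.1"`.
#' @export
stratum_keys <- function() {
  as.vector(t(outer(REGIONS, STAGES, stratum_key)))
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; all
#' remaining cells must be finite non-negative numbers (FPKM-like units).
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene-id column plus >= 1 sample", call. = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    stop(sprintf("duplicate gene id '%s' in %s", dup, path), call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    stop(sprintf("non-numeric expression values in column '%s' of %s",
                 names(vals)[bad[1L]], path), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  check_expression_matrix(m, "expression")
  m
}

#' Write an expression matrix as TSV
#' @param matrix Gene-by-sample numeric matrix.
#' @param path Output path.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample id, tissue code, age)
#'
#' @param path TSV with columns `sample_id`, `region`, `age`.  Ages are
#'   strings such as `"12 pcw"`, `"6 mon"`, `"15 yrs"`.
#' @return Tibble with parsed age value and unit.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "region", "age")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("metadata %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  meta <- tibble::as_tibble(df[need])
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if (anyDuplicated(meta$sample_id)) {
    dup <- meta$sample_id[duplicated(meta$sample_id)][1L]
    stop(sprintf("duplicate sample id '%s' in metadata", dup), call. = FALSE)
  }
  known <- names(tissue_regions())
  bad <- setdiff(unique(meta$region), known)
  if (length(bad)) {
    stop(sprintf("unknown tissue code(s) in metadata: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  parsed <- parse_age(meta$age)
  meta$age_value <- parsed$value
  meta$age_unit <- parsed$unit
  meta
}

# Parse age strings: "<number> <unit>" with unit pcw / mon / yrs (and common
# variants).  Returns value + canonical unit.
parse_age <- function(age) {
  age <- trimws(as.character(age))
  m <- regmatches(age, regexec("^(-?[0-9.]+)\\s*([A-Za-z]+)$", age))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("unparseable age '%s'", age[bad][1L]), call. = FALSE)
  }
  value <- as.numeric(vapply(m, `[`, character(1), 2L))
  unit_raw <- tolower(vapply(m, `[`, character(1), 3L))
  unit <- dplyr::case_when(
    unit_raw %in% c("pcw", "wpc", "w") ~ "pcw",
    unit_raw %in% c("mon", "mos", "m", "months", "month") ~ "mon",
    unit_raw %in% c("yrs", "y", "yr", "years", "year") ~ "yrs",
    TRUE ~ NA_character_
  )
  if (anyNA(unit)) {
    stop(sprintf("unknown age unit in '%s'", age[is.na(unit)][1L]), call. = FALSE)
  }
  list(value = value, unit = unit)
}

# Developmental stage windows (closed intervals):
#   1 embryonic  8-12 pcw; 2 fetal 13-26 pcw;
#   3 early infancy-late childhood 4 mon-11 yrs; 4 adolescence-adulthood 13-23 yrs.
# Ages between windows (e.g. 27-38 pcw, 12 yrs, > 23 yrs) map to NA (dropped).
stage_of_age <- function(value, unit) {
  stage <- rep(NA_integer_, length(value))
  pre <- unit == "pcw"
  stage[pre & value >= 8 & value <= 12] <- 1L
  stage[pre & value >= 13 & value <= 26] <- 2L
  yrs <- ifelse(unit == "mon", value / 12, value)
  post <- !pre
  stage[post & yrs >= 4 / 12 & yrs <= 11] <- 3L
  stage[post & yrs >= 13 & yrs <= 23] <- 4L
  stage
}

#' Stratify samples into (region, stage) groups
#'
#' Maps tissue codes onto the four super-regions (FC, SC, SM, TP), assigns a
#' developmental stage from the age (embryonic 8-12 pcw, fetal 13-26 pcw,
#' early infancy to late childhood 4 months-11 years, adolescence to adulthood
#' 13-23 years; closed windows) and partitions the matrix columns.  Samples
#' whose age falls outside every window are dropped with a message.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param meta Metadata as returned by [read_metadata()] (or any data frame
#'   with `sample_id`, `region` tissue code, `age`).
#' @return A `grouped_expression` object: a named list of per-stratum
#'   matrices (keys like `"FC.1"`), with the dropped-sample table in
#'   `attr(, "dropped")`.
#' @export
group_samples <- function(matrix, meta) {
  check_expression_matrix(matrix)
  meta <- validate_metadata(meta)
  missing <- setdiff(colnames(matrix), meta$sample_id)
  if (length(missing)) {
    stop(sprintf("no metadata for sample(s): %s",
                 paste(head(missing, 3L), collapse = ", ")), call. = FALSE)
  }
  meta <- meta[match(colnames(matrix), meta$sample_id), ]
  meta$super_region <- unname(tissue_regions()[meta$region])
  meta$stage <- stage_of_age(meta$age_value, meta$age_unit)

  dropped <- meta[is.na(meta$stage), c("sample_id", "region", "age")]
  if (nrow(dropped)) {
    message(sprintf("group_samples: dropped %d sample(s) outside all stage windows",
                    nrow(dropped)))
  }
  kept <- meta[!is.na(meta$stage), ]

  strata <- lapply(stratum_keys(), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    ids <- kept$sample_id[kept$super_region == parts[1L] &
                            kept$stage == as.integer(parts[2L])]
    matrix[, ids, drop = FALSE]
  })
  names(strata) <- stratum_keys()
  strata <- strata[vapply(strata, ncol, integer(1)) > 0L]
  new_grouped_expression(strata, dropped = tibble::as_tibble(dropped))
}

new_grouped_expression <- function(strata, dropped = NULL) {
  structure(strata,
            dropped = dropped %||% tibble::tibble(sample_id = character(),
                                                  region = character(),
                                                  age = character()),
            class = "grouped_expression")
}

#' @export
print.grouped_expression <- function(x, ...) {
  cat(sprintf("<grouped_expression> %d strata, %d genes, %d samples\n",
              length(x), nrow(x[[1L]]), sum(vapply(x, ncol, integer(1)))))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.grouped_expression <- function(x, ...) {
  keys <- strsplit(names(x), ".", fixed = TRUE)
  tibble::tibble(
    stratum = names(x),
    region = unname(vapply(keys, `[`, character(1), 1L)),
    stage = as.integer(vapply(keys, `[`, character(1), 2L)),
    n_samples = unname(vapply(x, ncol, integer(1))),
    n_genes = unname(vapply(x, nrow, integer(1)))
  )
}

#' Filter genes by mean expression across all samples
#'
#' Retains genes whose mean expression across every sample meets the cutoff
#' (default FPKM >= 1).  The comparison is `>=` by default; set
#' `strict = TRUE` for `>`.
#'
#' @param matrix Gene-by-sample matrix.
#' @param cutoff Non-negative mean-expression threshold.
#' @param strict Use strict inequality `>` instead of `>=`.
#' @return The filtered matrix, gene order preserved.
#' @export
filter_by_mean_expression <- function(matrix, cutoff = 1, strict = FALSE) {
  check_expression_matrix(matrix)
  check_scalar_in(cutoff, "cutoff", 0, Inf)
  mu <- rowMeans(matrix)
  keep <- if (strict) mu > cutoff else mu >= cutoff
  matrix[keep, , drop = FALSE]
}

#' Drop genes with zero expression in every tissue of every stratum
#'
#' @param grouped A `grouped_expression`.
#' @param genes Character vector of gene ids to screen.
#' @return The subset of `genes` with a nonzero value somewhere.
#' @export
drop_zero_expression_genes <- function(grouped, genes) {
  stopifnot(inherits(grouped, "grouped_expression"))
  genes <- as.character(genes)
  nonzero <- Reduce(`|`, lapply(grouped, function(m) {
    rowSums(m[genes, , drop = FALSE] > 0) > 0
  }))
  genes[nonzero]
}

#' Read a BED6 gene annotation
#'
#' Six whitespace-separated columns: chrom, start, end, name, score, strand;
#' coordinates are 0-based half-open.
#'
#' @param path Path to a BED file (no header).
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t| +")
  n <- vapply(fields, length, integer(1))
  if (any(n < 6L)) {
    stop(sprintf("malformed BED line %d in %s: expected 6 columns",
                 which(n < 6L)[1L], path), call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("non-numeric coordinate on BED line %d in %s",
                 which(is.na(start) | is.na(end))[1L], path), call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("BED line %d in %s has start >= end", bad[1L], path), call. = FALSE)
  }
  ann <- tibble::tibble(
    gene_id = vapply(fields, `[`, character(1), 4L),
    chrom = vapply(fields, `[`, character(1), 1L),
    start = start,
    end = end,
    strand = vapply(fields, `[`, character(1), 6L)
  )
  if (anyDuplicated(ann$gene_id)) {
    dup <- ann$gene_id[duplicated(ann$gene_id)][1L]
    stop(sprintf("duplicate gene id '%s' in %s", dup, path), call. = FALSE)
  }
  ann
}

#' Write a gene annotation as BED6
#' @param annotation Tibble as from [read_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(annotation$chrom, as.integer(annotation$start),
                   as.integer(annotation$end), annotation$gene_id, 0L,
                   annotation$strand %||% "+")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table from TSV
#'
#' Columns: `gene_id`, `chrom`, `start`, `end`, `log2fc`, `p` and optionally
#' `q`.  A `direction` column (`up`/`down`) is derived from the sign of
#' `log2fc` if absent.
#'
#' @param path TSV path with header.
#' @return Tibble of per-gene records.
#' @export
read_deg_table <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  validate_deg_table(df)
}

validate_deg_table <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "log2fc", "p")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("DEG table lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (any(df$p <= 0 | df$p > 1)) {
    stop("DEG table p-values must be in (0, 1]", call. = FALSE)
  }
  if (!"direction" %in% names(df)) {
    df$direction <- ifelse(df$log2fc >= 0, "up", "down")
  }
  tibble::as_tibble(df)
}
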