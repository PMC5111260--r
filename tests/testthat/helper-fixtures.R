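# Small in-code fixtures shared across test files.

# gene-by-sample matrix with named rows/columns
fixture_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# wrap per-stratum matrices into a grouped_expression
make_grouped <- function(strata) {
  stratanet:::new_grouped_expression(strata)
}

# a single-stratum grouped compendium of iid log-normal genes
random_stratum <- function(n_genes, n_samples, seed = 1, sdlog = 0.5,
                           key = "FC.1") {
  set.seed(seed)
  m <- matrix(exp(rnorm(n_genes * n_samples, 1, sdlog)), nrow = n_genes,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  make_grouped(setNames(list(m), key))
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
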