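# Shared in-code fixtures for the test suite.

# Small expression matrix with named genes/samples.
make_expr <- function(n_genes = 10, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 6, 1), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# Synthetic reference mutational-signature matrix: `n_sig` sparse peaked
# profiles over the 96 contexts, columns summing to 1.
make_reference_signatures <- function(n_sig = 4, seed = 42) {
  set.seed(seed)
  M <- matrix(0, 96, n_sig,
              dimnames = list(context96_labels(),
                              paste0("SBS_SYN", seq_len(n_sig))))
  for (j in seq_len(n_sig)) {
    peaks <- sample.int(96, 12)
    M[peaks, j] <- runif(12, 0.2, 1)
    M[, j] <- M[, j] / sum(M[, j])
  }
  M
}

# A matched pair of cell-line panels (two databases, same truth).
make_panel_pair <- function(n_lines = 40, truth = cell_panel_truth(),
                            seed = 7, noise_sd = 0.5) {
  list(db1 = simulate_cellline_panel(n_lines, truth, seed = seed,
                                     database = "DB1", noise_sd = noise_sd),
       db2 = simulate_cellline_panel(n_lines, truth, seed = seed + 1000,
                                     database = "DB2", noise_sd = noise_sd))
}

# Run the per-drug DE for every drug of a panel.
panel_de <- function(panel) {
  drugs <- unique(panel$response$drug)
  out <- lapply(drugs, function(d) {
    cls <- classify_lines(panel$response, d)
    suppressWarnings(drug_de(panel$expr, cls))
  })
  names(out) <- drugs
  out
}
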