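# Shared fixture builders: everything is generated in code at test time.

make_em <- function(values, layer = "log2_intensity") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_matrix(values, layer)
}

# Minimal two-condition protein design matching columns s01..s{2k}.
make_two_group_design <- function(n_rep = 3, assay = "protein") {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(2 * n_rep)),
    condition = rep(c("agonist", "vehicle"), each = n_rep),
    timepoint = "late",
    replicate = rep(seq_len(n_rep), 2),
    assay = assay, stringsAsFactors = FALSE)
}

two_group_contrast <- list(numerator = "agonist", denominator = "vehicle",
                           timepoint = "late")

# Default Gaddum world used across CETSA tests.
gaddum_params <- list(ec50 = 10e-9, ki = 100e-9, top = 100, bottom = 0,
                      hill = 1)
gaddum_doses <- 10^seq(-10, -5.5, length.out = 9)
gaddum_antag <- c(0, 1e-7, 3e-7, 1e-6, 3e-6, 1e-5)

# Default multi-omics simulation shared by concordance-level tests
# (computed once per test run; ~2 s).
default_sim_bundle <- local({
  cache <- NULL
  function(seed = 11) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    cfg <- sim_config(seed = seed)
    design <- simulate_design(5, 3)
    sim <- simulate_multiomics(cfg, design)
    tpm <- counts_to_tpm(sim$rna, sim$gene_lengths)
    rna_log2 <- ratio_normalize(
      log2_transform(tpm[filter_expressed_genes(tpm), ]))
    detected <- filter_detected_proteins(sim$protein, design)
    imp <- impute_missing(median_normalize(sim$protein[detected, ]),
                          seed = seed + 1)
    cache <<- list(seed = seed, cfg = cfg, design = design, sim = sim,
                   tpm = tpm, rna_log2 = rna_log2,
                   protein = imp$matrix,
                   rna_diff = run_differential(rna_log2, design),
                   prot_diff = run_differential(imp$matrix, design))
    cache
  }
})
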