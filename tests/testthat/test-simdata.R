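test_that("simulate_design builds the full factorial and validates replicates", {
  d <- simulate_design(5, 3)
  expect_equal(sum(d$assay == "rna"), 30L)       # 3 conditions x 2 tp x 5
  expect_equal(sum(d$assay == "protein"), 18L)   # 3 conditions x 2 tp x 3
  expect_false(anyDuplicated(d$sample_id) > 0)
  d2 <- simulate_design(2, 2)
  expect_equal(nrow(d2), 24L)
  expect_error(simulate_design(1, 3), "replicate counts")
})

test_that("simulate_multiomics honours the null configuration", {
  cfg <- sim_config(n_genes = 300, frac_induced = 0, frac_repressed = 0,
                    effect_mean = 0, protein_noise_sd = 0,
                    detect_mid = -100, seed = 5)
  sim <- simulate_multiomics(cfg, simulate_design(3, 2))
  lfc_cols <- grep("^lfc_", names(sim$truth), value = TRUE)
  expect_true(all(sim$truth[lfc_cols] == 0))
  expect_true(all(sim$truth$class == "null"))
  # protein matrix has no noise and no effects: rows are constant
  expect_equal(max(apply(em_values(sim$protein), 1, var)), 0)
})

test_that("discordant count follows the deterministic rounding rule", {
  cfg <- sim_config(n_genes = 5000, frac_discordant = 0.015, seed = 3)
  sim <- simulate_multiomics(cfg, simulate_design(2, 2))
  expect_equal(sum(sim$truth$discordant), 75L)
  expect_true(all(sim$truth$kappa[sim$truth$discordant] <= 0.1))
  expect_true(all(sim$truth$kappa[!sim$truth$discordant] ==
                    cfg$attenuation_lambda))
})

test_that("saturated detection yields a complete protein matrix", {
  cfg <- sim_config(n_genes = 200, detect_mid = -1e6, detect_slope = 1e6,
                    seed = 9)
  sim <- simulate_multiomics(cfg, simulate_design(2, 2))
  expect_false(anyNA(em_values(sim$protein)))
})

test_that("simulation is byte-identical under the same seed", {
  cfg <- sim_config(n_genes = 400, seed = 77)
  d <- simulate_design(3, 2)
  a <- simulate_multiomics(cfg, d)
  b <- simulate_multiomics(cfg, d)
  expect_identical(em_values(a$rna), em_values(b$rna))
  expect_identical(em_values(a$protein), em_values(b$protein))
  expect_identical(a$truth, b$truth)
  c2 <- simulate_multiomics(sim_config(n_genes = 400, seed = 78), d)
  expect_false(identical(em_values(a$rna), em_values(c2$rna)))
})

test_that("missingness is monotone non-increasing in abundance", {
  cfg <- sim_config(n_genes = 1000, detect_mid = 21, detect_slope = 1,
                    seed = 21)
  sim <- simulate_multiomics(cfg, simulate_design(2, 3))
  v <- em_values(sim$protein)
  det_rate <- rowMeans(!is.na(v))
  bins <- cut(sim$truth$prot_log2_baseline,
              quantile(sim$truth$prot_log2_baseline, 0:10 / 10),
              include.lowest = TRUE)
  rate_by_bin <- tapply(det_rate, bins, mean)
  expect_true(all(diff(rate_by_bin) >= -0.02))  # monotone up to noise
})

test_that("mean observed RNA log2FC recovers the planted effects", {
  cfg <- sim_config(n_genes = 2000, seed = 13)
  design <- simulate_design(10, 2)
  sim <- simulate_multiomics(cfg, design)
  tpm <- em_values(counts_to_tpm(sim$rna, sim$gene_lengths))
  rna_d <- design[design$assay == "rna" & design$timepoint == "late", ]
  ag <- rna_d$sample_id[rna_d$condition == "agonist"]
  veh <- rna_d$sample_id[rna_d$condition == "vehicle"]
  ind <- sim$truth$class == "induced"
  # ratio-of-means estimator with composition correction via null genes
  obs <- log2(rowMeans(tpm[, ag]) / rowMeans(tpm[, veh]))
  obs <- obs - median(obs[sim$truth$class == "null"])
  err <- obs[ind] - sim$truth$lfc_agonist_vs_vehicle_late[ind]
  se <- sd(err) / sqrt(sum(ind))
  expect_lt(abs(mean(err)), 3 * se + 0.01)
})

test_that("gene-set simulation respects sizes and enrichment weights", {
  cfg <- sim_config(n_genes = 500, seed = 31)
  sim <- simulate_multiomics(cfg, simulate_design(2, 2))
  sets <- simulate_gene_sets(sim$truth, n_sets = 5, set_size = 50,
                             enrich_factor = 1, seed = 1)
  expect_length(sets, 5L)
  expect_true(all(vapply(sets, function(s) length(unique(s)), 0L) == 50L))
  # Monte-Carlo: enriched induced set overshoots the universe fraction
  frac_ind <- mean(sim$truth$class == "induced")
  hits <- replicate(200, {
    s <- simulate_gene_sets(sim$truth, n_sets = 3, set_size = 50,
                            enrich_factor = 10)
    mean(s$SET_INDUCED %in% sim$truth$gene_id[sim$truth$class == "induced"])
  })
  expect_gt(mean(hits), frac_ind)
  expect_error(simulate_gene_sets(sim$truth, set_size = 1e4),
               "exceeds the gene universe")
})

test_that("simulate_cetsa reproduces the Gaddum-shifted 4PL exactly", {
  p <- list(ec50 = 1e-8, ki = 1e-6, top = 80, bottom = 20, hill = 1)
  # [B] = 0, [A] = ec50 -> midpoint
  d <- simulate_cetsa(c(1e-8, 1e-9, 1e-7, 1e-6), 0, p, noise_sd = 0)
  expect_equal(d$signal[d$agonist_dose == 1e-8], 50)
  # [B] = ki, [A] -> infinity: asymptote at top
  d2 <- simulate_cetsa(c(1e-2, 1e-9, 1e-8, 1e-7), 1e-6, p, noise_sd = 0)
  expect_equal(d2$signal[d2$agonist_dose == 1e-2], p$top, tolerance = 1e-5)
  # [B] = ki -> fitted EC50 doubles
  doses <- 10^seq(-10, -5, length.out = 9)
  d3 <- simulate_cetsa(doses, 1e-6, p, noise_sd = 0)
  fit <- fit_4pl(d3$agonist_dose, d3$signal)
  expect_equal(fit$ec50, 2e-8, tolerance = 1e-6)
  expect_error(simulate_cetsa(doses, 0, modifyList(p, list(hill = 0))),
               "hill")
})
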