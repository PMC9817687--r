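make_diff_table <- function(ids, lfc) {
  data.frame(feature_id = ids, log2fc = lfc, stringsAsFactors = FALSE)
}

test_that("pair_fold_changes inner-joins on mapped ids", {
  rna <- make_diff_table(letters[1:10], 1:10)
  prot <- make_diff_table(letters[4:10], 4:10)
  pairs <- pair_fold_changes(rna, prot)
  expect_equal(nrow(pairs), 7L)
  expect_equal(pairs$rna_lfc, pairs$prot_lfc)
  expect_error(pair_fold_changes(rna, make_diff_table(LETTERS[1:5], 1:5)),
               "no shared features")
  # protein ids mapped to gene ids
  prot2 <- make_diff_table(paste0("P_", letters[1:5]), 11:15)
  map <- setNames(letters[1:5], paste0("P_", letters[1:5]))
  expect_equal(nrow(pair_fold_changes(rna, prot2, id_map = map)), 5L)
})

test_that("fit_concordance matches the closed-form OLS oracle", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    x <- rnorm(n); y <- 0.7 * x + rnorm(n, sd = 0.3)
    pairs <- data.frame(feature_id = sprintf("g%03d", 1:n),
                        rna_lfc = x, prot_lfc = y)
    fit <- fit_concordance(pairs)
    ols <- lm(y ~ x)
    expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
    expect_equal(fit$table$studentized, unname(rstandard(ols)),
                 tolerance = 1e-8)
    expect_equal(sum(fit$table$leverage), 2, tolerance = 1e-10)
  }
})

test_that("exact linear data give slope, r and residuals exactly", {
  x <- seq(-3, 3, length.out = 20)
  p1 <- data.frame(feature_id = sprintf("g%02d", 1:20), rna_lfc = x,
                   prot_lfc = x)
  f1 <- fit_concordance(p1)
  expect_equal(f1$slope, 1); expect_equal(f1$intercept, 0)
  expect_equal(f1$pearson_r, 1)
  expect_true(all(f1$table$studentized == 0))
  expect_length(call_discordant(f1), 0L)
  p2 <- p1; p2$prot_lfc <- 0.7 * x
  expect_equal(fit_concordance(p2)$slope, 0.7)
  expect_error(fit_concordance(p1[1:5, ]), ">= 10")
  expect_error(fit_concordance(transform(p1, rna_lfc = 1)), "zero variance")
})

test_that("studentized residuals are standardized under Gaussian noise", {
  set.seed(88)
  x <- rnorm(5000); y <- 0.5 * x + rnorm(5000)
  fit <- fit_concordance(data.frame(feature_id = as.character(1:5000),
                                    rna_lfc = x, prot_lfc = y))
  r <- studentized_residuals(fit)
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(abs(var(r) - 1), 0.05)
})

test_that("a single planted outlier is the only flagged point", {
  x <- c(seq(-2, 2, length.out = 100), 5)
  y <- 0.5 * x; y[101] <- 0
  pairs <- data.frame(feature_id = sprintf("g%03d", 1:101),
                      rna_lfc = x, prot_lfc = y)
  fit <- fit_concordance(pairs)
  expect_equal(call_discordant(fit), "g101")
  expect_length(call_discordant(fit, threshold = Inf), 0L)
  expect_error(call_discordant(fit, threshold = 0), "> 0")
  # invariance to feature order
  perm <- sample(101)
  fit2 <- fit_concordance(pairs[perm, ])
  expect_setequal(call_discordant(fit2), "g101")
})

test_that("abundance_correlation and detection_overlap do set algebra", {
  ov <- detection_overlap(c("a", "b", "c", "d"), c("b", "c", "e"))
  expect_equal(ov$n_both, 2L)
  expect_equal(ov$n_rna_only, 2L)
  expect_equal(ov$n_protein_only, 1L)
  expect_equal(ov$fraction_genes_with_protein, 0.5)
  expect_equal(detection_overlap(letters[1:3],
                                 letters[1:3])$fraction_genes_with_protein, 1)
  expect_equal(detection_overlap(letters[1:3],
                                 LETTERS[1:3])$fraction_genes_with_protein, 0)

  x <- setNames(rnorm(20), letters[1:20])
  expect_equal(abundance_correlation(x, x), 1)
  expect_equal(abundance_correlation(x, -x), -1)
  expect_error(abundance_correlation(x[1:5], x[1:5]), ">= 10")
})

test_that("run_pca returns orthonormal loadings and unit variance fractions", {
  set.seed(12)
  v <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:8)))
  v[1:40, 1:4] <- v[1:40, 1:4] + 3
  pca <- run_pca(make_em(v), n_top = Inf)
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-9)
  expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)),
               ignore_attr = TRUE, tolerance = 1e-10)
  # duplicated samples -> identical scores
  v2 <- cbind(v, s9 = v[, 1])
  pca2 <- run_pca(make_em(v2), n_top = Inf)
  expect_equal(pca2$scores["s9", ], pca2$scores["s1", ], tolerance = 1e-8)
  vna <- v; vna[1, 1] <- NA
  expect_error(run_pca(make_em(vna)), "complete")
})

test_that("default simulation mirrors the qualitative published pattern", {
  b <- default_sim_bundle(11)
  key_late <- "agonist_antagonist_vs_agonist_late"
  key_early <- "agonist_antagonist_vs_agonist_early"
  pairs_late <- pair_fold_changes(b$rna_diff[[key_late]],
                                  b$prot_diff[[key_late]])
  pairs_early <- pair_fold_changes(b$rna_diff[[key_early]],
                                   b$prot_diff[[key_early]])
  # attenuation: fewer two-fold proteins than two-fold genes
  n2_prot <- sum(abs(b$prot_diff[[key_late]]$log2fc) >= 1)
  n2_rna <- sum(abs(b$rna_diff[[key_late]]$log2fc) >= 1)
  expect_lt(n2_prot, n2_rna)
  # correlation higher at the late timepoint (early effects are scaled down)
  expect_gte(cor(pairs_late$rna_lfc, pairs_late$prot_lfc),
             cor(pairs_early$rna_lfc, pairs_early$prot_lfc))
  # PC1 separates agonist from vehicle at the late timepoint
  pca <- run_pca(b$rna_log2)
  d <- b$design[match(rownames(pca$scores), b$design$sample_id), ]
  grp <- d$condition[d$timepoint == "late"]
  pc1 <- pca$scores[d$timepoint == "late", 1]
  gap <- abs(mean(pc1[grp == "agonist"]) - mean(pc1[grp == "vehicle"]))
  spread <- sqrt(mean(c(var(pc1[grp == "agonist"]),
                        var(pc1[grp == "vehicle"]))))
  expect_gt(gap, 3 * spread)
  # abundance correlation close to the generator's latent target
  r <- abundance_correlation(rowMeans(em_values(b$rna_log2)),
                             rowMeans(em_values(b$protein)))
  expect_lt(abs(r - 0.65), 0.05)
  # concordance slope recovers the attenuation coefficient
  fit <- fit_concordance(pairs_late)
  expect_lt(abs(fit$slope - 0.7), 0.05)
})
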