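test_that("counts_to_tpm matches the hand-computed example and normalizes", {
  cm <- make_em(matrix(c(10, 20), 2, 1,
                       dimnames = list(c("g1", "g2"), "s1")), "counts")
  tpm <- counts_to_tpm(cm, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(em_values(tpm)[, 1]), c(5e5, 5e5))
  # single gene -> 1e6; all-zero sample -> zero column with warning
  one <- make_em(matrix(7, 1, 1, dimnames = list("g1", "s1")), "counts")
  expect_equal(unname(em_values(counts_to_tpm(one, c(g1 = 500)))[1, 1]), 1e6)
  zeros <- make_em(matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "s1")),
                   "counts")
  expect_warning(tz <- counts_to_tpm(zeros, c(g1 = 100, g2 = 100)),
                 "all-zero")
  expect_true(all(em_values(tz) == 0))
})

test_that("TPM columns sum to 1e6 on simulated data", {
  cfg <- sim_config(n_genes = 300, seed = 2)
  sim <- simulate_multiomics(cfg, simulate_design(2, 2))
  tpm <- counts_to_tpm(sim$rna, sim$gene_lengths)
  expect_equal(unname(colSums(em_values(tpm))),
               rep(1e6, ncol(em_values(tpm))), tolerance = 1e-6)
})

test_that("filter_expressed_genes applies inclusive thresholds", {
  m <- make_em(rbind(g1 = c(1.2, 1.5, 0.9, 2.0),
                     g2 = c(0.5, 0.8, 1.1, 0.2),
                     g3 = c(1.0, 1.0, 1.0, 0.0)), "tpm")
  expect_equal(filter_expressed_genes(m), c("g1", "g3"))
  expect_equal(filter_expressed_genes(make_em(matrix(0, 2, 4), "tpm")),
               character())
  expect_equal(filter_expressed_genes(m, min_tpm = 0), c("g1", "g2", "g3"))
  expect_error(filter_expressed_genes(m, min_samples = 5), "min_samples")
  # idempotence
  kept <- filter_expressed_genes(m)
  expect_equal(filter_expressed_genes(m[kept, ], min_samples = 3), kept)
})

test_that("filter_detected_proteins keeps proteins complete in >= 1 group", {
  des <- make_two_group_design(2)
  v <- rbind(p_complete_first = c(1, 2, NA, NA),
             p_one_miss_each  = c(1, NA, 2, NA),
             p_all_obs        = c(1, 2, 3, 4))
  colnames(v) <- des$sample_id
  m <- expression_matrix(v, "log2_intensity")
  kept <- filter_detected_proteins(m, des)
  expect_setequal(kept, c("p_complete_first", "p_all_obs"))
  expect_equal(filter_detected_proteins(m[kept, ], des), kept)  # idempotent
  v2 <- v; colnames(v2)[1] <- "sX"
  expect_error(filter_detected_proteins(expression_matrix(v2,
    "log2_intensity"), des), "absent from design")
})

test_that("impute_missing draws from the sub-decile normal and is seeded", {
  set.seed(1)
  vals <- matrix(rep(1:100, 2) + 0, 100, 2,
                 dimnames = list(sprintf("p%03d", 1:100), c("s01", "s02")))
  vals[5, 1] <- NA
  m <- expression_matrix(vals, "log2_intensity")
  # identity on complete data
  full <- expression_matrix(matrix(rnorm(60, 20), 30, 2,
    dimnames = list(sprintf("p%02d", 1:30), c("a", "b"))), "log2_intensity")
  out0 <- impute_missing(full, seed = 1)
  expect_identical(em_values(out0$matrix), em_values(full))
  expect_equal(sum(out0$mask), 0L)
  # Monte-Carlo mean of imputed draws ~ mean of values <= 10th percentile
  draws <- vapply(1:1000, function(s) {
    em_values(impute_missing(m, seed = s)$matrix)[5, 1]
  }, 0)
  expect_lt(abs(mean(draws) - 5.5), 1)
  # determinism and observed-cell preservation
  a <- impute_missing(m, seed = 42)
  b <- impute_missing(m, seed = 42)
  expect_identical(em_values(a$matrix), em_values(b$matrix))
  expect_identical(em_values(a$matrix)[-5, ], vals[-5, ])
  expect_equal(sum(a$mask), 1L)
})

test_that("median_normalize equalizes sample medians", {
  v <- rbind(p1 = c(9, 11), p2 = c(10, 12), p3 = c(11, 13))
  colnames(v) <- c("s1", "s2")
  out <- em_values(median_normalize(expression_matrix(v, "log2_intensity")))
  expect_equal(unname(apply(out, 2, median)), c(11, 11))
  expect_equal(unname(out[, 1]), v[, 1] + 1, ignore_attr = TRUE)
  # identity cases
  same <- expression_matrix(v - cbind(rep(0, 3), rep(2, 3)),
                            "log2_intensity")
  expect_equal(em_values(median_normalize(same)), em_values(same))
  const <- expression_matrix(matrix(5, 3, 2,
    dimnames = list(letters[1:3], c("s1", "s2"))), "log2_intensity")
  expect_equal(em_values(median_normalize(const)), em_values(const))
})

test_that("tryptic peptide counting matches manual digests and an oracle", {
  expect_equal(count_theoretical_peptides("AAAAAAKCCCCCCRDDDDD"), 2L)
  expect_equal(count_theoretical_peptides("AAAAAAKPCCCCCR"), 1L)
  expect_equal(count_theoretical_peptides("AAAA"), 0L)
  expect_error(count_theoretical_peptides(""), "empty")
  expect_error(count_theoretical_peptides("AAAB"), "unknown residue")

  # exhaustive position-scan oracle, no regex
  oracle <- function(seq, min_len = 7, max_len = 30) {
    aa <- strsplit(seq, "")[[1]]
    n <- length(aa); count <- 0L; start <- 1L
    for (i in seq_len(n)) {
      cleave <- i < n && aa[i] %in% c("K", "R") && aa[i + 1L] != "P"
      if (cleave || i == n) {
        len <- i - start + 1L
        if (len >= min_len && len <= max_len) count <- count + 1L
        start <- i + 1L
      }
    }
    count
  }
  set.seed(7)
  residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:100) {
    s <- paste(sample(residues, sample(5:80, 1), replace = TRUE),
               collapse = "")
    expect_equal(count_theoretical_peptides(s), oracle(s), info = s)
  }
})

test_that("ibaq_transform divides by peptide counts and drops zeros", {
  v <- rbind(pA = c(1000, 2000), pB = c(1000, 2000), pC = c(10, 10))
  colnames(v) <- c("s1", "s2")
  m <- expression_matrix(v, "intensity")
  out <- ibaq_transform(m, c(pA = 4L, pB = 1L, pC = 2L))
  expect_equal(unname(em_values(out)["pA", 1]), 250)
  expect_equal(em_values(out)["pB", ], v["pB", ])  # count 1 -> identity
  # equal intensity, counts 2 vs 10 -> iBAQ ratio 5:1
  v2 <- matrix(100, 2, 1, dimnames = list(c("x", "y"), "s1"))
  m2 <- expression_matrix(v2, "intensity")
  out2 <- em_values(ibaq_transform(m2, c(x = 2L, y = 10L)))
  expect_equal(unname(out2["x", 1] / out2["y", 1]), 5)
  expect_warning(z <- ibaq_transform(m, c(pA = 4L, pB = 0L, pC = 2L)),
                 "zero observable")
  expect_false("pB" %in% rownames(em_values(z)))
})

test_that("ratio_normalize removes compositional shifts", {
  set.seed(3)
  n <- 2000
  base <- matrix(rnorm(n * 4, 10), n, 4,
                 dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:4)))
  shifts <- c(0, 0.5, -0.3, 1)
  out <- em_values(ratio_normalize(expression_matrix(
    sweep(base, 2, shifts, "+"), "log2_intensity")))
  # the per-sample shifts are removed: every normalized column differs from
  # the unshifted matrix by one common constant (up to median sampling
  # noise ~ 1.25 * sd / sqrt(n))
  rec <- apply(out - base, 2, median)
  expect_lt(max(rec) - min(rec), 0.1)
  expect_lt(abs(mean(rec) - mean(shifts)), 0.1)
})
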