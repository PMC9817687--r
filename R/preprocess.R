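#' Convert counts to transcripts per million
#'
#' `TPM_g = (count_g / length_kb_g) / sum_h(count_h / length_kb_h) * 1e6`,
#' computed per sample. Columns of the result sum to 1e6 whenever the sample
#' has any nonzero count; an all-zero sample yields an all-zero column with
#' a warning.
#'
#' @param counts `ExpressionMatrix` with layer `counts`.
#' @param lengths named numeric vector of gene lengths in bases, covering
#'   every feature of `counts`.
#' @return `ExpressionMatrix` with layer `tpm`.
#' @export
counts_to_tpm <- function(counts, lengths) {
  abort_if(em_layer(counts) != "counts", "input layer must be counts")
  v <- em_values(counts)
  miss <- setdiff(rownames(v), names(lengths))
  abort_if(length(miss) > 0L, "lengths missing for features: ",
           paste(head(miss, 5), collapse = ", "))
  len_kb <- lengths[rownames(v)] / 1000
  abort_if(any(len_kb <= 0), "gene lengths must be > 0")
  rate <- v / len_kb
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
    tot[zero] <- 1  # leaves the column all-zero
  }
  expression_matrix(sweep(rate, 2, tot, "/") * 1e6, "tpm")
}

#' Filter genes by minimum expression
#'
#' Keeps gene g iff `TPM_g >= min_tpm` in at least `min_samples` samples
#' (both thresholds inclusive, matching "at least").
#'
#' @param tpm `ExpressionMatrix` with layer `tpm`.
#' @param min_tpm TPM threshold (default 1).
#' @param min_samples sample-count threshold (default 3).
#' @return character vector of retained feature ids.
#' @export
filter_expressed_genes <- function(tpm, min_tpm = 1, min_samples = 3) {
  abort_if(em_layer(tpm) != "tpm", "input layer must be tpm")
  v <- em_values(tpm)
  abort_if(min_samples > ncol(v),
           "min_samples exceeds the number of samples")
  keep <- rowSums(v >= min_tpm) >= min_samples
  rownames(v)[keep]
}

#' Filter proteins by complete detection in at least one group
#'
#' Keeps protein p iff some (condition, timepoint) group has zero missing
#' values for p, i.e. the protein was quantified in all replicates of at
#' least one condition. Timepoints count as separate conditions.
#'
#' @param prot `ExpressionMatrix` on a protein layer (may contain `NA`).
#' @param design sample design covering every column of `prot`.
#' @return character vector of retained feature ids.
#' @export
filter_detected_proteins <- function(prot, design) {
  abort_if(!is_protein_layer(em_layer(prot)),
           "input must be a protein layer")
  validate_design(design)
  v <- em_values(prot)
  missing_design <- setdiff(colnames(v), design$sample_id)
  abort_if(length(missing_design) > 0L,
           "samples absent from design: ",
           paste(missing_design, collapse = ", "))
  d <- design[match(colnames(v), design$sample_id), ]
  grp <- interaction(d$condition, d$timepoint, drop = TRUE)
  complete <- matrix(FALSE, nrow(v), nlevels(grp))
  for (k in seq_len(nlevels(grp))) {
    cols <- grp == levels(grp)[k]
    complete[, k] <- rowSums(is.na(v[, cols, drop = FALSE])) == 0L
  }
  rownames(v)[rowSums(complete) > 0L]
}

#' Left-censored imputation from the low-abundance tail
#'
#' Replaces each missing cell of a sample by a draw from
#' `Normal(mu_s, sigma_s)`, where `mu_s` and `sigma_s` are the mean and SD
#' of that sample's observed values at or below its `lower_fraction`
#' quantile. This models non-detected proteins as coming from the lower end
#' of the abundance distribution.
#'
#' @param prot `ExpressionMatrix` with layer `log2_intensity`.
#' @param lower_fraction quantile defining the low-abundance tail
#'   (default 0.10).
#' @param seed optional integer seed.
#' @return list with `matrix` (complete `ExpressionMatrix`) and `mask`
#'   (logical matrix marking imputed cells).
#' @export
impute_missing <- function(prot, lower_fraction = 0.10, seed = NULL) {
  abort_if(em_layer(prot) != "log2_intensity",
           "input layer must be log2_intensity")
  abort_if(lower_fraction <= 0 || lower_fraction > 1,
           "lower_fraction must lie in (0, 1]")
  v <- em_values(prot)
  mask <- is.na(v)
  out <- v
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      obs <- v[!mask[, j], j]
      abort_if(length(obs) < 20L,
               "sample ", colnames(v)[j],
               " has fewer than 20 observed values")
      tail_vals <- obs[obs <= quantile(obs, lower_fraction)]
      abort_if(length(tail_vals) < 2L,
               "cannot estimate the imputation distribution for sample ",
               colnames(v)[j])
      n_miss <- sum(mask[, j])
      if (n_miss > 0L) {
        out[mask[, j], j] <- rnorm(n_miss, mean(tail_vals), sd(tail_vals))
      }
    }
  })
  list(matrix = new_em(out, "log2_intensity"), mask = mask)
}

#' Median-centre log2 samples
#'
#' Shifts each sample so its median over observed values equals the global
#' median of the per-sample medians. A simple stand-in for LFQ
#' delayed-normalization; missing cells are left untouched.
#'
#' @param mat `ExpressionMatrix` on a log2 layer.
#' @return normalized `ExpressionMatrix`.
#' @export
median_normalize <- function(mat) {
  abort_if(em_layer(mat) != "log2_intensity",
           "input layer must be log2_intensity")
  v <- em_values(mat)
  # medians over features observed in every sample, so shifts are comparable
  shared <- rowSums(is.na(v)) == 0L
  ref <- if (any(shared)) v[shared, , drop = FALSE] else v
  med <- apply(ref, 2, median, na.rm = TRUE)
  target <- median(med)
  new_em(sweep(v, 2, med - target, "-"), "log2_intensity")
}

#' Median-of-log-ratios normalization
#'
#' Removes per-sample compositional shifts from a complete log2 matrix:
#' each sample is shifted by the median, over features, of its log-ratio
#' to the feature-wise mean (a pseudo-reference sample). This mirrors
#' size-factor normalization in count-based differential expression and is
#' required for TPM data when a substantial gene fraction is regulated in
#' one direction, since TPM renormalizes each sample to a fixed total and
#' thereby shifts unregulated genes.
#'
#' @param mat complete `ExpressionMatrix` with layer `log2_intensity`.
#' @return normalized `ExpressionMatrix`.
#' @export
ratio_normalize <- function(mat) {
  abort_if(em_layer(mat) != "log2_intensity",
           "input layer must be log2_intensity")
  v <- em_values(mat)
  abort_if(anyNA(v), "ratio normalization requires a complete matrix")
  ref <- rowMeans(v)
  shift <- apply(v - ref, 2, median)
  new_em(sweep(v, 2, shift, "-"), "log2_intensity")
}

# In-silico tryptic digest: cleave after K or R unless followed by P.
digest_tryptic <- function(sequence) {
  abort_if(!nzchar(sequence), "empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(aa, valid)
  abort_if(length(bad) > 0L, "unknown residue(s): ",
           paste(unique(bad), collapse = ", "))
  n <- length(aa)
  cut_after <- aa %in% c("K", "R") &
    c(aa[-1] != "P", FALSE)        # never cut after the last residue
  bounds <- c(0L, which(cut_after), n)
  bounds <- unique(bounds)
  substring(paste(aa, collapse = ""), head(bounds, -1) + 1L, bounds[-1])
}

#' Count theoretically observable tryptic peptides
#'
#' Digests the sequence in silico (cleave after K or R except before P,
#' zero missed cleavages) and counts fragments whose length falls in
#' `[min_len, max_len]` — the peptide count used as the iBAQ denominator.
#'
#' @param sequence amino-acid string over the 20 standard residues.
#' @param min_len,max_len inclusive peptide-length window (default 7-30).
#' @return integer peptide count.
#' @examples
#' count_theoretical_peptides("AAAAAAKCCCCCCRDDDDD")  # 2
#' @export
count_theoretical_peptides <- function(sequence, min_len = 7, max_len = 30) {
  frags <- digest_tryptic(sequence)
  len <- nchar(frags)
  sum(len >= min_len & len <= max_len)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of sequences (first token of each header
#'   as name).
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  out
}

#' iBAQ transform
#'
#' Divides each protein's raw intensity by its theoretically observable
#' peptide count, yielding intensity-based absolute quantification values
#' that are comparable across proteins. Features with a peptide count of 0
#' are dropped with a warning.
#'
#' @param intensities `ExpressionMatrix` with layer `intensity` (raw,
#'   non-log).
#' @param peptide_counts named integer vector, feature -> peptide count.
#' @return `ExpressionMatrix` with layer `ibaq`.
#' @export
ibaq_transform <- function(intensities, peptide_counts) {
  abort_if(em_layer(intensities) != "intensity",
           "input layer must be raw intensity")
  v <- em_values(intensities)
  miss <- setdiff(rownames(v), names(peptide_counts))
  abort_if(length(miss) > 0L, "peptide counts missing for: ",
           paste(head(miss, 5), collapse = ", "))
  cnt <- peptide_counts[rownames(v)]
  if (any(cnt == 0)) {
    warning(sum(cnt == 0), " feature(s) with zero observable peptides ",
            "dropped", call. = FALSE)
    v <- v[cnt > 0, , drop = FALSE]
    cnt <- cnt[cnt > 0]
  }
  abort_if(any(cnt < 0), "peptide counts must be >= 0")
  new_em(v / cnt, "ibaq")
}
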