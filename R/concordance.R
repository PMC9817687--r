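#' Pair RNA and protein log2 fold changes
#'
#' Inner join of two `DiffTable`s on gene id. Protein ids are mapped to
#' gene ids through `id_map` (identity by default). The tables must come
#' from matching contrasts: the early RNA timepoint pairs with the early
#' protein timepoint (8 h RNA vs 14 h protein in the motivating design)
#' and late with late (22 h vs 28 h).
#'
#' @param rna,prot `DiffTable`s from [run_differential()].
#' @param id_map optional named character vector, protein id -> gene id.
#' @return data.frame with `feature_id`, `rna_lfc`, `prot_lfc`.
#' @export
pair_fold_changes <- function(rna, prot, id_map = NULL) {
  prot_gene <- prot$feature_id
  if (!is.null(id_map)) {
    mapped <- id_map[prot_gene]
    prot_gene <- ifelse(is.na(mapped), prot_gene, mapped)
  }
  shared <- intersect(rna$feature_id, prot_gene)
  abort_if(length(shared) == 0L,
           "no shared features between RNA and protein tables")
  data.frame(feature_id = shared,
             rna_lfc = rna$log2fc[match(shared, rna$feature_id)],
             prot_lfc = prot$log2fc[match(shared, prot_gene)],
             stringsAsFactors = FALSE)
}

#' Concordance regression of protein on RNA fold changes
#'
#' Ordinary least squares of protein log2FC (response) on RNA log2FC
#' (predictor) with intercept; the slope measures global attenuation of
#' the transcriptional response at the protein level. Internally
#' studentized residuals `r_i = e_i / (sigma_hat * sqrt(1 - h_ii))` with
#' `sigma_hat^2 = RSS / (n - 2)` flag genes whose protein response departs
#' from the value predicted by their RNA response; plain `e_i / sigma_hat`
#' z-scores are available with `studentized = FALSE`.
#'
#' @param pairs data.frame from [pair_fold_changes()].
#' @param threshold absolute-residual cutoff for the discordance flag
#'   (default 3).
#' @param studentized leverage-correct the residuals (default `TRUE`).
#' @return `ConcordanceFit`: list with `table` (per-feature lfcs,
#'   leverage, residual, studentized residual, outlier flag), `slope`,
#'   `intercept`, `pearson_r`, `sigma`, `n`, `threshold`.
#' @export
fit_concordance <- function(pairs, threshold = 3, studentized = TRUE) {
  abort_if(nrow(pairs) < 10L, "need >= 10 paired fold changes")
  abort_if(threshold <= 0, "threshold must be > 0")
  x <- pairs$rna_lfc; y <- pairs$prot_lfc
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  abort_if(sxx == 0, "zero variance in the RNA fold changes")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  e <- y - intercept - slope * x
  sigma <- sqrt(sum(e^2) / (n - 2))
  h <- 1 / n + (x - mean(x))^2 / sxx
  r <- if (studentized) e / (sigma * sqrt(1 - h)) else e / sigma
  r[sigma == 0] <- 0
  tab <- data.frame(feature_id = pairs$feature_id,
                    rna_lfc = x, prot_lfc = y,
                    leverage = h, residual = e, studentized = r,
                    outlier = abs(r) > threshold,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, slope = slope, intercept = intercept,
                 pearson_r = stats::cor(x, y), sigma = sigma, n = n,
                 threshold = threshold, studentized_used = studentized),
            class = "ConcordanceFit")
}

#' @export
print.ConcordanceFit <- function(x, ...) {
  cat(sprintf(paste0("ConcordanceFit: n = %d, slope = %.3f, ",
                     "intercept = %.3f, r = %.3f, %d outlier(s) at |r| > %g\n"),
              x$n, x$slope, x$intercept, x$pearson_r,
              sum(x$table$outlier), x$threshold))
  invisible(x)
}

#' Studentized residuals of a concordance fit
#'
#' @param fit a [fit_concordance()] result.
#' @return named numeric vector of (internally) studentized residuals.
#' @export
studentized_residuals <- function(fit) {
  abort_if(!inherits(fit, "ConcordanceFit"), "not a ConcordanceFit")
  abort_if(fit$n <= 2L, "need more than 2 points")
  setNames(fit$table$studentized, fit$table$feature_id)
}

#' Call discordant features
#'
#' Flags features with `|studentized residual| > threshold` (strict).
#'
#' @param fit a [fit_concordance()] result.
#' @param threshold positive cutoff (default 3).
#' @return character vector of flagged feature ids.
#' @export
call_discordant <- function(fit, threshold = 3) {
  abort_if(threshold <= 0, "threshold must be > 0")
  r <- studentized_residuals(fit)
  names(r)[abs(r) > threshold]
}

#' Correlation of average RNA and protein abundance
#'
#' Pearson correlation of per-gene mean log2 RNA abundance with mean log2
#' protein intensity over the shared detected features.
#'
#' @param rna_avg named vector of per-gene mean log2 TPM.
#' @param prot_avg named vector of per-protein mean log2 intensity.
#' @param id_map optional protein id -> gene id map.
#' @return Pearson R.
#' @export
abundance_correlation <- function(rna_avg, prot_avg, id_map = NULL) {
  if (!is.null(id_map)) {
    mapped <- id_map[names(prot_avg)]
    names(prot_avg) <- ifelse(is.na(mapped), names(prot_avg), mapped)
  }
  shared <- intersect(names(rna_avg), names(prot_avg))
  abort_if(length(shared) < 10L, "need >= 10 shared features")
  x <- rna_avg[shared]; y <- prot_avg[shared]
  abort_if(sd(x) == 0 || sd(y) == 0, "zero variance in abundances")
  stats::cor(x, y)
}

#' Detection overlap between assays
#'
#' @param gene_ids genes detected by RNA-seq (after expression filtering).
#' @param protein_gene_ids gene ids of detected proteins.
#' @return `OverlapSummary` list: `n_rna_only`, `n_protein_only`,
#'   `n_both`, `fraction_genes_with_protein` (= both / genes).
#' @export
detection_overlap <- function(gene_ids, protein_gene_ids) {
  g <- unique(gene_ids); p <- unique(protein_gene_ids)
  both <- length(intersect(g, p))
  list(n_rna_only = length(g) - both,
       n_protein_only = length(p) - both,
       n_both = both,
       fraction_genes_with_protein =
         if (length(g) == 0L) NA_real_ else both / length(g))
}

#' PCA of samples
#'
#' Singular-value decomposition of the centered (optionally unit-scaled)
#' samples x features matrix, after restricting to the `n_top` most
#' variable features. Variance fractions are taken over all returned
#' components and therefore sum to 1.
#'
#' @param mat complete `ExpressionMatrix` on the log2 scale.
#' @param center,scale passed to [stats::prcomp()].
#' @param n_top number of top-variance features to keep
#'   (default 500; `Inf` keeps all).
#' @return `PcaResult` list: `scores` (samples x components), `loadings`,
#'   `variance_explained`.
#' @export
run_pca <- function(mat, center = TRUE, scale = FALSE, n_top = 500) {
  v <- em_values(mat)
  abort_if(anyNA(v), "PCA requires a complete matrix (impute first)")
  if (is.finite(n_top) && n_top < nrow(v)) {
    rv <- apply(v, 1, var)
    v <- v[order(rv, decreasing = TRUE)[seq_len(n_top)], , drop = FALSE]
  }
  pc <- prcomp(t(v), center = center, scale. = scale)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_explained = ve)
}
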