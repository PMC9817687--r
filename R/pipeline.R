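#' Pipeline configuration
#'
#' Collects thresholds, input paths and simulation settings for
#' [run_pipeline()]. When `simulate = TRUE` (the default when no matrix
#' paths are given) the synthetic-data module generates all inputs.
#'
#' @param simulate generate inputs with the simulator.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param n_rep_rna,n_rep_protein replicates for the simulated design.
#' @param paths named list of input paths (used when `simulate = FALSE`):
#'   `rna_counts`, `design`, `gene_lengths`, `protein_log2`, `gmt`,
#'   `cetsa`.
#' @param min_tpm,min_samples RNA expression filter (see
#'   [filter_expressed_genes()]).
#' @param lower_fraction imputation tail quantile.
#' @param lfc_threshold two-fold-regulation threshold (log2).
#' @param residual_threshold discordance cutoff on studentized residuals.
#' @param fdr_threshold enrichment significance cutoff.
#' @param n_boot CETSA bootstrap resamples.
#' @param seed master seed for every stochastic stage.
#' @param outdir output directory.
#' @return `PipelineConfig` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = NULL,
                            n_rep_rna = 5L, n_rep_protein = 3L,
                            paths = list(),
                            min_tpm = 1, min_samples = 3,
                            lower_fraction = 0.10,
                            lfc_threshold = 1, residual_threshold = 3,
                            fdr_threshold = 0.25,
                            n_boot = 1000L, seed = 1L,
                            outdir = tempfile("tpconcord_run_")) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(simulate = simulate, sim = sim, n_rep_rna = n_rep_rna,
                 n_rep_protein = n_rep_protein, paths = paths,
                 min_tpm = min_tpm, min_samples = min_samples,
                 lower_fraction = lower_fraction,
                 lfc_threshold = lfc_threshold,
                 residual_threshold = residual_threshold,
                 fdr_threshold = fdr_threshold, n_boot = n_boot,
                 seed = as.integer(seed), outdir = outdir),
            class = "PipelineConfig")
}

#' Run the full integrative pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> differential testing ->
#' concordance -> enrichment, writing every stage's artifact plus a JSON
#' run manifest (package version, seed, thresholds, stage timings) into
#' `cfg$outdir`. Identical config and seed reproduce identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with all in-memory stage results and
#'   `outdir`.
#' @export
run_pipeline <- function(cfg) {
  abort_if(!inherits(cfg, "PipelineConfig"), "cfg must be a PipelineConfig")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- child_seeds(cfg$seed, 3L)  # gene sets, imputation, reserved
  timings <- list()
  tic <- function() Sys.time()
  lap <- function(stage, t0) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"),
                               3)
  }
  stage_try <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------------
  t0 <- tic()
  if (isTRUE(cfg$simulate)) {
    design <- simulate_design(cfg$n_rep_rna, cfg$n_rep_protein)
    sim <- simulate_multiomics(cfg$sim, design)
    rna_counts <- sim$rna; prot <- sim$protein
    lengths <- sim$gene_lengths; truth <- sim$truth
    sets <- simulate_gene_sets(truth, n_sets = 10L, set_size = 50L,
                               enrich_factor = 10, seed = seeds[1])
    write_design_tsv(design, file.path(cfg$outdir, "design.tsv"))
    write_expression_tsv(rna_counts, file.path(cfg$outdir,
                                               "rna_counts.tsv"))
    write_expression_tsv(prot, file.path(cfg$outdir, "protein_log2.tsv"))
    write_gene_lengths_tsv(lengths, file.path(cfg$outdir,
                                              "gene_lengths.tsv"))
    write_tsv_table(truth, file.path(cfg$outdir, "truth.tsv"))
    write_gmt(sets, file.path(cfg$outdir, "gene_sets.gmt"))
  } else {
    p <- cfg$paths
    for (nm in c("rna_counts", "design", "gene_lengths", "protein_log2")) {
      abort_if(is.null(p[[nm]]) || !file.exists(p[[nm]]),
               "missing input path: ", nm,
               if (!is.null(p[[nm]])) paste0(" (", p[[nm]], ")"))
    }
    design <- read_design_tsv(p$design)
    rna_counts <- read_expression_tsv(p$rna_counts, "counts")
    prot <- read_expression_tsv(p$protein_log2, "log2_intensity")
    lengths <- read_gene_lengths_tsv(p$gene_lengths)
    truth <- NULL
    sets <- if (!is.null(p$gmt)) {
      abort_if(!file.exists(p$gmt), "GMT file not found: ", p$gmt)
      read_gmt(p$gmt)
    } else NULL
  }
  lap("inputs", t0)

  # --- preprocess -----------------------------------------------------------
  t0 <- tic()
  res <- list()
  stage_try("preprocess", {
    tpm <- counts_to_tpm(rna_counts, lengths)
    expressed <- filter_expressed_genes(tpm, cfg$min_tpm, cfg$min_samples)
    rna_log2 <- ratio_normalize(log2_transform(tpm[expressed, ]))
    detected <- filter_detected_proteins(prot, design)
    prot_norm <- median_normalize(prot[detected, ])
    imp <- impute_missing(prot_norm, cfg$lower_fraction, seed = seeds[2])
    res$tpm <- tpm; res$expressed <- expressed; res$rna_log2 <- rna_log2
    res$detected <- detected; res$protein <- imp$matrix
    res$imputation_mask <- imp$mask
  })
  lap("preprocess", t0)

  # --- differential testing -------------------------------------------------
  t0 <- tic()
  stage_try("diffexp", {
    res$rna_diff <- run_differential(res$rna_log2, design)
    res$prot_diff <- run_differential(res$protein, design)
    for (nm in names(res$rna_diff)) {
      write_tsv_table(res$rna_diff[[nm]],
                      file.path(cfg$outdir, paste0("diff_rna_", nm, ".tsv")))
      write_tsv_table(res$prot_diff[[nm]],
                      file.path(cfg$outdir,
                                paste0("diff_protein_", nm, ".tsv")))
    }
  })
  lap("diffexp", t0)

  # --- concordance ----------------------------------------------------------
  t0 <- tic()
  stage_try("concord", {
    res$concordance <- list()
    for (tp in c("early", "late")) {
      key <- paste0("agonist_antagonist_vs_agonist_", tp)
      pairs <- pair_fold_changes(res$rna_diff[[key]], res$prot_diff[[key]])
      fit <- fit_concordance(pairs, threshold = cfg$residual_threshold)
      res$concordance[[tp]] <- fit
      write_tsv_table(fit$table,
                      file.path(cfg$outdir,
                                paste0("concordance_", tp, ".tsv")))
    }
    res$overlap <- detection_overlap(res$expressed, res$detected)
    res$abundance_r <- abundance_correlation(
      rowMeans(em_values(res$rna_log2)),
      rowMeans(em_values(res$protein)))
    res$pca <- list(rna = run_pca(res$rna_log2),
                    protein = run_pca(res$protein))
    for (assay in names(res$pca)) {
      sc <- res$pca[[assay]]$scores
      write_tsv_table(data.frame(sample_id = rownames(sc), sc),
                      file.path(cfg$outdir,
                                paste0("pca_scores_", assay, ".tsv")))
    }
    summ <- list(
      overlap = res$overlap, abundance_correlation = res$abundance_r,
      concordance = lapply(res$concordance, function(f) {
        list(slope = f$slope, intercept = f$intercept,
             pearson_r = f$pearson_r, n = f$n,
             n_discordant = sum(f$table$outlier),
             threshold = f$threshold)
      }))
    jsonlite::write_json(summ, file.path(cfg$outdir,
                                         "concordance_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  lap("concord", t0)

  # --- enrichment -----------------------------------------------------------
  t0 <- tic()
  if (!is.null(sets)) {
    stage_try("enrich", {
      res$enrichment <- list()
      for (tp in c("early", "late")) {
        fit <- res$concordance[[tp]]
        universe <- fit$table$feature_id
        query <- call_discordant(fit, cfg$residual_threshold)
        if (length(query) > 0L) {
          tab <- enrich(query, universe, sets, cfg$fdr_threshold)
          res$enrichment[[paste0("discordant_", tp)]] <- tab
          write_tsv_table(tab, file.path(cfg$outdir,
                                         paste0("enrichment_discordant_",
                                                tp, ".tsv")))
        }
        key <- paste0("agonist_antagonist_vs_agonist_", tp)
        for (dir in c("up", "down")) {
          q2 <- intersect(select_regulated(res$prot_diff[[key]],
                                           cfg$lfc_threshold, dir),
                          universe)
          if (length(q2) > 0L) {
            tab2 <- enrich(q2, universe, sets, cfg$fdr_threshold)
            res$enrichment[[paste0("protein_", dir, "_", tp)]] <- tab2
            write_tsv_table(tab2,
                            file.path(cfg$outdir,
                                      paste0("enrichment_protein_", dir,
                                             "_", tp, ".tsv")))
          }
        }
      }
    })
  }
  lap("enrich", t0)

  # --- CETSA (optional) ------------------------------------------------------
  if (!isTRUE(cfg$simulate) && !is.null(cfg$paths$cetsa)) {
    t0 <- tic()
    stage_try("cetsa", {
      cd <- read_cetsa_csv(cfg$paths$cetsa)
      res$cetsa <- analyze_cetsa(cd, n_boot = cfg$n_boot, seed = seeds[3])
      jsonlite::write_json(
        res$cetsa[c("ki", "pA2", "ci_low", "ci_high", "n_boot")],
        file.path(cfg$outdir, "cetsa_report.json"),
        auto_unbox = TRUE, digits = NA)
    })
    lap("cetsa", t0)
  }

  # --- manifest --------------------------------------------------------------
  manifest <- list(
    package = "tpconcord",
    version = as.character(utils::packageVersion("tpconcord")),
    seed = cfg$seed,
    thresholds = cfg[c("min_tpm", "min_samples", "lower_fraction",
                       "lfc_threshold", "residual_threshold",
                       "fdr_threshold")],
    simulate = isTRUE(cfg$simulate),
    sim_config = if (isTRUE(cfg$simulate)) unclass(cfg$sim) else NULL,
    input_checksums = if (!isTRUE(cfg$simulate)) {
      as.list(tools::md5sum(unlist(cfg$paths)))
    } else NULL,
    stage_timings_sec = timings)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$outdir <- cfg$outdir
  res$truth <- truth
  invisible(res)
}
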