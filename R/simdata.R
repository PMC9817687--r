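#' Simulation configuration for paired multi-omics data
#'
#' Describes the generative model for a synthetic prostate-cancer-cell-line
#' perturbation experiment: three arms (vehicle, agonist,
#' agonist + antagonist) at two
#' timepoints. A fraction of genes is induced or repressed by the agonist
#' with log2 effects `beta ~ Normal(effect_mean, effect_sd)` (sign forced by
#' class); early-timepoint effects are scaled by `time_factor_early`; the
#' antagonist reverses effects to `beta * (1 - reversal_rho)`. RNA counts
#' are negative binomial with dispersion trend
#' `phi(mu) = nb_dispersion_a0 + nb_dispersion_a1 / mu`. Protein log2
#' intensities follow the RNA shift through a per-gene coupling slope
#' `kappa`: `attenuation_lambda` for concordant genes, `Uniform(0, 0.1)` for
#' the planted discordant fraction, plus `Normal(0, protein_noise_sd)`
#' noise. Each protein cell is detected with probability
#' `logistic((x - detect_mid) * detect_slope)`, so low-abundance proteins
#' go missing more often (MNAR).
#'
#' @param n_genes number of genes.
#' @param frac_induced,frac_repressed fractions of genes up-/down-regulated
#'   by the agonist; their sum must be at most 1.
#' @param effect_mean,effect_sd log2 effect-size distribution.
#' @param time_factor_early effect scale at the early timepoint, in (0, 1].
#' @param reversal_rho antagonist reversal fraction in `[0, 1]`; 1 means a
#'   full reversal to vehicle level.
#' @param attenuation_lambda protein/RNA log2FC coupling slope in (0, 1].
#' @param frac_discordant fraction of genes whose protein level decouples
#'   from the RNA response (`kappa ~ Uniform(0, 0.1)`).
#' @param nb_dispersion_a0,nb_dispersion_a1 NB dispersion trend
#'   coefficients.
#' @param protein_noise_sd replicate noise of protein log2 intensity.
#' @param detect_mid,detect_slope logistic detection parameters on the
#'   protein log2-intensity scale.
#' @param rna_depth expected RNA library size in reads.
#' @param baseline_cor target correlation between RNA and protein baseline
#'   log2 abundance (shared latent factor construction).
#' @param seed integer seed; expanded into per-stage child seeds by
#'   [child_seeds()] so that identical configs reproduce identical data.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_genes = 5000L,
                       frac_induced = 0.10,
                       frac_repressed = 0.05,
                       effect_mean = 2,
                       effect_sd = 1,
                       time_factor_early = 0.6,
                       reversal_rho = 0.9,
                       attenuation_lambda = 0.7,
                       frac_discordant = 0.015,
                       nb_dispersion_a0 = 0.01,
                       nb_dispersion_a1 = 2,
                       protein_noise_sd = 0.25,
                       detect_mid = 13,
                       detect_slope = 6,
                       rna_depth = 21e6,
                       baseline_cor = 0.65,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), frac_induced = frac_induced,
              frac_repressed = frac_repressed, effect_mean = effect_mean,
              effect_sd = effect_sd, time_factor_early = time_factor_early,
              reversal_rho = reversal_rho,
              attenuation_lambda = attenuation_lambda,
              frac_discordant = frac_discordant,
              nb_dispersion_a0 = nb_dispersion_a0,
              nb_dispersion_a1 = nb_dispersion_a1,
              protein_noise_sd = protein_noise_sd,
              detect_mid = detect_mid, detect_slope = detect_slope,
              rna_depth = rna_depth, baseline_cor = baseline_cor,
              seed = as.integer(seed))
  abort_if(cfg$n_genes < 1L, "n_genes must be positive")
  abort_if(cfg$frac_induced < 0 || cfg$frac_repressed < 0 ||
             cfg$frac_induced + cfg$frac_repressed > 1,
           "frac_induced + frac_repressed must lie in [0, 1]")
  abort_if(cfg$frac_discordant < 0 || cfg$frac_discordant >= 1,
           "frac_discordant must lie in [0, 1)")
  abort_if(cfg$attenuation_lambda <= 0 || cfg$attenuation_lambda > 1,
           "attenuation_lambda must lie in (0, 1]")
  abort_if(cfg$time_factor_early <= 0 || cfg$time_factor_early > 1,
           "time_factor_early must lie in (0, 1]")
  abort_if(cfg$reversal_rho < 0 || cfg$reversal_rho > 1,
           "reversal_rho must lie in [0, 1]")
  abort_if(cfg$effect_sd < 0 || cfg$protein_noise_sd < 0,
           "standard deviations must be >= 0")
  abort_if(cfg$nb_dispersion_a0 < 0 || cfg$nb_dispersion_a1 < 0,
           "dispersion coefficients must be >= 0")
  abort_if(abs(cfg$baseline_cor) > 1, "baseline_cor must lie in [-1, 1]")
  abort_if(cfg$rna_depth <= 0, "rna_depth must be positive")
  structure(cfg, class = "SimConfig")
}

#' Full factorial sample design
#'
#' Builds the 3 conditions x 2 timepoints design for both assays. RNA and
#' protein timepoints are labelled `early`/`late`; the analysis pairs the
#' RNA early timepoint with the protein early timepoint (8 h RNA vs 14 h
#' protein in the motivating experiment) to account for the transcription ->
#' translation delay.
#'
#' @param n_rep_rna RNA replicates per condition/timepoint (>= 2).
#' @param n_rep_protein protein replicates per condition/timepoint (>= 2).
#' @return design data.frame (see [validate_design()]).
#' @examples
#' d <- simulate_design(5, 3)
#' table(d$assay)  # 30 rna, 18 protein
#' @export
simulate_design <- function(n_rep_rna = 5L, n_rep_protein = 3L) {
  abort_if(n_rep_rna < 2L || n_rep_protein < 2L,
           "replicate counts must be >= 2")
  conds <- c("vehicle", "agonist", "agonist_antagonist")
  tps <- c("early", "late")
  one <- function(assay, n_rep) {
    g <- expand.grid(replicate = seq_len(n_rep), timepoint = tps,
                     condition = conds, stringsAsFactors = FALSE)
    data.frame(
      sample_id = sprintf("%s_%s_%s_r%d", assay, g$condition, g$timepoint,
                          g$replicate),
      condition = g$condition, timepoint = g$timepoint,
      replicate = g$replicate, assay = assay, stringsAsFactors = FALSE)
  }
  design <- rbind(one("rna", as.integer(n_rep_rna)),
                  one("protein", as.integer(n_rep_protein)))
  validate_design(design)
  design
}

# True RNA log2 shift of `condition` relative to vehicle, per gene.
true_shift <- function(beta, condition, timepoint, cfg) {
  s <- if (timepoint == "early") cfg$time_factor_early else 1
  switch(condition,
         vehicle = rep(0, length(beta)),
         agonist = beta * s,
         agonist_antagonist = beta * (1 - cfg$reversal_rho) * s,
         stop("unknown condition ", condition, call. = FALSE))
}

#' Simulate paired RNA counts and protein log2 intensities
#'
#' Draws ground-truth gene classes and effects, then RNA counts (negative
#' binomial around condition-specific expected TPM) and protein log2
#' intensities (baseline + coupled RNA shift + Gaussian noise, with
#' abundance-dependent non-detection). The protein baseline shares a latent
#' factor with the RNA baseline so that average protein and RNA abundances
#' are correlated (target `cfg$baseline_cor`). The number of discordant
#' genes is `round(frac_discordant * n_genes)`, taken deterministically as
#' the first genes by index (class assignment is random, so the discordant
#' set is a class-independent subset).
#'
#' @param cfg a [sim_config()].
#' @param design a design containing both assays (see [simulate_design()]).
#' @return list with elements `rna` (`ExpressionMatrix` counts), `protein`
#'   (`ExpressionMatrix` log2_intensity with `NA` for non-detected cells),
#'   `gene_lengths` (named integer vector, bases), and `truth` (data.frame
#'   with per-gene class, `beta`, coupling slope `kappa`, discordance flag,
#'   baselines, and true RNA log2FC per contrast and timepoint).
#' @export
simulate_multiomics <- function(cfg, design) {
  abort_if(!inherits(cfg, "SimConfig"), "cfg must be a SimConfig")
  validate_design(design)
  abort_if(!all(c("rna", "protein") %in% design$assay),
           "design must contain both rna and protein assays")
  seeds <- child_seeds(cfg$seed, 4L)
  n <- cfg$n_genes
  genes <- sprintf("gene%05d", seq_len(n))

  # stage 1: ground truth ---------------------------------------------------
  truth <- with_seed(seeds[1], {
    n_ind <- round(cfg$frac_induced * n)
    n_rep <- round(cfg$frac_repressed * n)
    cls <- rep("null", n)
    regulated <- sample.int(n, n_ind + n_rep)
    cls[regulated[seq_len(n_ind)]] <- "induced"
    cls[regulated[seq_len(n_rep) + n_ind]] <- "repressed"
    beta <- numeric(n)
    beta[cls == "induced"] <- abs(rnorm(n_ind, cfg$effect_mean,
                                        cfg$effect_sd))
    beta[cls == "repressed"] <- -abs(rnorm(n_rep, cfg$effect_mean,
                                           cfg$effect_sd))
    # discordant genes: the first round(pi * n) genes by gene index,
    # irrespective of class (discordance is only observable for regulated
    # genes, but protein decoupling can affect any gene)
    n_disc <- round(cfg$frac_discordant * n)
    disc <- logical(n)
    disc[seq_len(n_disc)] <- TRUE
    kappa <- rep(cfg$attenuation_lambda, n)
    kappa[disc] <- runif(sum(disc), 0, 0.1)
    # shared-latent baselines: cor(rna, protein) -> baseline_cor
    z <- rnorm(n)
    e <- rnorm(n)
    r0 <- cfg$baseline_cor
    rna_base <- 5 + 2 * z                                # log2 TPM scale
    prot_base <- 22 + 3 * (r0 * z + sqrt(1 - r0^2) * e)  # log2 LFQ scale
    lengths <- pmax(200L, as.integer(round(exp(rnorm(n, log(1500), 0.6)))))
    df <- data.frame(gene_id = genes, class = cls, beta = beta,
                     discordant = disc, kappa = kappa,
                     rna_log2_baseline = rna_base,
                     prot_log2_baseline = prot_base,
                     gene_length = lengths, stringsAsFactors = FALSE)
    for (tp in c("early", "late")) {
      ag <- true_shift(beta, "agonist", tp, cfg)
      aa <- true_shift(beta, "agonist_antagonist", tp, cfg)
      df[[paste0("lfc_agonist_vs_vehicle_", tp)]] <- ag
      df[[paste0("lfc_agonist_antagonist_vs_vehicle_", tp)]] <- aa
      df[[paste0("lfc_agonist_antagonist_vs_agonist_", tp)]] <- aa - ag
    }
    df
  })

  rna_design <- design[design$assay == "rna", , drop = FALSE]
  prot_design <- design[design$assay == "protein", , drop = FALSE]
  len_kb <- truth$gene_length / 1000

  # stage 2: RNA counts -----------------------------------------------------
  rna <- with_seed(seeds[2], {
    m <- matrix(0, n, nrow(rna_design),
                dimnames = list(genes, rna_design$sample_id))
    for (j in seq_len(nrow(rna_design))) {
      shift <- true_shift(truth$beta, rna_design$condition[j],
                          rna_design$timepoint[j], cfg)
      tpm_true <- 2^(truth$rna_log2_baseline + shift)
      w <- tpm_true * len_kb
      mu <- cfg$rna_depth * w / sum(w)
      phi <- cfg$nb_dispersion_a0 + cfg$nb_dispersion_a1 / mu
      m[, j] <- ifelse(phi < 1e-12, stats::rpois(n, mu),
                       rnbinom(n, mu = mu, size = 1 / phi))
    }
    m
  })

  # stage 3: protein log2 intensities ---------------------------------------
  prot_full <- with_seed(seeds[3], {
    m <- matrix(0, n, nrow(prot_design),
                dimnames = list(genes, prot_design$sample_id))
    for (j in seq_len(nrow(prot_design))) {
      shift <- true_shift(truth$beta, prot_design$condition[j],
                          prot_design$timepoint[j], cfg)
      m[, j] <- truth$prot_log2_baseline + truth$kappa * shift +
        rnorm(n, 0, cfg$protein_noise_sd)
    }
    m
  })

  # stage 4: MNAR non-detection ----------------------------------------------
  prot <- with_seed(seeds[4], {
    p_detect <- plogis((prot_full - cfg$detect_mid) * cfg$detect_slope)
    p_detect[is.nan(p_detect)] <- 1  # detect_slope = Inf at x = mid
    miss <- matrix(runif(length(prot_full)), nrow(prot_full)) > p_detect
    prot_full[miss] <- NA_real_
    prot_full
  })

  list(rna = expression_matrix(rna, "counts"),
       protein = new_em(prot, "log2_intensity"),
       gene_lengths = setNames(truth$gene_length, genes),
       truth = truth)
}

#' Simulate a gene-set collection with optional planted enrichment
#'
#' Emits one set enriched for each non-empty gene class present in the
#' truth table (`induced`, `repressed`, `discordant`) followed by uniform
#' random sets, up to `n_sets` in total. Enriched sets sample members
#' without replacement with weight `enrich_factor` on the target class and
#' 1 elsewhere, so `enrich_factor = 1` gives uniform sets.
#'
#' @param truth truth table from [simulate_multiomics()].
#' @param n_sets number of sets.
#' @param set_size members per set.
#' @param enrich_factor sampling weight multiplier (>= 1) for target-class
#'   genes.
#' @param seed optional integer seed.
#' @return a named list of character vectors (class `GeneSetCollection`)
#'   with a `description` attribute.
#' @export
simulate_gene_sets <- function(truth, n_sets = 10L, set_size = 50L,
                               enrich_factor = 1, seed = NULL) {
  genes <- truth$gene_id
  abort_if(set_size > length(genes), "set_size exceeds the gene universe")
  abort_if(enrich_factor < 1, "enrich_factor must be >= 1")
  classes <- list(induced = truth$class == "induced",
                  repressed = truth$class == "repressed",
                  discordant = truth$discordant)
  classes <- classes[vapply(classes, any, logical(1))]
  with_seed(seed, {
    sets <- list()
    desc <- character()
    for (nm in names(classes)) {
      if (length(sets) >= n_sets) break
      w <- ifelse(classes[[nm]], enrich_factor, 1)
      sets[[paste0("SET_", toupper(nm))]] <-
        sample(genes, set_size, prob = w)
      desc <- c(desc, paste0("enriched for ", nm, " genes (weight ",
                             enrich_factor, ")"))
    }
    i <- 1L
    while (length(sets) < n_sets) {
      sets[[sprintf("SET_RANDOM_%02d", i)]] <- sample(genes, set_size)
      desc <- c(desc, "uniform random set")
      i <- i + 1L
    }
    structure(sets, description = setNames(desc, names(sets)),
              class = "GeneSetCollection")
  })
}

#' Simulate a competitive-antagonism CETSA dose-response plate
#'
#' Signals follow a four-parameter logistic in agonist dose `[A]` whose
#' EC50 is Gaddum-shifted by the antagonist:
#' `EC50_obs = ec50 * (1 + [B] / ki)`, i.e.
#' `signal = bottom + (top - bottom) / (1 + (EC50_obs/[A])^hill) + noise`.
#'
#' @param agonist_doses positive agonist doses (molar), >= 4 distinct.
#' @param antagonist_concs antagonist concentrations (molar), >= 0; include
#'   0 for the control curve.
#' @param params list with `ec50`, `ki` (molar, > 0), `top`, `bottom`
#'   (signal units, top > bottom), `hill` (> 0).
#' @param noise_sd Gaussian signal noise.
#' @param n_rep replicates per (dose, antagonist) cell.
#' @param seed optional integer seed.
#' @return data.frame (class `CetsaDataset`) with columns `agonist_dose`,
#'   `antagonist_conc`, `replicate`, `signal`, and attribute `true_params`.
#' @export
simulate_cetsa <- function(agonist_doses, antagonist_concs,
                           params = list(ec50 = 10e-9, ki = 100e-9,
                                         top = 100, bottom = 0, hill = 1),
                           noise_sd = 0, n_rep = 1L, seed = NULL) {
  abort_if(any(agonist_doses <= 0), "agonist doses must be > 0")
  abort_if(length(unique(agonist_doses)) < 4L,
           "need >= 4 distinct agonist doses")
  abort_if(any(antagonist_concs < 0), "antagonist concentrations must be >= 0")
  abort_if(params$hill <= 0, "hill slope must be > 0")
  abort_if(params$ec50 <= 0 || params$ki <= 0, "ec50 and ki must be > 0")
  abort_if(params$top <= params$bottom, "top must exceed bottom")
  abort_if(noise_sd < 0 || n_rep < 1L, "invalid noise_sd or n_rep")
  g <- expand.grid(replicate = seq_len(n_rep), agonist_dose = agonist_doses,
                   antagonist_conc = antagonist_concs)
  ec50_obs <- params$ec50 * (1 + g$antagonist_conc / params$ki)
  mu <- params$bottom + (params$top - params$bottom) /
    (1 + (ec50_obs / g$agonist_dose)^params$hill)
  signal <- with_seed(seed, mu + rnorm(nrow(g), 0, noise_sd))
  out <- data.frame(agonist_dose = g$agonist_dose,
                    antagonist_conc = g$antagonist_conc,
                    replicate = g$replicate, signal = signal)
  structure(out, true_params = params,
            class = c("CetsaDataset", "data.frame"))
}
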