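Package: tpconcord
Title: Transcriptome-Proteome Concordance and CETSA Schild Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of paired bulk RNA-seq and label-free
    proteomics data from ligand-perturbation experiments (androgen agonist
    and antiandrogen treatment of prostate cancer cells). Provides TPM
    transformation and expression filtering, detection filtering and
    left-censored imputation of protein intensities, iBAQ scaling with
    in-silico tryptic peptide counting, empirical-Bayes moderated-t
    differential abundance testing with Benjamini-Hochberg FDR, RNA-protein
    fold-change concordance regression with studentized-residual discordance
    calling, hypergeometric gene-set overlap testing, and isothermal CETSA
    dose-response analysis with 4PL EC50 fitting, Schild regression and
    bootstrap Ki confidence intervals. A synthetic-data module generates
    paired multi-omics and dose-response datasets with known ground truth
    for validation, so no external download is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
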