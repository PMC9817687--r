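#' Log2-transform an abundance layer
#'
#' @param mat `ExpressionMatrix` with layer `tpm`, `intensity` or `ibaq`.
#' @param pseudocount added before taking log2 (default 0.5; use 0 for
#'   strictly positive intensities).
#' @return `ExpressionMatrix` with layer `log2_intensity`.
#' @export
log2_transform <- function(mat, pseudocount = 0.5) {
  abort_if(!em_layer(mat) %in% c("tpm", "intensity", "ibaq"),
           "layer must be tpm, intensity or ibaq")
  new_em(log2(em_values(mat) + pseudocount), "log2_intensity")
}

#' Paper-design contrasts
#'
#' The three treatment contrasts at each timepoint: agonist vs vehicle,
#' agonist+antagonist vs agonist (the antagonist-effect contrast driving
#' the concordance analysis), and agonist+antagonist vs vehicle.
#'
#' @return named list of contrasts, each
#'   `list(numerator, denominator, timepoint)`.
#' @export
default_contrasts <- function() {
  out <- list()
  for (tp in c("early", "late")) {
    for (pair in list(c("agonist", "vehicle"),
                      c("agonist_antagonist", "agonist"),
                      c("agonist_antagonist", "vehicle"))) {
      nm <- paste0(pair[1], "_vs_", pair[2], "_", tp)
      out[[nm]] <- list(numerator = pair[1], denominator = pair[2],
                        timepoint = tp)
    }
  }
  out
}

#' Per-feature group-means linear model for one contrast
#'
#' Fits the two-group means model per feature: `coef` is the difference of
#' group means (log2FC, numerator minus denominator), `s2` the pooled
#' within-group variance on `df = n1 + n2 - 2` degrees of freedom, and
#' `stdev_unscaled = sqrt(1/n1 + 1/n2)` the unscaled standard error of the
#' coefficient.
#'
#' @param mat complete `ExpressionMatrix` on the log2 scale.
#' @param design sample design covering the matrix columns.
#' @param contrast `list(numerator, denominator, timepoint)`.
#' @return data.frame with `feature_id`, `coef`, `stdev_unscaled`, `s2`,
#'   `df`.
#' @export
fit_gene_models <- function(mat, design, contrast) {
  abort_if(em_layer(mat) != "log2_intensity",
           "fit requires a log2 layer")
  v <- em_values(mat)
  abort_if(anyNA(v), "matrix must be complete (impute first)")
  d <- design[match(colnames(v), design$sample_id), ]
  abort_if(anyNA(d$sample_id), "samples missing from design")
  pick <- function(cond) {
    which(d$condition == cond & d$timepoint == contrast$timepoint)
  }
  i1 <- pick(contrast$numerator)
  i2 <- pick(contrast$denominator)
  abort_if(length(i1) < 2L || length(i2) < 2L,
           "contrast group with < 2 replicates: ",
           contrast$numerator, " vs ", contrast$denominator, " at ",
           contrast$timepoint)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m2 <- rowMeans(v[, i2, drop = FALSE])
  ss1 <- rowSums((v[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, i2, drop = FALSE] - m2)^2)
  data.frame(feature_id = rownames(v),
             coef = m1 - m2,
             stdev_unscaled = sqrt(1 / n1 + 1 / n2),
             s2 = (ss1 + ss2) / (n1 + n2 - 2),
             df = n1 + n2 - 2,
             stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function (monotone decreasing on R+).
trigamma_inverse <- function(x) {
  abort_if(any(x < 0), "trigamma_inverse needs x >= 0")
  y <- ifelse(x > 1e7, 1 / sqrt(x), 0.5 + 1 / x)
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matching fit of the scaled inverse-chi-square prior for the
#' per-feature variances: with `e_g = log(s2_g) - digamma(df_g/2) +
#' log(df_g/2)`, the prior degrees of freedom solve
#' `trigamma(d0/2) = var(e) - mean(trigamma(df/2))` and the prior variance
#' is `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the
#' empirical spread of the log variances does not exceed their sampling
#' variance the prior is degenerate: `d0 = Inf` and `s0_sq = exp(mean(e))`.
#'
#' @param s2 per-feature residual variances (>= 0).
#' @param df residual degrees of freedom (scalar or per-feature, >= 1).
#' @return `EbayesPrior`: list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & df >= 1
  s2 <- s2[keep]; df <- df[keep]
  abort_if(length(s2) < 10L,
           "fewer than 10 finite variances: prior unidentifiable")
  abort_if(any(s2 < 0), "variances must be >= 0")
  if (any(s2 == 0)) {
    pos <- s2[s2 > 0]
    abort_if(length(pos) == 0L, "all variances are zero")
    s2[s2 == 0] <- min(pos) / 2  # log-variance offset for exact zeros
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    # d0 = Inf: E[s2] = s0_sq exactly, so the raw mean is unbiased
    prior <- list(d0 = Inf, s0_sq = mean(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    prior <- list(d0 = d0,
                  s0_sq = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
  }
  structure(prior, class = "EbayesPrior")
}

#' Moderated t-statistics
#'
#' Shrinks each feature's variance toward the prior,
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)` (equal to `s0_sq` when
#' `d0 = Inf` and to `s2` when `d0 = 0`), and tests
#' `t = coef / (stdev_unscaled * sqrt(s2_post))` against a t distribution
#' with `df + d0` degrees of freedom (standard normal when infinite).
#'
#' @param coef,stdev_unscaled,s2,df per-feature model summaries from
#'   [fit_gene_models()].
#' @param prior an [estimate_prior()] result.
#' @return data.frame with `t`, `p` (two-sided), `df_total`, `s2_post`.
#' @export
moderated_t <- function(coef, stdev_unscaled, s2, df, prior) {
  abort_if(!inherits(prior, "EbayesPrior"), "prior must be an EbayesPrior")
  abort_if(prior$d0 < 0 || prior$s0_sq <= 0, "invalid prior")
  s2_post <- if (is.infinite(prior$d0)) {
    rep_len(prior$s0_sq, length(s2))
  } else {
    (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
  }
  t <- coef / (stdev_unscaled * sqrt(s2_post))
  t[coef == 0] <- 0
  df_total <- df + prior$d0
  p <- 2 * pt(-abs(t), df = df_total)
  data.frame(t = t, p = p, df_total = df_total, s2_post = s2_post)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `fdr_(i) = min_{j >= i} min(1, m * p_(j) / j)`
#' over the p-values sorted increasingly, mapped back to input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  abort_if(anyNA(p) || any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(m / (m:1) * p[o]))[order(o)]
}

#' Moderated differential-abundance testing
#'
#' Composes [fit_gene_models()], [estimate_prior()] (one prior per
#' contrast, fitted across all features), [moderated_t()] and
#' [bh_adjust()] into one table per contrast.
#'
#' @param mat complete `ExpressionMatrix` on the log2 scale. RNA data
#'   enter as `log2(TPM + 0.5)` via [log2_transform()] — a moderated-t
#'   stand-in for count-model testing, adequate because downstream stages
#'   consume log2 fold changes.
#' @param design sample design.
#' @param contrasts list of contrasts (default [default_contrasts()]
#'   restricted to conditions present in the design).
#' @return named list of `DiffTable` data.frames with columns
#'   `feature_id`, `log2fc`, `avg_abund`, `s2`, `df`, `t`, `p`, `fdr`.
#' @export
run_differential <- function(mat, design, contrasts = default_contrasts()) {
  if (length(contrasts) == 0L) return(list())
  avg <- rowMeans(em_values(mat))
  out <- list()
  for (nm in names(contrasts)) {
    fit <- fit_gene_models(mat, design, contrasts[[nm]])
    prior <- estimate_prior(fit$s2, fit$df)
    mt <- moderated_t(fit$coef, fit$stdev_unscaled, fit$s2, fit$df, prior)
    out[[nm]] <- data.frame(feature_id = fit$feature_id,
                            log2fc = fit$coef,
                            avg_abund = avg[fit$feature_id],
                            s2 = fit$s2, df = fit$df,
                            t = mt$t, p = mt$p, fdr = bh_adjust(mt$p),
                            stringsAsFactors = FALSE)
    attr(out[[nm]], "prior") <- prior
    attr(out[[nm]], "contrast") <- contrasts[[nm]]
  }
  out
}
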