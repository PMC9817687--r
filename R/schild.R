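# Four-parameter logistic response at agonist dose(s).
fpl <- function(dose, top, bottom, log10_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^((log10_ec50 - log10(dose)) * hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `signal = bottom + (top - bottom) / (1 + 10^((log10_ec50 - log10(dose)) * hill))`
#' by quasi-Newton minimisation with data-driven initialisation (asymptotes
#' from the dose-mean extremes, EC50 from the half-maximal crossing, Hill
#' slope 1) and a polishing restart. `top` and/or `bottom` may be fixed,
#' e.g. to share anchors across curves.
#'
#' @param doses positive agonist doses (molar); >= 4 distinct values.
#' @param signals responses, same length as `doses`.
#' @param fixed optional named list fixing `top` and/or `bottom`.
#' @param antagonist_conc antagonist concentration the curve was measured
#'   at (molar), carried into downstream dose-ratio tables.
#' @param start optional named start values (warm start for refits).
#' @return `DoseResponseFit` list: `top`, `bottom`, `log10_ec50`, `ec50`,
#'   `hill`, `rss`, `n_points`, `antagonist_conc`, `converged`,
#'   `ec50_in_range` (EC50 within tested dose range x \[0.01, 100\]).
#' @export
fit_4pl <- function(doses, signals, fixed = NULL, antagonist_conc = NA_real_,
                    start = NULL) {
  abort_if(length(doses) != length(signals), "doses/signals length mismatch")
  abort_if(any(doses <= 0), "doses must be > 0")
  abort_if(length(unique(doses)) < 4L, "need >= 4 distinct doses")
  abort_if(anyNA(signals), "signals must be complete")
  ld <- log10(doses)

  dm <- tapply(signals, ld, mean)
  lvl <- as.numeric(names(dm))
  top0 <- max(dm); bottom0 <- min(dm)
  if (top0 == bottom0) top0 <- bottom0 + 1
  half <- (top0 + bottom0) / 2
  above <- which(dm >= half)
  lec0 <- if (length(above) == 0L || length(above) == length(dm)) {
    median(lvl)
  } else {
    # first crossing of the half-maximum, linear interpolation
    i <- min(above[above > 1L], length(dm))
    if (dm[i] == dm[i - 1L]) lvl[i]
    else lvl[i - 1L] + (half - dm[i - 1L]) / (dm[i] - dm[i - 1L]) *
      (lvl[i] - lvl[i - 1L])
  }
  init <- list(top = top0, bottom = bottom0, log10_ec50 = lec0,
               log_hill = 0)
  if (!is.null(start)) init <- modifyList(init, start)

  free <- setdiff(names(init), names(fixed))
  if ("top" %in% names(fixed)) init$top <- fixed$top
  if ("bottom" %in% names(fixed)) init$bottom <- fixed$bottom

  obj <- function(par) {
    th <- init
    th[free] <- as.list(par)
    mu <- fpl(doses, th$top, th$bottom, th$log10_ec50, exp(th$log_hill))
    sum((signals - mu)^2)
  }
  grad <- function(par) {
    th <- init
    th[free] <- as.list(par)
    h <- exp(th$log_hill)
    u <- 10^((th$log10_ec50 - ld) * h)
    F <- 1 / (1 + u)
    r <- signals - (th$bottom + (th$top - th$bottom) * F)
    ff <- F * (1 - F) * log(10) * (th$top - th$bottom)
    g <- c(top = -2 * sum(r * F),
           bottom = -2 * sum(r * (1 - F)),
           log10_ec50 = 2 * sum(r * ff * h),
           log_hill = 2 * sum(r * ff * (th$log10_ec50 - ld) * h))
    g[free]
  }
  ctrl <- list(rel.tol = 1e-14, x.tol = 1e-14, iter.max = 500L,
               eval.max = 2000L)
  fit <- nlminb(unlist(init[free]), obj, grad, control = ctrl)
  fit <- nlminb(fit$par, obj, grad, control = ctrl)  # polish
  abort_if(!is.finite(fit$objective), "4PL fit diverged")
  converged <- fit$convergence == 0 ||
    grepl("convergence", fit$message, fixed = TRUE)
  if (!converged) {
    cond <- simpleError(paste0("4PL fit did not converge: ", fit$message))
    cond$best_iterate <- fit
    stop(cond)
  }
  th <- init
  th[free] <- as.list(fit$par)
  if (th$top < th$bottom) {  # canonical orientation
    tmp <- th$top; th$top <- th$bottom; th$bottom <- tmp
    th$log_hill <- th$log_hill  # hill stays positive; swap handled by data
  }
  ec50 <- 10^th$log10_ec50
  structure(list(top = th$top, bottom = th$bottom,
                 log10_ec50 = th$log10_ec50, ec50 = ec50,
                 hill = exp(th$log_hill), rss = fit$objective,
                 n_points = length(doses),
                 antagonist_conc = antagonist_conc,
                 converged = converged,
                 ec50_in_range = ec50 >= min(doses) * 0.01 &&
                   ec50 <= max(doses) * 100),
            class = "DoseResponseFit")
}

#' Dose ratios relative to the antagonist-free control
#'
#' `DR_b = EC50(antagonist b) / EC50(control)`; competitive antagonism
#' predicts `DR = 1 + [B] / Ki` (Gaddum).
#'
#' @param fits list of `DoseResponseFit`s, one per antagonist
#'   concentration, including the control at `antagonist_conc = 0`.
#' @return data.frame with `antagonist_conc`, `dr`.
#' @export
dose_ratios <- function(fits) {
  conc <- vapply(fits, function(f) f$antagonist_conc, 0)
  abort_if(anyNA(conc), "fits must carry antagonist_conc")
  ctrl <- which(conc == 0)
  abort_if(length(ctrl) != 1L,
           "need exactly one control fit at antagonist_conc = 0")
  a0 <- fits[[ctrl]]$ec50
  out <- data.frame(
    antagonist_conc = conc[-ctrl],
    dr = vapply(fits[-ctrl], function(f) f$ec50, 0) / a0)
  out[order(out$antagonist_conc), ]
}

#' Schild regression
#'
#' Regresses `y = log10(DR - 1)` on `x = log10([B])` over rows with
#' `DR > 1` (rows at or below 1 are excluded and counted). The line's zero
#' crossing gives `pA2 = -x_intercept` and `Ki = 10^x_intercept`; a unit
#' slope is the signature of simple competitive antagonism. Rows with DR
#' in (1, 1.05] are retained but counted as low-information.
#'
#' @param table data.frame from [dose_ratios()].
#' @param constrain_unit_slope refit with slope fixed to 1 (off by
#'   default; the free slope is always reported).
#' @return `SchildFit` list: `points`, `n_used`, `n_excluded`,
#'   `n_low_information`, `slope`, `intercept`, `x_intercept`, `pA2`, `ki`
#'   (molar), plus `ki_unit_slope` when constrained.
#' @export
schild_regression <- function(table, constrain_unit_slope = FALSE) {
  use <- table$antagonist_conc > 0 & table$dr > 1
  n_excluded <- sum(!use)
  abort_if(sum(use) < 2L, "fewer than 2 usable points with DR > 1")
  x <- log10(table$antagonist_conc[use])
  y <- log10(table$dr[use] - 1)
  sxx <- sum((x - mean(x))^2)
  abort_if(sxx == 0, "antagonist concentrations not distinct")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  abort_if(slope <= 0,
           "non-positive Schild slope: pattern not competitive")
  intercept <- mean(y) - slope * mean(x)
  x_int <- -intercept / slope
  out <- list(points = data.frame(log10_conc = x, log10_dr_minus_1 = y),
              n_used = sum(use), n_excluded = n_excluded,
              n_low_information = sum(table$dr[use] <= 1.05),
              slope = slope, intercept = intercept,
              x_intercept = x_int, pA2 = -x_int, ki = 10^x_int)
  if (constrain_unit_slope) {
    # slope == 1: intercept = mean(y - x), Ki = 10^{-intercept}
    out$ki_unit_slope <- 10^(-mean(y - x))
  }
  structure(out, class = "SchildFit")
}

#' @export
print.SchildFit <- function(x, ...) {
  cat(sprintf("SchildFit: slope = %.3f, pA2 = %.3f, Ki = %.3g M (n = %d)\n",
              x$slope, x$pA2, x$ki, x$n_used))
  invisible(x)
}

# Point-estimate pipeline: per-antagonist 4PL fits -> dose ratios -> Schild.
cetsa_point_estimate <- function(data, fixed = NULL, starts = NULL) {
  concs <- sort(unique(data$antagonist_conc))
  fits <- lapply(concs, function(b) {
    rows <- data$antagonist_conc == b
    fit_4pl(data$agonist_dose[rows], data$signal[rows], fixed = fixed,
            antagonist_conc = b,
            start = starts[[as.character(b)]])
  })
  names(fits) <- as.character(concs)
  schild <- schild_regression(dose_ratios(fits))
  list(fits = fits, schild = schild)
}

#' Bootstrap confidence interval for Ki
#'
#' Resamples replicate signals with replacement within each
#' (agonist dose, antagonist concentration) cell, reruns the full
#' fit -> dose-ratio -> Schild pipeline, and returns the percentile
#' interval of the Ki estimates. Refits are warm-started from the
#' point-estimate parameters; failed refits are dropped and counted, with
#' an error if more than 20% fail.
#'
#' @param data `CetsaDataset` (or data.frame with `agonist_dose`,
#'   `antagonist_conc`, `replicate`, `signal`).
#' @param n_boot number of resamples (default 1000); 0 skips the interval.
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed.
#' @param small_sample_inflation apply the within-cell resampling variance
#'   correction: percentile endpoints are inflated around the point
#'   estimate by `sqrt(n/(n-1))` on the log scale, where `n` is the
#'   smallest per-cell replicate count. Resampling n values from n
#'   understates the sampling variance by the factor `(n-1)/n`, so the
#'   uncorrected percentile interval undercovers for small `n`
#'   (default `TRUE`).
#' @return list with `ci_low`, `ci_high` (molar), `ki_boot`, `n_failed`.
#' @export
bootstrap_ki <- function(data, n_boot = 1000L, conf = 0.95, seed = NULL,
                         small_sample_inflation = TRUE) {
  if (n_boot == 0L) {
    return(list(ci_low = NA_real_, ci_high = NA_real_,
                ki_boot = numeric(), n_failed = 0L))
  }
  point <- cetsa_point_estimate(data)
  starts <- lapply(point$fits, function(f) {
    list(top = f$top, bottom = f$bottom, log10_ec50 = f$log10_ec50,
         log_hill = log(f$hill))
  })
  cell <- interaction(data$agonist_dose, data$antagonist_conc, drop = TRUE)
  idx_by_cell <- split(seq_len(nrow(data)), cell)
  ki <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_cell, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      boot <- data[take, ]
      tryCatch(cetsa_point_estimate(boot, starts = starts)$schild$ki,
               error = function(e) NA_real_)
    }, 0)
  })
  n_failed <- sum(is.na(ki))
  abort_if(n_failed > 0.2 * n_boot,
           "more than 20% of bootstrap refits failed (", n_failed, "/",
           n_boot, ")")
  qs <- quantile(log(ki), c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 na.rm = TRUE)
  if (small_sample_inflation) {
    n_cell <- min(lengths(idx_by_cell))
    infl <- if (n_cell > 1L) sqrt(n_cell / (n_cell - 1L)) else 1
    qs <- log(point$schild$ki) + infl * (qs - log(point$schild$ki))
  }
  list(ci_low = unname(exp(qs[1])), ci_high = unname(exp(qs[2])),
       ki_boot = ki[!is.na(ki)], n_failed = n_failed)
}

#' Full CETSA Schild analysis
#'
#' Fits one 4PL curve per antagonist concentration (control included),
#' forms dose ratios, runs the Schild regression for pA2/Ki, and attaches
#' a bootstrap percentile confidence interval for Ki.
#'
#' @param data `CetsaDataset`; must include the `antagonist_conc = 0`
#'   control curve.
#' @param n_boot bootstrap resamples (default 1000; 0 = point estimate
#'   only).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return list with `fits`, `dose_ratios`, `schild`, `ki`, `pA2`,
#'   `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
analyze_cetsa <- function(data, n_boot = 1000L, conf = 0.95, seed = NULL) {
  need <- c("agonist_dose", "antagonist_conc", "replicate", "signal")
  abort_if(!all(need %in% names(data)), "CETSA data needs columns ",
           paste(need, collapse = ", "))
  abort_if(!any(data$antagonist_conc == 0),
           "dataset lacks the antagonist_conc = 0 control curve")
  point <- cetsa_point_estimate(data)
  ci <- bootstrap_ki(data, n_boot = n_boot, conf = conf, seed = seed)
  list(fits = point$fits, dose_ratios = dose_ratios(point$fits),
       schild = point$schild, ki = point$schild$ki,
       pA2 = point$schild$pA2, ci_low = ci$ci_low, ci_high = ci$ci_high,
       n_boot_failed = ci$n_failed, n_boot = n_boot, seed = seed)
}
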