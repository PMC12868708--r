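# The central model object: fits per-region HFE allele frequencies from a
# cohort, predicts risk genotypes under Hardy-Weinberg equilibrium, weights
# them by penetrance into a combined genetic risk, and - when a diagnosis
# registry is supplied - contrasts that risk with observed prevalence to
# rank regions by apparent under-diagnosis.

#' Fit the regional haemochromatosis risk model
#'
#' Estimates the allele frequencies of p.Cys282Tyr and p.His63Asp per
#' region from cohort genotypes, predicts the two risk-genotype frequencies
#' (q^2 and 2 p_C p_H) under triallelic Hardy-Weinberg equilibrium, and
#' combines them with genotype penetrances into a regional genetic risk.
#' Given a diagnosis table the fit also computes raw prevalence per region,
#' the risk/prevalence discrepancy ratio, and the Pearson correlation
#' between risk and prevalence.
#'
#' @param cohort an `hfe_cohort` (from [simulate_genotypes()] or
#'   [read_hfe_vcf()]).
#' @param diagnoses optional `diagnosis_table` whose strata are region
#'   labels matching the cohort.
#' @param penetrance a [penetrance_model()]; defaults to the male model
#'   (0.56 homozygote, 0.06 compound heterozygote, cumulative to age 80).
#' @param top_k how many highest-ratio regions to flag as candidate
#'   under-diagnosis areas.
#' @return an object of class `hfe_risk` with components `frequencies`,
#'   `risk` (sorted risk table), `hwe` (per-variant HWE tests),
#'   `prevalence`, `discrepancy`, `r` (risk-prevalence correlation),
#'   `penetrance`, `n`, `call`.
#' @examples
#' specs <- list(region_spec("North", 0.09, 0.15, 2000, ascertainment = 0.4),
#'               region_spec("South", 0.07, 0.15, 2000, ascertainment = 0.6))
#' cohort <- simulate_genotypes(specs, seed = 7)
#' diag <- simulate_diagnoses(cohort, penetrance_model(), specs, seed = 8)
#' fit <- fit_hfe_risk(cohort, diag)
#' summary(fit)
#' @export
fit_hfe_risk <- function(cohort, diagnoses = NULL,
                         penetrance = penetrance_model(), top_k = 2) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1,
            inherits(penetrance, "penetrance_model"))
  freqs <- estimate_frequencies(cohort)
  risk <- risk_table(freqs, penetrance)
  hwe <- list(
    C282Y = hwe_chisq(genotype_counts(cohort, "C282Y")),
    H63D = hwe_chisq(genotype_counts(cohort, "H63D"))
  )
  prev <- NULL
  disc <- NULL
  r <- NA_real_
  if (!is.null(diagnoses)) {
    stopifnot(is.data.frame(diagnoses))
    prev <- stratified_prevalence(diagnoses)
    common <- intersect(risk$region, prev$stratum)
    if (length(common) < nrow(risk) || length(common) < nrow(prev)) {
      warning("regions and diagnosis strata only partially overlap; ",
              "discrepancy restricted to ", length(common), " region(s)",
              call. = FALSE)
    }
    if (length(common) >= 1) {
      merged <- data.frame(
        region = common,
        prevalence_pct = prev$prevalence_pct[match(common, prev$stratum)],
        risk_pct = risk$risk_pct[match(common, risk$region)],
        stringsAsFactors = FALSE
      )
      disc <- rank_discrepancies(merged, top_k = top_k)
      if (length(common) >= 3 &&
          stats::sd(merged$prevalence_pct) > 0 &&
          stats::sd(merged$risk_pct) > 0) {
        r <- pearson_correlation(merged$prevalence_pct, merged$risk_pct)
      }
    }
  }
  structure(
    list(frequencies = freqs, risk = risk, hwe = hwe,
         prevalence = prev, discrepancy = disc, r = r,
         penetrance = penetrance, n = nrow(cohort),
         call = match.call()),
    class = "hfe_risk"
  )
}

#' @export
print.hfe_risk <- function(x, ...) {
  cat("Regional haemochromatosis risk model\n")
  cat(sprintf("  %d individuals in %d region(s); penetrance: %s\n",
              x$n, nrow(x$frequencies), x$penetrance$label))
  cat(sprintf("  risk range %.3f%% (%s) to %.3f%% (%s)\n",
              min(x$risk$risk_pct), x$risk$region[which.min(x$risk$risk_pct)],
              max(x$risk$risk_pct), x$risk$region[which.max(x$risk$risk_pct)]))
  if (!is.null(x$discrepancy)) {
    top <- x$discrepancy[x$discrepancy$flagged, "region"]
    cat(sprintf("  highest risk/prevalence ratios: %s\n",
                paste(top, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.hfe_risk <- function(object, ...) {
  structure(list(fit = object), class = "summary.hfe_risk")
}

#' @export
print.summary.hfe_risk <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nHardy-Weinberg (biallelic collapse, df = 1):\n")
  cat(sprintf("  C282Y: chi2 = %.2f, p = %.3g; H63D: chi2 = %.2f, p = %.3g\n",
              fit$hwe$C282Y$chi2, fit$hwe$C282Y$p_value,
              fit$hwe$H63D$chi2, fit$hwe$H63D$p_value))
  cat("\nGenetic risk by region:\n")
  rt <- fit$risk
  rt$risk_pct <- round(rt$risk_pct, 3)
  print(rt[, c("region", "p_c282y", "p_h63d", "risk_pct", "one_in")],
        row.names = FALSE)
  if (!is.null(fit$discrepancy)) {
    cat(sprintf(
      "\nRisk vs prevalence (r = %.2f; uniform penetrance assumed):\n",
      fit$r))
    d <- fit$discrepancy
    d$prevalence_pct <- round(d$prevalence_pct, 3)
    d$risk_pct <- round(d$risk_pct, 3)
    d$ratio <- round(d$ratio, 2)
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.hfe_risk <- function(object, ...) {
  m <- as.matrix(object$frequencies[, c("p_c282y", "p_h63d")])
  rownames(m) <- object$frequencies$region
  m
}

#' Predict genetic risk for new allele frequencies
#'
#' @param object an `hfe_risk` fit.
#' @param newdata optional data frame with columns `p_c282y`, `p_h63d`
#'   (and optionally `region`); defaults to the fitted frequencies.
#' @param ... unused.
#' @return data frame with `risk`, `risk_pct`, `one_in` per row.
#' @export
predict.hfe_risk <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$frequencies
  stopifnot(all(c("p_c282y", "p_h63d") %in% names(newdata)))
  if (!"region" %in% names(newdata)) {
    newdata$region <- sprintf("row%d", seq_len(nrow(newdata)))
  }
  risk_table(newdata, object$penetrance)
}

#' @export
residuals.hfe_risk <- function(object, ...) {
  if (is.null(object$discrepancy)) {
    stop("no diagnosis data in the fit: residuals undefined", call. = FALSE)
  }
  d <- object$discrepancy
  # log observed prevalence minus log genetic risk: negative values mean
  # fewer diagnoses than the genetics predicts (candidate under-diagnosis)
  setNames(log(d$prevalence_pct) - log(d$risk_pct), d$region)
}

#' Simulate cohorts from a fitted risk model
#'
#' Parametric re-simulation: new cohorts are drawn from the fitted
#' per-region allele frequencies under triallelic HWE, with the fitted
#' region sizes.
#'
#' @param object an `hfe_risk` fit.
#' @param nsim number of cohorts.
#' @param seed integer seed (required for reproducibility).
#' @param ... unused.
#' @return a list of `nsim` `hfe_cohort` objects.
#' @export
simulate.hfe_risk <- function(object, nsim = 1, seed = 1L, ...) {
  f <- object$frequencies
  specs <- lapply(seq_len(nrow(f)), function(i) {
    region_spec(f$region[i], f$p_c282y[i], f$p_h63d[i], f$n[i])
  })
  lapply(seq_len(nsim), function(s) {
    simulate_genotypes(specs, seed = seed + s - 1L)
  })
}

#' Plot genetic risk against observed prevalence
#'
#' Scatter of combined genetic risk versus raw prevalence per region with
#' the identity line; regions flagged for under-diagnosis are highlighted.
#' Without diagnosis data, draws a barplot of regional risk.
#'
#' @param x an `hfe_risk` fit.
#' @param ... passed to the underlying plotting function.
#' @export
plot.hfe_risk <- function(x, ...) {
  if (is.null(x$discrepancy)) {
    graphics::barplot(x$risk$risk_pct, names.arg = x$risk$region,
                      las = 2, ylab = "combined genetic risk (%)", ...)
    return(invisible(x))
  }
  d <- x$discrepancy
  lim <- c(0, max(d$prevalence_pct, d$risk_pct) * 1.05)
  graphics::plot(d$prevalence_pct, d$risk_pct, xlim = lim, ylim = lim,
                 xlab = "raw prevalence (%)",
                 ylab = "combined genetic risk (%)",
                 pch = ifelse(d$flagged, 19, 1), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::text(d$prevalence_pct, d$risk_pct, d$region, pos = 4,
                 cex = 0.7)
  invisible(x)
}
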