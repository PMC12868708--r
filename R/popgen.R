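# Allele counting, frequency estimation, Hardy-Weinberg genotype
# prediction, and the chi-square tests used throughout the analysis.

#' Count minor alleles of one HFE variant
#'
#' @param cohort an `hfe_cohort`.
#' @param variant `"C282Y"` or `"H63D"`.
#' @param stratum a region label, or `"all"` for the whole cohort.
#' @return an `allele_counts` object: list with `stratum`, `variant`,
#'   `mac` (minor allele count) and `total_alleles` (2 x individuals).
#' @examples
#' cohort <- simulate_genotypes(region_spec("demo", 0.1, 0.1, 200), seed = 1)
#' count_alleles(cohort, "C282Y")
#' @export
count_alleles <- function(cohort, variant = c("C282Y", "H63D"),
                          stratum = "all") {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  if (!identical(stratum, "all")) {
    if (!stratum %in% cohort$region) {
      stop("unknown stratum: ", stratum, call. = FALSE)
    }
    cohort <- cohort[cohort$region == stratum, , drop = FALSE]
  }
  dose <- if (variant == "C282Y") C282Y_DOSE else H63D_DOSE
  gidx <- match(as.character(cohort$genotype), GENOTYPE_CLASSES)
  structure(
    list(stratum = stratum, variant = variant,
         mac = sum(dose[gidx]), total_alleles = 2L * nrow(cohort)),
    class = "allele_counts"
  )
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %s in %s: MAC %d / %d alleles (MAF %.4f)\n",
              x$variant, x$stratum, x$mac, x$total_alleles,
              x$mac / x$total_alleles))
  invisible(x)
}

#' Minor allele frequency from allele counts
#'
#' @param counts an `allele_counts` object, or a bare MAC (with `total`).
#' @param total total allele count when `counts` is numeric.
#' @return MAC / total alleles (full precision; tables print 4 decimals).
#' @examples
#' allele_frequency(63763, 817560)  # 0.0780 in the printed table
#' @export
allele_frequency <- function(counts, total = NULL) {
  if (inherits(counts, "allele_counts")) {
    mac <- counts$mac
    total <- counts$total_alleles
  } else {
    mac <- counts
  }
  stopifnot(is.numeric(mac), is.numeric(total), total > 0, mac >= 0,
            mac <= total)
  mac / total
}

#' Triallelic HFE allele frequencies
#'
#' @param p_c282y,p_h63d pathogenic allele frequencies; the wild-type
#'   frequency is their complement.
#' @return an `hfe_freq` object with `p_wt`, `p_c282y`, `p_h63d`.
#' @export
hfe_frequencies <- function(p_c282y, p_h63d) {
  stopifnot(p_c282y >= 0, p_c282y <= 1, p_h63d >= 0, p_h63d <= 1)
  if (p_c282y + p_h63d > 1) {
    stop("p_c282y + p_h63d > 1", call. = FALSE)
  }
  structure(list(p_wt = 1 - p_c282y - p_h63d,
                 p_c282y = p_c282y, p_h63d = p_h63d),
            class = "hfe_freq")
}

#' Estimate per-region allele frequencies from a cohort
#'
#' @param cohort an `hfe_cohort`.
#' @return data frame with columns `region`, `n`, `p_c282y`, `p_h63d`,
#'   one row per region, sorted by region name.
#' @export
estimate_frequencies <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  regions <- sort(unique(cohort$region))
  rows <- lapply(regions, function(r) {
    cc <- count_alleles(cohort, "C282Y", r)
    ch <- count_alleles(cohort, "H63D", r)
    data.frame(region = r, n = cc$total_alleles / 2L,
               p_c282y = allele_frequency(cc),
               p_h63d = allele_frequency(ch),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict risk-genotype frequencies under Hardy-Weinberg equilibrium
#'
#' The major risk genotype (C282Y homozygote) has frequency q^2; the
#' compound heterozygote 2 p_C p_H; prediction from allele frequencies is
#' far more precise than counting the rare observed homozygotes because it
#' borrows strength from the much more numerous heterozygotes.
#'
#' @param freqs an [hfe_frequencies()] object.
#' @return a `genotype_prediction`: list with `hom_c282y`, `cmpd_het`,
#'   `hom_h63d`, `one_in_hom` (formatted), and `class_probs` (all six
#'   genotype classes, summing to 1).
#' @examples
#' predict_genotypes(hfe_frequencies(0.0780, 0.1510))
#' @export
predict_genotypes <- function(freqs) {
  stopifnot(inherits(freqs, "hfe_freq"))
  probs <- genotype_class_probs(freqs$p_c282y, freqs$p_h63d)
  structure(
    list(hom_c282y = freqs$p_c282y^2,
         cmpd_het = 2 * freqs$p_c282y * freqs$p_h63d,
         hom_h63d = freqs$p_h63d^2,
         one_in_hom = format_one_in(freqs$p_c282y^2),
         class_probs = probs),
    class = "genotype_prediction"
  )
}

#' @export
print.genotype_prediction <- function(x, ...) {
  cat(sprintf(
    "<genotype_prediction> hom C282Y %.5f (one in %s), C282Y/H63D %.5f, hom H63D %.5f\n",
    x$hom_c282y, x$one_in_hom, x$cmpd_het, x$hom_h63d))
  invisible(x)
}

# observed 0/1/2-copy genotype counts of one variant, third allele
# collapsed into the reference class (biallelic view of the triallelic locus)
genotype_counts <- function(cohort, variant = c("C282Y", "H63D")) {
  variant <- match.arg(variant)
  dose <- if (variant == "C282Y") C282Y_DOSE else H63D_DOSE
  gidx <- match(as.character(cohort$genotype), GENOTYPE_CLASSES)
  counts <- tabulate(dose[gidx] + 1L, nbins = 3L)
  setNames(counts, c("ref/ref", "ref/alt", "alt/alt"))
}

hfe_test <- function(chi2, df, p_value, sided) {
  structure(list(chi2 = chi2, df = df, p_value = p_value, sided = sided),
            class = "hfe_test")
}

#' @export
print.hfe_test <- function(x, ...) {
  cat(sprintf("<hfe_test> chi2 = %.3f, df = %d, %s-sided p = %.4g\n",
              x$chi2, x$df, x$sided, x$p_value))
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit of observed 0/1/2-copy genotype counts against
#' the HWE expectation at the sample allele frequency; 1 degree of freedom
#' (one frequency estimated from three classes).
#'
#' @param obs integer vector of length 3: (hom-ref, het, hom-alt) counts;
#'   alternatively an `hfe_cohort` together with `variant`.
#' @param variant when `obs` is a cohort, which variant to test.
#' @return an `hfe_test` with `chi2`, `df = 1`, two-sided `p_value`.
#' @examples
#' hwe_chisq(c(25, 50, 25))  # exactly at HWE: chi2 = 0, p = 1
#' @export
hwe_chisq <- function(obs, variant = c("C282Y", "H63D")) {
  if (is.data.frame(obs)) obs <- genotype_counts(obs, match.arg(variant))
  stopifnot(is.numeric(obs), length(obs) == 3, all(obs >= 0))
  n <- sum(obs)
  if (n == 0) stop("no individuals", call. = FALSE)
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(expected == 0)) {
    stop("degenerate input: an expected genotype count is zero",
         call. = FALSE)
  }
  chi2 <- sum((obs - expected)^2 / expected)
  hfe_test(unname(chi2), 1L,
           unname(stats::pchisq(chi2, df = 1, lower.tail = FALSE)),
           "two")
}

#' One-sided comparison of allele frequencies between two strata
#'
#' 2x2 Pearson chi-square on allele counts (no continuity correction),
#' 1 degree of freedom.  The one-sided p-value is half the two-sided one
#' when the observed direction matches `alternative`, else its complement.
#'
#' @param a,b `allele_counts` objects.
#' @param alternative `"greater"` (frequency in `a` exceeds `b`),
#'   `"less"`, or `"two.sided"`.
#' @return an `hfe_test`.
#' @export
compare_frequencies_chisq <- function(a, b,
                                      alternative = c("greater", "less",
                                                      "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(a, "allele_counts"), inherits(b, "allele_counts"),
            a$total_alleles > 0, b$total_alleles > 0)
  tab <- rbind(c(a$mac, a$total_alleles - a$mac),
               c(b$mac, b$total_alleles - b$mac))
  if (any(colSums(tab) == 0)) {
    stop("degenerate input: a margin of the 2x2 table is zero",
         call. = FALSE)
  }
  chi2 <- unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE))$statistic)
  p2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fa <- a$mac / a$total_alleles
  fb <- b$mac / b$total_alleles
  if (alternative == "two.sided") {
    return(hfe_test(chi2, 1L, p2, "two"))
  }
  matches <- (alternative == "greater" && fa >= fb) ||
    (alternative == "less" && fa <= fb)
  p1 <- if (matches) p2 / 2 else 1 - p2 / 2
  hfe_test(chi2, 1L, p1, "one")
}

#' Combined allele frequency of aggregated ultra-rare variants
#'
#' @param macs minor allele counts of the individual variants.
#' @param total_alleles shared allele denominator.
#' @return sum(macs) / total_alleles; 0 for an empty list.
#' @export
aggregate_rare_af <- function(macs, total_alleles) {
  stopifnot(is.numeric(total_alleles), total_alleles > 0,
            all(macs >= 0))
  if (length(macs) == 0) return(0)
  sum(macs) / total_alleles
}

#' Compound-heterozygote rate of an aggregated rare allele with C282Y
#'
#' Under HWE the frequency of carrying one ultra-rare pathogenic allele
#' together with one C282Y allele is 2 * af_rare * p_c282y.
#'
#' @param af_rare combined rare allele frequency.
#' @param p_c282y C282Y allele frequency.
#' @return list with `rate`, `one_in` (round(1/rate)) and `label`
#'   (formatted, e.g. "33k").
#' @export
rare_with_c282y_rate <- function(af_rare, p_c282y) {
  stopifnot(af_rare >= 0, af_rare <= 1, p_c282y >= 0, p_c282y <= 1)
  rate <- 2 * af_rare * p_c282y
  list(rate = rate, one_in = one_in(rate), label = format_one_in(rate))
}
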