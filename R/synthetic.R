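# Synthetic cohort generator.  Individual-level biobank and EHR data for
# haemochromatosis are access-controlled, so the package ships a generator
# that reproduces the statistical structure the analysis assumes: triallelic
# Hardy-Weinberg genotypes at region-specific allele frequencies,
# penetrance- and ascertainment-driven diagnosis counts with disclosure
# rounding, Gaussian principal-component clouds, and identity-by-descent
# segment sharing with planted community structure.

#' Define a region or population group
#'
#' A region spec carries the allele frequencies of the two pathogenic HFE
#' variants, the cohort size, and the region-specific probability that a
#' clinically affected person actually receives the E83.1 diagnosis code
#' (ascertainment).
#'
#' @param name region/group label.
#' @param p_c282y allele frequency of p.Cys282Tyr in \[0, 1\].
#' @param p_h63d allele frequency of p.His63Asp in \[0, 1\].
#' @param n_individuals cohort size (positive integer).
#' @param ascertainment probability in \[0, 1\] that an affected person is
#'   coded E83.1; a modelling convenience, not an estimate from data.
#' @return an object of class `region_spec`.
#' @examples
#' region_spec("NW Irish", p_c282y = 0.136, p_h63d = 0.151, n_individuals = 1000)
#' @export
region_spec <- function(name, p_c282y, p_h63d, n_individuals,
                        ascertainment = 1) {
  stopifnot(
    is.character(name), length(name) == 1, nzchar(name),
    is.numeric(p_c282y), p_c282y >= 0, p_c282y <= 1,
    is.numeric(p_h63d), p_h63d >= 0, p_h63d <= 1,
    is.numeric(n_individuals), n_individuals >= 1,
    is.numeric(ascertainment), ascertainment >= 0, ascertainment <= 1
  )
  if (p_c282y + p_h63d > 1) {
    stop("invalid allele frequencies: p_c282y + p_h63d > 1 for region '",
         name, "'", call. = FALSE)
  }
  structure(
    list(name = name, p_c282y = p_c282y, p_h63d = p_h63d,
         n_individuals = as.integer(n_individuals),
         ascertainment = ascertainment),
    class = "region_spec"
  )
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf(
    "<region_spec> %s: p(C282Y) = %.4f, p(H63D) = %.4f, n = %d, ascertainment = %.2f\n",
    x$name, x$p_c282y, x$p_h63d, x$n_individuals, x$ascertainment))
  invisible(x)
}

# Six-class genotype probabilities of the triallelic locus under HWE.
# Order matches GENOTYPE_CLASSES.
genotype_class_probs <- function(p_c282y, p_h63d) {
  stopifnot(p_c282y >= 0, p_h63d >= 0, p_c282y + p_h63d <= 1)
  p_wt <- 1 - p_c282y - p_h63d
  c(
    "WT/WT"       = p_wt^2,
    "WT/C282Y"    = 2 * p_wt * p_c282y,
    "WT/H63D"     = 2 * p_wt * p_h63d,
    "C282Y/C282Y" = p_c282y^2,
    "C282Y/H63D"  = 2 * p_c282y * p_h63d,
    "H63D/H63D"   = p_h63d^2
  )
}

#' Simulate cohort genotypes under triallelic Hardy-Weinberg equilibrium
#'
#' Draws, for every region, genotype classes from the six-class multinomial
#' implied by the region's allele frequencies.  The two variants are
#' modelled as three alleles of one locus (no cis haplotype), so the
#' compound-heterozygote probability is exactly `2 * p_C * p_H`.
#'
#' @param specs a single [region_spec()] or a list of them.
#' @param seed integer seed; equal seeds give identical cohorts.
#' @return an `hfe_cohort`: a data frame with columns `id`, `region`,
#'   `genotype` (factor over the six classes).
#' @examples
#' cohort <- simulate_genotypes(
#'   region_spec("demo", 0.078, 0.151, 500), seed = 1)
#' table(cohort$genotype)
#' @export
simulate_genotypes <- function(specs, seed) {
  if (inherits(specs, "region_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "region_spec")))
  out <- with_seed(seed, {
    pieces <- lapply(specs, function(sp) {
      probs <- genotype_class_probs(sp$p_c282y, sp$p_h63d)
      counts <- as.vector(stats::rmultinom(1, sp$n_individuals, probs))
      g <- rep(GENOTYPE_CLASSES, counts)
      # random order so ids carry no genotype information
      g <- sample(g)
      data.frame(
        id = sprintf("%s_%06d", gsub("[^A-Za-z0-9]+", "-", sp$name),
                     seq_len(sp$n_individuals)),
        region = sp$name,
        genotype = factor(g, levels = GENOTYPE_CLASSES),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, pieces)
  })
  rownames(out) <- NULL
  class(out) <- c("hfe_cohort", "data.frame")
  out
}

#' Penetrance model for HFE risk genotypes
#'
#' Cumulative incidence of clinical haemochromatosis to age 80 by genotype.
#' Defaults are the male values: 0.56 for C282Y homozygotes and 0.06 for
#' C282Y/H63D compound heterozygotes.  No female default is provided, so a
#' female model must be specified explicitly.
#'
#' @param pen_hom_c282y penetrance of the C282Y homozygote.
#' @param pen_cmpd_het penetrance of the C282Y/H63D compound heterozygote.
#' @param label free-text label carried into every report.
#' @return an object of class `penetrance_model`.
#' @export
penetrance_model <- function(pen_hom_c282y = 0.56, pen_cmpd_het = 0.06,
                             label = "male, cumulative to age 80") {
  stopifnot(
    is.numeric(pen_hom_c282y), pen_hom_c282y >= 0, pen_hom_c282y <= 1,
    is.numeric(pen_cmpd_het), pen_cmpd_het >= 0, pen_cmpd_het <= 1,
    is.character(label), length(label) == 1
  )
  if (pen_hom_c282y < pen_cmpd_het) {
    warning("homozygote penetrance below compound-heterozygote penetrance",
            call. = FALSE)
  }
  structure(list(pen_hom_c282y = pen_hom_c282y,
                 pen_cmpd_het = pen_cmpd_het, label = label),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("<penetrance_model> %s: P(hom C282Y) = %.2f, P(C282Y/H63D) = %.2f\n",
              x$label, x$pen_hom_c282y, x$pen_cmpd_het))
  invisible(x)
}

# per-class penetrance vector; only the two named risk genotypes carry risk
class_penetrance <- function(pen) {
  p <- setNames(numeric(length(GENOTYPE_CLASSES)), GENOTYPE_CLASSES)
  p["C282Y/C282Y"] <- pen$pen_hom_c282y
  p["C282Y/H63D"]  <- pen$pen_cmpd_het
  p
}

#' Simulate a diagnosis-count registry
#'
#' Each individual is coded E83.1 independently with probability
#' `penetrance(genotype) * ascertainment(region)`.  Per-region counts are
#' optionally rounded to the nearest multiple of 5, emulating the
#' disclosure-control convention of national EHR feasibility counts.
#'
#' @param cohort an `hfe_cohort`.
#' @param penetrance a [penetrance_model()].
#' @param specs region specs supplying per-region ascertainment; every
#'   cohort region must be covered.
#' @param round_to_5 round counts to increments of 5 (default `TRUE`).
#' @param seed integer seed.
#' @return a `diagnosis_table`: data frame with columns `stratum`, `count`,
#'   `denominator`.
#' @export
simulate_diagnoses <- function(cohort, penetrance, specs,
                               round_to_5 = TRUE, seed) {
  stopifnot(inherits(cohort, "hfe_cohort"),
            inherits(penetrance, "penetrance_model"))
  if (inherits(specs, "region_spec")) specs <- list(specs)
  asc <- setNames(
    vapply(specs, function(s) s$ascertainment, numeric(1)),
    vapply(specs, function(s) s$name, character(1))
  )
  missing_regions <- setdiff(unique(cohort$region), names(asc))
  if (length(missing_regions)) {
    stop("no region spec for: ", paste(missing_regions, collapse = ", "),
         call. = FALSE)
  }
  pen_by_class <- class_penetrance(penetrance)
  prob <- pen_by_class[as.character(cohort$genotype)] * asc[cohort$region]
  coded <- with_seed(seed, stats::rbinom(nrow(cohort), 1, prob))
  counts <- tapply(coded, cohort$region, sum)
  denom <- tapply(coded, cohort$region, length)
  stratum <- sort(names(counts))
  n <- as.integer(counts[stratum])
  if (round_to_5) n <- pmin(round_nearest_5(n), as.integer(denom[stratum]))
  out <- data.frame(stratum = stratum, count = n,
                    denominator = as.integer(denom[stratum]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("diagnosis_table", "data.frame")
  out
}

#' Simulate labelled principal-component clouds
#'
#' Isotropic Gaussian point clouds, one per population group, plus optional
#' uniform background noise, as a fixture for density-based ancestry
#' cluster selection on top-2 PC coordinates.
#'
#' @param groups data frame with columns `label`, `cx`, `cy`, `sd`, `n`.
#' @param noise_n number of uniform noise points (labelled `"noise"`).
#' @param noise_box bounds `c(xmin, xmax, ymin, ymax)` for the noise.
#' @param seed integer seed.
#' @return data frame with columns `id`, `pc1`, `pc2`, `declared_group`.
#' @export
simulate_pc_cloud <- function(groups, noise_n = 0,
                              noise_box = c(-10, 10, -10, 10), seed) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("label", "cx", "cy", "sd", "n") %in% names(groups)),
            all(groups$sd > 0), all(groups$n >= 1),
            noise_n >= 0, length(noise_box) == 4)
  with_seed(seed, {
    pts <- lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      data.frame(
        pc1 = stats::rnorm(g$n, g$cx, g$sd),
        pc2 = stats::rnorm(g$n, g$cy, g$sd),
        declared_group = g$label, stringsAsFactors = FALSE
      )
    })
    if (noise_n > 0) {
      pts <- c(pts, list(data.frame(
        pc1 = stats::runif(noise_n, noise_box[1], noise_box[2]),
        pc2 = stats::runif(noise_n, noise_box[3], noise_box[4]),
        declared_group = "noise", stringsAsFactors = FALSE
      )))
    }
    out <- do.call(rbind, pts)
    out <- cbind(id = sprintf("P%05d", seq_len(nrow(out))), out)
    out$id <- as.character(out$id)
    rownames(out) <- NULL
    out
  })
}

# default segment-length law: exponential (rate 0.25 / cM) truncated to the
# open interval (3, 30) cM, the decay shape typical of within-population IBD
default_length_law <- function(n) {
  rate <- 0.25
  lo <- stats::pexp(3, rate)
  hi <- stats::pexp(30, rate)
  stats::qexp(stats::runif(n, lo, hi), rate)
}

#' Simulate identity-by-descent segments with planted communities
#'
#' Per pair of individuals the number of shared segments is Poisson with
#' rate `within_rate` (same community) or `between_rate` (different
#' communities); lengths are drawn from `length_law`, supported on the open
#' interval (3, 30) cM so that every simulated segment survives the
#' analysis filter.
#'
#' @param communities data frame with columns `label`, `n`, or a named
#'   integer vector of community sizes.
#' @param within_rate expected segments per within-community pair.
#' @param between_rate expected segments per between-community pair; must
#'   not exceed `within_rate`.
#' @param length_law function `n -> n segment lengths` in (3, 30); default
#'   a truncated exponential.
#' @param seed integer seed.
#' @return list with `segments` (data frame `id_a`, `id_b`, `length_cm`)
#'   and `membership` (named character: planted community per individual).
#' @export
simulate_ibd_segments <- function(communities, within_rate, between_rate,
                                  length_law = default_length_law, seed) {
  if (!is.data.frame(communities)) {
    communities <- data.frame(label = names(communities),
                              n = as.integer(communities),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "n") %in% names(communities)),
            all(communities$n >= 1),
            within_rate > between_rate, between_rate >= 0,
            is.function(length_law))
  memb <- rep(communities$label, communities$n)
  ids <- sprintf("I%05d", seq_along(memb))
  names(memb) <- ids
  n <- length(ids)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- memb[pair[, 1]] == memb[pair[, 2]]
  rate <- ifelse(same, within_rate, between_rate)
  with_seed(seed, {
    k <- stats::rpois(nrow(pair), rate)
    idx <- rep.int(seq_len(nrow(pair)), k)
    segments <- data.frame(
      id_a = ids[pair[idx, 1]],
      id_b = ids[pair[idx, 2]],
      length_cm = length_law(length(idx)),
      stringsAsFactors = FALSE
    )
    list(segments = segments, membership = memb)
  })
}
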