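make_cohort <- function(genos, region = "r") {
  out <- data.frame(
    id = sprintf("s%02d", seq_along(genos)), region = region,
    genotype = factor(genos, levels = hfeRisk:::GENOTYPE_CLASSES),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hfe_cohort", "data.frame")
  out
}

test_that("allele counting matches hand counts", {
  cohort <- make_cohort(c("C282Y/C282Y", "WT/C282Y", "WT/WT"))
  cc <- count_alleles(cohort, "C282Y")
  expect_equal(cc$mac, 3)
  expect_equal(cc$total_alleles, 6L)
  expect_equal(count_alleles(cohort, "H63D")$mac, 0)
  expect_error(count_alleles(cohort, "C282Y", "nowhere"), "unknown stratum")
})

test_that("allele frequencies reproduce printed table rows", {
  expect_equal(round(allele_frequency(63763, 817560), 4), 0.0780)
  expect_equal(round(allele_frequency(34, 4342), 4), 0.0078)
  expect_equal(allele_frequency(0, 100), 0)
})

test_that("HWE genotype prediction and one-in formatting", {
  g <- predict_genotypes(hfe_frequencies(0.0780, 0.1510))
  expect_equal(g$hom_c282y, 0.0780^2)
  expect_equal(g$cmpd_het, 2 * 0.0780 * 0.1510)
  expect_equal(g$cmpd_het, 0.023556)
  expect_equal(g$one_in_hom, "164")

  zero <- predict_genotypes(hfe_frequencies(0, 0.1))
  expect_equal(zero$hom_c282y, 0)
  expect_equal(zero$one_in_hom, "Inf")
  expect_equal(one_in(0), Inf)
})

test_that("six predicted genotype-class frequencies always sum to one", {
  set.seed(31)
  for (i in 1:50) {
    pc <- runif(1)
    ph <- runif(1, 0, 1 - pc)
    probs <- predict_genotypes(hfe_frequencies(pc, ph))$class_probs
    expect_equal(sum(probs), 1)
  }
})

test_that("one-in labels use the printed k/M convention", {
  expect_equal(format_one_in(0.0192^2), "2.7k")
  expect_equal(format_one_in(0.0124^2), "6.5k")
  expect_equal(format_one_in((3 / 1308)^2), "190k")
  expect_equal(format_one_in(0.0010^2), "1M")
  expect_equal(format_one_in((2 / 4488)^2), "5M")
  expect_equal(format_one_in(0.5), "2")
})

test_that("HWE chi-square equals the direct formula and handles edge cases", {
  expect_equal(hwe_chisq(c(25, 50, 25))$chi2, 0)
  expect_equal(hwe_chisq(c(25, 50, 25))$p_value, 1)

  obs <- c(30, 40, 30)
  t <- hwe_chisq(obs)
  expect_equal(t$chi2, hwe_oracle(obs))
  expect_equal(t$df, 1L)
  expect_equal(t$p_value, pchisq(t$chi2, 1, lower.tail = FALSE))

  set.seed(32)
  for (i in 1:25) {
    obs <- as.vector(rmultinom(1, 200, c(0.5, 0.35, 0.15)))
    expect_equal(hwe_chisq(obs)$chi2, hwe_oracle(obs))
  }
  expect_error(hwe_chisq(c(10, 0, 0)), "degenerate")
})

test_that("cohort-level HWE test uses the biallelic collapse", {
  cohort <- make_cohort(c(rep("WT/WT", 10), rep("WT/C282Y", 8),
                          rep("C282Y/C282Y", 2), rep("WT/H63D", 5)))
  # H63D carriers collapse into the 0-copy class for the C282Y test
  t <- hwe_chisq(cohort, "C282Y")
  expect_equal(t$chi2, hwe_oracle(c(15, 8, 2)))
})

test_that("two-stratum allele comparison matches the 2x2 oracle", {
  a <- structure(list(stratum = "a", variant = "C282Y", mac = 20,
                      total_alleles = 200), class = "allele_counts")
  b <- structure(list(stratum = "b", variant = "C282Y", mac = 10,
                      total_alleles = 200), class = "allele_counts")
  t <- compare_frequencies_chisq(a, b, "greater")
  tab <- rbind(c(20, 180), c(10, 190))
  expect_equal(t$chi2, chisq_2x2_oracle(tab))
  expect_equal(t$p_value,
               pchisq(t$chi2, 1, lower.tail = FALSE) / 2)

  # swapping the samples under the same alternative maps p to 1 - p
  t_rev <- compare_frequencies_chisq(b, a, "greater")
  expect_equal(t_rev$p_value, 1 - t$p_value)

  # identical tables: chi2 = 0, one-sided p = 0.5
  t_eq <- compare_frequencies_chisq(a, a, "greater")
  expect_equal(t_eq$chi2, 0)
  expect_equal(t_eq$p_value, 0.5)

  # chi-square scales with n (approximately exactly for proportional counts)
  a2 <- a; a2$mac <- 40; a2$total_alleles <- 400
  b2 <- b; b2$mac <- 20; b2$total_alleles <- 400
  t2 <- compare_frequencies_chisq(a2, b2, "greater")
  expect_equal(t2$chi2, 2 * t$chi2)
})

test_that("ultra-rare aggregation and compound-het rate with C282Y", {
  expect_equal(aggregate_rare_af(c(100, 101), 980944), 201 / 980944)
  expect_equal(aggregate_rare_af(integer(0), 10), 0)
  expect_equal(aggregate_rare_af(34, 4342), allele_frequency(34, 4342))

  r <- rare_with_c282y_rate(201 / 980944, 71949 / 980944)
  expect_equal(r$rate, 2 * (201 / 980944) * (71949 / 980944))
  expect_equal(rare_with_c282y_rate(0, 0.1)$rate, 0)
  # linearity in the rare frequency
  expect_equal(rare_with_c282y_rate(2e-4, 0.08)$rate,
               2 * rare_with_c282y_rate(1e-4, 0.08)$rate)
})

test_that("frequency estimation recovers simulation parameters (3 SE)", {
  specs <- list(region_spec("a", 0.10, 0.15, 10000),
                region_spec("b", 0.05, 0.18, 10000))
  fr <- estimate_frequencies(simulate_genotypes(specs, seed = 33))
  for (i in 1:2) {
    p0 <- c(0.10, 0.05)[i]
    se <- sqrt(p0 * (1 - p0) / 20000)
    expect_lt(abs(fr$p_c282y[i] - p0), 3 * se)
    q2_se <- 2 * p0 * se  # delta method on p^2
    expect_lt(abs(fr$p_c282y[i]^2 - p0^2), 3 * q2_se)
  }
})
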