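test_that("degenerate allele frequencies give degenerate cohorts", {
  all_hom <- simulate_genotypes(region_spec("x", 1, 0, 50), seed = 1)
  expect_equal(nrow(all_hom), 50)
  expect_true(all(all_hom$genotype == "C282Y/C282Y"))

  all_wt <- simulate_genotypes(region_spec("x", 0, 0, 50), seed = 1)
  expect_true(all(all_wt$genotype == "WT/WT"))
})

test_that("invalid frequencies are rejected at spec construction", {
  expect_error(region_spec("x", 0.6, 0.5, 10), "p_c282y \\+ p_h63d > 1")
})

test_that("simulated allele frequency recovers the input within 3 SE", {
  sp <- region_spec("big", 0.078, 0.151, 100000)
  cohort <- simulate_genotypes(sp, seed = 2)
  phat <- allele_frequency(count_alleles(cohort, "C282Y"))
  se <- sqrt(0.078 * (1 - 0.078) / 200000)
  expect_lt(abs(phat - 0.078), 3 * se)
})

test_that("equal seeds reproduce identical cohorts, different seeds differ", {
  specs <- demo_specs(500)
  a <- simulate_genotypes(specs, seed = 9)
  b <- simulate_genotypes(specs, seed = 9)
  c <- simulate_genotypes(specs, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$genotype, c$genotype))
})

test_that("genotype draws follow the six-class multinomial (chi-square GOF)", {
  # non-rejection rate of a GOF test across replicates should sit near 95%
  probs <- predict_genotypes(hfe_frequencies(0.1, 0.2))$class_probs
  reject <- vapply(1:200, function(s) {
    cohort <- simulate_genotypes(region_spec("x", 0.1, 0.2, 600), seed = s)
    obs <- table(cohort$genotype)
    suppressWarnings(stats::chisq.test(obs, p = probs)$p.value) < 0.05
  }, logical(1))
  expect_gt(mean(!reject), 0.90)
})

test_that("diagnosis simulation honours penetrance and ascertainment", {
  specs <- list(region_spec("z", 0.3, 0.2, 400, ascertainment = 0))
  cohort <- simulate_genotypes(specs, seed = 3)
  none <- simulate_diagnoses(cohort, penetrance_model(), specs,
                             round_to_5 = FALSE, seed = 4)
  expect_equal(none$count, 0L)

  # full penetrance for homozygotes only, full ascertainment: count equals
  # the number of C282Y homozygotes exactly
  specs1 <- list(region_spec("z", 0.3, 0.2, 400, ascertainment = 1))
  pen <- penetrance_model(1, 0, label = "hom only")
  all_hom <- simulate_diagnoses(cohort, pen, specs1, round_to_5 = FALSE,
                                seed = 5)
  expect_equal(all_hom$count, sum(cohort$genotype == "C282Y/C282Y"))
})

test_that("rounding to 5 moves no count by more than 2.5", {
  specs <- demo_specs(3000, asc = 0.8)
  cohort <- simulate_genotypes(specs, seed = 6)
  raw <- simulate_diagnoses(cohort, penetrance_model(), specs,
                            round_to_5 = FALSE, seed = 7)
  rounded <- simulate_diagnoses(cohort, penetrance_model(), specs,
                                round_to_5 = TRUE, seed = 7)
  expect_true(all(rounded$count %% 5 == 0))
  expect_true(all(abs(rounded$count - raw$count) <= 2.5))
})

test_that("PC cloud generator labels groups and is deterministic", {
  g <- data.frame(label = "A", cx = 0, cy = 0, sd = 1, n = 30)
  pts <- simulate_pc_cloud(g, noise_n = 0, seed = 8)
  expect_equal(nrow(pts), 30)
  expect_true(all(pts$declared_group == "A"))
  expect_identical(pts, simulate_pc_cloud(g, noise_n = 0, seed = 8))

  noisy <- simulate_pc_cloud(g, noise_n = 10, seed = 8)
  expect_equal(sum(noisy$declared_group == "noise"), 10)
})

test_that("IBD segment lengths live strictly inside (3, 30) cM", {
  sim <- simulate_ibd_segments(c(A = 20, B = 20), within_rate = 1,
                               between_rate = 0.1, seed = 9)
  expect_true(all(sim$segments$length_cm > 3))
  expect_true(all(sim$segments$length_cm < 30))
  expect_equal(length(sim$membership), 40)
})

test_that("zero between-rate yields no inter-community edges downstream", {
  sim <- simulate_ibd_segments(c(A = 15, B = 15), within_rate = 1.5,
                               between_rate = 0, seed = 10)
  g <- build_ibd_graph(sim$segments)
  crossing <- sim$membership[g$edges$from] != sim$membership[g$edges$to]
  expect_equal(sum(crossing), 0)
})
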