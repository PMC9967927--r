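test_that("with no differentiation or inbreeding, sampled frequencies track ancestral", {
  cfg <- simulation_config(n_populations = 1, n_per_population = 500,
                           n_snp = 6, n_ssr = 0, fst = 0, inbreeding_f = 0,
                           missing_rate = 0, depth_mean = NULL, seed = 42)
  sim <- simulate_panel(cfg)
  freqs <- allele_frequencies(sim$matrix)
  for (loc in loci(sim$matrix)$locus) {
    anc <- sim$truth$ancestral_frequencies[[loc]]
    for (a in names(anc)) {
      obs <- freqs$freq[freqs$locus == loc & freqs$allele == a]
      if (!length(obs)) obs <- 0
      se <- sqrt(anc[[a]] * (1 - anc[[a]]) / (2 * 500))
      expect_lt(abs(obs - anc[[a]]), 3 * se + 1e-12)
    }
  }
})

test_that("complete inbreeding yields zero heterozygotes", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 50,
                           n_snp = 20, n_ssr = 2, inbreeding_f = 1,
                           naf_per_ssr_locus = 0, missing_rate = 0,
                           depth_mean = NULL, seed = 5)
  sim <- simulate_panel(cfg)
  cm <- calls(sim$matrix)
  called <- cm[!is.na(cm$a1), ]
  expect_true(all(called$a1 == called$a2))
})

test_that("the default configuration reproduces the study panel shape", {
  sim <- simulate_panel(simulation_config(seed = 2))
  expect_equal(n_individuals(sim$matrix), 180)
  expect_equal(n_loci(sim$matrix), 228)
  expect_equal(sum(loci(sim$matrix)$kind == "SNP"), 220)
  expect_equal(sum(loci(sim$matrix)$kind == "SSR"), 8)
  expect_equal(length(population_codes(sim$popmap)), 12)
  expect_true(all(table(sim$popmap$population) == 15))
  # truth frequency vectors are proper simplexes
  all_freqs <- unlist(lapply(sim$truth$population_frequencies,
                             function(pf) vapply(pf, sum, numeric(1))))
  expect_true(all(abs(all_freqs - 1) < 1e-9))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 10,
                           n_snp = 10, n_ssr = 3, seed = 99)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth, s2$truth)
})

test_that("null-allele overlay at r = 0 is the identity and preserves shape", {
  cfg <- simulation_config(n_populations = 2, n_per_population = 20,
                           n_snp = 5, n_ssr = 3, naf_per_ssr_locus = 0,
                           missing_rate = 0, depth_mean = NULL, seed = 8)
  sim <- simulate_panel(cfg)
  out <- apply_null_alleles(sim$matrix, sim$truth, naf = c(0, 0, 0), seed = 1)
  expect_same_matrix(sim$matrix, out)

  out2 <- apply_null_alleles(sim$matrix, sim$truth, naf = c(0.3, 0.3, 0.3), seed = 1)
  expect_equal(n_individuals(out2), n_individuals(sim$matrix))
  expect_equal(n_loci(out2), n_loci(sim$matrix))
  # only SSR loci may change
  snp_loci <- loci(sim$matrix)$locus[loci(sim$matrix)$kind == "SNP"]
  expect_same_matrix(select_loci(sim$matrix, snp_loci), select_loci(out2, snp_loci))
})

test_that("null alleles create the closed-form heterozygote deficit", {
  # r = 0.25, f = 0, 1 SSR locus with 4 visible alleles, n = 1000:
  # visible-genotype het among called = ((1-r)^2 - sum(q^2)) / (1 - r^2)
  r <- 0.25
  cfg <- simulation_config(n_populations = 1, n_per_population = 1000,
                           n_snp = 0, n_ssr = 1, fst = 0, inbreeding_f = 0,
                           naf_per_ssr_locus = r, ssr_allele_counts = 4,
                           missing_rate = 0, depth_mean = NULL, seed = 21)
  sim <- simulate_panel(cfg)
  loc <- loci(sim$matrix)$locus[1]
  q_vis <- sim$truth$population_frequencies[[1]][[loc]] * (1 - r)
  expected_het <- ((1 - r)^2 - sum(q_vis^2)) / (1 - r^2)
  ho <- observed_heterozygosity(sim$matrix, loc)
  expect_lt(abs(ho - expected_het), 0.05)
  # heterozygote deficit relative to He from apparent frequencies
  f <- allele_frequencies(sim$matrix, locus = loc)
  he_apparent <- expected_heterozygosity(f$freq)
  expect_lt(ho, he_apparent)
  # near-total nulls leave almost everything missing
  ext <- apply_null_alleles(sim$matrix, sim$truth, naf = 0.995, seed = 4)
  expect_gt(mean(is.na(calls(ext)$a1[calls(ext)$locus == loc])), 0.95)
})

test_that("missingness overlay is calibrated, deterministic, and identity at 0", {
  cfg <- simulation_config(n_populations = 1, n_per_population = 100,
                           n_snp = 100, n_ssr = 0, missing_rate = 0,
                           depth_mean = NULL, seed = 13)
  sim <- simulate_panel(cfg)
  expect_same_matrix(sim$matrix, apply_missingness(sim$matrix, 0, seed = 1))
  m1 <- apply_missingness(sim$matrix, 0.5, seed = 7)
  m2 <- apply_missingness(sim$matrix, 0.5, seed = 7)
  expect_identical(m1, m2)
  frac <- mean(is.na(calls(m1)$a1))
  expect_gte(frac, 0.48) # binomial bound on 10,000 calls
  expect_lte(frac, 0.52)
  expect_error(apply_missingness(sim$matrix, 1), "rate")
})

test_that("contig fixtures carry the planted repeats at recorded positions", {
  fx <- make_contig_fixtures(
    3,
    tibble::tibble(motif = c("AAC", "T", "CTGCA"), repeats = c(6, 10, 4),
                   left = c(80, 40, 75), right = c(80, 40, 75)),
    seed = 31
  )
  expect_equal(length(fx$sequences), 3)
  s1 <- fx$sequences[[1]]
  expect_equal(substr(s1, fx$truth$start[1], fx$truth$end[1]), strrep("AAC", 6))
  expect_equal(substr(fx$sequences[[2]], fx$truth$start[2], fx$truth$end[2]),
               strrep("T", 10))
  empty <- make_contig_fixtures(0, tibble::tibble(motif = "A", repeats = 10,
                                                  left = 1, right = 1))
  expect_equal(length(empty$sequences), 0)
  expect_equal(nrow(empty$truth), 0)
  # FASTA round trip of the fixture set
  fa <- tempfile(fileext = ".fasta")
  write_fasta(fx$sequences, fa)
  expect_identical(unname(read_fasta(fa)), unname(fx$sequences))
})

test_that("simulated panels recover their generative Fis", {
  # no inbreeding: per-population mean Fis near 0 despite strong drift
  reps <- vapply(1:3, function(s) {
    cfg <- simulation_config(n_populations = 4, n_per_population = 30,
                             n_snp = 200, n_ssr = 0, fst = 0.3, inbreeding_f = 0,
                             missing_rate = 0, depth_mean = NULL, seed = 100 + s)
    sim <- simulate_panel(cfg)
    pt <- population_summary_table(sim$matrix, sim$popmap, mean_row = FALSE)
    mean(pt$fis)
  }, numeric(1))
  expect_true(all(abs(reps) < 0.08))

  # strong inbreeding at large n: mean per-locus Fis near 0.3
  cfg <- simulation_config(n_populations = 1, n_per_population = 250,
                           n_snp = 200, n_ssr = 0, fst = 0.01, inbreeding_f = 0.3,
                           missing_rate = 0, depth_mean = NULL, seed = 77)
  sim <- simulate_panel(cfg)
  ls <- locus_summary(sim$matrix)
  expect_lt(abs(mean(ls$fis, na.rm = TRUE) - 0.3), 0.05)
})

test_that("invalid generator settings are rejected", {
  expect_error(simulation_config(fst = 1), "fst")
  expect_error(simulation_config(n_snp = -1), "n_snp")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(naf_per_ssr_locus = 1), "null allele")
})
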