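test_that("allele frequencies count called genotypes only", {
  gm <- geno_matrix(tibble::tibble(
    individual = c("w1", "w2", "w3"), locus = "L",
    a1 = c("A", "A", NA), a2 = c("A", "T", NA)
  ))
  f <- allele_frequencies(gm, locus = "L")
  expect_equal(f$freq[f$allele == "A"], 0.75)
  expect_equal(f$freq[f$allele == "T"], 0.25)
  expect_equal(unique(f$n_called), 2L)

  all_missing <- geno_matrix(tibble::tibble(
    individual = c("w1", "w2"), locus = "L",
    a1 = NA_character_, a2 = NA_character_
  ), loci = tibble::tibble(locus = "L", kind = "SNP", alleles = list(c("A", "T"))))
  expect_equal(nrow(allele_frequencies(all_missing)), 0)
})

test_that("PIC matches direct evaluation of the Botstein double sum", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
})

test_that("expected heterozygosity is the gene-diversity formula", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(c(0.7, 0.2, 0.1)), 0.46)
})

test_that("PIC never exceeds He and both peak at p = 0.5 for biallelic loci", {
  set.seed(424)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    p <- stats::rexp(k)
    p <- p / sum(p)
    expect_lte(pic(p), expected_heterozygosity(p) + 1e-12)
    expect_gte(pic(p), 0)
  }
  grid <- seq(0.01, 0.99, by = 0.01)
  pics <- vapply(grid, function(q) pic(c(q, 1 - q)), numeric(1))
  hes <- vapply(grid, function(q) expected_heterozygosity(c(q, 1 - q)), numeric(1))
  expect_equal(grid[which.max(pics)], 0.5)
  expect_equal(max(pics), 0.375)
  expect_equal(max(hes), 0.5)
})

test_that("observed heterozygosity and Fis follow the defining ratios", {
  gm <- geno_matrix(tibble::tibble(
    individual = c("w1", "w2"), locus = "L",
    a1 = c("A", "A"), a2 = c("T", "A")
  ))
  expect_equal(observed_heterozygosity(gm, "L"), 0.5)
  hom <- geno_matrix(tibble::tibble(
    individual = c("w1", "w2"), locus = "L", a1 = "A", a2 = "A"
  ))
  expect_equal(observed_heterozygosity(hom, "L"), 0)

  expect_equal(fis(0.5, 0.5), 0)
  expect_equal(fis(0.5, 0.3), 0.4)
  expect_true(is.na(fis(0, 0)))
})

test_that("locus summaries match hand tallies and the brute-force oracle", {
  mono <- geno_matrix(tibble::tibble(
    individual = c("w1", "w2"), locus = "L", a1 = "A", a2 = "A"
  ))
  ms <- locus_summary(mono)
  expect_equal(ms$maf, 1)
  expect_equal(ms$n_alleles, 1L)
  expect_equal(ms$n_genotypes, 1L)
  expect_equal(ms$he, 0)
  expect_equal(ms$ho, 0)
  expect_equal(ms$pic, 0)
  expect_true(is.na(ms$fis))

  toy <- geno_matrix(tibble::tibble(
    individual = c("w1", "w2"), locus = "S",
    a1 = c("124", "124"), a2 = c("136", "124")
  ))
  ts <- locus_summary(toy)
  expect_equal(ts$maf, 0.75)
  expect_equal(ts$n_alleles, 2L)
  expect_equal(ts$n_genotypes, 2L)
  expect_equal(ts$ho, 0.5)

  # exhaustive cross-check on simulated panels up to 20 x 10
  for (s in 1:3) {
    cfg <- simulation_config(n_populations = 2, n_per_population = 10,
                             n_snp = 6, n_ssr = 4, missing_rate = 0.1,
                             naf_per_ssr_locus = c(0.2, 0, 0.3, 0.1),
                             depth_mean = NULL, seed = 300 + s)
    sim <- simulate_panel(cfg)
    ls <- locus_summary(sim$matrix)
    for (loc in loci(sim$matrix)$locus) {
      bf <- bf_locus_stats(genotype_list(sim$matrix, loc))
      row <- ls[ls$locus == loc, ]
      expect_equal(row$n_called, bf$n_called)
      if (bf$n_called > 0) {
        expect_equal(row$maf, bf$maf)
        expect_equal(row$n_alleles, as.integer(bf$n_alleles))
        expect_equal(row$n_genotypes, as.integer(bf$n_genotypes))
        expect_equal(row$he, bf$he)
        expect_equal(row$ho, bf$ho)
        expect_equal(row$pic, bf$pic)
        if (is.na(bf$fis)) expect_true(is.na(row$fis)) else expect_equal(row$fis, bf$fis)
      }
    }
  }
})

test_that("population summaries aggregate per-locus statistics correctly", {
  # single population, single diallelic locus at Hardy-Weinberg counts
  gm <- geno_matrix(tibble::tibble(
    individual = sprintf("w%d", 1:16), locus = "L",
    a1 = c(rep("A", 12), rep("T", 4)),
    a2 = c(rep("A", 4), rep("T", 12))
  ))
  pm <- pop_map(tibble::tibble(individual = sprintf("w%d", 1:16), population = "P1"))
  pt <- population_summary_table(gm, pm, mean_row = FALSE)
  ls <- locus_summary(gm, scope = "P1", popmap = pm)
  expect_equal(pt$maf, ls$maf)
  expect_equal(pt$he, ls$he)
  expect_equal(pt$ho, ls$ho)
  expect_equal(pt$fis, ls$fis)
  expect_equal(pt$n, 16L)

  # grand Mean row equals arithmetic column means
  cfg <- simulation_config(n_populations = 4, n_per_population = 12, n_snp = 20,
                           n_ssr = 0, missing_rate = 0.02, depth_mean = NULL,
                           seed = 55)
  sim <- simulate_panel(cfg)
  full <- population_summary_table(sim$matrix, sim$popmap)
  body <- full[full$population != "Mean", ]
  mrow <- full[full$population == "Mean", ]
  for (col in c("maf", "n_alleles", "he", "ho", "pic", "fis")) {
    expect_equal(mrow[[col]], mean(body[[col]]))
  }
})

test_that("panels simulated without inbreeding give near-zero population Fis", {
  cfg <- simulation_config(n_populations = 4, n_per_population = 30, n_snp = 150,
                           n_ssr = 0, fst = 0.05, inbreeding_f = 0,
                           missing_rate = 0, depth_mean = NULL, seed = 400)
  sim <- simulate_panel(cfg)
  pt <- population_summary_table(sim$matrix, sim$popmap, mean_row = FALSE)
  expect_true(all(abs(pt$fis) < 0.1))
})

test_that("the Hardy-Weinberg permutation test is calibrated and detects excess", {
  # genotype counts at exact HW proportions: p = 0.5, n = 100 -> 25/50/25
  gm <- geno_matrix(tibble::tibble(
    individual = sprintf("w%03d", 1:100), locus = "L",
    a1 = c(rep("A", 75), rep("T", 25)),
    a2 = c(rep("A", 25), rep("T", 75))
  ))
  ps <- vapply(1:10, function(s) hwe_test(gm, "L", n_permutations = 2000, seed = s),
               numeric(1))
  expect_gte(mean(ps > 0.05), 0.99)

  # 50 individuals all heterozygous: extreme excess
  het <- geno_matrix(tibble::tibble(
    individual = sprintf("w%02d", 1:50), locus = "L", a1 = "A", a2 = "T"
  ))
  expect_lte(hwe_test(het, "L", n_permutations = 10000, seed = 1), 0.001)

  mono <- geno_matrix(tibble::tibble(
    individual = c("w1", "w2", "w3"), locus = "L", a1 = "A", a2 = "A"
  ))
  expect_true(is.na(hwe_test(mono, "L", seed = 1)))
})

test_that("dosage-collapse LD is 1 for duplicated loci and near 0 for independent ones", {
  cfg <- simulation_config(n_populations = 1, n_per_population = 500, n_snp = 12,
                           n_ssr = 0, fst = 0, missing_rate = 0,
                           depth_mean = NULL, seed = 62)
  sim <- simulate_panel(cfg)
  cm <- calls(sim$matrix)
  first <- loci(sim$matrix)$locus[1]
  dup <- cm[cm$locus == first, ]
  dup$locus <- "DUP"
  gm2 <- geno_matrix(dplyr::bind_rows(cm, dup))
  expect_equal(ld_r2(gm2, first, "DUP"), 1)

  lsum <- locus_summary(sim$matrix)
  poly <- lsum$locus[lsum$he > 0.1]
  pairs <- utils::combn(poly[1:min(6, length(poly))], 2)
  r2 <- apply(pairs, 2, function(pr) ld_r2(sim$matrix, pr[1], pr[2]))
  expect_gte(mean(r2 < 0.05), 0.95)

  # constant dosage is flagged undefined
  const <- geno_matrix(tibble::tibble(
    individual = rep(c("w1", "w2"), 2), locus = rep(c("L1", "L2"), each = 2),
    a1 = c("A", "A", "A", "A"), a2 = c("A", "A", "A", "T")
  ))
  expect_true(is.na(ld_r2(const, "L1", "L2")))
})
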