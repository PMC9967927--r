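# 48-sample single-locus panels with controlled call and depth patterns
make_filter_panel <- function(n_called, n_total = 48, het = 10, depth = 20L) {
  ids <- sprintf("s%02d", seq_len(n_total))
  a1 <- rep(NA_character_, n_total)
  a2 <- rep(NA_character_, n_total)
  if (n_called > 0) {
    a1[seq_len(n_called)] <- "A"
    a2[seq_len(n_called)] <- "A"
    if (het > 0) a2[seq_len(min(het, n_called))] <- "T"
  }
  geno_matrix(tibble::tibble(
    individual = ids, locus = "L1", a1 = a1, a2 = a2,
    depth = ifelse(is.na(a1), NA_integer_, depth)
  ), loci = tibble::tibble(locus = "L1", kind = "SNP",
                           alleles = list(c("A", "T"))))
}

test_that("variant hard filter enforces depth, MAF and the 32-of-48 call rule", {
  # called in only 31 of 48 samples: removed
  out <- filter_variants(make_filter_panel(31), min_called = 32, total = 48)
  expect_equal(n_loci(out$matrix), 0)
  expect_equal(out$report$removed$locus, "L1")
  # called in 32: retained (MAF well above threshold)
  out32 <- filter_variants(make_filter_panel(32), min_called = 32, total = 48)
  expect_equal(n_loci(out32$matrix), 1)

  # minor allele frequency exactly 0.05 is removed (strict inequality):
  # 40 called genotypes, 4 of 80 alleles minor
  gm_maf <- make_filter_panel(40, het = 4)
  expect_equal(1 - locus_summary(gm_maf)$maf, 0.05)
  out_maf <- filter_variants(gm_maf, min_called = 32, total = 48)
  expect_equal(n_loci(out_maf$matrix), 0)
  expect_match(out_maf$report$removed$reason, "minor allele frequency")
  # one more minor allele copy passes
  out_ok <- filter_variants(make_filter_panel(40, het = 5), min_called = 32, total = 48)
  expect_equal(n_loci(out_ok$matrix), 1)

  # all depths 7: every call zeroed at stage one, then removed for call count
  low <- make_filter_panel(48, depth = 7L)
  out_low <- filter_variants(low, min_called = 32, total = 48)
  expect_equal(n_loci(out_low$matrix), 0)
  expect_match(out_low$report$removed$reason, "call count|fewer than")

  expect_error(filter_variants(make_filter_panel(48), min_called = 49, total = 48),
               "exceeds")
})

test_that("two-stage depth gating precedes locus-level criteria on a toy trace", {
  # 5 individuals: depths 7,7,7,20,20 -> 3 calls lost, 2 remain; min_called 3 kills it
  gm <- geno_matrix(tibble::tibble(
    individual = paste0("s", 1:5), locus = "L1",
    a1 = c("A", "A", "A", "A", "A"), a2 = c("T", "T", "T", "T", "T"),
    depth = c(7L, 7L, 7L, 20L, 20L)
  ))
  out <- filter_variants(gm, min_depth = 8, min_maf = 0.05, min_called = 3, total = 5)
  expect_equal(n_loci(out$matrix), 0)
  out2 <- filter_variants(gm, min_depth = 8, min_maf = 0.05, min_called = 2, total = 5)
  expect_equal(n_loci(out2$matrix), 1)
  expect_equal(locus_summary(out2$matrix)$n_called, 2)
})

test_that("loci without depth information skip the depth criterion with a warning", {
  gm <- geno_matrix(tibble::tibble(
    individual = paste0("s", 1:5), locus = "L1",
    a1 = "A", a2 = c("T", "T", "A", "A", "A"), depth = NA_integer_
  ))
  expect_warning(out <- filter_variants(gm, min_called = 3, total = 5), "depth")
  expect_equal(n_loci(out$matrix), 1)
})

test_that("call-rate retention is strict and composes monotonically", {
  panel <- function(n_called) {
    ids <- sprintf("i%03d", 1:180)
    a1 <- c(rep("A", n_called), rep(NA_character_, 180 - n_called))
    a2 <- c(rep("T", min(20, n_called)), rep("A", max(0, n_called - 20)),
            rep(NA_character_, 180 - n_called))
    geno_matrix(tibble::tibble(individual = ids, locus = "L", a1 = a1, a2 = a2))
  }
  # 171/180 = 0.95 exactly: removed at threshold 0.95
  expect_equal(n_loci(filter_call_rate(panel(171), 0.95)$matrix), 0)
  # 172/180 = 0.9556: retained
  expect_equal(n_loci(filter_call_rate(panel(172), 0.95)$matrix), 1)
  expect_error(filter_call_rate(panel(172), 0), "threshold")

  # composing 0.90 then 0.95 equals 0.95 alone
  cfg <- simulation_config(n_populations = 2, n_per_population = 20, n_snp = 60,
                           n_ssr = 0, missing_rate = 0.06, depth_mean = NULL,
                           seed = 17)
  gm <- simulate_panel(cfg)$matrix
  once <- filter_call_rate(gm, 0.95)$matrix
  twice <- filter_call_rate(filter_call_rate(gm, 0.90)$matrix, 0.95)$matrix
  expect_identical(loci(once)$locus, loci(twice)$locus)
  # idempotence and report reconciliation
  again <- filter_call_rate(once, 0.95)
  expect_identical(loci(again$matrix)$locus, loci(once)$locus)
  rep1 <- filter_call_rate(gm, 0.95)$report
  expect_equal(rep1$n_in, rep1$n_out + nrow(rep1$removed))
})

test_that("flank availability checks are exact and mirror-symmetric", {
  expect_true(check_flanks(151, 76))   # 75 up, 75 down
  expect_false(check_flanks(150, 76))  # downstream only 74
  expect_true(check_flanks(300, 150))
  expect_false(check_flanks(100, 50))
  expect_error(check_flanks(100, 0))
  # reversal symmetry: position p on length L mirrors to L - p + 1
  for (L in c(150, 151, 300)) {
    for (p in c(1, 75, 76, L - 75, L)) {
      if (p >= 1 && p <= L) {
        expect_identical(check_flanks(L, p), check_flanks(L, L - p + 1))
      }
    }
  }
})

test_that("tandem-repeat scanning reports maximal leftmost-phase perfect repeats", {
  hits <- scan_ssr_motifs("GGCGGTAACAACAACAACAACAACGTTGAC")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$motif, "AAC")
  expect_equal(hits$repeats, 6L)
  expect_equal(hits$end - hits$start + 1L, 18L)

  # 9 T below the mononucleotide minimum of 10
  expect_equal(nrow(scan_ssr_motifs("GACGTTTTTTTTTGAC")), 0)
  # 10 T reported once, not additionally as (TT)5
  h10 <- scan_ssr_motifs("GACGTTTTTTTTTTGAC")
  expect_equal(nrow(h10), 1)
  expect_equal(h10$motif, "T")
  expect_equal(h10$repeats, 10L)
  # empty sequence
  expect_equal(nrow(scan_ssr_motifs("")), 0)
  # N never inside a reported repeat
  expect_equal(nrow(scan_ssr_motifs("TTTTTNTTTTT")), 0)
})

test_that("the scanner agrees with a regex oracle on planted fixtures", {
  planted <- tibble::tibble(
    motif = c("AAC", "AG", "CTGCA", "T", "AT", "ATG", "GATC", "C"),
    repeats = c(6, 7, 4, 12, 5, 5, 4, 11),
    left = c(80, 40, 75, 30, 55, 70, 45, 60),
    right = c(80, 40, 75, 30, 55, 70, 45, 60)
  )
  fx <- make_contig_fixtures(200, planted, seed = 201)
  hits <- scan_ssr_motifs(fx$sequences)
  expect_equal(nrow(hits), 200)
  merged <- merge(hits, fx$truth, by = "contig", suffixes = c("", ".truth"))
  expect_equal(merged$motif, merged$motif.truth)
  expect_equal(merged$repeats, merged$repeats.truth)
  expect_equal(merged$start, merged$start.truth)
  expect_equal(merged$end, merged$end.truth)
  # independent regex oracle, sequence by sequence
  for (nm in names(fx$sequences)[1:50]) {
    got <- scan_ssr_motifs(fx$sequences[nm])
    ora <- regex_ssr_oracle(fx$sequences[[nm]])
    expect_equal(nrow(got), nrow(ora))
    expect_equal(got$motif, ora$motif)
    expect_equal(got$start, ora$start)
    expect_equal(got$repeats, ora$repeats)
  }
})

test_that("primer screening applies every constraint independently", {
  # 17-nt primer fails on length
  short <- evaluate_primer_pair(strrep("A", 17), strrep("GC", 10), 150)
  expect_equal(short$verdict, "fail")
  expect_true(any(grepl("forward length", short$violations[[1]])))

  # product length 280 is inside the inclusive range
  p280 <- evaluate_primer_pair(strrep("GC", 10), strrep("GC", 10), 280)
  expect_false(any(grepl("product", p280$violations[[1]])))
  p281 <- evaluate_primer_pair(strrep("GC", 10), strrep("GC", 10), 281)
  expect_true(any(grepl("product", p281$violations[[1]])))

  # fixed GC formula: GCCTATAATAGACCGTTTGG has 9 GC over 20 nt
  pr <- evaluate_primer_pair("GCCTATAATAGACCGTTTGG", "GCCTATAATAGACCGTTTGG", 150)
  expect_equal(pr$tm_forward, 64.9 + 41 * (9 - 16.4) / 20)
  expect_equal(round(pr$tm_forward, 2), 49.73)
  expect_true(any(grepl("forward Tm", pr$violations[[1]])))
  expect_equal(pr$tm_delta, 0)

  # a compliant pair passes: 20-mer with 12 GC -> Tm = 55.88
  good <- "GCGCGCGCGCGCATATATAT"
  ok <- evaluate_primer_pair(good, good, 150)
  expect_equal(ok$verdict, "pass")
  expect_equal(ok$violations[[1]], character(0))
})
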