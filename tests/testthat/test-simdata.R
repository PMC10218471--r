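test_that("zero differentiation gives shared per-locus frequencies", {
  cfg <- pop_sim_config(samples_per_pop = 10, n_loci = 50, target_fst = 0,
                        seed = 5)
  g <- simulate_populations(cfg)
  truth <- attr(g, "truth")
  expect_equal(truth$pop_freq[1, ], truth$pop_freq[2, ])
  expect_equal(truth$pop_freq[1, ], truth$p_ancestral)
})

test_that("fixed seed reproduces the genotype matrix bit for bit", {
  cfg <- pop_sim_config(samples_per_pop = 8, n_loci = 200, seed = 42)
  g1 <- simulate_populations(cfg)
  g2 <- simulate_populations(cfg)
  expect_identical(g1$calls, g2$calls)
  expect_identical(g1$loci, g2$loci)
  g3 <- simulate_populations(pop_sim_config(samples_per_pop = 8,
                                            n_loci = 200, seed = 43))
  expect_false(identical(g1$calls, g3$calls))
})

test_that("simulated differentiation matches the target (Hudson recovery)", {
  cfg <- pop_sim_config(samples_per_pop = 50, n_loci = 8000,
                        target_fst = 0.1, seed = 9)
  g <- simulate_populations(cfg)
  cn <- allele_counts(g, attr(g, "pops"))
  comp <- site_fst(cn[[1]], cn[[2]])
  fst <- sum(comp$num, na.rm = TRUE) / sum(comp$den, na.rm = TRUE)
  expect_lt(abs(fst - 0.1), 0.02)
})

test_that("position and config invariants hold", {
  cfg <- pop_sim_config(samples_per_pop = 5, n_loci = 500,
                        chrom_lengths = c(c2 = 1e6, c10 = 2e6), seed = 2)
  g <- simulate_populations(cfg)
  for (ch in unique(g$loci$chrom)) {
    p <- g$loci$pos[g$loci$chrom == ch]
    expect_true(all(diff(p) > 0))
  }
  expect_error(pop_sim_config(target_fst = 1), "target_fst")
  expect_error(pop_sim_config(n_loci = 0), "n_loci")
})

test_that("sweep overlay reduces diversity and raises differentiation", {
  cfg <- pop_sim_config(samples_per_pop = 40, n_loci = 3000,
                        chrom_lengths = c(chr1 = 10e6), target_fst = 0.05,
                        seed = 17)
  g <- simulate_populations(cfg)
  region <- list(chrom = "chr1", start = 4e6, end = 5e6)

  expect_identical(simulate_sweep_region(g, region, strength = 0), g)

  gs <- simulate_sweep_region(g, region, strength = 5, seed = 18)
  pops <- attr(gs, "pops")
  inside <- gs$loci$pos - 1 >= region$start & gs$loci$pos - 1 < region$end
  cn <- allele_counts(gs, pops)
  pi_in <- mean(attr(nucleotide_diversity(
    lapply(cn$pop2, `[`, inside), 1), "per_site"))
  pi_out <- mean(attr(nucleotide_diversity(
    lapply(cn$pop2, `[`, !inside), 1), "per_site"))
  expect_lt(pi_in, pi_out)
  comp <- site_fst(cn$pop1, cn$pop2)
  fst_in <- sum(comp$num[inside]) / sum(comp$den[inside])
  fst_out <- sum(comp$num[!inside]) / sum(comp$den[!inside])
  expect_gt(fst_in, fst_out)
  # untouched outside the region and in the other population
  expect_identical(gs$calls[pops == "pop1", ], g$calls[pops == "pop1", ])
  expect_identical(gs$calls[, !inside], g$calls[, !inside])

  expect_warning(
    simulate_sweep_region(g, list(chrom = "chr1", start = 0, end = 10e6),
                          strength = 1), "whole genome")
  expect_error(
    simulate_sweep_region(g, list(chrom = "chr9", start = 0, end = 1e4),
                          strength = 1), "outside")
})

test_that("breeding values realize the requested heritability", {
  cfg <- pop_sim_config(samples_per_pop = 250, n_loci = 1000, seed = 31)
  g <- simulate_populations(cfg)
  bv <- simulate_breeding_values(
    g, breeding_sim_config(h2 = 0.3, n_causal = 100, seed = 32))
  expect_lt(abs(var(bv$tbv) / var(bv$phenotype) - 0.3), 0.05)
  expect_error(breeding_sim_config(h2 = 1.2), "h2")
  expect_error(simulate_breeding_values(
    g, breeding_sim_config(n_causal = 99999)), "n_causal")
})

test_that("EBV noise is calibrated to the drawn reliability", {
  cfg <- pop_sim_config(samples_per_pop = 500, n_loci = 800, seed = 33)
  g <- simulate_populations(cfg)
  bv <- simulate_breeding_values(
    g, breeding_sim_config(h2 = 0.5, n_causal = 200,
                           reliability_range = c(0.64, 0.64), seed = 34))
  expect_lt(abs(cor(bv$ebv_table$ebv, bv$tbv)^2 - 0.64), 0.05)

  # noiseless limit: reliability ~ 1 makes EBV equal TBV
  bv1 <- simulate_breeding_values(
    g, breeding_sim_config(h2 = 0.99, n_causal = 200,
                           reliability_range = c(1 - 1e-9, 1 - 1e-9),
                           seed = 35))
  expect_lt(max(abs(bv1$ebv_table$ebv - bv1$tbv)) / sd(bv1$tbv), 1e-3)
})

test_that("error-free capture reproduces the truth calls exactly", {
  cfg <- pop_sim_config(samples_per_pop = 10, n_loci = 300, seed = 51)
  g <- simulate_populations(cfg)
  panel <- g$loci[seq(1, 300, by = 3), c("chrom", "pos")]
  cap <- simulate_capture_experiment(
    g, panel, capture_sim_config(ado_prob = 0, dropout_prob = 0, seed = 52))
  expect_identical(cap$gbts$calls, cap$truth$calls)
  conc <- concordance_summary(cap$gbts, cap$truth)
  expect_equal(conc$concordance, 1)
  expect_error(
    simulate_capture_experiment(
      g, data.frame(chrom = "chrX", pos = 1), capture_sim_config()),
    "chrX 1")
})

test_that("allele drop-out hits heterozygotes at the configured rate", {
  cfg <- pop_sim_config(samples_per_pop = 60, n_loci = 500, seed = 53)
  g <- simulate_populations(cfg)
  panel <- g$loci[, c("chrom", "pos")]
  cap <- simulate_capture_experiment(
    g, panel, capture_sim_config(ado_prob = 0.1, dropout_prob = 0,
                                 seed = 54))
  het <- cap$truth$calls == 1L
  n_het <- sum(het)
  expect_gt(n_het, 4000)
  became_hom <- sum(cap$gbts$calls[het] != 1L)
  iv <- binom_interval99(n_het, 0.1)
  expect_gte(became_hom, iv[1])
  expect_lte(became_hom, iv[2])
  # dropped alleles land on either homozygote, never on a new het
  expect_true(all(cap$gbts$calls[het] %in% c(0L, 1L, 2L)))
})

test_that("simulated depths hit the three anchor means", {
  cfg <- pop_sim_config(samples_per_pop = 30, n_loci = 400, seed = 55)
  g <- simulate_populations(cfg)
  cap <- simulate_capture_experiment(
    g, g$loci[, c("chrom", "pos")], capture_sim_config(seed = 56))
  expect_lt(abs(mean(cap$depth) - 91) / 91, 0.05)
  offs <- abs(as.numeric(rownames(cap$flank_depth)))
  expect_lt(abs(mean(cap$flank_depth[offs == 100, ]) - 60) / 60, 0.05)
  expect_lt(abs(mean(cap$flank_depth[offs == 250, ]) - 26) / 26, 0.05)
  # expected decay is monotone non-increasing in |offset|
  mu <- capture_decay(0:500, capture_sim_config())
  expect_true(all(diff(mu) <= 1e-12))
})

test_that("fixture sets round-trip and are digest-stable under a seed", {
  make_all <- function(dir) {
    cfg <- pop_sim_config(samples_per_pop = 6, n_loci = 120,
                          chrom_lengths = c(chr1 = 1e6), seed = 71)
    g <- simulate_populations(cfg)
    bv <- simulate_breeding_values(
      g, breeding_sim_config(n_causal = 20, seed = 72))
    cap <- simulate_capture_experiment(
      g, g$loci[1:50, c("chrom", "pos")],
      capture_sim_config(seed = 73))
    qtl <- simulate_qtl_regions(c(chr1 = 1e6), n_regions = 3,
                                region_size = 1e5, seed = 74)
    write_fixture_set(g, cap, bv$ebv_table, qtl,
                      list(seed = 71), dir)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_all(d1); p2 <- make_all(d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  g_rt <- read_vcf(p1["truth"])
  cfg <- pop_sim_config(samples_per_pop = 6, n_loci = 120,
                        chrom_lengths = c(chr1 = 1e6), seed = 71)
  g <- simulate_populations(cfg)
  expect_identical(g_rt$calls, g$calls)
  dep <- read_depth_tsv(p1["depth"])
  expect_equal(dim(dep), c(50, 12))
  bed <- read_bed(p1["qtl"])
  expect_equal(nrow(bed), 3)
  ebv <- read_ebv_tsv(p1["ebv"])
  expect_true(all(c("id", "ebv", "rel", "pa_ebv", "pa_rel") %in% names(ebv)))
})

test_that("an empty panel aborts before any file is written", {
  cfg <- pop_sim_config(samples_per_pop = 4, n_loci = 50, seed = 81)
  g <- simulate_populations(cfg)
  cap <- simulate_capture_experiment(
    g, g$loci[1:5, c("chrom", "pos")], capture_sim_config(seed = 82))
  cap$gbts <- subset_geno(cap$gbts, loci = integer(0))
  d <- file.path(withr::local_tempdir(), "out")
  expect_error(write_fixture_set(g, cap, data.frame(), data.frame(),
                                 list(), d), "empty panel")
  expect_false(dir.exists(d))
})
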