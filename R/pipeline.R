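#' Default end-to-end pipeline configuration
#'
#' One nested list driving [run_pipeline()]: simulation conditions, site
#' filters, sweep-scan windows, GWAS settings and panel-assembly targets.
#' The simulation defaults emulate a two-group resequencing cohort
#' (reference vs selected breed group) with moderate differentiation, one
#' swept region, a polygenic trait, and a well-behaved capture assay
#' (91x on-target depth decaying to 60x/26x at 100/250 bp).
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
pf_default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    pop = list(n_populations = 2, samples_per_pop = c(55, 55),
               n_loci = 12000,
               chrom_lengths = c(chr1 = 40e6, chr2 = 40e6),
               target_fst = 0.1),
    sweep_truth = list(chrom = "chr1", start = 10e6, end = 10.4e6,
                       strength = 5),
    filters = list(max_miss = 0.1, min_maf = 0.05),
    sweep = list(window = 400e3, step = 200e3, min_snps = 5,
                 q = 0.99, combine = "vote2"),
    breeding = list(h2 = 0.3, n_causal = 80),
    gwas = list(h2 = 0.3, c_frac = 0.1),
    qtl = list(n_regions = 12, region_size = 500e3,
               traits = c("FU", "FL", "GA", "RU", "SL", "TE")),
    panel = list(K = 3000, target_spacing = 25e3, min_maf = 0.05),
    capture = list(target_mean_depth = 91, flank_depth_100bp = 60,
                   flank_depth_250bp = 26, ado_prob = 0.02,
                   dropout_prob = 0.01))
}

#' Simulate trait-tagged QTL regions
#'
#' Uniformly placed, non-validated intervals standing in for a public QTL
#' database extract.
#'
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param n_regions Number of intervals.
#' @param region_size Interval width in bp.
#' @param traits Trait tags to sample from.
#' @param seed Integer seed.
#' @return Sorted data frame `chrom`, `start`, `end`, `trait_tag`
#'   (0-based half-open).
#' @export
simulate_qtl_regions <- function(chrom_lengths, n_regions = 12,
                                 region_size = 500e3,
                                 traits = c("FU", "FL", "GA", "RU", "SL",
                                            "TE"),
                                 seed = 1L) {
  set.seed(seed)
  ch <- sample(names(chrom_lengths), n_regions, replace = TRUE,
               prob = chrom_lengths / sum(chrom_lengths))
  start <- vapply(ch, function(c)
    floor(stats::runif(1, 0, chrom_lengths[[c]] - region_size)), numeric(1))
  out <- data.frame(chrom = ch, start = start, end = start + region_size,
                    trait_tag = sample(traits, n_regions, replace = TRUE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Run the full panel design-and-validation pipeline on synthetic data
#'
#' Chains every stage end to end: simulate two diverged populations with a
#' known swept region; hard/site filtering; windowed sweep scan and region
#' selection; simulated breeding values, de-regression and mixed-model
#' GWAS; candidate merging and panel assembly to exactly `K` loci; a
#' simulated capture experiment on the assembled panel; and capture QC
#' (detection rates, flank profile, MAF spectrum, concordance).
#'
#' @param config From [pf_default_config()].
#' @param quiet Suppress progress messages.
#' @return List with each stage's outputs (`geno`, `filtered`, `windows`,
#'   `sweep_regions`, `qtl`, `debv`, `scan`, `panel`, `capture`, `qc`).
#' @export
run_pipeline <- function(config = pf_default_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  say("simulating populations ...")
  pcfg <- pop_sim_config(
    n_populations = config$pop$n_populations,
    samples_per_pop = config$pop$samples_per_pop,
    n_loci = config$pop$n_loci,
    chrom_lengths = config$pop$chrom_lengths,
    target_fst = config$pop$target_fst,
    seed = seed)
  geno <- simulate_populations(pcfg)
  st <- config$sweep_truth
  geno <- simulate_sweep_region(
    geno, list(chrom = st$chrom, start = st$start, end = st$end),
    strength = st$strength, seed = seed + 1L)
  pops <- attr(geno, "pops")
  say("filtering sites ...")
  filtered <- filter_sites(geno, max_miss = config$filters$max_miss,
                           min_maf = config$filters$min_maf)
  attr(filtered, "pops") <- pops
  say("sweep scan ...")
  windows <- sweep_scan(filtered, pops,
                        window = config$sweep$window,
                        step = config$sweep$step,
                        min_snps = config$sweep$min_snps)
  sweep_regions <- select_sweep_regions(
    windows, q_fst = config$sweep$q, q_pi = config$sweep$q,
    q_xpclr = config$sweep$q, combine = config$sweep$combine)
  sweep_loci <- loci_in_regions(filtered, sweep_regions)
  say("QTL overlap ...")
  qtl <- simulate_qtl_regions(config$pop$chrom_lengths,
                              n_regions = config$qtl$n_regions,
                              region_size = config$qtl$region_size,
                              traits = config$qtl$traits,
                              seed = seed + 2L)
  qtl_loci <- overlap_qtl(filtered$loci, qtl)
  say("breeding values and GWAS ...")
  bv <- simulate_breeding_values(
    filtered, breeding_sim_config(h2 = config$breeding$h2,
                                  n_causal = config$breeding$n_causal,
                                  seed = seed + 3L))
  debv <- deregress_ebv(bv$ebv_table$ebv, bv$ebv_table$rel,
                        bv$ebv_table$pa_ebv, bv$ebv_table$pa_rel,
                        h2 = config$gwas$h2, c_frac = config$gwas$c_frac)
  G <- build_grm(filtered)
  null <- fit_null_reml(debv$debv, G, weights = debv$weight)
  scan <- single_marker_scan(debv$debv, filtered, null)
  thr <- significance_lines()
  gwas_loci <- scan[scan$p < thr$suggestive, c("chrom", "pos")]
  say("assembling panel ...")
  pool <- cbind(filtered$loci, maf = locus_stats(filtered)$maf)
  panel <- assemble_panel(sweep_loci, qtl_loci, gwas_loci, pool,
                          K = config$panel$K,
                          target_spacing = config$panel$target_spacing,
                          min_maf = config$panel$min_maf,
                          chrom_lengths = config$pop$chrom_lengths)
  say("capture experiment and QC ...")
  ccfg <- capture_sim_config(
    target_mean_depth = config$capture$target_mean_depth,
    flank_depth_100bp = config$capture$flank_depth_100bp,
    flank_depth_250bp = config$capture$flank_depth_250bp,
    ado_prob = config$capture$ado_prob,
    dropout_prob = config$capture$dropout_prob,
    seed = seed + 4L)
  capture <- simulate_capture_experiment(geno, panel, ccfg)
  qc <- list(
    detection = detection_rates(capture$depth),
    flank = flank_profile(capture$flank_depth),
    maf = captured_maf_spectrum(capture$gbts),
    concordance = concordance_summary(capture$gbts, capture$truth))
  list(config = config, geno = geno, filtered = filtered,
       windows = windows, sweep_regions = sweep_regions,
       sweep_loci = sweep_loci, qtl = qtl, qtl_loci = qtl_loci,
       breeding = bv, debv = debv, null = null, scan = scan,
       gwas_loci = gwas_loci, panel = panel, capture = capture, qc = qc)
}
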