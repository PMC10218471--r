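#' Configuration for population genotype simulation
#'
#' Two (or more) populations diverged from a common ancestral pool under the
#' Balding-Nichols model: per locus an ancestral frequency `p` is drawn from
#' `ancestral_maf_law`, each population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = target_fst`, and diploid
#' genotypes are binomial in that frequency. `F = 0` collapses the Beta to a
#' point mass so all populations share `p` exactly.
#'
#' @param n_populations Number of populations (>= 1).
#' @param samples_per_pop Integer vector of diploid sample counts, recycled
#'   to `n_populations`.
#' @param n_loci Total number of biallelic loci across the genome.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param target_fst Differentiation parameter `F` in `[0, 1)`.
#' @param ancestral_maf_range Range of the uniform law for the ancestral
#'   allele frequency; default `c(0.05, 0.5)`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `pop_sim_config` list.
#' @export
pop_sim_config <- function(n_populations = 2, samples_per_pop = 50,
                           n_loci = 20000,
                           chrom_lengths = c(chr1 = 50e6, chr2 = 50e6),
                           target_fst = 0.1,
                           ancestral_maf_range = c(0.05, 0.5),
                           seed = 1L) {
  stopifnot(n_populations >= 1, all(samples_per_pop >= 1), n_loci >= 1,
            target_fst >= 0, target_fst < 1,
            length(chrom_lengths) >= 1, all(chrom_lengths > 0))
  structure(list(
    n_populations = as.integer(n_populations),
    samples_per_pop = rep_len(as.integer(samples_per_pop), n_populations),
    n_loci = as.integer(n_loci),
    chrom_lengths = chrom_lengths,
    target_fst = target_fst,
    ancestral_maf_range = ancestral_maf_range,
    seed = as.integer(seed)), class = "pop_sim_config")
}

#' Simulate diverged populations under the Balding-Nichols model
#'
#' @param cfg A [pop_sim_config()].
#' @return A `genotype_matrix` with attributes `pops` (character vector of
#'   population labels per sample) and `truth` (list with the ancestral and
#'   per-population allele frequencies per locus).
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  if (cfg$n_loci < 1 || any(cfg$samples_per_pop < 1))
    stop("need at least one locus and one sample per population")
  set.seed(cfg$seed)
  L <- cfg$n_loci
  # loci spread over chromosomes proportionally to length, positions sorted
  # and strictly increasing within chromosome
  lens <- cfg$chrom_lengths
  n_per <- as.vector(stats::rmultinom(1, L, lens / sum(lens)))
  chrom <- rep(names(lens), n_per)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    if (n_per[i] == 0) return(integer(0))
    sort(sample.int(lens[i] - 1L, n_per[i]))
  }), use.names = FALSE)
  p_anc <- stats::runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  F <- cfg$target_fst
  pop_freq <- matrix(NA_real_, nrow = cfg$n_populations, ncol = L)
  for (k in seq_len(cfg$n_populations)) {
    pop_freq[k, ] <- if (F == 0) p_anc else
      stats::rbeta(L, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  calls <- matrix(NA_integer_, nrow = sum(cfg$samples_per_pop), ncol = L)
  pops <- rep(paste0("pop", seq_len(cfg$n_populations)), cfg$samples_per_pop)
  row0 <- 0L
  for (k in seq_len(cfg$n_populations)) {
    nk <- cfg$samples_per_pop[k]
    calls[row0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * L, 2L, rep(pop_freq[k, ], each = nk)), nrow = nk)
    row0 <- row0 + nk
  }
  alleles <- matrix(c("A", "C", "G", "T"), 2)[, sample.int(2, L, replace = TRUE)]
  loci <- data.frame(chrom = chrom, pos = pos,
                     ref = alleles[1, ], alt = alleles[2, ],
                     stringsAsFactors = FALSE)
  ids <- sprintf("%s_ind%03d", pops, unlist(lapply(cfg$samples_per_pop, seq_len)))
  g <- genotype_matrix(calls, loci, ids, chrom_lengths = lens)
  # genotype_matrix() sorts loci by (chrom, pos); reorder truth the same way
  ord <- order(chrom, pos)
  attr(g, "pops") <- pops
  attr(g, "truth") <- list(p_ancestral = p_anc[ord],
                           pop_freq = pop_freq[, ord, drop = FALSE],
                           target_fst = F)
  g
}

#' Overlay a selective sweep on one population
#'
#' Within `region`, population `pop`'s alternate-allele frequencies are
#' pushed toward fixation by `p -> p^(1 / (1 + strength))` and that
#' population's genotypes in the region are redrawn from the new
#' frequencies; everything outside the region, and all other populations,
#' are untouched. `strength = 0` returns the input unchanged.
#'
#' @param geno A `genotype_matrix` from [simulate_populations()] (needs the
#'   `pops` and `truth` attributes).
#' @param region List or data frame with `chrom`, `start`, `end`
#'   (0-based half-open, bp).
#' @param strength Selection strength `>= 0`.
#' @param pop Population label to sweep; default the last population.
#' @param seed Integer seed for the genotype redraw.
#' @return The modified `genotype_matrix`; attribute `sweep_region` records
#'   the region and strength.
#' @export
simulate_sweep_region <- function(geno, region, strength, pop = NULL,
                                  seed = 1L) {
  stopifnot(strength >= 0)
  pops <- attr(geno, "pops")
  truth <- attr(geno, "truth")
  if (is.null(pops) || is.null(truth))
    stop("geno must carry simulation truth (use simulate_populations())")
  if (is.null(pop)) pop <- utils::tail(unique(pops), 1)
  lens <- attr(geno, "chrom_lengths")
  if (!region$chrom %in% geno$loci$chrom ||
      (!is.null(lens) && (region$start < 0 || region$end > lens[[region$chrom]])))
    stop("sweep region outside simulated coordinates: ",
         region$chrom, ":", region$start, "-", region$end)
  if (strength == 0) return(geno)
  span <- if (is.null(lens)) diff(range(geno$loci$pos)) else sum(lens)
  if (region$end - region$start >= span)
    warning("sweep region covers the whole genome")
  in_region <- geno$loci$chrom == region$chrom &
    geno$loci$pos - 1L >= region$start & geno$loci$pos - 1L < region$end
  k <- match(pop, unique(pops))
  rows <- which(pops == pop)
  set.seed(seed)
  p_new <- truth$pop_freq[k, in_region]^(1 / (1 + strength))
  geno$calls[rows, in_region] <- matrix(
    stats::rbinom(length(rows) * sum(in_region), 2L,
                  rep(p_new, each = length(rows))),
    nrow = length(rows))
  truth$pop_freq[k, in_region] <- p_new
  attr(geno, "truth") <- truth
  attr(geno, "sweep_region") <- c(region, list(strength = strength, pop = pop))
  geno
}

#' Configuration for breeding-value simulation
#'
#' @param h2 Narrow-sense heritability in (0, 1).
#' @param n_causal Number of causal loci.
#' @param effect_sd Standard deviation of the Gaussian allele-substitution
#'   effects.
#' @param reliability_range Range of the uniform law for per-animal EBV
#'   reliability (r-squared), over (0, 1).
#' @param pa_rel_range Range of the uniform law for parent-average
#'   reliability; kept strictly below each animal's own reliability.
#' @param seed Integer seed.
#' @return A `breeding_sim_config` list.
#' @export
breeding_sim_config <- function(h2 = 0.3, n_causal = 100, effect_sd = 1,
                                reliability_range = c(0.4, 0.9),
                                pa_rel_range = c(0.05, 0.2),
                                seed = 1L) {
  stopifnot(h2 > 0, h2 < 1, n_causal >= 1, effect_sd > 0,
            all(reliability_range > 0), all(reliability_range < 1),
            all(pa_rel_range > 0), all(pa_rel_range < 1))
  structure(list(h2 = h2, n_causal = as.integer(n_causal),
                 effect_sd = effect_sd,
                 reliability_range = reliability_range,
                 pa_rel_range = pa_rel_range, seed = as.integer(seed)),
            class = "breeding_sim_config")
}

#' Simulate polygenic phenotypes, EBVs and reliabilities
#'
#' True breeding values are sums of Gaussian effects at `n_causal` loci;
#' phenotypes add environmental noise scaled so that
#' `Var(TBV)/Var(phenotype) = h2`. EBVs are simulated as BLUP-consistent
#' shrunken predictors, `EBV = r2 * TBV + noise` with noise variance
#' `r2 * (1 - r2) * Var(TBV)`, which gives both the evaluation properties
#' de-regression assumes (`Cov(EBV, TBV) = Var(EBV)`) and a squared
#' correlation with TBV equal to each animal's drawn reliability `r2`.
#'
#' @param geno A `genotype_matrix`.
#' @param cfg A [breeding_sim_config()].
#' @return List with `ebv_table` (data frame: id, ebv, rel, pa_ebv, pa_rel,
#'   sire, dam), `phenotype`, `tbv`, `causal` (locus indices) and `effects`.
#' @export
simulate_breeding_values <- function(geno, cfg) {
  stopifnot(inherits(cfg, "breeding_sim_config"))
  if (cfg$n_causal > n_loci(geno))
    stop("n_causal exceeds the number of loci")
  if (cfg$h2 <= 0 || cfg$h2 >= 1) stop("h2 must lie in (0, 1)")
  set.seed(cfg$seed)
  n <- n_samples(geno)
  causal <- sort(sample.int(n_loci(geno), cfg$n_causal))
  effects <- stats::rnorm(cfg$n_causal, 0, cfg$effect_sd)
  Z <- geno$calls[, causal, drop = FALSE]
  Z[is.na(Z)] <- 0L
  tbv <- as.vector(Z %*% effects)
  var_g <- stats::var(tbv)
  if (var_g == 0) stop("degenerate genetic variance; increase n_causal or MAF")
  pheno <- tbv + stats::rnorm(n, 0, sqrt(var_g * (1 - cfg$h2) / cfg$h2))
  rel <- stats::runif(n, cfg$reliability_range[1], cfg$reliability_range[2])
  ebv <- rel * tbv + stats::rnorm(n, 0, sqrt(var_g * rel * (1 - rel)))
  pa_rel <- pmin(stats::runif(n, cfg$pa_rel_range[1], cfg$pa_rel_range[2]),
                 rel * 0.5)
  ebv_table <- data.frame(
    id = geno$samples, ebv = ebv, rel = rel,
    pa_ebv = 0, pa_rel = pa_rel,           # unrelated founders: PA centred at 0
    sire = NA_character_, dam = NA_character_,
    stringsAsFactors = FALSE)
  list(ebv_table = ebv_table, phenotype = pheno, tbv = tbv,
       causal = causal, effects = effects)
}

#' Configuration for the targeted-capture experiment simulator
#'
#' Defaults reflect a well-behaved in-solution capture assay: on-target mean
#' depth 91x decaying to 60x at 100 bp and 26x at 250 bp from the target,
#' modelled as a piecewise-exponential decay through those three anchors.
#'
#' @param target_mean_depth Mean read depth at the target base (reads).
#' @param flank_depth_100bp,flank_depth_250bp Mean depths at 100 and 250 bp.
#' @param flank_halfwidth Half-width of the profiled flank in bp.
#' @param flank_grid_step Offset grid step in bp for the emitted profile.
#' @param depth_shape Gamma shape for per-target depth dispersion.
#' @param ado_prob Probability that a heterozygote suffers allele drop-out
#'   and is emitted as one of its homozygotes (fair coin which).
#' @param dropout_prob Probability that a target yields no call at all.
#' @param seed Integer seed.
#' @return A `capture_sim_config` list.
#' @export
capture_sim_config <- function(target_mean_depth = 91,
                               flank_depth_100bp = 60,
                               flank_depth_250bp = 26,
                               flank_halfwidth = 500,
                               flank_grid_step = 25,
                               depth_shape = 10,
                               ado_prob = 0.02,
                               dropout_prob = 0.01,
                               seed = 1L) {
  stopifnot(target_mean_depth > 0, flank_depth_100bp > 0,
            flank_depth_250bp > 0,
            flank_depth_100bp <= target_mean_depth,
            flank_depth_250bp <= flank_depth_100bp,
            flank_halfwidth > 250, depth_shape > 0,
            ado_prob >= 0, ado_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(target_mean_depth = target_mean_depth,
                 flank_depth_100bp = flank_depth_100bp,
                 flank_depth_250bp = flank_depth_250bp,
                 flank_halfwidth = flank_halfwidth,
                 flank_grid_step = flank_grid_step,
                 depth_shape = depth_shape,
                 ado_prob = ado_prob, dropout_prob = dropout_prob,
                 seed = as.integer(seed)), class = "capture_sim_config")
}

#' Expected capture depth at a given offset from the target
#'
#' Piecewise-exponential decay interpolating the three anchor depths at
#' 0, 100 and 250 bp; beyond 250 bp the outer rate continues. Monotone
#' non-increasing in `|offset|`.
#'
#' @param offset Offset(s) from the target in bp (sign ignored).
#' @param cfg A [capture_sim_config()].
#' @return Expected depth(s).
#' @export
capture_decay <- function(offset, cfg) {
  d <- abs(offset)
  d0 <- cfg$target_mean_depth
  r1 <- log(d0 / cfg$flank_depth_100bp) / 100
  r2 <- log(cfg$flank_depth_100bp / cfg$flank_depth_250bp) / 150
  ifelse(d <= 100, d0 * exp(-r1 * d),
         cfg$flank_depth_100bp * exp(-r2 * (d - 100)))
}

#' Simulate a targeted-capture (GBTS) genotyping experiment
#'
#' Per panel target and sample, read depth is Gamma-distributed with mean
#' `target_mean_depth`; flank depths follow the piecewise-exponential decay
#' of [capture_decay()]. Capture calls copy the truth genotypes except that
#' with probability `dropout_prob` a target is emitted as no-call, and with
#' probability `ado_prob` a heterozygote loses one allele and is emitted as
#' either homozygote with probability 1/2 each.
#'
#' @param truth_geno A `genotype_matrix` holding the true genotypes.
#' @param panel A data frame with `chrom`, `pos` naming the panel loci
#'   (e.g. a `panel_spec`); every locus must exist in `truth_geno`.
#' @param cfg A [capture_sim_config()].
#' @return List with `gbts` (a `genotype_matrix` of capture calls at the
#'   panel loci), `depth` (targets x samples matrix), `flank_depth`
#'   (offsets x samples matrix of mean depths, offset grid in rownames) and
#'   `truth` (the truth calls at the panel loci).
#' @export
simulate_capture_experiment <- function(truth_geno, panel, cfg) {
  stopifnot(inherits(cfg, "capture_sim_config"))
  if (nrow(panel) == 0) stop("panel is empty")
  key_t <- paste(truth_geno$loci$chrom, truth_geno$loci$pos)
  key_p <- paste(panel$chrom, panel$pos)
  idx <- match(key_p, key_t)
  if (anyNA(idx))
    stop("panel locus absent from truth genotypes: ",
         key_p[which(is.na(idx))[1]])
  set.seed(cfg$seed)
  truth <- subset_geno(truth_geno, loci = sort(idx))
  n <- n_samples(truth); m <- n_loci(truth)
  shape <- cfg$depth_shape
  depth <- matrix(stats::rgamma(m * n, shape = shape,
                                rate = shape / cfg$target_mean_depth),
                  nrow = m, ncol = n,
                  dimnames = list(paste(truth$loci$chrom, truth$loci$pos,
                                        sep = ":"),
                                  truth$samples))
  offsets <- seq(-cfg$flank_halfwidth, cfg$flank_halfwidth,
                 by = cfg$flank_grid_step)
  mu <- capture_decay(offsets, cfg)
  # each entry is a mean over the m targets, so Gamma(m*shape, m*shape/mu)
  flank <- matrix(stats::rgamma(length(offsets) * n, shape = shape * m,
                                rate = shape * m / rep(mu, n)),
                  nrow = length(offsets), ncol = n,
                  dimnames = list(offsets, truth$samples))
  calls <- truth$calls
  drop <- matrix(stats::runif(n * m) < cfg$dropout_prob, n, m)
  calls[drop] <- NA_integer_
  is_het <- !is.na(calls) & calls == 1L
  ado <- is_het & matrix(stats::runif(n * m) < cfg$ado_prob, n, m)
  calls[ado] <- 2L * stats::rbinom(sum(ado), 1L, 0.5)
  gbts <- genotype_matrix(calls, truth$loci, truth$samples,
                          chrom_lengths = attr(truth_geno, "chrom_lengths"))
  list(gbts = gbts, depth = depth, flank_depth = flank, truth = truth)
}

#' Write a complete synthetic fixture set
#'
#' Emits, under `outdir`: `truth.vcf` (resequencing-style genotypes),
#' `gbts.vcf` (capture calls), `depth.tsv` (targets x samples),
#' `flank_depth.tsv` (offsets x samples), `qtl.bed` (trait-tagged regions),
#' `ebv.tsv` and `config.json`. All files round-trip through the package's
#' readers.
#'
#' @param truth_geno Truth `genotype_matrix`.
#' @param capture Result of [simulate_capture_experiment()].
#' @param ebv_table EBV table from [simulate_breeding_values()].
#' @param qtl Data frame of QTL regions (`chrom`, `start`, `end`,
#'   `trait_tag`).
#' @param config List of the simulation configs, snapshot to JSON.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_set <- function(truth_geno, capture, ebv_table, qtl, config,
                              outdir) {
  if (n_loci(capture$gbts) == 0) stop("empty panel; nothing to write")
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  paths <- c(truth = file.path(outdir, "truth.vcf"),
             gbts = file.path(outdir, "gbts.vcf"),
             depth = file.path(outdir, "depth.tsv"),
             flank = file.path(outdir, "flank_depth.tsv"),
             qtl = file.path(outdir, "qtl.bed"),
             ebv = file.path(outdir, "ebv.tsv"),
             config = file.path(outdir, "config.json"))
  write_vcf(truth_geno, paths["truth"])
  write_vcf(capture$gbts, paths["gbts"])
  utils::write.table(capture$depth, paths["depth"], sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(capture$flank_depth, paths["flank"], sep = "\t",
                     quote = FALSE, col.names = NA)
  write_bed(qtl, paths["qtl"])
  utils::write.table(ebv_table, paths["ebv"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(config, paths["config"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read/write BED interval tables (0-based half-open)
#'
#' @param x Data frame with `chrom`, `start`, `end` and optionally a name
#'   column (`trait_tag`).
#' @param path File path.
#' @return `read_bed` returns a data frame `chrom`, `start`, `end`,
#'   `trait_tag`; `write_bed` returns `path` invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("trait_tag" %in% names(x)) x$trait_tag else "."
  utils::write.table(
    data.frame(x$chrom, as.integer(x$start), as.integer(x$end), name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4) names(b)[4] <- "trait_tag" else b$trait_tag <- "."
  if (any(b$end <= b$start)) stop("BED interval with end <= start in ", path)
  b[, c("chrom", "start", "end", "trait_tag")]
}

#' Read a depth TSV (targets or offsets in rows, samples in columns)
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_depth_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}

#' Read an EBV/reliability TSV
#' @param path File path.
#' @return Data frame with at least `id`, `ebv`, `rel`, `pa_ebv`, `pa_rel`.
#' @export
read_ebv_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
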