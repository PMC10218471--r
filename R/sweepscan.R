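#' Per-population allele counts at every locus
#'
#' @param geno A `genotype_matrix`.
#' @param pops Character vector of population labels, one per sample.
#' @return List per population: `x` (alt allele count) and `n` (observed
#'   chromosomes) per locus.
#' @export
allele_counts <- function(geno, pops) {
  stopifnot(length(pops) == n_samples(geno))
  lapply(split(seq_along(pops), pops), function(rows) {
    sub <- geno$calls[rows, , drop = FALSE]
    list(x = colSums(sub, na.rm = TRUE),
         n = 2 * (length(rows) - colSums(is.na(sub))))
  })
}

#' Hudson Fst components per site
#'
#' Returns the per-site numerator and denominator of Hudson's estimator:
#' `num = (pa - pb)^2 - pa(1-pa)/(na-1) - pb(1-pb)/(nb-1)` and
#' `den = pa(1-pb) + pb(1-pa)`, with `na`, `nb` observed chromosome counts.
#' Windowed Fst is the ratio of averages `sum(num)/sum(den)`. Sites where
#' either population has fewer than 2 observed chromosomes are returned as
#' `NA` and counted in the `n_skipped` attribute.
#'
#' @param counts_a,counts_b Lists with `x` (alt count) and `n` (chromosome
#'   count) per site, as from [allele_counts()].
#' @return Data frame with columns `num`, `den`; attribute `n_skipped`.
#' @export
site_fst <- function(counts_a, counts_b) {
  na <- counts_a$n; nb <- counts_b$n
  pa <- counts_a$x / na; pb <- counts_b$x / nb
  ok <- na >= 2 & nb >= 2
  num <- den <- rep(NA_real_, length(na))
  num[ok] <- (pa[ok] - pb[ok])^2 -
    pa[ok] * (1 - pa[ok]) / (na[ok] - 1) -
    pb[ok] * (1 - pb[ok]) / (nb[ok] - 1)
  den[ok] <- pa[ok] * (1 - pb[ok]) + pb[ok] * (1 - pa[ok])
  out <- data.frame(num = num, den = den)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Weir-Cockerham Fst variance components per site (two populations)
#'
#' Provided for parity with per-site estimators in common VCF tooling;
#' windowed values again use the ratio of summed components.
#'
#' @inheritParams site_fst
#' @return Data frame with columns `num` (a) and `den` (a + b + c).
#' @export
site_fst_wc <- function(counts_a, counts_b) {
  na <- counts_a$n / 2; nb <- counts_b$n / 2  # diploid sample counts
  pa <- counts_a$x / counts_a$n; pb <- counts_b$x / counts_b$n
  ok <- na >= 1 & nb >= 1 & (na + nb) > 2
  r <- 2
  nbar <- (na + nb) / r
  nc <- (r * nbar - (na^2 + nb^2) / (r * nbar)) / (r - 1)
  pbar <- (na * pa + nb * pb) / (r * nbar)
  s2 <- (na * (pa - pbar)^2 + nb * (pb - pbar)^2) / ((r - 1) * nbar)
  # within-population heterozygosity is unobserved from allele counts alone;
  # use the HWE expectation 2p(1-p) per population
  hbar <- (na * 2 * pa * (1 - pa) + nb * 2 * pb * (1 - pb)) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  num <- den <- rep(NA_real_, length(na))
  num[ok] <- a[ok]
  den[ok] <- (a + b + cc)[ok]
  out <- data.frame(num = num, den = den)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Nucleotide diversity of a set of sites
#'
#' Per-site unbiased heterozygosity `n/(n-1) * 2*p*(1-p)` (equal to the
#' average pairwise difference among the `n` observed chromosomes), summed
#' over sites and divided by the window length in bp.
#'
#' @param counts List with `x`, `n` per site (one population), as from
#'   [allele_counts()].
#' @param window_bp Window length in bp (> 0).
#' @return Diversity per bp; attribute `per_site` carries the per-site
#'   values before length normalisation.
#' @export
nucleotide_diversity <- function(counts, window_bp) {
  if (window_bp <= 0) stop("window length must be positive")
  p <- counts$x / counts$n
  per_site <- ifelse(counts$n >= 2,
                     counts$n / (counts$n - 1) * 2 * p * (1 - p), 0)
  structure(sum(per_site) / window_bp, per_site = per_site)
}

make_windows <- function(chrom_lengths, window, step) {
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, max(0, chrom_lengths[[ch]] - 1), by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, chrom_lengths[[ch]]))
  }))
}

#' Windowed sweep statistics between two populations
#'
#' Slides fixed windows along each chromosome and computes, per window:
#' SNP count, Hudson (or Weir-Cockerham) Fst as a ratio of averages,
#' nucleotide diversity per population, `pi_ratio = log2(pi_a / pi_b)`, and
#' an XP-CLR-style composite likelihood score with population `a` as the
#' reference and `b` as the test (putatively swept) population.
#'
#' @param geno A filtered `genotype_matrix`.
#' @param pops Population labels per sample (exactly two distinct values).
#' @param pop_a,pop_b Which label is the reference (`a`) and test (`b`)
#'   population; default the first and second label in sort order.
#' @param window,step Window size and slide step in bp (defaults 50 kb /
#'   25 kb).
#' @param min_snps Minimum SNPs for a window to be scored (default 5);
#'   windows below it are kept with `NA` statistics.
#' @param fst_estimator `"hudson"` (default) or `"wc"`.
#' @param xpclr `TRUE` to compute the composite likelihood score (slower).
#' @param s_grid Selection-intensity grid for the XP-CLR score; must
#'   contain 0.
#' @return Data frame of class `window_stats`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_snps`, `fst`, `pi_a`, `pi_b`, `pi_ratio`,
#'   `xpclr`.
#' @export
sweep_scan <- function(geno, pops, pop_a = NULL, pop_b = NULL,
                       window = 50000, step = 25000, min_snps = 5,
                       fst_estimator = c("hudson", "wc"),
                       xpclr = TRUE, s_grid = c(0, 0.5, 1, 2, 5, 10)) {
  fst_estimator <- match.arg(fst_estimator)
  labs <- sort(unique(pops))
  if (length(labs) != 2) stop("exactly two populations required")
  if (is.null(pop_a)) pop_a <- labs[1]
  if (is.null(pop_b)) pop_b <- labs[2]
  cn <- allele_counts(geno, pops)
  ca <- cn[[pop_a]]; cb <- cn[[pop_b]]
  fst_fun <- if (fst_estimator == "hudson") site_fst else site_fst_wc
  comp <- fst_fun(ca, cb)
  pa <- ca$x / ca$n
  per_site_pi_a <- attr(nucleotide_diversity(ca, 1), "per_site")
  per_site_pi_b <- attr(nucleotide_diversity(cb, 1), "per_site")
  omega <- if (xpclr) estimate_omega(ca, cb) else NA_real_
  lens <- attr(geno, "chrom_lengths")
  if (is.null(lens)) {
    lens <- tapply(geno$loci$pos, geno$loci$chrom, max)
    lens <- stats::setNames(as.numeric(lens), names(lens))
  }
  win <- make_windows(lens, window, step)
  stats_list <- lapply(seq_len(nrow(win)), function(i) {
    in_w <- which(geno$loci$chrom == win$chrom[i] &
                    geno$loci$pos - 1L >= win$start[i] &
                    geno$loci$pos - 1L < win$end[i])
    bp <- win$end[i] - win$start[i]
    if (length(in_w) < min_snps)
      return(data.frame(n_snps = length(in_w), fst = NA_real_,
                        pi_a = NA_real_, pi_b = NA_real_,
                        pi_ratio = NA_real_, xpclr = NA_real_))
    fst <- sum(comp$num[in_w], na.rm = TRUE) / sum(comp$den[in_w], na.rm = TRUE)
    pia <- sum(per_site_pi_a[in_w]) / bp
    pib <- sum(per_site_pi_b[in_w]) / bp
    xp <- if (xpclr)
      xpclr_score(ca$x[in_w], ca$n[in_w], cb$x[in_w], cb$n[in_w],
                  omega = omega, s_grid = s_grid) else NA_real_
    data.frame(n_snps = length(in_w), fst = fst, pi_a = pia, pi_b = pib,
               pi_ratio = log2(pia / pib), xpclr = xp)
  })
  out <- cbind(win, do.call(rbind, stats_list))
  attr(out, "omega") <- omega
  attr(out, "params") <- list(window = window, step = step,
                              min_snps = min_snps,
                              fst_estimator = fst_estimator,
                              pop_a = pop_a, pop_b = pop_b)
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Genome-wide drift variance for the XP-CLR model
#'
#' Method-of-moments estimate of the scaled drift variance `omega` in the
#' Normal approximation `q ~ N(p, omega * p(1-p))` of test-population
#' frequency around the reference frequency, corrected for binomial
#' sampling noise in both populations.
#'
#' @inheritParams site_fst
#' @return Scalar `omega` (floored at 1e-4).
#' @export
estimate_omega <- function(counts_a, counts_b) {
  pa <- counts_a$x / counts_a$n
  pb <- counts_b$x / counts_b$n
  ok <- counts_a$n >= 2 & counts_b$n >= 2 & pa > 0 & pa < 1
  raw <- ((pa - pb)^2 -
            pa * (1 - pa) / counts_a$n -
            pb * (1 - pb) / counts_b$n) / (pa * (1 - pa))
  max(mean(raw[ok]), 1e-4)
}

# Truncated-normal site likelihood of observing x alt alleles out of n in
# the test population, given latent frequency q ~ N(m, s2) truncated to
# [0,1] with the clipped tails collapsed to point masses at 0 and 1, and
# binomial sampling integrated by Gauss-Legendre quadrature.
xpclr_site_loglik <- function(x, n, m, s2, n_nodes = 48) {
  sd <- sqrt(s2)
  p0 <- stats::pnorm(0, m, sd)
  p1 <- stats::pnorm(1, m, sd, lower.tail = FALSE)
  lo <- pmax(0, m - 10 * sd)
  hi <- pmin(1, m + 10 * sd)
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  # per-site affine map of the reference nodes onto [lo, hi]
  width <- hi - lo
  qmat <- outer(lo, rep(1, n_nodes)) + outer(width, gl$x)   # sites x nodes
  dens <- stats::dnorm(qmat, m, sd)
  lik_b <- stats::dbinom(x, n, pmin(pmax(qmat, 0), 1))
  integral <- (lik_b * dens) %*% gl$w * width
  lik <- p0 * stats::dbinom(x, n, 0) + p1 * stats::dbinom(x, n, 1) +
    as.vector(integral)
  log(pmax(lik, 1e-300))
}

#' XP-CLR-style composite likelihood score for one window
#'
#' For each selection intensity `s` on the grid and each choice of favoured
#' allele, the latent test-population frequency is modelled as Normal around
#' the selection-transformed reference frequency `p -> p^(1/(1+s))`
#' (applied to the favoured allele) with drift variance `omega * m(1-m)`,
#' truncated to `[0,1]` with boundary point masses; observed counts enter
#' through a binomial likelihood integrated over the latent frequency by
#' quadrature. The score is the maximised sum over sites of the
#' log-likelihood ratio against `s = 0`, hence `>= 0` by construction.
#'
#' @param x_a,n_a Reference-population alt counts and chromosome counts.
#' @param x_b,n_b Test-population alt counts and chromosome counts.
#' @param omega Drift variance scale from [estimate_omega()].
#' @param s_grid Grid of selection intensities; must contain 0.
#' @param n_nodes Quadrature nodes.
#' @return Scalar composite log-likelihood ratio.
#' @export
xpclr_score <- function(x_a, n_a, x_b, n_b, omega,
                        s_grid = c(0, 0.5, 1, 2, 5, 10), n_nodes = 48) {
  if (!any(s_grid == 0))
    stop("s_grid must contain 0 (the ratio is undefined without the null)")
  ok <- n_a >= 2 & n_b >= 2
  if (!any(ok)) return(NA_real_)
  pa <- (x_a[ok] + 0.5) / (n_a[ok] + 1)   # shrink away from 0/1
  xb <- x_b[ok]; nb <- n_b[ok]
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  loglik_s <- function(s, favoured_alt) {
    m <- if (favoured_alt) clamp(pa^(1 / (1 + s)))
         else clamp(1 - (1 - pa)^(1 / (1 + s)))
    sum(xpclr_site_loglik(xb, nb, m, pmax(omega, 1e-4) * m * (1 - m),
                          n_nodes = n_nodes))
  }
  l0 <- loglik_s(0, TRUE)   # both directions coincide at s = 0
  best <- max(vapply(s_grid, function(s)
    max(loglik_s(s, TRUE), loglik_s(s, FALSE)), numeric(1)))
  max(best - l0, 0)
}

#' Select candidate sweep regions from window statistics
#'
#' Windows are flagged where each statistic exceeds its top-quantile cut:
#' high `fst`, high `pi_ratio` (diversity loss in the test population) and
#' high `xpclr`. Flags are combined by intersection, union or a 2-of-3
#' vote, and selected windows are merged when they touch or overlap.
#'
#' @param stats A `window_stats` data frame from [sweep_scan()].
#' @param q_fst,q_pi,q_xpclr Quantile thresholds in (0, 1); default 0.99.
#' @param combine `"vote2"` (default), `"intersection"` or `"union"`.
#' @return Data frame of merged regions: `chrom`, `start`, `end`,
#'   `n_windows`, `max_fst`, `max_xpclr`.
#' @export
select_sweep_regions <- function(stats, q_fst = 0.99, q_pi = 0.99,
                                 q_xpclr = 0.99,
                                 combine = c("vote2", "intersection",
                                             "union")) {
  combine <- match.arg(combine)
  if (nrow(stats) == 0) stop("empty window statistics")
  stopifnot(q_fst > 0, q_fst < 1, q_pi > 0, q_pi < 1,
            q_xpclr > 0, q_xpclr < 1)
  cut_of <- function(v, q) {
    fin <- v[is.finite(v)]
    if (length(fin) == 0) Inf else stats::quantile(fin, q, names = FALSE)
  }
  pass <- cbind(
    fst = stats$fst >= cut_of(stats$fst, q_fst),
    pi = stats$pi_ratio >= cut_of(stats$pi_ratio, q_pi),
    xpclr = stats$xpclr >= cut_of(stats$xpclr, q_xpclr))
  pass[is.na(pass)] <- FALSE
  votes <- rowSums(pass)
  sel <- switch(combine,
                intersection = votes == 3,
                union = votes >= 1,
                vote2 = votes >= 2)
  if (!any(sel)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      max_fst = numeric(0), max_xpclr = numeric(0)))
  }
  w <- stats[sel, , drop = FALSE]
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  grp <- cumsum(c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                    w$start[-1] > w$end[-nrow(w)]))
  out <- do.call(rbind, lapply(split(w, grp), function(g)
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               n_windows = nrow(g),
               max_fst = max(g$fst, na.rm = TRUE),
               max_xpclr = suppressWarnings(max(g$xpclr, na.rm = TRUE)))))
  rownames(out) <- NULL
  out
}

#' Loci falling in a set of regions
#'
#' @param geno A `genotype_matrix`.
#' @param regions Data frame `chrom`, `start`, `end` (0-based half-open).
#' @return The loci table rows inside any region.
#' @export
loci_in_regions <- function(geno, regions) {
  if (nrow(regions) == 0) return(geno$loci[0, , drop = FALSE])
  hit <- rep(FALSE, n_loci(geno))
  for (i in seq_len(nrow(regions)))
    hit <- hit | (geno$loci$chrom == regions$chrom[i] &
                    geno$loci$pos - 1L >= regions$start[i] &
                    geno$loci$pos - 1L < regions$end[i])
  geno$loci[hit, , drop = FALSE]
}
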