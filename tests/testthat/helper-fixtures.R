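# Small builders shared across test files.

# genotype matrix from a dosage matrix, loci auto-numbered on one chromosome
toy_geno <- function(calls, chrom = "chr1", spacing = 1000, pos = NULL,
                     chrom_lengths = NULL) {
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * spacing
  genotype_matrix(calls, data.frame(chrom = chrom, pos = pos,
                                    ref = "A", alt = "C"),
                  chrom_lengths = chrom_lengths)
}

# independent Hudson per-site computation used as the brute-force oracle
oracle_hudson <- function(xa, na, xb, nb) {
  pa <- xa / na
  pb <- xb / nb
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  list(num = num, den = den)
}

# average pairwise difference per site over a haplotype matrix
# (haplotypes in rows, sites in columns, entries 0/1)
oracle_pairwise_pi <- function(hap) {
  n <- nrow(hap)
  total <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      total <- total + sum(hap[i, ] != hap[j, ])
  total / choose(n, 2)
}

# dense numeric integration oracle for the truncated-normal binomial
# site likelihood
oracle_site_lik <- function(x, n, m, s2) {
  sd <- sqrt(s2)
  p0 <- pnorm(0, m, sd)
  p1 <- pnorm(1, m, sd, lower.tail = FALSE)
  cont <- stats::integrate(function(q) dbinom(x, n, q) * dnorm(q, m, sd),
                           lower = 0, upper = 1, rel.tol = 1e-12,
                           subdivisions = 2000L)$value
  p0 * dbinom(x, n, 0) + p1 * dbinom(x, n, 1) + cont
}

# 99% binomial interval for a count
binom_interval99 <- function(n, p) qbinom(c(0.005, 0.995), n, p)
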