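#' De-regress an estimated breeding value
#'
#' Removes the parent-average contribution from an EBV and undoes the
#' shrinkage of genetic evaluation, following the two-equation
#' mixed-model-equations recipe of Garrick, Taylor and Fernando (2009).
#' With `lambda = (1 - h2)/h2`:
#' `alpha = 1/(0.5 - pa_rel)`, `delta = (0.5 - pa_rel)/(1 - rel)`,
#' `ZpZ_pa = lambda * (0.5 * alpha - 1)`,
#' `ZpZ_i = delta * ZpZ_pa + 2 * lambda * (2 * delta - 1)`;
#' the de-regressed information is `y* = -2 * lambda * pa_ebv +
#' (ZpZ_i + 2 * lambda) * ebv` and `debv = y* / ZpZ_i`. The de-regressed
#' reliability is `r2* = ZpZ_i / (ZpZ_i + lambda)` and the analysis weight
#' `w = (1 - h2) / ((c + (1 - r2*)/r2*) * h2)`.
#'
#' As parent-average information vanishes (`pa_rel -> 0`, `pa_ebv = 0`) the
#' de-regressed value tends to `ebv / rel`.
#'
#' @param ebv Estimated breeding value(s).
#' @param rel EBV reliability r-squared in (0, 1); must exceed `pa_rel`.
#' @param pa_ebv Parent-average EBV (default 0).
#' @param pa_rel Parent-average reliability in (0, 0.5).
#' @param h2 Heritability used for `lambda`; default 0.3.
#' @param c_frac Fraction of genetic variance not captured by markers, in
#'   [0, 1); default 0.1.
#' @return Data frame of class `debv_table`: `ebv`, `rel`, `pa_ebv`,
#'   `pa_rel`, `debv`, `debv_rel`, `weight`, `c`.
#' @export
deregress_ebv <- function(ebv, rel, pa_ebv = 0, pa_rel = 0.1,
                          h2 = 0.3, c_frac = 0.1) {
  stopifnot(h2 > 0, h2 < 1, c_frac >= 0, c_frac < 1)
  k <- max(length(ebv), length(rel))
  ebv <- rep_len(ebv, k); rel <- rep_len(rel, k)
  pa_ebv <- rep_len(pa_ebv, k); pa_rel <- rep_len(pa_rel, k)
  if (any(rel <= pa_rel))
    stop("no own information: reliability must exceed parent-average ",
         "reliability for every animal")
  if (any(pa_rel <= 0 | pa_rel >= 0.5))
    stop("parent-average reliability must lie in (0, 0.5)")
  rel <- pmin(rel, 1 - 1e-8)  # guard division at rel -> 1
  lambda <- (1 - h2) / h2
  alpha <- 1 / (0.5 - pa_rel)
  delta <- (0.5 - pa_rel) / (1 - rel)
  zpz_pa <- lambda * (0.5 * alpha - 1)
  zpz_i <- delta * zpz_pa + 2 * lambda * (2 * delta - 1)
  ystar <- -2 * lambda * pa_ebv + (zpz_i + 2 * lambda) * ebv
  debv <- ystar / zpz_i
  r2_star <- zpz_i / (zpz_i + lambda)
  weight <- (1 - h2) / ((c_frac + (1 - r2_star) / r2_star) * h2)
  structure(data.frame(ebv = ebv, rel = rel, pa_ebv = pa_ebv,
                       pa_rel = pa_rel, debv = debv, debv_rel = r2_star,
                       weight = weight, c = c_frac),
            class = c("debv_table", "data.frame"))
}

#' Blend a de-regressed value back into an EBV
#'
#' The forward counterpart of [deregress_ebv()]: given the parent average,
#' the de-regressed value and its weight, reconstructs the EBV and its
#' reliability by re-solving the same 2x2 mixed-model equations. Used to
#' verify the de-regression round-trips.
#'
#' @param debv De-regressed value(s).
#' @param weight De-regression weight(s).
#' @param pa_ebv,pa_rel Parent-average EBV and reliability.
#' @param h2,c_frac As in [deregress_ebv()].
#' @return Data frame with `ebv`, `rel`.
#' @export
blend_debv <- function(debv, weight, pa_ebv = 0, pa_rel = 0.1,
                       h2 = 0.3, c_frac = 0.1) {
  lambda <- (1 - h2) / h2
  t <- (1 - h2) / (weight * h2) - c_frac  # (1 - r2*)/r2*
  r2_star <- 1 / (1 + t)
  zpz_i <- lambda * r2_star / (1 - r2_star)
  alpha <- 1 / (0.5 - pa_rel)
  zpz_pa <- lambda * (0.5 * alpha - 1)
  delta <- (zpz_i + 2 * lambda) / (zpz_pa + 4 * lambda)
  rel <- 1 - (0.5 - pa_rel) / delta
  ystar <- debv * zpz_i
  ebv <- (ystar + 2 * lambda * pa_ebv) / (zpz_i + 2 * lambda)
  data.frame(ebv = ebv, rel = rel)
}

#' Realized (genomic) relationship matrix
#'
#' VanRaden method 1: `G = Z Z' / (2 * sum(p_k (1 - p_k)))` with `Z` the
#' call matrix centred by twice the allele frequency; missing genotypes are
#' mean-imputed before centring. A small ridge (1e-6) is added to the
#' diagonal so the matrix is numerically positive semi-definite.
#'
#' @param geno A `genotype_matrix`; monomorphic loci are dropped.
#' @return Symmetric n x n matrix with sample ids as dimnames.
#' @export
build_grm <- function(geno) {
  M <- geno$calls
  if (any(rowSums(!is.na(M)) == 0))
    stop("sample with no observed genotypes")
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all loci monomorphic: GRM denominator is zero")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  storage.mode(M) <- "double"
  idx <- which(is.na(M))
  if (length(idx) > 0)
    M[idx] <- (2 * p)[((idx - 1) %/% nrow(M)) + 1]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  diag(G) <- diag(G) + 1e-6
  dimnames(G) <- list(geno$samples, geno$samples)
  G
}

#' REML variance components under the polygenic null model
#'
#' Fits `y = mu + g + e`, `g ~ N(0, sigma_a^2 G)`,
#' `e ~ N(0, sigma_e^2 W^{-1})` (`W = diag(weights)`), by the
#' single-eigendecomposition trick: after scaling by `sqrt(W)` and rotating
#' into the eigenbasis of the scaled relationship matrix, the restricted
#' likelihood is profiled down to the scalar variance ratio
#' `lambda = sigma_e^2 / sigma_a^2` and maximised by bounded search on
#' `log(lambda)`.
#'
#' @param y Response vector (e.g. DEBVs).
#' @param G Relationship matrix from [build_grm()].
#' @param weights Positive analysis weights (e.g. de-regression weights);
#'   normalised to mean 1 so equal weights reproduce the unweighted fit.
#' @return List: `sigma_a2`, `sigma_e2`, `h2` (ratio on the G scale),
#'   `lambda`, `loglik`, plus the rotation (`U`, `d`, `sy`, `sX`) reused by
#'   [single_marker_scan()].
#' @export
fit_null_reml <- function(y, G, weights = NULL) {
  n <- length(y)
  if (n < 10) stop("need at least 10 observations for REML")
  stopifnot(nrow(G) == n, ncol(G) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive")
  w <- weights / mean(weights)
  sw <- sqrt(w)
  Gs <- G * tcrossprod(sw)
  eig <- eigen(Gs, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  sy <- as.vector(crossprod(U, sw * y))
  sX <- crossprod(U, matrix(sw, ncol = 1))
  neg2_reml <- function(loglam) {
    lam <- exp(loglam)
    v <- d + lam
    XtVX <- crossprod(sX / v, sX)
    beta <- solve(XtVX, crossprod(sX / v, sy))
    r <- sy - sX %*% beta
    S <- sum(r^2 / v)
    (n - 1) * log(S / (n - 1)) + sum(log(v)) + determinant(XtVX)$modulus[1]
  }
  opt <- stats::optimize(neg2_reml, interval = c(-12, 12))
  if (!is.finite(opt$objective))
    stop("non-finite restricted likelihood; check y and G for degeneracy")
  lam <- exp(opt$minimum)
  v <- d + lam
  XtVX <- crossprod(sX / v, sX)
  beta <- solve(XtVX, crossprod(sX / v, sy))
  S <- sum((sy - sX %*% beta)^2 / v)
  sigma_a2 <- S / (n - 1)
  sigma_e2 <- lam * sigma_a2
  list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
       h2 = sigma_a2 / (sigma_a2 + sigma_e2), lambda = lam,
       loglik = -0.5 * opt$objective,
       U = U, d = d, sy = sy, sX = sX, sw = sw)
}

#' Single-marker mixed-model association scan
#'
#' EMMAX-style scan: the variance ratio from [fit_null_reml()] is held
#' fixed across markers; each marker is tested by generalized least squares
#' in the rotated eigenbasis, with the residual scale re-profiled per
#' marker, and a two-sided Wald test of the marker effect against the
#' standard Normal. Missing genotypes are mean-imputed (consistent with the
#' GRM). Monomorphic markers are flagged and reported with `p = 1`.
#'
#' @param y Response vector.
#' @param geno A `genotype_matrix` (markers to test).
#' @param null Fit from [fit_null_reml()] on the same samples.
#' @return Data frame of class `assoc_scan`: `chrom`, `pos`, `beta`, `se`,
#'   `p`, `monomorphic`.
#' @export
single_marker_scan <- function(y, geno, null) {
  n <- length(y)
  stopifnot(n_samples(geno) == n)
  M <- geno$calls
  storage.mode(M) <- "double"
  p_frq <- colMeans(M, na.rm = TRUE) / 2
  idx <- which(is.na(M))
  if (length(idx) > 0)
    M[idx] <- (2 * p_frq)[((idx - 1) %/% nrow(M)) + 1]
  mono <- apply(M, 2, function(col) length(unique(col)) == 1)
  v <- null$d + null$lambda
  sy <- null$sy
  x0 <- as.vector(null$sX)
  SZ <- crossprod(null$U, null$sw * M)     # rotated, weighted markers
  iv <- 1 / v
  a11 <- sum(x0^2 * iv)
  a12 <- as.vector(crossprod(SZ, x0 * iv))
  a22 <- as.vector(crossprod(SZ^2, iv))
  b0 <- sum(x0 * sy * iv)
  b1 <- as.vector(crossprod(SZ, sy * iv))
  det <- a11 * a22 - a12^2
  beta1 <- (a11 * b1 - a12 * b0) / det
  beta0 <- (b0 - a12 * beta1) / a11
  yy <- sum(sy^2 * iv)
  rss <- yy - (beta0 * b0 + beta1 * b1)
  sigma2 <- pmax(rss, 0) / (n - 2)
  se <- sqrt(sigma2 * a11 / det)
  z <- beta1 / se
  p <- 2 * stats::pnorm(-abs(z))
  beta1[mono] <- 0
  se[mono] <- NA_real_
  p[mono] <- 1
  structure(data.frame(chrom = geno$loci$chrom, pos = geno$loci$pos,
                       beta = beta1, se = se, p = p, monomorphic = mono),
            class = c("assoc_scan", "data.frame"))
}

#' Genome-wide and suggestive significance thresholds
#'
#' @param genomewide Genome-wide significance level (default `5e-8`).
#' @param suggestive Suggestive-association level (default `1e-5`).
#' @return Named list with the two thresholds.
#' @export
significance_lines <- function(genomewide = 5e-8, suggestive = 1e-5) {
  if (genomewide <= 0 || suggestive <= 0)
    stop("significance thresholds must be positive")
  list(genomewide = genomewide, suggestive = suggestive)
}

#' Genomic inflation factor
#'
#' Median chi-squared statistic of the scan divided by the median of the
#' null chi-squared(1) distribution.
#'
#' @param p Vector of p-values.
#' @return Scalar lambda_GC.
#' @export
genomic_inflation <- function(p) {
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, df = 1,
                                                     lower.tail = FALSE)
}
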