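#' Target detection rates by depth threshold
#'
#' For each sample, the fraction of designed targets detected at each depth
#' cut. `dp0` counts targets with depth strictly greater than 0; the other
#' thresholds use depth `>= t` (so `dp5` means at least 5 reads). These
#' semantics make the rates monotone non-increasing in the threshold.
#'
#' @param depths Targets x samples matrix of non-negative read depths.
#' @param thresholds Integer depth cuts; default `c(1, 5, 20)` reported as
#'   `dp0`, `dp5`, `dp20` (threshold 1 is depth > 0).
#' @return List: `per_sample` (samples x thresholds data frame of rates)
#'   and `mean` (named vector of the across-sample averages), rates in
#'   [0, 1].
#' @export
detection_rates <- function(depths, thresholds = c(1, 5, 20)) {
  if (length(depths) == 0) stop("empty depth matrix")
  if (any(depths < 0)) stop("negative read depth")
  if (is.null(colnames(depths)))
    colnames(depths) <- paste0("S", seq_len(ncol(depths)))
  thresholds <- sort(thresholds)
  rates <- sapply(thresholds, function(t) colMeans(depths >= t))
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  lab <- ifelse(thresholds == 1, "dp0", paste0("dp", thresholds))
  colnames(rates) <- lab
  per_sample <- as.data.frame(rates)
  per_sample <- cbind(sample = colnames(depths), per_sample)
  rownames(per_sample) <- NULL
  list(per_sample = per_sample, mean = colMeans(rates))
}

#' Flank-depth profile and decay fit
#'
#' Averages depth per offset bin, pooling symmetric offsets (`-x` and `+x`),
#' and fits a two-segment exponential decay (inner segment up to 100 bp,
#' outer beyond) by log-linear regression, mirroring how capture depth
#' falls away from the probe target.
#'
#' @param flank Offsets x samples matrix; rownames are signed offsets in bp
#'   and must include 0.
#' @return List: `profile` (data frame `offset`, `mean_depth` over pooled
#'   absolute offsets), `fit` (named vector: `depth0`, `rate_inner`,
#'   `rate_outer` per bp) and `fitted_at` (fitted depths at 0/100/250 bp).
#' @export
flank_profile <- function(flank) {
  offs <- as.numeric(rownames(flank))
  if (!any(offs == 0)) stop("flank depths must include the on-target offset 0")
  pooled <- tapply(rowMeans(flank), abs(offs), mean)
  profile <- data.frame(offset = as.numeric(names(pooled)),
                        mean_depth = as.numeric(pooled))
  profile <- profile[order(profile$offset), ]
  inner <- profile$offset <= 100
  fit_seg <- function(rows) {
    if (sum(rows) < 2) return(c(intercept = NA_real_, rate = 0))
    co <- stats::coef(stats::lm(log(mean_depth) ~ offset,
                                data = profile[rows, ]))
    c(intercept = unname(co[1]), rate = -unname(co[2]))
  }
  fi <- fit_seg(inner)
  fo <- fit_seg(!inner | profile$offset == 100)
  depth0 <- exp(fi["intercept"])
  fitted_at <- c(`0` = unname(exp(fi["intercept"])),
                 `100` = unname(exp(fi["intercept"] - fi["rate"] * 100)),
                 `250` = unname(exp(fo["intercept"] - fo["rate"] * 250)))
  list(profile = profile,
       fit = c(depth0 = unname(depth0), rate_inner = unname(fi["rate"]),
               rate_outer = unname(fo["rate"])),
       fitted_at = fitted_at)
}

#' Minor-allele-frequency spectrum of captured genotypes
#'
#' @param gbts_geno A `genotype_matrix` of capture calls.
#' @param maf_cut Report the fraction of loci with MAF strictly above this
#'   value (default 0.05).
#' @param breaks Histogram breaks over [0, 0.5].
#' @return List: `fraction_above` (in [0, 1]), `maf` (per-locus values)
#'   and `hist`.
#' @export
captured_maf_spectrum <- function(gbts_geno, maf_cut = 0.05,
                                  breaks = seq(0, 0.5, by = 0.05)) {
  if (n_samples(gbts_geno) < 2)
    stop("MAF spectrum needs at least 2 samples")
  maf <- locus_stats(gbts_geno)$maf
  maf_obs <- maf[!is.na(maf)]
  list(fraction_above = mean(maf_obs > maf_cut),
       maf = maf,
       hist = table(cut(maf_obs, breaks = breaks, include.lowest = TRUE)))
}

concordance_categories <- function() {
  c("concordant", "gbts_miss", "wgs_miss", "gbts_hom", "wgs_hom",
    "opposite_hom")
}

#' Classify one capture-vs-WGS genotype pair
#'
#' Rulebook over dosage codes (`0` hom-ref, `1` het, `2` hom-alt, `NA`
#' no-call):
#' equal non-missing calls are `concordant`; a capture no-call against a
#' WGS call is `gbts_miss` (and the mirror `wgs_miss`); a capture
#' homozygote against a WGS heterozygote is `gbts_hom` (one allele lost on
#' capture; mirror `wgs_hom`); opposite homozygotes are `opposite_hom`.
#' Pairs missing on both platforms are not compared (`NA` returned).
#'
#' @param gbts_call,wgs_call Dosage codes, vectorised.
#' @return Character vector of categories (`NA` where both are no-calls).
#' @export
classify_genotype_pair <- function(gbts_call, wgs_call) {
  k <- max(length(gbts_call), length(wgs_call))
  g <- rep_len(as.integer(gbts_call), k)
  w <- rep_len(as.integer(wgs_call), k)
  valid <- function(x) is.na(x) | x %in% 0:2
  if (!all(valid(g)) || !all(valid(w)))
    stop("unknown genotype code; expected 0, 1, 2 or NA")
  out <- rep(NA_character_, k)
  out[!is.na(g) & !is.na(w) & g == w] <- "concordant"
  out[is.na(g) & !is.na(w)] <- "gbts_miss"
  out[!is.na(g) & is.na(w)] <- "wgs_miss"
  out[!is.na(g) & !is.na(w) & g != 1 & w == 1] <- "gbts_hom"
  out[!is.na(g) & !is.na(w) & g == 1 & w != 1] <- "wgs_hom"
  out[!is.na(g) & !is.na(w) & abs(g - w) == 2] <- "opposite_hom"
  out
}

#' Capture-vs-WGS concordance summary
#'
#' Applies [classify_genotype_pair()] over every shared sample x locus
#' pair (loci matched by chrom and position), and aggregates: overall
#' concordance among compared pairs, each discordance category's share of
#' the discordant pairs, and the capture-attributed share
#' (`gbts_miss + gbts_hom`). Two aggregations of concordance are reported:
#' pooled over all pairs, and the mean of per-sample concordances.
#'
#' @param gbts_geno,wgs_geno `genotype_matrix` objects sharing samples.
#' @param loci_subset Optional data frame `chrom`, `pos` restricting the
#'   comparison (e.g. the designed panel).
#' @return List of class `concordance_table`: `counts` (named category
#'   counts), `n_compared`, `concordance`, `concordance_by_sample` (vector)
#'   `mean_sample_concordance`, `discordant_shares`, `gbts_attributed`.
#' @export
concordance_summary <- function(gbts_geno, wgs_geno, loci_subset = NULL) {
  shared <- intersect(gbts_geno$samples, wgs_geno$samples)
  if (length(shared) == 0) stop("no shared samples")
  key_g <- paste(gbts_geno$loci$chrom, gbts_geno$loci$pos)
  key_w <- paste(wgs_geno$loci$chrom, wgs_geno$loci$pos)
  keys <- intersect(key_g, key_w)
  if (!is.null(loci_subset))
    keys <- intersect(keys, paste(loci_subset$chrom, loci_subset$pos))
  if (length(keys) == 0) stop("no shared loci between the two call sets")
  G <- gbts_geno$calls[match(shared, gbts_geno$samples),
                       match(keys, key_g), drop = FALSE]
  W <- wgs_geno$calls[match(shared, wgs_geno$samples),
                      match(keys, key_w), drop = FALSE]
  cat_mat <- matrix(classify_genotype_pair(as.vector(G), as.vector(W)),
                    nrow = nrow(G))
  lv <- concordance_categories()
  counts <- table(factor(cat_mat, levels = lv))
  n_compared <- sum(counts)
  disc <- counts[setdiff(lv, "concordant")]
  per_sample <- apply(cat_mat, 1, function(r) {
    cmp <- sum(!is.na(r))
    if (cmp == 0) NA_real_ else sum(r == "concordant", na.rm = TRUE) / cmp
  })
  names(per_sample) <- shared
  structure(list(
    counts = counts,
    n_compared = n_compared,
    concordance = as.numeric(counts["concordant"]) / n_compared,
    concordance_by_sample = per_sample,
    mean_sample_concordance = mean(per_sample, na.rm = TRUE),
    discordant_shares = if (sum(disc) > 0) disc / sum(disc) else disc * NA,
    gbts_attributed = if (sum(disc) > 0)
      as.numeric(counts["gbts_miss"] + counts["gbts_hom"]) / sum(disc)
      else NA_real_),
    class = "concordance_table")
}

#' @exportS3Method base::print
print.concordance_table <- function(x, ...) {
  cat(sprintf("concordance: %.2f%% of %d compared pairs\n",
              100 * x$concordance, x$n_compared))
  if (!is.na(x$gbts_attributed))
    cat(sprintf("capture-attributed discordance (gbts_miss + gbts_hom): %.2f%%\n",
                100 * x$gbts_attributed))
  print(x$counts)
  invisible(x)
}
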