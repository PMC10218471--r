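#' Construct a genotype matrix
#'
#' The central container for diploid biallelic genotype data: an integer
#' matrix of alternate-allele dosages (samples in rows, loci in columns,
#' `NA` = missing call) plus a per-locus metadata table.
#'
#' @param calls Integer matrix, samples x loci, values in `{0, 1, 2, NA}`
#'   counting copies of the alternate allele.
#' @param loci Data frame with at least columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`. Additional columns (e.g. `QUAL`, `QD`, `SOR`, `MQ`, `FS`,
#'   `MQRankSum`, `ReadPosRankSum`) are carried along as site annotations.
#' @param samples Character vector of sample ids, one per row of `calls`.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths
#'   in bp; used when writing VCF headers and when windowing.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, samples = rownames(calls),
                            chrom_lengths = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  stopifnot(is.data.frame(loci))
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0)
    stop("loci table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(loci) != ncol(calls))
    stop("loci table has ", nrow(loci), " rows but calls has ", ncol(calls),
         " columns")
  if (length(samples) != nrow(calls))
    stop("sample ids and call rows disagree")
  bad <- calls[!is.na(calls)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(loci$ref == loci$alt))
    stop("ref and alt alleles must differ at every locus")
  loci$chrom <- as.character(loci$chrom)
  ord <- order(loci$chrom, loci$pos)
  if (!identical(ord, seq_len(nrow(loci)))) {
    loci <- loci[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  if (anyDuplicated(paste(loci$chrom, loci$pos)))
    stop("duplicate (chrom, pos) in loci table")
  rownames(loci) <- NULL
  dimnames(calls) <- list(samples, NULL)
  structure(
    list(calls = calls, loci = loci, samples = as.character(samples)),
    chrom_lengths = chrom_lengths,
    class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$loci), "loci on", length(unique(x$loci$chrom)),
      "chromosome(s)\n")
  st <- locus_stats(x)
  cat(sprintf("  mean MAF %.3f, mean missing rate %.4f\n",
              mean(st$maf, na.rm = TRUE), mean(st$miss)))
  invisible(x)
}

#' Number of samples / loci in a genotype matrix
#' @param geno A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(geno) length(geno$samples)

#' @rdname n_samples
#' @export
n_loci <- function(geno) nrow(geno$loci)

#' Per-locus minor allele frequency and missing rate
#'
#' Both statistics are recomputed from the call matrix, never trusted from
#' annotations: `miss` is the fraction of samples with a missing call, `maf`
#' the folded allele frequency `min(p, 1 - p)` among observed alleles.
#'
#' @param geno A `genotype_matrix`.
#' @return Data frame with columns `chrom`, `pos`, `maf`, `miss`. `maf` is
#'   `NA` where no genotype is observed.
#' @export
locus_stats <- function(geno) {
  calls <- geno$calls
  n <- nrow(calls)
  n_miss <- colSums(is.na(calls))
  n_obs <- n - n_miss
  alt <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  data.frame(chrom = geno$loci$chrom, pos = geno$loci$pos,
             maf = pmin(p, 1 - p), miss = n_miss / n)
}

#' Subset a genotype matrix
#'
#' @param geno A `genotype_matrix`.
#' @param samples Index/logical/character vector of samples to keep.
#' @param loci Index or logical vector of loci (columns) to keep.
#' @return A `genotype_matrix`.
#' @export
subset_geno <- function(geno, samples = NULL, loci = NULL) {
  calls <- geno$calls
  tab <- geno$loci
  ids <- geno$samples
  if (!is.null(loci)) {
    calls <- calls[, loci, drop = FALSE]
    tab <- tab[loci, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, ids)
    calls <- calls[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  genotype_matrix(calls, tab, ids, chrom_lengths = attr(geno, "chrom_lengths"))
}

# The seven GATK-style hard-filter annotations handled on read/write.
# MORankSum is accepted as an alias for MQRankSum (a common transcription
# slip for that key).
info_keys <- function() {
  c("QD", "SOR", "MQ", "FS", "MQRankSum", "ReadPosRankSum")
}

#' Read a VCF file into a genotype matrix
#'
#' Parses a VCFv4.2 file (via \pkg{vcfR}) with diploid `GT` calls. `CHROM`,
#' `POS`, `REF`, `ALT`, `QUAL` and the hard-filter INFO annotations
#' (`QD`, `SOR`, `MQ`, `FS`, `MQRankSum`, `ReadPosRankSum`) are retained as
#' locus columns.
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @param multiallelic What to do with records carrying more than one ALT
#'   allele: `"error"` (default) aborts naming the first offending record,
#'   `"drop"` removes them.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic record at ", fix$CHROM[which(multi)[1]], ":",
           fix$POS[which(multi)[1]], "; rerun with multiallelic = \"drop\"")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field: ", path)
  gt_chr <- gsub("|", "/", gt_raw, fixed = TRUE)
  known <- c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  unknown <- setdiff(unique(as.vector(gt_chr[!is.na(gt_chr)])), known)
  if (length(unknown) > 0)
    stop("non-diploid or unsupported GT value(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  code <- matrix(NA_integer_, nrow = nrow(gt_chr), ncol = ncol(gt_chr))
  code[gt_chr == "0/0"] <- 0L
  code[gt_chr %in% c("0/1", "1/0")] <- 1L
  code[gt_chr == "1/1"] <- 2L
  calls <- t(code)
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  if (any(!is.na(qual))) loci$QUAL <- qual
  for (key in info_keys()) {
    val <- suppressWarnings(as.numeric(
      vcfR::extract.info(v, element = key)))
    if (key == "MQRankSum" && all(is.na(val)))
      val <- suppressWarnings(as.numeric(
        vcfR::extract.info(v, element = "MORankSum")))
    if (any(!is.na(val))) loci[[key]] <- val
  }
  # reject unsorted input rather than silently reordering
  ord <- order(loci$chrom, loci$pos)
  if (!identical(ord, seq_len(nrow(loci))))
    stop("VCF records are not sorted by (CHROM, POS): ", path)
  lens <- vcf_contig_lengths(path)
  genotype_matrix(calls, loci, colnames(gt_chr), chrom_lengths = lens)
}

vcf_contig_lengths <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lens <- c()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "##")) break
    m <- regmatches(line,
      regexec("^##contig=<ID=([^,>]+),length=([0-9]+)", line))[[1]]
    if (length(m) == 3) lens[m[2]] <- as.numeric(m[3])
  }
  if (length(lens) == 0) NULL else lens
}

#' Write a genotype matrix as VCFv4.2
#'
#' Emits a plain-text VCF with diploid `GT` calls; `QUAL` and any of the
#' hard-filter INFO annotations present as locus columns are round-tripped.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  loci <- geno$loci
  hdr <- c("##fileformat=VCFv4.2", "##source=panelforge")
  lens <- attr(geno, "chrom_lengths")
  if (!is.null(lens))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(lens), as.integer(lens)))
  present <- intersect(info_keys(), names(loci))
  hdr <- c(hdr, sprintf(
    "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
    present, present))
  hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", geno$samples),
                      collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 10))
  info <- rep("", nrow(loci))
  for (key in present) {
    val <- fmt_num(loci[[key]])
    piece <- ifelse(is.na(val), "", paste0(key, "=", val))
    info <- ifelse(piece == "", info,
                   ifelse(info == "", piece, paste(info, piece, sep = ";")))
  }
  info[info == ""] <- "."
  qual <- if ("QUAL" %in% names(loci)) {
    q <- fmt_num(loci$QUAL); ifelse(is.na(q), ".", q)
  } else rep(".", nrow(loci))
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(geno$calls), ncol = nrow(geno$calls))
  obs <- !is.na(t(geno$calls))
  gt[obs] <- gt_map[t(geno$calls)[obs] + 1L]
  body <- paste(loci$chrom, loci$pos, ".", loci$ref, loci$alt, qual, "PASS",
                info, "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' GATK-style hard-filter rules
#'
#' The default rule set used for site-level hard filtering of raw variant
#' calls: a site fails if any comparison fires.
#'
#' @return Data frame with columns `key`, `op`, `threshold`.
#' @export
default_hard_filters <- function() {
  data.frame(
    key = c("QD", "QUAL", "SOR", "MQ", "FS", "MQRankSum", "ReadPosRankSum"),
    op = c("<", "<", ">", "<", ">", "<", "<"),
    threshold = c(2.0, 30.0, 3.0, 40.0, 60.0, -12.5, -8.0),
    stringsAsFactors = FALSE)
}

#' Apply hard-filter rules to site annotations
#'
#' A locus fails if ANY rule fires (standard GATK hard-filter semantics).
#' A missing annotation cannot fire its rule, so the locus passes that rule;
#' the number of such skipped comparisons is attached as an attribute.
#'
#' @param geno A `genotype_matrix` whose loci table carries the annotation
#'   columns named by the rules (absent columns count as missing).
#' @param rules Data frame with columns `key`, `op` (`"<"` or `">"`) and
#'   `threshold`; defaults to [default_hard_filters()].
#' @return Logical vector, `TRUE` where the locus FAILS; attribute
#'   `n_missing_annotation` counts rule evaluations skipped for lack of the
#'   annotation.
#' @export
hard_filter_info <- function(geno, rules = default_hard_filters()) {
  stopifnot(all(c("key", "op", "threshold") %in% names(rules)))
  fails <- rep(FALSE, n_loci(geno))
  skipped <- 0L
  for (i in seq_len(nrow(rules))) {
    op <- rules$op[i]
    if (!op %in% c("<", ">"))
      stop("unknown operator in hard-filter rule: ", op)
    key <- rules$key[i]
    col <- if (key %in% names(geno$loci)) geno$loci[[key]]
           else rep(NA_real_, n_loci(geno))
    fire <- if (op == "<") col < rules$threshold[i] else col > rules$threshold[i]
    skipped <- skipped + sum(is.na(fire))
    fire[is.na(fire)] <- FALSE
    fails <- fails | fire
  }
  attr(fails, "n_missing_annotation") <- skipped
  fails
}

#' Site-level filtering by missing rate, MAF and chromosome
#'
#' Removes loci with missing rate `>= max_miss`, minor allele frequency
#' `< min_maf` (strict, so a locus at exactly `min_maf` survives), or
#' chromosome outside `keep_chroms`. Both statistics are recomputed from the
#' call matrix before filtering.
#'
#' @param geno A `genotype_matrix`.
#' @param max_miss Missing-rate cut in `[0, 1]`; default 0.1.
#' @param min_maf MAF cut in `[0, 0.5]`; default 0.05.
#' @param keep_chroms Character vector of chromosomes to keep; defaults to
#'   every chromosome present. An explicitly empty vector is an error.
#' @return The filtered `genotype_matrix`.
#' @export
filter_sites <- function(geno, max_miss = 0.1, min_maf = 0.05,
                         keep_chroms = NULL) {
  stopifnot(max_miss >= 0, max_miss <= 1, min_maf >= 0, min_maf <= 1)
  if (is.null(keep_chroms)) keep_chroms <- unique(geno$loci$chrom)
  if (length(keep_chroms) == 0) stop("keep_chroms must name >= 1 chromosome")
  st <- locus_stats(geno)
  maf <- st$maf
  maf[is.na(maf)] <- 0  # fully-missing locus: treat as monomorphic, removed
  keep <- st$miss < max_miss & maf >= min_maf & st$chrom %in% keep_chroms
  subset_geno(geno, loci = keep)
}
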