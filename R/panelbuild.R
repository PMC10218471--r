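#' Candidate loci overlapping QTL regions
#'
#' Returns the candidate loci whose position falls inside at least one
#' trait-tagged interval, annotated with all matching trait tags. BED
#' conventions: regions are 0-based half-open, so a locus sitting exactly
#' on a region start is included and one on the end is excluded. Interval
#' matching is done with \pkg{IRanges}; both inputs must be sorted.
#'
#' @param candidates Loci data frame with `chrom`, `pos` (1-based), sorted
#'   by (chrom, pos).
#' @param regions QTL data frame with `chrom`, `start`, `end`,
#'   `trait_tag`, sorted by (chrom, start).
#' @return The subset of `candidates` inside a region, with a `trait_tags`
#'   column (comma-joined when a locus hits several regions).
#' @export
overlap_qtl <- function(candidates, regions) {
  if (!identical(order(candidates$chrom, candidates$pos),
                 seq_len(nrow(candidates))))
    stop("candidate loci must be sorted by (chrom, pos)")
  if (nrow(regions) > 0 &&
      !identical(order(regions$chrom, regions$start),
                 seq_len(nrow(regions))))
    stop("QTL regions must be sorted by (chrom, start)")
  out <- candidates[0, , drop = FALSE]
  out$trait_tags <- character(0)
  if (nrow(regions) == 0 || nrow(candidates) == 0) return(out)
  hits_all <- integer(0)
  tags <- list()
  for (ch in unique(candidates$chrom)) {
    ci <- which(candidates$chrom == ch)
    ri <- which(regions$chrom == ch)
    if (length(ri) == 0) next
    q <- IRanges::IRanges(start = candidates$pos[ci] - 1L, width = 1L)
    s <- IRanges::IRanges(start = regions$start[ri],
                          end = regions$end[ri] - 1L)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    tag_by_locus <- tapply(regions$trait_tag[ri][sh], qh,
                           function(t) paste(unique(t), collapse = ","))
    loc <- ci[as.integer(names(tag_by_locus))]
    hits_all <- c(hits_all, loc)
    tags <- c(tags, as.list(tag_by_locus))
  }
  if (length(hits_all) == 0) return(out)
  ord <- order(hits_all)
  out <- candidates[hits_all[ord], , drop = FALSE]
  out$trait_tags <- unlist(tags)[ord]
  rownames(out) <- NULL
  out
}

adjacent_gaps <- function(pos, chrom_len = NULL) {
  # gaps between consecutive loci plus the two ends when a length is known
  bounds <- if (is.null(chrom_len)) pos else c(0, pos, chrom_len)
  diff(bounds)
}

#' Fill spacing gaps with pool loci
#'
#' Greedy left-to-right pass per chromosome: wherever two adjacent selected
#' loci (or a chromosome end and its nearest selection) lie more than
#' `target_spacing` apart, the pool locus with `maf >= min_maf` closest to
#' each ideal equally-spaced position inside the gap is inserted. Existing
#' selections are never removed, so the maximum adjacent gap can only
#' shrink or stay.
#'
#' @param selected Data frame `chrom`, `pos` of already-selected loci (may
#'   be empty).
#' @param pool Loci data frame `chrom`, `pos` with a `maf` column.
#' @param target_spacing Desired maximum spacing in bp.
#' @param min_maf Minimum MAF for a fill locus (default 0.05).
#' @param chrom_lengths Optional named lengths; when given, gaps to the
#'   chromosome ends are also filled.
#' @return Data frame of inserted pool rows; attribute `unfillable` lists
#'   gaps (chrom, start, end) where the pool had no eligible locus.
#' @export
fill_gaps <- function(selected, pool, target_spacing, min_maf = 0.05,
                      chrom_lengths = NULL) {
  pool_ok <- pool[!is.na(pool$maf) & pool$maf >= min_maf, , drop = FALSE]
  key_sel <- paste(selected$chrom, selected$pos)
  pool_ok <- pool_ok[!paste(pool_ok$chrom, pool_ok$pos) %in% key_sel, ,
                     drop = FALSE]
  chroms <- unique(c(selected$chrom,
                     if (!is.null(chrom_lengths)) names(chrom_lengths)
                     else pool_ok$chrom))
  added_idx <- integer(0)
  unfillable <- list()
  for (ch in chroms) {
    sel_pos <- sort(selected$pos[selected$chrom == ch])
    pl <- which(pool_ok$chrom == ch)
    pl_pos <- pool_ok$pos[pl]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else NULL
    bounds <- if (is.null(len)) sel_pos else c(0, sel_pos, len)
    if (length(bounds) < 2) next
    taken <- logical(length(pl))
    for (j in seq_len(length(bounds) - 1)) {
      a <- bounds[j]; b <- bounds[j + 1]
      gap <- b - a
      if (gap <= target_spacing) next
      k <- ceiling(gap / target_spacing) - 1
      ideal <- a + gap * seq_len(k) / (k + 1)
      cand <- which(!taken & pl_pos > a & pl_pos < b)
      for (tp in ideal) {
        free <- cand[!taken[cand]]
        if (length(free) == 0) break
        pick <- free[which.min(abs(pl_pos[free] - tp))]
        taken[pick] <- TRUE
      }
    }
    added_idx <- c(added_idx, pl[taken])
    # residual over-spacing the pool could not serve (empty or clustered)
    final_pos <- sort(c(sel_pos, pl_pos[taken]))
    bounds2 <- if (is.null(len)) final_pos else c(0, final_pos, len)
    if (length(bounds2) >= 2) {
      g2 <- diff(bounds2)
      for (j in which(g2 > target_spacing)) {
        a <- bounds2[j]; b <- bounds2[j + 1]
        if (!any(!taken & pl_pos > a & pl_pos < b))
          unfillable[[length(unfillable) + 1]] <-
            data.frame(chrom = ch, start = a, end = b)
      }
    }
  }
  out <- pool_ok[added_idx, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  unf <- if (length(unfillable) > 0) do.call(rbind, unfillable) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  if (nrow(unf) > 0)
    warning(nrow(unf), " gap(s) could not be filled from the pool")
  attr(out, "unfillable") <- unf
  out
}

#' Assemble the final panel from candidate sources
#'
#' Deduplicates the union of GWAS, QTL and sweep candidates with source
#' priority `gwas > qtl > sweep`, gap-fills toward uniform density, and
#' enforces an exact panel size `K`: if still short, extra pool loci are
#' inserted into the largest remaining gaps; if over, loci are dropped
#' lowest-priority-class first (`gapfill`, then `sweep`, then `qtl`, then
#' `gwas`), densest-packed loci first within a class. Ties break by genomic
#' order, so assembly is deterministic.
#'
#' @param sweep_loci,qtl_loci,gwas_loci Data frames `chrom`, `pos` (any of
#'   them may be empty); `qtl_loci` may carry `trait_tags`.
#' @param pool Filtered loci data frame `chrom`, `pos`, `ref`, `alt` with a
#'   `maf` column; all candidates must come from this pool.
#' @param K Target panel size (default 54188).
#' @param target_spacing Desired spacing in bp (default 50000).
#' @param min_maf Minimum MAF for gap-fill loci.
#' @param chrom_lengths Optional named chromosome lengths in bp.
#' @return Data frame of class `panel_spec`: `chrom`, `pos`, `ref`, `alt`,
#'   `source`, `trait_tags`, exactly `K` rows, sorted.
#' @export
assemble_panel <- function(sweep_loci, qtl_loci, gwas_loci, pool,
                           K = 54188, target_spacing = 50000,
                           min_maf = 0.05, chrom_lengths = NULL) {
  stopifnot(K > 0)
  pool_key <- paste(pool$chrom, pool$pos)
  if (K > nrow(pool))
    stop("K = ", K, " exceeds the achievable maximum of ", nrow(pool),
         " pool loci")
  src_frame <- function(x, src) {
    if (is.null(x) || nrow(x) == 0)
      return(data.frame(chrom = character(0), pos = numeric(0),
                        source = character(0), trait_tags = character(0)))
    data.frame(chrom = x$chrom, pos = x$pos, source = src,
               trait_tags = if ("trait_tags" %in% names(x)) x$trait_tags
                            else NA_character_)
  }
  cand <- rbind(src_frame(gwas_loci, "gwas"),
                src_frame(qtl_loci, "qtl"),
                src_frame(sweep_loci, "sweep"))
  miss <- !paste(cand$chrom, cand$pos) %in% pool_key
  if (any(miss))
    stop("candidate locus not present in the pool: ",
         paste(cand$chrom[miss][1], cand$pos[miss][1]))
  cand <- cand[!duplicated(paste(cand$chrom, cand$pos)), , drop = FALSE]
  panel <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  if (nrow(panel) < K) {
    fills <- fill_gaps(panel, pool, target_spacing, min_maf,
                       chrom_lengths = chrom_lengths)
    if (nrow(panel) + nrow(fills) > K)  # keep the exact-size contract:
      # thin the fills evenly along the genome rather than truncating
      fills <- fills[sort(unique(round(seq(1, nrow(fills),
                                           length.out = K - nrow(panel))))), ,
                     drop = FALSE]
    if (nrow(fills) > 0)
      panel <- rbind(panel, data.frame(chrom = fills$chrom, pos = fills$pos,
                                       source = "gapfill",
                                       trait_tags = NA_character_))
    panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  }
  # top up: drop extra pool loci into the current largest gaps
  while (nrow(panel) < K) {
    free <- !pool_key %in% paste(panel$chrom, panel$pos) &
      !is.na(pool$maf) & pool$maf >= min_maf
    if (!any(free)) {
      free <- !pool_key %in% paste(panel$chrom, panel$pos)  # relax MAF last
      if (!any(free)) stop("pool exhausted at ", nrow(panel), " loci; ",
                           "cannot reach K = ", K)
    }
    picks <- pick_in_largest_gaps(panel, pool[free, , drop = FALSE],
                                  K - nrow(panel), chrom_lengths)
    if (nrow(picks) == 0) stop("pool exhausted at ", nrow(panel),
                               " loci; cannot reach K = ", K)
    panel <- rbind(panel, data.frame(chrom = picks$chrom, pos = picks$pos,
                                     source = "gapfill",
                                     trait_tags = NA_character_))
    panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  }
  if (nrow(panel) > K) {
    for (drop_class in c("gapfill", "sweep", "qtl", "gwas")) {
      excess <- nrow(panel) - K
      if (excess == 0) break
      in_class <- which(panel$source == drop_class)
      if (length(in_class) == 0) next
      crowd <- locus_crowding(panel)
      ord <- in_class[order(crowd[in_class],
                            panel$chrom[in_class], panel$pos[in_class])]
      panel <- panel[-ord[seq_len(min(excess, length(ord)))], ,
                     drop = FALSE]
    }
  }
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  at <- match(paste(panel$chrom, panel$pos), pool_key)
  panel$ref <- pool$ref[at]
  panel$alt <- pool$alt[at]
  panel <- panel[, c("chrom", "pos", "ref", "alt", "source", "trait_tags")]
  rownames(panel) <- NULL
  attr(panel, "K") <- K
  attr(panel, "target_spacing") <- target_spacing
  class(panel) <- c("panel_spec", "data.frame")
  panel
}

# sum of the two adjacent gaps around each locus; small = densely packed
locus_crowding <- function(panel) {
  crowd <- rep(Inf, nrow(panel))
  for (ch in unique(panel$chrom)) {
    i <- which(panel$chrom == ch)
    p <- panel$pos[i]  # already sorted
    if (length(i) < 3) next
    inner <- 2:(length(i) - 1)
    crowd[i[inner]] <- (p[inner + 1] - p[inner - 1])
  }
  crowd
}

pick_in_largest_gaps <- function(panel, pool_free, n_needed,
                                 chrom_lengths = NULL) {
  gaps <- list()
  for (ch in unique(pool_free$chrom)) {
    p <- sort(panel$pos[panel$chrom == ch])
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      max(pool_free$pos[pool_free$chrom == ch])
    bounds <- unique(c(0, p, len))
    g <- diff(bounds)
    if (length(g) > 0)
      gaps[[length(gaps) + 1]] <- data.frame(
        chrom = ch, start = bounds[-length(bounds)], end = bounds[-1],
        gap = g)
  }
  gaps <- do.call(rbind, gaps)
  gaps <- gaps[order(-gaps$gap, gaps$chrom, gaps$start), , drop = FALSE]
  picks <- pool_free[0, c("chrom", "pos"), drop = FALSE]
  used <- character(0)
  for (i in seq_len(nrow(gaps))) {
    if (nrow(picks) >= n_needed) break
    mid <- (gaps$start[i] + gaps$end[i]) / 2
    cand <- which(pool_free$chrom == gaps$chrom[i] &
                    pool_free$pos > gaps$start[i] &
                    pool_free$pos < gaps$end[i] &
                    !paste(pool_free$chrom, pool_free$pos) %in% used)
    if (length(cand) == 0) next
    pick <- cand[which.min(abs(pool_free$pos[cand] - mid))]
    used <- c(used, paste(pool_free$chrom[pick], pool_free$pos[pick]))
    picks <- rbind(picks, pool_free[pick, c("chrom", "pos"), drop = FALSE])
  }
  picks
}

#' Probe designability proxy
#'
#' Flags pool loci whose 120 bp probe window contains no other pool
#' variant, a transparent stand-in for commercial capture-probe scoring
#' (sequence-level criteria such as GC content need a reference genome and
#' are out of scope here).
#'
#' @param pool Loci data frame `chrom`, `pos`, sorted.
#' @param probe_length Probe length in bp (default 120).
#' @return Logical vector, `TRUE` where designable.
#' @export
probe_designable <- function(pool, probe_length = 120) {
  half <- probe_length / 2
  ok <- rep(TRUE, nrow(pool))
  for (ch in unique(pool$chrom)) {
    i <- which(pool$chrom == ch)
    p <- pool$pos[i]
    d_prev <- c(Inf, diff(p))
    d_next <- c(diff(p), Inf)
    ok[i] <- d_prev > half & d_next > half
  }
  ok
}

#' Panel density report
#'
#' @param panel A `panel_spec` (or any sorted loci table).
#' @param breaks Histogram breaks for adjacent gaps in bp.
#' @return List: `gaps` (data frame chrom, gap), `fraction_le_100kb`,
#'   `per_chrom` (locus counts), `hist` (gap histogram), `max_gap`.
#' @export
density_report <- function(panel,
                           breaks = c(0, 10e3, 25e3, 50e3, 100e3, 250e3,
                                      Inf)) {
  if (nrow(panel) == 0) stop("empty panel")
  gaps <- do.call(rbind, lapply(unique(panel$chrom), function(ch) {
    p <- sort(panel$pos[panel$chrom == ch])
    if (length(p) < 2)
      return(data.frame(chrom = character(0), gap = numeric(0)))
    data.frame(chrom = ch, gap = diff(p))
  }))
  h <- if (nrow(gaps) > 0)
    table(cut(gaps$gap, breaks = breaks, right = TRUE)) else table(numeric(0))
  list(gaps = gaps,
       fraction_le_100kb = if (nrow(gaps) > 0) mean(gaps$gap <= 100e3)
                           else NA_real_,
       per_chrom = table(panel$chrom),
       hist = h,
       max_gap = if (nrow(gaps) > 0) max(gaps$gap) else NA_real_)
}
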