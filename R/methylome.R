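#' Pool cytosine calls over replicate samples
#'
#' Read counts are summed per cytosine (chrom, position, strand, context)
#' across the given samples — the standard treatment for a two-replicate
#' whole-genome bisulfite design — before any coverage filtering.
#'
#' @param calls cytosine calls ([read_cytosine_report()] rows, possibly
#'   several samples bound together).
#' @param sample_ids samples to pool (default: all present).
#' @return data.frame with one row per cytosine: `chrom`, `pos0`,
#'   `strand`, `context`, `meth_reads`, `total_reads`.
#' @export
pool_cytosines <- function(calls, sample_ids = unique(calls$sample_id)) {
  calls <- calls[calls$sample_id %in% sample_ids, , drop = FALSE]
  key <- paste(calls$chrom, calls$pos0, calls$strand, calls$context, sep = "\r")
  meth <- rowsum(calls$meth_reads, key)
  tot <- rowsum(calls$total_reads, key)
  first <- !duplicated(key)
  ord <- match(rownames(meth), key)
  out <- data.frame(chrom = calls$chrom[ord], pos0 = calls$pos0[ord],
                    strand = calls$strand[ord], context = calls$context[ord],
                    meth_reads = meth[, 1], total_reads = tot[, 1],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$chrom, out$pos0, out$strand), , drop = FALSE]
}

#' Weighted methylation level of a region
#'
#' WML = (sum of methylated reads) / (sum of total reads) over the
#' cytosines of the requested context inside the region whose pooled
#' coverage is at least `min_coverage` reads. Calls must already be
#' pooled over a genotype's replicates ([pool_cytosines()]). When no
#' cytosine passes the filter the WML is undefined and returned as `NA`
#' (never 0). The WML is invariant under uniform scaling of all read
#' counts in the region.
#'
#' @param calls pooled cytosine calls.
#' @param region a single-row [genomic_intervals()] (or data.frame with
#'   `chrom`, `start`, `end`).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage minimum pooled reads per cytosine (default 5).
#' @return List with `wml` (numeric or `NA`) and `n_cytosines`.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos0 = c(10, 20), strand = "+",
#'                     context = "CHH", meth_reads = c(3, 7),
#'                     total_reads = c(10, 10))
#' region <- genomic_intervals("chr1", 0, 100, ".", "sirna_cluster", "r1")
#' compute_wml(calls, region, "CHH")  # wml 0.5 over 2 cytosines
#' @export
compute_wml <- function(calls, region, context, min_coverage = 5) {
  stopifnot(nrow(region) == 1L)
  sel <- calls$context == context &
    calls$chrom == region$chrom &
    calls$pos0 >= region$start & calls$pos0 < region$end &
    calls$total_reads >= min_coverage
  n <- sum(sel)
  if (n == 0L) return(list(wml = NA_real_, n_cytosines = 0L))
  list(wml = sum(calls$meth_reads[sel]) / sum(calls$total_reads[sel]),
       n_cytosines = n)
}

#' Weighted methylation level of many regions at once
#'
#' Vectorized form of [compute_wml()]: assigns covered cytosines of one
#' context to regions by interval overlap and aggregates read counts per
#' region.
#'
#' @param calls pooled cytosine calls.
#' @param regions [genomic_intervals()].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage minimum pooled reads per cytosine.
#' @return data.frame with `region_id`, `context`, `wml`, `n_cytosines`;
#'   `wml` is `NA` for regions without passing cytosines.
#' @export
region_wml <- function(calls, regions, context, min_coverage = 5) {
  calls <- calls[calls$context == context &
                   calls$total_reads >= min_coverage, , drop = FALSE]
  wml <- rep(NA_real_, nrow(regions))
  ncyt <- integer(nrow(regions))
  if (nrow(calls)) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(calls$chrom,
                             IRanges::IRanges(calls$pos0 + 1L, calls$pos0 + 1L)),
      as_granges0(regions), ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(si)) {
      meth <- rowsum(calls$meth_reads[qi], si)
      tot <- rowsum(calls$total_reads[qi], si)
      idx <- as.integer(rownames(meth))
      wml[idx] <- meth[, 1] / tot[, 1]
      cnt <- rowsum(rep(1L, length(si)), si)
      ncyt[idx] <- cnt[, 1]
    }
  }
  data.frame(region_id = regions$id, context = context, wml = wml,
             n_cytosines = ncyt, stringsAsFactors = FALSE, row.names = NULL)
}

#' Tile chromosomes into fixed-width bins
#'
#' Non-overlapping, left-closed tiling; the last partial bin is retained,
#' so the total bin length equals the genome length and the bin count per
#' chromosome is `ceiling(size / width)`.
#'
#' @param chrom_sizes named numeric vector of chromosome sizes.
#' @param width bin width in bp (default 100).
#' @return [genomic_intervals()] of kind `dmr_bin`.
#' @export
make_bins <- function(chrom_sizes, width = 100) {
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("chrom_sizes must be a named vector of positive sizes")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    starts <- seq(0, size - 1, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, size))
  })
  df <- do.call(rbind, pieces)
  genomic_intervals(df$chrom, df$start, df$end, ".", "dmr_bin",
                    sprintf("%s_bin_%06d", df$chrom,
                            unlist(lapply(pieces, function(p) seq_len(nrow(p))))))
}

#' Two-sided Mann-Whitney U test with exact small-sample permutation
#'
#' For small vectors (at most `max_enum` splits) the permutation null of
#' the rank-sum statistic is enumerated exactly, which stays exact under
#' ties (midranks); the two-sided p is the probability of a rank sum at
#' least as far from its expectation as observed. Larger samples use the
#' normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param x,y numeric vectors.
#' @param max_enum enumeration budget (number of group-1 subsets).
#' @return Two-sided p-value.
#' @export
mwu_test <- function(x, y, max_enum = 20000) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  if (choose(n, n1) <= max_enum) {
    all_w <- utils::combn(n, n1, function(i) sum(r[i]))
    return(mean(abs(all_w - ew) >= abs(w - ew) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - ew
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Rank-based differential methylation test over predefined regions
#'
#' For each region, the per-cytosine methylation levels (methylated /
#' total reads, pooled within each group) are collected for cytosines of
#' the requested context covered by at least `min_coverage` reads in both
#' groups. The two groups' level vectors are compared with a two-sided
#' Mann-Whitney U test ([mwu_test()], exact by permutation enumeration
#' for small regions), p-values are BH-adjusted across the tested
#' regions of the context, and a region is called significant when it has
#' at least `min_cytosines` eligible cytosines, FDR < `alpha`, and an
#' absolute mean level difference of at least `diff_threshold` (0.1 for
#' CG and CHG, 0.05 for CHH). Regions without eligible cytosines are
#' excluded from testing and reported with `NA` p-values.
#'
#' @param calls cytosine calls for all samples (with `sample_id`).
#' @param regions [genomic_intervals()] to test.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param group1,group2 sample ids of the two groups (each >= 2
#'   replicates, pooled).
#' @param diff_threshold minimum absolute methylation difference.
#' @param min_coverage per-cytosine pooled coverage filter (default 5).
#' @param min_cytosines minimum eligible cytosines (default 4).
#' @param alpha FDR threshold.
#' @return data.frame with `region_id`, `context`, `n_cytosines`,
#'   `meth_diff` (group1 - group2 mean level), `p`, `fdr`, `significant`.
#' @export
region_dm_test <- function(calls, regions, context, group1, group2,
                           diff_threshold = 0.1, min_coverage = 5,
                           min_cytosines = 4, alpha = 0.05) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 replicates to pool")
  p1 <- pool_cytosines(calls, group1)
  p2 <- pool_cytosines(calls, group2)
  p1 <- p1[p1$context == context & p1$total_reads >= min_coverage, ]
  p2 <- p2[p2$context == context & p2$total_reads >= min_coverage, ]
  key1 <- paste(p1$chrom, p1$pos0, p1$strand, sep = "\r")
  key2 <- paste(p2$chrom, p2$pos0, p2$strand, sep = "\r")
  common <- intersect(key1, key2)
  p1 <- p1[match(common, key1), , drop = FALSE]
  p2 <- p2[match(common, key2), , drop = FALSE]
  lev1 <- p1$meth_reads / p1$total_reads
  lev2 <- p2$meth_reads / p2$total_reads
  n <- nrow(regions)
  ncyt <- integer(n)
  meth_diff <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  if (length(common)) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(p1$chrom,
                             IRanges::IRanges(p1$pos0 + 1L, p1$pos0 + 1L)),
      as_granges0(regions), ignore.strand = TRUE)
    by_region <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
    for (r in names(by_region)) {
      i <- as.integer(r)
      idx <- by_region[[r]]
      ncyt[i] <- length(idx)
      l1 <- lev1[idx]; l2 <- lev2[idx]
      meth_diff[i] <- mean(l1) - mean(l2)
      p[i] <- mwu_test(l1, l2)
    }
  }
  fdr <- rep(NA_real_, n)
  tested <- !is.na(p)
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  sig <- tested & ncyt >= min_cytosines & fdr < alpha &
    abs(meth_diff) >= diff_threshold
  sig[!tested] <- FALSE
  data.frame(region_id = regions$id, context = context, n_cytosines = ncyt,
             meth_diff = meth_diff, p = p, fdr = fdr, significant = sig,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select differentially methylated candidate regions from the trio
#'
#' Mirrors the expression rule: a region is a candidate when it is
#' differentially methylated between the parents (F vs M), or
#' differentially methylated in both hybrid contrasts with the same sign
#' of the methylation difference (commonly hyper- or hypo-methylated,
#' hybrid as group 1).
#'
#' @param dm_fm,dm_hf,dm_hm results of [region_dm_test()] for the three
#'   contrasts over the same regions.
#' @return Character vector of candidate region ids.
#' @export
select_methylation_candidates <- function(dm_fm, dm_hf, dm_hm) {
  ids <- dm_fm$region_id
  if (!setequal(ids, dm_hf$region_id) || !setequal(ids, dm_hm$region_id))
    stop("mismatched region universes across contrasts")
  hf <- dm_hf[match(ids, dm_hf$region_id), ]
  hm <- dm_hm[match(ids, dm_hm$region_id), ]
  common <- hf$significant & hm$significant &
    !is.na(hf$meth_diff) & !is.na(hm$meth_diff) &
    sign(hf$meth_diff) == sign(hm$meth_diff)
  ids[dm_fm$significant | common]
}

#' Classify hybrid methylation patterns from trio WMLs
#'
#' The methylation dominance/additivity statistic is
#' `Met_d/a = (WML_H - WML_MPV) / max(|WML_F - WML_MPV|, |WML_M -
#' WML_MPV|)` with `WML_MPV = (WML_F + WML_M)/2`. Regions with Met_d/a >
#' 0.5 are trans-chromosomal methylation (TCM), < -0.5 trans-chromosomal
#' demethylation (TCdM), and everything in between (boundaries included)
#' non-interactive methylation (NIM). When the parents are equal the
#' denominator vanishes: the call is NIM if the hybrid equals the
#' mid-parent value, otherwise TCM/TCdM by the sign of the deviation with
#' `met_da` recorded as +/-Inf. Note that whenever the parents differ,
#' `Met_d/a = 2 (WML_H - WML_MPV) / |WML_F - WML_M|`.
#'
#' @param wml_f,wml_m,wml_h numeric vectors of weighted methylation
#'   levels; all must be defined (no `NA`).
#' @param region_id optional region ids.
#' @param context optional context label(s) carried through.
#' @return data.frame with `region_id`, `context`, `wml_f`, `wml_m`,
#'   `wml_h`, `mpv_wml`, `met_da`, `pattern`.
#' @examples
#' classify_met_da(0.8, 0.2, 0.9)  # met_da 1.33, TCM
#' @export
classify_met_da <- function(wml_f, wml_m, wml_h, region_id = NULL,
                            context = NA_character_) {
  if (anyNA(wml_f) || anyNA(wml_m) || anyNA(wml_h))
    stop("undefined WML: classify_met_da needs all three levels")
  n <- length(wml_h)
  if (is.null(region_id)) region_id <- sprintf("region_%d", seq_len(n))
  mpv <- (wml_f + wml_m) / 2
  denom <- pmax(abs(wml_f - mpv), abs(wml_m - mpv))
  num <- wml_h - mpv
  met_da <- ifelse(denom > 0, num / denom,
                   ifelse(num > 0, Inf, ifelse(num < 0, -Inf, 0)))
  pattern <- ifelse(met_da > 0.5, "TCM",
                    ifelse(met_da < -0.5, "TCdM", "NIM"))
  data.frame(region_id = region_id, context = context,
             wml_f = wml_f, wml_m = wml_m, wml_h = wml_h, mpv_wml = mpv,
             met_da = met_da, pattern = pattern,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test for a genome-wide shift of hybrid WMLs against mid-parent values
#'
#' Two-sided Wilcoxon rank-sum test between the hybrid and mid-parent WML
#' vectors (paired by region but compared as two samples); the direction
#' is the sign of the median paired difference.
#'
#' @param wml_hybrid,wml_mpv equal-length numeric vectors over regions.
#' @return List with `direction` (-1, 0, 1), `p`, `n`.
#' @export
wml_shift_test <- function(wml_hybrid, wml_mpv) {
  if (length(wml_hybrid) != length(wml_mpv)) stop("length mismatch")
  keep <- !(is.na(wml_hybrid) | is.na(wml_mpv))
  wml_hybrid <- wml_hybrid[keep]
  wml_mpv <- wml_mpv[keep]
  if (length(wml_hybrid) == 0L) stop("no regions with defined WML")
  p <- suppressWarnings(
    stats::wilcox.test(wml_hybrid, wml_mpv,
                       alternative = "two.sided")$p.value)
  if (is.na(p)) p <- 1
  list(direction = sign(stats::median(wml_hybrid - wml_mpv)), p = p,
       n = length(wml_hybrid))
}
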