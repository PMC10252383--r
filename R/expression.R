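#' Normalize a count matrix to reads per million
#'
#' Each sample's column is scaled so that it sums to one million over the
#' features in the matrix. Scaling a sample's counts by any positive
#' constant leaves its RPM values unchanged.
#'
#' @param x a [trio_counts()] object with raw counts.
#' @return The same object with normalized values (`normalized = TRUE`).
#' @export
normalize_rpm <- function(x) {
  stopifnot(inherits(x, "trio_counts"))
  totals <- colSums(x$counts)
  if (any(totals <= 0))
    stop("zero-total sample: ",
         paste(colnames(x$counts)[totals <= 0], collapse = ", "))
  x$counts <- sweep(x$counts, 2, totals, "/") * 1e6
  x$normalized <- TRUE
  x
}

#' Filter features by minimum expression
#'
#' Keeps features whose normalized level is strictly greater than
#' `threshold` in at least `min_samples` samples. The defaults (`2`, `2`)
#' are the RPM filter for small-RNA features; gene (FPKM) matrices use
#' `0.5` and `2`.
#'
#' @param x a normalized [trio_counts()] object.
#' @param threshold expression cutoff (strict inequality).
#' @param min_samples minimum number of samples above the cutoff.
#' @return The filtered object.
#' @export
filter_expressed <- function(x, threshold = 2, min_samples = 2) {
  stopifnot(inherits(x, "trio_counts"))
  keep <- rowSums(x$counts > threshold) >= min_samples
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Negative-binomial Wald test for differential expression
#'
#' A compact re-implementation of the standard NB-GLM count test for the
#' two-group trio contrasts: median-of-ratios size factors, per-feature
#' method-of-moments dispersion (floored at 1e-8) pooled across the two
#' groups, and a Wald test on the log2 fold change. Because the
#' method-of-moments dispersion is estimated from very few replicates, the
#' Wald statistic is referred to a t distribution with `n1 + n2 - 2`
#' degrees of freedom rather than a normal; this keeps the type-I error
#' near the nominal level at n = 3 per group. No shrinkage of fold
#' changes or dispersions is performed, so exact numerical parity with
#' DESeq2 is not claimed.
#'
#' @param x a [trio_counts()] object with raw counts.
#' @param contrast `"FvsM"`, `"HvsF"` or `"HvsM"`; the second-named group
#'   is the baseline of the log2 fold change.
#' @param alpha FDR threshold for the `significant` flag.
#' @param lfc_threshold minimum `|log2fc|` for the `significant` flag
#'   (1 corresponds to the fold-change > 2 rule).
#' @return data.frame with columns `feature_id`, `contrast`, `base_mean`,
#'   `log2fc`, `p`, `fdr`, `significant`.
#' @export
nb_differential_test <- function(x, contrast = c("FvsM", "HvsF", "HvsM"),
                                 alpha = 0.05, lfc_threshold = 1) {
  stopifnot(inherits(x, "trio_counts"))
  if (x$normalized)
    stop("nb_differential_test needs raw counts, not normalized values")
  contrast <- match.arg(contrast)
  grp <- switch(contrast,
    FvsM = c("female", "male"),
    HvsF = c("hybrid", "female"),
    HvsM = c("hybrid", "male"))
  i1 <- geno_cols(x, grp[1])
  i2 <- geno_cols(x, grp[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs at least 2 replicates (",
         grp[1], ": ", length(i1), ", ", grp[2], ": ", length(i2), ")")
  k <- x$counts[, c(i1, i2), drop = FALSE]
  sf <- size_factors(k)
  q <- sweep(k, 2, sf, "/")
  j1 <- seq_along(i1)
  j2 <- length(i1) + seq_along(i2)
  n1 <- length(j1); n2 <- length(j2)
  m1 <- rowMeans(q[, j1, drop = FALSE])
  m2 <- rowMeans(q[, j2, drop = FALSE])
  v1 <- apply(q[, j1, drop = FALSE], 1, stats::var)
  v2 <- apply(q[, j2, drop = FALSE], 1, stats::var)
  # method-of-moments dispersion on the normalized scale, pooled over groups
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, NA_real_)
  alpha_hat <- pmax(rowMeans(cbind(a1, a2), na.rm = TRUE), 1e-8)
  alpha_hat[is.nan(alpha_hat)] <- 1e-8
  # continuity floor so all-zero groups give finite statistics
  m1a <- pmax(m1, 0.5)
  m2a <- pmax(m2, 0.5)
  inv_sf1 <- mean(1 / sf[j1]); inv_sf2 <- mean(1 / sf[j2])
  se2 <- (inv_sf1 / m1a + alpha_hat) / n1 + (inv_sf2 / m2a + alpha_hat) / n2
  log2fc <- log2(m1a / m2a)
  zero_both <- m1 == 0 & m2 == 0
  log2fc[zero_both] <- 0
  z <- log(m1a / m2a) / sqrt(se2)
  p <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)
  p[zero_both] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(
    feature_id = rownames(x$counts),
    contrast = contrast,
    base_mean = (m1 * n1 + m2 * n2) / (n1 + n2),
    log2fc = log2fc,
    p = p,
    fdr = fdr,
    significant = fdr < alpha & abs(log2fc) > lfc_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Median-of-ratios size factors
#'
#' Size factor of a sample is the median across features of its ratio to
#' the per-feature geometric mean, computed over features with all-
#' positive counts. Falls back to total-count ratios when no feature is
#' everywhere positive.
#'
#' @param k count matrix (features x samples).
#' @return numeric vector of positive size factors, one per column.
#' @export
size_factors <- function(k) {
  pos <- rowSums(k > 0) == ncol(k)
  if (any(pos)) {
    lgm <- rowMeans(log(k[pos, , drop = FALSE]))
    sf <- apply(k[pos, , drop = FALSE], 2, function(col)
      exp(stats::median(log(col) - lgm)))
  } else {
    tot <- colSums(k)
    if (any(tot <= 0)) stop("cannot compute size factors: zero-total sample")
    sf <- tot / exp(mean(log(tot)))
  }
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factors")
  sf
}

#' Select heterosis candidate features from the three trio contrasts
#'
#' A feature is a candidate when it is differentially expressed between
#' the parents (F vs M), or when it is differentially expressed in both
#' hybrid-vs-parent contrasts with the same direction of change (commonly
#' up- or down-regulated in H vs F and H vs M).
#'
#' @param de_fm,de_hf,de_hm results of [nb_differential_test()] for the
#'   `FvsM`, `HvsF` and `HvsM` contrasts over the same features.
#' @return Character vector of candidate feature ids.
#' @export
select_heterosis_candidates <- function(de_fm, de_hf, de_hm) {
  ids <- de_fm$feature_id
  if (!setequal(ids, de_hf$feature_id) || !setequal(ids, de_hm$feature_id))
    stop("mismatched feature universes across contrasts")
  hf <- de_hf[match(ids, de_hf$feature_id), ]
  hm <- de_hm[match(ids, de_hm$feature_id), ]
  common <- hf$significant & hm$significant &
    sign(hf$log2fc) == sign(hm$log2fc)
  ids[de_fm$significant | common]
}

#' Classify a dominance/additivity ratio into the five expression patterns
#'
#' The D/A ratio partitions hybrid expression into transgressive
#' high-parent (THPE, D/A > 2), dominant high-parent (DHPE, 0.5 < D/A <=
#' 2), additive (AE, -0.5 <= D/A <= 0.5), dominant low-parent (DLPE, -2
#' <= D/A < -0.5) and transgressive low-parent (TLPE, D/A < -2)
#' expression. Boundary values go to the less extreme class. `+Inf` and
#' `-Inf` (parents equal, see [classify_expression_pattern()]) map to
#' THPE and TLPE.
#'
#' @param da numeric vector of D/A ratios (may contain `Inf`).
#' @return Character vector of pattern labels.
#' @examples
#' classify_da(c(-3.39, 19.8, 0, 2))  # TLPE THPE AE DHPE
#' @export
classify_da <- function(da) {
  if (any(is.nan(da) | is.na(da))) stop("NaN D/A ratio")
  out <- character(length(da))
  out[da > 2] <- "THPE"
  out[da > 0.5 & da <= 2] <- "DHPE"
  out[da >= -0.5 & da <= 0.5] <- "AE"
  out[da >= -2 & da < -0.5] <- "DLPE"
  out[da < -2] <- "TLPE"
  out
}

#' Expression-pattern call from trio mean expression levels
#'
#' Computes, per feature, the mid-parent value `MPV = (F + M)/2`,
#' dominance `D = H - MPV`, additivity `A = HP - MPV` (HP = the higher
#' parent), the D/A ratio, and the five-class pattern via
#' [classify_da()]. Inputs are replicate-mean normalized expression (RPM
#' or FPKM). When the parents are equal (`A` below `eps`), the ratio is
#' recorded as +/-Inf and the pattern falls back to the sign of `D`: AE
#' when `|D| < eps * max(1, MPV)`, otherwise THPE (`D > 0`) or TLPE.
#'
#' @param rpm_f,rpm_m,rpm_h numeric vectors of mean normalized expression
#'   for female, male and hybrid.
#' @param feature_id optional feature ids.
#' @param eps degeneracy tolerance for equal parents.
#' @return data.frame with columns `feature_id`, `rpm_f`, `rpm_m`,
#'   `rpm_h`, `mpv`, `dominance_d`, `additivity_a`, `da_ratio`,
#'   `pattern`.
#' @export
classify_expression_pattern <- function(rpm_f, rpm_m, rpm_h,
                                        feature_id = NULL, eps = 1e-9) {
  if (any(rpm_f < 0 | rpm_m < 0 | rpm_h < 0)) stop("negative expression level")
  n <- length(rpm_h)
  if (is.null(feature_id)) feature_id <- sprintf("feature_%d", seq_len(n))
  mpv <- (rpm_f + rpm_m) / 2
  hp <- pmax(rpm_f, rpm_m)
  d <- rpm_h - mpv
  a <- hp - mpv
  da <- ifelse(a >= eps, d / a, ifelse(d > 0, Inf, ifelse(d < 0, -Inf, 0)))
  pattern <- character(n)
  ok <- a >= eps
  pattern[ok] <- classify_da(da[ok])
  deg <- !ok
  if (any(deg)) {
    tol <- eps * pmax(1, mpv[deg])
    pattern[deg] <- ifelse(abs(d[deg]) < tol, "AE",
                           ifelse(d[deg] > 0, "THPE", "TLPE"))
    da[deg][abs(d[deg]) < tol] <- 0
  }
  data.frame(feature_id = feature_id, rpm_f = rpm_f, rpm_m = rpm_m,
             rpm_h = rpm_h, mpv = mpv, dominance_d = d, additivity_a = a,
             da_ratio = da, pattern = pattern,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression-pattern calls for candidate features of a trio matrix
#'
#' Convenience wrapper: takes a normalized matrix and a set of candidate
#' features, averages replicates per genotype and delegates to
#' [classify_expression_pattern()].
#'
#' @param x a normalized [trio_counts()] object.
#' @param features feature ids to classify (default: all).
#' @return data.frame as in [classify_expression_pattern()].
#' @export
call_expression_patterns <- function(x, features = rownames(x$counts)) {
  stopifnot(inherits(x, "trio_counts"))
  if (!x$normalized)
    stop("call_expression_patterns needs a normalized matrix; see normalize_rpm()")
  miss <- setdiff(features, rownames(x$counts))
  if (length(miss))
    stop("features not in matrix: ", paste(utils::head(miss, 3), collapse = ", "))
  m <- x$counts[features, , drop = FALSE]
  f <- rowMeans(m[, geno_cols(x, "female"), drop = FALSE])
  mm <- rowMeans(m[, geno_cols(x, "male"), drop = FALSE])
  h <- rowMeans(m[, geno_cols(x, "hybrid"), drop = FALSE])
  classify_expression_pattern(f, mm, h, feature_id = features)
}

#' Tally pattern calls by class and superclass
#'
#' HPE = THPE + DHPE, LPE = TLPE + DLPE; AE is its own superclass. The
#' class counts partition the input.
#'
#' @param patterns character vector of pattern labels (or a data.frame
#'   with a `pattern` column).
#' @return Named list with `class_counts`, `superclass_counts`, `total`.
#' @export
summarize_patterns <- function(patterns) {
  if (is.data.frame(patterns)) patterns <- patterns$pattern
  lv <- c("THPE", "DHPE", "AE", "DLPE", "TLPE")
  bad <- setdiff(unique(patterns), lv)
  if (length(bad)) stop("unknown pattern label: ", paste(bad, collapse = ", "))
  cls <- table(factor(patterns, levels = lv))
  sup <- c(HPE = unname(cls["THPE"] + cls["DHPE"]),
           LPE = unname(cls["TLPE"] + cls["DLPE"]),
           AE = unname(cls["AE"]))
  list(class_counts = c(cls), superclass_counts = sup,
       total = length(patterns))
}

#' Superclass (HPE/LPE/AE) of a five-class pattern label
#'
#' @param pattern character vector of THPE/DHPE/AE/DLPE/TLPE labels.
#' @return Character vector of HPE/AE/LPE labels.
#' @export
pattern_superclass <- function(pattern) {
  out <- rep(NA_character_, length(pattern))
  out[pattern %in% c("THPE", "DHPE")] <- "HPE"
  out[pattern %in% c("TLPE", "DLPE")] <- "LPE"
  out[pattern == "AE"] <- "AE"
  if (anyNA(out)) stop("unknown pattern label")
  out
}
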