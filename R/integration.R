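#' Group siRNA clusters by expression and methylation pattern
#'
#' Joins, per cytosine context, the cluster expression superclass
#' (HPE/LPE/AE) with the cluster methylation pattern (TCM/TCdM/NIM) and
#' collects member clusters and their associated protein-coding genes
#' (categories gene_body, up2kb, down2kb of the cluster annotation,
#' deduplicated per group). By default only the six focal groups
#' (HPE-*-TCM and LPE-*-TCdM for CG/CHG/CHH) are returned; with
#' `focal_only = FALSE` every observed combination is emitted. Clusters
#' with an expression call but no methylation call in a context are
#' excluded and counted in the `n_excluded` attribute.
#'
#' @param expr_calls data.frame with `feature_id` and `pattern` columns
#'   (cluster expression calls, see [call_expression_patterns()]).
#' @param meth_calls data.frame with `region_id`, `context`, `pattern`
#'   (see [classify_met_da()]); region ids are cluster ids.
#' @param annotations result of [annotate_clusters()].
#' @param focal_only return only the six focal groups (default `TRUE`).
#' @return data.frame with one row per group: `name`,
#'   `expression_superclass`, `context`, `methylation_pattern`,
#'   `n_clusters`, `n_genes`, and list-columns `member_cluster_ids`,
#'   `associated_gene_ids`.
#' @export
build_pattern_groups <- function(expr_calls, meth_calls, annotations,
                                 focal_only = TRUE) {
  sup <- data.frame(cluster_id = expr_calls$feature_id,
                    superclass = pattern_superclass(expr_calls$pattern),
                    stringsAsFactors = FALSE)
  mm <- meth_calls[meth_calls$region_id %in% sup$cluster_id, , drop = FALSE]
  n_excluded <- sum(!(sup$cluster_id %in% meth_calls$region_id))
  mm$superclass <- sup$superclass[match(mm$region_id, sup$cluster_id)]
  gene_of <- annotations[annotations$category %in%
                           c("gene_body", "up2kb", "down2kb"), , drop = FALSE]
  combos <- if (focal_only) {
    data.frame(superclass = rep(c("HPE", "LPE"), each = 3),
               context = rep(c("CG", "CHG", "CHH"), 2),
               meth = rep(c("TCM", "TCdM"), each = 3),
               stringsAsFactors = FALSE)
  } else {
    unique(data.frame(superclass = mm$superclass, context = mm$context,
                      meth = mm$pattern, stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- mm$superclass == combos$superclass[i] &
      mm$context == combos$context[i] &
      mm$pattern == combos$meth[i]
    members <- unique(mm$region_id[sel])
    genes <- unique(stats::na.omit(
      gene_of$linked_gene_id[gene_of$cluster_id %in% members]))
    data.frame(name = paste(combos$superclass[i], combos$context[i],
                            combos$meth[i], sep = "-"),
               expression_superclass = combos$superclass[i],
               context = combos$context[i],
               methylation_pattern = combos$meth[i],
               n_clusters = length(members), n_genes = length(genes),
               member_cluster_ids = I(list(members)),
               associated_gene_ids = I(list(genes)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Two-sided Fisher's exact test of association between two memberships
#'
#' Builds the 2x2 contingency table of two logical membership vectors
#' over the same universe and computes the two-sided Fisher exact p-value
#' from the hypergeometric distribution (all tables with the observed
#' margins whose probability does not exceed that of the observed table).
#' The odds ratio is the sample odds ratio of the table; a 0.5 Haldane
#' correction is applied to the reported odds ratio only when a cell is
#' zero, never to the p-value.
#'
#' @param in_a,in_b logical vectors of equal length.
#' @return List with `table` (2x2), `odds_ratio`, `p`.
#' @export
fisher_association <- function(in_a, in_b) {
  if (length(in_a) != length(in_b)) stop("membership vectors differ in length")
  if (length(in_a) == 0L) stop("empty universe")
  tab <- table(factor(in_a, levels = c(TRUE, FALSE)),
               factor(in_b, levels = c(TRUE, FALSE)))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  t2 <- tab
  if (any(tab == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(table = tab, odds_ratio = unname(or), p = min(p, 1))
}

#' miRNA-target pairs with opposing hybrid expression patterns
#'
#' Retains pairs in which one end is high-parent expressed (THPE/DHPE)
#' and the other low-parent expressed (TLPE/DLPE); both D/A ratios are
#' carried in the output. Pairs whose miRNA or gene lacks a pattern call
#' are skipped and counted in the `n_skipped` attribute.
#'
#' @param pairs data.frame with `mirna_id`, `target_gene_id` and
#'   optionally `source` (`degradome`/`predicted`).
#' @param mirna_calls,gene_calls pattern-call data.frames with
#'   `feature_id`, `da_ratio`, `pattern`.
#' @return data.frame with `mirna_id`, `mirna_pattern`, `mirna_da`,
#'   `target_gene_id`, `gene_pattern`, `gene_da`, `source`.
#' @export
opposing_pairs <- function(pairs, mirna_calls, gene_calls) {
  mi <- match(pairs$mirna_id, mirna_calls$feature_id)
  gi <- match(pairs$target_gene_id, gene_calls$feature_id)
  known <- !is.na(mi) & !is.na(gi)
  out <- data.frame(
    mirna_id = pairs$mirna_id[known],
    mirna_pattern = mirna_calls$pattern[mi[known]],
    mirna_da = mirna_calls$da_ratio[mi[known]],
    target_gene_id = pairs$target_gene_id[known],
    gene_pattern = gene_calls$pattern[gi[known]],
    gene_da = gene_calls$da_ratio[gi[known]],
    source = if (!is.null(pairs$source)) pairs$source[known] else NA_character_,
    stringsAsFactors = FALSE, row.names = NULL)
  ms <- pattern_superclass(out$mirna_pattern)
  gs <- pattern_superclass(out$gene_pattern)
  keep <- (ms == "HPE" & gs == "LPE") | (ms == "LPE" & gs == "HPE")
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- sum(!known)
  res
}

#' Enrichment of gene expression superclasses within pattern groups
#'
#' For each (group, gene superclass) pair, a 2x2 Fisher test compares
#' group membership against superclass membership over the background of
#' all pattern-called genes associated with any cluster (the union of
#' `associated_gene_ids` over all supplied groups, restricted to genes
#' with a call), or a caller-supplied universe. Empty groups are skipped
#' and reported via the `skipped` attribute.
#'
#' @param groups result of [build_pattern_groups()].
#' @param gene_calls gene pattern calls (`feature_id`, `pattern`).
#' @param universe optional character vector of background gene ids.
#' @return data.frame with `group`, `gene_superclass`, `n_group`,
#'   `n_overlap`, `odds_ratio`, `p`.
#' @export
gene_pattern_enrichment_in_groups <- function(groups, gene_calls,
                                              universe = NULL) {
  if (is.null(universe))
    universe <- unique(unlist(groups$associated_gene_ids))
  universe <- intersect(universe, gene_calls$feature_id)
  if (length(universe) == 0L) stop("empty gene universe")
  sup <- pattern_superclass(
    gene_calls$pattern[match(universe, gene_calls$feature_id)])
  skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    genes <- intersect(groups$associated_gene_ids[[i]], universe)
    if (length(genes) == 0L) {
      skipped <- c(skipped, groups$name[i])
      next
    }
    in_group <- universe %in% genes
    for (s in c("HPE", "LPE", "AE")) {
      ft <- fisher_association(in_group, sup == s)
      rows[[length(rows) + 1L]] <- data.frame(
        group = groups$name[i], gene_superclass = s,
        n_group = length(genes), n_overlap = sum(in_group & sup == s),
        odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), gene_superclass = character(0),
               n_group = integer(0), n_overlap = integer(0),
               odds_ratio = numeric(0), p = numeric(0))
  attr(out, "skipped") <- skipped
  out
}

#' Hypergeometric term enrichment for a gene set
#'
#' Generic over-representation analysis against a user-supplied gene-term
#' annotation: for each term, the upper tail of the hypergeometric
#' distribution (`k` or more of the `n` set genes among the `K` term
#' genes in a universe of `N`), BH-adjusted across terms.
#'
#' @param gene_set character vector, a subset of `universe`.
#' @param annotation data.frame with columns `gene`, `term` (a gene may
#'   carry several terms).
#' @param universe character vector of background genes.
#' @return data.frame with `term`, `k`, `K`, `n`, `N`, `p`, `fdr`.
#' @export
term_enrichment <- function(gene_set, annotation, universe) {
  if (!all(gene_set %in% universe)) stop("gene_set must be a subset of universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  n <- length(gene_set)
  N <- length(universe)
  terms <- sort(unique(ann$term))
  K <- vapply(terms, function(t) length(unique(ann$gene[ann$term == t])), 0L)
  k <- vapply(terms, function(t)
    length(intersect(gene_set, ann$gene[ann$term == t])), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare hybrid expression between methylation patterns
#'
#' Welch two-sided t-tests on `log2(RPM + 1)` hybrid expression of
#' clusters, for every pair of methylation patterns present (TCM, TCdM,
#' NIM) within one context.
#'
#' @param expr_levels data.frame with `cluster_id` and `rpm_h` (mean
#'   hybrid RPM).
#' @param meth_calls methylation pattern calls for one context
#'   (`region_id`, `pattern`).
#' @return data.frame with `pattern_a`, `pattern_b`, `n_a`, `n_b`,
#'   `t_statistic`, `p`.
#' @export
expression_by_methylation_pattern <- function(expr_levels, meth_calls) {
  x <- log2(expr_levels$rpm_h[match(meth_calls$region_id,
                                    expr_levels$cluster_id)] + 1)
  ok <- !is.na(x)
  x <- x[ok]
  pat <- meth_calls$pattern[ok]
  pats <- intersect(c("TCM", "NIM", "TCdM"), unique(pat))
  rows <- list()
  for (i in seq_along(pats)) for (j in seq_along(pats)) {
    if (j <= i) next
    xa <- x[pat == pats[i]]
    xb <- x[pat == pats[j]]
    if (length(xa) < 2 || length(xb) < 2)
      stop("each pattern group needs at least 2 clusters (",
           pats[i], ": ", length(xa), ", ", pats[j], ": ", length(xb), ")")
    tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      pattern_a = pats[i], pattern_b = pats[j],
      n_a = length(xa), n_b = length(xb),
      t_statistic = if (is.null(tt)) 0 else unname(tt$statistic),
      p = if (is.null(tt)) 1 else tt$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("need at least two methylation patterns to compare")
  do.call(rbind, rows)
}
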