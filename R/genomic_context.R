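#' Annotate siRNA clusters to genomic features
#'
#' Each cluster is assigned to exactly one category with the precedence
#' gene_body > up2kb > down2kb > TE > intergenic, using base overlap (at
#' least one shared base) on half-open intervals. Flank windows are
#' strand-aware: for a `+` strand gene the 5' upstream 2-kb window is
#' `[TSS - 2000, TSS)` and the 3' downstream window is `(TES, TES +
#' 2000]`; both are mirrored for `-` strand genes. Among several genes in
#' the winning tier the nearest gene is linked (distance 0 for overlaps),
#' with ties broken by lexicographic gene id.
#'
#' @param clusters [genomic_intervals()] of the clusters.
#' @param genes stranded [genomic_intervals()] of kind `gene`.
#' @param tes [genomic_intervals()] of TEs (may be empty).
#' @return data.frame with `cluster_id`, `category`, `linked_gene_id`
#'   (`NA` for TE/intergenic clusters).
#' @export
annotate_clusters <- function(clusters, genes, tes) {
  if (nrow(genes) && any(genes$strand == "."))
    stop("genes must be stranded")
  plus <- genes$strand == "+"
  up <- genes
  up$start <- ifelse(plus, genes$start - 2000, genes$end)
  up$end <- ifelse(plus, genes$start, genes$end + 2000)
  down <- genes
  down$start <- ifelse(plus, genes$end, genes$start - 2000)
  down$end <- ifelse(plus, genes$end + 2000, genes$start)
  # clip windows running off the chromosome start
  up$start <- pmax(up$start, 0); down$start <- pmax(down$start, 0)
  n <- nrow(clusters)
  category <- rep("intergenic", n)
  linked <- rep(NA_character_, n)

  link_tier <- function(windows, tier, current) {
    if (nrow(windows) == 0L) return(current)
    ok <- windows$end > windows$start
    windows <- windows[ok, , drop = FALSE]
    if (nrow(windows) == 0L) return(current)
    hits <- GenomicRanges::findOverlaps(as_granges0(clusters),
                                        as_granges0(windows),
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    open <- current == "unset"
    for (i in unique(qi)) {
      if (!open[i]) next
      cand <- si[qi == i]
      g <- windows[cand, , drop = FALSE]
      # distance from the cluster to the gene itself (not the window)
      gi <- match(g$id, genes$id)
      dist <- pmax(genes$start[gi] - clusters$end[i],
                   clusters$start[i] - genes$end[gi], 0)
      best <- order(dist, g$id)[1]
      category[i] <<- tier
      linked[i] <<- g$id[best]
      current[i] <- tier
    }
    current
  }

  state <- rep("unset", n)
  state <- link_tier(genes, "gene_body", state)
  state <- link_tier(up, "up2kb", state)
  state <- link_tier(down, "down2kb", state)
  te_hit <- overlaps_any(clusters, tes)
  open <- state == "unset"
  category[open & te_hit] <- "TE"
  data.frame(cluster_id = clusters$id, category = category,
             linked_gene_id = linked, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Category distribution of annotated clusters
#'
#' Fractions over the five categories (summing to 1) plus the
#' gene-associated fraction (gene_body + up2kb + down2kb).
#'
#' @param annotations result of [annotate_clusters()].
#' @return Named list with `fractions` (named numeric over the five
#'   categories), `gene_associated`, `n`.
#' @export
category_distribution <- function(annotations) {
  if (nrow(annotations) == 0L) stop("no annotated clusters")
  lv <- c("gene_body", "up2kb", "down2kb", "TE", "intergenic")
  tab <- table(factor(annotations$category, levels = lv))
  fr <- c(tab) / nrow(annotations)
  list(fractions = fr,
       gene_associated = unname(fr["gene_body"] + fr["up2kb"] + fr["down2kb"]),
       n = nrow(annotations))
}

#' Dominant size class of a small-RNA cluster
#'
#' Clusters are labelled 18- to 24-nt by the read length holding the most
#' reads. An exact tie for the maximum makes the call ambiguous
#' (`dominant_class = NA`); ambiguous clusters are excluded from
#' size-class summaries.
#'
#' @param length_histogram named numeric vector of read counts with names
#'   among `"18"` ... `"24"`.
#' @return List with `dominant_class` (integer or `NA`), `ambiguous`
#'   (logical) and the completed `length_histogram`.
#' @examples
#' dominant_size_class(c(`24` = 90, `22` = 10))$dominant_class  # 24
#' @export
dominant_size_class <- function(length_histogram) {
  if (length(length_histogram) == 0L) stop("empty length histogram")
  sizes <- as.integer(names(length_histogram))
  if (anyNA(sizes) || any(sizes < 18L | sizes > 24L))
    stop("length histogram names must be sizes 18..24")
  full <- stats::setNames(numeric(7), as.character(18:24))
  full[names(length_histogram)] <- length_histogram
  mx <- max(full)
  top <- as.integer(names(full)[full == mx])
  if (length(top) > 1L)
    return(list(dominant_class = NA_integer_, ambiguous = TRUE,
                length_histogram = full))
  list(dominant_class = top, ambiguous = FALSE, length_histogram = full)
}

#' Fraction of DMRs overlapping at least one siRNA cluster
#'
#' Base overlap on half-open intervals: abutting intervals do not count.
#'
#' @param dmrs,clusters [genomic_intervals()] in the same coordinate
#'   space.
#' @return List with `fraction` and the per-DMR logical `flags`.
#' @export
dmr_sirna_overlap <- function(dmrs, clusters) {
  flags <- overlaps_any(dmrs, clusters)
  list(fraction = if (length(flags)) mean(flags) else 0, flags = flags)
}
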