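#' Construct a set of genomic intervals
#'
#' The package stores every coordinate track (genes, TEs, siRNA clusters,
#' DMR bins) in a single 0-based half-open convention: an interval covers
#' bases `start, start+1, ..., end-1`. Conversion from the 1-based closed
#' GFF3 convention happens only at the I/O boundary ([read_gff3_genes()]).
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval. Genes must be
#'   stranded: `"."` is only permitted for non-gene tracks, because flank
#'   annotation (5'/3' 2-kb windows) needs gene orientation.
#' @param kind feature kind: `"gene"`, `"TE"`, `"sirna_cluster"`,
#'   `"dmr_bin"` or `"other"` (recycled).
#' @param id character vector of unique identifiers.
#' @return A `data.frame` of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`, `strand`, `kind`, `id`.
#' @examples
#' genomic_intervals("chr1", 999, 2000, "+", "gene", "g1")
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              kind = "other", id) {
  kinds <- c("gene", "TE", "sirna_cluster", "dmr_bin", "other")
  n <- length(start)
  start <- as.numeric(start)
  end <- as.numeric(end)
  chrom <- rep_len(as.character(chrom), max(n, 1L))[seq_len(n)]
  strand <- rep_len(as.character(strand), max(n, 1L))[seq_len(n)]
  kind <- rep_len(as.character(kind), max(n, 1L))[seq_len(n)]
  id <- as.character(id)
  if (length(end) != n || length(id) != n)
    stop("start, end and id must have equal length")
  if (!all(kind %in% kinds))
    stop("unknown interval kind: ", paste(setdiff(kind, kinds), collapse = ", "))
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1],
         ": [", start[bad[1]], ", ", end[bad[1]], ")")
  if (anyDuplicated(id))
    stop("duplicate interval id: ", id[anyDuplicated(id)])
  if (any(kind == "gene" & strand == "."))
    stop("genes must be stranded ('+' or '-')")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    strand = strand, kind = kind, id = id,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' @keywords internal
#' @noRd
as_granges0 <- function(x) {
  # internal 0-based half-open -> GRanges (1-based closed)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand)
  )
}

#' Test which query intervals overlap any subject interval
#'
#' Base-overlap (at least one shared base) on the half-open convention, so
#' abutting intervals (query end equals subject start) do not overlap.
#'
#' @param query,subject `genomic_intervals` (or data.frames with `chrom`,
#'   `start`, `end` columns). Strand is ignored.
#' @return Logical vector, one element per `query` row.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  if (nrow(query) == 0L) return(logical(0))
  IRanges::overlapsAny(as_granges0(query), as_granges0(subject),
                       ignore.strand = TRUE)
}
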