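#' Read a sample sheet
#'
#' A sample sheet maps library identifiers to the trio design. It is a TSV
#' with columns `sample_id`, `genotype` (one of `female`, `male`,
#' `hybrid`) and `replicate` (positive integer).
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with the three validated columns.
#' @export
read_sample_sheet <- function(path) {
  stop_if_missing(path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "")
  names(df) <- sub("^X\\.", "", names(df))
  sample_sheet(df$sample_id, df$genotype, as.integer(df$replicate))
}

#' Construct and validate a sample sheet
#'
#' @param sample_id unique library identifiers.
#' @param genotype `female`, `male` or `hybrid` per sample.
#' @param replicate positive integer per sample.
#' @return A validated `data.frame`.
#' @export
sample_sheet <- function(sample_id, genotype, replicate) {
  if (is.null(sample_id) || is.null(genotype) || is.null(replicate))
    stop("sample sheet needs sample_id, genotype and replicate columns")
  genotype <- as.character(genotype)
  if (!all(genotype %in% c("female", "male", "hybrid")))
    stop("genotype must be one of female/male/hybrid; got: ",
         paste(unique(setdiff(genotype, c("female", "male", "hybrid"))),
               collapse = ", "))
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ", sample_id[anyDuplicated(sample_id)])
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("replicate must be a positive integer")
  data.frame(sample_id = as.character(sample_id), genotype = genotype,
             replicate = replicate, stringsAsFactors = FALSE)
}

#' Construct a trio count matrix
#'
#' Container for feature-by-sample counts (or normalized levels) together
#' with the trio sample sheet, analogous to a minimal
#' `SummarizedExperiment` restricted to this design.
#'
#' @param counts numeric matrix, features in rows (rownames are feature
#'   ids), samples in columns (colnames match the sample sheet).
#' @param samples sample sheet (see [sample_sheet()]).
#' @param feature_kind `"miRNA"`, `"sirna_cluster"` or `"gene"`.
#' @param normalized logical; `TRUE` once values are on the
#'   reads-per-million (or FPKM) scale rather than raw counts.
#' @return An object of class `trio_counts`.
#' @export
trio_counts <- function(counts, samples, feature_kind = "sirna_cluster",
                        normalized = FALSE) {
  feature_kind <- match.arg(feature_kind, c("miRNA", "sirna_cluster", "gene"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ", rownames(counts)[anyDuplicated(rownames(counts))])
  unknown <- setdiff(colnames(counts), samples$sample_id)
  if (length(unknown))
    stop("unknown sample: ", paste(unknown, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  if (ncol(counts) != nrow(samples))
    stop("column count must equal sample-sheet rows")
  if (!normalized) {
    if (any(counts < 0)) stop("negative count")
    if (any(counts != round(counts))) stop("non-integer count")
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, samples = samples,
                 feature_kind = feature_kind, normalized = normalized),
            class = "trio_counts")
}

#' @export
print.trio_counts <- function(x, ...) {
  cat(sprintf("trio_counts: %d %s features x %d samples (%s)\n",
              nrow(x$counts), x$feature_kind, ncol(x$counts),
              if (x$normalized) "normalized" else "raw counts"))
  tab <- table(x$samples$genotype)
  cat("  samples:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Genotype column indices of a trio count matrix
#' @keywords internal
#' @noRd
geno_cols <- function(x, genotype) {
  which(x$samples$genotype == genotype)
}

#' Read a feature-by-sample count matrix
#'
#' TSV with one header row of sample ids (first column: feature ids) and
#' integer cells. Every header sample must be present in the sample sheet.
#'
#' @param path path to the TSV file.
#' @param samples sample sheet ([sample_sheet()] / [read_sample_sheet()]).
#' @param feature_kind `"miRNA"`, `"sirna_cluster"` or `"gene"`.
#' @return A [trio_counts()] object aligned to the sample sheet.
#' @export
read_counts <- function(path, samples, feature_kind = "sirna_cluster") {
  stop_if_missing(path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "")
  names(df)[1] <- sub("^#\\s*", "", names(df)[1])
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    line <- anyDuplicated(ids) + 1L  # header is line 1
    stop("duplicate feature id '", ids[anyDuplicated(ids)], "' at line ", line)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in count matrix")
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at line ", bad[1, 1] + 1L,
         " (feature ", ids[bad[1, 1]], ")")
  rownames(m) <- ids
  trio_counts(m, samples, feature_kind = feature_kind)
}

#' Write a count matrix in the canonical TSV layout
#'
#' The header line starts with `#feature_id` followed by the sample ids;
#' `read_counts(write_counts(x))` round-trips exactly.
#'
#' @param x a [trio_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#feature_id", colnames(x$counts)), collapse = "\t"), con)
  fmt <- if (x$normalized) format_num else function(v) format(v, scientific = FALSE, trim = TRUE)
  body <- apply(x$counts, 1, function(r) paste(fmt(r), collapse = "\t"))
  writeLines(paste(rownames(x$counts), body, sep = "\t"), con)
  invisible(path)
}

#' Read a per-sample cytosine methylation report
#'
#' Accepts the Bismark cytosine-report dialect: one row per cytosine with
#' columns chromosome, 1-based position, strand, count methylated, count
#' unmethylated, context (`CG`/`CHG`/`CHH`) and an optional trinucleotide
#' column (ignored). Positions are converted to the internal 0-based
#' convention; `total_reads = methylated + unmethylated`. Zero-coverage
#' rows are retained — the >= 5-read coverage filter is applied downstream
#' by [compute_wml()] and [region_dm_test()], after replicate pooling.
#'
#' @param path path to the TSV file (no header).
#' @param sample_id library identifier to attach to every row.
#' @return A `data.frame` with columns `sample_id`, `chrom`, `pos0`,
#'   `strand`, `context`, `meth_reads`, `total_reads`.
#' @export
read_cytosine_report <- function(path, sample_id) {
  stop_if_missing(path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 6) stop("cytosine report needs at least 6 columns")
  meth <- suppressWarnings(as.numeric(df[[4]]))
  unmeth <- suppressWarnings(as.numeric(df[[5]]))
  ctx <- df[[6]]
  bad <- which(!(ctx %in% c("CG", "CHG", "CHH")))
  if (length(bad))
    stop("malformed context '", ctx[bad[1]], "' at line ", bad[1])
  bad <- which(is.na(meth) | is.na(unmeth) | meth < 0 | unmeth < 0)
  if (length(bad))
    stop("negative or malformed count at line ", bad[1])
  bad <- which(!(df[[3]] %in% c("+", "-")))
  if (length(bad))
    stop("malformed strand '", df[[3]][bad[1]], "' at line ", bad[1])
  pos <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad))
    stop("malformed position at line ", bad[1])
  data.frame(sample_id = sample_id, chrom = df[[1]], pos0 = pos - 1,
             strand = df[[3]], context = ctx, meth_reads = meth,
             total_reads = meth + unmeth, stringsAsFactors = FALSE)
}

#' Write a cytosine report for one sample
#'
#' Inverse of [read_cytosine_report()] (the seventh, trinucleotide column
#' is written as `NNN`).
#'
#' @param calls data.frame as returned by [read_cytosine_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path) {
  df <- data.frame(calls$chrom, calls$pos0 + 1, calls$strand,
                   calls$meth_reads, calls$total_reads - calls$meth_reads,
                   calls$context, "NNN")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps rows of type `gene` and converts the 1-based closed GFF3
#' convention to the internal 0-based half-open one (`start - 1`). Gene
#' ids are taken from the `ID` attribute (falling back to `Name`).
#'
#' @param path path to the GFF3 file.
#' @return [genomic_intervals()] of kind `gene`.
#' @export
read_gff3_genes <- function(path) {
  stop_if_missing(path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no gene records in ", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids))
    stop("gene records must carry an ID or Name attribute")
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*")) stop("genes must be stranded ('+' or '-')")
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = st, kind = "gene", id = as.character(ids)
  )
}

#' Read an interval track from a BED file
#'
#' BED is already 0-based half-open, so coordinates pass through
#' unchanged. BED3 is accepted (ids are generated, strand `"."`); BED6
#' keeps name and strand.
#'
#' @param path path to the BED file.
#' @param kind feature kind to attach (`"TE"`, `"sirna_cluster"`,
#'   `"dmr_bin"`, `"other"`).
#' @return [genomic_intervals()] of the requested kind.
#' @export
read_bed <- function(path, kind = "other") {
  stop_if_missing(path)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(genomic_intervals(character(0), numeric(0),
                                                 numeric(0), character(0),
                                                 kind, character(0)))
  ids <- gr$name
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
    ids <- sprintf("%s_%05d", kind, seq_along(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = st, kind = kind, id = as.character(ids)
  )
}

#' Write intervals as BED6
#'
#' @param x [genomic_intervals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   x$id, 0L, x$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a GFF3 gene track
#'
#' @param genes [genomic_intervals()] of kind `gene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\ttriopatterns\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, as.integer(genes$start) + 1L,
                   as.integer(genes$end), genes$strand, genes$id)
  writeLines(lines, con)
  invisible(path)
}

#' Write a result table as TSV with a commented header
#'
#' All tabular outputs of the pipeline use a header line starting with
#' `#` so downstream tools can skip it.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) format_num(col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' @keywords internal
#' @noRd
format_num <- function(v) {
  out <- formatC(v, digits = 10, format = "g")
  out[is.na(v)] <- "NA"
  trimws(out)
}

#' @keywords internal
#' @noRd
stop_if_missing <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  invisible(path)
}
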