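#' Pipeline run configuration
#'
#' Collects every input path and every analysis constant in one place.
#' The defaults are the thresholds of the targeted study design: FDR
#' 0.05 with fold change > 2 for differential expression; RPM > 2 in at
#' least 2 samples for small-RNA features and FPKM > 0.5 in at least 2
#' samples for genes; per-cytosine coverage >= 5 reads, >= 4 cytosines
#' per region, and minimum methylation differences 0.1 (CG), 0.1 (CHG)
#' and 0.05 (CHH); D/A cutpoints 0.5 and 2; Met_d/a cutpoint 0.5; 100-bp
#' DMR bins; 2-kb gene flanks.
#'
#' @param counts_mirna,counts_sirna,counts_gene count matrix TSVs.
#' @param samples_expr,samples_meth sample sheet TSVs for the expression
#'   and methylome designs.
#' @param cytosine_reports named character vector: per-sample cytosine
#'   report paths, names are the methylome sample ids.
#' @param genes_gff3,tes_bed,clusters_bed annotation tracks.
#' @param pairs_tsv miRNA-target pair table (columns `mirna_id`,
#'   `target_gene_id`, optional `source`).
#' @param out_dir output directory.
#' @param seed integer seed recorded in the report (the pipeline itself
#'   is deterministic).
#' @param fdr,fold_change DE significance constants.
#' @param rpm_threshold,rpm_min_samples small-RNA expression filter.
#' @param fpkm_threshold,fpkm_min_samples gene expression filter.
#' @param min_coverage,min_cytosines methylation filters.
#' @param diff_cg,diff_chg,diff_chh context methylation-difference
#'   thresholds.
#' @param bin_width DMR bin width (bp).
#' @param flank gene flank width (bp) used by the annotator.
#' @param gene_matrix_normalized set `TRUE` when `counts_gene` already
#'   holds FPKM values (they are then used as-is).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(counts_mirna, counts_sirna, counts_gene,
                       samples_expr, samples_meth, cytosine_reports,
                       genes_gff3, tes_bed, clusters_bed, pairs_tsv,
                       out_dir, seed = 1L,
                       fdr = 0.05, fold_change = 2,
                       rpm_threshold = 2, rpm_min_samples = 2,
                       fpkm_threshold = 0.5, fpkm_min_samples = 2,
                       min_coverage = 5, min_cytosines = 4,
                       diff_cg = 0.1, diff_chg = 0.1, diff_chh = 0.05,
                       bin_width = 100, flank = 2000,
                       gene_matrix_normalized = FALSE) {
  cfg <- as.list(environment())
  thr <- c(fdr = fdr, fold_change = fold_change,
           rpm_threshold = rpm_threshold, rpm_min_samples = rpm_min_samples,
           fpkm_threshold = fpkm_threshold,
           fpkm_min_samples = fpkm_min_samples,
           min_coverage = min_coverage, min_cytosines = min_cytosines,
           diff_cg = diff_cg, diff_chg = diff_chg, diff_chh = diff_chh,
           bin_width = bin_width, flank = flank)
  if (any(thr <= 0)) stop("all thresholds must be positive: ",
                          paste(names(thr)[thr <= 0], collapse = ", "))
  paths <- c(counts_mirna, counts_sirna, counts_gene, samples_expr,
             samples_meth, cytosine_reports, genes_gff3, tes_bed,
             clusters_bed, pairs_tsv)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file not found: ", paste(missing, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' @keywords internal
#' @noRd
expr_stage <- function(counts, cfg, threshold, min_samples) {
  de <- lapply(c("FvsM", "HvsF", "HvsM"), function(ct)
    nb_differential_test(counts, ct, alpha = cfg$fdr,
                         lfc_threshold = log2(cfg$fold_change)))
  names(de) <- c("FvsM", "HvsF", "HvsM")
  norm <- filter_expressed(normalize_rpm(counts), threshold, min_samples)
  cand <- intersect(select_heterosis_candidates(de$FvsM, de$HvsF, de$HvsM),
                    rownames(norm$counts))
  calls <- call_expression_patterns(norm, cand)
  list(de = de, normalized = norm, candidates = cand, calls = calls,
       summary = if (nrow(calls)) summarize_patterns(calls) else
         summarize_patterns(character(0)))
}

#' Run the integrated trio pipeline end to end
#'
#' Stages: (1) read all inputs; (2) differential expression, candidate
#' selection and five-class D/A pattern calls for miRNAs, siRNA clusters
#' and genes; (3) per-context differential methylation of the cluster
#' regions, candidate selection, trio WMLs and TCM/TCdM/NIM calls; (4)
#' cluster annotation to genomic features; (5) integration: hybrid-vs-MPV
#' WML shift tests, expression-by-methylation comparisons, the six focal
#' pattern groups, expression/methylation association tests, gene-
#' pattern enrichment within groups, and opposing miRNA-target pairs.
#' Every intermediate is written as TSV/BED under `out_dir` together
#' with a machine-readable `summary.json`; a rerun with the same inputs
#' reproduces the outputs exactly. One progress line per stage reports
#' input/output record counts.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress lines.
#' @return Invisibly, the report list (also serialized as JSON).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outp <- function(f) file.path(config$out_dir, f)
  manifest <- character(0)
  emit <- function(df, f) {
    write_tsv_report(df, outp(f))
    manifest <<- c(manifest, f)
  }

  # stage 1: inputs
  samples_expr <- read_sample_sheet(config$samples_expr)
  samples_meth <- read_sample_sheet(config$samples_meth)
  mirna <- read_counts(config$counts_mirna, samples_expr, "miRNA")
  sirna <- read_counts(config$counts_sirna, samples_expr, "sirna_cluster")
  gene <- read_counts(config$counts_gene, samples_expr, "gene")
  genes <- read_gff3_genes(config$genes_gff3)
  tes <- read_bed(config$tes_bed, "TE")
  clusters <- read_bed(config$clusters_bed, "sirna_cluster")
  pairs <- utils::read.delim(config$pairs_tsv, sep = "\t",
                             stringsAsFactors = FALSE)
  calls_meth <- do.call(rbind, lapply(names(config$cytosine_reports),
    function(s) read_cytosine_report(config$cytosine_reports[[s]], s)))
  say("inputs: %d miRNAs, %d clusters, %d genes, %d cytosine rows",
      nrow(mirna$counts), nrow(sirna$counts), nrow(gene$counts),
      nrow(calls_meth))

  # stage 2: expression patterns per layer
  ex <- list(
    mirna = expr_stage(mirna, config, config$rpm_threshold,
                       config$rpm_min_samples),
    sirna = expr_stage(sirna, config, config$rpm_threshold,
                       config$rpm_min_samples),
    gene = expr_stage(gene, config, config$fpkm_threshold,
                      config$fpkm_min_samples))
  for (layer in names(ex)) {
    emit(ex[[layer]]$calls, sprintf("expression_patterns_%s.tsv", layer))
    for (ct in names(ex[[layer]]$de))
      emit(ex[[layer]]$de[[ct]], sprintf("de_%s_%s.tsv", layer, ct))
    say("expression[%s]: %d candidates of %d features", layer,
        length(ex[[layer]]$candidates), nrow(ex[[layer]]$de$FvsM))
  }

  # stage 3: methylome over the cluster regions
  geno_samples <- split(samples_meth$sample_id, samples_meth$genotype)
  pooled <- lapply(geno_samples, function(s) pool_cytosines(calls_meth, s))
  contexts <- c("CG", "CHG", "CHH")
  diff_thr <- c(CG = config$diff_cg, CHG = config$diff_chg,
                CHH = config$diff_chh)
  meth_calls <- list()
  meth_tallies <- list()
  shift_tests <- list()
  for (ctx in contexts) {
    dm <- lapply(list(FvsM = c("female", "male"), HvsF = c("hybrid", "female"),
                      HvsM = c("hybrid", "male")), function(gr)
      region_dm_test(calls_meth, clusters, ctx,
                     geno_samples[[gr[1]]], geno_samples[[gr[2]]],
                     diff_threshold = diff_thr[[ctx]],
                     min_coverage = config$min_coverage,
                     min_cytosines = config$min_cytosines,
                     alpha = config$fdr))
    cand <- select_methylation_candidates(dm$FvsM, dm$HvsF, dm$HvsM)
    wml <- lapply(pooled, function(p)
      region_wml(p, clusters, ctx, config$min_coverage))
    ok <- clusters$id %in% cand &
      !is.na(wml$female$wml) & !is.na(wml$male$wml) & !is.na(wml$hybrid$wml)
    mc <- classify_met_da(wml$female$wml[ok], wml$male$wml[ok],
                          wml$hybrid$wml[ok], region_id = clusters$id[ok],
                          context = ctx)
    meth_calls[[ctx]] <- mc
    meth_tallies[[ctx]] <- table(factor(mc$pattern,
                                        levels = c("TCM", "TCdM", "NIM")))
    def <- !is.na(wml$hybrid$wml) & !is.na(wml$female$wml) &
      !is.na(wml$male$wml)
    shift_tests[[ctx]] <- wml_shift_test(
      wml$hybrid$wml[def],
      (wml$female$wml[def] + wml$male$wml[def]) / 2)
    for (nm in names(dm)) emit(dm[[nm]], sprintf("dm_%s_%s.tsv", ctx, nm))
    emit(mc, sprintf("methylation_patterns_%s.tsv", ctx))
    say("methylome[%s]: %d candidates, %d classified", ctx,
        length(cand), nrow(mc))
  }
  all_meth <- do.call(rbind, meth_calls)

  # stage 4: genomic context
  annot <- annotate_clusters(clusters, genes, tes)
  catdist <- category_distribution(annot)
  emit(annot, "cluster_annotation.tsv")
  write_bed(clusters, outp("clusters_used.bed"))
  manifest <- c(manifest, "clusters_used.bed")
  say("annotation: %d clusters, %.1f%% gene-associated", nrow(annot),
      100 * catdist$gene_associated)

  # stage 5: integration
  groups <- build_pattern_groups(ex$sirna$calls, all_meth, annot)
  expr_levels <- data.frame(
    cluster_id = ex$sirna$calls$feature_id,
    rpm_h = ex$sirna$calls$rpm_h, stringsAsFactors = FALSE)
  exp_by_meth <- lapply(meth_calls, function(mc) {
    counts <- table(mc$pattern[mc$region_id %in% expr_levels$cluster_id])
    if (sum(counts >= 2) < 2) return(NULL)
    keep <- mc$pattern %in% names(counts)[counts >= 2]
    expression_by_methylation_pattern(expr_levels, mc[keep, , drop = FALSE])
  })
  assoc <- list()
  for (ctx in contexts) {
    mc <- meth_calls[[ctx]]
    idx <- match(mc$region_id, ex$sirna$calls$feature_id)
    sup <- pattern_superclass(ex$sirna$calls$pattern[idx[!is.na(idx)]])
    pat <- mc$pattern[!is.na(idx)]
    if (length(pat) == 0L) next
    assoc[[paste0("HPE_TCM_", ctx)]] <-
      fisher_association(sup == "HPE", pat == "TCM")
    assoc[[paste0("LPE_TCdM_", ctx)]] <-
      fisher_association(sup == "LPE", pat == "TCdM")
  }
  enrich <- NULL
  if (length(intersect(unique(unlist(groups$associated_gene_ids)),
                       ex$gene$calls$feature_id)))
    enrich <- gene_pattern_enrichment_in_groups(groups, ex$gene$calls)
  opp <- opposing_pairs(pairs, ex$mirna$calls, ex$gene$calls)
  grp_tab <- groups[, c("name", "expression_superclass", "context",
                        "methylation_pattern", "n_clusters", "n_genes")]
  emit(grp_tab, "pattern_groups.tsv")
  gene_lists <- data.frame(
    group = rep(groups$name, vapply(groups$associated_gene_ids, length, 0L)),
    gene_id = unlist(groups$associated_gene_ids), stringsAsFactors = FALSE)
  emit(gene_lists, "pattern_group_genes.tsv")
  emit(opp, "opposing_pairs.tsv")
  if (!is.null(enrich)) emit(enrich, "gene_pattern_enrichment.tsv")
  say("integration: %d focal-group clusters, %d opposing pairs",
      sum(grp_tab$n_clusters), nrow(opp))

  report <- list(
    seed = config$seed,
    n_features = list(mirna = nrow(mirna$counts), sirna = nrow(sirna$counts),
                      gene = nrow(gene$counts)),
    candidates = lapply(ex, function(e) length(e$candidates)),
    expression_tallies = lapply(ex, function(e)
      as.list(e$summary$class_counts)),
    superclass_tallies = lapply(ex, function(e)
      as.list(e$summary$superclass_counts)),
    methylation_tallies = lapply(meth_tallies, as.list),
    wml_shift = lapply(shift_tests, function(s)
      list(direction = s$direction, p = s$p, n = s$n)),
    category_fractions = as.list(catdist$fractions),
    gene_associated_fraction = catdist$gene_associated,
    focal_groups = stats::setNames(
      lapply(seq_len(nrow(groups)), function(i)
        list(n_clusters = groups$n_clusters[i], n_genes = groups$n_genes[i])),
      groups$name),
    association_tests = lapply(assoc, function(a)
      list(odds_ratio = a$odds_ratio, p = a$p)),
    expression_by_methylation = lapply(exp_by_meth, function(t)
      if (is.null(t)) NULL else
        stats::setNames(as.list(t$p), paste(t$pattern_a, t$pattern_b,
                                            sep = "_vs_"))),
    n_opposing_pairs = nrow(opp),
    manifest = manifest)
  jsonlite::write_json(report, outp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  say("report written to %s", outp("summary.json"))
  invisible(report)
}
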