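#' Configuration for the synthetic trio generator
#'
#' Bundles every knob of the synthetic expression, methylome and
#' annotation generators, with defaults chosen to emulate the study
#' design the package targets: three expression replicates and two
#' methylome replicates per genotype, negative-binomial counts with
#' dispersion 0.05, a four-fold parental expression difference, and
#' five-class proportions matching the frequencies observed among
#' differentially expressed siRNA clusters in maize hybrid data
#' (AE-dominant, transgressive classes rare).
#'
#' @param seed integer seed; every generator draw derives from it.
#' @param n_features number of expression features.
#' @param class_proportions named fractions over THPE/DHPE/AE/DLPE/TLPE
#'   (must sum to 1).
#' @param base_mean_range range of expected base counts (log-uniform).
#' @param nb_dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha mu^2).
#' @param parental_log2fc parental log2 fold change for planted
#'   features. Must be positive. For TLPE-planted features the parental
#'   log2 ratio is capped at 0.7: a hybrid mean with D/A = -3 equals
#'   `2*low - high`, which is negative whenever the parental ratio
#'   exceeds 2, so transgressive-low features require close parents.
#' @param n_reps_expr expression replicates per genotype.
#' @param n_regions number of methylome regions.
#' @param meth_class_proportions named fractions over TCM/TCdM/NIM.
#' @param cytosines_per_region integer range (min, max) of cytosines per
#'   region.
#' @param coverage_mean mean per-cytosine read coverage (Poisson).
#' @param bb_overdispersion beta-binomial intra-class correlation in
#'   `[0, 1)`; 0 gives binomial draws.
#' @param parental_meth_levels the two parental WML targets (distinct).
#' @param n_reps_meth methylome replicates per genotype.
#' @param n_mirnas,n_genes,n_tes,n_clusters,n_pairs annotation sizes.
#' @param gene_length,gene_spacing,te_length,cluster_length geometry of
#'   the toy genome (bp).
#' @param cluster_category_proportions named fractions over
#'   gene_body/up2kb/down2kb/TE/intergenic for placed clusters.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_features = 2000L,
    class_proportions = c(THPE = 0.02, DHPE = 0.15, AE = 0.69,
                          DLPE = 0.13, TLPE = 0.01),
    base_mean_range = c(100, 10000),
    nb_dispersion = 0.05,
    parental_log2fc = 2,
    n_reps_expr = 3L,
    n_regions = 1000L,
    meth_class_proportions = c(TCM = 0.25, TCdM = 0.25, NIM = 0.5),
    cytosines_per_region = c(10L, 30L),
    coverage_mean = 50,
    bb_overdispersion = 0.05,
    parental_meth_levels = c(0.3, 0.7),
    n_reps_meth = 2L,
    n_mirnas = 50L,
    n_genes = 30L,
    n_tes = 10L,
    n_clusters = 100L,
    n_pairs = 20L,
    gene_length = 3000,
    gene_spacing = 12000,
    te_length = 500,
    cluster_length = 200,
    cluster_category_proportions = c(gene_body = 0.12, up2kb = 0.17,
                                     down2kb = 0.14, TE = 0.18,
                                     intergenic = 0.39)) {
  cfg <- as.list(environment())
  chk_prop <- function(p, nm) {
    if (abs(sum(p) - 1) > 1e-8)
      stop(nm, " must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop(nm, " must be non-negative")
  }
  chk_prop(class_proportions, "class_proportions")
  chk_prop(meth_class_proportions, "meth_class_proportions")
  chk_prop(cluster_category_proportions, "cluster_category_proportions")
  if (!setequal(names(class_proportions),
                c("THPE", "DHPE", "AE", "DLPE", "TLPE")))
    stop("class_proportions needs names THPE/DHPE/AE/DLPE/TLPE")
  if (!setequal(names(meth_class_proportions), c("TCM", "TCdM", "NIM")))
    stop("meth_class_proportions needs names TCM/TCdM/NIM")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (bb_overdispersion < 0 || bb_overdispersion >= 1)
    stop("bb_overdispersion must be in [0, 1)")
  if (diff(range(base_mean_range)) < 0 || any(base_mean_range <= 0))
    stop("base_mean_range must be positive and ordered")
  structure(cfg, class = "simulation_config")
}

# planted D/A per class: midpoints of the finite class intervals,
# +/-3 for the open transgressive intervals
planted_da <- c(THPE = 3, DHPE = 1.25, AE = 0, DLPE = -1.25, TLPE = -3)

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' @keywords internal
#' @noRd
trio_sample_sheet <- function(n_reps) {
  sample_sheet(
    sample_id = c(sprintf("F_%d", seq_len(n_reps)),
                  sprintf("M_%d", seq_len(n_reps)),
                  sprintf("H_%d", seq_len(n_reps))),
    genotype = rep(c("female", "male", "hybrid"), each = n_reps),
    replicate = rep(seq_len(n_reps), 3))
}

#' Simulate a parent-hybrid count matrix with planted expression classes
#'
#' Each feature is assigned one of the five D/A classes by
#' `class_proportions`. For non-AE features the parental expected counts
#' differ by `parental_log2fc` (which parent is high is random per
#' feature) and the hybrid expected count is placed so that the expected
#' D/A ratio equals the planted class value (interval midpoints; +/-3
#' for the transgressive classes), i.e. truth is planted on the same
#' scale the classifier measures. AE features have equal parents and a
#' mid-parent hybrid: they carry no differential signal in any contrast,
#' and the candidate gate is expected to leave them unclassified (the
#' additive conclusion). Counts are negative-binomial per replicate.
#' Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param feature_ids optional feature ids (length `n_features`).
#' @return List with `counts` (a [trio_counts()] of raw counts),
#'   `truth` (data.frame `feature_id`, `planted_class`, `planted_effect`
#'   = planted D/A) and `samples`.
#' @export
simulate_trio_counts <- function(config, feature_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$parental_log2fc <= 0)
    stop("infeasible config: parental_log2fc must be > 0 ",
         "(equal parents make every D/A class degenerate)")
  n <- config$n_features
  if (is.null(feature_ids)) feature_ids <- sprintf("feature_%05d", seq_len(n))
  if (length(feature_ids) != n) stop("feature_ids must have length n_features")
  with_seed(config$seed, {
    cls <- sample(names(config$class_proportions), n, replace = TRUE,
                  prob = config$class_proportions)
    da <- planted_da[cls]
    base <- exp(stats::runif(n, log(config$base_mean_range[1]),
                             log(config$base_mean_range[2])))
    # parents differ only for non-AE features; AE features are additive
    # with equal parents, so the bulk of the matrix is non-DE and
    # median-of-ratios normalization is well posed
    lfc <- ifelse(cls == "AE", 0,
                  ifelse(cls == "TLPE",
                         # transgressive-low needs close parents (ratio < 2)
                         pmin(config$parental_log2fc, 0.7),
                         config$parental_log2fc))
    hi <- sample(c(1, -1), n, replace = TRUE)
    mu_f <- base * 2^(hi * lfc / 2)
    mu_m <- base * 2^(-hi * lfc / 2)
    mpv <- (mu_f + mu_m) / 2
    a <- pmax(mu_f, mu_m) - mpv
    mu_h <- mpv + da * a
    if (any(mu_h < 0))
      stop("infeasible config: planted hybrid mean is negative")
    nr <- config$n_reps_expr
    size <- 1 / config$nb_dispersion
    draw <- function(mu) matrix(stats::rnbinom(n * nr, mu = rep(mu, nr),
                                               size = size), ncol = nr)
    m <- cbind(draw(mu_f), draw(mu_m), draw(mu_h))
    samples <- trio_sample_sheet(nr)
    dimnames(m) <- list(feature_ids, samples$sample_id)
    list(counts = trio_counts(m, samples, feature_kind = "sirna_cluster"),
         truth = data.frame(feature_id = feature_ids, planted_class = cls,
                            planted_effect = unname(da),
                            stringsAsFactors = FALSE),
         samples = samples)
  })
}

#' Simulate a null trio count matrix (no planted effect)
#'
#' All nine samples share each feature's expected count; used to study
#' the calibration (type-I error) of [nb_differential_test()].
#'
#' @param config a [simulation_config()]; uses `n_features`,
#'   `base_mean_range`, `nb_dispersion`, `n_reps_expr` and `seed`.
#' @return A [trio_counts()] object of raw counts.
#' @export
simulate_null_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_features
  nr <- config$n_reps_expr
  with_seed(config$seed, {
    mu <- exp(stats::runif(n, log(config$base_mean_range[1]),
                           log(config$base_mean_range[2])))
    m <- matrix(stats::rnbinom(n * nr * 3, mu = rep(mu, nr * 3),
                               size = 1 / config$nb_dispersion), ncol = nr * 3)
    samples <- trio_sample_sheet(nr)
    dimnames(m) <- list(sprintf("feature_%05d", seq_len(n)),
                        samples$sample_id)
    trio_counts(m, samples)
  })
}

#' @keywords internal
#' @noRd
rbetabinom <- function(size, prob, rho) {
  if (rho <= 0) return(stats::rbinom(length(size), size, prob))
  shape <- 1 / rho - 1
  p <- stats::rbeta(length(size), prob * shape, (1 - prob) * shape)
  stats::rbinom(length(size), size, p)
}

#' Simulate parental and hybrid methylomes with planted patterns
#'
#' Each region receives a cytosine context (cycling CG/CHG/CHH) and a
#' planted pattern from `meth_class_proportions`. The two parental WML
#' targets are the (distinct) `parental_meth_levels`, randomly assigned;
#' the hybrid target is the mid-parent value for NIM, the high parent
#' for TCM (Met_d/a = +1) and the low parent for TCdM (Met_d/a = -1).
#' Per cytosine, per replicate, coverage is Poisson and methylated reads
#' are beta-binomial around the target, so replicate overdispersion
#' stresses the rank-based region test realistically. Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param regions optional [genomic_intervals()] to use as regions
#'   (default: `n_regions` non-overlapping 300-bp regions spaced 1 kb
#'   apart on `chr1`).
#' @return List with `calls` (cytosine calls for all samples), `regions`,
#'   `samples` (methylome sample sheet), `truth` (data.frame `region_id`,
#'   `context`, `planted_class`, `planted_effect` = planted Met_d/a).
#' @export
simulate_methylome <- function(config, regions = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  lv <- config$parental_meth_levels
  if (abs(lv[1] - lv[2]) < 1e-12)
    stop("infeasible config: parental_meth_levels must be distinct ",
         "(Met_d/a denominator would vanish)")
  if (is.null(regions)) {
    n <- config$n_regions
    starts <- (seq_len(n) - 1) * 1000 + 100
    regions <- genomic_intervals("chr1", starts, starts + 300, ".",
                                 "sirna_cluster",
                                 sprintf("region_%05d", seq_len(n)))
  }
  n <- nrow(regions)
  nr <- config$n_reps_meth
  samples <- trio_sample_sheet(nr)
  geno_target <- c(female = NA, male = NA, hybrid = NA)
  with_seed(config$seed + 1L, {
    ctx <- rep(c("CG", "CHG", "CHH"), length.out = n)
    cls <- sample(names(config$meth_class_proportions), n, replace = TRUE,
                  prob = config$meth_class_proportions)
    eff <- c(TCM = 1, TCdM = -1, NIM = 0)[cls]
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    p_f <- ifelse(swap, lv[2], lv[1])
    p_m <- ifelse(swap, lv[1], lv[2])
    mpv <- (p_f + p_m) / 2
    amp <- abs(p_f - p_m) / 2
    p_h <- pmin(pmax(mpv + eff * amp, 0), 1)
    ncyt <- sample(seq(config$cytosines_per_region[1],
                       config$cytosines_per_region[2]), n, replace = TRUE)
    # cytosine positions within each region
    reg_idx <- rep(seq_len(n), ncyt)
    pos <- unlist(lapply(seq_len(n), function(i)
      sort(sample(seq(regions$start[i], regions$end[i] - 1), ncyt[i]))))
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    target <- cbind(female = p_f, male = p_m, hybrid = p_h)
    calls <- lapply(seq_len(nrow(samples)), function(si) {
      pv <- target[reg_idx, samples$genotype[si]]
      tot <- stats::rpois(length(pos), config$coverage_mean)
      meth <- rbetabinom(tot, pv, config$bb_overdispersion)
      data.frame(sample_id = samples$sample_id[si],
                 chrom = regions$chrom[reg_idx], pos0 = pos,
                 strand = strand, context = ctx[reg_idx],
                 meth_reads = meth, total_reads = tot,
                 stringsAsFactors = FALSE)
    })
    list(calls = do.call(rbind, calls), regions = regions,
         samples = samples,
         truth = data.frame(region_id = regions$id, context = ctx,
                            planted_class = cls, planted_effect = unname(eff),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a toy genome annotation with clusters in known categories
#'
#' Lays out a single chromosome with evenly spaced stranded genes, TEs in
#' the intergenic gaps (outside every 2-kb gene flank), and siRNA
#' clusters placed deliberately in the requested categories (gene body,
#' 5'-2kb, 3'-2kb, TE, intergenic), recording the intended category and
#' linked gene in the truth table. Also generates a random miRNA-target
#' pair table. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return List with `genes`, `tes`, `clusters` ([genomic_intervals()]),
#'   `pairs` (data.frame `mirna_id`, `target_gene_id`, `source`),
#'   `truth` (data.frame `cluster_id`, `category`, `linked_gene_id`) and
#'   `genome_length`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ng <- config$n_genes
  gl <- config$gene_length
  sp <- config$gene_spacing
  if (sp < gl + 9000)
    stop("overcrowded genome: gene_spacing must exceed gene_length + 9000")
  cl_len <- config$cluster_length
  n_cl <- config$n_clusters
  counts <- round(config$cluster_category_proportions * n_cl)
  counts[1] <- counts[1] + n_cl - sum(counts)  # fix rounding drift
  if ((counts["TE"] > 0) && config$n_tes == 0)
    stop("overcrowded genome: TE clusters requested but n_tes = 0")
  if ((counts["gene_body"] + counts["up2kb"] + counts["down2kb"] > 0) && ng == 0)
    stop("overcrowded genome: gene-linked clusters requested but n_genes = 0")
  with_seed(config$seed + 2L, {
    gstart <- 3000 + (seq_len(ng) - 1) * sp
    genes <- genomic_intervals("chr1", gstart, gstart + gl,
                               sample(c("+", "-"), ng, replace = TRUE),
                               "gene", sprintf("gene_%04d", seq_len(ng)))
    # TEs live in the gap beyond both 2-kb flanks of the bracketing genes
    te_slot <- ((seq_len(config$n_tes) - 1) %% ng) + 1
    te_start <- genes$end[te_slot] + 2200 +
      500 * ((seq_len(config$n_tes) - 1) %/% ng)
    if (any(te_start + config$te_length > genes$end[te_slot] + 3300))
      stop("overcrowded genome: too many TEs per gap")
    tes <- if (config$n_tes > 0)
      genomic_intervals("chr1", te_start, te_start + config$te_length, ".",
                        "TE", sprintf("te_%04d", seq_len(config$n_tes)))
    else genomic_intervals(character(0), numeric(0), numeric(0),
                           character(0), "TE", character(0))

    cat_of <- rep(names(counts), counts)
    slot <- unlist(lapply(counts, seq_len))  # index within category
    place <- function(category, k) {
      switch(category,
        gene_body = {
          g <- ((k - 1) %% ng) + 1
          off <- 500 + (cl_len + 20) * ((k - 1) %/% ng)
          if (off + cl_len > gl - 200)
            stop("overcrowded genome: too many gene-body clusters per gene")
          c(genes$start[g] + off, g)
        },
        up2kb = {
          g <- ((k - 1) %% ng) + 1
          off <- 300 + (cl_len + 20) * ((k - 1) %/% ng)
          if (off + cl_len > 1900)
            stop("overcrowded genome: too many flank clusters per gene")
          s <- if (genes$strand[g] == "+") genes$start[g] - 2000 + off
               else genes$end[g] + 2000 - off - cl_len
          c(s, g)
        },
        down2kb = {
          g <- ((k - 1) %% ng) + 1
          off <- 300 + (cl_len + 20) * ((k - 1) %/% ng)
          if (off + cl_len > 1900)
            stop("overcrowded genome: too many flank clusters per gene")
          s <- if (genes$strand[g] == "+") genes$end[g] + off
               else genes$start[g] - off - cl_len
          c(s, g)
        },
        TE = {
          t <- ((k - 1) %% config$n_tes) + 1
          off <- 50 + (cl_len + 20) * ((k - 1) %/% config$n_tes)
          if (off + cl_len > config$te_length)
            stop("overcrowded genome: too many TE clusters per TE")
          c(tes$start[t] + off, NA)
        },
        intergenic = {
          g <- ((k - 1) %% ng) + 1
          off <- 3300 + (cl_len + 20) * ((k - 1) %/% ng)
          if (genes$end[g] + off + cl_len > genes$start[g] + sp - 2000)
            stop("overcrowded genome: too many intergenic clusters per gap")
          c(genes$end[g] + off, NA)
        })
    }
    placed <- t(mapply(place, cat_of, slot))
    clusters <- genomic_intervals("chr1", placed[, 1], placed[, 1] + cl_len,
                                  ".", "sirna_cluster",
                                  sprintf("cluster_%05d", seq_len(n_cl)))
    truth <- data.frame(
      cluster_id = clusters$id, category = cat_of,
      linked_gene_id = ifelse(is.na(placed[, 2]), NA_character_,
                              genes$id[placed[, 2]]),
      stringsAsFactors = FALSE, row.names = NULL)
    mirna_ids <- sprintf("mirna_%03d", seq_len(config$n_mirnas))
    pairs <- data.frame(
      mirna_id = sample(mirna_ids, config$n_pairs, replace = TRUE),
      target_gene_id = sample(genes$id, config$n_pairs, replace = TRUE),
      source = sample(c("degradome", "predicted"), config$n_pairs,
                      replace = TRUE),
      stringsAsFactors = FALSE)
    pairs <- unique(pairs)
    list(genes = genes, tes = tes, clusters = clusters, pairs = pairs,
         truth = truth, genome_length = 3000 + ng * sp)
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates a mutually consistent set of pipeline inputs — expression
#' matrices for miRNAs, siRNA clusters and genes, per-sample cytosine
#' reports over the cluster coordinates, the toy annotation, sample
#' sheets and the miRNA-target table — plus `truth_*.tsv` tables holding
#' every planted label. The cluster ids are shared between the
#' expression matrix, the methylome regions and the annotation, so the
#' full pipeline ([run_all()]) can be exercised against ground truth.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the generated file paths plus the
#'   in-memory `truth` tables.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  ann <- simulate_annotation(config)

  cfg_cl <- config; cfg_cl$n_features <- nrow(ann$clusters)
  cl <- simulate_trio_counts(cfg_cl, feature_ids = ann$clusters$id)
  cfg_mi <- config; cfg_mi$n_features <- config$n_mirnas
  cfg_mi$seed <- config$seed + 3L
  mi <- simulate_trio_counts(cfg_mi,
                             feature_ids = sprintf("mirna_%03d",
                                                   seq_len(config$n_mirnas)))
  cfg_ge <- config; cfg_ge$n_features <- config$n_genes
  cfg_ge$seed <- config$seed + 4L
  ge <- simulate_trio_counts(cfg_ge, feature_ids = ann$genes$id)
  meth <- simulate_methylome(config, regions = ann$clusters)

  utils::write.table(cl$samples, pth("samples_expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(meth$samples, pth("samples_meth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_counts(mi$counts, pth("counts_mirna.tsv"))
  write_counts(cl$counts, pth("counts_sirna.tsv"))
  write_counts(ge$counts, pth("counts_gene.tsv"))
  write_gff3_genes(ann$genes, pth("genes.gff3"))
  write_bed(ann$tes, pth("tes.bed"))
  write_bed(ann$clusters, pth("clusters.bed"))
  utils::write.table(ann$pairs, pth("pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reports <- character(0)
  for (s in meth$samples$sample_id) {
    f <- pth(sprintf("meth_%s.tsv", s))
    write_cytosine_report(meth$calls[meth$calls$sample_id == s, ], f)
    reports[s] <- f
  }
  write_tsv_report(cl$truth, pth("truth_sirna_expression.tsv"))
  write_tsv_report(mi$truth, pth("truth_mirna_expression.tsv"))
  write_tsv_report(ge$truth, pth("truth_gene_expression.tsv"))
  write_tsv_report(meth$truth, pth("truth_methylation.tsv"))
  write_tsv_report(ann$truth, pth("truth_annotation.tsv"))
  invisible(list(
    dir = dir,
    samples_expr = pth("samples_expr.tsv"),
    samples_meth = pth("samples_meth.tsv"),
    counts_mirna = pth("counts_mirna.tsv"),
    counts_sirna = pth("counts_sirna.tsv"),
    counts_gene = pth("counts_gene.tsv"),
    genes_gff3 = pth("genes.gff3"),
    tes_bed = pth("tes.bed"),
    clusters_bed = pth("clusters.bed"),
    pairs_tsv = pth("pairs.tsv"),
    cytosine_reports = reports,
    truth = list(sirna = cl$truth, mirna = mi$truth, gene = ge$truth,
                 methylation = meth$truth, annotation = ann$truth)))
}
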