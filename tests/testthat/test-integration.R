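test_that("Fisher association matches enumeration on worked tables", {
  balanced <- fisher_association(rep(c(TRUE, FALSE), each = 10),
                                 rep(c(TRUE, FALSE, TRUE, FALSE), each = 5))
  expect_equal(balanced$odds_ratio, 1)
  expect_equal(balanced$p, 1)
  perfect <- fisher_association(rep(c(TRUE, FALSE), each = 10),
                                rep(c(TRUE, FALSE), each = 10))
  expect_equal(perfect$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_true(is.finite(perfect$odds_ratio))  # Haldane-corrected
  mild <- fisher_association(rep(c(TRUE, FALSE), each = 4),
                             c(TRUE, TRUE, TRUE, FALSE,
                               TRUE, FALSE, FALSE, FALSE))
  expect_equal(mild$p, 34 / 70, tolerance = 1e-9)
  expect_equal(mild$odds_ratio, 9)
  expect_error(fisher_association(logical(0), logical(0)), "empty universe")
  expect_error(fisher_association(TRUE, c(TRUE, FALSE)), "length")
})

test_that("Fisher p equals hypergeometric enumeration across margins", {
  for (n in c(8, 12, 20)) {
    for (r1 in unique(pmax(1, round(n * c(0.25, 0.5))))) {
      for (c1 in unique(pmax(1, round(n * c(0.25, 0.5))))) {
        for (a in max(0, r1 + c1 - n):min(r1, c1)) {
          memb_a <- rep(c(TRUE, FALSE), c(r1, n - r1))
          memb_b <- rep(c(TRUE, FALSE, TRUE, FALSE),
                        c(a, r1 - a, c1 - a, n - r1 - c1 + a))
          got <- fisher_association(memb_a, memb_b)$p
          want <- fisher_p_enum(a, r1 - a, c1 - a, n - r1 - c1 + a)
          expect_equal(got, want, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("pattern groups collect members and deduplicated genes", {
  expr <- data.frame(feature_id = c("c1", "c2", "c3", "c4"),
                     pattern = c("THPE", "DHPE", "AE", "TLPE"))
  meth <- data.frame(region_id = c("c1", "c2", "c3", "c4"),
                     context = c("CG", "CG", "CG", "CHH"),
                     pattern = c("TCM", "TCM", "TCM", "TCdM"))
  ann <- data.frame(cluster_id = c("c1", "c2", "c3", "c4"),
                    category = c("gene_body", "up2kb", "gene_body", "down2kb"),
                    linked_gene_id = c("G1", "G1", "G2", "G3"))
  g <- build_pattern_groups(expr, meth, ann)
  expect_equal(nrow(g), 6)  # the six focal groups
  hpe_cg <- g[g$name == "HPE-CG-TCM", ]
  expect_setequal(hpe_cg$member_cluster_ids[[1]], c("c1", "c2"))
  expect_equal(hpe_cg$associated_gene_ids[[1]], "G1")  # deduplicated
  expect_equal(hpe_cg$n_genes, 1)
  lpe_chh <- g[g$name == "LPE-CHH-TCdM", ]
  expect_equal(lpe_chh$member_cluster_ids[[1]], "c4")
  # the AE cluster c3 appears in no focal group
  expect_false(any(vapply(g$member_cluster_ids, function(m) "c3" %in% m,
                          TRUE)))
  # a cluster with no methylation call is excluded and counted
  g2 <- build_pattern_groups(expr, meth[1:3, ], ann)
  expect_equal(attr(g2, "n_excluded"), 1)
  all_groups <- build_pattern_groups(expr, meth, ann, focal_only = FALSE)
  expect_equal(sum(all_groups$n_clusters), 4)  # partition refinement
})

test_that("opposing pairs keep only HPE-LPE combinations", {
  mirna <- data.frame(feature_id = c("m1", "m2", "m3", "m4"),
                      da_ratio = c(5.23, -0.2, 1.2, -3.39),
                      pattern = c("THPE", "AE", "DHPE", "TLPE"))
  gene <- data.frame(feature_id = c("gA", "gB", "gC"),
                     da_ratio = c(-15.86, 8.51, 2.5),
                     pattern = c("TLPE", "THPE", "THPE"))
  pairs <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4", "m1", "zz"),
    target_gene_id = c("gA", "gB", "gC", "gB", "gB", "gA"),
    source = "degradome")
  got <- opposing_pairs(pairs, mirna, gene)
  # m1(THPE)-gA(TLPE) in; m2 is AE out; m3(HPE)-gC(HPE) out;
  # m4(TLPE)-gB(THPE) in; m1-gB both high out; zz unmatched skipped
  expect_equal(got$mirna_id, c("m1", "m4"))
  expect_equal(got$mirna_da, c(5.23, -3.39))
  expect_equal(got$gene_da, c(-15.86, 8.51))
  expect_equal(attr(got, "n_skipped"), 1)
})

test_that("gene-superclass enrichment inside groups uses the right
          background and enumeration p-values", {
  groups <- data.frame(name = c("HPE-CG-TCM", "LPE-CG-TCdM"),
                       expression_superclass = c("HPE", "LPE"),
                       context = "CG",
                       methylation_pattern = c("TCM", "TCdM"),
                       n_clusters = c(2, 0), n_genes = c(5, 0))
  groups$member_cluster_ids <- list(c("c1", "c2"), character(0))
  groups$associated_gene_ids <- list(sprintf("L%d", 1:5), character(0))
  gene_calls <- data.frame(
    feature_id = c(sprintf("L%d", 1:5), sprintf("H%d", 1:5)),
    pattern = rep(c("DLPE", "DHPE"), each = 5))
  res <- gene_pattern_enrichment_in_groups(groups, gene_calls,
                                           universe = gene_calls$feature_id)
  row <- res[res$group == "HPE-CG-TCM" & res$gene_superclass == "LPE", ]
  expect_equal(row$n_overlap, 5)
  expect_gt(row$odds_ratio, 1)
  expect_equal(row$p, fisher_p_enum(5, 0, 0, 5), tolerance = 1e-9)
  expect_equal(attr(res, "skipped"), "LPE-CG-TCdM")
  # group identical in composition to the background: p = 1
  g1 <- groups[1, ]
  g1$associated_gene_ids <- list(gene_calls$feature_id)
  res2 <- gene_pattern_enrichment_in_groups(g1, gene_calls,
                                            universe = gene_calls$feature_id)
  expect_true(all(res2$p == 1))
})

test_that("term enrichment is an upper-tail hypergeometric with BH", {
  universe <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene = c(universe[1:5], universe[1:10]),
                    term = rep(c("exact", "broad"), c(5, 10)))
  hit <- term_enrichment(universe[1:5], ann, universe)
  exact <- hit[hit$term == "exact", ]
  expect_equal(exact$k, 5)
  expect_equal(exact$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(hit$fdr, stats::p.adjust(hit$p, "BH"))
  all_in <- term_enrichment(universe, ann, universe)
  expect_true(all(all_in$p == 1))
  none <- term_enrichment(universe[16:20], ann[1:5, ], universe)
  expect_equal(none$k, 0)
  expect_equal(none$p, 1)
  expect_error(term_enrichment("zz", ann, universe), "subset")
})

test_that("expression differs between methylation patterns when planted", {
  set.seed(21)
  levels <- data.frame(
    cluster_id = sprintf("c%03d", 1:400),
    rpm_h = 2^c(stats::rnorm(200, 8, 1), stats::rnorm(200, 6, 1)))
  meth <- data.frame(region_id = levels$cluster_id,
                     context = "CHH",
                     pattern = rep(c("TCM", "TCdM"), each = 200))
  res <- expression_by_methylation_pattern(levels, meth)
  expect_equal(nrow(res), 1)
  expect_lt(res$p, 1e-10)
  expect_gt(res$t_statistic, 0)  # TCM listed first, higher expression
  tiny <- meth; tiny$pattern <- rep(c("TCM", "TCdM"), c(1, 399))
  expect_error(expression_by_methylation_pattern(levels, tiny),
               "at least 2 clusters")
})
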