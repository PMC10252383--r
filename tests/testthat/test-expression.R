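test_that("RPM normalization scales every sample to one million", {
  x <- tiny_trio()
  n <- normalize_rpm(x)
  expect_equal(unname(colSums(n$counts)), rep(1e6, 9))
  # 2-feature sample: counts (1,1) -> (500000, 500000); (3,7) -> (3e5, 7e5)
  s <- sample_sheet(c("F_1", "F_2", "M_1", "M_2", "H_1", "H_2"),
                    rep(c("female", "male", "hybrid"), each = 2), rep(1:2, 3))
  m <- matrix(c(1, 3, 1, 3, 1, 3,
                1, 7, 1, 7, 1, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), s$sample_id))
  r <- normalize_rpm(trio_counts(m, s))
  expect_equal(unname(r$counts[, "F_1"]), c(5e5, 5e5))
  expect_equal(unname(r$counts[, "F_2"]), c(3e5, 7e5))
  # scale invariance: multiplying a library leaves its RPM unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 10
  r2 <- normalize_rpm(trio_counts(m2, s))
  expect_equal(r2$counts, r$counts)
  bad <- m; bad[, 3] <- 0
  expect_error(normalize_rpm(trio_counts(bad, s)), "zero-total")
})

test_that("expression filter uses a strict threshold over enough samples", {
  s <- tiny_trio()$samples
  m <- matrix(c(rep(2, 9),          # exactly at threshold: dropped
                c(3, 3, rep(0, 7)), # above in exactly 2 samples: kept
                c(3, rep(0, 8))),   # above in only 1: dropped
              nrow = 3, byrow = TRUE,
              dimnames = list(c("at", "twice", "once"), s$sample_id))
  x <- trio_counts(m, s); x$normalized <- TRUE
  kept <- filter_expressed(x, threshold = 2, min_samples = 2)
  expect_equal(rownames(kept$counts), "twice")
  empty <- x; empty$counts <- x$counts[0, , drop = FALSE]
  expect_equal(nrow(filter_expressed(empty, 2, 2)$counts), 0)
})

test_that("classify_da reproduces the five-interval rule everywhere", {
  # worked values with known classes
  expect_equal(classify_da(c(-3.39, 19.8, 5.23, 0, -0.79, -1.37)),
               c("TLPE", "THPE", "THPE", "AE", "DLPE", "DLPE"))
  # boundaries go to the less extreme class
  expect_equal(classify_da(c(2, 0.5, -0.5, -2)),
               c("DHPE", "AE", "AE", "DLPE"))
  expect_equal(classify_da(c(Inf, -Inf)), c("THPE", "TLPE"))
  expect_error(classify_da(NaN), "NaN")
  # the intervals partition the extended real line (vs independent cut)
  set.seed(42)
  da <- c(stats::rcauchy(2000), -2, 2, -0.5, 0.5)
  lab <- classify_da(da)
  expect_false(any(lab == ""))
  oracle <- classify_da_oracle(da)
  expect_equal(lab, oracle)
})

test_that("pattern calls compute D, A, D/A and handle equal parents", {
  one <- classify_expression_pattern(10, 20, 15)
  expect_equal(one$dominance_d, 0)
  expect_equal(one$additivity_a, 5)
  expect_equal(one$pattern, "AE")
  two <- classify_expression_pattern(100, 50, 120)
  expect_equal(two$mpv, 75)
  expect_equal(two$da_ratio, 45 / 25)
  expect_equal(two$pattern, "DHPE")
  deg <- classify_expression_pattern(50, 50, 80)
  expect_equal(deg$da_ratio, Inf)
  expect_equal(deg$pattern, "THPE")
  expect_equal(classify_expression_pattern(50, 50, 50)$pattern, "AE")
  expect_error(classify_expression_pattern(-1, 2, 3), "negative")
})

test_that("pattern calls are parent-swap invariant and transgressive classes
          bound the hybrid by the parents", {
  set.seed(7)
  f <- stats::runif(500, 0, 100)
  m <- stats::runif(500, 0, 100)
  h <- stats::runif(500, 0, 200)
  a <- classify_expression_pattern(f, m, h)
  b <- classify_expression_pattern(m, f, h)
  expect_equal(a$da_ratio, b$da_ratio)
  expect_equal(a$pattern, b$pattern)
  expect_equal(a$dominance_d, b$dominance_d)
  thpe <- a$pattern == "THPE"
  expect_true(all(h[thpe] > pmax(f, m)[thpe]))
  tlpe <- a$pattern == "TLPE"
  expect_true(all(h[tlpe] < pmin(f, m)[tlpe]))
})

test_that("NB test is null on identical groups and finds strong effects", {
  s <- tiny_trio()$samples
  m <- matrix(rep(c(30, 40, 50), each = 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), s$sample_id))
  de <- nb_differential_test(trio_counts(m, s), "FvsM")
  expect_equal(de$log2fc, rep(0, 3))
  expect_true(all(de$p > 0.99))
  expect_false(any(de$significant))
  # planted 4-fold changes (10 up, 10 down) among 180 null features at
  # low dispersion: recovered with the right sign
  set.seed(11)
  mu_f <- c(rep(400, 10), rep(100, 10), rep(150, 180))
  mu_m <- c(rep(100, 10), rep(400, 10), rep(150, 180))
  k <- cbind(sapply(1:3, function(i) stats::rnbinom(200, mu = mu_f,
                                                    size = 100)),
             sapply(1:3, function(i) stats::rnbinom(200, mu = mu_m,
                                                    size = 100)),
             sapply(1:3, function(i) stats::rnbinom(200, mu = mu_m,
                                                    size = 100)))
  dimnames(k) <- list(sprintf("g%03d", 1:200), s$sample_id)
  de2 <- nb_differential_test(trio_counts(k, s), "FvsM")
  expect_gt(mean(de2$significant[1:20]), 0.9)
  expect_true(all(de2$log2fc[1:10][de2$significant[1:10]] > 1))
  expect_true(all(de2$log2fc[11:20][de2$significant[11:20]] < -1))
  expect_lt(mean(de2$significant[21:200]), 0.1)
  expect_error(nb_differential_test(trio_counts(
    k[, c(1, 4:6, 7:9)], s[c(1, 4:6, 7:9), ]), "FvsM"), "2 replicates")
})

test_that("candidate selection follows the F-vs-M or common-direction rule", {
  mk <- function(sig, lfc) data.frame(
    feature_id = c("a", "b", "c", "d"), contrast = "x", base_mean = 1,
    log2fc = lfc, p = 0.01, fdr = 0.01, significant = sig)
  fm <- mk(c(TRUE, FALSE, FALSE, FALSE), c(2, 0, 0, 0))
  hf <- mk(c(FALSE, TRUE, TRUE, TRUE), c(0, 2, 2, 2))
  hm <- mk(c(FALSE, TRUE, FALSE, TRUE), c(0, 2, 2, -2))
  # a: FvsM only -> in; b: both hybrid contrasts same sign -> in
  # c: one hybrid contrast only -> out; d: opposite signs -> out
  expect_setequal(select_heterosis_candidates(fm, hf, hm), c("a", "b"))
  expect_error(select_heterosis_candidates(fm, hf[1:3, ], hm), "universes")
})

test_that("pattern tallies partition candidates into classes and superclasses", {
  calls <- rep(c("THPE", "DHPE", "AE"), c(2, 1, 3))
  s <- summarize_patterns(calls)
  expect_equal(unname(s$superclass_counts), c(3, 0, 3))
  expect_equal(s$total, 6)
  expect_equal(sum(s$class_counts), s$total)
  z <- summarize_patterns(character(0))
  expect_equal(unname(z$class_counts), rep(0L, 5))
  expect_error(summarize_patterns("HIGH"), "unknown pattern")
  expect_equal(pattern_superclass(c("THPE", "DLPE", "AE")),
               c("HPE", "LPE", "AE"))
})

test_that("NB test agrees with an independent NB-GLM implementation on
          fold changes and planted-effect detection", {
  set.seed(19)
  s <- tiny_trio()$samples
  mu_f <- c(rep(400, 15), rep(100, 15), rep(150, 170))
  mu_m <- c(rep(100, 15), rep(400, 15), rep(150, 170))
  k <- cbind(sapply(1:3, function(i) stats::rnbinom(200, mu = mu_f, size = 20)),
             sapply(1:6, function(i) stats::rnbinom(200, mu = mu_m, size = 20)))
  dimnames(k) <- list(sprintf("g%03d", 1:200), s$sample_id)
  mine <- nb_differential_test(trio_counts(k, s), "FvsM")
  suppressMessages({
    cd <- data.frame(condition = factor(s$genotype[1:6],
                                        levels = c("male", "female")))
    dds <- DESeq2::DESeqDataSetFromMatrix(k[, 1:6], cd, ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds)
  })
  expect_gt(stats::cor(mine$log2fc, ref$log2FoldChange), 0.95)
  planted <- 1:30
  expect_gte(mean(mine$significant[planted]), 0.85)
  expect_gte(mean(ref$padj[planted] < 0.05 &
                    abs(ref$log2FoldChange[planted]) > 1, na.rm = TRUE),
             0.85)
  # both implementations see the same direction on the planted features
  expect_true(all(sign(mine$log2fc[planted]) ==
                    sign(ref$log2FoldChange[planted])))
})
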