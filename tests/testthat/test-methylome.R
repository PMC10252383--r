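region1 <- function() genomic_intervals("chr1", 0, 1000, ".",
                                        "sirna_cluster", "r1")

test_that("weighted methylation level pools reads and applies the
          coverage filter per cytosine", {
  expect_equal(compute_wml(tiny_cytosines(c(3, 7), c(10, 10)),
                           region1(), "CHH")$wml, 0.5)
  expect_equal(compute_wml(tiny_cytosines(c(0, 0, 0), c(10, 8, 6)),
                           region1(), "CHH")$wml, 0)
  # (2/4, 5/10) at min coverage 5: first cytosine excluded -> 5/10
  r <- compute_wml(tiny_cytosines(c(2, 5), c(4, 10)), region1(), "CHH")
  expect_equal(r$wml, 0.5)
  expect_equal(r$n_cytosines, 1)
  # nothing passes -> explicit missing value, not zero
  none <- compute_wml(tiny_cytosines(c(1, 1), c(2, 3)), region1(), "CHH")
  expect_true(is.na(none$wml))
  expect_equal(none$n_cytosines, 0)
  # context selectivity and scale invariance
  calls <- rbind(tiny_cytosines(c(3, 9), c(10, 10), "CG"),
                 tiny_cytosines(8, 10, "CHH", start = 100))
  expect_equal(compute_wml(calls, region1(), "CG")$wml, 12 / 20)
  scaled <- calls
  scaled$meth_reads <- scaled$meth_reads * 7
  scaled$total_reads <- scaled$total_reads * 7
  expect_equal(compute_wml(scaled, region1(), "CG")$wml, 12 / 20)
})

test_that("region_wml matches compute_wml over many regions", {
  set.seed(3)
  regions <- genomic_intervals("chr1", seq(0, 900, 100),
                               seq(0, 900, 100) + 80, ".", "dmr_bin",
                               sprintf("b%02d", 1:10))
  calls <- data.frame(chrom = "chr1", pos0 = sample(0:999, 200),
                      strand = "+", context = sample(c("CG", "CHH"), 200, TRUE),
                      meth_reads = stats::rbinom(200, 10, 0.4),
                      total_reads = 10, stringsAsFactors = FALSE)
  fast <- region_wml(calls, regions, "CG")
  slow <- lapply(seq_len(10), function(i)
    compute_wml(calls, regions[i, ], "CG"))
  expect_equal(fast$wml, vapply(slow, `[[`, 0, "wml"))
  expect_equal(fast$n_cytosines, vapply(slow, function(s)
    as.integer(s$n_cytosines), 0L))
})

test_that("pooling sums read counts per cytosine across replicates", {
  a <- tiny_cytosines(c(1, 2), c(4, 4))
  b <- tiny_cytosines(c(3, 0), c(6, 2))
  a$sample_id <- "F_1"; b$sample_id <- "F_2"
  p <- pool_cytosines(rbind(a, b))
  expect_equal(p$meth_reads, c(4, 2))
  expect_equal(p$total_reads, c(10, 6))
})

test_that("bin tiling conserves genome length and keeps the partial bin", {
  b <- make_bins(c(chrA = 250), width = 100)
  expect_equal(b$start, c(0, 100, 200))
  expect_equal(b$end, c(100, 200, 250))
  sizes <- c(chr1 = 1234, chr2 = 999, chr3 = 100)
  bins <- make_bins(sizes, width = 100)
  expect_equal(sum(bins$end - bins$start), sum(sizes))
  expect_equal(as.vector(table(bins$chrom)[names(sizes)]),
               as.vector(ceiling(sizes / 100)))
  expect_error(make_bins(c(5, 5)), "named")
})

test_that("region DM test matches exact rank-test enumeration and applies
          the cytosine-count gate", {
  mk_calls <- function(sample_id, levels, cov = 10, start = 0) {
    data.frame(sample_id = sample_id, chrom = "chr1",
               pos0 = start + seq_along(levels) * 5, strand = "+",
               context = "CG", meth_reads = round(levels * cov),
               total_reads = cov, stringsAsFactors = FALSE)
  }
  reg <- region1()
  # 6 cytosines, group1 all 1.0, group2 all 0.0: exact two-sided MWU
  calls <- rbind(mk_calls("g1a", rep(1, 6), 6), mk_calls("g1b", rep(1, 6), 6),
                 mk_calls("g2a", rep(0, 6), 6), mk_calls("g2b", rep(0, 6), 6))
  r <- region_dm_test(calls, reg, "CG", c("g1a", "g1b"), c("g2a", "g2b"),
                      diff_threshold = 0.1)
  expect_equal(r$meth_diff, 1)
  expect_equal(r$n_cytosines, 6)
  expect_equal(r$p, 2 * factorial(6)^2 / factorial(12), tolerance = 1e-12)
  expect_true(r$significant)
  # identical level vectors: p = 1, never significant
  same <- rbind(mk_calls("g1a", c(.2, .4, .6, .8), 10),
                mk_calls("g1b", c(.2, .4, .6, .8), 10),
                mk_calls("g2a", c(.2, .4, .6, .8), 10),
                mk_calls("g2b", c(.2, .4, .6, .8), 10))
  r2 <- region_dm_test(same, reg, "CG", c("g1a", "g1b"), c("g2a", "g2b"), 0.1)
  expect_equal(r2$p, 1)
  expect_false(r2$significant)
  # 3 cytosines: never significant regardless of separation
  three <- rbind(mk_calls("g1a", rep(1, 3), 10), mk_calls("g1b", rep(1, 3), 10),
                 mk_calls("g2a", rep(0, 3), 10), mk_calls("g2b", rep(0, 3), 10))
  r3 <- region_dm_test(three, reg, "CG", c("g1a", "g1b"), c("g2a", "g2b"), 0.1)
  expect_equal(r3$n_cytosines, 3)
  expect_false(r3$significant)
  # region with no eligible cytosines is excluded but reported
  low <- rbind(mk_calls("g1a", rep(1, 4), 1), mk_calls("g1b", rep(1, 4), 1),
               mk_calls("g2a", rep(0, 4), 1), mk_calls("g2b", rep(0, 4), 1))
  r4 <- region_dm_test(low, reg, "CG", c("g1a", "g1b"), c("g2a", "g2b"), 0.1)
  expect_true(is.na(r4$p))
  expect_false(r4$significant)
  expect_error(region_dm_test(calls, reg, "CG", "g1a", c("g2a", "g2b"), 0.1),
               "2 replicates")
})

test_that("methylation candidate selection mirrors the expression rule", {
  mk <- function(sig, diff) data.frame(
    region_id = c("r1", "r2", "r3", "r4"), context = "CG", n_cytosines = 5,
    meth_diff = diff, p = 0.01, fdr = 0.01, significant = sig)
  fm <- mk(c(TRUE, FALSE, FALSE, FALSE), c(.3, 0, 0, 0))
  hf <- mk(c(FALSE, TRUE, TRUE, TRUE), c(0, .3, .3, .3))
  hm <- mk(c(FALSE, TRUE, FALSE, TRUE), c(0, .3, .3, -.3))
  expect_setequal(select_methylation_candidates(fm, hf, hm), c("r1", "r2"))
})

test_that("Met_d/a classification follows the formula, its closed form,
          and parent-swap invariance", {
  one <- classify_met_da(0.8, 0.2, 0.9)
  expect_equal(one$met_da, 0.4 / 0.3)
  expect_equal(one$pattern, "TCM")
  expect_equal(classify_met_da(0.8, 0.2, 0.5)$pattern, "NIM")
  # printed-style worked values: met_da = mpv + ratio * |F-M| / 2
  trip <- function(md) classify_met_da(0.75, 0.25, 0.5 + md * 0.25)
  expect_equal(trip(0.55)$pattern, "TCM")
  expect_equal(trip(-0.9)$pattern, "TCdM")
  expect_equal(trip(-0.9)$met_da, -0.9)
  # boundaries are NIM; degenerate parents resolved by sign
  expect_equal(trip(0.5)$pattern, "NIM")
  expect_equal(trip(-0.5)$pattern, "NIM")
  deg <- classify_met_da(c(0.4, 0.4, 0.4), c(0.4, 0.4, 0.4), c(0.4, 0.9, 0.1))
  expect_equal(deg$pattern, c("NIM", "TCM", "TCdM"))
  expect_equal(deg$met_da, c(0, Inf, -Inf))
  expect_error(classify_met_da(NA, 0.5, 0.5), "undefined WML")
  # closed form 2(H - MPV)/|F - M| and parent swap, random triples
  set.seed(9)
  f <- stats::runif(3000); m <- stats::runif(3000); h <- stats::runif(3000)
  keep <- abs(f - m) > 1e-9
  a <- classify_met_da(f[keep], m[keep], h[keep])
  closed <- 2 * (h[keep] - (f[keep] + m[keep]) / 2) / abs(f[keep] - m[keep])
  expect_equal(a$met_da, closed, tolerance = 1e-12)
  b <- classify_met_da(m[keep], f[keep], h[keep])
  expect_equal(a$met_da, b$met_da)
  expect_equal(a$pattern, b$pattern)
  expect_true(all(a$pattern %in% c("TCM", "TCdM", "NIM")))
})

test_that("the genome-wide WML shift test detects a planted shift", {
  set.seed(5)
  mpv <- stats::runif(100, 0.2, 0.6)
  same <- wml_shift_test(mpv, mpv)
  expect_equal(same$p, 1)
  up <- wml_shift_test(mpv + 0.2, mpv)
  expect_equal(up$direction, 1)
  expect_lt(up$p, 1e-10)
  expect_error(wml_shift_test(numeric(0), numeric(0)), "no regions")
  expect_error(wml_shift_test(1:3 / 10, 1:4 / 10), "length mismatch")
})
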