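# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (enumeration / brute force) and share no code with
# the package implementation they check.

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed that of the observed table (with the usual
# relative tolerance for floating-point ties).
fisher_p_enum <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, n - r1, c1)
  obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Quadratic-time base-overlap oracle on 0-based half-open intervals.
overlap_any_brute <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          query$start[i] < subject$end)
  }, logical(1))
}

# D/A interval rule written independently: classify the magnitude into
# additive/dominant/transgressive bands (boundaries to the milder band),
# then attach the direction.
classify_da_oracle <- function(da) {
  mag <- abs(da)
  band <- ifelse(mag <= 0.5, "A", ifelse(mag <= 2, "D", "T"))
  ifelse(band == "A", "AE",
         ifelse(da > 0, paste0(band, "HPE"), paste0(band, "LPE")))
}

# Final five-class label of the end-to-end expression pipeline: the
# classifier's call for candidates, additive for everything the
# candidate gate screened out.
final_expression_labels <- function(truth_ids, calls) {
  lab <- stats::setNames(rep("AE", length(truth_ids)), truth_ids)
  lab[calls$feature_id] <- calls$pattern
  unname(lab)
}

# Tiny trio counts fixture: 3 features x 9 samples with known values.
tiny_trio <- function() {
  samples <- sample_sheet(
    c("F_1", "F_2", "F_3", "M_1", "M_2", "M_3", "H_1", "H_2", "H_3"),
    rep(c("female", "male", "hybrid"), each = 3), rep(1:3, 3))
  m <- matrix(c(10, 12, 11, 20, 22, 21, 15, 16, 14,
                100, 110, 105, 50, 55, 52, 120, 118, 122,
                5, 6, 4, 5, 4, 6, 5, 5, 5),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("f1", "f2", "f3"), samples$sample_id))
  trio_counts(m, samples)
}

# Cytosine calls fixture over one region.
tiny_cytosines <- function(meth, total, context = "CHH", chrom = "chr1",
                           start = 10) {
  data.frame(chrom = chrom, pos0 = start + seq_along(meth) * 3,
             strand = "+", context = context,
             meth_reads = meth, total_reads = total,
             stringsAsFactors = FALSE)
}
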