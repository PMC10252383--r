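# triopatterns

Integrative analysis of small-RNA, transcriptome and DNA-methylome
data from an F1 hybrid and its two inbred parents (a *trio*), aimed at
heterosis studies: which miRNAs, siRNA clusters and genes behave
non-additively in the hybrid, how hybrid methylation of siRNA-cluster
regions deviates from the mid-parent expectation, and whether the two
layers associate at co-localized genes. The package is written for
analysts working with maize-style hybrid designs (three expression
replicates, two bisulfite replicates per genotype), but nothing in it
is species-specific.

## The statistics at its core

**Expression patterns.** For each feature, with replicate-mean
normalized expression F, M (parents) and H (hybrid),

    MPV = (F + M)/2        D = H − MPV        A = max(F, M) − MPV

the dominance/additivity ratio D/A partitions hybrid behaviour into
five classes: THPE (D/A > 2), DHPE (0.5 < D/A ≤ 2), AE (|D/A| ≤ 0.5),
DLPE (−2 ≤ D/A < −0.5), TLPE (D/A < −2); HPE = THPE ∪ DHPE and
LPE = TLPE ∪ DLPE. Classification is applied to *candidates*: features
differentially expressed between the parents, or in the same direction
in both hybrid-vs-parent contrasts (NB Wald test, FDR < 0.05 and fold
change > 2).

**Methylation patterns.** Region methylation is the weighted
methylation level (WML = Σ methylated / Σ total reads over cytosines
with pooled coverage ≥ 5). The hybrid state of a differentially
methylated region is classified by

    Met_d/a = (WML_H − WML_MPV) / max(|WML_F − WML_MPV|, |WML_M − WML_MPV|)

into TCM (> 0.5, trans-chromosomal methylation), TCdM (< −0.5,
demethylation) and NIM otherwise. Region tests are two-sided
Mann–Whitney U on per-cytosine levels (exact by permutation for small
regions), gated at ≥ 4 cytosines, FDR < 0.05 and absolute differences
0.1/0.1/0.05 for CG/CHG/CHH.

**Integration.** Clusters are annotated to gene body / 5′-2kb /
3′-2kb / TE / intergenic (strand-aware 2-kb flanks, precedence in that
order), grouped by expression superclass × context × methylation
pattern, and associations are tested with two-sided Fisher exact
tests; a generic hypergeometric term-enrichment test and opposing
miRNA–target pair detection round out the layer. Phenotypic heterosis
is computed as MPH = 100·(F1 − MPV)/MPV and BPH = 100·(F1 − BPV)/BPV.

A built-in seeded generator (`simulate_trio_counts`,
`simulate_methylome`, `simulate_annotation`, `simulate_bundle`) plants
ground-truth labels on exactly the scales the classifiers measure, so
the whole pipeline is testable without sequencing data.

## Worked example

```r
library(triopatterns)

cfg  <- simulation_config(seed = 42, n_features = 500)
sim  <- simulate_trio_counts(cfg)
de   <- lapply(c("FvsM", "HvsF", "HvsM"),
               function(ct) nb_differential_test(sim$counts, ct))
cand <- select_heterosis_candidates(de[[1]], de[[2]], de[[3]])
calls <- call_expression_patterns(normalize_rpm(sim$counts), cand)
summarize_patterns(calls)$class_counts
#> THPE DHPE   AE DLPE TLPE
#>   15   59    3   67    1
summarize_patterns(calls)$superclass_counts
#> HPE LPE  AE
#>  74  68   3
```

145 of 500 simulated features pass the candidate gate (the planted
additive features have equal parents and no differential signal, so
they are screened out rather than classified); among candidates the
D/A ratio assigns the five classes, 74 HPE and 68 LPE. Counting
screened-out features as additive, 97.6% of the 500 planted labels are
recovered. The classifiers also work directly on reported summary
numbers:

```r
classify_da(c(-3.39, 19.8, 0.92, -1.37))
#> [1] "TLPE" "THPE" "DHPE" "DLPE"
classify_met_da(0.8, 0.2, 0.9)[, c("met_da", "pattern")]
#>     met_da pattern
#> 1 1.333333     TCM
mph(233, 151, 169); bph(233, 151, 169)
#> [1] 45.625
#> [1] 37.86982
```

A hybrid measuring 233 cm against parents of 151 and 169 cm shows
45.6% mid-parent and 37.9% better-parent heterosis.

The full pipeline runs from files: `simulate_bundle(cfg, dir)` writes
a mutually consistent input set, and `run_all(run_config(...))`
executes every stage, writes all intermediates as TSV/BED and a
`summary.json` report. A thin command-line wrapper lives at
`inst/scripts/triopatterns-cli.R` (subcommands `simulate`, `run-all`,
`classify-expression`, `annotate`, `heterosis`).

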