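---
title: "Classifying hybrid expression and methylation patterns in parent-hybrid trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hybrid expression and methylation patterns in parent-hybrid trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triopatterns)
```

## The analysis problem

An F1 hybrid and its two inbred parents (a trio) are profiled on three
molecular layers: small-RNA expression (miRNAs and siRNA clusters),
mRNA expression, and whole-genome bisulfite methylation. Heterosis
work asks, per feature, whether the hybrid behaves *additively*
(halfway between its parents) or *non-additively*, and whether
non-additive 24-nt siRNA clusters — the guides of RNA-directed DNA
methylation (RdDM) — co-locate with non-additive methylation at genes.
`triopatterns` implements this analysis as composable, tested R
functions plus a single orchestrating pipeline, and ships a seeded
synthetic-data generator with planted ground truth so every stage can
be validated without sequencing data.

## The dominance/additivity classifier

For a feature with replicate-mean normalized expression $F$, $M$
(parents) and $H$ (hybrid):

* mid-parent value $\mathrm{MPV} = (F + M)/2$,
* dominance $D = H - \mathrm{MPV}$,
* additivity $A = \mathrm{HP} - \mathrm{MPV}$ with
  $\mathrm{HP} = \max(F, M)$.

The ratio $D/A$ locates the hybrid relative to the parental range:
$D/A = 1$ means the hybrid sits at the high parent, $D/A = -1$ at the
low parent, $0$ at the mid-parent. Five classes partition the line:
THPE ($D/A > 2$), DHPE ($0.5 < D/A \le 2$), AE ($|D/A| \le 0.5$),
DLPE ($-2 \le D/A < -0.5$) and TLPE ($D/A < -2$); HPE = THPE ∪ DHPE
and LPE = TLPE ∪ DLPE are the usual superclasses. The defining
inequalities are strict in both directions, which leaves the boundary
values unassigned; we assign boundaries to the *less extreme* class
(e.g. $D/A = 2$ is DHPE), a conservative, total rule. When the parents
are equal $A = 0$ and the ratio is undefined; such features can only
enter the classified set through the hybrid-vs-both-parents route, and
the only usable information is the sign of $D$: the call is AE when
$|D|$ is negligible, otherwise THPE/TLPE with `da_ratio` recorded as
±Inf.

Two algebraic consequences are asserted package-wide as invariants:
a THPE call implies the hybrid exceeds the high parent, TLPE implies
it undercuts the low parent; and all of $D$, $A$, $D/A$ and the class
are invariant under swapping the parent labels.

$D/A$ is computed from replicate-mean RPM (or FPKM for genes), not
from model-fitted means — the classifier is kept on the same scale as
the field's standard definition, and the differential test below is used
only as a gate.

## Differential expression and the candidate gate

Not every feature deserves a pattern call: classification is applied
to *candidates* — features differentially expressed between the
parents (F vs M), or differentially expressed in the same direction in
both hybrid contrasts (H vs F and H vs M). Everything else is, for the
purposes of the analysis, additive.

`nb_differential_test()` is a compact negative-binomial Wald test:
median-of-ratios size factors; per-feature method-of-moments
dispersion pooled across the two groups (floored at $10^{-8}$); Wald
statistic on the log2 fold change with the delta-method standard
error. Because a moment dispersion estimated from three replicates is
itself noisy, the statistic is referred to a $t$ distribution with
$n_1 + n_2 - 2$ degrees of freedom rather than a normal; in null
simulations at dispersion 0.05 and $n = 3$ per group this keeps the
empirical type-I fraction at $p < 0.05$ near 0.045–0.05, where the
normal reference more than doubles it. Significance combines
BH-adjusted FDR < 0.05 with $|\log_2 \mathrm{FC}| > 1$ (fold change
> 2) on the unshrunken estimate. No fold-change shrinkage, dispersion
trending or outlier replacement is attempted, and numerical parity
with full NB-GLM machinery is deliberately not claimed.

## Weighted methylation and the Met~d/a~ classifier

Methylation of a region in one cytosine context (CG, CHG, CHH) is
summarized as the weighted methylation level: replicate read counts
are first summed per cytosine within a genotype, cytosines with pooled
coverage below 5 reads are dropped, and
$\mathrm{WML} = \sum \text{meth} / \sum \text{total}$ over the
survivors. A region with no surviving cytosine has an *undefined* WML
(`NA`, never 0). CG dyads are not strand-collapsed: each cytosine is
its own observation, the simplest testable convention.

The hybrid methylation state of a region is classified by

$$\mathrm{Met}_{d/a} = \frac{\mathrm{WML}_H - \mathrm{WML}_{MPV}}
{\max(|\mathrm{WML}_F - \mathrm{WML}_{MPV}|,
      |\mathrm{WML}_M - \mathrm{WML}_{MPV}|)},$$

which equals $2(\mathrm{WML}_H - \mathrm{WML}_{MPV}) /
|\mathrm{WML}_F - \mathrm{WML}_M|$ whenever the parents differ (an
identity asserted to machine precision in the tests).
$\mathrm{Met}_{d/a} > 0.5$ is trans-chromosomal methylation (TCM, the
hybrid pulled toward/beyond the methylated parent), $< -0.5$
trans-chromosomal demethylation (TCdM), and the closed middle band
non-interactive methylation (NIM) — boundaries again go to the milder
class. Equal parents make the denominator vanish; the call is then NIM
if the hybrid sits exactly at the mid-parent, otherwise TCM/TCdM by
the sign of the deviation.

Differential methylation over predefined regions mirrors the
expression gate. Per region and context, the per-cytosine methylation
levels (pooled within each group, coverage ≥ 5 in both) are compared
by a two-sided Mann–Whitney U test; a region is significant with ≥ 4
eligible cytosines, BH-FDR < 0.05 and an absolute mean difference of
at least 0.1 (CG), 0.1 (CHG) or 0.05 (CHH). This kind of analysis is
often run through the metilene program in its predefined-region mode;
we implement the same statistic family directly rather than wrapping
the binary, and make one numerical choice explicitly: for small
regions (at most 20,000 group assignments) the permutation null of the
rank sum is enumerated exactly — `wilcox.test()` abandons exactness
under ties, and methylation level vectors are full of ties — while
larger regions use the tie-corrected normal approximation with
continuity correction. Exact parity with metilene (which also offers
de novo segmentation, out of scope here) is not claimed.

## Genomic context and integration

siRNA clusters are annotated to one of five categories with the
precedence gene body > 5′-2kb > 3′-2kb > TE > intergenic; flank
windows are 2 kb measured from the annotated gene start/end,
strand-aware, and any shared base counts as overlap (half-open
intervals, so abutting features do not touch). The precedence order is
a design choice — a total, deterministic rule is required for
reproducible category partitions — and ties within a tier go to the
nearest gene, then to the lexicographically smaller id. All interval
arithmetic is 0-based half-open internally; GFF3's 1-based closed
convention is converted exactly once, at the parser.

The integration layer joins cluster expression superclasses with
per-context methylation patterns into groups (the six focal ones being
HPE-*-TCM and LPE-*-TCdM), collects the associated genes (gene body
and both flanks, deduplicated per group), and tests associations with
two-sided Fisher exact tests. The reported odds ratio is the sample
odds ratio of the 2×2 table (with a 0.5 Haldane correction only when a
cell is zero, and only for the ratio — never the p-value). The
enrichment background is all expressed siRNA clusters for
cluster-level tests, and all pattern-called genes associated with any
cluster for gene-level tests; `term_enrichment()` provides a generic
one-sided hypergeometric over-representation test against a
user-supplied gene–term map (real GO/KEGG databases are out of
scope). Expression differences between methylation patterns use Welch
t-tests on $\log_2(\mathrm{RPM} + 1)$.

Phenotypic heterosis is computed per environment as
$\mathrm{MPH} = 100\,(F_1 - \mathrm{MPV})/\mathrm{MPV}$ and
$\mathrm{BPH} = 100\,(F_1 - \mathrm{BPV})/\mathrm{BPV}$ on genotype
replicate means, with the spread over all replicate pairings reported
alongside; for positive traits $\mathrm{BPH} \le \mathrm{MPH}$
always.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions the package is validated under:

* **Expression** (`simulate_trio_counts`): 2,000 features, 3
  replicates per genotype, negative-binomial counts with dispersion
  0.05 and base means log-uniform on [100, 10,000]. Class proportions
  default to the frequencies observed among differentially expressed
  siRNA clusters in maize hybrid data (AE 0.69, DHPE 0.15, DLPE 0.13,
  THPE 0.02, TLPE 0.01). Non-AE features receive a parental log2 fold
  change of 2 (high parent random) and a hybrid mean planted so the
  *expected* D/A equals the class midpoint (±1.25; ±3 for the open
  transgressive intervals) — truth lives on the same scale the
  classifier measures, which makes recovery a well-posed test. AE
  features have equal parents and a mid-parent hybrid: they carry no
  differential signal, and the candidate gate, not the ratio, is what
  recovers them. One feasibility constraint is worth spelling out:
  a hybrid mean with $D/A = -3$ equals $2\,\mathrm{LP} - \mathrm{HP}$,
  which is negative once the parental ratio exceeds 2 (and the whole
  TLPE interval is unreachable beyond ratio 3), so TLPE-planted
  features cap their parental log2 ratio at 0.7 regardless of the
  configured effect.
* **Methylome** (`simulate_methylome`): 1,000 regions, contexts
  cycling CG/CHG/CHH, 10–30 cytosines per region, 2 replicates per
  genotype, Poisson coverage (mean 50) and beta-binomial methylated
  reads (intra-class correlation 0.05) — replicate overdispersion is
  the realistic failure mode of the rank-based region test, which a
  plain binomial would hide. Parental WML targets are 0.3/0.7
  (assignment random per region); the hybrid target is the mid-parent
  for NIM and the high/low parent for TCM/TCdM (planted
  $\mathrm{Met}_{d/a} = \pm 1$, comfortably inside the open
  intervals).
* **Annotation** (`simulate_annotation`): a single toy chromosome with
  evenly spaced stranded genes (3 kb genes every 12 kb), TEs confined
  to the gaps beyond every 2-kb flank, and clusters placed
  deliberately inside their requested category, so the annotator's
  output can be compared against construction labels exactly.

All draws derive from one integer seed through R's Mersenne-Twister
stream; two runs with the same configuration are identical.

What the generator does *not* emulate: count outliers and
heavy-tailed dispersion across features, library-size imbalance,
chromosome-scale methylation gradients, linked effects between the
expression and methylation layers beyond shared coordinates, TE
families, and partially overlapping annotation categories. Passing
recovery tests therefore demonstrates the correctness and calibration
of the implemented statistics under the stated noise model, not
performance on any particular real dataset.

## Validation strategy and problem sizes

The test suite checks worked examples against hand arithmetic,
properties (parent-swap invariance, interval partitions, round-trip
I/O, conservation of bin tilings) against randomized inputs, and the
implementation against independent oracles: Fisher p-values against
full hypergeometric enumeration over fixed-margin families up to
n = 40, the Met~d/a~ max-form against its closed form on $10^5$ random
triples, interval overlap against a quadratic brute force on $10^3$
random intervals, and the exact rank test against factorial
enumeration. End-to-end recovery runs use 2,000 features / 1,000
regions — large enough for stable proportions, small enough that the
whole suite runs in well under a minute — and recover planted labels
at ≥ 95% (expression) and ≈ 99.9% (methylation), with the null type-I
fraction of the NB test inside [0.03, 0.07].

## Known limitations

* The DE and DM tests are calibrated re-implementations of their
  statistic families, not numerical clones of DESeq2 or metilene.
* The D/A classifier inherits the noise of ratio estimators: with
  three replicates and dispersion 0.05, calls near the 0.5 and 2
  boundaries are genuinely uncertain, and recovery hovers just above
  95% under the default conditions. Tighter dispersion or more
  replicates sharpens it quickly.
* Features whose parents are equal but whose hybrid deviates are only
  reachable through the common-direction hybrid route, and their
  ratio is reported as ±Inf rather than a number.
* The annotator emits exactly one category per cluster; clusters
  spanning several features are resolved by precedence, not split.
* Conversion-rate estimation, alignment, cluster discovery and
  size-class quantification from reads are out of scope; the package
  starts from count matrices, cytosine reports and interval tracks.
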