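---
title: "Methods: scoring genes targeted by recurrent copy-number deletions"
author: "cndscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring genes targeted by recurrent copy-number deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cndscan)
```

## The problem

Somatic copy-number deletions (CND) in tumors range from focal knockouts of
a single tumor suppressor to chromosome-arm losses dragging hundreds of
passenger genes along. Recurrence counting alone cannot tell the target
from its co-deleted neighbourhood, and amplitude-and-frequency peak callers
report regions, not gene-wise statistics that can be compared across
cohorts. `cndscan` models the one feature deletions add over point
mutations: **segmental breakpoints**. Short deletions concentrate in
gene-rich regions, and breakpoints interrupt cancer genes more often than
their genomic footprint predicts; a gene that is deleted *specifically*
tends to be covered by many short, independently bounded segments rather
than incidentally swept by long ones.

## Model

### Collective track

Per-sample deletion segments are first normalized (0-based half-open
coordinates; within a sample, overlapping or book-ended segments are
merged, so a caller artefact splitting one event cannot count a sample
twice). All samples' segments are then collapsed into a **collective
track**: each chromosome is partitioned at every distinct segment
boundary, and each atom with coverage at least 1 becomes a collective
segment with length $L_i$ and deleted-sample count $S_i$. Atoms are never
merged across breakpoints, even when adjacent atoms carry equal $S_i$:
each atom is a separate score term, and a boundary always marks a change
in the covering sample set. Construction is verified in the tests against
naive per-bp coverage counting, together with the conservation identity
$\sum_i S_i L_i = \text{total deleted bp over samples}$.

### Gene score

For gene $g$ with length $L_g$,

$$\mathrm{Score}_g \;=\; \sum_{i \,:\, \mathrm{overlap}(i, g)\ \ge\ 1\,\mathrm{bp}}
\frac{S_i}{L_i + L_g},$$

in units of 1/bp. Any overlap of at least 1 bp counts — partially
overlapping segments are genuine disruption events. Recurrence raises the
score linearly; segment and gene length enter the denominator, so a long
segment sweeping the gene incidentally contributes little, and long genes
do not accumulate score merely by being large targets. Units cancel in the
permutation test, so no rescaling is applied.

### Shuffling null and significance

The positions of the collective segments are shuffled **within their
chromosomes**: each segment is independently re-placed with start uniform
on $\{0, \dots, \mathrm{chrom\_len} - L_i\}$, carrying its $S_i$ and $L_i$
along. The collective partition is *not* re-derived after placement, and
overlaps among shuffled segments are allowed: re-collapsing would change
the null's segment-length distribution, and rejection sampling would bias
placement on crowded chromosomes. This preserves genomic context in the
null — two genes inside the same recurrent segment receive the same
background recurrence, while a gene that accumulates extra independent
segments stands out against the same background. Shuffling the full
assembly length (not the deleted-region envelope) is used; the sizes table
defines the bounds.

Gene scores are recomputed per shuffle with the identical scoring rule.
With $B$ permutations each gene gets the add-one empirical p-value

$$p = \frac{1 + \#\{ \mathrm{null} \ge \mathrm{observed} \}}{1 + B},$$

ties counting as exceedances. The estimator is strictly positive and
valid, at the cost of a floor of $1/(B+1)$. P-values are adjusted with the
Benjamini–Yekutieli step-up ($q_{(i)} = \min_{j \ge i} p_{(j)} \, m \,
c(m) / j$, $c(m) = \sum_{k\le m} 1/k$), which controls FDR under the
arbitrary dependence created by shared segments; the family is all scored
genes of one analysis. Genes on chromosomes without any collective segment
have a degenerate null and receive $p = 1$.

### Permutation resolution — read before choosing B

The add-one floor interacts with BY: if $k$ genes are tied at the floor,
their adjusted p is $\frac{m\,c(m)}{k\,(B+1)}$, so calls at level
$\alpha$ require

$$B + 1 \;\ge\; \frac{m \, c(m)}{\alpha \, k}.$$

With $m = 200$ genes and $k \approx 15$ floor genes, $B = 1000$ gives
adjusted p $\approx 0.08$ — the targets rank perfectly but cannot be
*called* at $\alpha = 0.05$; $B = 2500$ resolves them. `cndscan` warns
when `n_permutations` is very small, and the fitted object reports the
floor; for genome-scale annotations ($m \sim 2\times 10^4$) tens of
thousands of shuffles are needed for FDR calls, which is why the default
`n_permutations = 1000` should be raised for production analyses. The
ranking itself (scores, empirical p-values, the significance profile used
for cohort clustering) is informative at any $B$.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_permutations` | 1000 | shuffles | null resolution; floor $1/(B+1)$ |
| `alpha` | 0.05 | — | threshold on BY-adjusted p |
| `seed` | none | — | full determinism of shuffles |
| overlap threshold | 1 | bp | any intersection counts as disruption |
| deletion state filter | `DEL`, `HOMODEL`, `HLDEL`, `-1`, `-2` | — | no numeric default threshold: platform log-ratio cutoffs must be set explicitly |

Coordinates are 0-based half-open throughout (lengths are `end - start`);
readers convert 1-based inclusive input on ingest. Chromosome names are
taken verbatim; a sizes table supplied to a reader or to the fit enables
strict bounds checking.

## Diagnostics

Two analyses motivate the length penalty and are exposed as outputs, not
assertions. **Gene-hit frequency (GHF)**: for each collective segment, the
number of genes it overlaps per 100 kb of segment length; each of the
$S_i$ carrying samples contributes one event, implemented as record
multiplicity (not as $\mathrm{ghf}\times S_i$), so the characteristic
curves of discrete hit counts divided by length remain visible. The binned
quartile summary and the sample-weighted Spearman correlation between
length and GHF quantify the decay. **Breakpoint enrichment**: one-sided
Fisher tests of breakpoint localization inside a curated driver-gene
footprint, (a) at bp resolution (footprint bp vs rest-of-genome bp,
breakpoint vs not), and (b) length-corrected, dichotomizing genes at the
genome-median per-bp breakpoint rate and crossing with driver membership.
Construction (b) is this package's concrete choice for "length-corrected";
it is labeled in the output (`mode`) and swappable. One-sided Fisher
p-values are computed as hypergeometric upper tails (`phyper`), which is
the identical statistic and stays fast for bp-scale margins; tests verify
equality with `fisher.test` and with brute-force tail sums.

## Downstream

Significant genes are tested for over-representation in named gene sets
(driver catalogs, pathways) with the same one-sided Fisher machinery; the
universe is the set of *scored* genes, since the question is selection
among tested genes, not catalog coverage. Across analyses, per-pathway
$\log_{10} p$ values are min–max standardized per pathway to $[0,1]$ (0 at
the strongest enrichment; all-equal columns are set to 0 by convention,
where the min–max rule is undefined), and clustered with Euclidean
distance and average linkage; a small canonical-pathway panel is compared
on raw p-values without standardization, clustered on the pathway axis
only. Genome-wide profiles of per-gene *empirical* p-values (the adjusted
values are a monotone transform and add nothing; empirical is the default
and configurable) are embedded in 2-D with UMAP (`uwot`), aligned on
shared symbols, deterministic given a seed.

## Synthetic cohorts

The generator defines the study conditions used throughout the tests: 100
samples; one 10 Mb chromosome; 200 non-overlapping genes with log-uniform
lengths 5–200 kb; background deletions per sample Poisson(2) with lengths
uniform 50 kb–1 Mb and uniform starts; 5 planted target genes; penetrance
0.3; focal deletion lengths uniform on $[L_g, L_g + 100\,\mathrm{kb}]$,
positioned uniformly among placements overlapping the gene, so whole and
partial knockouts both occur and breakpoints fall inside the target — the
disruption signature the model scores.

Two generation details are this package's own choices. First, the
configured length law makes the *expected* total gene footprint
($\approx 10.6$ Mb) exceed the chromosome, so the length vector is redrawn
until it fits (bounded retries, then an error) and the remaining slack is
distributed as uniform gaps (uniform order statistics) — the natural
meaning of "uniformly placed, non-overlapping" under a tight packing; the
resulting annotation tiles most of the chromosome, which mimics gene-dense
regions. Second, the truth table records every segment pre-normalization
with its origin (background vs planted, and the targeted gene), so events
merged during normalization stay attributable.

What the simulation does *not* emulate: amplifications, subclonality and
purity, chromothripsis-like hyper-segmentation, probe-density bias of
WES-derived calls, multi-chromosome karyotypes, or realistic gene-length
and inter-gene spacing distributions. Passing recovery tests therefore
demonstrates correctness of the machinery under controlled targeting, not
performance on real tumor cohorts.

Because the focal events extend up to 100 kb beyond the target, the
immediate neighbours of a planted gene are genuinely co-deleted at nearly
the same recurrence; they reach the empirical-p floor together with the
target. A deletion-only statistic cannot separate such co-segregating
neighbours, so "false positives" in recovery runs are concentrated there
— the same co-segregation ambiguity real CND analyses face.

## Numerical choices and degenerate inputs

* Scores are plain double sums; the sweep scorer is tested against the
  brute-force definition at $10^{-12}$ relative tolerance.
* Ties in the null count as exceedances (conservative).
* Empty cohorts, zero-gene annotations, segments longer than their
  chromosome, p-values outside $(0,1]$, non-finite matrices and fewer than
  3 embedding profiles are errors, not warnings.
* Malformed segment rows (non-numeric coordinates, `end <= start`) are
  dropped with a warning naming their line numbers; counts reconcile as
  `rows_in = rows_kept + rows_filtered + rows_malformed`.
* `hclust` with average linkage is deterministic (lowest-index merge on
  ties); UMAP is run single-threaded with a seeded RNG for bit
  reproducibility.
* Duplicate annotation symbols are merged to their spanning interval in
  lax mode and are an error in strict mode.

## Problem sizes in the test suite

The suite exercises the oracle comparisons at 200 random mini-cohorts
(≤ 10 samples, ≤ 10 kb chromosomes), 50 scoring instances of 1000 genes ×
500 segments, BY vectors up to $m = 10^4$, calibration and recovery at the
full default study conditions (10 seeds × 1000 permutations each), 10,000
placement draws for the uniformity test, and 10-profile embeddings —
sizes chosen so the whole suite completes in a few minutes on one core
while still covering the defaults end to end.

## Known limitations

* The score is deletion-specific by design; amplification mechanics
  (whole-gene dosage rather than disruption) need a different statistic.
* Within one recurrent segment, co-segregating genes are inseparable;
  neighbourhood context (see above) is preserved but cannot create
  information that is not in the breakpoints.
* FDR resolution is bounded by the permutation count (closed form above);
  underpowered settings rank correctly but call nothing significant.
* The length-corrected breakpoint test is one concrete dichotomization;
  other corrections (e.g. covariate-adjusted Poisson rates) are plausible
  and the result object labels the mode to keep substitutions explicit.
* Sample counts, not deletion depth, drive the score: homozygous and
  hemizygous losses count equally.
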