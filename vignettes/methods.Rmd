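---
title: "Methods: profiling driver-negative thyroid carcinomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling driver-negative thyroid carcinomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyroprofiler)
```

# The problem

Differentiated thyroid carcinomas usually carry one of a short list of
driver alterations — BRAF V600E, RAS-family point mutations, or fusions such
as PAX8–PPARg — but a substantial minority is negative for all of them.
These driver-negative tumours are clinically real yet molecularly
uncharacterised. The workflow in this package asks a concrete question of
such a cohort: *do the driver-negative tumours fall into the same two
expression programmes that the known drivers produce, and if so, which
programme does each tumour follow?* The answer is produced by a chain of
steps — variant and fusion filtering, expression-matrix construction,
clusterability testing, consensus cluster-number inference, hierarchical
clustering, and a four-score panel — each of which is an exported, tested
function.

# The synthetic cohort generator

No patient data ship with the package. Instead, `cohort_config()` /
`generate_counts()` simulate cohorts with the statistical structure the
analysis assumes, plus ground truth, so that every downstream stage can be
tested against a known answer.

**Count model.** Counts are negative binomial,
$X_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi)$ with
$\mathrm{Var} = \mu + \phi\mu^2$ and dispersion $\phi = 0.2$ by default —
the standard bulk RNA-seq assumption, and the one matched by the
median-of-ratios normalisation used downstream. Gene base means are
log-normal (meanlog $\log 100$, sdlog 1.25); per-sample depths are uniform
over a 0.8–1.2 M library-size range.

**Archetypes.** Each sample belongs to a BRAF-like or RAS-like expression
archetype (default fractions 0.3/0.7 — the BRAF-like group is the smaller
one in the motivating setting). Three disjoint signature gene sets (71
BRS-like, 16 TDS-like, 52 ERK-like) are shifted between archetypes by
`archetype_effect` = 2 log2 units, applied *symmetrically*: half of each
signature up in one archetype, half in the other, so both signs of the
BRAF–RAS score are exercised. Signature genes have their base means floored
at 100 — they model well-expressed marker genes and must survive the
prevalence filter in either archetype. A consequence of the symmetric
design is that the *mean* TDS/ERK score difference between archetypes is
close to zero on default cohorts (up- and down-shifted genes cancel); tests
of the TDS/ERK direction therefore use cohorts with a one-sided planted
shift.

**Driver statuses.** 14/30 samples are driver-negative by default.
Positives are typed by archetype — BRAF V600E point mutations in BRAF-like
samples; RAS point mutations or PAX8–PPARg fusions (at the 11:3 ratio of
the motivating cohort) in RAS-like samples. Negatives are allocated
proportionally within archetypes, capped so every archetype keeps at least
one driver-positive member; without such an anchor the cluster-typing step
has, correctly, nothing to type a cluster by.

**Variants.** Each sample receives 300 background (passenger) calls. This
magnitude is calibrated so that the retained non-synonymous burden lands
near 3.8 mutations/Mb at the 50 Mb capture size — the overall mean burden
scale of the motivating cohort; per-group burden differences are *not*
modelled, since no per-sample counts are available to calibrate them.
Records fall into the filterable strata independently (10% low mapping
quality, 10% common in a population database, 10% shared with normal
tissue), with COSMIC-gene records guaranteed inside filtered strata so the
rescue path is always exercised. Planted drivers have passing quality and
rare frequency.

**Fusions.** Genuine fusions per sample are Poisson with archetype means
1.0 (BRAF-like) and 2.8 (RAS-like) — the fusion-burden asymmetry the
analysis is expected to recover — and carry passing support by
construction. Separately, about one artifact fusion per sample is emitted
with shifted-geometric support statistics that straddle the filter
thresholds, half of them drawn from a fixed normal-tissue blacklist pool.
The rate parameter therefore has a sharp meaning: it is the mean count of
*filter-surviving* fusions, which is what the burden summary measures.

**Reference matrix.** `generate_reference_matrix()` emulates an external
mutation-typed reference cohort (26 BRAF + 61 RAS samples) drawn from the
*same* gene universe (same base means, signatures and shift directions) as
the study cohort, so centroids fitted on it are commensurable with the
cohort's FPM profiles.

All randomness flows from one explicit seed through labelled sub-streams
(`substream_seed()`), so each table is reproducible independently of the
others.

What the generator does *not* emulate: batch effects, gene–gene
correlation beyond the archetype structure, gene-length effects,
histology-specific subgroups (e.g. Hürthle-cell tumours), and per-group
mutation-burden differences. Tests passing on synthetic cohorts show the
pipeline recovers planted structure under its own model assumptions; they
do not certify behaviour on real data that violates them.

# Filter chains

Both filter chains share a principle: **filters only add removal reasons,
never drop rows**. Final statuses are resolved once, at the end. This makes
the three variant-flagging stages commutative (order affects nothing but
provenance text), gives conservation (`pass + rescued + removed = input`)
for free, and leaves a complete audit trail.

Variant thresholds are read literally: mapping quality *strictly below* 20
removes; population allele frequency *strictly above* 0.001 in either
database removes (OR semantics). A frequency missing from both databases
means the variant is absent from them — absence is evidence of rarity, so
such records are kept. Normal-tissue subtraction keys on the full
`(chrom, pos, ref, alt)` tuple, 1-based and VCF-style; allele
normalisation is the upstream caller's responsibility. The COSMIC rescue
applies to *all* removal reasons, including low mapping quality; because a
rescued low-quality call is analytically risky, such records carry a
`low_quality_rescued` warning flag in the audit table.

Fusion support thresholds are also strict (> 0.1 FFPM, > 10 reads). The
support clause "junction and spanning counts > 10" is ambiguous between
both-exceed and sum-exceeds readings; the default `support_mode = "each"`
requires both (the stricter, more natural reading), with `"sum"` available.
The normal-tissue blacklist matches *ordered* gene pairs: a 5′/3′ swap is a
different fusion transcript.

# Expression matrix

The gene pipeline is set algebra:
`final = (prevalence-pass ∖ pseudogenes) ∪ COSMIC-genes`. Prevalence
(count > 10 in ≥ 90% of samples, computed on raw counts before
normalisation) uses `ceiling` on the sample quota, so 27/30 qualifies as
90%. Pseudogenes are detected by case-insensitive biotype substring match —
"any pseudogene-associated class" spans many biotype labels. The COSMIC
rescue deliberately overrides both exclusions (union semantics): the point
of the reimport is that every cancer-related expressed gene is represented.

Size factors are median-of-ratios against a geometric-mean pseudo-sample,
using only genes positive in all samples; the implementation is
cross-checked in the tests against the independent reference
implementation in the count-model package. FPM is defined with the robust
library size, $\mathrm{FPM}_{gj} = 10^6 \, x_{gj} / (s_j \bar L)$ with
$\bar L$ the mean of $\mathrm{libsize}_j / s_j$; with all factors 1 this
reduces to counts-per-million with column sums of $10^6$. A useful exact
invariant (tested): doubling every count of one sample changes neither its
own nor any other sample's FPM values — the size factor and $\bar L$ absorb
the depth shift completely. The final transform is $\log_2(x + 1)$.

# Cluster inference

**Clusterability.** The Hopkins statistic contrasts nearest-neighbour
distances of $m$ uniform pseudo-points (drawn in the bounding box of the
data) against those of $m$ real probe points:
$H = \sum u / (\sum u + \sum w)$, $m$ = 10% of samples. $H \approx 0.5$
for spatial randomness, $H \to 1$ for clustered data; the decision rule is
clusterable iff mean $1 - H < 0.5$ over 512 bootstrap replicates (fresh
probes and pseudo-points each). Distances are computed in a reduced space
of at most 10 principal components: in thousands of gene dimensions
nearest-neighbour distances concentrate and the statistic degenerates. One
numerical subtlety: when the input already has at most 10 feature
dimensions, the data are centred but *not* rotated onto PCs — rotating a
low-dimensional cloud inflates its axis-aligned bounding box (pseudo-points
land outside the support) and biases $H$ upward, destroying the
$H \approx 0.5$ null behaviour. Reduction engages only when it actually
reduces dimension.

**Consensus k.** Each of the (default 1080) replicates draws 10% of genes
without replacement, builds WPGMA partitions for every k in 2…8, and lets
each index of a panel vote for its best k; the modal k over all
(replicate × index) votes wins, ties toward smaller k (parsimony). The
panel holds ten implementable internal validity indices —
Calinski–Harabasz, average silhouette, Davies–Bouldin, Dunn, C-index,
McClain–Rao, point-biserial, Krzanowski–Lai, Hartigan, and the gap
statistic (8 uniform reference sets, one-standard-error rule). The
majority-vote consensus is the essence of the procedure; the exact panel is
configurable. Index evaluations that cannot decide (e.g. Hartigan when no k
satisfies its $H(k) \le 10$ rule, or degenerate pair sums) are recorded as
invalid rather than forced, and the vote count plus invalid count always
equals replicates × indices.

**Clustering and outliers.** The final clustering is WPGMA (McQuitty)
linkage — after merging $a$ and $b$, $d(ab, x) = (d(a,x) + d(b,x))/2$ — on
Euclidean distances over log2(FPM + 1); the implementation is verified
against a naive $O(n^3)$ agglomerator on 1000 random instances. PCA
coordinates fix each component's sign so its largest-magnitude gene loading
is positive, making plots reproducible across platforms. A sample is an
outlier when its mean distance to the others exceeds the cohort mean by
more than 3 SD of that quantity; outliers are excluded from clustering and
group summaries but still scored, mirroring how a discrepant sample is
handled in practice.

**BL/RL assignment.** Each cluster is typed by the majority driver among
its driver-positive members (BRAF V600E vs RAS/PAX8–PPARg, the fusion
counting toward the RAS type); driver-negative members inherit the type as
negative-BL or negative-RL. A tie, or a cluster holding negatives but no
positives, raises an error naming the affected samples — assigning them
silently would manufacture a finding. Negatives with a flagged histology
(e.g. Hürthle-cell) are reported separately as negative-other.

# Score panel

**BRS.** Centroids are fitted per mutation-typed reference group on the
FPM expression of the 71-gene signature; with groups fixed by mutation
status, k-means within a group is degenerate at k = 1, so each centroid is
the group mean. The score is the distance difference
$d(x, c_\mathrm{BRAF}) - d(x, c_\mathrm{RAS})$, scaled by the cohort's
maximum absolute value — the simplest map onto $[-1, 1]$ that preserves
sign and guarantees at least one sample at $\pm 1$ (a cohort whose raw
differences are all zero scores 0 everywhere). Negative = BRAF-like. BRS is
computed on the FPM scale, not log scale, matching the reference-centroid
construction.

**TDS / ERK.** Per gene, $\log_2(\mathrm{FPM} + 1)$, centred by the gene's
cohort median; the score is the per-sample mean over the signature. The
phrase "centered by their median and log2 transformed" is order-ambiguous,
and centring *before* the log can produce negative arguments — hence
log-then-centre. Median-centring makes the scores exactly invariant to
adding a constant to any gene across all samples.

**TMB.** Retained (pass or rescued) non-synonymous calls — every class
except silent, InDels included — divided by a 50 Mb capture size.

# Problem sizes and budgets

Defaults reflect the study conditions (30 samples, 2000 genes, 512 Hopkins
replicates, 1080 consensus replicates). The test suite exercises the same
code at smaller sizes chosen for a tight feedback loop: a 600-gene cohort
for most module tests, 100 consensus replicates for the headline
cluster-number check, 30 replicates per seed for the 20-seed recovery
sweeps, and 10-point instances for the WPGMA oracle comparison. The
acceptance script uses 100 consensus replicates and the full 512 Hopkins
replicates.

# Known limitations

- The 71/16/52 signature gene identities are cohort configuration, not
  shipped constants; synthetic signatures stand in for them everywhere.
- The BRS scaling is cohort-relative: a score is only comparable within the
  cohort it was scaled in.
- The Hopkins statistic in PCA space inherits the bounding-box geometry of
  the reduced data; its absolute value is less interpretable than its
  position relative to the 0.5 decision bound.
- The outlier rule (mean + 3 SD) flags ~2–4% of perfectly homogeneous
  30-sample cohorts — the right-skew of mean-distance statistics at small n
  — so a single flagged sample is a prompt for inspection, not proof of
  artefact.
- `summarize_groups()` reports means as-is; it performs no inference, and
  group differences on synthetic cohorts reflect only what the generator
  plants (fusion-rate asymmetry yes, burden asymmetry no).
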