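---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprdeck)
```

exprdeck is a headless analytics library for log-scale expression matrices
(probes in rows, experiments in columns), built around a small number of
well-defined statistical and algorithmic components. This vignette explains
each component's model and assumptions, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic-data generator
does and does not emulate.

## The data model

An `ExpressionDataSet` is a real matrix with unique probe and experiment
names, optional per-experiment sampling times (hours), and a version counter
that strictly increases on every mutation. The version counter is the
backbone of *dynamic probe lists*: a dynamic list caches its members
together with the dataset version they were computed from, and
`refresh_dynamic()` re-evaluates the filter rule only when the version has
moved. This gives the observable behaviour of reactive filtering (membership
always reflects the current data) without callback machinery — laziness is
keyed purely on version stamps, which also makes it easy to test.

Meta-information groups attach one typed value (numeric, string, category)
per probe, with partial coverage allowed. Statistics computed by the package
(p-values, PFP, WAD scores, cluster labels) can be converted to
meta-information with `result_to_meta()` and then drive filter rules, so
"p < 0.05 AND plus strand" is an ordinary rule tree.

Missing values are ignored row-wise in the transforms and variance
computations; a row with fewer than two finite values has undefined variance
and is treated as zero-variance with a warning, so filter pipelines on
sparse data do not abort.

## Transforms and the regularized variance

Row z-scoring uses the sample (n−1) standard deviation. Constant rows are
mapped to all-zero rows rather than raising an error: after variance
filtering, constant rows are rare but possible (e.g. after subsetting
experiments), and a hard error in the middle of a pipeline would be worse
than the natural convention of "no deviation from the mean". Z-scoring is
idempotent on non-constant rows to 1e−9.

Smoothing is a centered moving average whose window shrinks symmetrically at
the row edges. No padding values are invented; position `i` averages over
`i−h … i+h` with `h` reduced so both ends stay inside the row. A window of 1
is the identity.

The *regularized variance* of probe *i* is

&nbsp;&nbsp;&nbsp;&nbsp;v′ᵢ = vᵢ / (vᵢ + v₀),

where vᵢ is the sample variance of the probe's row and v₀ is the median of
all per-probe variances. The score is bounded in [0, 1), equals 0.5 exactly
at the median variance, is strictly monotone in vᵢ (hence rank-preserving),
and is robust because the regularizer is a median. The package uses it with
`threshold_filter()` to define "most variant probes" lists; a threshold of
0.3 keeps everything above roughly half the median variance. Other bounded
variance scores would serve equally well — the properties that matter are
boundedness, monotonicity and robustness of the regularizer.

## Filter rules

Rules form trees of AND / OR / NOT over five leaf kinds: row statistics
compared to a constant, meta-information comparisons, probe-name prefix or
regex matches, membership in other (possibly dynamic) probe lists, and
query-by-example similarity (distance to a named probe under any of the
distance measures, within a cutoff). Conventions:

* an empty AND group accepts all probes, an empty OR group none — the
  identity elements of conjunction and disjunction;
* probes *missing* a meta value fail the leaf rather than erroring, so
  partially annotated datasets remain filterable;
* NOT is supported even though two-operator rule sets (AND, OR) suffice for
  most uses — completeness costs nothing and De Morgan's laws are part of
  the property-test suite;
* membership leaves referencing a dynamic list evaluate against that list's
  *refreshed* state; dependency cycles among dynamic lists are rejected at
  registration time;
* evaluation is pure: it never touches the dataset version, and always
  returns probes in dataset order.

Expression leaves see the dataset exactly as passed in: whether you filter
raw or z-scored values is decided by which dataset object you hand to the
evaluator, not by hidden state.

## Distances and clustering

Distance measures: euclidean, manhattan, Minkowski (p > 0), and the Pearson
correlation distance 1 − r (range [0, 2], undefined for constant profiles —
an error, not a silent NA). Experiment-space clustering is performed by
explicitly transposing the dataset (`transpose_dataset()`); there is no
separate code path to diverge.

**QT clustering.** The quality parameter is the cluster *diameter* — the
maximum pairwise distance tolerated inside a cluster. (The term "radius" is
sometimes used for this parameter in the literature; we name it by what the
implementation actually bounds.) For every unassigned item a candidate is
grown greedily by adding the item causing the smallest diameter increase
while the bound holds; the largest candidate is accepted, removed, and the
process repeats until the largest candidate would fall below `min_size`.
All candidate seeds are tried in every round (the original
quality-threshold formulation), and every tie is broken by smallest item
index, so results are deterministic and oracle-comparable. The returned
clusters provably satisfy the diameter bound; leftover items are reported
as unassigned rather than forced into clusters.

**k-means** uses k-means++ initialisation from an explicit seed followed by
Lloyd iterations to an assignment fixpoint (ties to the smallest-index
center, empty clusters refilled with the worst-fitting point). The seed is a
required, explicit parameter — also in pipelines — so runs are reproducible
by construction.

**UPGMA/WPGMA** merge the closest pair at ultrametric height d/2, ties by
smallest index pair. UPGMA weights the distance update by cluster size
(giving the unweighted average over item pairs); WPGMA weights both clusters
equally. On exactly ultrametric input, UPGMA reproduces all cophenetic
distances; on random matrices the merge heights coincide with
`hclust(..., "average")`/`"mcquitty"`, which serves as the independent
cross-check in the tests.

**Neighbor joining** minimises Q(i,j) = (n−2)d(i,j) − rᵢ − rⱼ with the
standard branch-length formulas; negative branch lengths are clamped to
zero with a warning (a common convention; the alternative of propagating
negatives breaks downstream tree consumers). The *rapid* variant keeps one
ascending-distance candidate list per row and prunes the Q search with the
bound (n−2)d(i,j) − rᵢ − r_max: scanning a row in ascending distance, once
that bound exceeds the best Q seen, the rest of the row cannot contain the
minimum. Because merges reuse the smaller slot with *changed* distances,
each slot carries a creation stamp and list entries referring to nodes
recreated after the list was built are skipped; every pair is then
reachable through the row of its younger member, whose list is fresh. With
identical tie-breaking (lexicographically smallest index pair), the rapid
search provably returns the same tree as the naive scan — the central
oracle test runs both on 200 random 12-taxon matrices and requires 100%
topological agreement.

**Validation.** Silhouette widths use s(i) = (b−a)/max(a,b) with the
convention s = 0 for members of singleton clusters (their a is undefined;
zero is the neutral choice). Partition agreement is the adjusted Rand
index from the pair-counting contingency table; identical-up-to-relabeling
partitions give 1 and random labelings are at chance level 0.

## Differential expression

The two-sample t-test (pooled by default, Welch optional) is delegated to
R's `t.test` per probe; the table adds BH/Holm/Bonferroni adjustment via
`p.adjust` and significance ranks.

**WAD** (weighted average difference) scores probe *i* as
(mean_B − mean_A) · wᵢ, with wᵢ the probe's average expression over all
design experiments rescaled to [0, 1] across probes. On log-scale data this
promotes genes that are both strongly changed and highly expressed, and
demotes low-expression genes whose fold changes are noise-dominated. WAD is
a ranking statistic with no distributional p-value; the table reports
statistic, weight and rank only.

**Rank product** uses the unpaired scheme: every A×B pair of experiments
contributes one log fold change, the fold changes are ranked across probes
within each comparison (descending for `direction = "up"`), and RP is the
geometric mean of a probe's ranks. Significance is the permutation-based
*percentage of false positives*: probe values are permuted within each
comparison, null rank products are recomputed, and
PFP(i) = E[#null RP ≤ RPᵢ] / rank(i). With `n_perm = 200` on pure-noise
data, the fraction of probes with PFP < 0.05 stays below 0.08 (checked in
the acceptance suite); `n_perm ≥ 100` is recommended for stable estimates.

## Profile logos

A profile logo discretises the expression of a probe list into B bins
defined by B−1 strictly ascending thresholds and shows, per experiment, the
frequency of member probes per bin. Bins are left-open/right-closed:
(−∞, t₁], (t₁, t₂], …, (t_{B−1}, ∞); a value exactly on a threshold counts
into the lower bin. Frequencies rather than counts are stored so logos of
different-sized probe lists are directly comparable; every column sums to 1.
Heights are plain frequencies, not information content — the point is to
show the general direction of regulation per experiment, not sequence-logo
bit scores. The SVG renderer is a deliberately small static export (stacked
rectangles, low-to-high colour ramp).

## Time-series alignment

For two datasets sharing probes on a common time grid, `estimate_shift()`
scores every integer lag ℓ ∈ [−max_lag, +max_lag] and returns the
score-maximising lag; positive shift means the query runs later than the
reference. Lags are integer grid steps only — the motivating use case is a
one-hour delay on an hourly grid, and sub-step interpolation would suggest
precision the data does not have.

The score is the *pooled* Pearson correlation: each shared probe's profile
is centered on its own mean over the overlapping timepoints, and one
correlation is computed over all (probe, timepoint) pairs. This weights
probes by their expression amplitude. The obvious alternative — averaging
per-probe correlations with equal weights — is markedly less robust in
realistic data where many probes are flat: a flat probe's correlation with
anything is pure noise, and with equal weights those noise terms can
outvote the small score margin between adjacent lags of a smooth switch
profile. (In simulations at noise = 0.3 × signal sd, equal-weight averaging
recovers a 2-step shift in barely half the runs; pooled correlation
recovers it in ≈99/100.) Per-probe best lags, reported alongside, do use
each probe's own correlation curve. Correlation-based scoring keeps the
procedure invariant to offsets and positive scaling of either dataset, so
replicate runs with amplitude differences still align. Ties between lags
resolve toward smaller |ℓ|, then the negative one.

Per-probe comparison tracks default to the log fold change
(reference − query on log-scale data); plain difference and ratio are
available as alternative statistics.

## Pipelines and persistence

Pipelines are ordered steps over a registry of operations with declared
parameter schemas. Validation (unknown operations, unknown parameters,
unbound slots) happens before any execution; slot references can only point
to outputs of earlier steps, making the dataflow acyclic by construction.
The provenance log records operation, parameters, input/output slots,
output element counts and wall time per step. Stochastic steps take their
seeds as explicit pipeline parameters. Pipelines serialise to JSON with a
format-version field; loading rejects a higher major version explicitly.

Snapshots store a complete analysis state — dataset, static and dynamic
probe lists (the latter as rule trees), meta-information, cluster trees —
as a gzip-compressed tar of plain-text entries (TSV, JSON, Newick) plus a
JSON manifest. Text entries keep the container inspectable with standard
tools; numbers are serialised as round-trip-exact decimals (`%.17g`), so a
load reproduces the matrix bit-for-bit. Dynamic probe lists re-evaluate to
the same members after loading. Individual writers are deterministic
(sorted entries, fixed number format); the tar wrapper itself embeds file
timestamps, so whole-container byte identity is not promised — structural
fidelity is.

## The synthetic-data generator

`generate_synthetic()` emulates the shape of a dense prokaryotic
fermentation time course: 32 hourly timepoints starting at 20 h; three
clusters of co-regulated genes switching sigmoidally (up at 35 h, down at
39 h, up at 43 h — successive transitions around a nutrient-depletion
event); switch amplitude 4 log₂ units, which is a strong but common change
for metabolic-switch genes; Gaussian measurement noise with sd 0.1 on the
log scale for a well-normalised array experiment; and 25% flat background
probes at random baseline levels. Signal probes get SCO-style gene names
and alternating strand annotations with sequential 1-based loci, background
probes get intergenic-region names — enough structure for name-prefix and
strand-based filter rules to be meaningful. Everything is deterministic
given the mandatory seed.

`generate_replicate_pair()` produces two replicates of the same program in
which the second runs `shift_steps` grid steps later; the underlying
noiseless sigmoids are evaluated on the shifted time grid, so the true
shift is exact by construction, with independent noise per replicate.

What the generator does *not* emulate: probe-level microarray physics
(hybridisation, saturation, normalisation artefacts), correlated noise
across probes or timepoints, missing values, outlier samples, and the
scale of real arrays (tens of thousands of probes). Passing tests on this
data therefore demonstrates algorithmic correctness and calibration under
clean, known-truth conditions — not robustness to every failure mode of
real experiments. Problem sizes used by the test and acceptance suites
(120–2000 probes, 6–32 timepoints, 200 random 12-taxon matrices, 100–200
permutations/seeds) were chosen as the smallest sizes at which the checked
properties are statistically meaningful.

## Known limitations

* QT clustering is O(n³)-ish in the worst case (all seeds, each grown over
  all items); it is intended for filtered probe lists (tens to hundreds of
  items), not whole arrays.
* The rapid NJ implementation targets exact agreement with the naive
  search, including tie-breaking; it prunes well on random metrics but
  makes no worst-case complexity guarantee.
* Time-grid alignment assumes a shared uniform grid; non-uniform sampling
  and sub-step (interpolated) shifts are out of scope, as is dynamic time
  warping.
* The t-test and rank product assume complete data in the tested columns;
  rows with missing values must be filtered first.
* Choosing a QT diameter under the Pearson distance interacts with profile
  similarity: monotone profiles switching at nearby times can correlate
  strongly (two up-switches 8 h apart correlate at r ≈ 0.64 on this grid),
  so a diameter of 0.4 merges them while 0.2 separates them. The
  query-radius that suits a dataset depends on its dynamics; the silhouette
  output is the built-in guide for that choice.
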