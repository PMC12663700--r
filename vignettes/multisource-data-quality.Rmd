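---
title: "Multisource variability metrics for multicenter questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisource variability metrics for multicenter questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msvdq)
```

## The problem

Multicenter cohort studies collect the same questionnaire at several sites.
Before pooling the sites, one wants to know *how comparable* they are — both
in what participants answered (response distributions) and in what they did
not answer (missingness patterns). `msvdq` quantifies both with a single
geometric construction: each site is turned into a probability distribution
over a common grid, pairwise Jensen–Shannon distances between those
distributions are embedded as a simplex, and two bounded metrics are read
off the geometry:

* **SPO** (source probabilistic outlyingness), per site: the distance from
  that site's vertex to the case-weighted centroid of the simplex, the
  "informed average distribution" of all sites.
* **GPD** (global probabilistic deviation): the case-weighted mean of those
  vertex–centroid distances — the average variability across sites.

Both lie in $[0, 1]$: 0 when all sites have identical distributions, 1 when
their distributions are pairwise non-overlapping.

## The metric core

For two probability vectors $p, q$ on the same bins, the package uses the
Jensen–Shannon distance

$$\mathrm{JSD}(p,q) = \tfrac12 \mathrm{KL}(p\,\|\,m) +
  \tfrac12 \mathrm{KL}(q\,\|\,m), \qquad m = \tfrac{p+q}{2},$$

with base-2 logarithms and $0\log 0 = 0$, and reports $\sqrt{\mathrm{JSD}}$,
which is a true metric bounded by 1 (1 exactly for disjoint supports). The
$s \times s$ matrix of these distances is Euclidean-embeddable, so classical
(Torgerson) scaling — $B = -\tfrac12 J D^{\circ 2} J$, eigen-decomposition,
coordinates $V\Lambda^{1/2}$ — reproduces it exactly as a simplex with one
vertex per site. Numerically negative eigenvalues above $-10^{-10}\lambda_{\max}$
are clipped to zero; anything worse aborts, since it signals corrupted input
rather than round-off.

With $d_i$ the distance from vertex $i$ to the centroid
$\bar{x} = \sum_i w_i x_i / \sum_i w_i$ (weights $w_i$ = retained case
counts), the metrics are normalized by

$$c_s = \sqrt{\frac{s-1}{2s}},$$

the vertex–centroid distance of the *unit-edge regular simplex*, i.e. the
maximal-separation configuration where all pairwise distances are 1:

$$\mathrm{SPO}_i = \min\!\left(1, \frac{d_i}{c_s}\right), \qquad
  \mathrm{GPD} = \min\!\left(1, \frac{\sum_i w_i d_i}{c_s \sum_i w_i}\right).$$

This is the unique scaling for which "all sources identical" gives exactly 0
and "all sources pairwise disjoint, equal weights" gives exactly 1 for any
number of sources; the clip guards the unequal-weight corner, where a
low-weight source can sit slightly beyond $c_s$. The bounds and their
endpoint semantics are the contract; the normalization constant is this
package's documented choice for realizing it.

The MSV plot projects the vertices on the highest-eigenvalue axes of the
embedding, drawing each site as a circle whose radius is proportional to its
case count.

## The two analysis branches

**Values branch** (`run_values_analysis()`): text and multiple-choice
questions are excluded (few selections per option, little usable
variability); categorical and ordinal answers are encoded as 0-based codes
in their declared category order and continuous answers parsed as numbers;
missing cells are filled by chained-equations imputation (below); the
completed matrix is reduced by PCA to 3 dimensions; each site is separately
cleaned with the local outlier factor; 3-D histograms with 10 bins per
dimension on shared pooled-range edges give the per-site probability
vectors; then the metric core runs.

**Completeness branch** (`run_completeness_analysis()`): every cell is
classified as ordinary missing (0), dependent/not-applicable missing (1), or
observed (2). Code 1 captures skip logic: a blank "cigarettes per day" is
not a data-collection fault when the participant answered "no" to "do you
smoke?". The codebook carries these branch rules (parent question +
activating values). The 0/1/2 matrix is treated as categorical data and
reduced by multiple correspondence analysis (indicator-matrix
correspondence analysis); outlier filtering, histogramming and the metric
core then proceed exactly as in the values branch. A scope with no
missingness at all is reported as GPD = 0, all SPO = 0, with a
`no-missingness` flag rather than running a degenerate MCA.

Both branches run hierarchically (`run_hierarchical()`): once on the whole
questionnaire and once per section, top-down.

### Chained imputation

Missing cells are initialized at their column's observed mean; incomplete
columns are then swept in ascending order of missing count, each regressed
on all other columns (current imputations filled in) with a ridge-penalized
linear fit on the rows where the target is observed, and the predictions
overwrite that column's missing cells. Sweeps stop when the largest change
of any imputed cell drops below `tol` (default $10^{-3}$) times the
column's SD, or after `max_iter` (default 10) sweeps. The penalty
`ridge_lambda` (default $10^{-3}$) exists to keep collinear questionnaire
items from producing singular fits; the contract is "linear fit with
shrinkage", and recovery accuracy — not estimator identity — is what the
test suite pins down. Imputation pools all sites' rows, is performed once
on the full analyzable matrix, and sections are sliced from the completed
matrix afterwards; this keeps per-section analyses mutually consistent at
the price of letting other sections inform a section's imputed values.
Categorical columns are imputed on their numeric encoding and finally
rounded to the nearest valid code. Observed cells are never altered.

### Missing-category cascade

The skip-logic rule set decides code 1 directly only when the parent answer
is observed. When the parent is itself blank, the child's applicability is
unknowable; the default codes such blanks as ordinary (0) — never
understating potential data-collection faults — except that a parent whose
*own* code is 1 (a definitely-not-applicable chain) cascades code 1 to its
blank children. `cascade = "ordinary"` disables even that inheritance.
Chains deeper than 10 abort as suspected cycles (the codebook validator
independently rejects cyclic rules).

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `reduce_k` | 3 | embedding axes retained by PCA/MCA; 3-D histograms keep $10^3$ bins tractable |
| `reduce_top_vars` | 20 | contributor list length; contribution = explained-weighted squared loading (categories aggregated to their variable for MCA) |
| `reduce_standardize` | TRUE | correlation PCA; questionnaire encodings have heterogeneous scales |
| `lof_k` | 20 | LOF neighbourhood; customary default for cohorts of 100–200 per site |
| `lof_threshold` | 1.5 | LOF removal cutoff; ~1 means "as dense as neighbours" |
| `lof_max_removed_frac` | 0.10 | per-site trimming cap protecting the density estimate of small sites |
| `hist_bins_per_dim` | 10 | histogram resolution; capped so direct low-dimensional binning stays ≤ 1000 bins |
| `impute_*` | 10 / 1e-3 / 1e-3 | sweeps, tolerance, ridge penalty (see above) |

Determinism: every stage is deterministic — PCA/MCA axes get a fixed sign
convention (largest-magnitude loading positive), ties in contributor
ranking keep codebook order, and repeated runs of the pipeline are
byte-identical.

## The synthetic generator

`reference_cohort()` emulates a four-site European multicenter cohort at
baseline: sites of 142, 158, 197 and 155 participants (652 in total), 130
analyzable questions in 9 sections ($652 \times 130 = 84{,}760$ cells), 26
skip-logic question pairs whose gate activates with probability 0.63
(putting roughly 7.4% of cells in the structurally not-applicable state),
and ordinary missingness (rate 0.147 in the five affected sections, zero in
the other four) calibrated to roughly 9.6% of cells overall. One site
("site C") carries concentrated missingness (rate 0.35) in two sections and
a moderate response shift ($\delta = 0.5$ SD, Dirichlet concentration 20)
— a realistic single-divergent-site pattern. Continuous items are standard
normals (site shifts in SD units), ordinal items threshold a latent normal
at equal-probability cut points so shifts act on them too, and categorical
site probabilities are drawn once per site from a Dirichlet centred on a
mildly skewed base. Each (site, variable, channel) triple owns a seeded
stream, so adding a variable never perturbs the others' draws. MNAR
missingness is available by linking the missingness log-odds to the
standardized cell value.

What the generator does **not** emulate: real item wording, clinical score
distributions (quality-of-life utilities, symptom inventories), instrument
redundancy and cross-item correlation beyond what shifts induce, or
longitudinal waves. Passing tests therefore demonstrate that the pipeline
detects the *kinds* of structure it claims to detect (shifts, concentrated
missingness, skip-logic blanks) — not that any particular real cohort has
them.

## The sampling-noise floor

GPD compares *empirical* histograms. With ~150 cases per site spread over a
$10^3$-bin grid, two samples from the *same* law already produce largely
disjoint sparse histograms: the package's Monte-Carlo null experiment (four
sites drawn from one law, no missingness) puts the GPD floor near 0.8 at
these sample sizes. Exact duplication of rows across sites still yields
GPD = 0, and GPD grows monotonically with an injected mean gap, but small
GPD differences between scopes should be read against this floor, not
against 0. This is inherent to fixed-grid histogram fingerprints at survey
sample sizes and is why per-site case counts enter the plot radii and the
centroid weights.

## Numerical choices and degenerate inputs

* Histogram edges are shared across sources (pooled min–max per dimension,
  upper edge inclusive, row-major flattening); unaligned bins would make
  the Jensen–Shannon comparison meaningless. Zero-range dimensions collapse
  to one bin with a warning; out-of-range points (impossible in the
  pipeline, possible in direct calls) are clamped with a warning.
* LOF floors density denominators at $10^{-12}$ so coincident points score
  exactly 1; `k_neighbors` ≥ site size falls back to size − 1.
* PCA drops zero-variance columns (scaling undefined) and MCA drops
  constant columns, both with logged warnings; dropped variables keep a
  zero contribution slot in the ranking.
* For balanced independent categorical columns, indicator-matrix MCA shows
  a flat spectrum (equal singular values) rather than the all-zero spectrum
  of plain contingency-table CA — absence of association appears as absence
  of a *dominant* axis.
* Sections with ≤ 3 analyzable variables skip the reduction and are binned
  directly on their encoded variables, with bins per dimension capped so
  the grid stays at ≤ 1000 cells.
* All validation failures raise classed errors (`msvdq_*_error`) naming the
  offending variable, row or column.

## Problem sizes in the test suite

The suite exercises the full 652 × 130 reference scenario end-to-end; the
stochastic recovery experiments (a site shifted by 2 SD in one section, and
the concentrated-missingness site) each run 20 seeded replicas and require
the affected site to attain the top SPO in ≥ 90% of them; oracle
equivalence checks (brute-force LOF, direct-summation Jensen–Shannon,
direct eigen-decomposition CA, closed-form simplex geometry) run on
instances of up to 50 points where exhaustive computation is exact.

## Known limitations

* Single imputation only; imputation uncertainty is not propagated into
  the metrics.
* The GPD/SPO normalization constant $c_s$ is this package's documented
  realization of the $[0,1]$ endpoint contract; other implementations may
  scale differently between the endpoints.
* Histogram fingerprints at 10 bins/dimension are noisy at n ≈ 150 per
  site (see the noise-floor section); GPD values are comparable across
  scopes of similar size, not absolute measures of divergence.
* Per-section values-branch results share one pooled imputation, so a
  section's metrics can be influenced by other sections through imputed
  cells.
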