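---
title: "Methods: consensus transcriptional components and barcode-based gene function prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus transcriptional components and barcode-based gene function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeGBA)
```

## Model

The package assumes the linear latent-factor model of independent
component analysis: the observed expression of gene $g$ in sample $t$ is

$$ X_{gt} = \sum_{j=1}^{k} A_{gj}\, S_{jt} + \varepsilon_{gt}, $$

where the rows of $S$ are statistically independent, non-Gaussian latent
activity patterns (transcriptional components), $A$ is the gene × component
mixing matrix, and $\varepsilon$ is noise. The *genes* are the observed
variables; samples are observations. Row $g$ of $A$ — the gene's
transcriptional regulatory barcode — summarizes how every latent program
affects that gene, and is the object all downstream similarity
computations operate on.

Guilt-by-association then rests on one assumption: genes participating in
the same biological process are driven by similar combinations of latent
programs, so their barcodes are similar, and a gene whose barcode
resembles a gene set's average barcode is a plausible (current or future)
member of that set.

## Pipeline stages and their parameters

### Sample quality control (`qc_filter_samples`)

In large compendia the first principal component of the sample–sample
correlation matrix captures a shared, platform-wide signature; samples
that fail to correlate with it are typically corrupted. We realize that
component in gene space as the PC1-weighted combination of sample
profiles and discard samples with Pearson $r <$ `r_min` (default 0.8)
against it. The component's sign is fixed so the majority of sample
correlations are positive, making the filter deterministic and invariant
to sample order. Among several readings of "correlation of a sample with
PC1" (correlating against the eigenvector, against the rows of the
correlation matrix, or against the gene-space metasample) we chose the
metasample because it is well defined even when the correlation matrix is
degenerate (e.g. identical samples).

### Whitening (`whiten`)

PCA on the gene covariance, computed through the SVD of the row-centered
matrix. The number of retained axes is the smallest that reaches
`var_threshold` (default 0.90) of total variance: enough to keep the
biology, few enough to make ICA tractable and to exclude axes dominated
by noise. Per-axis sign is fixed by making the largest-magnitude gene
loading positive, so the basis does not depend on gene order or on
LAPACK sign conventions. The retained whitened variables have zero mean,
unit variance, and zero correlation by construction.

### Consensus ICA (`run_consensus_ica`)

FastICA is a fixed-point method with a random start; individual runs can
return unstable components. We therefore restart it `n_runs = 25` times
(log-cosh contrast, symmetric extraction by default; deflation is
available), extract as many components per run as there are whitened
variables, and match components across runs greedily at absolute Pearson
`match_r = 0.98`: each run's components (in descending variance order,
ties by index) either join an existing cluster — at most one component
per run per cluster — or seed a new one. A cluster's *credibility index*
is the fraction of runs it covers; clusters covering fewer than
`min_match_runs = 13` runs are dropped, which at the defaults equals the
rule "credibility > 0.5". The consensus component is the sign-aligned
mean of the cluster members, rescaled to unit variance.

Design points that were genuinely open:

* **Matching scheme.** The exact consensus-clustering procedure is not
  canonical; we use greedy reference-cluster growth because it is
  deterministic, one-to-one within a run, and cheap. Components absent
  from the first run can still form clusters (they seed new ones on the
  run where they first appear), which the credibility threshold then
  adjudicates.
* **Non-convergent runs** are retried once with a fresh derived seed and
  otherwise excluded from matching while still counting in the
  credibility denominator — the conservative choice: instability lowers
  credibility rather than silently shrinking the denominator.
* **Component order.** ICA fixes neither order nor sign. We order
  consensus components by the variance they explain in gene space (the
  whitened-space mixing column weighted by the retained eigenvalues);
  the sources' own variances are all ~1, so they cannot serve as a key.
  This makes output order reproducible and independent of gene ordering.
* **Sign.** Within a cluster, members are aligned to the cluster seed.
  Prediction scores are invariant to a global sign flip of any component
  because gene and set barcodes flip together (both derive from the same
  mixing matrix); the test suite asserts this end to end.

### Mixing-matrix recomputation (`recompute_mixing`)

The "inversion" of the data against the consensus sources is implemented
as least squares: $A = X_c S_c^{\top}(S_c S_c^{\top})^{-1}$ with both the
genes and the sources row-centered. Centering both makes the projection
exact for data generated as $X = AS + \text{const}$ and invariant to
duplicating samples. Numerically rank-deficient source sets fall back to
an SVD pseudo-inverse with a warning.

### Barcodes and similarity (`set_barcode`, `distance_correlation`)

The ICA path uses the member mean barcode and the *distance correlation*
— the classical biased V-statistic built from double-centered pairwise
absolute-difference matrices. It lies in $[0,1]$, detects nonlinear
association, and is zero (in population) exactly under independence.
Degenerate inputs (zero distance variance) map to 0 by convention. The
PCA comparator path uses the per-component Welch-*T* barcode and plain
Pearson correlation. A query gene that is a member of the set is *not*
excluded from the set barcode (the set barcode is the mean over declared
members); a leave-one-out flag exists for sensitivity analysis but is off
by default.

Note one geometric subtlety of distance correlation between barcodes: it
compares *distance structure* over components, so two barcodes loaded on
complementary halves of the components can be maximally "similar". In
practice barcodes are dense and heterogeneous and this degeneracy is not
observed; it matters only for hand-built toy examples.

### Permutation null and prediction score (`build_null`, `prediction_score`)

The null for a (gene, set) pair is built by redrawing the set: `n_perm`
(default 1000, minimum 100) random same-size gene sets drawn uniformly
without replacement from the mixing-matrix universe, each reduced to its
barcode and compared to the query gene. Because the null depends only on
the gene and the set *size*, it is cached per (gene, size); random draws
are made over the id-sorted gene order with seeds derived from the global
seed, a hash of the gene identifier, and the set size — so results are
independent of row order, set grouping, and caching strategy. The
permuted unit (set membership, rather than gene labels or expression
values) was an open choice; it directly answers "how unusual is this
similarity compared to an arbitrary set of the same size", and makes
caching sound.

A Gaussian KDE with Silverman's rule-of-thumb bandwidth smooths the null
samples; the p-value is the *analytic* survival probability of the
mixture (never a tail count), clamped away from 0 and 1, and
$Z = \Phi^{-1}(1-p)$ is the prediction score. Consequences: $Z$ is finite
for any finite observed statistic, strictly increasing in it, and
comparable between the ICA and PCA paths because both use the same
permutation machinery. The PCA path can instead use the parametric
one-sided correlation test ($p$ from the $t$-transform of $r$,
$Z = \Phi^{-1}(1-p)$), reproducing the convention of eigenvector-based
GBA tools; permutation remains the default for comparability. Degenerate
nulls (e.g. the exhaustive set) receive a tiny floor bandwidth so the KDE
stays defined.

### Evaluation statistics

Member/nonmember evaluation takes, per set, the median score of current
members and of collection-wide nonmembers (genes in no set of that
collection), and compares groups with the Mann–Whitney AUC
($U/(n_1 n_2)$ with midranks; two-sided normal approximation with
tie-corrected variance). Improvement deltas are per-set differences of
member medians between two score tables, classed by sign with exact zeros
kept as "tied" rather than forced into either class. The
version-update experiment (`version_update_eval`,
`simulate_version_update`) scores held-out true members under a sparser
and a fuller set barcode. Multifunctionality is the size-weighted
membership sum $\sum_i 1/(N_{\text{in},i} \times N_{\text{out},i})$;
the pan-collection score is the sum of per-collection scores over a
shared universe (the combining rule was unstated; a sum preserves
additivity and collection weighting by annotation density).

### Co-functionality and clustering

Co-functionality is `|Pearson r|` between prediction-score profiles
(constant profiles get 0 off-diagonal, 1 on the diagonal); networks keep
genes with at least one edge above the threshold (default 0.5) and export
deterministically ordered GraphML or TSV edge lists. Barcode clustering
uses Ward agglomeration ("ward.D2") on $1 -$ distance correlation with a
default cut height of 2.5; score-profile clustering uses $1 -$ Pearson
correlation with a default cut of 0.8. Clusters outside the declared size
range are flagged rather than re-cut: the height that keeps all cluster
sizes inside a target range is a property of the data, and silently
re-cutting would hide that. Cluster similarity (median pairwise distance
correlation of member barcodes) is reported on the correlation scale, so
higher means more coherent; cluster predictability is the median over
members of each member's best score across all supplied sets, and their
across-cluster Pearson correlation is reported as a single diagnostic.

## The synthetic-data generator

`generate_expression()` emulates exactly the structure the model assumes:
$k$ unit-variance super-Gaussian sources (Laplace by default; a
two-component Gaussian scale mixture as an alternative; Gaussian as a
negative control for which independent components are unidentifiable and
consensus filtering should prune aggressively), a mixing matrix with
disjoint (optionally overlapping) blocks of 20 genes carrying positive
loadings of magnitude ~1 on one designated source each, dense background
loadings of SD 0.05 on all sources, and i.i.d. Gaussian measurement noise
of SD 0.1. Defaults (300 genes × 600 samples, $k = 6$) are the study
conditions used throughout the tests and the acceptance script; the
version-update experiment uses 20 replicates of 150 × 300 with $k = 4$,
5 ICA restarts (retention at 3), and 300 permutations per null, and the
null-calibration check uses a 500-gene × 12-component i.i.d. Gaussian
mixing matrix with 2000 pairs at 1000 permutations — sizes chosen so the
statistics of interest are stable at desk scale.

What the generator does *not* emulate: microarray probe effects, batch
structure, count noise of sequencing data, correlated sources, or
realistic gene-set overlap topology. Passing tests on this generator
therefore demonstrate correctness of the machinery — source recovery,
calibration, ranking behaviour — not performance on real compendia,
which depends on data volume and heterogeneity.

## Numerical choices

* FastICA convergence: tolerance $10^{-6}$ on the rotation update, 200
  iterations, one retry per run with a derived seed.
* Whitening drops numerically zero eigenvalues (relative tolerance
  $10^{-12}$) before the variance threshold is applied.
* Distance correlation clamps tiny negative $\mathrm{dCov}^2$ (floating
  point) to zero and caps results at 1.
* KDE tail probabilities are clamped to $[10^{-300}, 1 - 10^{-16}]$ so
  Z-scores stay finite; a degenerate null receives a floor bandwidth of
  $\max(10^{-8}, 10^{-8}\,|s|)$.
* All randomness flows from one integer seed through a multiplicative
  congruential mix (`derive_seed`), keeping every derived seed a valid
  31-bit R seed; per-gene null seeds hash the gene identifier, not its
  row index.
* The Mann–Whitney p-value uses no continuity correction, matching the
  plain normal approximation with tie correction.

## Known limitations

* Consensus matching is greedy; an adversarial run ordering could split
  a borderline cluster that all-pairs clustering would join. The
  credibility filter mitigates this.
* Distance correlation between short barcodes (few components) carries a
  positive small-sample bias of order $k^{-1/2}$; with very few retained
  components, absolute score magnitudes should be interpreted with care
  (the permutation null removes most, but not all, of this effect from
  the Z-scores).
* Null caching per (gene, set size) assumes the collection's sets are
  exchangeable in size; sets with unusual internal correlation structure
  share the same null as any other set of their size by design.
* The PCA comparator's parametric mode treats components as independent
  observations of the correlation, the classical convention it
  reproduces; its permutation mode is preferable for comparisons.
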