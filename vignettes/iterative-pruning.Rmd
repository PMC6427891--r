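---
title: "Iterative pruning PCA: model, parameters, and design decisions"
author: "ipclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative pruning PCA: model, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipclust)
```

## Scope and assumptions

`ipclust` detects population substructure in a panel of *independent*
biallelic SNPs in additive coding. It assumes quality control has already
happened outside the package — founders only, autosomes, LD pruning,
Hardy–Weinberg and call-rate filters, MAF filter (the README reproduces
the recommended PLINK flags). The only preprocessing the package performs
itself is SNP-wise median imputation of residual missing genotypes and,
optionally, per-SNP least-squares removal of user-supplied covariates
(reference ancestry PCs or AIM dosages) for patient-sample settings where
broad ancestry must not drive the clustering.

The clustering is fully unsupervised: sample labels are carried through
for reporting only and never influence any decision.

## The engine

`iterativePrune()` grows a rooted tree of nested sample subsets. At a node
with `N` individuals:

1. Nodes with fewer than `2 * minGroupSize` members, or at `maxDepth`,
   stop immediately — a split could not produce two viable groups.
2. The node's sub-matrix is re-normalized *within the node* (allele
   frequencies recomputed on the subset) and its top `nPCs` components are
   computed. Re-normalizing inside each node is what lets residual,
   finer-scale variation surface once the dominant axes of the parent have
   been used; whether to re-scale inside sub-nodes is genuinely open, and
   we chose to apply one global `scaleMode` at every node for simplicity
   and reproducibility.
3. The EigenFit statistic — the largest difference between logarithms of
   consecutive eigenvalues, sorted from high to low — is compared with
   `eigenfitCutoff`. A null (single-population) spectrum decays smoothly,
   so all log-gaps are small; axes of real structure stand above the bulk
   and open a large gap. The statistic is defined here as the *maximum*
   gap: which gap index to use is not fixed by the criterion's name, and
   the maximum makes the test sensitive to structure at any number of
   axes while remaining scale-invariant.
4. The rotation-search splitter is tried first on PC1–PC3; if it proposes
   nothing, the CEM Gaussian mixture (up to three components) is tried on
   the same scores. No proposal means the node stops.
5. Proposed children are vetted by Hudson F\_ST: the split is kept only if
   the *largest* pairwise estimate among the children reaches
   `fstThreshold`. Using the maximum (not the minimum) retains a split as
   soon as at least one pair of children is genuinely differentiated —
   the children that are not will be merged back implicitly by their own
   sub-trees stopping early. The veto is computed on the raw imputed
   genotypes even when covariate regression is active, since F\_ST is
   only meaningful on genotype frequencies.

After the recursion, terminal nodes smaller than `minGroupSize` become
outlier groups: clusters containing few members are reported as outlying
individuals, excluded from the main group numbering but fully present in
the outputs. Every sample belongs to exactly one final or outlier group.

The evaluation order — spectrum test before splitting, F\_ST as a
post-split veto — is a design choice: the three stopping rules are
naturally of different kinds (a priori size, pre-split evidence,
post-split confirmation) and this ordering avoids ever fitting a mixture
to a node whose spectrum already looks null.

### Defaults

| parameter | default | units / meaning |
|---|---|---|
| `minGroupSize` | 20 | individuals; outlier cutoff and minimal final group |
| `fstThreshold` | 8e-4 | Hudson F\_ST; split veto |
| `eigenfitCutoff` | 0.15 | log-eigenvalue gap |
| `maxDepth` | 10 | recursion bound |
| `nPCs` | 10 | components per node (splitters use the first 3) |
| `scaleMode` | `"eigenstrat"` | per-SNP normalization |
| `seed` | 1 | threads only into mixture initialization |

`eigenfitCutoff = 0.15` sits an order of magnitude above the largest null
log-gaps we observe for panels of a few hundred individuals by a few
thousand SNPs (about 0.01–0.05) and well below gaps opened by even weak
structure (F\_ST = 0.005 at 10,000 SNPs gives gaps above 0.5), so the
test has a wide indifference zone. `fstThreshold = 8e-4` is far below the
differentiation the engine is meant to resolve yet above the small
positive estimates produced by an arbitrary cut through a homogeneous
sample. Both are exposed and tunable; none of these values is printed by
an external authority, so they are the package's own calibration.

## The rotation-search splitter

The first-stage splitter scans composed rotations about PC1, then PC2,
then PC3 (grid `0, angleStep, …` below 90°, lexicographic order; the
identity comes first, so raw axes are always tried before any rotation)
and after each rotation applies a largest-gap test to each rotated
coordinate. The first cut in scan order wins; the procedure recurses on
both sides up to `maxGroups = 5` groups per invocation. It is entirely
deterministic.

The gap test accepts the largest admissible gap `g` (at least
`minGapPoints` on each side) when either

* `g > gapFactor × IQR(larger side)` (larger side ≥ 5 points) — a compact
  clump or single individual far from a unimodal body; this is what makes
  outlier shaving fast, or
* `g > dominanceFactor × (range − g)` (both sides ≥ 4 points) — the gap
  dominates everything that is not the gap, which still fires when both
  sides are themselves wide multi-cluster regions (three collinear groups
  have no cut with a unimodal side).

The side-size guards exist because the rotation search maximizes over
thousands of projections: the sparse tail of a perfectly homogeneous
cluster will eventually present a moderately large extreme-value spacing
in *some* projection, and an unguarded relative-gap rule shaves those
tail points. With the guards and the defaults (`gapFactor = 3`,
`dominanceFactor = 0.5`, `minGapPoints = 1`), across repeated draws the
splitter separates two 10-σ blobs exactly, isolates a distant 5-point
clump intact, returns three groups for three collinear blobs, and leaves
a single Gaussian blob whole. A scan of `gapFactor` over 2.5/3/3.5 on
those four geometries (50 replicates each) showed 3 to be the robust
choice. Singleton outliers can still be shaved — only via the IQR branch,
which demands a sizeable unimodal main body.

No published description fixes this procedure's split test, angle
schedule, or stopping rule; the whole construction above is this
package's own and is documented as such.

## The CEM mixture stage

When no gap exists — closely related populations overlap in PC space —
the node's first three PC scores go to a full-covariance multivariate
Gaussian mixture fitted by classification EM: the E-step hard-assigns
every point to its maximum-posterior component, the M-step re-estimates
weights, means and covariances from the partition, and the classification
likelihood is non-decreasing until the partition fixes. Each
k ∈ {1, 2, 3} is fitted from 10 k-means++-style seedings; k is selected
by BIC on the classification likelihood (`ν = (k−1) + kD + kD(D+1)/2`
parameters), ties toward smaller k, and k = 1 means "no substructure".
Near-singular covariances get `1e-6 × mean(diag)` ridge; a component that
empties or stays degenerate invalidates that start.

Open choices resolved here: how many PCs enter the mixture (3, matching
the dimensionality the rotation stage uses) and the model-selection rule
(BIC, the standard default family for this kind of fit). Scores enter
untransformed — no whitening.

## Hudson F\_ST

With `p_i` the sample counted-allele frequency and `n_i` the allele count
(2 × individuals with non-missing calls) in group i at SNP j:

$$N_j = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad D_j = p_1(1-p_2) + p_2(1-p_1)$$

The genome-wide value is the ratio of averages `sum(N) / sum(D)` over
retained SNPs, never the average of per-SNP ratios. SNPs monomorphic for
the same allele in both groups (`D = 0`) are excluded; missing genotypes
are dropped from the frequency estimates per SNP per group, never
re-imputed. Negative estimates are meaningful (the estimator is unbiased
at zero differentiation) and are not clipped. Inside the engine's veto a
child group may temporarily be a single individual; the estimator stays
finite there because `n − 1 = 1`, and the ≥ 2-individuals requirement is
enforced per retained SNP rather than per group so that shaved outlier
singletons can still be vetted against their siblings.

`topDiscriminators()` ranks SNPs by per-SNP Hudson F\_ST between any two
groups of a finished run (default top 100; excluded SNPs never appear).

## The benchmark simulator

`simulatePopulations()` draws, per SNP, an ancestral counted-allele
frequency `p ~ Uniform(0.1, 0.9)` (avoiding near-monomorphic SNPs) and,
per population, `p_pop ~ Beta(p(1−F)/F, (1−p)(1−F)/F)` — the
Balding–Nichols model, whose intra-class correlation is exactly F, so the
expected pairwise Hudson F\_ST between independently drifted populations
equals the nominal F (the calibration tests verify realized values within
a few percent at the benchmark scale). Genotypes are `Binomial(2,
p_pop)`, independent across SNPs.

`injectOutliers()` centers the base matrix, decomposes it as
`X = U S Vᵀ`, builds outlier score rows whose PC1/PC2 coordinates sit at
a random sign times `outlierScale = 3` times the observed score range
(other coordinates: noise at 5% of each score SD), maps them back through
`Vᵀ`, un-centers, and rounds/clips to legal {0, 1, 2}. "Extreme values"
is not quantified anywhere authoritative; this construction is verified
by its observable consequence — in a fresh PCA of the augmented panel
every planted outlier falls outside the PC1/PC2 bounding box of all base
individuals. Base individuals are never altered.

The default `SimConfig()` is the benchmark design: 10,000 SNPs, three
populations of 250 at F = 0.005, 10 outliers. `benchmarkDataset()` also
writes the panel as a PLINK trio plus a label sidecar.

What the generator does *not* emulate: linkage disequilibrium, admixture
gradients, related individuals, genotyping error, and missingness.
Passing the benchmark therefore shows the engine resolves weak
mean-frequency differentiation and planted PC-space outliers in
independent-SNP panels; it does not certify behavior under LD leakage or
cryptic relatedness, which QC must handle upstream.

## Numerical choices and degenerate inputs

* Genotype orientation is individuals × SNPs everywhere; text input
  (SNPs × individuals) is transposed at read time; multi-file text input
  is row-concatenated in the order given.
* Missing tokens accepted in text input: `NA`, `-9`, `9` (documented and
  closed); any other token outside {0, 1, 2} is an error. Which allele
  the text coding counts is the caller's convention; PLINK input counts
  bim allele 2, and the same convention is used on output.
* The run cache is gzip-compressed TSV (`sample_id`, `label`, one column
  per SNP) — a documented, language-neutral format; parsing R-native
  serialized data is deliberately not supported.
* PCA runs on the N × N matrix `X Xᵀ / M` (N ≪ M in genotype panels);
  eigenvalues are clamped at zero, and component signs are fixed by
  making the largest-magnitude score entry positive, so plots and tests
  are reproducible. Constant SNP columns stay all-zero after centering —
  the shrunk frequency estimate keeps the eigenstrat denominator
  strictly positive.
* Median imputation uses the even-count convention (mean of the central
  order statistics), so fractional dosages like 0.5 can appear; container
  validity therefore checks the range [0, 2], while file readers enforce
  {0, 1, 2} at parse time.
* EigenFit drops non-positive eigenvalues (and everything below the first
  one); with fewer than two left it reports "no evidence" and the node
  stops.
* Stop reasons are `min_size`, `max_depth`, `eigenfit`, `fst`, and
  `no_split` (neither splitter proposed a partition).
* The engine's only stochastic step is mixture initialization, seeded per
  node from the run seed: identical input and seed reproduce
  `groups.txt` and `tree.txt` byte-identically.

## Problem sizes used in the checks

The test suite exercises the full benchmark (760 × 10,000, five seeds)
for recovery, a 200 × 5,000 homogeneous panel over ten seeds for null
soundness, 30 × 50 panels against a dense SVD oracle, 100-SNP panels
against a brute-force Hudson implementation, and smaller structured
panels (e.g. 120 × 1,200 at F = 0.05) for determinism, export, and
covariate-regression behavior. These sizes were chosen so the whole suite
completes in a couple of minutes while still covering the benchmark at
full scale.

## Known limitations

* The rotation grid is 10° by default; separations that require finer
  angles than the grid are found only through the mixture stage.
* At most three clusters per mixture invocation and five per rotation
  invocation; deeper multiplicity is resolved across recursion levels
  rather than in one step.
* `maxGroups`-capped rotation splits and BIC's conservatism can, in
  principle, leave very weak substructure (F\_ST near `fstThreshold`)
  unsplit; the thresholds are exposed for such cases.
* Patient-sample covariate regression assumes per-SNP linear effects;
  whether AIMs should enter as markers or as derived PCs is left to the
  caller — both fit the covariate interface.
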