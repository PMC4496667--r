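---
title: "Weighted ensemble similarity: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted ensemble similarity: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Ligand-based target fishing asks: given a query molecule, which proteins
does it bind directly? The premise of ensemble similarity methods is that a
protein is better represented by its *whole set* of known ligands than by
any single ligand. Real ligand sets are chemically heterogeneous — a target
like COX-2 or P-glycoprotein binds several distinct chemotypes — so a
query's similarity to its best single analog (the 1NN view) misses binders
that resemble the set's *shared pharmacophore* without resembling any one
member closely.

`wesim` implements a weighted ensemble similarity pipeline in five stages:

1. **Feature weighting.** Each target's ligand set is compared against the
   full training ligand library, feature by feature. Binary fingerprint
   bits are tested for over-representation with one-sided Fisher exact
   tests (vectorized hypergeometric tails); continuous descriptors with
   two-sample Wilcoxon rank-sum tests. P-values are Benjamini–Hochberg
   adjusted to q-values, and a feature's weight is
   `w = -log10(q)` when `q < 0.05`, else 0 — non-negative, zero at the
   significance boundary, and strictly increasing with evidence strength.
   The top-m weighted features per channel are retained.
2. **Weighted similarity.** Between two molecules, the binary channel uses
   the weighted Tanimoto coefficient
   `sum(w * (a & b)) / sum(w * (a | b))` over the selected bits; the
   continuous channel uses the cosine of the weighted sub-vectors, with
   negative cosines clipped to 0 so both channels share the `(0, 1)`
   cutoff domain.
3. **Raw ensemble score.** A query's raw score against a target is the sum
   of its pairwise weighted similarities to the set members at or above a
   global cutoff `S_cut`; weaker similarities are discarded. `S_cut` is
   chosen once per channel by scanning the grid 0.01–0.99 (step 0.01) for
   the highest ROC AUC of the resulting Z-scores on the labeled training
   pairs.
4. **Null calibration (Z-scores).** Raw scores grow with ligand-set size,
   so they are standardized against a random null: 50 ligands drawn at
   random from the training pool are scored against each target, and the
   per-target null mean and standard deviation are regressed linearly on
   set size (`mu = a1*n + b1`, `sigma = a2*n + b2`). A raw score becomes
   `Z = (raw - mu(n)) / max(sigma(n), floor)`.
5. **Bayesian fusion.** The two channel Z-scores are fused into a binding
   likelihood through two-class Bayes with class-conditional bivariate
   Gaussian kernel densities over `(z1, z2)` — a joint 2-D KDE, no
   independence assumption — and empirical class priors. The decision
   thresholds (per-channel Z and hybrid `theta`) are the F1 maximizers
   over pooled leave-one-out scores.

```{r}
library(wesim)
bench <- generate_benchmark(wes_benchmark_config())
cv <- wes_loocv(bench$fp, bench$desc, bench$sets, bench$pairs,
  wes_config(seed = 1))
cv$auc
```

## Assumptions

* Binding is detectable from 2-D structural features: the model sees
  hashed fingerprints and global physicochemical descriptors, not
  conformations or binding-site structure.
* A target's ligands share enriched features against the library
  background; enrichment is estimated per target independently.
* Random-molecule raw scores are approximately linear in ligand-set size
  in both moments — the regression form of the null. Diagnostics (R² of
  both fits, the full per-target moment table) are stored in the model.
* Labeled negatives are exchangeable with random pairs. Training negatives
  are generated uniformly from non-positive (protein, ligand) pairs, as in
  the source data design.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `q_threshold` | 0.05 | significance cutoff below which a feature gets weight `-log10(q)` |
| `m_binary`, `m_continuous` | 256, 64 | caps on retained features per channel; the count used is `min(cap, #significant)`. `optimize_feature_count()` exposes the grid-search alternative with a user objective |
| `n_random` | 50 | random-ligand draw per target for null calibration |
| `sigma_floor` | 1e-6 | lower bound on the predicted null SD (raw-score units) |
| `grid` | 0.01–0.99 | `S_cut` scan grid, step 0.01 |
| `bandwidth_rule` | `"scott"` | KDE bandwidth: `n^(-2/(d+4))` times the class covariance (full matrix); `"silverman"` and `"fixed"` available |
| `priors` | `"empirical"` | class priors for the Bayesian fusion; `"uniform"` available |
| `seed` | 1 | master seed; all draws derive from it via `split_seed()` |

## What the synthetic generator emulates — and what it does not

`generate_benchmark()` produces the statistical structure the method
assumes, with unambiguous ground truth: each protein plants a signature of
`n_signature_bits` fingerprint bits expressed at `p_on` (background bits at
`p_bg`) and `n_signature_desc` descriptors shifted by `desc_effect` SD;
background molecules carry background statistics only. Ligand-set sizes
vary uniformly within `ligands_per_protein ± size_jitter` — the variation
the null-model size regressions are fitted on. With `n_clusters >= 2` the
signature splits into disjoint per-cluster subsets, giving multi-chemotype
sets. Optional "generic" bits (on with high probability in every molecule)
mimic the ubiquitous substructure bits of real hashed fingerprints, which
inflate plain Tanimoto similarity without carrying target information.

Problem sizes used throughout the package's own evaluation: the default
benchmark is 50 proteins × ~20 ligands (1024 bits, 128 descriptors, ~1000
positive and 1000 negative pairs); the scaffold-hopping benchmark
(`wes_scaffold_config()`) is 25 two-cluster proteins × ~16 ligands with
160 generic bits and 20 probes per protein. These sizes keep a full
leave-one-out evaluation to well under a minute while leaving every
statistical estimate (Fisher tails over a ~1500-molecule library,
regressions over 50 set sizes, KDEs over ~2000 points) in a sane regime.

Passing tests on this generator shows that the pipeline recovers planted
enrichment, calibrates its null, and fuses channels correctly. It does
*not* show performance on real chemistry: real fingerprints have
correlated bits, hash collisions, heavy-tailed bit frequencies; real
descriptors are strongly collinear; real affinity labels are noisy and
censored. The chemistry-facing interfaces (`read_ligands()`,
`compute_binary_features()`, `compute_continuous_features()` over
ChemmineR/OpenBabel) let the identical downstream path run on real
SMILES/SDF corpora, but no claim about real-data accuracy is made here.

The scaffold-hopping experiment was calibrated, once, at design time so
that its probe families reproduce the qualitative regime of interest:
analog probes (lightly mutated copies of set members) retrieve their
target at nearest-neighbour Tc > 0.6; "hopper" probes — fresh molecules
from one chemotype cluster expressing the cluster pharmacophore at 75%
strength — sit below Tc 0.4, inside the decoy distribution, so the 1NN
baseline's own F1-optimal threshold gives up on them; decoys outnumber
actives 3:1, as in a screening library. The enriched-bit weighted score is
blind to generic bits (they are equally frequent in the background, hence
never significant) and still accumulates hopper evidence across the
ensemble.

## Numerical choices and degenerate inputs

* **Self-similarity exclusion.** A labeled positive pair's ligand is
  itself a set member; during fitting its self-similarity (identically 1)
  is removed from its similarity vector and the effective set size reduced
  by one. Without this, the `S_cut` scan drifts to the top of the grid
  where self-matches alone separate the training classes.
* **Degenerate nulls in the `S_cut` scan.** At high cutoffs no random
  ligand may score at all: every null SD is zero and the sigma regression
  is degenerate. Such cutoffs cannot calibrate a Z-score and are excluded
  from the scan (with a full-grid fallback if all are degenerate).
* **Featureless ensembles abstain.** If no feature passes the q-threshold
  (as for every target under a no-signal configuration), every similarity
  is exactly zero and the target's own null is a point mass at zero. The
  model reports Z = 0 — the value its own degenerate null implies — rather
  than inheriting the pooled regression's prediction; pairs whose target
  abstained on *all* channels get likelihood equal to the class prior and
  are excluded from the KDE training clouds.
* **Sigma floor.** The null SD regression can predict non-positive values
  at small set sizes; predictions are floored at `sigma_floor` so Z stays
  defined.
* **KDE degeneracies.** A singular class covariance triggers a diagonal,
  variance-floored bandwidth with a warning; points where both class
  densities vanish numerically get the binder prior.
* **Tie-breaks are deterministic everywhere**: feature selection prefers
  the smaller feature index, threshold scans the smaller threshold, the
  `S_cut` scan the smaller cutoff, the feature-count optimizer the smaller
  count, and the intra-set Tanimoto pruning removes the most-connected
  ligand first with ties by ascending ligand id.
* **Serialization.** Models are saved as version-stamped JSON with 17
  significant digits, so save → load → predict is bit-identical.

## Leave-one-out protocol

`wes_loocv()` scores every labeled pair with that pair excluded from the
trainable state. For a held-out positive, the ligand is removed from its
protein's set; the protein's enrichment tests are recomputed with the
ligand counted in the background remainder (column ranks and bit totals
over the library are precomputed once — the pooled sample never changes —
so the refit is exact and cheap); the refit is scored at the reduced set
size. With `refit = "full"` (the default) the protein's null moments and
the global null regressions are refit too; `refit = "ensemble"` freezes
the null regressions at the base fit. `S_cut` is treated as a
hyperparameter fixed once by the global scan before cross-validation, in
the spirit of a retrospective cutoff analysis; the leakage test in the
suite verifies that a held-out score equals the prediction of a model fit
from scratch without that pair at the same cutoff. Held-out negatives
touch no trainable component. Decision thresholds and the fusion densities
are then derived from the pooled held-out scores, with each point's own
kernel left out of its class density (exact leave-one-out evaluation).

The hybrid's fusion is intentionally evidence-conservative; on a benchmark
where one channel already separates the classes perfectly, the smoothed
posterior can lose a knife-edge pair that the raw channel threshold keeps,
so the ablation ordering (hybrid at least as good as each channel) is
expected where both channels carry signal short of saturation.

## Known limitations

* Feature independence is assumed by the per-feature tests; correlated
  bits inflate effective weights. The BH adjustment controls FDR per
  target, not family-wide across targets.
* The weight form `-log10(q)` is one monotone choice consistent with the
  contract (zero at the threshold, decreasing in q); alternatives
  (`1 - q/q0`, probit scales) would change weight ratios but not
  selections.
* The null is Gaussian-summarized (mean/SD); heavy-tailed random-score
  distributions at high cutoffs are only partially captured. An
  extreme-value null (as in sequence-search statistics) is out of scope by
  design.
* Negative training pairs are random non-positives, not assayed
  non-binders; prevalence estimates inherit that convention.
* The 1NN comparison binning uses Tc bins of width 0.05; bin edges are
  configurable since published figures leave them approximate.
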