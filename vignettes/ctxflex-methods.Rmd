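---
title: "Structural-context flexibility and catalytic-residue prediction with ctxflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-context flexibility and catalytic-residue prediction with ctxflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxflex)
```

## The model

Catalytic residues of enzymes tend to sit in structurally rigid surroundings:
not only is the residue itself tightly packed, its sequence and spatial
neighbours are too. `ctxflex` quantifies this with the weighted contact
number (WCN). For a chain of $N$ residues represented by their C$\alpha$
coordinates, residue $i$ has

$$D_i = \sum_{j \ne i}^{N} \frac{1}{r_{ij}^2},$$

where $r_{ij}$ is the C$\alpha$–C$\alpha$ distance in Å. WCN is a packing
density: large in buried cores, small at termini and loops. Its inverse
$D_i^{-1}$ is oriented like a crystallographic B-factor (large = flexible)
and is the unit everything downstream averages.

Two context profiles summarize the neighbourhood of each residue:

* **SEQ** (sequence-neighbour flexibility): the mean of $D_x^{-1}$ over
  residues $i-n \dots i+n$. Window positions beyond the termini are ignored.
* **STR** (structure-neighbour flexibility): the mean of $D_x^{-1}$ over the
  residue itself and all residues strictly closer than a cutoff distance.

SEQ, STR and the experimental B-factor are each standardized *within one
protein* to z-scores,

$$z_i = \frac{x_i - \bar{x}}{\sigma_x},$$

giving $Z_\mathrm{SEQ}$, $Z_\mathrm{STR}$ and $Z_B$. Per-protein
standardization is essential: raw WCN depends on protein size and B-factors
on experimental conditions, so only within-protein contrasts are comparable
across structures. Catalytic residues are expected at the low (rigid) end of
$Z_\mathrm{SEQ}$ and $Z_\mathrm{STR}$.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `n` | SEQ window half-width (residues) | 1 | discrimination between catalytic and background residues is strongest for small windows and degrades beyond roughly 10 |
| `cutoff` | STR neighbourhood radius (Å) | 3 | nearest-contact shell of a C$\alpha$ trace; larger cutoffs blur the local context |
| `edge` | SEQ divisor at the termini | `"mean"` | divide by the number of included terms, so truncated windows are true averages; `"fixed_denominator"` divides by $2n+1$ and deflates the termini, kept for sensitivity checks |
| `cost`, `gamma` | C-SVC / RBF hyper-parameters | grid $2^{-5..15}$, $2^{-15..3}$ | the standard libsvm coarse grid, tuned by inner 5-fold CV maximizing MCC |

Two conventions are deliberate choices where either reading is defensible.
First, the SEQ divisor: with a fixed $2n+1$ divisor, windows truncated at the
chain ends would be systematically deflated, creating artificial "rigidity"
at the termini — the opposite of the physics — so the true average is the
default. Interior residues (all worked catalytic examples) are unaffected.
Second, $\sigma_x$ is the population standard deviation (divide by $N$): the
z-profiles then have unit variance exactly, and the difference from the
sample convention is $O(1/N)$, well inside any tolerance used here.
Residues at exactly the STR cutoff distance are excluded (strict
inequality), and a residue always belongs to its own STR neighbourhood.

## Classification protocol

Catalytic residues are extremely rare (a few per several hundred residues),
so the classifier is never trained on raw class frequencies. The protocol
is:

1. **Protein-level outer folds.** Proteins — not residues — are partitioned
   into 5 folds. Residues of one protein never appear on both sides of a
   split, which prevents leakage through per-protein standardization and
   makes per-protein ROC curves well-defined on held-out proteins.
2. **Balanced subsampling.** Each training set keeps every catalytic residue
   and an equal-sized uniform draw of noncatalytic residues.
3. **Tuning.** (cost, gamma) are selected by inner 5-fold CV on the balanced
   training table, maximizing the Matthews correlation coefficient; ties go
   to the smallest cost, then the smallest gamma. MCC is the criterion
   because it is the headline metric and is robust when both error types
   matter.
4. **Evaluation.** Sensitivity, specificity and MCC are reported on a
   *balanced* subsample of each held-out fold (so the three numbers are
   comparable across feature sets), while ROC curves are computed on the
   *unbalanced* held-out residues: one curve per protein, linearly
   interpolated onto a false-positive-rate grid (step 0.01) and vertically
   averaged. Proteins lacking a positive or negative residue in a fold are
   excluded from the ROC average and counted.

Probabilities come from libsvm's Platt scaling (`e1071`), and each protein's
residues are ranked by descending probability, ties broken by ascending
residue number. Features are not rescaled before training: the z-profiles
are already standardized per protein, the amino-acid indicator block is
binary, and conservation stays on its native information scale (bits); the
RBF gamma grid absorbs residual scale differences.

## The synthetic generator

Real, annotated enzyme structures cannot be bundled, so `synthetic_spec()` /
`make_dataset()` generate structure-like chains with known ground truth:

* **Geometry.** The default architecture is a self-avoiding random walk with
  step length 3.8 ± 0.1 Å (the C$\alpha$ virtual bond), a 3.0 Å excluded
  volume, and a drift toward the centroid, producing a collapsed globule
  with a dense core and flexible termini. An ideal α-helix (rise 1.5 Å,
  radius 2.3 Å, 100°/residue) and a two-lobed variant are also available.
* **B-factors.** $B = 30 + 25\,u(D^{-1}) + \varepsilon$, where $u(\cdot)$
  rescales inverse WCN to $[0,1]$ within the chain and $\varepsilon$ is
  Gaussian with SD 10 Å² (clamped at 0). The affine part encodes the
  empirical correlation between packing and B-factor; the noise makes
  $Z_B$ a strictly noisier copy of the packing signal, emulating the
  experimental artefacts (crystal contacts, refinement conventions,
  temperature) that make B-factors less reliable than computed flexibility.
  With zero noise the correlation with inverse WCN is exactly 1.
* **Labels.** Three "catalytic" residues per 100-residue chain are planted
  among the residues whose $Z_\mathrm{SEQ}$ ($n=1$) lies below the chain's
  0.1 quantile — rigid-context positions, the property the classifier is
  supposed to exploit. A `random` placement mode provides the matching null
  model.

The benchmark configuration used by the test suite and the acceptance
script is 20 proteins × 100 residues × 3 planted sites (60 positives among
2,000 residues), a size chosen so the whole pipeline — profiles, tuning over
the full grid, 5-fold protein-level CV, ROC averaging — runs in well under a
minute per feature set on one core.

**What the generator does not emulate.** Chains are single compact globules
with uniformly random sequences: there are no secondary-structure segments,
no clefts or active-site pockets, no relationship between amino-acid type
and planted labels (so the amino-acid feature is uninformative here, unlike
on real enzymes where most catalytic residues are polar or charged), and no
inter-protein homology structure. One consequence is measurable: because the
packing field of a single globule varies smoothly along the sequence,
widening the SEQ window beyond $n \approx 1$ initially *sharpens* the
planted/background separation after re-standardization, and the separation
only begins to fall beyond $n \approx 10$. On real enzymes the
discrimination decays with window size throughout, because catalytic
contexts are rigid only at short range. Passing the synthetic recovery tests
therefore demonstrates that the machinery (profiles → features → balanced
SVM → per-protein evaluation) is correct and leak-free, not that the
generator reproduces every distributional property of crystallographic
data.

## Numerical and degenerate-case choices

* Duplicate C$\alpha$ coordinates make WCN singular and are an error, as are
  chains with fewer than two residues and constant profiles (z-score
  undefined; reported per protein rather than silently zeroed).
* Metrics with zero denominators (e.g. sensitivity with no actual
  positives) are `NA`, never 0.
* ROC interpolation preserves vertical segments of the threshold-sweep
  polyline: a grid point on a jump takes the top of the jump; between two
  distinct false-positive rates the curve interpolates from the top of the
  left jump to the bottom of the right one. Tied probabilities advance both
  counts together (a diagonal segment).
* PDB reading keeps the highest-occupancy alternate location (first wins on
  ties), uses model 1 unless asked otherwise, maps MSE to methionine, and
  drops residues without a C$\alpha$ (with a count). Heteroatoms, waters
  and ligands are always removed.
* All stochastic steps (subsampling, fold assignment, libsvm's probability
  calibration) run under seeds derived from the configuration seed, and the
  ambient RNG stream of the caller is restored afterwards, so every result
  is a pure function of (data, configuration).

## Known limitations

* WCN is computed on the selected chain only; for oligomeric enzymes whose
  active site borders another subunit, packing at the interface is
  underestimated. Published per-chain worked examples suggest this is the
  convention used for the reference values, and it is the default here.
* The PSSM parser consumes PSI-BLAST ASCII output only; generating profiles
  (running PSI-BLAST) is out of scope, and PSSM rows are aligned to the
  chain positionally, which assumes the query sequence was the chain itself.
* Balanced-mode metrics depend on the negative subsample draw; they are
  reported with the seed and should be averaged over repeats for small
  datasets.
* The B-factor column of synthetic chains is a one-parameter caricature of
  experimental mobility; it supports ordering claims (computed context
  beats noisy B-factors) but not quantitative comparison with real
  refinement output.
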