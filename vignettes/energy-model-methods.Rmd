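---
title: "Thermodynamic models of enzyme allostery from deep mutational scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic models of enzyme allostery from deep mutational scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomap)
library(dplyr)
```

## The model

An enzyme is modelled as occupying three states — unfolded-inactive (the
reference), folded-inactive, and folded-active — with Boltzmann-distributed
occupancies. Two free energies describe a protein variant: the folding
energy $\Delta G_f$ (unfolded $\to$ folded-inactive) and a phenomenological
activity energy $\Delta G_a$ (folded-inactive $\to$ folded-active). The
fraction of molecules that are folded is the two-state quantity

$$p_f = \frac{1}{1 + e^{\Delta G_f / RT}},$$

and the fraction folded *and* active is

$$p_{fa} = \frac{1}{1 + e^{\Delta G_a/RT}\left(1 + e^{\Delta G_f/RT}\right)}.$$

$\Delta G_a$ is deliberately phenomenological: any molecular change that
alters catalytic output without altering soluble abundance — conformational
equilibria, $k_{cat}$, substrate affinity — is absorbed into it. No physical
calibration of $\Delta G_a$ is attempted.

A variant's energies are additive over its substitutions:
$\Delta G = \Delta G^{wt} + \sum_m \Delta\Delta G(m)$. Abundance-type
selections read out an affine function of $p_f$; activity-type selections an
affine function of $p_{fa}$, with one intercept and slope per assay
$\times$ library block, absorbing block-specific scaling of the selection.
Two alternative observation models are included for model comparison: a
two-state model in which both phenotypes are functions of the single
folding trait, and a four-state model with two independently perturbable
active states whose occupancies sum to the activity phenotype.

**Constants.** $R = 0.001987$ kcal/(mol·K) and $T = 303.15$ K (growth
selections at 30 °C), so $RT \approx 0.6025$ kcal/mol. Both are arguments
of `thermo_const()`; every energy in the package scales with this choice.

**Numerics.** All occupancies are computed in log space
(log-sum-exp), and Boltzmann exponents are clamped at $\pm 500$, so the
model is stable for $|\Delta G|/RT$ far beyond anything an optimiser
explores.

## Fitting

`fit_energy_model()` minimises the error-weighted residual sum of squares
$\sum_i (y_i - \hat y_i)^2 / \sigma_i^2$ jointly over all assays and blocks,
sharing the per-mutation energies. Identifiability of the energy scale and
sign comes from the fixed $RT$ in the Boltzmann nonlinearity together with
genotypes observed in multiple genetic backgrounds spanning a range of
phenotypes; no global sign flip survives a joint activity + abundance fit.

Optimisation proceeds in three stages:

1. **Analytic warm start.** Affine layers are initialised from the pooled
   per-assay fitness span; wild-type and single-mutant energies are
   obtained by directly inverting $p_f$ and $p_{fa}$ on their observations
   (clamped to $[10^{-3}, 1-10^{-3}]$). This lands each parameter in the
   correct basin and, for variants beyond the assay's dynamic range, at the
   detection limit.
2. A short L-BFGS-B pass with analytic gradients.
3. Damped Gauss–Newton (Levenberg–Marquardt) on the weighted residuals
   with an analytically assembled sparse Jacobian, run to machine-precision
   convergence. The accepted-step loss trace is monotone by construction.

**Saturated variants.** A strongly destabilised or inactivated variant can
leave the assay's dynamic range: its likelihood becomes flat above some
energy, and the unpenalised estimate can drift arbitrarily. The fit
therefore adds a very weak Gaussian tether (SD `anchor_tau`, default
10 kcal/mol at a reference fitness error of 0.1, scaled inversely with the
dataset's median error so it vanishes for error-free data) centred on each
energy's warm-start inversion estimate. For data-identified parameters the
tether's curvature is ~10⁻⁴ of the data curvature and has no measurable
effect; for data-flat parameters it pins the estimate at the detection
limit, which is the smallest magnitude consistent with the data. This is
not ridge shrinkage toward zero, which the estimator deliberately avoids;
it can be disabled with `anchor_tau = NULL`.

**Cross-validation** (`crossvalidate()`) folds partition the double-mutant
genotypes only; wild type and singles always train, because singles carry
the parameters of interest and each appears in many doubles. Performance is
reported as predicted-vs-observed $R^2$ on held-out doubles, per assay and
pooled.

**Explainable variance.** `explainable_variance()` subtracts the mean
technical variance from the total fitness variance (MEV) and normalises by
the total (FEV), after discarding variants whose errors fall in the top
15th percentile; $R^2$/FEV is the natural normalised model performance.

**Uncertainty.** `estimate_uncertainty()` reports the SD of each energy
across an ensemble of refits, one per cross-validation training subset
(default 10). This approximates the confidence procedure of the original
fitting tools, which is not fully specified; treat the SDs as comparative,
not calibrated.

## The synthetic-study generator

`synth_study()` emulates the statistical structure of a tiled
two-phenotype deep mutational scan with known ground truth:

* a toy self-avoiding 3-D backbone (`generate_structure()`) with a
  spatially clustered active site and a heteroatom ligand group at its
  centroid;
* per-mutation energies drawn from class-specific distributions
  (`generate_truth()`): neutral folding effects $N(0, 0.1)$; destabilising
  core effects $\Gamma(2.5, \text{scale}=0.6)$ at the most buried 30% of
  each tile; stabilising effects $-|N(0, 0.6)|$ at 10% of surface
  positions; inhibitory activity effects at active-site and planted
  allosteric positions with expected magnitude $a\,e^{kd}$ ($a = 2$
  kcal/mol, $k = -0.07$ Å⁻¹, lognormal scatter sdlog 0.3) against distance
  from the active site; and distance-independent activating effects
  $-|N(0, 1.25)|$ at designated sites;
* a tiled library (`generate_library()`): every single substitution in
  every genetic background of its tile, backgrounds being the wild type
  plus singles picked by fixed quantile spacing of their true effects on
  each energy — weak to strong on both axes;
* fitness observations (`generate_observations()`) through the generating
  model's affine layers with heteroscedastic Gaussian noise (SD = 10% of
  each layer's output span by default; `noise_frac = 0` gives error-free
  data with a 10⁻³ floor on the recorded error);
* state-specific contact tables, overlapping pocket sets across
  pseudo-structures (with one pocket planted on allosteric residues and
  one below the druggability filter), and per-residue annotations (rSASA,
  secondary structure, lobes, active-site and second-shell flags).

Three generator choices deserve comment. First, effect sizes are sized to
the assays' dynamic range: a background operating point constrains
energies within roughly $\pm 1.3$ kcal/mol, so the spread of backgrounds
determines the measurable window (about $\pm 4$ kcal/mol here), and the
class distributions keep all but a percent or two of effects inside it —
mirroring real landscapes, where reported per-site folding penalties
plateau around 2–3 kcal/mol for the same reason. Second, activating and
stabilising positions are stratified across tiles: backgrounds are chosen
per tile, and without them a tile would have no backgrounds able to rescue
saturated inhibitory or destabilising effects, making those parameters
unidentifiable in principle. Third, the per-variant Gaussian error model
with known SD is an idealisation: real count-derived fitness errors are
heteroscedastic in fitness itself and only estimated. Passing tests on
this generator therefore demonstrates correctness of the inference
machinery under the stated error model, not robustness to error-model
misspecification.

An optional saturated background (`saturated_background = TRUE`) plants an
activity-dead, unstable background whose narrow fitness range would bias
its block's energies; `fit_energy_model(exclude_backgrounds = ...)`
removes such backgrounds by id.

## Downstream analytics

**Classification** (`classify_mutations()`): one-sided z-tests against the
signed $\pm$0.5 kcal/mol boundary on the side of the point estimate
(two-sided tests against zero would contradict the
"beyond-the-threshold *and* FDR" call definition), BH-adjusted per energy
across all mutations. **Site enrichment** (`major_allosteric_sites()`):
per-residue Fisher's exact tests of activity-modulating mutations against
the rest of the domain, BH across residues, active-site residues excluded;
inhibitory sites use OR > 2 and FDR < 0.1, activating sites the weaker
OR > 1, p < 0.05 convention (they are far rarer, and FDR control there
would have no power). Odds ratios are sample ORs, reported as `Inf`/0 on a
zero cell without continuity correction — the exact p carries the
inference.

**Distance decay** (`fit_exponential_decay()`): $y = a e^{b d}$ by `nls`,
initialised from log-linear regression of $\log(y + 10^{-6})$ with a
Levenberg–Marquardt fallback; the 95% CI of $k$ is asymptotic, and
$d_{1/2} = \ln 2 / |k|$ for every fit. Residues inside the reference
selection sit at $d = 0$, anchoring the intercept. **Directional decay**
(`directional_decay()`): signed displacements are taken along the
structure's native axes from the centroid of the reference selection's
heavy atoms (a single well-defined origin); residues within a 10 Å slab on
the two remaining axes are fitted against absolute axial displacement by
default, or against the radial active-site distance
(`distance = "radial"`), which with an infinite slab reproduces the global
fit exactly. **Matched subsampling**
(`matched_subsample_decay_test()`): inactivating mutations are resampled
with replacement to match the activating set's size and magnitude
distribution on deciles of $|\Delta\Delta G_a|$; each subsample's decay
rate is the closed-form log-linear slope on per-site means (10,000 `nls`
fits would dominate runtime for no inferential gain), and the p-value is
the fraction of subsample rates at or above the activating rate — the
probability, under magnitude matching, that the inactivating decay is no
steeper than the activating one.
**Clustering tests** (`site_clustering_test()`): median pairwise or
nearest-neighbour Cα distances against equal-size random residue subsets.
**Distance correction** (`distance_corrected_effects()`): a loess smooth
(default span 0.75) of effect size on distance; residuals are compared
across secondary-structure classes.

**Contacts** (`parse_contacts()` and friends): only salt bridges,
pi-cation interactions and side-chain hydrogen bonds (to side chain or
backbone) are retained, as the conformation-specific types; duplicate
salt-bridge/hbss annotations collapse to the salt bridge. Residue dynamics
are classified per (residue, interaction type) by comparing partner
*residue* sets between the active and inactive structures — partner atoms
are deliberately ignored. Class effect distributions are compared by
two-sided Wilcoxon rank-sum tests on $|\Delta\Delta G_a|$, BH-adjusted,
with classes under 3 mutations excluded.

**Pockets** (`cluster_pockets()`, `score_pockets()`): pockets below
druggability 5 are dropped; the rest are clustered on
1 − Szymkiewicz–Simpson overlap with average linkage cut at 0.75 (the
exact threshold producing a given published pocket inventory is not
recoverable, so both are configurable); pockets are sorted canonically
before clustering so results are input-order invariant. Per-member
summaries (mean/max/min of per-site mean $\Delta\Delta G_a$, activating
and inactivating FET enrichments) aggregate as medians across members,
with BH across unique pockets and ranking by inactivating enrichment.

**Prediction and regulatory comparison**: `fit_ddga_predictor()` is OLS on
one-hot features with distance entering through the exponential transform
$d_{tr} = e^{kd}$ ($k = -0.063$ Å⁻¹ by default), evaluated by 10-fold CV
with collinear columns dropped to zero; `compare_constructs()` regresses
full-length on domain-only energies (unweighted, as the residual — not the
fit — is the quantity of interest), with
$z = \text{residual}/\sqrt{sd_{FL}^2 + sd_{KD}^2}$, one-sided p per
direction and BH within direction; flagged sites cluster spatially on
Cα distances with a 10 Å default cut.

## Problem sizes and seeds

The packaged tests and the acceptance script run: the standard recovery
study at 5 tiles × 10 positions, 10 backgrounds per tile (~17,000
observations, 1,900 energy parameters; fits converge in seconds to tens of
seconds on one core); model comparison on a 2-tile, 16-position study
(10-fold CV × three models = 30 refits); calibration checks at 20 seeds
(enrichment, CI coverage) and 200 runs (uniformity of subsampling and
clustering p-values, with 150–200 subsamples/null draws per run). These
sizes were chosen so the full statistical structure — multi-background
tiles, both phenotypes, planted spatial signal — is exercised while any
single check runs in minutes.

## Known limitations

* $\Delta G_a$ is phenomenological; agreement with equilibrium
  measurements of conformational free energies is not implied.
* The Gaussian, known-SD error model understates the difficulty of real
  count-derived fitness data.
* Saturated energies are reported at the assay detection limit (see the
  tether above); their ensemble SDs are large and should gate downstream
  use.
* The affine output layers are unconstrained per assay × block; replicate
  structure within a block is not modelled.
* The four-state alternative exists for model comparison; its two active
  states are exchangeable (label-unidentifiable) by construction.
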