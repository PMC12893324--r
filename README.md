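# allomap

Mapping the allosteric landscape of an enzyme from deep mutational
scanning (DMS) data.

Pooled selection assays can measure, for tens of thousands of protein
variants at once, both an enzyme's **catalytic activity** and its
**folded abundance**. A mutation that kills activity may simply unfold
the protein — or it may act allosterically, rewiring activity from a
distance while leaving abundance untouched. `allomap` disentangles the
two by fitting a three-state thermodynamic model to paired
activity/abundance fitness data and then maps where, and how, allostery
operates across the structure.

## The model

Each variant occupies three states — unfolded-inactive, folded-inactive,
folded-active — with Boltzmann weights set by two free energies: the
folding energy ΔG<sub>f</sub> and a phenomenological activity energy
ΔG<sub>a</sub>. The fraction folded and the fraction folded-and-active are

```
p_f  = 1 / (1 + exp(ΔG_f/RT))
p_fa = 1 / (1 + exp(ΔG_a/RT) (1 + exp(ΔG_f/RT)))
```

Mutation effects (ΔΔG<sub>f</sub>, ΔΔG<sub>a</sub>, kcal/mol) are
additive over a genotype's substitutions; abundance fitness is an affine
function of `p_f` and activity fitness of `p_fa`, with one affine layer
per assay × library block. Fitting the model jointly across assays and
blocks, with each mutation measured in multiple genetic backgrounds,
pins every mutation's causal effect on folding and on activity.

On top of the fitted energies the package provides the downstream
allosteric analytics: mutation classification (z-tests + BH-FDR),
Fisher-exact site enrichment (major allosteric sites), exponential
distance-decay and directional (anisotropic) decay fits with half-decay
distances ln2/|k|, effect-size-matched subsampling, spatial clustering
tests, active/inactive contact-dynamics classification, surface-pocket
clustering by the Szymkiewicz–Simpson overlap coefficient with
druggability ranking, linear prediction of ΔΔG<sub>a</sub> from
structural features, and full-length vs isolated-domain regulatory
comparison (ΔΔΔG<sub>a</sub>). A synthetic-study generator with known
ground truth makes the whole pipeline testable end to end.

## Worked example

```r
library(allomap)
library(dplyr)

# a synthetic study: 5 tiles x 10 positions, 10 genetic backgrounds per
# tile, activity + abundance fitness with 10% noise
study <- synth_study(synth_config(), seed = 42)
study
#> <synth_study> 17390 observations, 8695 genotypes, seed 42

# fit the three-state folding-and-activation model
fit <- fit_energy_model(study$observations, n_states = 3)
fit
#> <energy_fit> 3-state, 950 mutations, 17390 observations
#>   weighted loss 15639, convergence code 0

# how well are the planted energies recovered?
joined <- inner_join(study$truth$ddG, tidy(fit), by = "mutation",
                     suffix = c(".true", ".fit"))
cor(joined$ddGf.true, joined$ddGf.fit)   # 0.968
cor(joined$ddGa.true, joined$ddGa.fit)   # 0.957

# distance decay of activity effects away from the active site
sites <- study$truth$ddG |>
  filter(site_class %in% c("allosteric", "active_site")) |>
  group_by(position) |>
  summarise(v = mean(abs(ddGa)))
d <- study$truth$site_class$distance[
  match(sites$position, study$truth$site_class$residue)]
fit_exponential_decay(d, sites$v)
#> <decay_fit> a = 2.085 kcal/mol, k = -0.07955 1/A
#>   (95% CI -0.0951..-0.064), d_half = 8.713 A, n = 10
```

The correlations say the fit separates folding from activity effects at
realistic noise; the decay fit recovers the planted exponential distance
law (amplitude ≈ 2 kcal/mol at the active site, rate ≈ −0.07/Å, i.e. the
allosteric signal halves every ~9 Å).

## Package layout

| File | Contents |
|---|---|
| `R/thermo.R` | state occupancies, genotypes, energy models, fitness prediction |
| `R/fitting.R` | weighted NLS fit, cross-validation, MEV/FEV, uncertainty |
| `R/synthetic.R` | ground-truth, library, observation and annotation generators |
| `R/structure.R` | toy structures, PDB I/O, active-site distances |
| `R/variant_stats.R` | classification, BH-FDR, Fisher enrichment, site calls |
| `R/spatial.R` | decay fits, directional decay, subsampling, clustering tests |
| `R/contacts.R` | contact-table parsing and dynamics classification |
| `R/pockets.R` | pocket clustering and allosteric ranking |
| `R/predict.R` | feature-based prediction and construct comparison |

The methods vignette (`vignettes/energy-model-methods.Rmd`) documents the
model, the estimator, the generator's assumptions and the package's known
limitations.
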