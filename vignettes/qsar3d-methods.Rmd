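---
title: "Grid-based 3D-QSAR with qsar3d: models, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based 3D-QSAR with qsar3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsar3d)
```

## The problem

Congeneric small-molecule series — sets of compounds sharing a rigid
scaffold and differing by substituents — are the classical setting for
grid-based 3D-QSAR. After the molecules are rigidly superposed on a
template, a cubic lattice of probe points is laid around them and, at every
point, interaction or similarity descriptors are computed per molecule.
Partial least squares (PLS) then regresses the biological activity (as
pKi or pIC50, i.e. $-\log_{10}$ of a micromolar potency) on these
thousands of correlated descriptors, and the model is judged almost
entirely by its cross-validated and external predictivity. `qsar3d`
implements that whole workflow: alignment, CoMFA and CoMSIA fields, PLS
with the full classical validation battery, exhaustive field-combination
search, residual-outlier flagging, and StDev*Coeff contour extraction.

## Fields

**Lattice.** `build_lattice()` constructs the minimal axis-aligned cubic
lattice with spacing 2.0 Å (the classical default) whose box extends a
margin (default 4.0 Å, configurable; the classical sources do not fix it)
beyond every atom. All descriptor columns and contour grids refer to the
same x-fastest enumeration of lattice points.

**CoMFA.** At each point $q$, a probe atom (sp³ carbon: vdW radius
1.52 Å, charge +1) accumulates over atoms $i$:

- steric: Lennard-Jones 6-12, $\varepsilon_{pair}\left[(R/r)^{12} -
  2(R/r)^6\right]$ with $R = R_{probe} + R_i$ and
  $\varepsilon_{pair} = \sqrt{\varepsilon_{probe}\varepsilon_i}$
  (Lorentz–Berthelot);
- electrostatic: $332.06\, q_i q_{probe} / r^2$ kcal/mol under the
  distance-dependent dielectric $\epsilon(r) = r$ (a constant-dielectric
  $1/r$ mode is available; which form the classical implementations used
  is not documented, so it is exposed as configuration).

Both sums are truncated symmetrically at ±30 kcal/mol (configurable).
Truncation also handles the singularities at atom positions: a probe point
inside an atom reports exactly the cutoff.

**CoMSIA.** The similarity index for property $k$ is

$$A_k(q) = -\sum_i \omega_{probe,k}\,\omega_{ik}\, e^{-\alpha r_{iq}^2}$$

with attenuation $\alpha = 0.3$ by default and the conventional leading
minus sign. The Gaussian form is finite everywhere, including at atom
positions. Atomic property weights follow standard practice: steric
$\omega = R_i^3$, electrostatic $\omega = q_i$, hydrophobic $\omega$ = an
atomic hydrophobicity contribution, donor/acceptor $\omega \in \{0,1\}$.
The probe is radius 1.0 Å, charge +1, hydrophobicity +1.

**Atom parameters.** The classical sources never state which radii,
charges or hydrophobicity parameters feed the fields. All five per-atom
weights therefore come from a pluggable, element-keyed table
(`default_atom_params()`): Bondi-style radii, Tripos-like well depths,
crude Crippen-style hydrophobicity contributions, and a deliberately
simple polarity-increment charge placeholder. MOL2 charges, SDF data
fields and user tables override every column; serious work should supply
real charges (e.g. Gasteiger-type, from any external tool).

**Descriptor assembly.** `assemble_descriptors()` drops columns whose SD
across molecules falls below a per-kind minimum sigma (default 2.0
kcal/mol for CoMFA energies — the conventional noise floor — and 0 for
CoMSIA indices), then applies block-standard ("CoMFA-STD") scaling: each
field block is divided by one block-wide SD so no field dominates by
numeric scale. The returned object maps every column back to its lattice
point and can project new molecules onto exactly the same columns and
scales for external prediction.

## PLS and the validation battery

`fit_pls()` is single-response NIPALS PLS: mean-centering always,
per-column autoscaling optional and off by default (the block scaling
upstream already equalizes field scales). Coefficients are returned on the
input descriptor scale. Component extraction stops early only when the
residual is numerically exhausted (tolerance $10^{-12}$ on the weight and
score norms), i.e. at a perfect fit.

The battery mirrors the classical summary tables:

- $q^2 = 1 - PRESS/\sum(y-\bar y)^2$ from leave-one-out refits, with the
  full-training-set mean in the denominator (the SYBYL convention; the
  per-fold alternative is not implemented because the cross-check against
  the published F values supports this one), and
  $SEP = \sqrt{PRESS/(n - N_c - 1)}$;
- $r^2_{ncv} = 1 - RSS/\sum(y-\bar y)^2$ and
  $SEE = \sqrt{RSS/(n - N_c - 1)}$;
- $F = (r^2/N_c) / ((1-r^2)/(n - N_c - 1))$. Published summary tables
  sometimes describe F as $r^2/(1-r^2)$ in a footnote, but their printed
  values are only consistent with the standard form above, which is what
  the package implements;
- predictive $r^2_{pred} = (SD - PRESS)/SD$ on an external test set, with
  $SD$ the sum of squared deviations of the test activities from the
  *training* mean — so predicting the training mean scores exactly 0, and
  the statistic is undefined (a clean error) when every test activity
  equals that mean;
- bootstrap (default 100 runs): resample rows with replacement, refit at
  the parent model's $N_c$ (whether the classical studies re-selected
  $N_c$ per resample is undocumented; fixing it is the reproducible
  choice), record $r^2$ and SEE on the resample; report mean $r^2$, its
  SD, and mean SEE. A constant-activity resample is redrawn.

**Component selection.** `select_components()` scans 1..max (default
$\min(10, n/3)$) and takes the count with the highest LOO $q^2$; counts
within `tie_tol` = 0.005 of the best count as ties and the smallest wins.
One NIPALS path per fold yields predictions at every count, so the scan
costs one LOO, not one per count.

## Model search, parsimony, outliers

`run_search()` evaluates every non-empty subset of the five CoMSIA
properties (31 candidates) plus, optionally, the CoMFA steric+electrostatic
pair, each with the full battery, and ranks by $q^2$ descending with two
documented refinements:

- *component parsimony*: a candidate whose $q^2$ beats a model with ≥ 2
  fewer components by < 0.02 is demoted below all non-demoted candidates
  (the classical rejection of 9-component models with merely comparable
  predictions, quantified);
- *simplicity on ties*: candidates within `tie_tol` of the best $q^2$ are
  ordered by fewer field kinds, then fewer components. On noiseless or
  low-noise data every superset of the informative fields fits equally
  well and raw $q^2$ ranking would pick an arbitrary superset; at that
  resolution the models are statistically indistinguishable and the
  simpler description should win.

A candidate whose assembly or fit fails (e.g. a zero-variance field) is
recorded as failed and ranked last; the search continues.

**Outliers.** `flag_outliers()` reports residuals (actual − predicted)
sorted by magnitude and flags those beyond 1.0 log unit (the classical
rule). For compounds inside the candidate's own training set the
*cross-validated* (leave-one-out) prediction is used: a fitted
$p \gg n$ PLS model shrinks the training residual of even a grossly
mislabeled compound toward zero — on the package's planted-outlier
series a +1.5 log-unit shift leaves a fitted residual of ~0.02 but an
LOO residual of ~1.2 — so only held-out residuals can reveal it. Flagged
compounds are reported, never removed automatically; the intended flow is
flag, exclude by hand, re-run, as in classical practice.

## Contour maps

`stdev_coeff_grid()` maps each surviving column of a field back to its
lattice point with value (column SD over training molecules) × (PLS
coefficient); filtered-out columns are *absent* (NA), not zero.
"N% contribution" levels are, by default, the N-th percentiles of the
value distribution over present points with linear interpolation
(`stats::quantile` type 7). Whether the commercial tools' contribution
percentages are percentiles of values, of |values|, or of cumulative
|value| mass is not documented anywhere public; this is the package's
major interpretive decision, and an alternative `"abs_mass"` mode
(weighted quantiles by |value| mass) is provided. Note that over a whole
lattice most points are far from the molecules, so the value distribution
concentrates near zero and percentile levels are numerically small; maps
are meant to be read relative to their own distribution.

Grids export as OpenDX (Å) or Gaussian cube (Bohr, the format's
convention) text volumes, with a JSON sidecar recording the kind, levels,
level rule, and absent-point indices (so zeros in the volume are
distinguishable from absent values).

## The synthetic generator

Real series of this kind live in supplementary material processed with
commercial software, so the package ships a generator whose output every
stage can be tested against, end to end:

- a rigid scaffold (ring of carbons) shared atom-for-atom by all
  molecules — the series is pre-aligned by construction;
- substituent atoms at fixed sites along an arm, with ~0.1 Å positional
  jitter;
- *substitution-site property model*: like the R1/R2/R3 groups of a real
  medicinal-chemistry series, site 1 varies steric bulk (radius), site 2
  electronics (charge, plus donor/acceptor flags on their own independent
  H-bond-character axis — H-bond capacity is chemically distinct from net
  charge, and keeping the axes independent keeps each field kind's signal
  its own), site 3 lipophilicity, each driven by a per-molecule latent
  factor in [−1, 1] with small per-atom jitter; property bounds default
  to radii 1.2–1.9 Å, charges ±0.5 e, hydrophobicity ±1;
- activities are planted as a linear function of the package's own field
  values at one lattice point per planted kind (the point nearest the
  kind's source site), plus Gaussian noise (default SD 0.25 log units, a
  realistic assay scatter), affinely rescaled to a target activity span.

Two design points deserve emphasis. First, each planted weight is
normalized by its field column's SD so every planted kind contributes
comparably to the activity variance — raw steric values scale like
$R^3$ and electrostatic like $q$, so unnormalized weights would make the
signal effectively single-kind. Second, planting one hotspot per kind at
that kind's source site keeps the planted weights *identifiable*: smooth
Gaussian fields make within-kind columns correlate near 0.99 across a
congeneric series, so no linear method could apportion coefficients among
several planted columns of one kind, and a recovery check phrased in
terms of coefficients would be meaningless.

`planted_recovery_stats()` packages the end-to-end check: top-candidate
field set vs planted set, its q² and predictive r², and the cosine
between planted weights and fitted coefficients at the planted columns.
The cosine is evaluated on a fit of the winning field set at the
component count with the *highest* LOO q² over the scanned range rather
than at the parsimony-selected count: the parsimonious model optimizes
held-out prediction, but along strongly correlated field columns the
coefficient at any single column converges to its planted value only as
the fit deepens toward the least-squares limit (at minimal components
PLS spreads the coefficient over the whole correlated block, which
changes single-column ratios without affecting predictions). This
separation — a parsimonious model for prediction, a deeper fit for
parameter attribution — parallels the relaxed refit used after support
selection in sparse regression.

What the generator does **not** emulate: real valence chemistry and
bonding, conformational flexibility, alignment uncertainty, correlated
assay error, activity cliffs, or inter-site correlations. Passing
recovery tests therefore demonstrates internal consistency of the
pipeline — fields, PLS, search and contours agree with each other — not
performance on real data.

`benchmark_fixtures()` provides three fixed-seed series sized like the
inhibitor classes of a classical three-series Aurora-B kinase campaign: A, 24
train / 8 test, activities spanning 0.002–2.097 p-units,
steric+electrostatic signal; B, 33/8, electrostatic+donor, one planted
outlier shifted +1.5 log units; C, 24/7, hydrophobic+donor. The B span
(0.3–3.0) is a plausible choice for low-nM-to-µM potencies; no range is
published for that class.

## Numerical choices and degenerate inputs

- NIPALS stopping tolerances $10^{-12}$; ties in component selection
  0.005 $q^2$ units; search parsimony window 0.02 with component gap 2.
- SEP/SEE denominators $n - N_c - 1$, consistent with the F cross-check.
- Kabsch alignment rejects < 3 mapped pairs and collinear maps (second
  singular value < $10^{-8}$); reflections are excluded via the sign of
  the determinant.
- Constant activity vectors, out-of-range component counts, zero
  surviving descriptor columns, SD = 0 in predictive $r^2$, and planted
  points outside the lattice all raise immediate, specific errors.
- A perfect fit reports $F = \infty$ rather than failing.
- All randomness (generator, bootstrap) is scoped through explicit seeds
  via `withr::with_seed`; the global RNG state is never touched.

## Problem sizes

The shipped analysis scripts and tests run the three fixture series
(32–41 molecules, lattices of ~1000–1500 points, up to ~7000 descriptor
columns over seven field kinds) and complete the full 32-candidate search
with a 100-run bootstrap in well under a minute per series; the package's
own test battery uses these sizes as its standard conditions.

## Interface notes

The package is organized as an analysis workflow: `analysis/01–03`
scripts drive series generation, the exhaustive search with outlier
handling, and contour extraction, writing tables under `results/`; all
computation lives in the package functions, and `run_full_analysis()` /
`run_predict()` orchestrate the same flow programmatically from a single
(optionally YAML) configuration with one seed. No separate shell tool is
provided — the scripts and functions are the interface.

## Known limitations

- The charge placeholder is not a real charge model; results with it are
  only as meaningful as element-level increments can be.
- Substructure alignment requires an explicit atom map (or the
  shared-prefix convenience); no maximum-common-substructure perception.
- CoMSIA hydrophobic contributions are element-level, not
  environment-aware.
- The contour "contribution" semantics are an interpretation (see above).
- Electrostatics at sterically occluded points are clamped, not replaced
  by column means as some commercial implementations do; a mask mode is
  left to future work.
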