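# qsar3d

Grid-based 3D-QSAR in R: CoMFA/CoMSIA molecular fields, PLS with the full
classical validation battery, exhaustive field-combination model search,
residual-outlier flagging, and StDev*Coeff contour maps — for congeneric
small-molecule series with activity data.

## Who this is for

Computational and medicinal chemists who want the classical grid-QSAR
workflow — the one behind countless published CoMFA/CoMSIA studies of
inhibitor series — as open, tested, scriptable R code: read an aligned (or
alignable) series from SDF/MOL2 with pKi/pIC50 annotations, build
descriptor fields on a cubic lattice, search all field combinations for
the best PLS model, validate it the way the field expects, and extract the
contour volumes that show where bulky, charged, hydrophobic or
hydrogen-bonding substituents help or hurt potency.

## The model

Molecules rigidly superposed on a template (Kabsch least squares over a
substructure atom map) are surrounded by a cubic lattice (2 Å spacing).
At each lattice point `q`:

- **CoMFA steric**: Lennard-Jones 6-12 probe-atom energy,
  `eps_pair[(R/r)^12 - 2(R/r)^6]`, sp3-carbon probe (1.52 Å, +1 e);
- **CoMFA electrostatic**: `332.06 q_i q_probe / r^2` (distance-dependent
  dielectric), both truncated at ±30 kcal/mol;
- **CoMSIA** similarity indices for five properties k (steric,
  electrostatic, hydrophobic, H-bond donor, H-bond acceptor):

  `A_k(q) = - sum_i w_probe,k * w_ik * exp(-0.3 * r_iq^2)`

Activities `y = pKi or pIC50 = -log10(K in µM)` are regressed on the
pooled, block-standard-scaled descriptor columns by NIPALS PLS. Models are
judged by leave-one-out `q2 = 1 - PRESS/SS`, `SEP`, non-cross-validated
`r2`, `SEE`, `F = (r2/Nc)/((1-r2)/(n-Nc-1))`, a 100-run bootstrap, and
predictive `r2_pred = (SD - PRESS)/SD` on an external test set. All 31
combinations of the five CoMSIA fields (plus the CoMFA pair) are searched;
training compounds whose cross-validated residual exceeds 1 log unit are
flagged as outliers. Contour grids carry (column SD × PLS coefficient)
per lattice point, with favored/disfavored isolevels at stated
contribution percentiles, exported as OpenDX or Gaussian cube volumes.

A synthetic congeneric-series generator (rigid scaffold, substitution
sites varying bulk/electronics/lipophilicity, activities planted through
the package's own fields at known lattice points) makes the entire
pipeline testable end to end; see the methods vignette
(`vignettes/qsar3d-methods.Rmd`) for the design rationale.

## Worked example

```r
library(qsar3d)

# a 24 train / 8 test congeneric series with a hydrophobic + donor signal
ser <- generate_series(synthetic_spec(n_train = 24, n_test = 8, seed = 7,
                                      planted_kinds = c("comsia_H", "comsia_D"),
                                      noise_sd = 0.25))

search <- run_search(ser$train, ser$test, lattice = ser$lattice,
                     sconfig = search_config(bootstrap_runs = 100, seed = 1))
head(search$report[, c("fields", "n_components", "q2", "r2_ncv", "fstat", "r2_pred")], 3)
#>                       fields n_components    q2 r2_ncv fstat r2_pred
#> 1          comsia_D+comsia_H            2 0.957  0.965   293   0.952
#> 2 comsia_D+comsia_H+comsia_S            2 0.957  0.965   292   0.952
#> 3 comsia_A+comsia_D+comsia_H            3 0.954  0.966   192   0.956
```

The search recovers the planted hydrophobic+donor combination as the top
model: internal LOO `q2` 0.957 with 2 components (well above the 0.5
conventionally called significant), external `r2_pred` 0.952 on the 8
held-out compounds, and field contributions split 0.57 / 0.43 between the
hydrophobic and donor fields:

```r
stats_table(search)
#> $fields      "comsia_D+comsia_H"
#> $q2          0.957      $r2_ncv   0.965     $see   0.157
#> $fstat       293        $r2_pred  0.952     $sep   0.174
#> $n_components 2         $r2_boot  0.967     $sd_boot 0.0128
#> $field_contributions  comsia_D 0.427, comsia_H 0.573

top <- top_candidate(search)
g <- stdev_coeff_grid(top$model, top$dset, search$lattice, "comsia_H")
g <- levels_by_contribution(g, 80, 20)   # the 80%/20% contribution levels
export_grid(g, "contour_H.dx")           # OpenDX volume + JSON sidecar
```

`flag_outliers(search, ser$train)` reports per-compound cross-validated
residuals and flags anything beyond 1 log unit; the intended flow is
flag → exclude by hand → re-run, as in classical practice.

The `analysis/` directory holds the same workflow as numbered scripts:
`01_generate_series.R` (three fixture series shaped like the classical
three-class study layout), `02_model_search.R` (full search + bootstrap +
outlier handling per series, summary table), `03_contour_maps.R` (contour
volumes at the classical per-field levels). Each writes its tables under
`results/`.

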