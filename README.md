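# vhvlpack

Measure and predict the packing angle between the VH and VL domains of an
antibody Fv from Chothia-numbered structures or from sequence alone.

The relative orientation ("packing") of the two variable domains tilts the
CDR loops against each other and so reshapes the antigen-binding site;
being able to predict it from sequence matters for antibody modelling,
humanization and engineering. The package is aimed at structural
bioinformaticians working with AbDb/PDB-style antibody files, and at
anyone who needs a reproducible, fully synthetic test bed for this class
of predictor.

## What it computes

**The packing angle.** For each domain a total-least-squares line is
fitted through the Cα positions of eight conserved framework residues
(L35–L38, L85–L88 in VL; H36–H39, H89–H92 in VH), oriented by the residue
numbering. The packing angle is the signed torsion

&nbsp;&nbsp;&nbsp;&nbsp;θ = dihedral(c_L + v_L, c_L, c_H, c_H + v_H)

where v_L, v_H are the fitted unit axes and c_L, c_H the projections of
each residue set's centroid onto its line. Natural antibodies score near
−46°, nearly all within [−61°, −31°].

**The predictor.** The amino acids at up to 37 interface positions are
encoded by four physical parameters each (side-chain atom count,
compactness, charge with His = +0.5, Eisenberg hydrophobicity), optionally
joined by the lengths of CDR-L1, CDR-H2 and CDR-H3, giving 52/55/148/151
features (schemas `gbr1`–`gbr4`). A gradient-boosted regression ensemble
(learning rate 0.1, depth 2, min 10 samples per leaf, 50000 trees,
seed 100) maps features to the angle. A variant first routes each example
through a three-class "gatekeeper" classifier (normal = [−50°, −40°],
min/max outliers outside it) to one of three class-specific regressors.
A single-hidden-layer ReLU MLP (15 units) is included as a baseline.

Supporting machinery: AbDb-style PDB reading/writing with insertion
codes, quality filtering (X-ray, ≤ 3 Å, no missing residues),
residue+rounded-angle non-redundantization that preserves flexible
antibodies, seeded 90/10 splitting and temporal holdout, repeated K-fold
cross-validation, the standard metric set (Pearson's r, MAE, RMSE,
RELRMSE, slope, intercept; multiclass MCC for the gatekeeper), ggplot2
diagnostics, and synthetic generators for geometrically exact Fv fixtures
and planted-signal sequence→angle datasets.

## Worked example

```r
library(vhvlpack)

# a synthetic Fv built to have a -46 degree packing angle, with 0.15 A
# coordinate jitter
fv <- make_fv_fixture(target_angle_deg = -46, jitter_sd = 0.15, seed = 42)
fv
#> <fv_structure synth_-46>  L: 107 residues, H: 113 residues
#>   method:     X-RAY DIFFRACTION
#>   resolution: 1.8 A
packing_angle(fv)
#> VH/VL packing angle: -45.89 degrees

# a planted-signal dataset: angle = -46 + hydrophobicity signal + N(0, 1)
d  <- make_planted_dataset(2000, schema = "gbr4", noise_sd = 1, seed = 1)
sp <- split_dataset(d, test_fraction = 0.1, seed = 100)
sp
#> <dataset_split> train: 1800, test: 200 (seed 100)

model <- train_gbr(sp$train, "gbr4", gbr_config(n_estimators = 500))
pred  <- predict(model, sp$test)
regression_metrics(sp$test$angle_deg, pred)
#>     n pearson_r mean_error     rmse   relrmse     slope intercept
#> 1 200 0.9669755  0.9302169 1.183405 0.0256286 0.9061867 -4.318974
```

The jittered fixture reads back −45.89° against the −46° construction
target (0.15 Å of coordinate noise moves the angle by about a tenth of a
degree). On the planted data the regressor recovers the signal almost to
the 1° noise floor: r = 0.967, RMSE = 1.18°, and RELRMSE = RMSE divided
by the RMS of the actual angles (≈ 46°), hence ≈ 0.026. Slope below 1
with a matching negative intercept is the usual mild shrinkage of a
regularized predictor toward the mean.

For real structures, replace the fixture with `read_fv("file.pdb")` or
score a directory with `batch_angles()`; sequence-only prediction takes a
numbered-sequence file (`L38 Q`, `H100A Y`, one residue per line). A thin
CLI wrapping these functions ships at `inst/cli/vhvlpack.R`
(`angle`, `prepare`, `train`, `predict`, `fixtures` subcommands).

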