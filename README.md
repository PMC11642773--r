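# confeff

Conformation-fraction models of receptor signaling efficacy.

## The problem

Seven-transmembrane receptors (GPCRs) such as the mu opioid receptor signal
through more than one pathway — G protein activation and beta-arrestin-2
recruitment — and a single ligand can drive the two to different degrees
(biased signaling). Spectroscopy and simulation both indicate that a
receptor–ligand complex visits an ensemble of *intracellular pocket
conformations*, and that how a ligand redistributes the equilibrium among
them determines how strongly each pathway is switched on.

`confeff` implements that hypothesis as a fully tested analysis pipeline
for people who have (or can simulate) ensembles of receptor configurations
per ligand and measured efficacies, and who want a quantitative,
cross-validated model connecting the two:

1. **Featurization** — each configuration becomes three feature blocks:
   backbone/side-chain torsions θ (ψ, φ, χ1, χ2 over a residue selection),
   pairwise alpha-carbon distances C ("at least one residue in between"),
   and hydrogen-bond donor–acceptor distances H (candidates admitted within
   8.0 Å of a reference frame).
2. **Combined distance** — between configurations *i* and *j*:

       D_ij = w_θ·D_θ(i,j)/max D_θ + w_C·D_C(i,j)/max D_C + w_H·D_H(i,j)/max D_H

   with RMS components (the torsion component uses the shortest circular
   arc, 180 − ||Δ| − 180| in degrees) and weights constrained to sum to 1.
3. **Two-stage clustering** — complete-linkage agglomeration under D into
   H clusters, then spectral grouping of the cluster medoids into C
   conformations using the Gaussian similarity S = exp(−D_rmsd²/2δ²) of
   their pairwise superposed (Kabsch) RMSDs, with deterministic pivoted-QR
   label assignment.
4. **Efficacy regression** — per pathway, E_l = β₀ + Σ_c β_c f_{l,c},
   where f_{l,c} is the fraction of ligand *l*'s frames in conformation
   *c*; minimum-norm least squares. Hyperparameters (w_θ, w_C, w_H, H, δ,
   C) are chosen by grid search under an inner leave-one-out loss, and the
   whole model is validated by an outer leave-one-out over ligands that
   never shows a fold its held-out efficacy.
5. **Efficacy response functions** — per structural feature,
   r(x) = Σ_c β̄_c p_c(x) (conformation densities weighted by mean
   cross-validated slopes; torsion densities are seam-continuous through
   sample triplication at ±2π). General activation a(x) = min(|r_G|,|r_B|)
   where both pathways agree in sign, selective activation s(x) = |r_G−r_B|
   where they disagree, and 1000-point Riemann integral scores rank
   features by their link to shared or pathway-specific activation.

A seeded synthetic-ensemble generator (planted conformation templates,
ligand-specific mixtures, the same linear forward model for efficacies)
makes every stage testable at desk scale without molecular dynamics.

## Worked example

```r
library(confeff)

study <- synthetic_study(n_templates = 4, n_ligands = 10,
                         n_frames_per_ligand = 600, n_replicas = 3, seed = 42)
grid <- efficacy_grid(weights = list(distance_weights(1/3, 1/3, 1/3),
                                     distance_weights(0.25, 0.25, 0.5)),
                      H = c(8, 10), delta = 2, C = 4)
fit <- conf_efficacy(study$features, study$efficacies, grid, stride = 10)
fit
#> Conformation-fraction efficacy model
#>   selected: w = (0.25, 0.25, 0.5), H = 10, delta = 2, C = 4
#>   ligands: 10  frames: 6000
#>   held-out: G MAE 1.62 / RMSE 1.78 / R2 0.993;  B MAE 4.06 / RMSE 4.84 / R2 0.970

coef(fit)
#>   (Intercept)   conf_1    conf_2    conf_3    conf_4
#> G    24.07276 73.39583 -14.87609 -65.14432  30.69735
#> B    20.94130 22.23997 -60.13075  70.29884 -11.46676

head(erf_scores(fit), 3)
#>   feature periodic score_general score_selective
#> 1   ca_10    FALSE      54.43343        27.04361
#> 2    hb_4    FALSE      39.90788       155.98319
#> 3   ca_11    FALSE      39.74792        81.06130
```

Reading the output: the grid search settled on C = 4 conformations with
distance weights (0.25, 0.25, 0.5). Held-out mean absolute errors of
1.6% / 4.1% (on the percent-of-reference-agonist scale, against 2%
injected noise) say the ligand-level efficacies are predicted almost to
the noise floor for both pathways. The coefficient rows are each pathway's
intercept and per-conformation slopes: conformation 1 promotes G-pathway
signaling strongly (+73) but the B pathway only mildly (+22), while
conformation 3 represses G (−65) and promotes B (+70) — a selective
conformation. `erf_scores()` ranks structural features: here an
alpha-carbon distance (`ca_10`) carries the largest shared-activation
score and a hydrogen-bond distance (`hb_4`) the largest selective score.

`summary(fit)`, `plot(fit)` (observed vs held-out predicted),
`predict(fit, newdata)` for new ensembles, `residuals(fit, "cv")` and
`simulate(fit)` behave as for any fitted R model. `run_pipeline("config.yaml")`
drives generation → clustering → cross-validation → feature ranking from
one YAML config and writes CSV/JSON artifacts plus a run manifest.

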