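---
title: "Modeling signaling efficacy from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling signaling efficacy from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confeff)
```

## The model

`confeff` rests on one hypothesis: the signaling efficacy of a
receptor–ligand complex along a pathway is linear in the equilibrium
occupancies of a shared set of intracellular pocket conformations,

$$E_{l} = \beta_0 + \sum_{c=1}^{C} \beta_c\, f_{l,c},$$

with $f_{l,c}$ the fraction of ligand $l$'s configurations assigned to
conformation $c$ and one coefficient vector per pathway (G protein and
beta-arrestin-2 style recruitment, called `G` and `B` throughout). The
model is deliberately small — with of order ten ligands nothing richer is
identifiable — and every inferential claim the package makes is routed
through held-out prediction, never through training fit.

Everything upstream of that regression is the definition of "conformation",
which is where all the hyperparameters live.

### Features and the combined distance

Each configuration is described by three blocks: torsions $\theta$
(ψ, φ, χ1, χ2 over a residue selection; angles are stored in radians and
handled on the circle everywhere), alpha-carbon pair distances $C$ (all
pairs of a selection with at least one residue in between, i.e. a sequence
separation of at least 2), and hydrogen-bond donor–acceptor distances $H$
(candidate pairs admitted once, by an inclusive 8.0 Å cutoff in a
designated reference frame, and frozen thereafter). A bundled YAML spec
(`inst/extdata/mor_feature_spec.yaml`) carries the mu-opioid-receptor
intracellular selections; its donor/acceptor atom-name sets are a
conventional polar-atom reconstruction, since no curated atom list exists,
and are flagged as such in the file.

Distances between configurations are root-mean-square per block — the
torsion block uses the shortest circular arc
$180 - \lvert\,\lvert\Delta\rvert - 180\,\rvert$ (degrees) so a
179°/−179° pair is 2° apart — and the blocks are combined after dividing
each by its maximum over the dataset being clustered:

$$D_{ij} = w_\theta \frac{D_\theta(i,j)}{\max D_\theta}
         + w_C \frac{D_C(i,j)}{\max D_C}
         + w_H \frac{D_H(i,j)}{\max D_H}, \qquad w_\theta + w_C + w_H = 1.$$

Max-normalization makes the combination unit-free: rescaling a feature
block (Å vs nm, degrees vs radians) cancels exactly, which the test suite
asserts. The three normalizers are stored with the model so new frames can
be placed on the same scale. A block that is constant across the dataset
(max 0) contributes zero rather than erroring, which keeps toy inputs
usable.

### Two-stage clustering

Frames are first agglomerated by complete linkage under $D$ into `H`
clusters (`stats::hclust`). Each cluster is represented by its **medoid**
— the member minimizing the summed distance to the rest, ties to the
lowest frame index — rather than a mean, because a mean of configurations
is not a configuration and the next stage needs real coordinates. Pairwise
RMSDs between medoid structures are computed after optimal rigid-body
(Kabsch) superposition of the alpha-carbon selection, converted to a
similarity $S = \exp(-D_\mathrm{rmsd}^2 / 2\delta^2)$, and the medoids are
grouped into `C` conformations by spectral clustering: the `C` smallest
eigenvectors of the symmetric normalized graph Laplacian, random-walk
scaled, with the deterministic pivoted-QR assignment strategy (a
column-pivoted QR of the transposed embedding picks `C` representative
medoids; each medoid joins the representative with the largest
polar-rotated overlap). The QR strategy was chosen over k-means on the
embedding because it has no random initialization, so the entire pipeline
is a pure function of its inputs. Whether the original analysis
superposed its RMSDs, and over which atoms, is not documented anywhere we
could find; superposed alpha-carbons of the intracellular selection are
the package default and both choices are arguments.

Every frame's conformation label is the composition of the
medoid-to-conformation map with its hierarchical cluster label — the
spectral stage never reassigns individual frames. If the spectral
assignment leaves a conformation id unused, that hyperparameter point is
scored infeasible (infinite loss) instead of being silently reindexed.

### Subsampling and out-of-sample assignment

The pairwise matrix is $O(n^2)$, so clustering runs on every
`stride`-th frame. Frames outside the subsample still need labels for the
occupancy fractions — with ~1500 frames per ligand the subsample alone
would carry several points of pure multinomial noise per fraction — so
they are assigned to the hierarchical cluster of their nearest medoid
under the combined distance with the frozen normalizers, the standard
extension used for Markov-state-model assignment. Subsampled frames keep
their agglomerative labels, so the composition invariant above holds for
every frame. Fractions then pool replicas per ligand and always sum to
one per row.

### Training protocol

Hyperparameters $(w_\theta, w_C, w_H, H, \delta, C)$ are selected by grid
search. The loss at a grid point is the sum over both pathways of the
inner leave-one-out mean squared error on the training ligands (each
training ligand held out once against the rest). Validation is an outer
leave-one-out over ligands: per fold, the grid search and the regression
are re-run without the held-out ligand, whose efficacy is then predicted.
A poisoning test in the suite verifies the held-out value cannot leak
into its own prediction. Clustering, by contrast, is fit once on all
ligands' frames at each grid point and shared across folds: it is
unsupervised, never sees an efficacy, and a single conformational space
is what makes per-conformation slopes comparable across folds.

The default grid mirrors the full study ranges — weight triples built
from $w \in \{0.1, 0.2, 0.25, 0.33, 1\}$ under the three patterns
$(w,w,1{-}2w)$, $(w,1{-}2w,w)$, $(1{-}2w,w,w)$ restricted to nonnegative
entries plus the three pure triples; $H \in 2..40$; $\delta \in \{1,2,3\}$
Å; $C \in 2..H{-}1$. The third pattern is our repair of a malformed triple
in the printed source of this grid, chosen so that every valid printed
point survives. $w = 1$ under the mixed patterns would give negative
weights and is dropped by the nonnegativity filter. Ties in the grid
break deterministically toward the simpler model: smaller $C$, then $H$,
then $\delta$, then weight order.

Because fractions sum to one and are collinear with the intercept — and
because a realistic study can have more conformations than ligands — the
normal equations are rank-deficient. `fit_mlr()` returns the
minimum-norm least-squares solution (SVD pseudoinverse). Predictions and
residuals are unique; individual slopes are unique only up to the null
directions, which is why the response-function stage uses slopes averaged
over cross-validation folds and why slope tables should be read
comparatively, not as absolute activities.

### Efficacy response functions

For a structural feature $x$, each conformation's sample density
$p_c(x)$ is estimated by a histogram with density normalization (the
upstream description calls this a KDE, but the computation is a
histogram; we keep the computation and say so). Torsion samples are
triplicated at $x \pm 2\pi$ before binning — with bin edges anchored at
the data range, not the domain — so mass near the ±π seam spreads
continuously across it; the result is renormalized to integrate to one
over $[-\pi, \pi]$, exactly, via bin-overlap arithmetic. Defaults are 72
bins per period (5° bins) and 100 bins for linear features, with the
linear domain taken as the pooled sample range padded 5% per side to
avoid boundary truncation; none of these values is documented upstream,
so they are package choices, exposed as arguments.

The response function is $r(x) = \sum_c \bar\beta_c\, p_c(x)$ per
pathway, with $\bar\beta$ the mean slopes over the outer folds that
selected the final hyperparameters (folds that selected different ones
are excluded with a warning — under well-separated synthetic data many
grid points tie almost exactly, so this warning is common and benign
there). The general activation $a(x) = \min(|r_G|, |r_B|)$ where both
responses are strictly same-signed (exact zeros excluded, as the strict
inequalities are printed), the selective activation $s(x) = |r_G - r_B|$
where strictly opposite-signed, and each is scored by a 1000-point
Riemann sum — 1000 evenly spaced points from domain start to end
inclusive, so the spacing is $(b-a)/999$; the endpoint convention shifts
scores by well under any tolerance used anywhere.

## The synthetic generator

`synthetic_study()` is the package's study-condition generator, not a
mock: planted conformation templates (uniform torsions, coordinates in a
box whose side scales with the requested separation, hydrogen-bond
distances), ligand mixtures over them, and efficacies from the same
linear forward model the regression assumes, plus Gaussian noise.

Concrete choices, made once:

* **Angular noise** is von Mises (Best–Fisher sampler, written here
  because no installed package provides one) rather than wrapped
  Gaussian: correct support on the circle, one concentration parameter.
  `kappa = Inf` gives the exact zero-noise limit, reproducing template
  features bit-identically — a tested contract.
* **H distances** are independently jittered and truncated at zero rather
  than derived from geometry, matching their role as an independent
  feature block.
* **Ground truth for fraction recovery is the mixture weights**, not the
  realized label frequencies, so sampling error and estimation error stay
  separable.
* **Separation rule**: a candidate template must be at least
  `separation` reference-noise-units from every accepted one in each
  block (reference scales 10°, 0.5 Å, 0.5 Å); placement gives up after
  1000 rejections. The per-block form is used because the combined
  distance is max-normalized and unitless, so a threshold on it would
  not mean anything physically.
* **Default study conditions**: 6 templates at separation 6, 18
  pseudo-ligands with Dirichlet(0.6) mixture rows, 1500 frames per ligand
  in 3 replicas, torsion concentration 50 (≈8° noise), 0.3 Å coordinate
  and H jitter, 2% efficacy noise. Slopes span 100 to −40 for `G` with a
  rotated, damped copy for `B` so that some conformations are selective.
  Desk-scale analyses cluster every 25th frame; the recovery tests and
  the acceptance script use a small grid bracketing the planted
  configuration.

What the generator does **not** emulate: real receptor geometry,
correlated feature noise, slow conformational kinetics (frames are
i.i.d. given the template), rare conformations unique to one ligand, or
assay heterogeneity. Passing the recovery tests therefore shows the
machinery is correct and calibrated under the model's own assumptions; it
does not show that real trajectories satisfy those assumptions.

## Numerical choices and degenerate inputs

* Torsions live in $[-\pi, \pi)$; wrapping leaves in-range values
  bit-identical.
* Medoid ties break to the lowest frame index; grid ties as above; QR
  assignment ties (`max.col`) to the first column — all so reruns are
  byte-identical, which the suite checks end to end through
  `run_pipeline()`.
* The SVD pseudoinverse uses the LAPACK-conventional tolerance
  `max(dim) * eps * d[1]`.
* Duplicate frames (zero distance) always share a hierarchical cluster;
  constant feature blocks contribute zero to the combined distance; a
  ligand with no frames, a frame set with no efficacy row, or a fraction
  row not summing to one are rejected before any heavy computation.

## Limitations

The regression is linear by hypothesis and unregularized by design;
slopes from rank-deficient fits are not individually interpretable (use
the fold means and their spread from `summary()`). The clustering-wide
normalizers mean a fitted model should only be asked to assign frames
comparable to its training distribution. At desk scale the grid is meant
to be narrowed by the caller; the full default grid over tens of
thousands of frames implies distance matrices the stride must keep
tractable.
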