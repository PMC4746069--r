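---
title: "Measuring fluctuating asymmetry in shapes and counts: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fluctuating asymmetry in shapes and counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymmorph)
```

## The problem

Fluctuating asymmetry (FA) — small random left–right deviations around an
organism's bilateral symmetry — is the classical morphological readout of
developmental instability. It is also the easiest quantity in morphometrics
to measure wrongly, because three other signals live in the same data:
ordinary among-individual variation, directional asymmetry (DA, a
population-level handedness), and digitizing error, which in careful studies
is of the same order as FA itself. `asymmorph` implements the standard
separation machinery for structures with *object symmetry* (a midline runs
through the structure, as in an echinoid test viewed from the oral side)
and the parallel protocol for bilateral counts.

## Shape model

### Superimposition

All landmark analysis happens in Procrustes shape space. Configurations are
centred, rescaled to unit centroid size, and rotated to a consensus by
iterated least squares (`gpa_align()`). Scaling is part of the fit: shape is
what remains after size removal, and centroid size is the size variable.
Numerical choices, all deliberate:

* **Rotations** are solved by cross-covariance SVD with a determinant
  correction, so improper rotations (reflections) are excluded unless
  explicitly requested. In 2D a vectorised closed-form angle is used; it is
  verified against the SVD path in the tests.
* **Convergence** is declared when the root-mean-square change of the
  consensus falls below `1e-10` (default), with a hard cap of 100
  iterations; shape variation in this regime converges in well under ten.
  Non-convergence is an error, never a silent return.
* **Orientation frame.** The consensus orientation is anchored to the first
  observation, making every output deterministic. The anchored frame means
  the consensus is *equivariant* (not elementwise invariant) under a
  rotation of input 1; every shape-level quantity — Procrustes distances,
  residual and ANOVA sums of squares, eigenvalues — is invariant, and the
  tests check exactly that.
* **No tangent projection** is applied on top of the Procrustes residuals.
  At the variation scale this machinery targets (Procrustes SS of order
  1e-2 and below) the curvature correction is far below every effect of
  interest; an orthogonal-projection flag would only add a knob with no
  observable consequence, so v1 omits it.
* Degenerate inputs (all landmarks coincident; rank-zero configurations)
  are hard errors, as are non-finite coordinates. Missing landmarks are not
  imputed: incompletely preserved specimens should be excluded before
  import, which is also the usual practice in the fossil material this
  package targets.

### Object symmetry and the symmetric/asymmetric split

For object symmetry each configuration is paired with its
reflected-and-relabelled copy: coordinates are mirrored across the plane
orthogonal to the first axis and left/right labels are swapped within each
landmark pair (`reflect_relabel()`; an exact involution). Originals and
copies are superimposed in one joint Procrustes fit using proper rotations
only, after which

* symmetric component = (aligned original + aligned copy) / 2,
* asymmetric component = (aligned original − aligned copy) / 2,

an exact, orthogonal split (the tests enforce reconstruction to 1e-9 and
energy conservation to 1e-8). A useful property of this construction: if
the initial consensus is elementwise symmetric, the optimal rotation for a
mirrored copy is the mirrored rotation of its original, so the consensus
stays *exactly* symmetric through the iteration. `symmetry_decompose()`
therefore orients the starting consensus canonically — the best-fitting
reflection of the symmetrised first observation is found by SVD, its
mirror-plane normal is rotated onto the first coordinate axis, and the
result is symmetrised elementwise. That is also why the mirror plane can be
fixed to "negate axis 1" without loss of generality: the joint fit
re-rotates everything, and a fixed plane keeps the output deterministic.

The symmetric and asymmetric subspaces have known dimensions: with `k`
landmark pairs, `u` median landmarks, in 2D `s = a = 2k + u − 2`; in 3D
`s = 3k + 2u − 4`, `a = 3k + u − 3` (`symmetry_dims()`). The tests confirm
these as the empirical ranks of the two component covariances on simulated
samples. One caveat for published tables in this field: degrees of freedom
printed by older software sometimes imply trait-specific landmark subsets
that are not fully documented; this package always derives `s` and `a` from
the declared symmetry map and refuses parametric P values (with a warning)
if the realised component rank falls short of the declared dimension.

### Procrustes ANOVA

`procrustes_anova()` is a two-factor mixed ANOVA — individuals random,
sides fixed — computed coordinate-wise over the `2 n r` aligned
observations (originals and mirrored copies of `n` specimens × `r`
replicates) and summed over coordinates:

| effect | SS source | df | F denominator |
|---|---|---|---|
| Individual | specimen symmetric means about the grand mean | `(n−1)s` | Individual × Side |
| Side | grand asymmetric mean (DA) | `a` | Individual × Side |
| Individual × Side | specimen asymmetric means about the grand asymmetric mean (FA) | `(n−1)a` | Measurement error |
| Measurement error | replicate deviations about specimen×side means | `n(r−1)(s+a)` | — |

Conventions worth stating explicitly:

* The SS are those of the full `2 n r`-observation two-way layout. A
  per-original convention would halve every SS; all F ratios and P values
  are identical either way, and `assemble_anova_table()` reproduces
  published F ratios from printed SS and df by plain division. The
  brute-force oracle in the tests loops explicitly over specimens, sides,
  replicates and coordinates and agrees to 1e-9.
* P values are parametric (F distribution). Permutation tests are a
  deliberate non-goal for v1.
* Only balanced designs (equal `r`) are accepted; unbalanced replication is
  an error, not a silently reweighted fit. Average or subset replicates
  upstream if needed. With `r = 1` the error stratum is absent and FA has
  no test.
* Under the doubled-observation convention the expected mean squares are
  `E[MS_err] = 2σ²_me`, `E[MS_ind×side] = 2σ²_me + 2rσ²_fa`,
  `E[MS_ind] = 2σ²_me + 2rσ²_ind` (per shape dimension);
  `summary.procrustes_anova()` inverts these into variance-component
  estimates, and parameter-recovery tests confirm them within 10% at survey
  scale.

### FA scores and their comparison

`individual_fa_scores()` reduces each specimen's replicate-averaged
asymmetric component to a scalar Procrustes (Euclidean) norm, by default
after subtracting the sample mean asymmetry so DA does not inflate the
scores. A Euclidean rather than Mahalanobis norm is used deliberately:
sample sizes in this domain (tens of specimens against dozens of shape
dimensions) cannot support a stable covariance inversion. Scores are
compared across populations with the Brown–Forsythe variant of Levene's
test (absolute deviations from the group *median*), chosen for robustness
against the skewness that norms of near-Gaussian vectors necessarily have;
mean-centering is available by flag. Replicates enter the decomposition as
separate observations (the ANOVA needs the error stratum) but scores are
computed from replicate averages.

## Meristic model

For a bilateral count trait the data are integers per side and a body-size
covariate; counts are treated as error-free (recounting gives the same
number), so there is no measurement stratum. The protocol in
`fa_indices()`, in fixed order:

1. **Grubbs screen** (two-sided, iterated, default α = 0.05) on signed
   `R − L`. The critical value uses the standard t-quantile formula; the
   screen removes at most one value per round. Zero-variance samples are
   returned untouched.
2. **Size dependence**: Spearman ρ of `|R − L|` against trait size
   `(R + L)/2`. Size-dependent FA would confound population comparisons.
3. **Shapiro–Wilk** on signed differences: ideal FA is normal with mean 0;
   strong non-normality (bimodality) flags antisymmetry, which disqualifies
   an FA interpretation.
4. **One-sample t** of `R − L` against 0: the DA test.
5. **Indices**: FA1 = mean |R − L| and FA4a = 0.798·√var(R − L) with the
   `n − 1` variance. Under pure Gaussian FA both estimate 0.798σ (the
   half-normal identity E|X| = σ√(2/π) ≈ 0.798σ); FA4a is additionally
   invariant under a DA shift, FA1 is not — the tests assert both facts.
   When DA is present its weight is judged by `|mean(R − L)|` versus FA4a.

No multiplicity correction is applied across traits and populations; all
raw P values are reported so users can adjust as they see fit.

`allometry_ancova()` regresses `(R + L)/2` on test length per population
and tests slope homogeneity by the size × population interaction. The
default is untransformed axes with a log₁₀–log₁₀ option: published
allometric slopes near 0.9 for pore counts are compatible with either
reading, and the choice is surfaced as a documented flag rather than baked
in. `tabulate_states()` handles the categorical characters (subanal
fasciole development, labrum projection) as counts and percentages in a
declared vocabulary order — tabulation only, no inference, by design.

## The synthetic-data generator

`simulate_landmarks()` is the generative mirror of the ANOVA model:

```
obs(i, rep) = template + sym(Z_i σ_ind) + antisym(W_i σ_fa) + DA + E_(i,rep) σ_me
```

with `sym`/`antisym` the orthogonal projections under reflection-
relabelling, a built-in exactly symmetric 21-landmark (9 pairs + 3 medians)
2D template sketching an echinoid oral surface at unit centroid size, and
all σ in units of centroid size per raw coordinate. Defaults
(σ_ind, σ_fa, σ_me) = (0.03, 0.01, 0.003) with n = 33 specimens × 2
replicates reproduce the regime of a typical fossil study: individual
variation an order of magnitude above FA, FA several-fold above digitizing
error, and the replicate design sized like the published tables this
package's ANOVA layout mirrors. The injected DA direction is projected
into shape space proper (orthogonal to translations and rotations), because
any component along a similarity direction is removed by superimposition
and would be unrecoverable by construction.

`simulate_meristic()` draws test lengths uniformly (default 25–60 mm),
builds mean counts from an allometric line (default intercept 10, slope
0.9 counts/mm — pore-count scale), adds specimen-level residual scatter
around that line (default SD 2 counts; this is biological scatter, moving
`(R+L)/2` but not `R − L`), and splits `R − L = da_shift + N(0, σ²_fa)`
half to each side. Rounding to integers is applied after side-splitting,
which attenuates FA4a noticeably for σ ≲ 1 — a real feature of meristic
data, and the reason calibration tests can disable rounding.

What the generator does **not** emulate: correlated landmark noise
(digitizing error is isotropic per landmark), antisymmetry mixtures
(bimodal `R − L`), size-dependent FA, taphonomic deformation, and
photogrammetric artefacts. Passing parameter-recovery tests therefore shows
the estimators are correct under the stated model, not that real fossil
data meet the model; the screening steps (Shapiro–Wilk, Spearman, Grubbs)
exist precisely to check those assumptions on real material.

## Validation scales and determinism

The test suite validates at sizes chosen to make Monte-Carlo noise
negligible relative to each tolerance: brute-force oracle equivalence on
tiny designs (n = 3, r = 2, 5 landmarks) at 1e-9; variance-component and DA
recovery from 200 replicate surveys of n = 200 × r = 2 at 10%; calibration
of Levene, t and the FA1/FA4a identity from 1000 simulations (bands
0.03–0.07 at nominal 0.05, ratio 0.98–1.02 at n = 10⁴). All simulation is
seed-driven; identical parameters and seed give byte-identical samples, and
the workflows write identical output files on rerun.

## Known limitations

* Balanced designs only; no missing-landmark handling; no semilandmarks.
* Parametric P values only (no permutation/MANOVA machinery).
* Matching symmetry (paired separate structures) is out of scope — the
  decomposition here is specific to object symmetry.
* The Euclidean FA score ignores the asymmetric component's covariance
  structure; with very large samples a Mahalanobis variant would use more
  information.
* 2D and 3D are supported throughout, but the built-in template is 2D;
  3D users supply their own template/symmetry map.
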