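# asymmorph

Geometric-morphometric analysis of shape variation and **fluctuating
asymmetry (FA)** in bilaterally symmetric structures, built for studies of
organisms with *object symmetry* — structures whose midline runs through the
object itself, such as the test of a spatangoid echinoid — together with the
classical **meristic FA protocol** for bilateral counts (e.g. pore pairs per
petal, left vs right).

Fluctuating asymmetry — small, random, individual-level departures from
perfect bilateral symmetry — is the standard morphological proxy for
developmental instability. Measuring it honestly requires separating it from
three confounders: ordinary individual variation, *directional asymmetry*
(DA; a consistent mean difference between sides) and digitizing error.
`asymmorph` implements the full separation machinery for both landmark data
and count data, plus a synthetic-data generator with known variance
components so every stage can be validated by parameter recovery.

## What the package computes

**Shape side.** Landmark configurations (from MeshLab PickPoints `.pp`, TPS
or CSV files) are superimposed by generalized Procrustes analysis: each
configuration is centred, rescaled to unit centroid size
(CS = √Σ‖xᵢ − centroid‖²) and rotated to best fit. For object symmetry,
every configuration is superimposed jointly with its reflected-and-relabelled
copy; each observation then splits exactly into a **symmetric component**
(the average of the pair) and an **asymmetric component** (half the
difference). The mixed-model **Procrustes ANOVA** partitions the summed
squared Procrustes coordinates into

| effect            | meaning                          | F denominator      |
|-------------------|----------------------------------|--------------------|
| Individual        | symmetric individual variation   | Individual × Side  |
| Side              | directional asymmetry            | Individual × Side  |
| Individual × Side | fluctuating asymmetry            | Measurement error  |
| Measurement error | replicate digitizing error       | —                  |

with degrees of freedom `(n−1)s`, `a`, `(n−1)a` and `n(r−1)(s+a)`, where
`s` and `a` are the symmetric/asymmetric subspace dimensions implied by the
landmark pairing (in 2D, `s = a = 2k + u − 2` for `k` pairs and `u` median
landmarks). PCA of either component and per-specimen FA scores (compared
across populations with Brown–Forsythe/Levene tests) complete the workflow.

**Count side.** For a bilateral count trait the protocol on the signed
differences `R − L` runs, in fixed order: iterated Grubbs outlier screen →
Spearman test of `|R − L|` against trait size `(R+L)/2` → Shapiro–Wilk
normality check (antisymmetry screen) → one-sample *t* test for DA → the
indices **FA1 = mean |R − L|** and **FA4a = 0.798·√var(R − L)** (FA4a is
unbiased by DA) → Levene comparisons across populations, plus the
count-versus-test-length allometry ANCOVA with a slope-homogeneity test.

## Worked example

```r
library(asymmorph)
tpl <- echinoid_oral_template()            # 21 landmarks: 9 pairs + 3 medians

erwitte <- simulate_landmarks(n_individuals = 33, replicates = 2,
                              sigma_individual = 0.03, sigma_fa = 0.01,
                              sigma_me = 0.003, da_magnitude = 0.01,
                              population = "Erwitte", seed = 1)
fit <- procrustes_anova(erwitte, tpl$map)
fit
#> Procrustes ANOVA ('Erwitte'): 33 individuals, 2 replicate(s), subspace dims s = 19, a = 19
#>             Effect         SS         MS   df     F       P
#>         Individual 2.16135220 3.5549e-03  608  8.95 <0.0001
#>               Side 0.01758856 9.2571e-04   19  2.33  0.0012
#>  Individual x Side 0.24151268 3.9722e-04  608 21.15 <0.0001
#>  Measurement error 0.02354891 1.8779e-05 1254
summary(fit)$variance_components
#>        individual                fa measurement_error
#>      8.840191e-04      9.461144e-05      9.389518e-06
```

The fit recovers the simulated regime: FA is highly significant
(Individual × Side, F = 21.15 over measurement error), the injected DA shows
up in the Side factor (P = 0.0012), and the variance components land close
to the generating values (0.03², 0.01², 0.003²). On the count side:

```r
counts <- rbind(
  simulate_meristic(n = 36, da_shift = 1.9, sigma_fa_count = 2.8,
                    population = "Liencres", seed = 2),
  simulate_meristic(n = 35, da_shift = 0.6, sigma_fa_count = 1.5,
                    population = "Erwitte", seed = 3))
fa_indices(counts, trait = "anterior_petals", population = "Liencres")
#> FA report: trait 'anterior_petals', population 'Liencres' (n = 36)
#>   FA1 = 2.833   FA4a = 2.605   mean(R-L) = 1.444
#>   DA t-test: t = 2.66, P = 0.0118
#>   Shapiro-Wilk P = 0.685   size-dependence rho = -0.164 (P = 0.34)
#>   variation attributed mainly to developmental instability (|DA| <= FA4a)
```

FA1 ≈ FA4a ≈ 0.798·σ, DA is detected but does not exceed FA4a, so the side
variation is read as developmental instability rather than handedness.
`run_shape_workflow()` and `run_meristic_workflow()` chain all stages and
write CSV tables plus a JSON provenance sidecar.

## Documentation

The methods vignette (`vignettes/shape-asymmetry.Rmd`) describes the model,
its assumptions, all tunable parameters, what the synthetic-data generator
does and does not emulate, and the package's numerical choices.
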