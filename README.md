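# deswax

Screening hydrophobic natural deep eutectic solvents (hNADESs) against
hydrophobic solutes such as beeswax, and modelling the kinetics of the
resulting dispersion.

Beeswax coatings on heritage objects are traditionally removed with white
spirit. Eutectic mixtures of natural hydrophobic components (fatty acids,
terpenes, quaternary ammonium salts) are candidate green replacements,
and evaluating them involves a well-defined computational chain that this
package implements for conservation scientists and formulation chemists:

1. **Hansen solubility parameters by group contribution**
   (Hoftyzer–Van Krevelen): for a component with molar volume *V*,

   δ<sub>d</sub> = ΣF<sub>d,i</sub>/V,  δ<sub>p</sub> = √(ΣF<sub>p,i</sub>²)/V,  δ<sub>h</sub> = √(ΣE<sub>h,i</sub>/V)

2. **Mixture parameters and Teas fractions**: volume-fraction mixing
   δ<sub>k,M</sub> = δ<sub>k,1</sub>s₁φ₁ + δ<sub>k,2</sub>s₂φ₂ with
   φᵢ = xᵢvᵢ/Σxⱼvⱼ, and the ternary-chart percentages
   F<sub>k</sub> = 100 δ<sub>k</sub>/(δ<sub>d</sub>+δ<sub>p</sub>+δ<sub>h</sub>).

3. **Compatibility scoring**:
   R<sub>a</sub>² = 4Δδ<sub>d</sub>² + Δδ<sub>p</sub>² + Δδ<sub>h</sub>²,
   RED = R<sub>a</sub>/R₀ (< 1 predicts compatibility), plus calibration
   of an unpublished solute center and radius from a published RED list
   by deterministic multistart least squares.

4. **Dispersion kinetics**: the Hill saturation law
   f(t) = a·tᶜ/(bᶜ + tᶜ) (c = 1: the Michaelis–Menten form, solution of
   df/dt = (a/b)(1 − f/a)², a *quadratic*-deficit alternative to
   first-order Noyes–Whitney kinetics), fitted by log-parameterized
   Levenberg–Marquardt with the full statistics panel (R², aR², SE, F, p,
   AIC, BIC, AICc), turbidity–mass linear calibration, and a seeded
   generator of paired turbidimetric/gravimetric time series.

The package ships a twelve-formulation worked panel (component group
decompositions, eutectic ratios, literature reference Hansen/Teas/RED
values) under `inst/extdata/`.

## Worked example

```r
library(deswax)

## Hansen parameters of the dodecanoic/decanoic 1:2 eutectic (DES 8)
components <- read_component_table(
  system.file("extdata", "components.csv", package = "deswax"))
des8 <- des_mixture(components[c("dodecanoic acid", "decanoic acid")],
                    c(1, 2), name = "DES 8")
h <- mixture_hansen(des8)
h
#> <hansen> delta_d = 15.96, delta_p = 2.04, delta_h = 6.96 MPa^0.5
round_teas(teas_fractions(h))
#> F_d F_p F_h
#>  64   8  28
```

The mixture sits at (16.0, 2.0, 7.0) MPa^0.5 after reporting-layer
rounding — a strongly dispersive, weakly polar solvent, 64% of whose
cohesion is dispersive: exactly the profile that matches an aliphatic wax.

```r
## screen the twelve-formulation panel against the calibrated beeswax sphere
ref <- beeswax_reference()
ref
#> <solute_reference> center (15.80, 0.06, 0.16) MPa^0.5, R0 = 10.05
#>   calibration RMS residual: 0.002381 RED units
scores <- rank_by_red(score_compatibility(des_reference_hansen(), ref))
print(head(cbind(scores[1:2], RED = round(scores$RED, 2),
                 compatible = scores$compatible), 4), row.names = FALSE)
#>  des_name       Ra  RED compatible
#>     DES 3 6.531902 0.65       TRUE
#>     DES 8 7.151492 0.71       TRUE
#>     DES 7 7.413772 0.74       TRUE
#>     DES 9 8.094618 0.81       TRUE
```

The calibrated solute center lands on white-spirit-like coordinates (the
solvent conservators actually use for beeswax), and the tetrabutylammonium
bromide/octanoic (DES 3) and fatty-acid (DES 8, DES 7) eutectics lead the
compatibility ranking; the two choline chloride formulations fall outside
the sphere (RED > 1).

```r
## fit dispersion kinetics on a simulated strongly-dispersing experiment
sim <- simulate_dispersion(synthetic_spec("high", seed = 42))
fit_hill(average_replicates(sim, "mass"))
#> Hill dispersion fit (mass, c fixed at 1)
#> <hill_params> a = 5.034, b = 85.55 min, c = 1 (k = b/c = 85.55 min)
#>   a = 5.034 +/- 0.0908   b = 85.55 +/- 5.69 min
#>   R2 = 0.9987  aR2 = 0.9985  SE = 0.0624  p = 7.1e-10
#>   AIC = -42.69  BIC = -42.53  F = 4559  DoF = 6  AICc = -40.29
```

The fit recovers the generating saturation level (a = 5 g) and
half-saturation time (b = 80 min) within their standard errors: the
solvent would hold ~5 g of wax at saturation and reaches half of that in
~1.4 h.

A thin command-line wrapper drives the same pipeline
(`hsp`, `screen`, `fit`, `simulate`, `report` subcommands):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "deswax.R", package = "deswax"))')" \
  report --out out/ --seed 1
```

All reports are header-bearing delimited text embedding the package
version, configuration hash and seed.

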