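# neotissue

Curvature-driven simulation of neotissue growth in porous bone-scaffold
geometries, with Bayesian calibration of the growth coefficient against
observed pore-filling data.

## The problem

In bone tissue engineering, skeletal progenitor cells seeded on a
calcium-phosphate scaffold progressively fill its pores with neotissue (cells
plus the extracellular matrix they produce). How fast a pore fills depends
strongly on its local geometry: growth starts in corners and narrow features,
the tissue front circularizes, and larger pores fill disproportionately more
slowly. `neotissue` is aimed at scaffold designers who want to compare
candidate pore shapes and sizes in silico before printing them.

The core model is a level-set description of the tissue/void interface. A
field φ is positive in neotissue, negative in void, zero on the interface;
the interface advances with velocity

    V = A · g(κ) · n,   g(κ) = -κ if κ > 0, else 0

where n = ∇φ/|∇φ| points toward the tissue, κ = ∇·n is the local mean
curvature (positive where the void is concave as seen from the tissue), and
A (mm²/day) is the one free coefficient, calibrated per material. Flat and
convex regions are stationary; the tissue never retracts. A cylindrical void
of radius r therefore closes as r(t) = √(r₀² − 2At), giving the
size-squared scaling of filling times that the data show.

The package provides:

* **Geometry** — signed-distance generators for prismatic channel
  cross-sections (`channel_spec()`/`channel_sdf()`: triangle, square,
  hexagon, circle), gyroid scaffolds with solved period and wall threshold
  (`gyroid_spec()`/`gyroid_sdf()`), spheres, and seeded initial states
  (`initial_levelset()`).
* **Level-set core** — regularized normals and curvature, the one-sided
  growth velocity, midpoint semi-Lagrangian advection, eikonal redistancing,
  and the adaptive time loop (`simulate_growth()`).
* **Quantification** — sub-cell-accurate filling fractions
  (`filling_fraction()`) and circularity/sphericity diagnostics
  (`circularity()`).
* **Calibration** — `calibrate_growth()` fits A by sequential model-based
  (Bayesian) optimization — a Gaussian-process surrogate with expected
  improvement over log10(A) — minimizing the RMSE against observed filling
  percentages; the result is a classed fit with `coef`, `summary`,
  `predict`, `residuals`, `plot` and `simulate` methods.
* **Data** — packaged day-10/21 filling percentages for channels printed in
  hydroxyapatite (HAp), tricalcium phosphate (TCP) and their 60/40 blend
  (BCP) (`load_observations()`), and a seeded pseudo-data generator for
  recovery experiments (`generate_pseudo_observations()`).
* **Runs** — YAML-configured pipelines (`run_channel()`, `run_gyroid()`)
  writing CSV series, VTK ImageData snapshots, and a metadata JSON sufficient
  to re-run the simulation; a thin CLI in `inst/scripts/neotissue-cli.R`.

## Worked example

Calibrate the growth coefficient for hydroxyapatite from the packaged
observations and predict day-21 filling of 1 mm channels:

```r
library(neotissue)

fit <- calibrate_growth(material = "HAp", n_iter = 25, seed = 1)
print(fit)
#> Curvature-driven neotissue growth model
#>   material:     HAp
#>   A (growth coefficient): 0.0026896 mm^2/day
#>   RMSE at optimum: 13.94 percentage points
#>   calibration: 25 evaluations, seed 1

predict(fit, data.frame(shape = c("triangle", "square", "hexagon", "circle"),
                        d_mm = 1, day = 21))
#>      shape d_mm day filling_pct
#> 1 triangle    1  21    93.82309
#> 2   square    1  21    40.36385
#> 3  hexagon    1  21    45.76298
#> 4   circle    1  21    49.83916
```

The calibrated coefficient (~0.0027 mm²/day) reproduces the experimental
ordering: the 1 mm triangular channel is nearly full at day 21, circle and
hexagon sit at intermediate filling, the square trails, and (not shown)
all 2 mm channels stay below ~26%. A single simulation is equally direct:

```r
f  <- channel_sdf(channel_spec("circle", 1.0), spacing = 0.02)
st <- initial_levelset(f, layer = 0.01)          # 10 um seeded layer
sim <- simulate_growth(st, growth_params(A = 0.003), t_end = 21,
                       record_at = c(10, 21))
sim$filling_fraction                              # 0.283, 0.552
```

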