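# myconet

Quantification of extraradical mycorrhizal (hyphal) network architecture
from micrographs, plus the assay arithmetic that links network structure to
nutrient transfer.

Arbuscular mycorrhizal fungi trade soil phosphorus for plant carbon through
filamentous networks growing outside the root. Experiments that image these
networks in a fungus-only compartment, and trace phosphorus with
quantum-dot-labelled apatite, need a reproducible path from raw images and
assay tables to a few interpretable numbers. `myconet` provides that path
for researchers analysing such plate systems:

* **Image pipeline** — `binarize()` (Otsu or fixed threshold),
  `clean_mask()` (morphological closing + removal of isolated noise
  clusters), `skeletonize()` (Zhang–Suen thinning to a 1-px centreline),
  `extract_rois()` (labelled square crops along the barrier→centre axis).
* **Architecture metrics** — `box_count()` and `estimate_dimension()`
  implement the box-counting mass fractal dimension from the scaling law

  *N(s) ∝ s^(−D_m)*

  where *s* is the grid size and *N(s)* the number of boxes containing
  hyphae; *D_m* is minus the slope of the ordinary least-squares fit of
  log *N(s)* on log *s* (default grids 8–64 px). `surface_density()` is the
  exact foreground-pixel fraction, and `profile_gradient()` assembles both
  metrics into tidy barrier→centre profiles.
* **Assays** — `fit_calibration()` (per-strain linear qPCR copy-number →
  dry-biomass calibration), `copies_to_biomass()`, and
  `transfer_efficiency()`: quantum-dot signal in the focal root per mg of
  focal extraradical hyphae (focal-compartment biomass + focal biomass in
  the central compartment).
* **Synthetic ground truth** — `generate_network()` grows branching,
  fusing hyphal-tip random walks into sparse binary networks with known
  coverage, centreline length and branch count; `make_fixture()` builds
  analytic rasters (filled square, line, point, Sierpinski carpet) whose
  fractal dimension is known in closed form.
* **Workflow** — `run_architecture_pipeline()` / `run_assay_pipeline()`
  tie everything into deterministic tidy tables, with a thin `myconet`
  command-line wrapper (`inst/cli/myconet`) offering `synth`, `quantify`,
  `assay` and `fixtures` verbs.

## Worked example

Generate a synthetic barrier→centre series with rising coverage targets
(4%, 6%, 8%), run the preprocessing chain, and profile it:

```r
library(myconet)

params <- synthetic_network_params(rng_seed = 11)
series <- generate_gradient_series(params, 3, c(0.04, 0.06, 0.08))
masks  <- lapply(series, function(im) clean_mask(binarize(im))$pixels)
profile_gradient(masks)
#>   label   D_m r_squared coverage_frac coverage_percent
#> 1     1 1.406    0.9993       0.04005            4.005
#> 2     2 1.458    0.9993       0.06010            6.010
#> 3     3 1.527    0.9986       0.08014            8.014
```

Each row is one location: the realized density tracks its target to within
one growth step, and the skeleton's fractal dimension rises with density —
denser networks fill space more completely. `r_squared` close to 1 says the
box counts follow the power law well over the fitted grid range.

A calibration table (copy numbers against weighed 0.5–5 mg subsamples)
fits one line per strain:

```r
cal <- data.frame(strain = "A5",
                  copy_number = c(0.25, 0.5, 1, 1.5, 2.5) / 5e-7,
                  biomass_mg  = c(0.52, 1.01, 2.48, 3.05, 4.95))
fit_calibration(cal)
#>   strain     slope intercept r_squared n_samples
#> 1     A5 9.771e-07    0.1546    0.9857         5
```

`slope` is mg of dry fungal biomass per qPCR copy; predictions come from
`copies_to_biomass()`, which clamps negative values at low copy numbers
to zero with a flag.

From the shell, the same architecture run is:

```sh
myconet quantify --preset gradient --seed 11 --out results.csv
```

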