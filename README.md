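# lambdamap

Poisson spectral unmixing and fraction mapping for hyperspectral
("lambda-stack") fluorescence images of solvatochromic membrane probes.

## What problem this solves, and for whom

Laurdan-family probes report the polarity of their lipid environment by
a large emission shift: ~440 nm in apolar, ordered (Lo-like) bilayers,
~490 nm in polar, water-exposed (Ld-like) ones. Acquiring stained cells
in lambda mode — a stack of narrow spectral channels (e.g. 17 channels
of 9.8 nm between 418 and 584 nm) — records a full emission spectrum at
every pixel. `lambdamap` is for microscopists and image analysts who
want to turn such stacks into quantitative membrane-order maps:

* **Unmixing.** Each pixel's counts `y` over `C` channels are modelled
  as `y ~ Poisson(S a)` with unit-area reference spectra `S` (C×K) and
  nonnegative abundances `a`. Abundances minimize the generalized
  Kullback–Leibler divergence `Σ y log(y/Sa) − y + Sa` — the Poisson
  maximum-likelihood objective, right for photon counting — via
  multiplicative NMF updates. Both fixed-reference and blind
  (spectra-unknown) modes are provided, with the standard working
  defaults: 10 iterations, background threshold 50 (channel sum),
  saturation threshold 4000 (per channel), spectrum-update stride 2,
  "minimal values" background spectrum.
* **Fraction mapping.** For two components, `f = I1/(I1+I2)` (the
  apolar component's share; `f1 + f2 = 1` always). Rendering uses a
  discrete six-colour LUT with bin widths 2,3,3,3,3,2 over [0,1],
  brightness scaled by total intensity; 0/0 pixels are undefined and
  render black. Generalized polarisation is the same information on
  another scale: `GP = 2f − 1`.
* **Gating & band ratios.** 2D intensity histograms with polygon gates
  projected back into the image, and cytometer-style 450/50 vs
  505LP+530/30 band-ratio summaries over cell ensembles.
* **Synthetic scenes.** Ground-truthed vesicle, cell and two-dye
  phantoms with exact linear mixing and Poisson shot noise, so the
  whole pipeline is testable without a microscope.

## Worked example

Simulate a 192×192 px cell phantom (plasma-membrane ring 75% apolar,
cytoplasm 30%, lipid droplets 95%), add shot noise, unmix against the
two-state Gaussian basis, and read compartment fractions back:

```r
library(lambdamap)

grid  <- build_channel_grid(418, 584, 9.8)   # 17 detector channels
refs  <- two_state_refs(grid)                # apolar 440 nm, polar 490 nm
scene <- make_cell_scene(grid, refs, size = 192, seed = 1)
stack <- add_poisson_noise(scene$stack, seed = 2)
stack
#> <lambda_stack> 192 x 192 px (100 nm/px), 17 channels, total counts 2.392e+07

maps <- unmix_fixed(stack, refs, unmix_params(n_iterations = 60))
maps
#> <abundance_maps> 192 x 192 px, 2 components (apolar, polar); 19412 background, 0 saturated px

fmap <- fraction_map(maps)
fmap
#> <fraction_map> 192 x 192 px, 'apolar' fraction; 17452 defined px, median 0.303

lab <- scene$phantom$compartments
median(fmap$fraction[lab == "pm"], na.rm = TRUE)         # 0.750 (GP +0.499)
median(fmap$fraction[lab == "cytoplasm"], na.rm = TRUE)  # 0.300 (GP -0.400)
median(fmap$fraction[lab == "droplet"], na.rm = TRUE)    # 0.950
```

The medians recover the configured compartment compositions from the
noisy stack: the PM ring reads three-quarters ordered, the cytoplasm
disordered-dominated, the droplets strongly apolar. Render and inspect:

```r
img <- colorize_fraction(fmap, lut_six_colour())  # H×W×3 RGB in [0,1]
h2  <- intensity_histogram_2d(maps, n_bins = 64)  # cytometry-style 2D plot
```

A thin command-line interface over the same functions ships in
`inst/cli/lambdamap.R` (subcommands `synth`, `unmix`, `fractionmap`,
`gp`, `gate`, `ratio`, `pipeline`), and `run_pipeline()` drives the
whole chain from one YAML config, writing abundance/fraction TIFFs,
PNG renderings, CSV tables and a reproducibility manifest.

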