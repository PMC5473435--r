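---
title: "Poisson spectral unmixing and fraction mapping of membrane-probe lambda stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson spectral unmixing and fraction mapping of membrane-probe lambda stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lambdamap)
```

## The problem

Solvatochromic membrane probes of the laurdan family report the polarity
of their immediate lipid environment through a large emission shift: in
apolar, dehydrated bilayers (liquid-ordered, Lo) their emission peaks
near 440 nm, while in polar, water-exposed bilayers (liquid-disordered,
Ld) it peaks near 490 nm. Imaging a stained cell in *lambda mode* — a
stack of narrow spectral channels instead of one or two broad detector
bands — captures the full emission spectrum at every pixel. The analysis
problem is then to decompose each pixel's spectrum into the contributions
of known (or unknown) emitting species, and to render the result so that
membrane order differences between compartments are visible and
quantifiable.

`lambdamap` implements that workflow end to end:

1. **spectral model** — channel grids, reference emission spectra, ROI
   spectrum extraction;
2. **unmixing** — per-pixel nonnegative decomposition under a Poisson
   likelihood (fixed-reference and blind NMF modes);
3. **fraction mapping** — fractional intensities, discrete-LUT colour
   rendering scaled by total intensity, GP conversion, 2D intensity
   histograms and polygon gating;
4. **band ratios** — cytometer-style 450/530 band-integrated intensity
   ratios over cell ensembles;
5. **synthetic scenes** — ground-truthed phantoms with Poisson shot
   noise, so that every stage above is testable without microscope data.

## Channel grids

A spectral detector delivers contiguous wavelength bins. We describe a
grid by the lower edge of its first bin, the bin width, and the bin
count; `build_channel_grid(start, end, step)` interprets the stated
endpoints as outer bin *edges* and sets the count to
`round((end - start) / step)`. This is the only reading that reproduces
both standard acquisitions of the instrument class we model: 17 channels
between 418 and 584 nm and 29 channels between 418 and 700 nm, both at
9.8 nm resolution ((584−418)/9.8 ≈ 16.9 and (700−418)/9.8 ≈ 28.8, which
a centre-based reading cannot round to 17 and 29 simultaneously).
Whether the instrument reports edges or centres is not documented
anywhere we could verify, so this is a recorded design decision, not an
instrument fact. All wavelengths are in nm throughout.

```{r grids}
g17 <- build_channel_grid(418, 584, 9.8)
g17
```

## The unmixing model

Each pixel's observed counts $y \in \mathbb{N}^C$ over $C$ channels are
modelled as a nonnegative mixture of $K$ unit-area reference spectra
$S \in \mathbb{R}^{C \times K}$:

$$y_c \sim \mathrm{Poisson}\!\left(\textstyle\sum_k S_{ck}\, a_k\right),$$

and the abundances $a \ge 0$ are estimated by minimizing the generalized
Kullback–Leibler divergence

$$D(y \,\|\, Sa) = \sum_c y_c \log\frac{y_c}{(Sa)_c} - y_c + (Sa)_c,$$

which is, up to a constant, the negative Poisson log-likelihood — the
right objective for shot-noise-limited photon counts, as opposed to the
least-squares objective implicit in "linear unmixing" tools. Because
reference spectra are unit-area, an abundance is the component's total
(channel-summed) intensity at that pixel.

Estimation uses the standard multiplicative KL-NMF update

$$a_k \leftarrow a_k \cdot
  \frac{\sum_c S_{ck}\, y_c / (Sa)_c}{\sum_c S_{ck}},$$

which preserves nonnegativity and never increases the objective. An
epsilon of $10^{-12}$ guards logarithms and denominators; this is the
usual KL-NMF numerical safeguard and is far below one photon count.

### Working parameters

`unmix_params()` carries the working defaults for fixed-spectrum
decompositions of two-photon lambda stacks:

* `n_iterations = 10` — the standard fixed-mode setting. Ten
  multiplicative sweeps are enough for rendering purposes at typical
  SNR; tight quantitative tolerances (our oracle-equivalence tests use
  relative error ≤ 10⁻³) need 100–600 sweeps, which is why the count is
  a parameter and tests raise it.
* `background_threshold = 50` counts — applied to the per-pixel
  **channel sum**. The alternative (per-channel) reading is not
  documented for the original tool; we chose the sum because total
  intensity is also what the fraction mapper thresholds downstream, so
  one consistent convention governs both stages. Background is strict
  (`sum < 50`): a pixel summing exactly to the threshold is fitted.
* `saturation_threshold = 4000` counts — a pixel with **any** channel at
  or above this is flagged. Saturated pixels are excluded from spectrum
  estimation (blind mode and the background spectrum) but are still
  fitted and reported, carrying their flag; whether the original
  analyses also dropped them from abundance output is unstated, so we
  keep them and let the user mask.
* `background_spectrum = "minimal-values"` — the per-channel minimum
  over non-saturated pixels, fitted as one extra *fixed* component and
  dropped from the output. This is our closest reading of the option
  name; on clean synthetic scenes the minimum is all-zero and the
  component is omitted (a zero column is inert under multiplicative
  updates).
* `subsample_stride = 2` ("subsamples, 2") — in blind mode, spectrum
  updates use every second usable pixel; abundance updates always use
  all non-background pixels. This is an interpretation of a tersely
  named option, recorded as such.
* `segregation_bias = 0` — an optional penalty proportional to the
  overlap of normalized abundance maps can be added to the blind-mode
  objective (a multiplicative-update correction in the denominator).
  The exact functional form in the original plugin is not published; our
  term is a stand-in that is exact only at the default 0, which is also
  the only value we ever use.

### Blind mode

`unmix_blind()` alternates spectrum and abundance updates. Each sweep
runs the spectrum half-step first (on the strided pixel subsample), then
renormalizes spectra to unit area (pushing scale into the abundances),
then the abundance half-step over all fitted pixels — so every sweep
*ends* with a step that provably decreases the full objective. With
stride 1 the whole sweep is monotone by the standard KL-NMF argument;
with stride > 1 the spectrum half-step only provably decreases the
subsampled objective, and monotonicity of the full objective is checked
empirically (it held in every configuration we tested, including the
test suite's random stacks). Initialization draws component spectra from
randomly chosen usable pixels (lightly smoothed, seeded RNG) with
uniform abundances; identical inputs and seed give bit-identical
results. Components come back in discovered order — blind NMF is
identifiable only up to permutation, and only the tests, which know the
truth, permute to match.

## Fraction mapping

For a two-component decomposition the fraction map is
$f = I_1 / (I_1 + I_2)$, the first component's share of total unmixed
intensity. Since the two fractions sum to exactly 1, one number indexes
pixel composition. Three conventions matter and are worth stating
prominently:

* **The first component is the apolar one.** High fraction = ordered,
  dehydrated membrane. Flipping the reference order inverts every image
  and statistic.
* **0/0 is undefined, not 0 or 0.5.** Pixels with zero total intensity
  or below the background threshold carry `NA`, render black, and are
  excluded from histograms and statistics. A mid-scale colour at an
  empty pixel would be a lie.
* **GP is an affine alias of the fraction**: generalized polarisation,
  classically $(I_{440} - I_{490})/(I_{440} + I_{490})$, equals
  $2f - 1$ when computed from the same two intensities.
  `gp_map_from_channels()` and `fraction_to_gp(fraction_map(...))` agree
  to machine precision, and the package tests assert ≤ 10⁻¹².

Rendering uses a discrete LUT over $[0,1]$. The default
(`lut_six_colour()`) has six colours from red (polar) to dark blue
(very ordered) with relative bin widths 2,3,3,3,3,2 over a denominator
of 16 — bin edges 0, 2/16, 5/16, 8/16, 11/16, 14/16, 1. The width
digits admit only this reading; bins are half-open with the last closed
so every fraction maps to exactly one colour. Each pixel's colour is
scaled by `min(total/ceiling, 1)` — linear with clipping, no gamma; the
ceiling defaults to the maximum total intensity over defined pixels.

The 2D intensity histogram bins included pixels by their two unmixed
intensities, like a cytometry dot plot; its total count equals the
number of included pixels by construction. Linear binning is the
default and log-scale binning (on $\log_{10}(1+I)$) is offered, since
the convention for such plots varies. Polygon gates drawn in intensity
space project back into the image; the point-in-polygon test counts
boundary points as inside, so a gate drawn as the bounding box of the
data captures every point.

## Band-ratio emulation

Flow cytometers read the same two-state chemistry through filter pairs
rather than spectra. `ratio_450_530()` integrates a spectrum through a
450/50 bandpass ([425, 475] nm) and a 505 long-pass + 530/30 bandpass
([515, 545] nm) and takes the ratio — decoding the standard
centre/width filter codes, with partial channel coverage weighted by
overlap length. The ratio is scale-invariant and strictly decreasing in
the polar mixing weight, which is what makes it a GP-like proxy:
treatments that disorder membranes (e.g. cholesterol depletion) lower
it. Absolute values are instrument-dependent, so the package draws no
quantitative conclusions from them — only orderings and within-run
comparisons, mirroring how such measurements are used in practice.
`ensemble_summary()` reports the mean of per-cell ratios as the primary
statistic, with the ratio of means alongside, because which of the two
a given instrument's software plots is rarely documented.

## The synthetic scenes

All tests and the acceptance script run on generated phantoms whose
per-pixel composition is known exactly:

* `make_mlv_scene()` — disjoint disks of pure components on an empty
  background: the phantom analogue of recording reference spectra on
  multilamellar vesicles of defined composition. The ROI-mean spectrum
  over any vesicle of the noiseless stack equals its reference spectrum
  identically.
* `make_cell_scene()` — one round cell: an annular plasma membrane
  (default thickness 2 px = 200 nm at the default 100 nm pixels, i.e.
  the optical resolution limit), interior cytoplasm, bright circular
  lipid droplets, an empty nucleus. Compartment compositions default to
  PM 0.75 apolar — the literature estimate that the plasma membrane of
  live mammalian cells is about three quarters ordered — cytoplasm 0.30
  and droplets 0.95. The latter two are **placeholders**: no
  quantitative intracellular fractions are established; they were
  chosen once to be respectively disordered-dominated and strongly
  apolar, and the recovery tests test *recovery of the configured
  value*, not biology.
* `make_two_dye_scene()` — a four-component scene (two dyes × two
  polarity states) in which lipid droplets carry both apolar states,
  internal membranes both polar states, and the PM only the first dye's
  apolar state — the qualitative staining pattern of a red
  droplet-seeking dye that leaves the PM unstained. The second dye's
  Gaussian spectra (peaks 590/630 nm) are synthetic stand-ins, not
  measured curves.

Expected counts obey $\mathbb{E}[y] = \sum_k a_k s_k$ exactly;
`add_poisson_noise()` draws one independent Poisson count per voxel.
Scene intensity defaults (channel sums of 1200–3000 counts, peak channel
counts of several hundred) sit in the shot-noise-limited regime of a
typical two-photon acquisition, comfortably above the background
threshold and below saturation. Default scenes are 512×512 px at
100 nm/px to mirror real acquisitions; unit tests use 64–192 px scenes,
which give thousands of pixels per compartment while keeping the full
suite under half a minute.

What the phantoms deliberately do **not** model: realistic morphology,
point-spread blurring (an optional Gaussian blur exists for robustness
checks, off by default), 3D optics, photobleaching, probe kinetics, or
detector read noise. Passing tests therefore demonstrate that the
*algorithms* are correct under the Poisson linear-mixing model they
assume — not that real cellular images will be this clean. On real data
the dominant additional effects are chromatic aberration, spectral
calibration error and out-of-focus light, none of which the unmixer
corrects.

## Numerical choices and degenerate inputs

* Zero-protection epsilon $10^{-12}$ in multiplicative updates (above).
* Reference spectra are unit-area normalized on `reference_set()`
  construction; an all-zero spectrum is a construction error.
* Resampling between grids is linear interpolation at channel centres,
  clipped at zero, with out-of-range channels set to zero; disjoint
  ranges error.
* An all-background stack unmixes to all-zero maps with a warning
  rather than an error, since batch pipelines meet empty fields.
* More components than channels is an error (the system is
  underdetermined).
* Ties in LUT binning: an edge value belongs to the upper bin; a
  fraction of exactly 1 belongs to the last bin.
* Gate polygons must be simple with nonzero area; a repeated closing
  vertex is tolerated and dropped.
* Float-map TIFFs store values affinely rescaled to [0, 1] with the
  offset/scale in a YAML sidecar and `NA` masks as extra pages, because
  the available TIFF writer only stores samples in [0, 1]; round-trips
  preserve values to 32-bit float precision and `NA` exactly.

## Problem sizes

The shipped test-suite and acceptance-script scenes are: 512×512 for
the fraction-conservation check, 192×192 for statistical fraction
recovery (≈1000 PM pixels, ≈15000 cytoplasm pixels), 96–128 px for the
four-component and GP checks, and 64 px for solver-oracle comparisons —
sizes chosen so each quantity is estimated from thousands of pixels
while the whole acceptance run completes in well under a minute on one
CPU.

## Known limitations

* The blind mode's segregation-bias penalty is a documented stand-in,
  exact only at its default 0.
* Monotonicity of the blind objective with `subsample_stride > 1` is
  empirical, not proven (discussed above).
* No proprietary microscope formats (.czi/.lsm); stacks travel as
  multi-page TIFF with a plain-text grid sidecar.
* Saturated pixels are flagged but fitted; their abundances are not
  trustworthy and downstream users should mask them.
* The Gaussian spectral model is symmetric while real laurdan spectra
  are not; all downstream mathematics is shape-agnostic, so this only
  matters if synthetic and measured spectra are mixed in one basis.
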