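---
title: "Quantification methods: kinetic and in situ pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: kinetic and in situ pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cox2quant)
options(cox2quant.quiet = TRUE)
```

cox2quant packages the quantification machinery used to read out
inducible cyclooxygenase-2 (COX-2) from two very different assays: PET
kinetic analysis of a reversible radioligand, and RNAscope-style
fluorescent in situ hybridization (FISH) of the corresponding
transcript. Both pipelines come with synthetic-data generators whose
ground truth is known exactly, so every estimator in the package can be
validated end to end without access to raw scans or slides.

## The kinetic model

Tissue kinetics follow the reversible two-tissue compartment model.
With plasma parent concentration $C_p(t)$ driving the system,

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2, \qquad
  \frac{dC_2}{dt} = k_3 C_1 - k_4 C_2,$$

where $K_1$ (mL cm$^{-3}$ min$^{-1}$) is delivery, $k_2$ (min$^{-1}$)
washout, and $k_3, k_4$ (min$^{-1}$) exchange with the specifically
bound pool. The total distribution volume is

$$V_T = \frac{K_1}{k_2}\left(1 + \frac{k_3}{k_4}\right),$$

reducing to $K_1/k_2$ for one-tissue kinetics. `simulate_tac()` solves
the system by convolving the model's analytic impulse response with
the input function on a fine grid (0.1 min, trapezoidal rule; below
1% quadrature error against an independent ODE solution, which the
test suite checks with `deSolve`), averages within frames, and adds an
optional fractional blood-volume term and frame-level noise with
standard deviation proportional to value over the square root of frame
duration — the count-statistics scaling — without modelling
radioactive decay explicitly: all concentrations are assumed
decay-corrected to injection time, as SUV and $V_T$ presuppose.

The arterial input is a peaked tri-exponential (one rising, two
decaying terms), zero at injection. The defaults (amplitudes 35 and 3
kBq/mL, decays 0.25 and 0.0015 min$^{-1}$, rise 4 min$^{-1}$) were
chosen once to resemble a carbon-11 bolus: peak within the first
minute, terminal level below 10% of peak at 120 min, and a terminal
decay slow relative to the tissue rate constants so that late-scan
tissue-to-plasma ratios approach $V_T$. Metabolite correction uses a
single decaying exponential with plateau,
$pf(t) = (1-c)e^{-\lambda t} + c$ with $0 \le c \le 1$, fitted by
bounded least squares; the functional form is a documented default
(two parameters, monotone, typical of carbon-11 parent fractions) and
is swappable. Interpolation of the built input is linear — not spline
— to avoid overshoot across the sparse late samples of the reference
protocol (15-s draws for 2 min, then 3, 5, 10, 30, 60, 90, 120 min).

## Logan and Lassen estimation

`logan_vt()` forms the Logan coordinates
$x(t) = \int_0^t C_p / C_T(t)$, $y(t) = \int_0^t C_T / C_T(t)$ at
frame midpoints (trapezoid on the frame grid, input resampled to
midpoints) and fits ordinary least squares to the points at or after
$t^*$; the slope is $V_T$. OLS is used because the weighting of the
commercial tool this mirrors is unreported, and the noise-free
recovery this package validates is weighting-independent. $t^*$
defaults to 30 min; `select_t_star()` offers a rule — the earliest
midpoint from which all later points stay within a relative tolerance
of a line fitted to the final third — because no published rule
exists for these data. Logan's transient bias is the known
underestimation: it shrinks with later $t^*$ and longer scans, and for
slow kinetics (small $k_2 k_4$) a 120-min scan leaves a few percent of
it; the package's parameter-box validation therefore runs 240-min
simulated scans with $t^* = 120$, while the reference two-tissue case
($V_T = 2$, 120 min, $t^* = 30$) recovers within 0.5%.

`lassen()` regresses $V_T^{base} - V_T^{block}$ on $V_T^{base}$ across
regions: the slope is the occupancy and the x-intercept the shared
nondisplaceable volume $V_{ND}$; $BP_{ND} = (V_T - V_{ND})/V_{ND}$.
The fit is gated: $r^2$ below 0.5 or a non-positive slope flags the
result unreliable, operationalizing the narrative rejection of plots
that do not support a straight line. The gate threshold is exposed in
configuration. The slope's p-value is the standard two-sided t test,
the test the source did not name. A variant accepts regional SUVs as
a surrogate when no arterial input exists; it is labelled as such
because its validity rests on SUV being proportional to $V_T$, which
cannot be checked without arterial data.

One printed value deliberately does not reproduce: a published
binding potential of 0.21 alongside $V_T = 5.32$ and $V_{ND} = 4.3$,
for which the formula gives 0.237. The formula is implemented as
defined and the discrepancy is carried in `worked_examples()` rather
than forced to agree; the likely cause is an unprinted regional value
upstream.

## The FISH scene generator

`generate_scene()` builds a three-channel field: DAPI nuclei, Cy3
(the COX-2 transcript) and Cy5 (Eno2, a neuronal marker). Nuclei are
ellipses (radius 3.5 ± 0.5 µm) placed by rejection sampling; a
configurable fraction is planted as touching pairs to exercise
watershed splitting. Per-cell spot counts are Poisson. Under the
neuron-weighted coexpression model a `neuron_fraction` (default 0.6)
subpopulation carries the high Cy5 rate, and the non-neuron Cy3 rate
is derived so that the expected fraction of Cy3-positive cells that
are also Cy5-positive equals `coloc_weight` (default 0.75, the
approximate neuronal colocalization reported for this transcript in
primate cortex and putamen). Spots are Gaussian blobs (σ = 1.2 px,
peak 10 noise-SDs) placed within the nucleus plus a 1-µm
peripheral-labelling margin — deliberately inside the 2-µm search
dilation the quantifier uses, which exists precisely to capture
peripheral labelling with margin. Autofluorescent artifacts are
rendered at identical coordinates in Cy3 and Cy5, brighter (1.2×) and
wider (1.5×) than real spots. Pixel size defaults to 0.31 µm
(a typical 20× confocal sampling; the source omits it).

What the generator does not emulate: optics beyond Gaussian blobs
(no Airy rings, no depth dependence), intensity variation between
transcript spots, chromatic misregistration, uneven illumination,
tissue autofluorescence gradients, or 3-D structure. Passing
recovery tests therefore demonstrate that the pipeline's logic is
correct under idealized imaging, not that it would hit the same
numbers on real slides.

## The FISH quantification pipeline

`quantify_image()` chains four stages under one configuration:

1. **Segmentation** — global Otsu threshold on DAPI, connected
   components, watershed splitting (distance transform) of
   cluster-sized components (> 60 µm²), area filter, edge-object
   removal, and 2-µm dilation into per-cell search regions with
   contested pixels resolved to the nearest nucleus centroid.
2. **Spot detection** — per channel, threshold at median + 2 SD of
   the search-region pixels (whole-image scope available), intensity
   watershed to separate touching spots (tolerance one background
   SD), size filter, and assignment by the search region containing
   the intensity-weighted centroid.
3. **Autofluorescence exclusion** — greedy nearest-pair matching of
   Cy3/Cy5 centroids within 1 px; each spot removable once, ties to
   the lowest index. The gate widens by the components'
   equivalent-radius excess over the unit spot when both members are
   oversized, because a merged component's centroid is displaced by
   up to its radius.
4. **Scoring** — per-cell dot counts (components weighted by an
   intensity-estimated multiplicity, see below); a cell expresses a
   transcript at ≥ 2 dots; summaries report expressing fractions,
   colocalization among Cy3-positive cells, and fold changes against
   a reference region.

Three defaults depart from the most literal reading of the upstream
description, each for a measured reason:

* **Nuclear area filter.** A literal "masks greater than 20 µm² are
  excluded" discards essentially every intact nucleus (a 3.5-µm
  nucleus covers ~38 µm²) and is presumably a bound-direction typo.
  The default keeps masks ≥ 20 µm² with no upper bound; the literal
  direction remains available (`min_area_um2 = 0, max_area_um2 = 20`).
* **Spot size filter, [4, 150] px.** At a 2-px minimum, paired noise
  pixels above the threshold pass as spots (about ten false spots per
  default scene); at a 50-px maximum, components formed by several
  merged spots in the dense channel are discarded wholesale. Four
  pixels is still well below a focused spot's ~14-px footprint.
* **Autofluorescence tolerance, 1 px.** Artifacts are the same
  physical object imaged twice, so their centroid disagreement is
  sub-pixel measurement jitter (median 0.15 px in the generator);
  2 px at this sampling spans two spot radii and removes a measurable
  share of real Cy3 spots that coincidentally neighbour dense Cy5
  signal.

**Dot multiplicity.** Two transcripts closer than the optical merge
distance (~0.8 µm at these settings) form a single component that
cannot be split by any intensity watershed. The scorer therefore
estimates each component's dot content as its integrated
above-threshold intensity divided by the channel's unit (median)
component intensity, rounded, after autofluorescence removal —
removal first, so artifacts neither pollute the unit estimate nor
earn multiplicities. The estimate is skipped when fewer than ten
components survive in a channel: below that the unit cannot be
calibrated, and merging is negligible at such densities anyway.
Single-spot and merged-pair intensity distributions are well
separated (99th percentile of singles ≈ 1.3× unit; pairs ≥ 1.75×).

Fold-change scenarios calibrate the control condition to a 5%
expressing fraction (2% for 20-fold, keeping the treated condition at
40%) and pool about 2,050 cells per condition across 22 scenes,
matching the upstream protocol's "> 2,000 cells per area". Recovered
folds run a few percent low because the control denominator carries a
small false-positive floor (~0.4% of cells: boundary spot assignment
and rare unremoved artifacts); this compression is well inside the
±25% validation band.

## Problem sizes and determinism

Validation sizes were chosen to give tight statistics at desk scale:
default scenes are 384 × 384 px (119 µm field) with 100 nuclei;
classification metrics pool 20 scenes (~1,900 matched cells);
Poisson-law checks use 500-cell scenes; kinetic recovery uses 8
regions over 120-min scans and the parameter-box property 240-min
scans. All randomness flows through explicit integer seeds
(`withr::local_seed`; no hidden global state), so every scene, TAC,
demo report and JSON file is byte-reproducible at a fixed seed.

## Known limitations

* No dispersion or delay correction of the arterial line, no
  compartmental (NLS) fitting of individual rate constants, no
  reference-tissue models, and no voxelwise imaging: the kinetic
  stage works at the regional-TAC level.
* The Logan estimator inherits its transient bias for slow kinetics
  within clinical scan lengths; users fitting $k_2 k_4 \lesssim
  0.002$ min$^{-2}$ should extend the scan or defer $t^*$.
* The SUV surrogate of the Lassen plot is reported with its caveat
  flag and should not be interpreted as quantitative occupancy
  without checking SUV–$V_T$ proportionality.
* The FISH pipeline is 2-D, assumes roughly uniform background, and
  scores nuclei-proximal signal only; cytoplasmic transcripts beyond
  the 2-µm ring are invisible to it by design.
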