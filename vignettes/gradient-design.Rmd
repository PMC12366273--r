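---
title: "Designing counter-current growth-factor gradients and quantifying the tissues they grow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing counter-current growth-factor gradients and quantifying the tissues they grow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradientchip)
```

## The problem

A microfluidic chip for vasculogenesis–adipogenesis co-culture feeds a
fibrin hydrogel compartment (1.3 mm x 7.9 mm) from media channels at its
two ends: vasculogenic media on one side, stromal/adipogenic media on the
other. Whether each growth factor actually reaches the cells at a
*bioactive* concentration — at or above its EC50 — depends on how far it
diffuses into the gel before it degrades, and on how often the media is
replenished. `gradientchip` models this transport problem, converts the
resulting concentration fields into design metrics, and provides the
image-quantification tools (vessel-network morphometry, lipid coverage)
used to read out the cultures such chips grow.

## The transport model

Each factor's concentration $C(x, y, t)$ in the compartment obeys a 2D
diffusion equation with first-order decay,

$$\frac{\partial C}{\partial t} =
  D \left(\frac{\partial^2 C}{\partial x^2} +
          \frac{\partial^2 C}{\partial y^2}\right) + kC,
  \qquad k = \frac{\ln 0.5}{t_{1/2}} < 0,$$

where $D$ (um^2/s) is the factor's free-solution diffusivity and
$t_{1/2}$ (s) its half-life in culture media. The model deliberately
ignores cell secretion, matrix binding and hydrogel-altered kinetics:
supplementation and half-life decay are taken to dominate. Media channels
are fixed-concentration (Dirichlet) boundaries whose value also decays by
half-life between media exchanges — the channel holds a static media
volume that degrades just like the compartment contents until it is
replaced. Walls are no-flux.

Parameters for the seven modelled factors (supplemented concentration,
molecular weight, diffusivity, half-life, EC50) ship with the package:

```{r}
t(vapply(default_growth_factors(), function(gf)
  c(C0 = gf$supplemented_conc, D = gf$diffusivity,
    t_half = gf$half_life, EC50 = gf$ec50), numeric(4)))
```

IBMX is not modelled: no usable diffusivity/half-life estimates exist.
The two proprietary adipogenic media are approximated as carrying
dexamethasone (392 ng/mL) and insulin (1000 ng/mL).

### Where the boundary lives: the channel-overlap reading

The device's four media channels run over and under the hydrogel at each
end, overlapping the compartment for 2.6 mm of its length. Because the
model is a 2D plan view, the package's default (`channel_style =
"overlap"`) holds the *full width* of each overlapped end region at the
channel concentration. We also implemented the alternative reading — the
channels as thin in-plane strips clamping only the first/last grid rows
(`channel_style = "edge"`) — and compared both against the seven published
maximum distribution distances for this chip: the overlap reading
reproduces all seven within 0.25 mm, while the edge reading is
systematically short (by up to 0.55 mm for EGF) because the source then
injects through a one-cell-thin strip instead of the channel's full
footprint. The overlap reading is therefore the default; distances carry
a stated +/-0.3 mm tolerance reflecting grid resolution and this
boundary-placement ambiguity.

A channel whose media does not contain a factor is treated as a wall for
that factor, not as a zero-concentration sink: static media neither
supplies nor actively removes it. (Sink treatment measurably caps
long-lived factors' reach at ~5.8 mm and is inconsistent with their
observed full-length coverage.)

## Numerics

The solver is explicit forward-time central-space (FTCS) on a
cell-centred grid (default spacing 0.05 mm, i.e. 158 x 26 cells). The
time step is `0.9 * spacing^2 / (4 D)` — inside the FTCS stability bound
— rounded down so a whole number of steps fits each snapshot interval
(default 0.5 h). Decay is applied as the exact per-step factor
`exp(k dt)`, so a pure-decay problem is integrated without time-step
error and the diffusion-decay splitting error is O(dt). No-flux walls
are mirrored ghost cells, which conserves mass to round-off; boundary
cells are re-clamped after every step. The interior starts at zero
(fresh hydrogel), reservoirs at full supplemented concentration at their
first event.

Verification, all in the test suite: pure decay against the closed form
(0.1%); mass conservation over 10^4 steps (1e-6 relative); the maximum
principle and non-negativity on every snapshot; exact linear scaling in
the supplemented concentration; mirror symmetry under mirrored feeding;
agreement with an independent dense matrix-exponential solution of the
same semi-discrete system on a 5 x 5 grid (< 0.5% RMS); and grid
convergence (halving the spacing moves the day-2 field by < 2% RMS and
a distribution distance by one 0.05 mm cell).

## Design metrics

* **Bioactive fraction** — per snapshot, the fraction of compartment
  cells with $C \ge$ EC50 (threshold inclusive; ties are immaterial at
  float precision).
* **Distribution distance** — the furthest extent from the fed end, along
  the length, at which *any* cell across the width is bioactive, measured
  to the far edge of that cell so full coverage reads the full 7.9 mm. A
  mid-width-profile variant is available (`mid_width_only = TRUE`); for
  the default overlap boundary the field is nearly uniform across the
  width and the two agree, but the any-cell definition is primary because
  the edge-channel variant would otherwise report zero for factors that
  never reach mid-width.
* **Maximum distribution and its time** — the maximum of the distance
  series over snapshots; `time_of_max` is the earliest snapshot achieving
  it and `time_max_ends` the last one still at it. Both are reported at
  snapshot resolution (default 0.5 h). The distinction matters
  scientifically: short-lived factors (IGF-1, VEGF, FGF-alpha) peak
  within hours and recede as their boundary decays below EC50, while
  long-lived factors (FGF-beta, insulin) reach full-length coverage
  within hours and then *hold* it through the full 2-day feeding window —
  their maximal distribution persists to day 2.
* **Limiting factor** — per media side, the fed factor with the smallest
  maximum distribution distance. On the default 2-day runs this
  identifies IGF-1 (vascular), FGF-alpha (stromal) and DEX (adipogenic),
  driven by short half-life (IGF-1), low supplementation-to-EC50 ratio
  (FGF-alpha) and low diffusivity (DEX) respectively.

```{r, eval = FALSE}
fs <- default_growth_factors()
med <- default_media(fs)
res <- simulate_media(list(left = med$vascular,
                           right = med$adipogenic_initiation),
                      chip_geometry(), duration = 2 * 86400,
                      snapshot_interval = 1800, factor_set = fs)
limiting_factor(res, "left")$factor    # "IGF-1"
```

## The feeding schedule

`build_gradient_schedule()` encodes the 31-day co-culture protocol: day-0
loading (vascular one side, stromal the other), day-1 full refreshes,
initiation-media half-exchanges on the adipogenic side on days 3 and 5,
maturation half-exchanges every 2–3 days to day 17, inversion of the
gradient on day 17, and the mirrored pattern to day 31. A half exchange
mixes the decayed reservoir contents 50:50 with fresh media, so repeated
half exchanges converge geometrically on the fresh composition. The
"every 2–3 days" cadence is encoded as the day list
{0, 1, 3, 5, 7, 10, 12, 14, 17, 19, 21, 24, 26, 28, 31}
(config-overridable, since only the cadence is specified). The short
design simulations use `single_loading_schedule()`: one loading at t = 0,
boundaries decaying freely for 2 days — the window between successive
media exchanges.

## Image morphometry

Vessel-network analysis mirrors the standard skeleton-based pipeline:
threshold (user-defined intensity on the 8-bit scale, Otsu by default),
remove small particles (default 500 um^2), fill small holes (default
100 um^2), thin to a one-pixel skeleton (Zhang–Suen, implemented here, with
a corner-cleanup pass that removes redundant staircase pixels), then
count endpoints (skeleton pixels with one neighbour) and junctions
(8-connected clusters of pixels with crossing number >= 3, clustered
within one vessel radius so a thick crossing counts once). Total length
sums skeleton links (diagonals weighted sqrt(2), triangle shortcuts
dropped); total area is the mask area. Terminal skeleton branches
shorter than the typical vessel radius are pruned as thinning artefacts
of rounded caps and bends. Diameters are read from the Euclidean
distance transform at mid-segment skeleton pixels as `2 d - 1` pixels, an
automated surrogate for manual calliper lines between junctions.

Exact numeric parity with any particular GUI tool's internals is not
claimed; the package instead validates against synthetic ground truth
(below). Time-lapse stacks are analysed every n-th frame; the default
endpoint mode analyses one frame per *complete* group of n
(`floor(478/10) = 47` frames for the reference 478-frame stack), with an
inclusive mode (48) also available — the ambiguity between the two
conventions is one frame at the stack's tail.

Lipid coverage thresholds dark droplet-like pixels inside a two-sided
intensity band (default `[0, otsu]`) and reports the percentage of a
region of interest covered — for the whole region, for each length-third
(labelled vasculogenesis / middle / adipogenesis along the chip), and in
370-um bins along the length (last bin may be partial).

## Synthetic data: what it does and does not show

No imaging data accompanies the design study, so validation uses
generators whose ground truth is known by construction and computed from
the generating geometry, never from the rendered image:

* **Vessel networks** — nodes on a jittered lattice, edges between
  lattice-adjacent nodes with a connection probability. This guarantees
  planarity (no tube crossings), so graph degree counts are exactly the
  image's topological truth. Edges render as tubes (widths 14–22 um),
  Gaussian-blurred, with additive Gaussian noise (sd 8 of 255) and
  salt-and-pepper corruption; defaults are chosen so default segmentation
  recovers the truth.
* **Lipid images** — dark non-overlapping discs on a bright background,
  placed until a target area fraction is reached (within 1 point;
  feasible up to ~60%).
* **Time-lapse stacks** — a master network whose active edge subset
  rises to a peak at the end of a configurable rise phase (default 0.5
  days), declines (3.5 days), then plateaus (3 days), emulating the
  three morphogenetic phases of in vitro vasculogenesis: early
  vessel-like structure formation, anastomosis and remodelling,
  maturation.

Passing these tests shows the operators are correct on images whose
truth is known; it does not show agreement with any specific biological
dataset — real micrographs add uneven illumination, out-of-focus light
and genuinely ambiguous topology that no synthetic default captures.

## Problem sizes and reproducibility

The shipped test-suite and acceptance runs use the full default grid
(0.05 mm, 158 x 26 cells) for the seven 2-day factor simulations —
about 20 s total — and 250 x 250 px synthetic images for morphometry.
All generators are pure functions of their spec and seed (bit-identical
reruns); `run_simulate()`/`run_morphometry()` write a manifest with a
config hash and seed, and rerunning a config reproduces its outputs
byte-for-byte.

## Known limitations

* The transport model is 2D and advection-free; no secretion, binding or
  hydrogel partitioning. Parameters were measured in liquid media, so
  absolute distances in fibrin will differ.
* `time_of_max` is quantised to the snapshot interval, and for factors
  whose extent plateaus the "time of maximum" is better characterised by
  the reported persistence window (`time_of_max` through
  `time_max_ends`) than by either endpoint alone.
* Junction clustering within one vessel radius can merge genuinely
  distinct junctions closer than a vessel diameter; at realistic network
  densities this does not occur in the validation suite.
* The lipid threshold band is global per image, as in the manual
  procedure it automates; staining or illumination drift across an image
  is not corrected.
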