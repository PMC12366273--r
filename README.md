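# gradientchip

Transport modelling and image morphometry for microfluidic hydrogel
co-cultures that grow vascularised adipose tissue under counter-current
growth-factor gradients.

A chip's fibrin culture compartment (1.3 mm x 7.9 mm) is fed from media
channels overlapping its two ends: vasculogenic media on one side,
stromal/adipogenic media on the other. Whether a growth factor reaches
cells deep in the gel at a *bioactive* concentration — at or above its
EC50 — is a race between diffusion and degradation. `gradientchip`
answers that design question quantitatively and provides the
morphometric readouts for the resulting cultures.

## What it computes

**Transport.** Each factor's concentration field `C(x, y, t)` obeys

    dC/dt = D (d²C/dx² + d²C/dy²) + k C,      k = ln(0.5) / t½  (< 0)

solved by an explicit (FTCS) finite-difference scheme on a cell-centred
grid (default 0.05 mm). Media channels are fixed-concentration boundaries
whose value itself decays by half-life between media exchanges; chip
walls are no-flux. A schedule engine encodes the full 31-day
vasculogenesis–adipogenesis feeding protocol (full and half media
exchanges, day-17 gradient inversion) as well as the 2-day single-loading
window used for design simulations. Parameters for seven factors
(FGF-α, EGF, FGF-β, IGF-1, VEGF, dexamethasone, insulin) ship with the
package.

**Design metrics.** Fields are summarised as the bioactive area fraction
over time, the maximum bioactive distribution distance from the fed end,
the snapshot times at which that maximum is first reached and last held,
and the limiting factor per media (the shortest-reaching factor of each
side).

**Morphometry.** Vessel-network images are segmented (Otsu or
user-defined threshold, particle removal, hole filling), skeletonised
(Zhang–Suen thinning) and measured: junction count, endpoint count,
total vessel length, total vessel area, and diameter from the distance
transform. Time-lapse stacks are analysed every n-th frame. Brightfield
lipid images yield percentage coverage for a region of interest, its
length-thirds, and 370-µm bins along the compartment.

**Synthetic data.** Generators render ground-truthed vessel networks,
lipid-droplet images, morphogenesis time-lapses and analytic PDE test
cases, so the whole pipeline is validated without any external data.

## Worked example

Simulate IGF-1 fed from the vasculogenic end for the 2-day window between
media exchanges, and summarise its bioactive reach:

```r
library(gradientchip)

fs    <- default_growth_factors()
geom  <- chip_geometry()                       # 1.3 x 7.9 mm, 2.6 mm channels
med   <- default_media(fs)
none  <- media_composition("none", setNames(numeric(0), character(0)), fs)
sched <- single_loading_schedule(med$vascular, none, duration_days = 2)

fld <- simulate_factor(fs[["IGF-1"]], geom, sched, sim_grid(geom),
                       snapshot_interval = 1800, factor_set = fs)
fld
#> <concentration_field> IGF-1: 26 x 158 cells, 97 snapshots over 2.00 days, max 15 ng/mL

distribution_report(fld, "left", factor_set = fs)
#> <distribution_report> IGF-1 (fed left): max distribution 2.75 mm at 0.5 h; peak bioactive fraction 0.35
```

IGF-1 barely escapes the 2.6 mm channel-overlap region: its 24-minute
half-life kills the boundary supply within the first hour, so only about
a third of the compartment ever sees a bioactive (≥ 5 ng/mL) dose, and
that maximum is reached half an hour after feeding. Long-lived factors
(FGF-β, insulin) instead cover the full 7.9 mm and hold it through day 2.
Running all factors of a media pair and asking which limits each side:

```r
res <- simulate_media(list(left = med$vascular, right = med$adipogenic_initiation),
                      geom, duration = 2 * 86400, snapshot_interval = 1800,
                      factor_set = fs)
limiting_factor(res, "left")$factor   # "IGF-1"  (vascular side)
limiting_factor(res, "right")$factor  # "DEX"    (adipogenic side)
```

`run_simulate()` wraps this into a config-driven run that writes field
CSVs, heatmap PNGs, a JSON design report and a manifest;
`run_morphometry()` does the same for directories of images.

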