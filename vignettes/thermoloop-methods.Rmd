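---
title: "thermoloop: model, controller and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermoloop: model, controller and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoloop)
```

`thermoloop` couples three components — a bioheat plant model, a virtual
infrared array and a feedback controller — so that closed-loop
temperature-controlled laser irradiation can be studied without hardware.
This vignette documents the model and its assumptions, the parameters that
matter, the numerical choices, and what the virtual testbed can and cannot
say about the physical system it emulates.

## The plant: ex vivo bioheat conduction with Beer–Lambert deposition

The sample is a disc-shaped slab (default radius 2 cm, thickness 6.5 mm,
matching ~6–7 mm bench samples) heated on axis by a laser spot. Because both
the slab and the beam are rotationally symmetric, the temperature field is
solved on a 2-D axisymmetric r–z grid. The governing equation is the bioheat
equation for excised tissue — plain conduction with a volumetric source:

$$\rho c \,\frac{\partial T}{\partial t} = k \nabla^2 T + Q(r, z, t),$$

with no perfusion and no metabolic term (the samples are ex vivo and stored
in saline). The source is pure Beer–Lambert absorption,

$$Q(r, z) = \mu_a\, I(r)\, e^{-\mu_a z},$$

with scattering deliberately ignored: the two sample types are characterized
in the literature by their absorption coefficient alone, and the controller
under study only distinguishes "absorbs strongly" from "absorbs weakly".
The consequences of this simplification are discussed under *Limitations*.

Key physical parameters, all configurable:

| parameter | default | unit | rationale |
|---|---|---|---|
| μₐ agar | 0.15 | cm⁻¹ | below the 0.20 cm⁻¹ bound reported for agar at ~800 nm |
| μₐ liver | 0.9 | cm⁻¹ | midpoint of 0.80 (porcine) – 0.99 (rat) at 808 nm |
| agar k, ρ, c | 0.6, 1000, 4186 | SI | water-like (agar gel is ~96 % water) |
| liver k, ρ, c | 0.52, 1060, 3600 | SI | literature-typical soft tissue values |
| beam | 3 W max, flat-top, 0.85 cm² | — | emulated diode and spot geometry |
| ambient / initial | 25 | °C | room-temperature storage; not reported for the bench system, so a plain room temperature is assumed |
| top surface h | 10 | W/(m²K) | free convection in still air |
| side/bottom BC | ambient Dirichlet | — | sample resting on a large dish |

The beam profile defaults to flat-top (uniform irradiance over the spot); a
Gaussian option with the same effective area is provided for sensitivity
studies. Under the flat-top default the surface temperature is radially
non-increasing from the axis, which is what makes the "four central pixels
read the hottest region" convention meaningful.

## Numerical scheme

The solver is a cell-centered finite-volume discretization in cylindrical
coordinates with explicit Euler time stepping:

* **Conservation.** Fluxes are written between cell pairs, so with insulated
  boundaries and no source the volume integral of ρcT is conserved to
  machine precision, and per-call energy bookkeeping (absorbed power in,
  boundary losses out, internal energy change) closes exactly. The test
  suite asserts closure to well under 1 % over heated windows.
* **Stability.** The explicit step is bounded by
  `dt ≤ min(ρcV / ΣG)` over cells (`G` = face conductances including the
  boundary films). `advance_field()` sub-steps at 90 % of this bound and
  always lands on the requested end time exactly, so sensor frames (every
  1/3 s) and controller ticks (every 0.35 s) occur at their nominal times
  with no drift. A user-supplied `dt` beyond the bound is rejected.
* **Deposition.** Each cell receives the exact integral of the Beer–Lambert
  source over its volume (closed-form in both r and z), so the map integrates
  to `P(1 − e^{−μₐL})` exactly and monotonicity in μₐ holds cell-wise.
* **Verification.** The solver is checked against the constant-flux
  semi-infinite-slab solution `ΔT_s = (2q/k)√(αt/π)` (agreement within 2 %,
  compared at the first cell-center depth, which is what the surface node
  represents), and a grid-refinement study (64×32 vs 128×64 cells changes
  the 60 s surface temperature by < 0.1 % of the rise). The default 64×32
  grid is therefore well inside the converged regime while keeping a full
  300 s closed-loop run to a couple of seconds of compute.

## The virtual sensor

The emulated device is a 32×32 thermopile array, 25 mm above the sample with
a ~33° field of view, operated at 3 Hz (the hardware supports 2–27 Hz). The
footprint is modelled as a square of side `2·d·tan(FOV/2)` ≈ 14.8 mm centered
on the beam axis; the oblique mounting angle of the physical setup is ignored
because the device is used only after manual centering, and no emissivity
model is applied (the hardware is factory-calibrated). Each pixel averages
the true surface temperature over a 3×3 sub-grid of its footprint cell and
adds independent Gaussian noise.

The noise standard deviation is **not** documented for the hardware; the
reported ±0.39 °C stability of controlled runs conflates sensor and process
noise. The default `noise_sd = 0.1` °C is a plausible single-frame pixel
noise for a small thermopile array and is configurable; all stochastic tests
draw it from a seeded stream, and runs with the same seed are bit-identical.

The controller's process variable is `center_average()`: the mean of the 2×2
pixel block at rows 16–17, columns 16–17 (1-based; the code stores pixels as
an R matrix, so the same block is `pixels[16:17, 16:17]`).

## The controller

The control loop refreshes every 350 ms and always consumes the most recent
completed frame (zero-order hold — the 3 Hz sensor and the loop are
asynchronous, so a frame may serve one or two ticks and stale frames are
flagged in the log).

**Discrimination.** For the first 5 s the loop is live with the fast-sample
gain (g = 0; starting 17.5 °C below a 42.5 °C target this commands full
power). At the first tick at or after t = 5 s the rise since the first
measurement selects the gain once and for all: rise > 5 °C → g = 0,
otherwise g = 30. The inequality is strict — a rise of exactly 5 °C selects
the slow law.

**Regulation.** With ΔT = measured − target, the output in percent of the
3 W maximum is

* 100 if ΔT < −1.0 °C,
* `floor_percent` if ΔT > +0.6 °C,
* `(50 + g) − ΔT·(50 − g)` otherwise, clamped to [0, 100].

Design notes, where the device's published description left choices open:

* *Floor above the band.* The hardware description only says the drive is
  "reduced" above target + 0.6 °C. `floor_percent = 0` (laser off) is the
  default as the safest reading; it is configurable, and the in-band formula
  already reaches only 20 % (g = 0) or 68 % (g = 30) at the upper edge.
* *Clamping.* The formula output is interpreted as percent of maximum power
  and clamped to [0, 100]; 100 % is explicitly 3 W, and at the lower band
  edge the formula equals exactly 100 for every g — the full-power override
  is continuous with the formula (an algebraic identity the tests assert).
* *Signed difference.* ΔT is signed (measured − target); negative errors
  raise the output, consistent with the threshold overrides.
* *Boundary ties.* ΔT exactly at a threshold falls into the formula branch:
  the overrides use strict inequalities, mirroring "smaller than −1.0" /
  "larger than 0.6".
* *Drive during discrimination.* The loop is assumed active with g = 0
  during the window (the gain is documented as "initially zero"), which at
  room-temperature starts means full power — the rise measured by the
  discrimination step is a full-power rise.
* *Current calibration.* The physical current↔power curve is not available;
  it is modelled as the standard laser-diode form, linear above threshold:
  `I = I_th + (I_max − I_th)·P/P_max` with defaults `I_th = 0.4 A`,
  `I_max = 4.0 A` typical of a 3 W 808 nm diode. Both directions are exact
  inverses, which the equivalent-fixed-power protocol relies on.

## Protocols and what the testbed shows

`run_temperature_controlled()` co-simulates plant, sensor and controller.
`run_fixed_power()` is the open-loop contrast: the *equivalent* power is
computed by trapezoidal integration of the paired controlled run's current
trace divided by the duration, then mapped through the inverse calibration —
within the simulation, not taken from bench current values, which depend on
hardware calibration. `run_replicates()` repeats with seeds
`seed + 0:(n−1)`, mirroring three-fold bench repeats.

Under the default study conditions (liver-like sample, 42.5 °C target,
300 s), the closed loop ramps at full power, and after the ramp the measured
temperature is regulated inside the band [41.5, 43.1] °C, settling near the
upper threshold; the paired fixed-power run delivers the same integrated
current but crosses the band and keeps heating — the qualitative separation
the feedback exists to produce. The post-ramp analysis window defaults to
the final two-thirds of a run and is always reported alongside the
statistics, since the bench reports do not state their averaging window.

**A caveat the testbed makes explicit.** With absorption-only optics and the
default thermal parameters, the liver-like sample's five-second full-power
surface rise is ≈ 4 °C — *below* the 5 °C discrimination threshold — so the
virtual controller classifies both built-in samples as slow-heating
(g = 30). Physically, the absorption depth 1/μₐ ≈ 11 mm spreads the
deposited power through the slab, whereas real liver scatters strongly at
808 nm, confining fluence near the surface and heating it faster; the
hardware threshold was calibrated against that reality. The discrimination
*rule* is therefore exercised exactly at unit level (both branches), and the
closed-loop tests assert that the locked-in gain is consistent with the
simulated rise rather than with the bench classification. Raising μₐ or
adding an effective attenuation coefficient would flip the classification,
but would misrepresent the stated optical properties, so the defaults stand.

Because the slow law's minimum in-band output (68 %) exceeds the ~40 %
steady-state demand of the liver-like sample at 42.5 °C, the regulated
trajectory rides the +0.6 °C override — small oscillations around 43.1 °C —
rather than sitting at the formula's fixed point. This is faithful to the
algorithm; bench liver runs likewise settle near the top of the band.

## Reporting

`summarize_run()` reports mean, sample SD, extremes and quartiles
(linear-interpolation convention, `quantile(type = 7)`) of the measured
temperature over the analysis window. `arrhenius_damage()` integrates
Ω(t) = ∫A·exp(−Eₐ/RT)dτ by the trapezoidal rule (temperatures converted to
kelvin; halving the sampling step changes Ω(300 s) by < 0.1 % on smooth
traces). Kinetic constants are tissue-specific and not fixed by the emulated
device; `arrhenius_presets()` ships the classic Henriques–Moritz skin fit
(A = 3.1×10⁹⁸ s⁻¹, Eₐ = 6.28×10⁵ J/mol) and a literature-typical liver
coagulation fit (A = 7.39×10³⁹ s⁻¹, Eₐ = 2.577×10⁵ J/mol).

Runs persist as CSV plus a JSON metadata sidecar (schema version, material,
seed, configuration and an FNV-1a configuration fingerprint); sensor frame
logs round-trip through CSV and can be replayed through `run_loop()`, which
reproduces the logged commands exactly.

## Problem sizes used by the test suite

Unit tests run on coarse grids (16×8 to 48×24 cells) where the physics
contracts are grid-independent; the solver verification and the end-to-end
closed-loop checks use the full default conditions (64×32 grid, 300 s runs,
with one 128×64 refinement run), which keeps the whole suite under a minute
on a single core.

## Limitations

* Optics: no scattering, no temperature- or damage-dependent optical
  properties, no charring or moisture loss; fluence is attenuated only by
  absorption. Surface heating rates of strongly scattering tissue are
  underestimated (see the discrimination caveat above).
* Geometry: normal incidence, perfectly centered beam and sensor; no 3-D
  misalignment.
* Sensor: no emissivity model, dead pixels or self-heating; noise is white
  and Gaussian.
* Controller: the proportional law as documented, not a PID; microcontroller
  timing jitter is not modelled (the loop ticks at exactly 350 ms).
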