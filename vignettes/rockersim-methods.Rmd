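---
title: "Methods: flow, shear and thermal models in rockersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow, shear and thermal models in rockersim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rockersim)
```

`rockersim` characterises a seesaw rocking platform for biofilm incubation:
the free-surface flow in a rectangular culture-plate well, the wall shear
stress on the growth surface, the resonance between rocking and the
travelling wavefront, equivalent laminar pipe-flow conditions, and the
Peltier/PID temperature control loop. This vignette records the models, the
parameters that matter, the numerical choices, and — importantly — what the
models can and cannot be expected to reproduce quantitatively.

## Geometry and kinematics

A well is a flat-bottomed channel of length $L = 8$ cm. The published device
description fixes $L$ and the 24 mL capacity but not the width; we default
to $W = 26$ mm, the footprint of the microscope slides the wells are sized
for, which puts the capacity at a plausible 11.5 mm depth against the 14.5 mm
plate height. Width only enters through the volume-to-depth conversion
$h = V/(LW)$ (5 mL $\to$ 2.40 mm, 9 mL $\to$ 4.33 mm).

The tilt $\theta(t)$ is a triangular wave of amplitude $\alpha$ traversed at
constant rate $\omega$, the two quantities the device exposes (1–19 degrees,
1–99 deg/s). We place the pivot at the channel mid-point at floor level; the
actual pivot height is not published, and a different height adds only a
small vertical acceleration that is immaterial at these speeds. The phase
convention is $\theta(0) = +\alpha$ (right end down). With instantaneous
reversals the period is $T = 4\alpha/\omega$. With a finite reversal
acceleration $a$ each reversal lasts $t_r = 2\omega/a$; working out the
trapezoidal speed profile that still reaches $\pm\alpha$ exactly gives
$T = 4\alpha/\omega + 2\omega/a$ — each reversal adds $t_r$ but also advances
the tilt, shortening the cruise phases by half of it. The default is
instantaneous reversal, which is what the $60/(4\alpha)$ RPM conversion
implies.

## Free-surface flow model

Fill depths (2–4 mm) are thirty times smaller than the channel length, so we
model the layer with the 1D shallow-water equations in the co-rotating frame
rather than a full two-phase Navier–Stokes computation. On the flat tilting
bed, gravity splits into a bed-parallel drive $g\sin\theta$ and a normal
component $g\cos\theta$; this is exactly equivalent to shallow water over a
linear bathymetry $b(x) = -x\tan\theta$ under gravity $g\cos\theta$, the
form the solver uses. Rotating-frame (centrifugal and Euler) accelerations
are at most a couple of percent of $g$ at the device's maximum angular speed
($\approx 1.7$ rad/s) and are therefore off by default
(`include_euler_forcing`).

Bed friction uses the laminar parabolic-profile closure: a thin film in
local viscous equilibrium has a semi-parabolic velocity profile, giving the
depth-averaged drag $3\mu u/h^2$ per unit mass and the wall shear stress

$$\tau = \frac{3\mu u}{h}.$$

The momentum flux keeps the conventional plug-flow coefficient
($\beta = 1$). We evaluated the profile-consistent Boussinesq value
$\beta = 6/5$: the sloshing bulk is inertia-dominated and far from the
viscous-equilibrium profile, so applying the parabolic correction everywhere
is not better physics, and the standard shallow-water form is retained.

### Numerics

* Finite-volume scheme, 400 cells by default over $[-L/2, L/2]$; reflective
  walls.
* Piecewise-linear reconstruction of surface elevation $h + b$ and discharge
  $q$ with minmod limiting; slopes are dropped next to dry cells.
* HLL flux with a hydrostatic-reconstruction bed source, which preserves a
  lake at rest on any fixed tilt to machine precision (the suite asserts
  $\max|u| < 10^{-10}$ m/s) and vanishes on a level bed.
* SSP-RK2 in time with an adaptive step from a CFL number of 0.4 on
  $|u| + \sqrt{g\cos\theta\, h}$.
* Wetting/drying: cells below `dry_threshold` ($10^{-6}$ m) carry no
  momentum; a donor-cell limiter scales outgoing fluxes so no cell drains
  negative within a step. Because the limiter scales the interface flux
  itself, mass stays conserved exactly (observed drift $\sim 10^{-15}$ over
  20 periods against a $10^{-8}$ requirement).
* Friction is applied as an unconditionally stable semi-implicit split step,
  which matters in thin films where $3\nu/h^2$ is stiff.
* Runs start from fluid at rest pooled under the initial tilt, advance five
  spin-up periods, then record one period at 1 kHz. One extra spin-up period
  changes the period-averaged shear map by under 0.01%, so the recorded
  period is fully developed. The solver contains no randomness.

Grid convergence on the period-averaged shear map contracts monotonically
over 100–800 cells, and the headline maxima change by under 2% from 200 to
1600 cells; 400 cells is the accuracy/runtime default (a seven-speed sweep
runs in a few seconds).

Oracle validations in the test suite: the inviscid dam break against the
closed-form Ritter rarefaction (L1 depth error 0.5%, required < 2%), small
surface pulses travelling at $\sqrt{gh}$ within 5%, and mirror symmetry of
period-averaged maps within 2%.

## What the shear maps do and do not reproduce

Two independent checks show the *flow* is right. First, simulated wavefront
velocities at the channel centre for a 9 mL fill — 16, 24 and 29 cm/s at 30,
40 and 50 deg/s — agree closely with the published measurements and with the
resonance formula $\nu = \omega L/(2\alpha)$ (17, 23, 29 cm/s). Second, the
period-averaged shear map attains its maximum at 25–30 deg/s, inside the
published 25–50 deg/s resonance window and next to the shallow-water
estimate $\omega^* = 2\alpha\sqrt{g\bar h}/L \approx 27$ deg/s for 5 mL.

The shear *magnitudes*, however, sit about a factor two below the published
finite-element (Navier–Stokes) values: our sweep maxima are roughly
0.24 N/m² period-averaged and 0.9–1.1 N/m² instantaneous, against 0.46 and
2.4 N/m². This is a structural property of the depth-averaged closure, not a
resolution artefact (the values are grid-converged). A resolved 2D
simulation develops a transient boundary layer of thickness
$\delta \sim \sqrt{\nu t} \approx 0.2$–0.5 mm during each flow reversal and
end-wall impact; its instantaneous wall shear $\mu u/\delta$ exceeds the
equilibrium-film value $3\mu u/h$ severalfold precisely where and when the
peaks occur. Users who need absolute peak magnitudes should treat the
`rockersim` maps as lower bounds with the correct spatial pattern, speed
dependence and resonance location. Thin-film clinging to the substrate
(observed in dyed-water experiments) is likewise not modelled: dry cells are
fully dry, which tends to make simulated fronts slightly fast.

## Wavefront detection and velocimetry

`detect_front` tracks the outermost crossing of a depth threshold in each
snapshot, interpolated linearly between cells, splits the trajectory into
monotone traversals and keeps those passing the channel centre, where
velocity is measured. In these simulations the shallow end retains a
0.5–1 mm dynamic film rather than drying out, so the advancing feature is a
bore; a threshold around 0.7 of the mean fill depth separates the film ahead
of the bore from the surge behind it and tracks the bore front. Above the
resonance region the sloshing amplitude drops and no contour traverses the
centre — the simulated counterpart of the wavefront becoming less pronounced
off resonance.

`coc_velocity` fits position against time by ordinary least squares within
±2 cm of the centre (the published protocol) and reports the slope standard
error. The synthetic trace generator emulates a 50-frames-per-second camera
recording. Its default position noise follows the worked example
(0.5 mm); for tests that emulate the published fit precision (slope SE
below 0.2 cm/s) we use 0.15 mm, because the OLS slope-variance formula
$\mathrm{SE} = \sigma/\sqrt{S_{tt}}$ shows that at 50 Hz and a ±2 cm window
the faster fronts (0.35 m/s) leave only ~6 frames in the window, requiring
$\sigma \lesssim 0.17$ mm to reach that precision — consistent with
sub-pixel dye-edge localisation. Box-plot summaries use linear-interpolation
quartiles and the 1.5 IQR outlier fence stated with the published figures.

## Pipe equivalence

Fully developed laminar pipe flow gives $\tau = 4\mu Q/(\pi R^3)$,
$Q = \pi R^2 U$, so $\tau = 4\mu U/R$. The equivalence chart masks
conditions with $Re = \rho U d/\mu > 2100$ and shear outside the range a
supplied sweep map shows to be achievable; the default mask basis is the
peak map (most permissive), with the averaged basis selectable since the
published chart does not say which it used. Built-in scenarios carry the
published figures: urethral catheters (12/18 Fr, literature velocity ranges
— no pressure-to-flow model is published, so these are quoted, not
recomputed), venous catheters (16/24 G), hemodialysis (5 mm bloodlines and
9 mm pump tubing at 200–400 mL/min), and household drinking-water pipes
(1.0–2.5 cm). For the last, the source text's "1 L/s" is dimensionally
inconsistent with its own printed velocities of 21–3.4 cm/s, which require
1 L/min; the package defaults to 1 L/min and leaves the L/s reading
selectable.

## Thermal control

The Peltier stage, aluminium holder and well water form two lumped nodes
(holder+stage, water) with linear conductances between them and to ambient.
Defaults: $C_\mathrm{plate} = 180$ J/K ($\approx 200$ g aluminium),
$C_\mathrm{water} = 117$ J/K (four wells at 7 mL),
$k_\mathrm{plate\to water} = 2$ W/K, leakages 0.5 and 0.2 W/K, heating limit
40 W and cooling limit 20 W (Peltier cooling is the weaker direction, which
is what bounds the reachable floor temperature). These were chosen once so
step responses settle on the minutes scale like the hardware (simulated:
about 3 min to 37 °C and 7 min to 4 °C within 0.5 °C, from 21 °C ambient;
the hardware reports 8 and 15 min) — qualitative fidelity is the goal, as
the true values are hardware-specific. Spatial gradients (reported as a few
tenths of a degree at the plate corners) are outside a lumped model.

The PID controller is the standard discrete positional form with clamped
integral and output saturation to ±1 duty; PWM at 490 Hz is far faster than
any thermal time constant, so the actuator sees the duty-cycle mean. The
controller samples the water node by default (matching an in-well sensor);
with integral action the steady-state water error is below 0.05 °C, and with
proportional-only control the simulation matches the hand-derived droop of
the two-node steady state exactly. Integration uses fixed Euler substeps at
least twenty times shorter than the fastest node time constant — the plant
is linear within each controller interval, so this is cheap and robust.
Thermistors use the beta equation (the published description names no
specific law; the three-coefficient Steinhart–Hart form would be a drop-in
extension).

`fit_plant_parameters` recovers plant constants from a logged trace by
replaying the recorded duty open loop and least-squares matching both
temperature channels (Nelder–Mead on log-parameters). From a synthetic trace
with 0.05 °C sensor noise it recovers $C_\mathrm{water}$ and
$k_\mathrm{plate\to water}$ within a few percent.

## Reproducibility and scale choices

All fixtures are generated in code under explicit seeds and leave the
caller's RNG stream untouched; the flow and thermal simulators are
deterministic. Default problem sizes — 400 cells, five spin-up periods, one
recorded period, seven-speed sweeps — were chosen so a full
characterisation runs on a laptop in seconds while staying within 2% of
grid-converged values; finer grids and the published 4–100 deg/s speed grid
are plain configuration changes.

## Known limitations

* Depth-averaged shear underestimates reversal/impact peaks (factor ~2;
  see above). No transverse (width-wise) waves, so side-wall effects at the
  lowest speeds are absent.
* No surface tension or contact-angle physics: no clinging film on
  receding, and menisci are ignored.
* The laminar pipe formulas are for water; blood and other non-Newtonian
  fluids are out of scope, as is any turbulent-regime shear model.
* The thermal model has no Peltier device physics (Seebeck/Joule
  asymmetry) beyond asymmetric power limits, and no spatial gradients.
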