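# rockersim

Flow, wall-shear and thermal simulation for seesaw rocking platforms used to
incubate bacterial biofilms in rectangular culture-plate wells.

Biofilm growth on a surface depends strongly on two environmental variables:
temperature and the wall shear stress exerted by the liquid flowing over the
growth surface. Laboratory rockers generate that flow by periodically tilting
a culture plate so a wave of medium washes back and forth along each well.
`rockersim` models this device class end to end, for researchers who want to

* translate rocker settings (tilt amplitude, rocking speed, fill volume) into
  the shear stress a biofilm actually experiences,
* match rocker conditions to real-world laminar pipe scenarios where biofilms
  cause problems (urinary and venous catheters, hemodialysis lines,
  drinking-water pipes), and
* simulate the Peltier/PID temperature control loop that holds the wells at
  setpoints from psychrotrophic (down to a few degC) to thermophilic ranges.

## Models

**Free-surface flow.** The liquid layer in one well (channel length
L = 8 cm, width 26 mm, fill depths of a few millimetres) is simulated with
the 1D shallow-water equations in the co-rotating frame of the tilting
channel. The tilt theta(t) enters as an equivalent linear bathymetry
b(x) = −x·tan(theta) under reduced gravity g·cos(theta). The solver (C++ via
Rcpp) is a well-balanced finite-volume scheme: minmod-limited piecewise
linear reconstruction of surface elevation and discharge, HLL fluxes, SSP
Runge-Kutta time stepping under a CFL condition, wetting/drying with a
donor-cell flux limiter that keeps depths non-negative and mass conserved to
machine precision. Bed friction and wall shear use the laminar
parabolic-profile closure

    tau = 3 mu u / h,

the thin-film Poiseuille result for depth-averaged velocity u.

**Rocking kinematics.** The tilt is a triangular wave of amplitude alpha
(degrees) traversed at constant speed omega (deg/s), with optional
acceleration-limited reversals; with instantaneous reversals the period is
T = 4 alpha / omega, which also gives the RPM conversion factor
60/(4·alpha) = 2.143 at alpha = 7 deg. A travelling wavefront resonates with
the rocking when it crosses the channel in one half-period, at velocity

    nu = omega L / (2 alpha).

**Pipe equivalence.** Fully developed laminar pipe flow obeys
tau = 4 mu Q / (pi R^3) with Q = pi R^2 U; `rockersim` charts tau over bulk
velocity and diameter, masking turbulent conditions (Re > 2100) and shear
levels the rocker cannot reach, with built-in catheter/hemodialysis/
drinking-water scenarios.

**Thermal control.** The Peltier stage, aluminium sample holder and well
water are modelled as two lumped thermal nodes under a discrete PID
controller with anti-windup and output saturation (PWM represented by its
duty-cycle mean); NTC thermistor readings are converted through the beta
equation.

## Worked example

```r
library(rockersim)

geom <- well_geometry()                       # 8 cm x 26 mm, 24 mL well
prof <- make_motion_profile(motion_settings(max_angle = 7, max_speed = 40))
prof
#> motion_profile: +/-7 deg at 40 deg/s, period 0.700 s

rocking_speed_to_rpm(40, 7)                   # 85.7 RPM equivalent
resonance_velocity(40) * 100                  # 22.9 cm/s resonant wavefront
resonant_speed_estimate(geom, 5e-6)           # 26.9 deg/s from sqrt(g h)

rec <- simulate_rocking_flow(geom, fill_volume = 5e-6, prof,
                             water_properties(37), solver_config())
rec
#> shear_record: 702 samples x 400 positions, fill 5.0 mL, 40 deg/s at +/-7 deg
#>   peak |tau| 0.347 N/m^2, volume drift 4.2e-16
```

The record holds wall shear stress, depth and velocity at 1 kHz over one
rocking period after spin-up. At 40 deg/s the shear peaks at 0.35 N/m^2 near
the channel ends — about 11.6 pN on a single attached cell
(`force_on_cell`) — and stays above 0.3 N/m^2 for at most 15 ms per period
(`peak_and_exceedance`). The matching laminar pipe condition is computed
directly:

```r
q <- 200e-6 / 60                              # 200 mL/min, a dialysis line
pipe_wall_shear(q, R = 2.5e-3, mu = water_properties(37)$mu)  # 0.188 N/m^2
bulk_velocity(q, 2.5e-3) * 100                # 17 cm/s
```

A full speed sweep (`speed_sweep`) stacks one period-averaged and one peak
shear profile per rocking speed into a map; `find_resonant_speed` locates
the sweep row with the strongest shear, and `equivalence_grid` masks the
pipe chart to the range that map shows to be achievable.

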