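---
title: "Methods: a virtual-flux lattice Boltzmann model of hovering flapping flight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual-flux lattice Boltzmann model of hovering flapping flight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`flapwing` simulates a hovering fruit-fly-scale insect: two rigid,
zero-thickness rectangular wings beating at 218 Hz, driven by prescribed
three-angle kinematics, coupled to an incompressible lattice Boltzmann
fluid through a virtual-flux immersed boundary.  This vignette records the
model, the conventions and parameter choices that are not forced by the
equations, and the numerical decisions a maintainer would want to know.

## The wing model and its kinematics

The insect is reduced to its two wings (hovering lift is insensitive to the
body): rectangles of mean chord $C_m = 0.78$ mm and span $R = 2.39$ mm,
flapping at $f = 218$ Hz with cycle-mean tip speed
$\bar u_{tip} = 2.58$ m/s in air
($\nu = 1.5\times10^{-5}\ \mathrm{m^2/s}$, $\rho = 1.2\ \mathrm{kg/m^3}$).
The wing-tip Reynolds number is
$Re = \bar u_{tip} C_m / \nu \approx 134$; sweeping the tip speed
(0.645–10.32 m/s, with the frequency scaled in proportion) gives
$Re \approx 33.5$–$536$.

Each wing's orientation combines three rotations (angles in degrees,
time in seconds):

$$\theta_p = \theta_{p,amp}\cos(2\pi f t + \varphi_p), \qquad
  \theta_f = \theta_{f,amp}\sin(2\pi f t + \varphi_f), \qquad
  \theta_e = \theta_{e,amp}\cos(2\pi\,(2f)\,t - \varphi_{e0}) + \varphi_e,$$

with defaults $70/70/10$ for the amplitudes and $10/0/10$ for the phase
offsets.  The elevation angle oscillates at **twice** the wingbeat
frequency; its initial phase $\varphi_{e0}$ selects the shape of the
wing-tip path: a planar stroke when $\theta_{e,amp}=0$, a U-shaped path at
$\varphi_{e0}\in\{0^\circ,180^\circ\}$, and a self-intersecting
figure-eight otherwise (`tip_trajectory()` and
`count_self_intersections()` classify these).

Conventions the equations do not fix, chosen once:

* **Axes.**  $z$ is vertical (lift is $F_z$), the stroke plane is
  horizontal.  The positional rotation is about $z$, elevation about the
  lab $y$ axis, feathering about the spanwise wing axis, composed
  lab-to-wing in that order.  For the elevation rotation about the fixed
  $y$ axis to be meaningful the wing reference span must lie along $x$;
  the two wings are therefore mirror images through the $y$–$z$ plane
  (body axis along $y$), and both tips rise and sweep fore–aft together,
  as hovering insects do.
* **Feathering reference.**  The chord is vertical at stroke reversal
  (where the feathering angle crosses zero) and pitches to $20^\circ$
  above the stroke plane at mid-stroke.  The feathering axis is the
  mid-chord line.
* **Root separation.**  The wing hinges sit $0.5\,C_m$ apart on the $x$
  axis (a thorax-width scale).  A shared hinge point is not usable: lattice
  links next to the common root are cut by both plates with conflicting
  reconstructions and the solver destabilizes.  The separation is a
  configuration key (`wing$root_separation`).
* `mean_tip_speed` is an input; the cycle-mean of the simulated tip speed
  is reported as a cross-check (it agrees within 2%), never used to rescale.

## Fluid solver

The flow is solved with the normalized incompressible lattice Boltzmann
method on the 27-velocity lattice (weights $8/27$, $2/27$, $1/54$,
$1/216$; $c_s = c/\sqrt3$).  The solver evolves pressure distributions
$p_\alpha$ with

$$p = \sum_\alpha p_\alpha,\qquad
  u = \frac{1}{\rho_0 c_s^2}\sum_\alpha e_\alpha p_\alpha,\qquad
  p_\alpha^{eq} = \omega_\alpha\Big[p + \rho_0\Big(e_\alpha\!\cdot\!u
    + \tfrac{3(e_\alpha\cdot u)^2}{2c^2} - \tfrac{u^2}{2}\Big)\Big],$$

single-relaxation-time BGK collision
$p_\alpha(t{+}\delta t, x{+}e_\alpha\delta t) = p_\alpha^{eq} +
(1 - 1/\tau)\,p_\alpha^{neq}$ and $\tau = 3\nu/(c\,\delta x) + 1/2$.
$\rho_0 = 1$, $c = 1$, initial $p = 1/3$, $u = 0$.  No MRT or
regularization is used.  The planar Taylor–Green vortex (an exact
Navier–Stokes solution) reproduces the analytic energy decay
$e^{-4\nu k^2 t}$ to 0.02% at $32^2$ and anchors the convergence and
multiblock tests.

**Units.**  The reference length is the mean chord ($L = C_m$,
`resolution` = cells per chord) and the reference speed is the lattice
tip speed $U$ (default $0.04$).  Steps per cycle follow from the tip-path
length: $\mathrm{round}(P_{tip}/(U\,\delta x))$, rounded to a multiple of
$2^{tiers-1}$.  The lattice viscosity on the finest tier is
$U\,\mathrm{res}/Re$.

## Virtual flux boundaries

Each wing is a zero-thickness rectangle.  Every lattice link cut by a
plate gets its incoming (post-streaming) distribution rebuilt from the
boundary conditions at the crossing point $x_{vb}$ (internal ratio $a:b$
along the link): no-slip velocity $u_{vb} = u_{wall}$ and zero normal
pressure gradient, imposed through the two-probe extrapolation
$p_{vb} = (h_2^2 p_1 - h_1^2 p_2)/(h_2^2 - h_1^2)$ with probes at
$h_1 = \sqrt3\,\delta x$ and $h_2 = 2\sqrt3\,\delta x$ along the signed
normal (order-one distances keep the probes from straddling the surface;
both are configuration keys).  The equilibrium at the virtual node beyond
the wall is extrapolated linearly through the crossing,
$p^{eq*}_\alpha = \frac{a+b}{a}p^{eq}_\alpha(x_{vb}) -
\frac{b}{a}p^{eq}_\alpha(x_D)$, the nonequilibrium part is copied from
the fluid-side anchor, and both are combined exactly as in the interior
update.  Numerical details:

* probes are interpolated trilinearly from the 8 surrounding nodes,
  **masking** corners that lie over the rectangle on the far side (the
  weights are renormalized; this replaces shifting the probe outward);
* when $a < 1/2$ the anchor moves one node inward along the link
  (extrapolation distance $a{+}1$); if that node is missing or on the far
  side, the $a = 1/2$ form is used;
* the plate is two-sided: each side keeps its own crossings, normals and
  probes, and no link ever streams through the surface;
* if several plates cut one link (possible near the wing roots), the
  crossing nearest the fluid node wins — a deterministic tie-break.

Validation: a resting plate in uniform fluid preserves the state to
round-off; steady Couette flow between two virtual-flux walls at
$\tau = 1$ reproduces the linear profile to $10^{-8}$; a plate pair holds
a pressure difference for 1000 steps with leakage velocities below
$10^{-6}$.

## Forces

Two estimators are computed every step:

* **Momentum exchange** (primary, used for $C_L$, $C_T$, $C_{PWR}$): the
  momentum the link reconstruction transfers across all cut links,
  $F = \sum 3\,e_\alpha\,(p_\alpha^{out} + p_{\bar\alpha}^{in} -
  2\omega_\alpha p_{ref})$, and the aerodynamic power
  $P = \sum f_{link}\cdot u_{wall}$.  In a fully periodic box this equals
  the rate of change of total fluid momentum to machine precision — it *is*
  the force the discrete boundary exerts.
* **Traction integration** (secondary): per surface panel on each face,
  $-(p_{vb} - p_{ref})\,n$ plus the tangential viscous stress
  $\rho_0\nu\,\partial u_t/\partial n$ from a one-sided quadratic fit
  through the wall value and the two probes.  This provides the
  pressure/viscous split of the lift coefficient and an independent
  cross-check.  Its wall-pressure extrapolation assumes
  $\partial p/\partial n = 0$, which degrades below $Re \sim 10$ and
  during impulsive starts; in the boundary-layer regime the two
  estimators agree at the tens-of-percent level at the coarse resolutions
  used in the tests, and converge with resolution.

Coefficients use the **combined** two-wing reference area
$S_W = 2 C_m R$:
$C_L = F_z / (\tfrac12\rho \bar u_{tip}^2 S_W)$, likewise $C_T$ with
$F_y$ and $C_{PWR} = P/(\tfrac12\rho \bar u_{tip}^3 S_W)$.  The combined
area is forced by arithmetic consistency of the published dimensional
values ($C_L = 0.302$ at $Re=134$ with $\rho = 1.2$, $\bar u_{tip}=2.58$
gives exactly $F_z = 4.50\ \mu N$ with the two-wing area, and twice that
with a single wing).  Flow diagnostics follow the usual definitions:
$Q = (\|\Omega\|^2 - \|S\|^2)/2$ normalized by $(U/L)^2$ and the
normalized helicity density $u\cdot\omega/(|u||\omega|)$, masked where
the magnitudes vanish.

## Multiblock grids

Four nested Cartesian tiers (default) with spacing ratio exactly 2 and
acoustic scaling ($\delta t \propto \delta x$, so lattice velocities are
tier-invariant and $\tau_k - 1/2$ halves per coarsening).  The domain is
$40L$ per side with pressure clamped to $1/3$ on the $y = +20L$ face and
zero-gradient conditions elsewhere.  Per coarse step, the coarse tier
advances first; the fine tier then takes two sub-steps with ghost values
interpolated trilinearly in space and linearly in time from the coarse
solution (equilibrium rebuilt from interpolated $p$, $u$; nonequilibrium
interpolated separately), after which fine values are restricted onto
coincident coarse nodes.  The nonequilibrium rescaling factor between
tiers is the Chapman–Enskog one, $(\tau\,\delta t)$-ratio, *not* the
$(\tau - 1/2)\,\delta t$ ratio: near $\tau = 1/2$ the two differ by a
factor of 2, and only the former keeps the viscous stress continuous
(verified by the two-tier Taylor–Green test, which matches a uniform-fine
run to 0.4% where 1% is required).

## Desk-scale protocol

The full study conditions (32 cells per chord, $40L$ domain, seven cycles,
ten runs per sweep) are cluster-scale.  The package's own test suite runs a
scaled-down protocol chosen once:

* 4 cells per chord, $16L$ domain, 3 tiers, lattice tip speed $U = 0.08$
  (twice the full-scale value: it halves the steps per cycle and doubles
  $\tau - 1/2$, and at these resolutions the added Mach-number error is
  far below the discretization error);
* one to two flapping cycles, reporting the **first** cycle.  In the
  reduced $16L$ box the wake recirculates and the later cycles sink into
  the accumulated downwash; the first cycle preserves the
  motion-to-motion contrasts that the tests assert.  At full scale the
  protocol is the published one (report cycle 6 of 7; per-cycle means
  stabilize to <1% from cycle 5).
* assertions are *orderings* (which motion is most efficient, whether the
  figure-eight beats the planar stroke, how the ellipse aspect ratio moves
  with $Re$), never absolute coefficient values, which at 4 cells per
  chord are compressed relative to the converged ones;
* the Reynolds range of the scaled sweeps is restricted to
  $Re \le 134$: at 4 cells per chord and $Re = 536$, plain BGK sits at
  its stability margin ($\tau - 1/2 \approx 2\times10^{-3}$) and the
  per-phase results are noise.

What the scaled tests do show: the solver plus boundary treatment
reproduce the qualitative physics of the elevation-phase sweep.  What
they cannot show: grid-converged coefficient values, the exact published
magnitudes, or wake structures beyond the first cycle in a small box.

## The efficiency ellipse

`ellipse_fit()` is a numerically stable direct least-squares conic fit
constrained to an ellipse, in the $(\bar C_{PWR}, \bar C_L)$ data
coordinates, on all eight figure-eight motions (the U-shaped
$\varphi_{e0}\in\{0,180\}$ cases included).  `most_efficient_phase()`
finds the point where the line through the origin is tangent to the
ellipse with the greatest slope (the maximal $\bar C_L/\bar C_{PWR}$) and
maps it to an elevation phase by interpolating, proportionally in the
ellipse parameter, between the two neighbouring swept phases.  On the
published full-resolution sweep this estimate decreases monotonically
from $\approx 70^\circ$ at $Re = 33.5$ to $\approx 22^\circ$ at
$Re = 536$.

One discrepancy is worth recording.  Fitting the published sweep values,
the centre, the inclination (53–54°) and the long side agree with the
published ellipse parameters to 1–2%, but the fitted aspect ratios run
2–6% low (2.76 vs 2.93 at $Re=536$), and every standard fitting method
(algebraic, Taubin, geometric orthogonal-distance) agrees to three
digits.  Compressing the power axis by exactly $7/8$ — the axis-length
ratio of the published scatter panel — reproduces *all five* published
aspect ratios within 0.6–4%, at the cost of no longer matching the
published inclination.  The published aspect ratios therefore appear to
have been measured in figure coordinates.  The package reports the
data-coordinate fit.

## Known limitations

* BGK without regularization destabilizes when $\tau - 1/2$ is small:
  at 4 cells per chord the solver is usable up to $Re \approx 536$ only
  with the $U = 0.08$ setting; production Reynolds sweeps should use
  16+ cells per chord.
* The traction-based pressure/viscous split is approximate at coarse
  resolution (see Forces above); the momentum-exchange totals are exact
  for the discrete system.  The two estimators agree to 12–19% on
  developed impulsively-started plates at desk resolutions, converging
  slowly (first order in the cell size) as the wall extrapolation
  resolves.
* The per-panel no-slip residual diagnostic (wall velocity linearly
  extrapolated from the two probes minus the prescribed wall velocity)
  measures boundary-layer resolution relative to the probe span rather
  than the boundary enforcement itself: it plateaus near 0.2 of the tip
  speed on desk-scale flapping runs, while the resolved Couette check
  drives the same enforcement to 1e-8.
* Rigid wings and prescribed kinematics only: no wing flexibility, no
  fluid–structure interaction, no body.
* The oscillating-plate validation case (heave $x = L\sin 2\pi ft$,
  pitch $\theta = \pi/2 - (\pi/4)\sin(2\pi ft + \pi/3)$, span 4 chords,
  $Re = 100$ on the peak heave speed) reproduces the expected waveform
  shape at desk resolutions; its published cycle-mean lift (0.223) is a
  full-resolution target.
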