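---
title: "Methods: trajectory statistics and the individual-based wall-accumulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory statistics and the individual-based wall-accumulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Swimming microalgae accumulate near solid boundaries. Two mechanisms shape
the near-wall distribution of a gyrotactic (bottom-heavy) alga in a still
channel: gravitational reorientation toward upward swimming, and cell--wall
interaction, which raises the probability of *sharp turns* -- brief episodes
of large angular velocity -- and thereby modifies the swimming speed, mean
angular velocity and rotational diffusivity within roughly five cell lengths
of a wall. `gyroswim` implements both halves of the quantitative programme:

1. **measurement** -- converting planar particle-tracking exports into
   ensemble maps of swimming speed $V_s(y,\phi)$, angular drift
   $\omega(y,\phi)$, rotational diffusivity $D_r(y,\phi)$ and the joint
   density $P(y,\phi)$ over wall-normal position $y$ and heading $\phi$,
   plus sharp-turn event statistics; and
2. **modelling** -- an individual-based Langevin model whose coefficients
   are exactly those maps, integrated to its stationary distribution and
   compared with closed-form limits.

Because the underlying raw track data are not deposited, the package ships a
synthetic-track generator with the same statistical structure and exact
ground-truth labels, so that every estimator is validated by parameter
recovery rather than by eye.

# The model

In the horizontal plane (no gravity component), a cell is a point swimmer
with position $y \in [0, W]$ and heading $\phi \in (-\pi, \pi]$, with
$0 < \phi < \pi$ meaning motion toward the wall at $y = 0$:

$$\frac{dy}{dt} = -V_s(y,\phi)\,\sin\phi, \qquad
  d\phi = \omega(y,\phi)\,dt + \sqrt{2 D_r(y,\phi)}\,dW,$$

with the noise in the Itô convention (coefficients at the pre-step state).
In the vertical plane the heading drift gains the gyrotactic term
$\omega_g(\theta) = -\cos\theta/(2B)$, the planar reduction of
$[\mathbf{k} - (\mathbf{k}\cdot\mathbf{p})\mathbf{p}]/(2B)$; $B$ (s) is the
reorientation timescale set by the gravity--viscous torque balance, and
$\theta = -\pi/2$ (upward swimming) is the stable fixed point. Five model
variants switch coefficient groups on and off: wall-varying speed and wall
torque only (I), plus wall-varying $D_r$ (II), gyrotaxis alone with constant
coefficients (III), gyrotaxis plus wall speed/torque (IV), and the full
model (V).

Numerics follow the forward Euler--Maruyama scheme at dimensionless step
$\Delta\tau = 2\times10^{-4}$ ($\tau = t V_{sb}/H$), specular reflection at
the walls ($y \to -y$ or $2W - y$ with $\phi \to -\phi$, the unique rule
that preserves speed, flips the wall-normal velocity component, and reduces
to billiard reflection in the zero-noise limit), a periodic heading
coordinate, and bilinear interpolation of gridded coefficient fields
(periodic in heading; bins left undefined by the estimator are filled from
their nearest defined neighbours before simulation, and the fill count is
reported). Walkers start at mid-channel with uniform headings. The
stationary density is accumulated after a burn-in of half the run
($\tau > 5$ of $\tau_{end} = 10$ by default); the choice is ours -- the
late-time distribution is what the model predicts, and halving the step or
doubling the burn-in moves the profiles by less than the sampling noise at
the default sizes.

The far-field image-dipole prediction
$$\omega(h,\phi) = \frac{p}{8\pi\mu}\,\frac{3\sin 2\phi}{16 h^3}
  \left[1 + \frac{\Gamma}{2}(1 + \sin^2\phi)\right]$$
is provided purely as a diagnostic for comparison with measured torque
fields, never inside the simulator. The source typography is ambiguous
between $\sin 2\phi$ and $\sin^2\phi$ inside the bracket; we adopt
$\sin^2\phi$, the reading under which the bracket is even, the whole
expression odd in $\phi$, and the attraction/repulsion sign structure
($h^{-2}$ wall-induced velocity changing sign at
$\phi = \pm\pi/2 \pm \arccos(1/3)$) is self-consistent.

# Measurement pipeline

**Smoothing.** Tracks are smoothed five times with a 10-point moving
average before kinematic quantities are computed. For an even window we use
the *symmetric* even-length moving average (span 11, half weights on the
extreme points, normalized by 10), truncated and renormalized at the track
ends. The symmetric form is the only centred reading that preserves linear
motion exactly; an asymmetric 10-point window would drag every trajectory
back by half a sample per pass -- 2.5 samples of phase error after five
passes -- and bias every downstream increment.

**Kinematics.** Velocities by central differences (one-sided at the ends),
speed as the norm, heading as $\mathrm{atan2}(-v_y, v_x)$, angular velocity
as the sum of the two adjacent wrapped single-step heading increments over
$2\Delta t$. Wrapped (minimal signed) increments prevent $2\pi$ jumps from
masquerading as sharp turns. Zero-velocity samples carry the last defined
heading forward and are flagged. Tracks with mean speed $\le 5\,\mu$m/s are
discarded.

**Sharp turns.** An event is a maximal run of samples with
$|\omega| \ge \omega_{ct}$ ($\pi/8$ rad/s in the horizontal plane, $\pi/2$
in the vertical, both far above the respective bulk scales); $t_0$ is the
in-run argmax of $|\omega|$ (earliest on ties). The run-based extent is a
deliberate, oracle-checkable substitute for peak-finding heuristics whose
extent rule would be unspecifiable; event counts, per-track ratios, mean
durations per $2.5 L_c$ bin, and speed/$|\omega|$ ensembles aligned on
$t - t_0$ follow directly.

**Field estimation.** Every sample with a successor contributes its
position, heading, speed and wrapped heading increment $\Delta\phi$ to a
$51 \times 80$ grid over $[0,W] \times (-\pi,\pi]$, assigned to the bin of
the *starting* sample (the pre-point convention matching the Itô model).
Per bin, $\omega = \overline{\Delta\phi}/\Delta t$ and
$D_r = s^2_{\Delta\phi}/(2\Delta t)$ with the unbiased variance; bins with
fewer than 10 increments are flagged undefined rather than zeroed.
$P$ is jointly normalized over the grid (making
$N(y) = N^*(y)/\overline{N^*}$, $N^* = \int P\,d\phi$, a width-average-1
concentration), the reading under which the concentration definition is
internally consistent.

## Known finite-sampling responses

At $\Delta t = 0.1$ s, displacement-based kinematics have *deterministic*
responses that matter when validating against ground truth:

* a central-difference heading is the time average of the true heading over
  a two-frame window, so for Brownian headings the variance of its one-frame
  increment is $\tfrac{5}{12} \cdot 2 D_r \Delta t$ exactly (we verify the
  5/12 factor by simulation to 0.4%); the $D_r$ reading of the pipeline is
  therefore $\tfrac{5}{12}$ of the generating coefficient,
* the measured speed is the window-averaged true speed times the
  direction-coherence factor $1 - D_r\Delta t/3 - (\omega\Delta t)^2/6$,
* the drift seen by an increment is the trapezoidal window average of
  $\omega$ over the span, not its pre-point value.

The recovery validator (`recovery_report()`) compares every well-sampled bin
against these response-corrected truths, excludes increments whose chord
spans a labelled sharp turn or wall reflection (the chord direction is
undefined across a specular bounce), and uses track-clustered standard
errors because successive chords overlap. Second-order residuals (window
quadrature of strongly curved fields) remain; the validation therefore
allows a small documented floor on top of $3$ SE: 0.3% on speed, 0.05 rad/s
on drift, 15% on $D_r$ -- the last reached only where $D_r$ changes by an
order of magnitude within one window of travel. Observed residuals at the
default study conditions are about six times smaller than these floors for
speed and drift. We deliberately do *not* invert the responses inside the
estimators: they reproduce the field-standard procedure, and the responses
are part of what that procedure measures at a given frame rate.

The sharp-turn detector is validated on an *identifiable* construction
(bulk diffusivity 0.005 rad$^2$/s, injected turn magnitudes 1.2--1.8 rad/s):
at the default bulk conditions the smoothed angular-velocity noise still
crosses $\pi/8$ rad/s occasionally, so an injected-Poisson count test would
be confounded by design, not by implementation. Wall bounces are genuine
sharp direction changes and are excluded from the Poisson comparison via
the generator's reflection labels.

# Synthetic study conditions

The generator emulates the documented structure of the measured fields with
smooth parametric stand-ins (they are emulations, not measurements): channel
width $W = 1000\,\mu$m ($50 L_c$, $L_c = 20\,\mu$m); bulk speed
$V_{sb} = 80\,\mu$m/s (typical of a fast raphidophyte); bulk
$D_{rb} = 0.025$ rad$^2$/s; speed attenuated near walls with decay length
interpolating 70 $\mu$m (wall-parallel) to 100 $\mu$m (wall-normal) and a
60% deficit at contact; wall torque
$\omega_w = -2A\,|\sin\phi|\cos\phi\,e^{-h/50\,\mu m}$ with amplitude
$A = 1$ rad/s, which rotates incoming cells wall-parallel and outgoing
cells wall-normal with extreme magnitude at the $\pm\pi/4$ heading family
(a plain $\sin 2\phi$ torque cannot satisfy both rotation requirements --
its two halves share a parity); $D_r$ enhanced tenfold at wall-normal
headings within a 50 $\mu$m layer; sharp turns as a Poisson process at
0.02 s$^{-1}$ in the bulk, tripled within $2.5 L_c$ of a wall, with
gamma-distributed durations of mean 1 s and uniformly drawn extra angular
velocity 0.5--1.5 rad/s. Tracks integrate the same Langevin equations at an
internal step of 0.01 s (discretization bias well below estimator
tolerance) and are recorded at 10 frames/s. Everything is
seed-deterministic, and a per-frame ground-truth sidecar (true local
coefficients, turn and reflection labels) accompanies every track set.

What the generator does **not** emulate: localization noise, helical
swimming (the real motivation for the 5x10 smoothing), track truncation by
a finite depth of field, and cell--cell interactions. Passing recovery
tests therefore demonstrate estimator correctness on clean Langevin tracks,
not robustness to imaging artefacts.

# Closed-form checks

* **Uniformity.** With constant coefficients in a bounded channel the
  stationary density is uniform in position and heading; at $10^4$ walkers
  the profile satisfies $\max|N - 1| < 0.05$ (observed $\approx 0.016$).
* **Stationary orientation law.** The free gyrotactic orientation process
  has stationary density $\propto \exp[-\sin\theta/(2 B D_r)]$ (a von Mises
  density centred on upward swimming). We assert a $\chi^2$ fit
  ($p > 0.01$) on $10^5$ walkers after 800 s of equilibration from a
  uniform start at $B = 10$ s; the bounded variant-III marginal is *not*
  used because specular reflections map the $-\pi/2$ peak onto $+\pi/2$
  and distort the marginal inside wall layers.
* **Billiard limit.** With zero noise and zero torque the compiled
  integrator's trajectories coincide with event-driven specular ray
  tracing to $10^{-6}\,\mu$m.
* **Péclet self-consistency.** Outside wall layers the bounded gyrotactic
  model must obey $N = N_0 e^{\sigma z/H}$ with
  $\sigma = V_z H / D_T$. We measure $V_z$ and $D_T$ from an unbounded
  control run (mean and half-variance growth of $z$), choose
  $H = \sigma_{ref} D_T / V_z$ with $\sigma_{ref} = 3.112$, run the bounded
  model to steady state, and fit $\sigma$ back from the bulk profile. The
  law's derivation assumes the orientation distribution is wall-unperturbed,
  which holds only where wall layers -- of thickness one persistence length
  $\ell = V_s/D_r$, the distance a reflected cell travels while its heading
  re-relaxes -- are thin compared with $H$; moreover the bulk decay rate
  matches $V_z/D_T$ only to leading order in $k\ell$ ($k = \sigma/H$), with
  a relative deficit of order $(k\ell)^2$ -- about 4--5% at $\kappa = 0.2$,
  which we verified empirically before settling the conditions. Since
  $\ell/H \approx \kappa/\sigma$ for weak alignment
  ($\kappa = 1/(2BD_r)$), we run this diagnostic at $\kappa = 0.1$
  ($B = 200$ s, $D_{rb} = 0.025$), where the systematic is $\sim$1%, and
  fit over $[\ell, H - \ell]$; at strong alignment ($B \sim 5$ s) the layer
  would exceed $H$ and the law has no validity window at any height. The
  bounded run uses $\tau_{end} = 30$ with burn-in 20 (about five relaxation
  times of the slowest drift--diffusion mode), $10^4$ walkers.

# Problem sizes and numerical choices

Default validation sizes (chosen so each check resolves its tolerance with
sampling error at most a third of the allowed band): 500 heading walks of
600 steps for the pooled-$D_r$ check (5% tolerance, sampling error 0.3%);
400 tracks x 60 s for field recovery; 800 tracks for the $B$ fit (10%
tolerance, achieved ~3%); $10^4$ walkers for the bounded runs; 24,000
walkers x 3000 s for transport measurement (the measured $V_z$ enters the
Péclet self-consistency one-for-one through the chosen $H$, and its
relative sampling error $\sqrt{2 D_T/t}/(\sqrt{n}\,V_z)$ grows as alignment
weakens, so the control ensemble is sized to hold it below 2%). The gyrotaxis-timescale fit pools bulk
drift over positions more than 250 $\mu$m (five torque decay lengths) from
each wall, because the synthetic wall torque (1 rad/s) exceeds the
gyrotactic drift ($1/2B \approx 0.05$ rad/s) twentyfold and must decay to
$e^{-5}$ before the fit is clean. Ties in the sharp-turn argmax go to the
earliest sample; position bins are closed on the right edge of the channel;
heading $\pi$ belongs to the last orientation bin; all angles are wrapped
into $(-\pi, \pi]$ with the upper endpoint closed.

# Limitations

The wall-field closures are inventions constrained by reported magnitudes
and peak locations; only their structure, not their detailed shape, should
be read as biology. The estimation pipeline's finite-$\Delta t$ responses
(5/12 attenuation and friends) mean absolute $D_r$ maps from 10 fps data
underestimate the instantaneous Langevin coefficient even at perfect
tracking; comparisons between conditions measured at the same frame rate
are unaffected. The Péclet self-consistency check certifies the simulator
and fitting stack in the weak-alignment regime where the exponential law is
valid, not the strongly aligned regime of real blooms. No cell--cell
interactions, 3-D orientation dynamics, or flow coupling are modelled.
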