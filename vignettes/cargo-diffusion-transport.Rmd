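---
title: "Modelling single-kinesin cargo transport in a viscous medium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-kinesin cargo transport in a viscous medium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinesim)
```

## The model

`kinesim` simulates the transport of a single cargo by one kinesin-1 motor
walking along a one-dimensional microtubule lattice through a viscous
medium. The motor and cargo are coupled by an ideal spring with stiffness
$\kappa$ and rest length $L_0$: no force is transmitted while the
cargo–motor displacement $\Delta$ satisfies $|\Delta| \le L_0$, and beyond
that the load on the motor is $\pm\kappa(|\Delta| - L_0)$, *assisting*
(positive) when the cargo leads the motor and *hindering* (negative) when
it lags. The cargo obeys overdamped dynamics: deterministic drift at
velocity $F_\mathrm{cargo}/\xi$ plus thermal diffusion with coefficient
$D = k_BT/\xi$, where $\xi$ is its friction coefficient.

The motor's kinetics are load-dependent:

* **Stepping.** The motor advances in $\Delta x = 8$ nm steps at rate
  $k_\mathrm{step}(F) = (v_0/\Delta x)\,(1-(F/F_s)^2)$ for hindering loads
  up to the stall force $F_s = 7$ pN, zero at and beyond stall, and at the
  unloaded rate $v_0/\Delta x$ under any assisting load.
* **Detachment.** A Bell-type, direction-asymmetric law
  $$\varepsilon(F) = \begin{cases}
    \varepsilon_0\, e^{|F|/F_{d-}} & F \le 0 \\
    \varepsilon_0\,(1 + 3.8247\,F) & 0 < F \le 2\ \mathrm{pN}\\
    7.4\,\varepsilon_0\, e^{F/F_{d+}} & F > 2\ \mathrm{pN}
  \end{cases}$$
  with $\varepsilon_0 = v_0/l_0$ the unloaded rate,
  $F_{d\pm} = k_BT/\delta_{\pm}$ the detachment force scales
  ($\delta_- = 0.60$ nm, $\delta_+ = 0.32$ nm, so $F_{d-} = 6.85$ pN and
  $F_{d+} = 12.84$ pN). The linear 0–2 pN branch bridges a force range
  where direct measurements are unavailable; its coefficients make the
  law continuous at 0 exactly and at $+2$ pN to better than 0.1%. The
  essential feature is the *asymmetry*: detachment accelerates much faster
  under assisting than under hindering load.

The run length of a cargo is the distance the motor travels before
detaching. Because thermal diffusion of the cargo occasionally throws it
ahead of the motor — where the steep assisting branch applies — diffusion
*shortens* runs. Viscous drag biases the cargo to lag behind, suppressing
those assisting excursions, so moderate drag *recovers* run length before
large drag shortens it again through the ordinary hindering mechanism.
This non-monotonic dependence on drag is the headline behaviour of the
model, and it survives only with the measured asymmetric law:
`detachment_profile()` also offers `symmetric_hindering`,
`symmetric_assisting` and `reversed` variants (even extensions of each
measured branch, and the exact mirror $F \to -F$), all of which give
monotonic drag dependence. The functional form of these variants is this
package's interpretation: only their symmetry properties are fixed by the
behaviour they are meant to probe.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `v0` | 800 | nm/s | unloaded velocity |
| `l0` | 1500 | nm | unloaded run length |
| `step_size` | 8 | nm | lattice step |
| `Fs` | 7 | pN | stall force |
| `kappa` | 0.32 | pN/nm | tether stiffness |
| `L0` | 40 | nm | tether rest length |
| `k_on` | 5 | 1/s | microtubule binding rate |
| `kBT` | 4.11 | pN nm | thermal energy |
| `delta_minus`, `delta_plus` | 0.60, 0.32 | nm | detachment distances |
| `d` | 500 | nm | cargo diameter |
| `eta` | `water_viscosity` | pN s/nm² | solution viscosity |
| `chi` | 3 | — | wall correction on friction |
| `dt` | 1e-5 (1e-6 if `kappa` > 0.32) | s | time step |

Internal units are pN, nm, s. Water viscosity (1 mPa s) is
`1e-9 pN s/nm²`; configurations may give viscosity as a multiple of water
(`eta_water`).

**The friction convention.** The drift relation is sometimes written with
the free-space Stokes friction $3\pi\eta d$, while the drag that the
moving cargo exerts on the motor is characterised as the near-wall value
$9\pi\eta d\,v$ — mutually inconsistent if taken literally. `fluid_cargo()`
resolves this with a wall-correction multiplier `chi` on the free-space
friction. The default `chi = 3` uses $\xi = 9\pi\eta d$ for *both* drift
and diffusion ($D = k_BT/\xi$, so fluctuation–dissipation holds exactly),
which makes the steady-state tether load of a diffusion-free simulation
equal the analytic drag $9\pi\eta d\,v$ — the choice required for the
engine and the closed-form model to agree. `chi = 1` selects the
free-space reading. All quoted defaults follow `chi = 3`.

## The Monte Carlo engine

Each time step executes, in order: (1) the tether load is evaluated from
the displacement; (2) the motor detaches with probability
$\varepsilon(F)\,\Delta t$ (a Bernoulli trial; a warning is emitted if any
relevant rate times $\Delta t$ exceeds 0.1); (3) the motor advances one
step with probability $k_\mathrm{step}(F)\,\Delta t$; (4) the cargo moves
by Euler–Maruyama, $(-F/\xi)\,\Delta t + \sqrt{2D\,\Delta t}\,\zeta$ with
$\zeta$ standard normal; (5) time advances. Runs start with the cargo at
the motor position ($\Delta = 0$, the only symmetric choice) and end at
the first detachment (no rebinding). Placing detachment before stepping
follows the narrative order of the update cycle; the alternative ordering
differs at $O(\mathrm{rate}\cdot\Delta t)$, far below statistical
resolution. The loop is compiled (Rcpp) and consumes R's RNG, so results
are reproducible from a single master seed; `advance_one_step()` is a pure-R
reference implementation of the same update, tested to agree draw-for-draw.

Stability: the explicit tether update requires
$\kappa\,\Delta t/\xi < 2$; the engine warns beyond 1. At the default
$\Delta t = 10\,\mu$s this bounds the usable viscosity from below
(about $0.2\times$ water for a 500-nm cargo); the limit of vanishing drag
is therefore taken at small-but-resolved viscosity, not at
$\eta \to 0$ literally. Halving $\Delta t$ leaves summary statistics
unchanged within sampling error (tested).

**Equilibrium mode** fixes the motor (velocity zero — exactly zero drag)
and disables detachment, which would otherwise be ill-defined at
$v_0 = 0$; it records the displacement each step. In the continuous limit
the displacement is Boltzmann-distributed in the flat-bottomed harmonic
tether potential: uniform on $[-L_0, L_0]$ with half-Gaussian tails of
scale $\sigma = \sqrt{k_BT/\kappa}$ = 3.58 nm at defaults. Closed forms
(per-side tail mass $\sigma\sqrt{\pi/2}/(2L_0 + 2\sigma\sqrt{\pi/2})$ =
5.05%, mean excursion $\sigma\sqrt{2/\pi}$ = 2.86 nm) are provided by
`boltzmann_tether()` and serve as engine oracles; the test suite verifies
them at reduced $\Delta t$ with burn-in, and verifies the full stationary
density by a Kolmogorov–Smirnov comparison on a short-tether
configuration where stride-thinned samples decorrelate quickly enough for
the comparison to have power. Study-protocol runs (20,000 steps, no
burn-in, started at $\Delta = 0$) are kept distinct from these oracle
settings.

Two protocol choices deserve note:

* **Zero-drag condition grid.** A 0.2-s run can only sample the
  stationary displacement distribution if the cargo's free-range crossing
  time $(2L_0)^2/2D$ fits well inside the run. Beyond
  $\eta d \approx 10^4$ (water units × nm) it does not, and the recorded
  distribution reflects the initial condition instead of tethered
  diffusion. `zero_drag_grid()` therefore spans viscosities 1–100× water
  and diameters 100–1000 nm subject to $\eta d \le 10^4$.
* **Stiffness sweep.** Stiff tethers resolve to $\Delta t = 1\,\mu$s; a
  fixed 20,000-step budget would then observe stiff cells for one tenth
  of the time of soft cells, confounding the comparison.
  `run_equilibrium_sweep()` defaults to equal *observation time*
  (0.2 s per run, i.e. 20,000 steps at the base step); a literal fixed
  step count remains available via `equilibrium_steps`.

## Analysis procedures

* `fit_run_length()` fits the empirical cumulative distribution of run
  lengths to $1 - A e^{-x/l}$ by unweighted nonlinear least squares
  (Levenberg–Marquardt via minpack.lm) on all empirical points, with both
  parameters free; the mean run length is the decay constant $l$, and its
  SEM comes from a nonparametric bootstrap (default 1000 resamples, SEM =
  SD of resampled estimates).
* `trajectory_velocity()` takes the least-squares slope of cargo position
  against time (bead-tracking convention; motor positions optional),
  rejecting trajectories shorter than 0.2 s or moving less than 100 nm.
* `displacement_stats()` classifies displacements into the free range and
  the two tethered ranges, with per-class probabilities and mean
  excursions beyond $L_0$.
* `effective_detachment_rate()` / `effective_stepping_rate()` are the
  frequency-weighted rates over a displacement sample; the implied
  normalized run length is
  $(k_\mathrm{eff}\,\Delta x/\varepsilon_\mathrm{eff})/(v_0/\varepsilon_0)$
  and `predicted_run_length()` is the generic $v/\varepsilon$.
* `stiffness_scaling_slope()` fits
  $\log_{10}(\text{mean load}) \sim \log_{10}\kappa$. The mean is taken
  *conditional on nonzero load*: under the stationary density the
  unconditional mean is $\kappa$-independent, so only the conditional
  reading can exhibit the equipartition $\sqrt{\kappa}$ scaling
  (conditional mean tail load $\sqrt{2\kappa k_BT/\pi}$, slope exactly
  1/2), which is indeed what the sweeps measure.

## The diffusion-free analytic model

Without diffusion the only load is the hindering drag at the motor's own
velocity, $|F| = 9\pi\eta d\,v$. Self-consistency with the parabolic
force–velocity law gives the closed form implemented in
`diffusion_free_velocity()` (with the $\eta \to 0$ limit guarded), and the
run length follows as
$l = (v/\varepsilon_0)\exp(-9\pi\eta d\,v/F_{d-})$
(`diffusion_free_run_length()`). `drag_threshold()` inverts the relative
reduction $(1-(F/F_s)^2)e^{-F/F_{d-}}$ by bisection on $(0, F_s)$ to
$10^{-6}$ pN; at a 5% reduction the threshold is 0.34 pN (0.3 to one
significant figure). Diffusion-free ensembles agree with these closed
forms within sampling error (tested over a 1000-fold viscosity range).

## What the simulations do and do not show

The generator *is* the study: all data are synthetic, produced by the
engine at the parameter values above, and the tests and
`scripts/acceptance.R` recompute every quoted quantity from scratch. The
model idealises aggressively: one motor, one dimension, an ideal linear
spring beyond a sharp rest length, memoryless (purely viscous) fluid,
load-independent binding, no backstepping, no rebinding after
detachment, no nucleotide dependence. Passing tests show the engine
faithfully realises *this* model, not that the model captures intracellular
transport; in particular viscoelastic cytoplasm, motor teams and 3-D
geometry are out of scope.

Two quantitative caveats from our own cross-checks. First, pushing the
stationary displacement statistics at defaults (~5% per-side tail
occupancy, ~3 nm mean excursion) through the detachment law gives an
effective detachment rate about 18% above unloaded (the quadrature and
the sampled estimate agree), and correspondingly a ~16% implied
run-length reduction at vanishing drag; transport ensembles at near-zero
drag measure the same ~16–18% shortening. Reports of a ~30% rate increase
and ~24–26% shortening for nominally identical conditions require
displacement tails substantially fatter than the stationary distribution
of this engine; with the `chi = 3` friction convention (which the
diffusion-free/analytic agreement forces) we find no time step at which
the Euler dynamics produce them. Second, under drag the hindering
excursions widen slightly (~3.2 nm pooled over 0.01–0.2 pN drags) while
assisting excursions stay near 2.9 nm, and the assisting-load probability
at 0.2 pN drag is ~0.5%. The package reports what it computes.

## Configuration and reproducibility

`load_config()` reads a YAML file with sections `motor`, `detachment`,
`fluid`, `simulation`, `sweep`, applies the defaults above, validates
every key (collecting all offenders), and `write_config_sidecar()` echoes
the fully resolved configuration — including derived $\xi$, $D$ and the
seed — as JSON next to the outputs. Ensembles derive per-replicate seeds
from the master seed up front, so results are independent of execution
order; sweep cells derive theirs from the cell index, so a one-cell sweep
equals a direct `simulate_ensemble()` call. The command-line front end
(`inst/cli/kinesim`) exposes `rates`, `simulate`, `equilibrium` and
`sweep` over these functions with exit codes 0/2/3
(success/validation/runtime).

Typical problem sizes: transport ensembles use $N = 1000$ replicates per
condition (seconds per condition with the compiled engine); equilibrium
protocols use $N = 10$ runs of 0.2 s; the test suite scales some
property checks down to $N = 250$–400 where the check does not require
the full ensemble.

```{r example, eval = FALSE}
ens <- simulate_ensemble(
  fluid = fluid_cargo(d = 500, eta = 22 * water_viscosity),
  config = sim_config(n_replicates = 1000, seed = 1))
normalized_run_length(fit_run_length(run_lengths(ens)))
```
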