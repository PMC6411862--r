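# kinesim

Monte Carlo simulation of cargo transport by a single kinesin-1 motor in a
viscous medium, for biophysicists studying how thermal diffusion of the
cargo and viscous drag jointly shape single-motor run length.

A cargo of diameter *d* diffuses (diffusion coefficient *D* = k<sub>B</sub>T/ξ,
friction ξ = 9πηd) while tethered to a stepping motor through an ideal
spring (stiffness κ = 0.32 pN/nm, rest length L₀ = 40 nm) that transmits
load only beyond the rest length. The motor steps 8 nm at rate
k<sub>step</sub>(F) = (v₀/Δx)(1 − (F/F<sub>s</sub>)²) under hindering load
(stall F<sub>s</sub> = 7 pN; unloaded rate under assisting load) and
detaches with the direction-asymmetric Bell-type law

```
eps(F) = eps0 * exp(|F|/Fd-)          F <= 0        (hindering)
       = eps0 * (1 + 3.8247 F)        0 < F <= 2    (bridge)
       = eps0 * 7.4 * exp(F/Fd+)      F > 2         (assisting)
```

with eps0 = v₀/l₀ = 0.533 /s, Fd− = k<sub>B</sub>T/0.60 nm = 6.85 pN,
Fd+ = k<sub>B</sub>T/0.32 nm = 12.84 pN. Because assisting load accelerates
detachment far more steeply than hindering load, cargo diffusion shortens
runs at low drag, moderate drag recovers them by biasing the cargo to lag,
and large drag shortens them again — a non-monotonic dependence of run
length on the single control parameter 9πηd·v. The package includes the
stochastic engine (compiled inner loop), the diffusion-free closed-form
velocity/run-length model, the estimation procedures (exponential-CDF run
length fit with bootstrap SEM, velocity filters, displacement and load
statistics, effective detachment rates, stiffness scaling), symmetry
variants of the detachment law, a YAML-configured sweep driver with
figure-style presets, and a small CLI.

## Worked example

Run length of a 0.5-µm cargo at 22× the viscosity of water:

```r
library(kinesim)

ens <- simulate_ensemble(
  fluid = fluid_cargo(d = 500, eta = 22 * water_viscosity),
  config = sim_config(n_replicates = 1000, seed = 1))
est <- fit_run_length(run_lengths(ens))
est
#> Run length: l = 1362.9 +/- 48.6 nm (A = 0.976, n = 1000)
normalized_run_length(est)$value
#> [1] 0.9086226
diffusion_free_run_length(22 * water_viscosity, 500)
#> [1] 1444.736
drag_threshold(0.05)
#> [1] 0.3355964
```

The fit says a thousand simulated runs at this condition have mean run
length ≈ 1363 ± 49 nm, i.e. ≈ 0.91 of the unloaded 1500 nm — close to the
diffusion-free prediction (1445 nm) because at ≈ 0.25 pN of drag the
cargo rarely pushes the motor from in front. At the viscosity of water the
same ensemble protocol gives ≈ 0.83: *more* drag gave *longer* runs. The last
number is the drag at which viscous load alone costs 5% of the run length
(0.3 pN to one significant figure).

Equilibrium (zero-drag) displacement sampling and sweeps:

```r
eq <- simulate_equilibrium(config = sim_config(mode = "equilibrium",
                                               n_replicates = 10, seed = 3))
displacement_stats(eq$samples)

summ <- run_sweep(preset_sweep("fig1", n_replicates = 1000, seed = 1))
```

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/kinesim", package="kinesim"))') \
  simulate --config my_run.yaml --out out/
```

with subcommands `rates`, `simulate`, `equilibrium`, `sweep`; see
`load_config()` for the YAML schema (sections `motor`, `detachment`,
`fluid`, `simulation`, `sweep`).

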