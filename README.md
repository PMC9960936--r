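# switchsense

Soft sensors for bioprocesses built from banks of switching linear
observers.

In a chemostat — the continuous-culture bioreactor behind wastewater
treatment and industrial fermentation — the substrate concentration is
measurable online but the micro-organism (biomass) concentration usually is
not. `switchsense` designs a *soft sensor* that estimates the biomass in
real time from the dilution rate `u(t)` and the substrate measurement
`y(t)` alone, without knowing the growth parameters: it identifies a
first-order input/output model around each operating point, recovers the
state-space linear approximant from those coefficients, attaches a
full-order Luenberger observer to each point, and orchestrates the bank of
observers with a stepwise switching supervisor so that large operating-point
transitions are executed as chains of small, accurate ones.

## The model and the design

The plant is the Monod chemostat

```
dx1/dt = u (s_in - x1) - mu_m x1 x2 / (delta (x1 + K))
dx2/dt = mu_m x1 x2 / (x1 + K) - u x2,        y = x1
```

with yield `delta`, maximum growth rate `mu_m`, half-saturation `K` and feed
concentration `s_in` (defaults `1/6.6`, `1.2`, `4.95`, `9`). Its operating
trajectory is `Y = K U / (mu_m - U)`, admissible for
`U ∈ (0, s_in mu_m / (K + s_in))`.

Around an operating point `(U, Y)` the input/output behavior reduces to
`dΔy/dt + hD Δy = hN Δu`. The pair `(hD, hN)` is identified by recursive
least squares on Butterworth-filtered records, and — the key structural
property — together with `(U, Y, delta)` it determines the full state-space
approximant, so a two-state observer

```
dΔz/dt = F Δz + g Δy + m Δu,    F = A - g c,    x̂ = Δz + X̃
```

can be designed from data alone. Poles `{-rho1, -rho2}` are chosen by
minimizing a normalized steady-state error metric `J̃e,O` subject to a
convergence bound `Je,A = e^{-a}(||Phi1|| + ||Phi2||) ≤ ζO,A`, where
`Phi1, Phi2` are the spectral projectors of `F` and `a` is the stability
margin. Each observer then owns a *target operating area* — the interval of
destination dilution rates where both thresholds hold — and transitions are
planned through overlapping areas (the *dense web* principle), with the
supervisor switching observers at 1.1 times each stage's settling time.

## Worked example

Identify the plant at `U = 0.45` 1/day, design the observer, and inspect its
steady-state accuracy:

```r
library(switchsense)

params <- chemostat_params()            # delta = 1/6.6, mu_m = 1.2, K = 4.95, s_in = 9
op <- equilibrium_from_input(0.45, params)
#>       U     Y    X1    X2
#>    0.45  2.97  2.97 0.914

rec <- identification_experiment(params, U = 0.45, seed = 7)
fit <- rls_identify(rec, U = 0.45, Y = op$Y)
#> hD_hat = 0.563143 (fluctuation 1.28%), hN_hat = 6.00324 (fluctuation 1.1%)

obs <- design_observer(fit$io, U = 0.45, Y = op$Y, delta = params$delta,
                       a = 3.5, zeta_oa = 0.5)
glance(obs)
#>      U     Y     a  rho1  rho2  je_a je_o_tilde
#>   0.45  2.97   3.5  3.50  4.51 0.500     0.0396

steady_state_error(obs, uw = 0.05)
#> steady-state error for a +0.05/day step: (6.28e-04, 5.72e-03), ratio 9.89e-05
```

The true coefficients at this point are `(hD, hN) = (0.571, 6.03)`: the
noisy identification lands within about 1.5%, the optimizer pushes the slow
pole onto the stability margin (`rho1 = a`) with the convergence bound
active (`Je,A = 0.5`), and a +0.05/day step command leaves a steady biomass
estimation error of 5.7e-3 kg/m³ — about 0.6% of the biomass operating
value, and a squared-error ratio `Je,O ≈ 1e-4` far below the 0.001 area
threshold.

A complete multi-step experiment (a 0.2134 → 0.6000 1/day transition through
three intermediate operating points, with identification, bank design,
target areas, dense-web gate, planning and execution) ships as a config:

```r
cfg <- read_experiment_config(system.file("extdata", "exp1-multistep.yaml",
                                          package = "switchsense"))
bundle <- run_pipeline(cfg)
summarize_pipeline(bundle)     # per-stage steady / peak estimation errors
autoplot(bundle$run)           # plant vs estimates with switch markers
```

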