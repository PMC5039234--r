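# knotweedbc

Simulator and analytical toolkit for a stage-structured delay model of
the biological control of Japanese knotweed (*Fallopia japonica*) by the
sap-sucking psyllid *Aphalara itadori*.

Japanese knotweed is one of the most damaging invasive weeds in Europe
and North America: it has no natural enemies outside its native range,
its rhizome system is nearly indestructible, and herbicide control is
expensive and environmentally costly. The psyllid *A. itadori* — whose
larvae suck sap from knotweed stems and whose diet is specific to the
plant — has been released as a classical biocontrol agent. The question
this package addresses quantitatively: **under what conditions can the
insect actually control the plant?**

## The model

Four coupled delay differential equations track larval and adult psyllid
numbers `L(t)`, `A(t)` and stem and rhizome biomass `S(t)`, `R(t)` on a
single isolated stand:

```
L'(t) = -mu_l(S) L + S b_p(A/S) - M(t)
A'(t) =  M(t) - mu_a A
S'(t) = -(mu_s + e s L / (1 + h e s S)) S + k_s R
          - exp(-mu_s tau_s) exp(-int_{t-tau_s}^t e s L/(1+h e s S)) k_s R(t - tau_s)
R'(t) =  k_r S - mu_r R

M(t)  =  S(t-tau_p) b_p(A(t-tau_p)/S(t-tau_p)) exp(-int_{t-tau_p}^t mu_l(S))
```

with the Ricker per-stem egg-laying rate `b_p(x) = P x exp(-q x)`, the
stem-dependent larval mortality `mu_l(S) = k_l exp(-S) + m`, a Holling
type II feeding response with handling time `h`, and linear stem/rhizome
production (an invasive stand has no carrying capacity — unbounded growth
is a real outcome). `M(t)` is the maturation rate: eggs laid one
maturation delay `tau_p` ago, discounted by stem-dependent larval
survival.

Everything hinges on `h`, the days a larva needs to digest one unit of
stem biomass. The package computes the critical handling time `h_crit`
below which controlled (bounded) dynamics are predicted, the coexistence
equilibrium and its linearised real-root stability, the growth rates with
and without insects, and full nonlinear trajectories via a method-of-steps
integrator with compiled core (distributed-delay survival factors are
carried as auxiliary cumulative-integral channels; the stiff stem
collapses that occur when a large larval load strips the stand are
handled by stability-limited sub-stepping).

## Worked example

```r
library(knotweedbc)

p <- kw_params()                 # standard parameter set, h still unset
alpha_ratio(0, p)                # 4.6906  adults per stem
(hc <- critical_handling_time(p))# 17.4172 days per unit biomass per larva
insect_free_growth_rate(p)       # 0.0900  per day

p1 <- set_handling_time(p, hc - 1)
solve_equilibrium(p1)
#> Coexistence equilibrium at h = 16.4172
#>   L* = 32.6454  A* = 0.375454  S* = 1.94766  R* = 19.4766
#>   c* = 0.99 per day, phi(S*) = 0.192772 adults/stem
#>   max residual = 1.52e-12

tr <- simulate_stand(p1, make_history(p1, A0 = 50, R0 = 500), t_end = 3000)
tr
#> Knotweed model trajectory: 6001 samples on [0, 3000] d (step 0.05 d)
#>   h = 16.4172, status = ok
#>   terminal state: L = 32.6454, A = 0.375461, S = 1.94765, R = 19.4766
classify_regime_numeric(tr)
#> [1] "converged"
```

Read: without insects the stand grows exponentially at 9% per day; with
a handling time one day below threshold the simulated stand converges
(after a ~3-year oscillatory transient) to the independently computed
coexistence equilibrium — about 33 larvae, a fraction of an adult, and
two units of standing stem biomass: effective control by remarkably few
insects. Increasing `h` past the threshold walks the system through slow
convergence (`h_crit + 5`, with ~12-day predator–prey transient cycles),
sustained oscillation (`+10`), and unbounded oscillatory growth (`+15`);
`run_scenario("fig1")` … `run_scenario("fig5")` reproduce this family
end to end.

A command-line driver for shell use ships at
`inst/cli/knotweedbc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","knotweedbc.R", package="knotweedbc"))')" \
    hcrit --config my_params.yaml
```

with subcommands `simulate`, `equilibrium`, `spectral`, `hcrit` and
`scenario` (configs are flat YAML/JSON; see `?load_config`).

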