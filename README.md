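# motorlattice

Stochastic lattice simulation and analytic theory of cargo transport by
finite clusters of molecular motors.

Intracellular cargoes — vesicles, lipid droplets, mitochondria — are
hauled along cytoskeletal filaments by small teams of motors such as
kinesin-1 (processive: it essentially never lets go) or Ncd/kinesin-14
(non-processive: it binds and unbinds constantly). `motorlattice` is for
biophysicists who want to ask quantitative questions about such teams:
how fast does a cluster of *N* motors move against a load, how many
motors are bound at any moment when binding sites under the cargo are
limited, what force stalls the team, how far does the cargo run before
every motor has detached — and, turned around, how many motors does an
observed velocity/run-length pair imply?

## The model

The filament is a one-dimensional lattice of period dx (8 nm). A bound
motor steps forward at rate *p* and backward at rate *q*, with simple
exclusion (no two motors on one site). The whole dimensionless load
f = F·dx/k_BT rests on the leading (forwardmost bound) motor, whose
rates acquire Boltzmann factors

    p1 = p·e^(−fδ),   q1 = q·e^(f(1−δ)),   δ ∈ [0,1].

A permanently bound cluster of *n* motors then moves at (r = q/p)

    V_n = p (1 − e^f r^n)(1 − r) / [ e^(fδ)(1 − r) + e^f (r − r^n) ]

steps per second, stalling at f_s(n) = n·ln(p/q). Non-processive motors
unbind (k_off) and rebind (k_on); the number bound follows a
birth–death chain whose stationary law is binomial for unlimited
binding sites, or, when the cargo can only reach M sites
(k_on per site = k_on/M),

    P_n(N,M) ∝ [N! M! / (n!(N−n)!(M−n)!)] · (k_on / (M·k_off))^n .

The cluster velocity is the occupancy average
V̄ = Σ_{n≥1} P_n V_n / (1 − P_0). A compiled fixed time-step Monte
Carlo engine simulates the full process — including sequence-preserving
rebinding (scenario B), fixed binding windows with swapping
(scenario A), leader episodes and run lengths — and an event-driven
Gillespie engine samples the identical Markov process exactly as a
cross-check. See the vignette `vignettes/motor-transport-model.Rmd` for
the modelling and numerical details.

## A worked example

Three weakly non-processive kinesin-1 motors (p = 100, q = 10,
k_on = 5, k_off = 1 s⁻¹) pulling a mitochondrion against f = 2
(≈ 1.1 pN at 310 K):

```r
library(motorlattice)
ax  <- motor_preset("kinesin1-axonal")
cfg <- sim_config("B", N = 3, f = 2, n_steps = 1e6, burn_in = 2500,
                  n_runs = 10, seed = 1)
sim <- simulate_cluster(cfg, ax, keep_raw = FALSE)

cluster_velocity(sim, units = "um")
#>         mean           sd           se
#> 0.2125675033 0.0011234392 0.0003552627

run_length_stats(sim, units = "um")$mean
#> [1] 2.586967
```

The cargo advances at 0.213 µm/s and travels about 2.6 µm between
complete detachments — the duration-weighted leader velocity and the
mean signed displacement per attachment period. Against tracked axonal
mitochondria moving at 0.26 ± 0.10 µm/s with 1.82 ± 1.19 µm runs,
`infer_motor_number(c(0.26, 0.10), c(1.82, 1.19), 2:10, ax)` ranks
N = 3 as the most likely team size.

The analytic layer is instant:

```r
bound_distribution(motor_preset("ncd"), N = 10, M = 20)
#> Bound-motor distribution (N = 10 motors)
#>     P0     P1     P2     P3     P4     P5     P6     P7     P8     P9    P10
#> 0.0000 0.0009 0.0079 0.0379 0.1128 0.2165 0.2706 0.2165 0.1056 0.0281 0.0031

sapply(1:3, stall_force, params = motor_preset("kinesin1-processive"))
#> [1] 2.302585 4.605170 6.907755      # f_s = N·ln(10)
```

A thin command-line front end over the same functions ships in
`inst/cli/motorlattice` (subcommands `analytic`, `simulate`,
`experiment`, `infer-n`), and `run_experiment()` drives named study
designs (force–velocity curves, occupancy distributions, stall and
run-length scans, in-vitro/in-vivo comparisons) writing TSV results
with JSON metadata.

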