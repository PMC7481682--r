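---
title: "Collective motor transport: model, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective motor transport: model, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorlattice)
```

## The model

A cargo (a vesicle, mitochondrion or bead) carries a fixed team of $N$
molecular motors that walk along a cytoskeletal filament, modelled as a
one-dimensional lattice with spacing equal to the motor step size
$\mathrm{d}x$ (8 nm for kinesins on microtubules). Each bound motor
steps forward at rate $p$ and backward at rate $q$ (s$^{-1}$), subject
to simple exclusion: a step onto an occupied site fails. A single rate
per direction presumes saturating ATP, i.e. the chemical cycle is not
rate limiting.

The cargo exerts a load on the team. We use the *leading-motor* load
rule: the entire dimensionless force $f = F\,\mathrm{d}x / k_B T$ acts
on the forwardmost bound motor, whose rates are reweighted by Boltzmann
factors
$$p_1 = p\,e^{-f\delta}, \qquad q_1 = q\,e^{f(1-\delta)},$$
with $\delta \in [0,1]$ apportioning the load penalty between the two
directions ($\delta = 1/2$ throughout the presets). Trailing motors step
load-free. This rule suits viscous drag and bead assays in which one
motor bears the load; the equal-sharing mean-field relation
$V_n(F) = v\,(1 - (F/F_s n)^w)$ is provided in
`mean_field_velocity()` for comparison only.

For a cluster of $n$ permanently bound motors the steady-state velocity
of the leader is, with $r = q/p$,
$$V_n \;=\; \frac{p\,(1 - e^{f} r^{\,n})\,(1 - r)}
  {e^{f\delta}(1 - r) + e^{f}\,(r - r^{\,n})}
  \quad\text{(steps s}^{-1}\text{)},$$
implemented in `leading_motor_velocity()`. It collapses to $p - q$ at
$f = 0$, to $p\,e^{-f\delta}$ for unidirectional motors ($q = 0$), and
vanishes at the stall force $f_s(n) = n \ln(p/q)$ — stall grows
*linearly* with team size.

Non-processive motors additionally unbind at rate $k_\mathrm{off}$ and
rebind at rate $k_\mathrm{on}$, so the bound count $n(t)$ performs a
birth–death process. With unlimited binding sites the stationary law is
binomial, $P_n \propto \binom{N}{n} (k_\mathrm{on}/k_\mathrm{off})^n$.
A cargo of finite size can only reach $M$ filament sites; with the
per-site rate $k_\mathrm{on}^s = k_\mathrm{on}/M$ the binding rate in
state $n$ becomes $(N-n)(M-n)\,k_\mathrm{on}^s$ and
$$P_n(N, M) \;\propto\; \frac{N!\,M!}{n!\,(N-n)!\,(M-n)!}
  \left(\frac{k_\mathrm{on}^s}{k_\mathrm{off}}\right)^{\!n},
  \qquad n \le \min(N, M),$$
(`bound_distribution()`, with `master_equation_steady_state()` as an
independent linear-algebra check of the same chain). Averaging the
bound-cluster velocity over this law, conditioned on at least one motor
bound, gives the cluster velocity
$\bar V = \sum_{n\ge 1} P_n V_n / (1 - P_0)$
(`average_cluster_velocity()`). The quasi-static assumption behind
$\bar V$ — each $n$-motor configuration travels at its steady $V_n$ —
holds when stepping is fast relative to (un)binding and degrades at
large loads.

## The simulator as data generator

The package's stochastic data come from `simulate_cluster()`, a compiled
fixed time-step Monte Carlo kernel; an event-driven Gillespie sampler of
the identical Markov process (`engine = "gillespie"`) serves as an exact
cross-validation oracle and is a few-fold slower here. Each time step
has two phases, visiting motors in a fresh random permutation per phase:

1. **Binding/unbinding** (non-processive runs only). A bound motor
   unbinds with probability $k_\mathrm{off}\,\mathrm{d}t$. An unbound
   motor attempts binding with probability
   $k_\mathrm{on}\,\mathrm{d}t$; where it may land depends on the
   scenario (below).
2. **Stepping.** Each bound motor draws one uniform variate: forward if
   $u < p_\mu\,\mathrm{d}t$, else backward if
   $u < (p_\mu + q_\mu)\,\mathrm{d}t$ — the two moves are mutually
   exclusive within a step. The leader (fixed for the whole phase, and
   re-identified only after the binding phase, since exclusion forbids
   overtaking) uses $p_1, q_1$; a move onto an occupied site is a no-op.

Two binding-window scenarios bracket what a real cargo allows:

* **Scenario A — fixed window, swapping allowed.** $M$ consecutive
  sites, the cargo's reach, with the left edge tracking the rearmost
  bound motor (the window's kinematics only matter for velocities, not
  for occupancy, and the fixed-window scenario is used for occupancy
  studies at $f = 0$). A binding attempt is accepted with probability
  $(M-n)/M$ — the motor reaches a uniformly random one of its $M$ sites
  and fails on the $n$ occupied — and the successful binder lands
  uniformly on a free window site. The bound-count chain then has
  *exactly* the limited-site master-equation rates, so the simulated
  occupancy reproduces $P_n(N, M)$ regardless of window kinematics.
  Motor identities may swap on rebinding.
* **Scenario B — variable window, sequence preserved.** The window is
  the bound cluster's span plus one extra site beyond each end (the
  "stretch" sites). A motor may rebind only strictly between its
  nearest bound neighbours in motor index (those sites are always free,
  bound positions being ordered), extended by the end sites; the
  attempt succeeds whenever that interval is non-empty, with the site
  drawn uniformly from it. Motor order along the filament is therefore
  invariant — steric hindrance for motors tethered to one cargo. With
  $N = 2$ an admissible site always exists, so the bound-count chain is
  effectively unlimited; for larger teams interior motors are often
  squeezed out, shifting occupancy below the limited-site law — an
  effect of sequence preservation that the closed forms do not capture.
  When every motor is detached the window is retained from the last
  attached configuration.

The scenario-A acceptance factor and the scenario-B
"accept-if-any-admissible-site" rule are deliberately different: the
first is what makes the fixed-window occupancy match the limited-site
closed form; the second is what gives two-motor teams unlimited-law
occupancy and reproduces the axonal run lengths. A single common kernel
cannot do both.

**Observables.** Processive runs report the end-to-end velocity of the
leading motor after burn-in. Non-processive runs report *episode*
velocities: an episode is one motor's tenure as the forwardmost bound
motor, opened when it becomes leader (by binding in front or by the
previous leader detaching) and closed when it unbinds or is overtaken
by a new binder. The headline estimator weights each episode by its
duration — total leader displacement over total leader-attached time —
which converges to the occupancy-averaged velocity; the unweighted mean
over episodes is also available (`estimator = "episode_mean"`) but is
dominated by the many very short leaderships that occur while few
motors are bound and sits systematically lower. Run lengths are the
signed displacement from the site where the first motor binds to the
site where the last motor lets go; they can be negative for small teams
under load. The occupancy histogram is accumulated every step
(time-weighted in the event-driven engine).

## Parameters and defaults

| quantity | meaning | default / preset values |
|---|---|---|
| $p$, $q$ | stepping rates (s$^{-1}$) | kinesin-1: 100/10 (110/11 single); Ncd: 22/2.2 (11/1.1 single); all presets keep $p = 10q$ |
| $\delta$ | load split | 0.5 |
| $k_\mathrm{on}$, $k_\mathrm{off}$ | binding kinetics (s$^{-1}$) | Ncd: 20/10; axonal kinesin-1: 5/1; processive: 0/0 |
| $\mathrm{d}x$ | step size (nm) | 8 |
| $k_B T$ | thermal energy (pN nm) | 4.28 (310 K; physiological — configurable, the choice only affects unit conversion) |
| $\mathrm{d}t$ | time step (s) | $10^{-3}$ |
| steps / burn-in | run length | $5\times10^6$ / 1000 (processive); $5\times10^7$ / 2500 ($N \le 10$) or 25 000 ($N > 10$) |
| replicates | independent runs | 100 |

Tests and examples scale the run lengths and replicate counts down (run
lengths of $10^5$–$5\times10^6$ steps, 3–20 replicates) so that the
whole suite completes in a few minutes; the estimators are unchanged.

## Numerical choices

* **Distributions in log space.** The limited-site weights contain
  factorial ratios that overflow near $N, M \approx 170$; weights are
  accumulated as log-gamma terms and normalized by log-sum-exp, exact to
  ~1e-12 relative well beyond $N, M = 200$. `k_off = 0` with
  `k_on > 0` is treated as the all-bound limit (mass at
  $\min(N, M)$) rather than an error, recovering the processive case
  smoothly; `k_on = 0` puts all mass at $n = 0$, and velocity averages
  then signal the never-bound condition.
* **Stall roots by bracketed bisection.** $\bar V(f)$ is continuous and
  strictly decreasing on $[0, N\ln(p/q)]$ with a sign change, so
  bisection to $10^{-8}$ in $f$ is guaranteed; the closed processive
  form is used directly.
* **Time-step validity.** Transition probabilities are first-order in
  $\mathrm{d}t$; `simulate_cluster()` warns when
  $\max(\text{rate})\,\mathrm{d}t > 0.1$ and refuses above 1. The
  fixed-step scheme carries an $O(\mathrm{d}t)$ bias wherever exclusion
  couples motors within a step (a loaded leader with a fast trailing
  motor is the worst case); the bias shrinks linearly in $\mathrm{d}t$
  and the quantitative force–velocity checks therefore run at
  $\mathrm{d}t = 10^{-4}$–$2\times10^{-4}$ s, where it is far below
  sampling error, with the event-driven engine as the exact reference.
* **Simulated stall threshold.** The stall force is extracted from
  simulations as the first force on a grid whose measured velocity
  drops to $\le 10^{-5}$ of the zero-force velocity, refined by
  bisection to 0.05 in $f$. The criterion is applied one-sidedly: near
  stall the measured velocity fluctuates around zero with a sampling
  error far above $10^{-5} V_0$, so a two-sided band of that width can
  never be hit at finite run length; the one-sided rule locates the
  zero crossing, which is what the threshold is for.
* **Reproducibility.** One root seed generates per-replicate sub-seeds;
  each replicate runs on its own stream, so results are identical for a
  given seed regardless of how summaries are later computed.
* **Event-driven engine.** Rates are rebuilt in full after every event
  ($O(N)$); at the team sizes used here (up to $N = 100$) this costs a
  few times $10^8$ operations per run and correctness is easier to
  audit than an incremental update.

## What agreement does and does not show

The simulator reproduces the closed forms where the closed forms apply:
processive force–velocity curves, the limited/unlimited occupancy laws
in scenario A, stall linearity, and the two engines agree within
mutual sampling error on matched parameters. Deviations that remain are
properties of the model, not of the numerics, and go in the directions
expected from sequence preservation:

* scenario-B occupancy sits below the limited-site law for larger teams
  and loads, because interior motors often have no admissible site;
* simulated scenario-B stall forces fall below the analytic
  non-processive stall for $N > 3$;
* for $N = 100$ the cluster is *as processive as* a permanently bound
  team, but its velocity is a few per cent above the bound-cluster
  relation at low load (the compact, rebinding-packed cluster blocks
  the leader's backward steps, which the analytic relation ignores) and
  falls below it as stall is approached (sequence preservation plus
  leader unbinding under load). The bound-cluster relation itself is a
  per-cent-level approximation to the exact exclusion process once the
  loaded leader is usually blocked from behind, as the event-driven
  engine shows at $N = 2$, $f = 4$.

The generator emulates a single filament, a rigid cargo, fixed team
size, load-independent unbinding and neutral motor–motor interactions.
Passing tests therefore say nothing about multi-filament geometries,
cargo elasticity or diffusion, force-dependent detachment (which would
lower stall forces and velocities via a zipper of successive leaders),
or motor crowding effects beyond simple exclusion — all out of scope
here. Comparisons with tracking data further assume the preset kinetic
constants; `infer_motor_number()` ranks candidate team sizes by a sum
of squared z-distances using the *observed* standard deviations as
scale, a formalization of what is otherwise a by-eye comparison, and
its answer inherits any error in those constants.

## A worked example

```{r example, eval = FALSE}
ax <- motor_preset("kinesin1-axonal")
cfg <- sim_config("B", N = 3, f = 2, n_steps = 5e6, burn_in = 2500,
                  n_runs = 20, seed = 1)
sim <- simulate_cluster(cfg, ax, keep_raw = FALSE)
cluster_velocity(sim, units = "um")   # ~0.21 um/s
run_length_stats(sim, units = "um")   # mean ~2.5 um, often > 2 um sd
```

Against mitochondrial tracking statistics (0.26 ± 0.10 µm/s,
1.82 ± 1.19 µm) this identifies a team of three as the most likely
carrier (`infer_motor_number()`), the computation reproduced end to end
by `scripts/acceptance.R`.
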