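---
title: "Modeling and optimizing run-and-tumble chemotaxis strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing run-and-tumble chemotaxis strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoevolve)
```

## The model

`chemoevolve` simulates a single run-and-tumble bacterium in a
one-dimensional periodic world of length $\ell = 100$. The cell either runs
at constant speed $v = 1$ (left or right) or tumbles in place; it starts
tumbling at rate $\alpha(t)$ and stops tumbling at constant rate $\beta$.
Chemotaxis enters through a linear-response modulation of the
tumble-start rate by the attractant concentration $c$ the cell has
experienced along its trajectory $x_B(t)$:

$$
\alpha(t) = \max\!\Big(0,\; \alpha_0 + \int_{-\infty}^{t}
  R(t - t')\, c(x_B(t'), t')\, dt'\Big),
\qquad
R(s) = \Big(\frac{A}{\tau} + \frac{B s}{\tau^2}\Big) e^{-s/\tau}.
$$

The kernel $R$ has net area $\int_0^\infty R = A + B$. Three sign
constraints on $(A, B)$ define the strategies:

* **adaptive** ($A = -B$, $B > 0$): zero net area, hence *perfect
  adaptation* — under any constant concentration the steady-state rate is
  exactly $\alpha_0$; the cell responds only to concentration changes.
* **inverted** ($A > 0$, $B = 0$): a single positive lobe; the rate tracks
  the absolute concentration, so the cell tumbles (and thereby stays) where
  attractant is plentiful.
* **speculator** ($A > 0 > B$, $|B| < A$): a bilobed kernel with positive
  net area. The cell compares the recent past against a long-term average:
  it tumbles persistently while conditions beat the average and swims off
  when they decline.

A fourth tag, `null`, sets $A = B = 0$ and $\alpha_0 = 0$: the
always-running, non-chemotaxing baseline against which fitness is scaled.

### Exact evaluation of the convolution

The response integral is evaluated through two exponentially weighted
memories, $M_1 = \int_0^\infty e^{-s/\tau} c(t-s)\,ds$ and
$M_2 = \int_0^\infty s\, e^{-s/\tau} c(t-s)\,ds$, so that the integral is
$(A/\tau) M_1 + (B/\tau^2) M_2$. Both memories admit an exact $O(1)$
update over a step of length $\Delta t$ during which $c$ is constant
(split the defining integrals at age $\Delta t$). Since the simulation
produces piecewise-constant concentrations by construction, the recursion
carries **no within-step discretization error**; the test suite checks it
against brute-force Simpson quadrature of the defining integrals to a
relative $10^{-9}$. Memory is initialized at the cell's local equilibrated
concentration, i.e. at the steady state $M_1 = c\tau$, $M_2 = c\tau^2$ (an
alternative zero-memory start with burn-in is available through
`init_memory(params, 0)`).

## The stochastic attractant field

The 1D field is a truncated Fourier series with $p^* = \ell/L$ modes whose
cosine and sine weights follow independent AR(1) (discrete
Ornstein–Uhlenbeck) processes with correlation time $T$, updated every
$\Delta t_c = T/100$ and scaled so the stationary per-weight variance is
$\approx 1/p^*$. Negative excursions of the sum carry no attractant (the
field is clipped at zero at evaluation). Three consequences the tests
verify:

* the total unclipped variance is $\approx 1$, so the **mean available
  attractant** at stationarity is the clipped-Gaussian mean
  $1/\sqrt{2\pi} \approx 0.399$, independent of $T$ and $L$;
* the spatial covariance of the unclipped sum is
  $(1/p^*)\sum_p \cos(2\pi p d/\ell)$, giving correlation length
  $L = \ell/p^*$;
* weight autocorrelation decays with time constant $T$.

Fields are equilibrated for $2T$ (twice the minimum needed) from zero
weights before an agent is released. $\ell/L$ is rounded to the nearest
integer number of modes with a warning when it is not already integral;
between updates the field is held constant (no interpolation is implied by
the update rule). Each field instance draws from a private, seeded PCG32
stream, so a realization is bit-reproducible from its seed — the backbone
of the paired fitness evaluation below — while all agent-level randomness
flows from R's global RNG and `set.seed()`.

For the 3D traversal experiment, a static field sums
$X_{pqr}\cos(\xi_p(x)+\xi_q(y)+\xi_r(z)) +
Y_{pqr}\sin(\xi_p(x)+\xi_q(y)+\xi_r(z))$ over $p,q,r = 1..p^*$ with i.i.d.
Gaussian weights of variance $p^{*-3}$. (A literal reading of the
construction with an imaginary sine term would make the field complex; we
take the real combination, matching the 1D construction.) These values are
left unclipped by default — the traversal experiment compares correlation
structure, for which clipping is irrelevant — with clipping available via
a flag.

## Agent dynamics

The agent state advances every
$\Delta t_B = \min(T,\ L/v,\ \tau/20)$: the step resolves the field's
temporal change, the inter-peak distance at running speed, and the
response memory. Mode switching uses the exact first-order two-state
probabilities $1 - e^{-\alpha \Delta t_B}$ and $1 - e^{-\beta \Delta t_B}$
(rather than the linearized $r\,\Delta t$, which would misbehave at large
rates), with one switch attempt per step, resolved before movement; a cell
leaving a tumble picks its direction with equal probability. Tumbling
cells do not move. Field updates and agent steps run on independent
clocks; the agent reads the most recent field state.

Two numerical choices worth noting:

* **Threshold crossing.** A fitness run ends at the first step end at
  which the accumulated experienced attractant reaches the threshold; the
  error in the stopping time $D$ is at most one $\Delta t_B \ll D$.
* **Tumble fast-forwarding.** While tumbling, the exit is a Bernoulli
  trial per step independent of $\alpha$ and the position is frozen, so on
  the non-recording path the dwell is drawn geometrically and the memory
  and accumulation are advanced in closed form over constant-concentration
  segments. This is an exact-distribution shortcut (the test suite
  compares the two paths); it matters because optimized inverted and
  speculator cells spend most of their time in long tumbles.

## Fitness and its evaluation

Fitness approximates the division rate as
$F = T\,\langle 1/D_i \rangle_i$, where $D_i$ is the time replicate $i$
needs to experience $50\,T$ attractant units. Each replicate runs in a
fresh field realization; the same field seeds are re-used for the mutant
in a wild-type/mutant pair (common random numbers, so a lucky environment
cannot fix a mutation), while agent randomness stays fresh. Relative
fitness divides by the always-running null baseline evaluated on the same
seeds (and the same per-replicate agent seeds, so the baseline scores
exactly 1 against itself). Runs that hit the safety cap
$t_{\max} = 10^4\,T$ contribute the lower bound $1/t_{\max}$ and are
counted; an all-truncated evaluation raises an error rather than
returning a fabricated fitness.

## Evolutionary optimization

`run_evolution()` is a single-lineage Metropolis–Hastings chain. Per
generation: one parameter (chosen uniformly from the strategy's mutable
set; the adaptive $A$ is slaved to $-B$) is multiplied by $e^r$,
$r \sim U(-0.2, 0.2)$, sign preserved; wild type and mutant are evaluated
on shared fresh field seeds; the mutant is accepted with probability 1 if
$F_m \ge F_w$ and $\exp\{(F_m - F_w)/(U F_w)\}$ otherwise, at fixed
temperature $U = 0.005$.

Magnitude floors ($\alpha_0 > 10^{-3}$ for adaptive and inverted;
$A, |B| > e^{-1}$ for the speculator; $\tau > 0.01$ for adaptive; plus a
numerical-safety floor $\beta > 10^{-6}$) are enforced by redrawing $r$,
not by clamping, to avoid boundary pile-up. Initialization draws each
parameter uniformly on $(0, 1)$ *inside* its floor (rejection sampling):
a parameter initialized below a floor could never satisfy it under
bounded multiplicative mutation, so the floors must bind at
initialization too. At $T \ge 10^4$ the adaptive $B$ initializes on
$(1, 10)$ instead; the speculator $B$ on $(-1, 0)$.

"Fitness stops increasing" is operationalized as: no chain fitness in the
last 600 generations exceeds the window-start fitness by more than 1%
relative (`has_converged()`); with the noisy desk-scale fitness this test
is conservative and chains often run to their generation cap instead.
End-of-run summaries average each parameter over the chain states of the
final 600 generations; replicate runs are summarized as (min, max) ranges
of replicate means.

### Desk-scale presets and problem sizes

Full-scale optimization (threshold $50\,T$, 10 replicate cells,
open-ended generations) is a cluster-scale computation. The `"desk"`
preset — threshold $5\,T$, 5 replicate cells, at most 3000 generations —
is a first-class configuration used by the package's own benchmark at
$T = 10^3$, $L = 50$: it reproduces the direction of the optimized
parameters (all strategies beat the baseline; the speculator's $B/A$
departs from $-1$; the speculator memory exceeds the adaptive memory by
well over an order of magnitude) at roughly a thousandth of the
computational cost, at the price of noisier fitness estimates and
parameter summaries that have not fully converged to their asymptotic
ranges (the adaptive sensitivity in particular keeps growing slowly at
the cap).

## Diagnostic experiments

**Step responses.** `step_response_timecourse()` integrates $\alpha(t)$
on a spatially uniform step; the closed-form solution (a superposition of
saturating ramps) is used as its oracle. The illustrative adaptive
responder ($\alpha_0 = 10$, $A = -20$, $B = 20$, $\tau = 5$) dips on
attractant addition, returns exactly to $\alpha_0$, and spikes on
removal.

**Kernel fitting.** `fit_step_response()` recovers the five response
parameters from a tumbling time course by nonlinear least squares on a
log-parameter scale with deterministic multi-start (systematic ladders
along the amplitude and memory directions, where the clipped response
surface develops local minima). The observable is the tumbling
probability obtained by integrating the two-state master equation
$dP/dt = \alpha(t)(1 - P) - \beta P$ driven by the closed-form
$\alpha(t)$. We chose the dynamic probability over the quasi-steady ratio
$\alpha/(\alpha+\beta)$ deliberately: the quasi-steady observable is
exactly invariant under a joint rescaling of
$(\alpha_0, A, B, \beta)$, which would make the parameters structurally
unidentifiable; the master-equation lag $1/(\alpha + \beta)$ breaks that
degeneracy. Raw-rate fitting is available via `observable = "rate"`.

The companion generator `synthetic_step_series()` is a synthetic stand-in
for digitized experimental tumbling data. Its default step concentration
is weak ($c_0 = 10^{-3}$, against generating amplitudes
$A = 1300,\ B = -1000$ per unit concentration): this keeps the rate
within a few multiples of $\beta$, so the probability spans its dynamic
range. At a saturating step the probability pins at 1 during stimulation
and the amplitude scale is carried only by sub-second transients; we
measured that model curves with $A$ varied several-fold then differ by
only $\sim 0.1\%$ of peak, so noisy recovery of the amplitude block is
information-limited for *any* fitting algorithm. Parameter-recovery
claims in the tests therefore use the weak-step protocol.

**Oscillating two-Gaussian world.** Two Gaussian bumps ($\sigma = 3$, at
positions 25 and 75) trade amplitude in antiphase with period 5000; we
use the smooth waveform $A_1(\theta) = (1 + \cos(2\pi\theta/5000))/2$,
the simplest choice meeting antiphase oscillation between 0 and 1.
Position statistics are wrap-aware (circular mean and dispersion), since
the world is periodic; phase folding starts after one full burn-in
period. With published optimized parameter sets, the adaptive cell tracks
the declining peak tightly until well past quarter-period while the
speculator departs earlier and with visibly larger spread — the
exploitation/exploration contrast.

**3D traversal.** A ballistic probe crosses the static 3D field,
re-orienting uniformly after every traversed distance $2\ell$. The
direction-averaged autocorrelation of the experienced concentration is
analytically a mode-averaged sinc rather than the 1D cosine sum; the two
agree closely over the initial decay and share the half-height
correlation length, which is the sense in which a 1D world is
representative of 3D foraging. The test compares the initial decay, the
half-height crossing, and long-range decorrelation rather than demanding
pointwise equality in the negative lobe, where the two closed forms
genuinely differ by up to $\approx 0.25$.

## Known limitations

* The linear-response kernel ignores receptor saturation and adaptation
  biochemistry; at large stimuli the clipped rate is the only
  nonlinearity.
* One switch attempt per step (no run–tumble–run within a single
  $\Delta t_B$); justified by $\Delta t_B \le \tau/20$ and the small
  optimized $\alpha_0$, but formally an $O(\Delta t_B^2)$ approximation
  of the two-state process.
* The synthetic data generator emulates i.i.d. Gaussian measurement noise
  on the tumbling probability; real digitized time courses carry
  correlated, heteroscedastic errors and possible baseline drift, so
  passing recovery tests bound algorithmic, not experimental, error.
* Desk-scale evolution demonstrates directions, not converged published-scale
  parameter ranges; full-scale runs are out of desk reach.
* No 2D fields, no run-and-reverse motility, no motility energy costs.
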