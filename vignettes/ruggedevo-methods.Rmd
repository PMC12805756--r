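---
title: "Evolution on rugged landscapes: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution on rugged landscapes: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruggedevo)
```

## The model

`ruggedevo` treats the evolution of a lineage's mean phenotype
$\mathbf{x}_t \in \mathbb{R}^2$ as an Itô diffusion

$$ d\mathbf{x}_t = \mathcal{F}(\mathbf{x}_t)\,dt + \sqrt{2D}\,d\mathbf{W}_t, $$

where the drift $\mathcal{F}$ bundles selection and developmental
constraint (in quantitative-genetics terms, $\mathcal{F} = \mathbf{G}\beta$;
see `lande_drift()`) and the isotropic diffusion constant $D$ bundles
genetic drift and mutational input.  The scientific question the package
operationalises is a *regularity* question about $\mathcal{F}$: classical
gradualism implicitly assumes a globally Lipschitz drift,
$\lVert\mathcal{F}(\mathbf{x})-\mathcal{F}(\mathbf{y})\rVert \le
K\lVert\mathbf{x}-\mathbf{y}\rVert$, which by Picard–Lindelöf guarantees a
unique, stable trajectory — stasis.  If the drift is merely Hölder
continuous with exponent $\alpha < 1$, two qualitatively new behaviours
appear at the singular locus: trajectories can reach (or leave) it in
*finite time*, and uniqueness fails, so arbitrarily small noise selects
among diverging futures.  The package maps these behaviours onto
macroevolutionary phenomenology: finite-time escape as extinction,
noise-resolved non-uniqueness on a watershed as speciation, and a tilted
double well crossing a tipping point as a bifurcation-driven radiation.

Four canonical drift families cover the regimes:

| family | drift | regularity |
|---|---|---|
| `landscape_quadratic(center, eta)` | $\eta(\mathbf{c}-\mathbf{x})$ | Lipschitz ($\alpha = 1$) |
| `landscape_cusp(center, alpha, k, repulsive)` | $\mp k\alpha r^{\alpha-2}(\mathbf{x}-\mathbf{c})$, $1<\alpha<2$ | Hölder, exponent $\alpha - 1$ at $\mathbf{c}$ |
| `landscape_double_well(a, b, h)` | $(-4x(x^2-a^2)+h,\,-2by)$ | smooth; watershed geometry at $x=0$ |
| `landscape_limit_cycle(R, kappa, beta, ...)` | radial $\kappa\,\mathrm{sign}(R-r)|R-r|^\beta$, rotation $\omega_0+\omega_1(r-R)$ | Hölder exponent $\beta$ on $r=R$; non-gradient |

Potentials are written with proportionality constants fixed as
$U = (\eta/2)r^2$ and $U = \pm k r^\alpha$ so that $-\nabla U$ reproduces
the quadratic family's printed drift form exactly; the tests verify
drift/potential consistency by central differences at 100 random points
per family.

Two conventions at singular points are worth stating.  The cusp drift is
*defined* as the zero vector exactly at $\mathbf{c}$ — the unique
rotationally symmetric completion — so a noise-free trajectory started
there stays put and non-uniqueness is realised only through noise, which
the discrete scheme supplies anyway.  The limit-cycle drift is likewise
zero at the origin, a coordinate singularity with no preferred radial
direction.  The cusp's `repulsive` flag defaults to `TRUE` (the extinction
scenario); whether the ejection regime is best read as a repulsive
fractional potential or an attractive cusp with noise-driven escape is
left open, and both signs are supported.

## Integration and events

The integrator is the plain Euler–Maruyama map

$$ \mathbf{x}_{k+1} = \mathbf{x}_k + \mathcal{F}(\mathbf{x}_k)\Delta t
   + \sqrt{2D\Delta t}\,\mathbf{W}_k, $$

with fixed step $\Delta t$ and $\mathbf{W}_k$ a pair of independent
standard normals.  The defaults $\Delta t = 0.01$ and $D = 0.5$ give a
per-step, per-component noise standard deviation of
$\sqrt{2D\Delta t} = 0.1$; "per component" is the natural reading for a
vector of independent normals scaled by a scalar.  No adaptive stepping
is used: reproducibility of the discrete map takes precedence over
integrator sophistication, and near-singular safety is handled by events
instead.  A trajectory terminates in one of four states:

* **completed** — the step budget ran out;
* **escaped** — distance from the landscape's reference centre exceeded
  `escape_radius` (default 10, far beyond every feature scale of the
  canonical families); this is the operational reading of extinction by
  ejection into unviable phenotype space;
* **diverged** — a single drift step exceeded `step_guard`, the numerical
  blow-up guard;
* **absorbed** — a *noise-free* run came within `absorb_tol` of an
  attractive cusp, where the drift vanishes and finite-time arrival is
  exact.

Seeding discipline: each trajectory owns one seed and draws its noise as
consecutive pairs of standard normals; ensembles derive replicate seeds as
`base_seed + replicate index`, so any replicate can be re-simulated
standalone, bitwise.  The vectorised ensemble engine advances all
replicates in lockstep but consumes exactly the per-replicate streams, and
a test asserts bitwise agreement with standalone runs.

Numerical cross-checks anchor the scheme to closed forms: the quadratic
family is an Ornstein–Uhlenbeck process whose stationary per-component
variance $D/\eta$ and correlation time $1/\eta$ are both recovered within
5% over $2\times 10^5$ steps; gradient families relax to the Boltzmann
density $\propto e^{-U/D}$ (total-variation distance below 0.08 between
500 double-well endpoints and the analytic marginal); and the noise-free
attractive cusp realised as $\dot x = -\mathrm{sign}(x)|x|^{1/2}$ reaches
the threshold $|x| < 10^{-3}$ from $x_0 = 1$ within 1% of the exact
time-to-threshold $t^*(x_0) - t^*(\varepsilon)$ with
$t^*(x) = |x|^{1-\beta}/(k(1-\beta))$.  The time-to-threshold form matters:
the first passage to $\varepsilon = 10^{-3}$ is
$2 - 2\sqrt{\varepsilon} \approx 1.937$, which no integrator could bring
within 1% of the arrival time at zero itself ($t^* = 2$); comparing
like with like isolates discretisation error, which is tiny.

For the Boltzmann check the comparison uses 25 bins on $[-2.5, 2.5]$:
with 500 replicates the sampling-noise floor of the total-variation
statistic grows like $\sqrt{k_\mathrm{eff}}$ in the bin count, and at the
display default of 60 bins the floor alone would exceed the bound; 25
bins keep discretisation bias and sampling noise both well below it.

## Regularity estimation

`holder_exponent()` turns the Hölder definition into an estimator: probe
the field at log-spaced radii $r$ (default 24 radii spanning
$[10^{-6}, 10^{-1}]$) along 16 random directions *reused across radii*,
record the maximal increment $M(r)$, and regress $\log M$ on $\log r$.
The slope estimates $\alpha$ and $e^{\mathrm{intercept}}$ estimates the
constant $K$.  Reusing directions across radii makes any directional bias
a constant offset, which the slope ignores — this is why the estimator is
exact (to floating point) on homogeneous fields such as the cusp drift and
linear fields.  The scale floor $10^{-8}$ guards against cancellation in
double precision; constant fields are flagged undefined rather than
assigned an exponent.  `lipschitz_constant_scan()` is the complementary
diagnostic: the per-decade maxima of increment ratios stabilise at $K$
for Lipschitz fields and diverge toward small separations when a
singularity lies in the box.  Because pairs at separation $d$ near a point
singularity have probability $\sim d^2$ under uniform sampling, the scan
draws separations log-uniformly and zooms half of its base points toward
the box centre; centre the box on the suspected locus.

## Ensembles, bifurcation and the tipping point

`run_ensemble()` collects terminal states, statuses and event times;
`branch_fractions()` classifies double-well outcomes by the sign of final
$x$ (exact for the symmetric and mildly tilted well at default noise;
full basin geometry is deliberately out of scope), and `count_modes()`
counts histogram modes by smoothed-prominence — deterministic and
dependency-free, with defaults (60 bins, 3-bin smoothing, 10% prominence)
adequate at the ensemble sizes used, rather than a statistical dip test.

`bifurcation_sweep()` scans the tilt $h$ of
$U = (x^2-a^2)^2 + by^2 - hx$: per tilt value it reports the cubic's
equilibria (roots of $4x^3 - 4a^2x - h$, stable iff $12x^2 - 4a^2 > 0$,
fold at $|h| = 8a^3/3\sqrt{3}$) alongside the simulated mode structure,
and `critical_point_estimate()` locates the dominant-mode sign switch.
With a finite sweep the switch is fitted as the best single change point
of the sign sequence — identical to the adjacent-midpoint rule for a
clean switch, but robust to an isolated noise flip near the boundary.
Two sweeps coexist deliberately: the tilt sweep reproduces the
tipping-point picture (dominant phenotype jumps wells at $h = 0$), while
the true supercritical pitchfork lives in the $a^2$ direction
(`pitchfork_equilibria()`: one stable branch for $a^2 < 0$, two at exactly
$\pm a$ beyond), and the package reports measured quantities without
adjudicating which reading of "phase transition" is intended.

## Clades: splitting rule, disparity and the DFE

`simulate_clade()` lifts single trajectories to lineage trees with a
minimal operationalisation of watershed speciation: a lineage whose $x$
stays within `split_eps` (default 0.05) of the ridge for `split_dwell`
(default 10) consecutive steps is replaced by daughters at
$x \pm$ `split_offset` (default 0.05).  All three knobs are exposed; the
rule is the smallest one that converts "uniqueness is lost on the ridge"
into an event.  Diversity is the extant-lineage count; disparity is the
trace of the phenotypic covariance (divisor $n$), the most common
paleobiological proxy.  Trees export to Newick with lifespans as branch
lengths.

The dwell rule dictates the demonstrator's noise scale: splits require
the per-step noise ($\sqrt{2D\Delta t}$) to be small against the band
half-width, so the clade experiments run at $D = 0.01$ (per-step sd
$\approx 0.014$) rather than the single-trajectory default.  The
`clade_scaling_experiment()` conditions are then fixed by two time-scale
requirements: a well deep enough that a clade seeded in a niche actually
*resides* there (barrier $a^4 = 2.56\,D$ at $a = 0.4$), and a horizon
(120 time units, about 1.4 Kramers escape times) long enough that most
background clades still diversify before it.

Two desk-scale directional claims are examined and reported honestly:

* **Disparity vs diversity.**  The hypothesis is that clades radiating
  from a vacated, unstable region (seeded on the watershed) should show a
  steeper log–log disparity-vs-diversity slope than clades diversifying
  from within a niche.  Under the dwell-split rule this contrast *does not
  emerge* (50 paired seeds: median recovery slope 1.39 vs background
  1.79).  The reason is structural: every diversification episode, in
  either scenario, is the same local event — a watershed cascade followed
  by exponential divergence with e-folding time $1/4a^2 \approx 1.6$ —
  so disparity and diversity rise together on a single fast timescale and
  the slope carries no scenario signal.  A decoupling would require
  disparity growth slow relative to lineage accumulation, which this
  splitting rule cannot produce.  The corresponding acceptance test is
  left failing rather than redefining the statistic around the result.
* **Heavy-tailed mutational effects.**  With effects defined as drift
  increments $\lVert\mathcal{F}(x_0+\delta)-\mathcal{F}(x_0)\rVert$, the
  cusp's effects are a *monotone power transform* (exponent $\alpha - 1$)
  of the linear field's at matched seeds, so Hill log-spacings scale by
  $\alpha-1$ and the inverted tail exponent is strictly *larger* at the
  cusp ($1/(\alpha-1) \approx 2\times$ at $\alpha = 1.5$; measured 15.99
  vs 7.99).  The raw-increment reading is therefore *lighter*-tailed at
  the singularity, and the test asserting the opposite direction is left
  failing.  The quantity that genuinely is heavy-tailed is the
  *amplification factor* — effect per unit mutational step,
  `dfe_sample(..., relative = TRUE)` — whose cusp distribution follows a
  power law with index $2/(2-\alpha) \approx 4$ (measured 4.4) while a
  Lipschitz field's amplification is degenerate.  That contrast, rare
  large leaps from ordinary-sized mutations, is the package's concrete
  reading of a "fractal" genotype–phenotype map, and is what the property
  suite asserts.

## What the synthetic data does and does not show

Everything here is generated by the package itself; there is no external
data.  The simulations emulate a two-dimensional phenotype under constant
isotropic noise on stationary landscapes — no state-dependent diffusion
$\sigma(\mathbf{x})$, no landscape feedback (niche construction), no
population structure, and dimensions above two are out of scope.  Passing
tests therefore certify the *dynamical-systems* claims (finite-time
singularities, noise-resolved non-uniqueness, tipping points, the
regularity estimator's calibration) on the canonical families, not any
statement about empirical fossil, genomic or mutational-scanning data.
The horizon lengths, ensemble sizes (200–500 replicates, $10^4$–$2\times
10^4$ steps) and the 50-pair clade design are the package's own choices,
sized so the whole suite doubles as a practical regression harness.

## Degenerate inputs and tie-breaks

Drift at a singular point: zero by symmetry (both cusp and limit-cycle
origin).  `alpha = 1` and `alpha = 2` are rejected, not coerced — they are
different regularity classes.  Histogram values outside the bin range are
clamped into the end bins so counts always sum to the sample size.
Replicates landing exactly on the watershed are reported as unresolved
rather than assigned a basin.  An all-zero-increment probe, an all-equal
Hill sample, a sweep without a sign switch, and a series with fewer than
five informative samples all return explicit `defined = FALSE` flags
instead of numbers.  The clade lineage cap suppresses further splits and
flags truncation instead of erroring, so long runs degrade gracefully.
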