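---
title: "Modeling evolutionary dynamics under phenotypic uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling evolutionary dynamics under phenotypic uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propgen)
```

## The model

Classical population-genetic dynamics assume each genotype determines a single
phenotype with a single fitness. `propgen` models haploid asexual populations
in which that map is probabilistic. An individual is a genotype-phenotype pair
$(g, p)$; phenotype $p$ carries a Malthusian fitness $X(p)$ (exponential
growth rate per unit time). Five processes act on the population:

* **Selection.** Individuals of phenotype $p$ reproduce at rate $X(p)$;
  renormalization to a fixed population size subtracts the mean fitness
  $\bar X(t) = \sum_{g,p} f_g(p)\, X(p)$.
* **Mutation at birth.** An offspring of a genotype-$g$ parent carries
  genotype $h$ with probability $\mu_{g \to h}$ (rows include the no-mutation
  diagonal and sum to one). Because mutation rides on replication, its flux is
  fitness-weighted.
* **Phenotype noise at birth.** The offspring's phenotype is drawn from
  $\varphi_g(k \to p)$, conditioned on its (new) genotype $g$ and the parental
  phenotype $k$ — biased phenotype inheritance (e.g. epigenetic marks or
  organelle partitioning) is expressible, though the built-in scenario models
  use $k$-independent maps.
* **Spontaneous mutation.** During its lifetime an individual of phenotype
  $p$ mutates at rate $R(p)$ to a genotype drawn from $m_{g \to h}$
  (off-diagonal rows summing to one), after which its phenotype is re-drawn
  through the *new* genotype's noise tensor. This re-draw is what couples
  lifetime mutation to phenotypic uncertainty.
* **Stochastic phenotype switching (SPS).** At rate $S(p)$ an individual
  switches phenotype within its genotype, to a target drawn from
  $\sigma_g(k \to p)$ with no self-transitions. SPS is *not* multiplied by
  fitness — the distinction between replication-coupled noise and lifetime
  switching is a central modeling point, and the persister case study below
  turns on it.

In the infinite-population limit the frequency tensor $f_g(p)$ obeys a
replicator-mutator system whose replication terms collapse to

$$\dot f_g(p) \;=\; \sum_{h,k} X(k)\, f_h(k)\, \mu_{h\to g}\,
\varphi_g(k \to p) \;-\; f_g(p)\, \bar X(t) \;+\; \text{(spontaneous)} +
\text{(SPS)},$$

implemented in `propgen_rhs()` and integrated by `propgen_integrate()`
(lsoda, relative tolerance $10^{-10}$, states renormalized onto the simplex at
recording points). Genetic drift is a finite-$N$ effect: it is realized only
through the stochastic simulator, never by adding noise to the deterministic
integrator.

## The serial-dilution simulator

`run_prosed()` is a discrete-time agent-based scheme patterned on laboratory
serial-dilution protocols, with overlapping generations. Within one step of
length $dt$: every individual of phenotype $p$ produces one offspring with
probability $dt\,X(p)$ (parents persist); offspring mutate and receive
phenotypes through $\mu$ and $\varphi$; every individual spontaneously
mutates with probability $dt\,R(p)$ and switches with probability $dt\,S(p)$;
finally the pooled population is diluted back to exactly $N$ individuals by
uniform sampling without replacement (multivariate hypergeometric — the
closest analogue of pipetting an aliquot). The within-step order
(reproduce → spontaneous-mutate → switch → dilute) matters only at
$O(dt^2)$ and is fixed for reproducibility.

Two engines produce identical statistics: `"serial"` gives every trial its
own substream (per-trial seeds drawn deterministically from `base_seed`), so
single trials can be reproduced in isolation; `"batch"` advances all trials
in lock-step through vectorized draws, roughly two orders of magnitude faster
for 100-trial ensembles, at the price of per-trial re-runnability.

**Choosing `dt`.** The default `1/(2 max X)` keeps per-step reproduction
probabilities below one half. For *quantitative comparison against
continuous-time theory* a much smaller step is needed: the Bernoulli
$(dt\,X)$ clock makes per-step log-growth $\log(1 + dt\,X)$ rather than
$dt\,X$, so relative rates — and therefore relaxation time constants — carry
a systematic $O(dt \cdot \max X)$ bias (we measured $\approx 1.0\,dt\,X_0$ on
the valley model's slow mode). Tests that assert "ensemble mean within
$3\,\mathrm{SE}$ of the ODE" therefore run at $dt \cdot \max X \le 0.01$;
the bridge sweep uses $dt\,X_0 = 0.005$, chosen from the deterministic
discrete-map bias before any stochastic run. Equilibrium comparisons are
insensitive to $dt$ (the discrete map's fixed point solves the same
eigenproblem as the continuous flow), so dilution-count criteria use the
scenario's native $dt = 1$.

## Exact results

### Two genotypes, two phenotypes

With $k$-independent maps $\pi_g \equiv \varphi_g(0)$ (the probability of
mapping onto the fitter phenotype 0), symmetric mutation $\mu$, and no
lifetime processes, the equilibrium factorizes through per-genotype growth
outputs $\alpha_g = \pi_g X(0) + (1-\pi_g) X(1)$. Writing
$\beta = (1-\mu)(\alpha_0 + \alpha_1)$, the equilibrium mean fitness is the
dominant root

$$\bar X_{eq} = \tfrac12\left(\beta + \sqrt{\beta^2 -
4\alpha_0\alpha_1(1-2\mu)}\right),$$

and the frequency 4-vector is $(\pi_0 w_0, (1-\pi_0)w_0, \pi_1 w_1,
(1-\pi_1)w_1)/(w_0+w_1)$ with $(w_0, w_1) \propto (\mu\alpha_1,\;
\bar X_{eq} - (1-\mu)\alpha_0)$ the dominant eigenvector of the $2\times2$
genotype growth matrix. `equilibrium_2x2()` ships this closed form *and* an
independent route through the dominant eigenvector of the full $4\times4$
equilibrium matrix; the test suite holds them to $10^{-8}$ of each other and
of the ODE fixed point over a thousand random parameter draws. This is the
package's core exactness chain: any regression in the drift implementation,
the closed form, or the eigen path breaks it.

The closed form makes the *phenotypic buoy* quantitative: at
$\pi_0 = 0.4$, $X = (0.1, 0.05)$, $\mu = 0.05$, the low-fitness
low-probability pair $(g{=}1, p{=}1)$ outranks the fitter $(g{=}0, p{=}0)$
pair across the whole $1 - \pi_1 \in \{0.5, \dots, 0.2\}$ sweep, because the
high-probability high-fitness $(g{=}1, p{=}0)$ pair acts as a source feeding
it through noisy replication.

`phase_diagram()` labels every cell of a $(\pi_1, \mu)$ lattice by the
descending order of the four equilibrium frequencies. Orderings are decoded
from the six pairwise comparisons (win counts), never from sorting a single
representative cell — sorting a cell that happens to sit on an exact tie
would propagate an arbitrary tie-break to every cell sharing its comparison
code. Cells whose smallest pairwise gap falls below `tie_tol` (default
$10^{-9}$ relative) are boundary-flagged and excluded from sector counting;
the simulator shows exactly this noise band around the theoretical
boundaries. At $\pi_0 = 0.4$ or $0.6$ with the default fitnesses the count
is 11 (of at most $4!/2 = 12$ once fixing $\pi_0 \ne 0$ pins the genotype-0
pair order), and the count is insensitive to the fitness ratio over
$X(0)/X(1) \in \{1.5, 2, 4\}$. Two degenerate slices behave differently and
are asserted as such: at $\pi_0 = 0.5$ the structural tie
$f_0(0) = f_0(1)$ boundary-flags the entire plane, and at $X(0) = X(1)$ the
mutation axis drops out entirely, leaving $\mu$-independent rows with four
sectors set by mapping probabilities alone.

### Valley crossing through a phenotypic bridge

Three genotypes, two phenotypes: the outer genotypes map deterministically
onto the peak phenotype ($X_0$), the middle genotype reaches it only with
probability $\pi$ (the bridge) and otherwise sits in the valley at
$\gamma X_0$. With birth-coupled mutation $\mu$ (split $\mu/2$ toward each
neighbor from the middle genotype), the four live nodes $(s, b, v, e)$ follow
a closed replicator system (`bridge_rhs()`, verified term-by-term against the
general drift to $10^{-12}$).

The equilibrium genotype-1 mass $z$ solves
$(1-\theta)z^2 - [(1-\theta) + \mu(1+\theta)]z + \mu = 0$ with
$\theta = \pi + \gamma(1-\pi)$, and the slow relaxation mode is the
*antisymmetric* imbalance $f_s - f_e$ — the mode that actually transports
population across the valley — decaying at rate $\bar X_{eq} - (1-\mu)X_0$.
Eliminating $z$ gives the equilibration time constant (in units of
$1/X_0$):

$$\tau = \frac{2}{\sqrt{(1+\theta)^2(1-\mu)^2 - 4\theta(1-2\mu)} -
(1-\theta)(1-\mu)}.$$

Forced limits: $\tau(\mu = 0) = \infty$ (no deterministic crossing) and
$\tau(\gamma = 1) = 1/\mu$. `tau_jacobian()` re-derives $\tau$ numerically
(central-difference Jacobian at the equilibrium, projected onto the simplex
tangent space to remove the normalization zero mode); the suite holds the two
to $10^{-6}$ relative over a $10^3$-point lattice. $\tau$ falls
monotonically in $\pi$ and the gain from a bridge grows as the valley
deepens.

**Fitting empirical time constants.** `tau_empirical()` fits
$f_e(t) = f_{eq}(1 - A e^{-t/\tau})$ by nonlinear least squares with the
asymptote fixed at the exact equilibrium. The amplitude $A$ is free by
default: $f_e$ leaves zero with zero slope (mass must first spread through
$b$ and $v$), an S-shaped transient that a pure $1 - e^{-t/\tau}$ model
absorbs into a 2–9% upward bias on $\tau$; freeing $A$ tracks the slow
eigenmode and brings the bias on exact ODE trajectories below 0.4% at the
scenario parameters ($\mu = 0.05$, $\gamma \in [0.3, 0.7]$). The
fixed-amplitude and free-asymptote variants remain available as options, and
the fit reports its residual norm so the transient structure is visible in
diagnostics.

### Persister resuscitation

The four-compartment resuscitation model (dormant P, damaged D, failed F,
healthy H) uses a time-varying switching rate $S(t) = \alpha e^{\beta t}$
and no bottleneck, so it is written for absolute abundances with no
mean-fitness term. It is the package's sharpest illustration of the
SPS-vs-noise distinction: resuscitation is lifetime switching
(fitness-independent), while a damaged cell's chance $\varphi_{D\to H}$ of
producing a healthy offspring rides on its replication rate $X_D$ — the
regression test shows no reshuffling of switching probabilities can imitate
it.

The closed form combines $n_P(t) = n_P(0)\exp(-c(e^{\beta t}-1))$,
$c = \alpha/\beta$, with differences of lower incomplete gamma functions
$\gamma(q,\, c e^{\beta t}) - \gamma(q,\, c)$ of orders $q_D = 1 - a/\beta$,
$q_H = 1 - X_H/\beta$ (with $a = X_D(1-\varphi_{D\to H})$), which are
negative whenever growth outpaces $\beta$. Since the lower endpoint $c > 0$,
the difference is a convergent definite integral for *any* real $q$:
orders above 0.01 go through the regularized-gamma upper-tail form, the rest
through adaptive quadrature of the log-domain integrand, and the two routes
are cross-checked where both apply. The removable singularity at $X_H = a$
(where the shorthand $k = X_D\varphi_{D\to H}/(X_H - a)$ blows up) is
evaluated through the exact variation-of-constants integral for $n_H$ — the
analytic limit, not a parameter perturbation.

Correctness is established against adaptive integration of the rate
equations at `rtol = 1e-12`, holding the worst componentwise relative error
below $10^{-6}$ over 100 random parameterizations ($\alpha \in [0.2,2]$,
$\beta \in [0.1,2]$, $X_H \in [0.2,2]$, $X_D \in [0,1.5]$, Dirichlet
switching probabilities). Components are compared relative to
$\max(|n_i|,\ 10^{-9}\sum_j |n_j|)$: below that floor the reference
integrator returns its own rounding noise (abundances like $10^{-95}$),
which no relative comparison can meaningfully resolve. The reference
parameterization ($\alpha=1$, $\beta=0.5$, $\sigma = (0.2, 0.3, 0.5)$,
$X_D=0.3$, $X_H=1$, $\varphi_{D\to H}=0.4$) is a package default chosen to
produce the experimentally observed shape — damaged and failed fractions
that rise, peak within a few hours, and vanish as healthy cells take over;
the source experiments' fitted values are not published, so these numbers
are ours and are marked `"defaulted"` in the scenario metadata.

## Absolute fitness matters under uncertainty

With a deterministic map and no mutation, shifting every fitness by a
constant $A$ cancels exactly against the mean-fitness term: the ODE
trajectories are invariant to $10^{-10}$, and shifted/unshifted simulator
ensembles are statistically indistinguishable. With a probabilistic map the
reassignment flux $X(k) f_g(k) \varphi_g(k\to p)$ scales with *absolute*
fitness, and the same shift visibly changes the dynamics (sup-norm
difference well above $10^{-3}$ at the scenario parameters: maps
$0.8/0.2$, $X = (0.1, 0.05)$, $A = 0.05$). The discrete simulator is only
asymptotically shift-invariant even for deterministic maps (per-step
probabilities $dt\,X(p)$ are not shift-invariant), so the simulator half of
this property is asserted statistically at $dt = 0.05$, where the residual
drift ($\sim 3\times10^{-4}$) sits far below sampling error.

The same mechanism can push the population's mean fitness *down*: with
$X = (0.09, 0.02)$, maps $\varphi_0(0) = 0.1$, $\varphi_1(0) = 0.8$, no
mutation, and initial frequencies $(0.4, 0.1, 0.05, 0.45)$, the
high-probability low-fitness pair of the initially common genotype grows
first, $\mathrm{d}\bar X/\mathrm{d}t|_0 < 0$, and $\bar X(t)$ dips before
rising to its equilibrium value $0.8 \cdot 0.09 + 0.2 \cdot 0.02 = 0.076$.

## Scenario catalog and what the tests do (and do not) show

`make_scenario()` packages the study conditions: `buoy` (equilibrium
ranking and the 250-dilution settling budget), `phase` (sector structure),
`bridge` (the $\tau$ sweep over $\pi \in \{0, 0.05, 0.1, 0.15, 0.4\}$, 100
trials), `absolute_fitness`, `mean_fitness_decrease`, and `persister`. Every
number the motivating literature does not pin — fitness scale 0.1, buoy
mutation probability 0.05, bridge depth $\gamma = 0.5$ and $\mu = 0.05$,
$N = 10^4$, time steps — is a documented default recorded in the scenario's
`defaulted` field, set once when the catalog was written. `random_model()`
draws valid models from Dirichlet tensors for property tests
(sum-conservation of the drift, builder validity, serialization
round-trips).

The synthetic populations emulate well-mixed, constant-environment,
fixed-$N$ serial-dilution cultures with known, stationary rate parameters.
Passing tests therefore demonstrate internal consistency (simulator ↔
theory ↔ closed forms) under those idealizations; they say nothing about
environment fluctuation, spatial structure, density-dependent fitness,
non-exponential resuscitation schedules, or parameter uncertainty in real
assays. Sample sizes used by the heavy checks — $10^3$-point lattices,
$10^4$ individuals, 10–100 trials — were chosen as the smallest ensembles
at which the asserted tolerances are comfortably resolved by the sampling
error analysis above.

## Numerical choices, in one place

* Simplex handling: the integrators renormalize the solver state (the flow
  conserves the sum, so this only strips roundoff); recorded states are
  renormalized and drift is asserted below $10^{-9}$ per unit time. Negative
  entries beyond $-10^{-12}$ are errors, never clipped silently.
* Equilibria: closed forms where they exist (2×2, bridge), each verified
  against an independent eigen/fixed-point route at $10^{-10}$ residual;
  general models integrate then polish by damped Picard iteration.
* Tie-breaking: ordering labels come from pairwise-win decoding;
  `tie_tol` is relative to the largest frequency; boundary cells never enter
  sector counts.
* RNG: every stochastic entry point takes an explicit seed; serial trials
  use derived substreams; batch ensembles share one stream.
* Fits: `nlsLM` with log-linear initialization; fit standard errors are
  parametric, and the acceptance-grade stochastic comparisons use
  trial-level bootstrap intervals instead (correlated residuals make the
  parametric intervals optimistic).

## Known limitations

* The drift (finite-$N$ noise) term exists only through simulation; there is
  no stochastic integrator for the frequency SDE itself.
* The discrete simulator's clock bias is first order in $dt\,X$; comparisons
  against continuous-time rates must budget for it (see above). A
  non-overlapping-generations (Wright-Fisher-style) mode is out of scope.
* Closed-form equilibria cover the 2×2 and bridge geometries; larger models
  go through numerical fixed points.
* Config round-trips are lossless to $10^{-15}$ for JSON and YAML; TOML is
  not written.
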