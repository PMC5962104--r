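---
title: "Models and methods behind debfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind debfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debfit)
```

# The model

debfit simulates and calibrates the standard Dynamic Energy Budget (DEB)
model and its typified extensions. An individual is described by four state
variables: reserve $E$ (J), structural length $L$ (cm, the cubic root of
structural volume), maturity $E_H$ (J, cumulative energy invested in
development) and the reproduction buffer $E_R$ (J). Food is assimilated into
reserve; reserve is mobilized to fuel everything else. A fixed fraction
$\kappa$ of the mobilized flux goes to the soma (somatic maintenance first,
growth with the rest), the remainder to maturity maintenance and maturation
(juveniles) or reproduction (adults) — the $\kappa$-rule. Stage transitions
(birth $b$, metamorphosis $j$, puberty $p$) occur at fixed maturity
thresholds. The fluxes, with $f \in [0,1]$ the scaled functional response and
$s_M \ge 1$ the shape correction during metabolic acceleration:

$$
\begin{aligned}
\dot p_A &= \{\dot p_{Am}\}\, f\, s_M L^2 \quad (0 \text{ for embryos}),\\
\dot p_S &= [\dot p_M] L^3 + \{\dot p_T\}\, s_M L^2,\qquad
\dot p_J = \dot k_J \min(E_H, E_H^p),\\
\dot p_C &= \frac{E\,([E_G]\,\dot v\, s_M L^2 + \dot p_S)}{[E_G]\,L^3 + \kappa E},\qquad
\dot p_G = \kappa \dot p_C - \dot p_S,\qquad
\dot p_R = (1-\kappa)\dot p_C - \dot p_J,
\end{aligned}
$$

with $\mathrm{d}E/\mathrm{d}t = \dot p_A - \dot p_C$,
$\mathrm{d}L/\mathrm{d}t = \dot p_G / (3 [E_G] L^2)$, and
$\mathrm{d}E_H/\mathrm{d}t = \dot p_R$ until $E_H^p$, after which $\dot p_R$
accumulates in the reproduction buffer. The $\kappa$-rule identities hold
exactly, by construction, at every state — the test suite asserts them at
machine precision along whole trajectories. Written this way (numerator and
denominator of $\dot p_C$ multiplied by $L^3$), the mobilization flux is
finite as $L \to 0$, so the embryo can be integrated from a tiny initial
structure without a change of variables; we start at $L_0 = 10^{-5} L_m$.

Aging follows the standard two-parameter damage model: aging acceleration
$q$ (driven by the Weibull aging acceleration $\ddot h_a$ and amplified by
the Gompertz stress coefficient $s_G$), hazard $h$, and survival $S$:

$$
\dot q = \left(q \frac{L^3}{L_m^3} s_G + \ddot h_a\right) e
\left(\frac{\dot v s_M}{L} - r\right) - rq, \qquad
\dot h = q - rh, \qquad \dot S = -hS,
$$

with $e$ the scaled reserve density and $r$ the specific growth rate of
structure. Mean lifespan is reported as the expectation of the survival
distribution, $\int_0^\infty S\,\mathrm{d}t$, evaluated up to the age where
$S < 10^{-6}$ (the median convention is not used; reports say so).

## Primary parameters and covariation

The fourteen primary parameters (time–length–energy frame: d, cm, J) default
to the generalized-animal values at 20 °C for a maximum structural length of
1 cm. Extensive parameters covary with the dimensionless zoom factor $z$:
$\{\dot p_{Am}\} \propto z$ and the maturity thresholds $\propto z^3$, so
`scale_with_zoom()` produces a species of maximum length $z$ cm and
`scale_out_size()` removes the size dependence for cross-species comparison.
Temperature enters through a single Arrhenius correction
$\exp(T_A/T_{ref} - T_A/T)$ applied to every rate-dimension parameter
($T_A = 8000$ K, $T_{ref} = 293.15$ K by default; the aging acceleration,
per time squared, gets the squared factor). Because all rates scale
identically, a trajectory at temperature $T$ is the reference-temperature
trajectory with time compressed by the correction factor; predictions exploit
this rather than re-integrating per temperature.

## Typified models

The ten model types differ in stage logic, not in the core energetics:

* **s-models** (isomorphic throughout): `std`; `stf` (fetal development:
  structural growth unconstrained by reserve, $\mathrm{d}L/\mathrm{d}t =
  \dot v/3$, reserve density set to $f$ at birth); `stx` (fetal development
  after a gestation preparation delay $t_0$, plus a weaning transition at
  $E_H^x$ with a separate milk food level); `ssj` (a non-feeding shrinking
  stage of duration $t_{sj}$ starting at $E_H^s$); `sbp` (growth ceases at
  puberty; the whole mobilized flux beyond maintenance goes to reproduction).
* **a-models** (V1-morphic acceleration window): `abj` (birth to $E_H^j$),
  `asj` (delayed onset at $E_H^s$), `abp` (birth to puberty, no adult
  growth). During the window the shape correction $s_M = L/L_{start}$
  multiplies both the surface-specific assimilation rate and the energy
  conductance; after it, $s_M$ freezes at the ratio of lengths at the end and
  start of acceleration — the metabolic acceleration factor.
* **h-models** (acceleration extends into the adult stage): `hep` (larva
  matures to puberty while accelerating, accumulates a reproduction buffer,
  and emerges as a non-growing imago when the buffer density $E_R/L^3$ hits a
  threshold); `hex` (the larva never matures past birth but allocates to
  reproduction; pupation at the buffer-density threshold converts larval
  structure to pupal reserve, the pupa redevelops like an embryo, and the
  imago neither grows nor allocates, mobilizing reserve to match constant
  maintenance).

Degenerate settings collapse each extension to its parent model (`abj` with
$E_H^j = E_H^b$ is `std`, `stx` with $t_0 = 0$ and $E_H^x = E_H^b$ is `stf`,
and so on); the tests assert trajectory equality in each case.

Where the sources leave a rule open we chose, once:

* **ssj shrinking**: feeding stops for $t_{sj}$ days; growth is suppressed,
  and when $\kappa \dot p_C < \dot p_S$ the deficit is paid by burning
  structure at a yield of `kap_shrink` $\times [E_G]$ J per cm³ (default
  0.8). Configurable; "metabolically controlled shrinking" fixes no rule.
* **hex pupation**: the energy held in structure is taken as $[E_G]V$; a
  fraction `kap_V` (default 0.8) arrives in the pupal reserve, the rest is
  overhead. The reproduction buffer passes through unchanged. Lacking a
  separate emergence-maturity parameter, the pupa re-develops to $E_H^p$.
  The imago keeps the frozen larval $s_M$.
* **Fetal cost**: mothers are not modelled, so the initial energy of a fetal
  (stf/stx) offspring is reported as the energy in place at birth,
  $E_b + [E_G]V_b + E_H^b$, ignoring the mother's maintenance overhead.
* **Egg vs fetus timing**: an egg with enough initial reserve to reach
  scaled reserve density $f = 1$ at birth has $e \ge 1$ throughout
  development, so its mobilization — and hence maturation — exceeds the
  fetus's ($e = 1$) at every size, while both grow near the limiting rate
  $\dot v/3$ early on. Fetal development therefore yields a *larger*, not an
  earlier, neonate at the same maturity threshold; the test suite asserts
  exactly that.
* **Starvation**: when $\dot p_G < 0$ outside the stages with an explicit
  rule, the trajectory is flagged (`starved` attribute) but no rescue rule is
  imposed.
* **Time-varying forcing**: the functional response may be an arbitrary
  function of time; temperature is a per-simulation scalar. Since every rate
  carries the same Arrhenius factor, a scalar temperature per dataset is
  exact for the designs the package supports.

## Numerics

Integration uses `deSolve::lsodar` with the stage dynamics compiled in C;
events (maturity thresholds, stage durations, reproduction-buffer density
thresholds, reserve exhaustion, the survival floor) are located by the
solver's root-finding. Defaults: relative tolerance $10^{-8}$, absolute
$10^{-10}$, survival floor $10^{-6}$, all exposed as arguments. When a
threshold is already met at stage entry the stage has zero length — this is
what makes the degenerate model reductions exact. Two events crossed within
one step are processed in maturity order by the stage machine's sequencing.
The initial reserve of an egg solves $e(a_b) = f$ by bracketing and Brent
bisection over embryo integrations; it is deterministic and strictly
increasing in both $f$ and $E_H^b$. Against the closed-form von Bertalanffy
solution for `std` at constant food (exact because $e$ stays at $f$ when the
egg is provisioned to hatch at $e = f$), the integrated length curve agrees
to better than $10^{-4}$ relative; the acceptance tests pin this.

# Estimation in context

One species' data form an *entry*: zero-variate observations (scalar
life-history quantities with units, temperature and a weight multiplier) and
uni-variate datasets (time–length `tL`, time–weight `tW`, length–fecundity
`LN`, each with an auxiliary temperature and food level). Weights default to
$w_{ij} = 1/n_i$ — each dataset, not each point, contributes equally — times
the user's multipliers. Pseudo-data (generalized-animal values of $\dot v$,
$\kappa$, $\kappa_R$, $[\dot p_M]$, $\dot k_J$, $\kappa_G$) act as weak
priors with loss-dependent default weights an order of magnitude below the
data; the growth efficiency pseudo-datum is predicted as
$\kappa_G = \mu_V [M_V]/[E_G]$ from the chemical parameters.

Three loss functions are available; the symmetric bounded `sb` is the
default, `su` the symmetric unbounded alternative, and `re` is retained only
for historical context (it is deprecated at runtime: it can move the
estimate in the wrong direction even near the optimum, and cannot handle
zero-valued data).

The minimizer is a Nelder–Mead simplex with a feasibility filter called
before *every* objective evaluation: no prediction is ever computed for a
parameter vector that fails positivity, fraction bounds, threshold ordering,
birth reachability (an embryo integration) or the puberty maturity ceiling
$(1-\kappa)\dot p_S(L_i)/\kappa > \dot k_J E_H^p$. Cheap algebraic checks run
before the embryo integration. Free parameters are searched on a log scale
(logit for fractions), which keeps positivity and fraction bounds by
construction. Candidates that fail the filter are halved toward the best
vertex (at most 10 times); a halved candidate is accepted only if it improves
on the best vertex — otherwise the move is skipped and the ordinary
contraction step proceeds. Without that guard the simplex can collapse onto a
feasibility boundary; with it, and with continuation restarts (each round
re-inflates the simplex around the current best point, 500 steps per round by
default), the search behaves well in practice. One inherent limitation
remains: if the constrained optimum lies *exactly on* a filter boundary, any
hard-reject simplex stalls within about one simplex width of it. Filters are
feasibility guards, and in practice the loss optimum is interior.

## Goodness of fit

Fit quality is reported as the mean relative error
$\mathrm{MRE} = \frac{1}{n'}\sum_i RE_i$ with
$RE_i = \sum_j \frac{w_{ij}}{w_i}\,|p_{ij}-d_{ij}| / |\bar d_i|$ (range
$[0,\infty]$, additive) and the symmetric mean squared error
$\mathrm{SMSE} = \frac{1}{n'}\sum_i SSE_i$ (range $[0,1]$, multiplicative),
where $n'$ counts datasets with positive total weight. For the SSE
denominator we use the weighted per-point sum $\sum_j w_{ij}(d_{ij}^2 +
p_{ij}^2)$: since $(p-d)^2 \le d^2 + p^2$ for non-negative values, every
$SSE_i$ — and hence the SMSE — is guaranteed to lie in $[0,1]$, and for a
single-value dataset the expression reduces to the familiar
$(p/d - 1)^2/(1 + (p/d)^2)$. A per-dataset-mean denominator would violate
the $[0,1]$ range for spread-out multi-point datasets, which is why we do
not use it. Pseudo-data are excluded from MRE/SMSE: they are priors, not
observations, and the reports say so. Note that minimizing any of the loss
functions does not in general minimize MRE or SMSE (the tests carry a
two-point counterexample). Data completeness is scored 1–10 by an additive,
editable rubric over the kinds of metabolic information present.

## Automatic initialization

`auto_init_9()` exploits the near-bijection between the nine standard
zero-variate observations (`ab`, `ap`, `am`, `Lb`, `Lp`, `Li`, `Wwb`,
`Wwi`, `Ri`) and nine primary parameters: the generalized animal is zoomed to
the observed ultimate length and a short filtered-simplex run matches the
implied properties to the nine observations. We use a least-squares match
rather than literal root-finding — same map, but robust to noisy or slightly
inconsistent observations. With labels missing, the zoom-scaled generalized
set is returned as a safe fallback.

# The synthetic-entry generator

`generate_synthetic_entry()` emulates a typical entry from a known parameter
set: the nine standard zero-variate observations plus configurable
uni-variate series, all computed by the package's own prediction rules and
perturbed by multiplicative lognormal noise with mean one
($\sigma_{\log}^2 = \log(1+cv^2)$). Defaults: a 30-point growth curve
spanning three von Bertalanffy time constants, everything at the reference
temperature and $f = 1$, noise CV 5%. A separate `cv_zero` controls the
zero-variate noise, because designs differ in whether the scalar
life-history constants are treated as exact. The generator is deterministic
under a seed and byte-identical entry files follow from equal seeds.

What it does *not* emulate about real data: temperature and food histories
that vary within a dataset, inconsistent length measures (standard vs total
length), between-individual parameter scatter, and mis-specified models. A
passing recovery experiment therefore shows the estimation machinery is
correct and well-conditioned — not that field data of similar size determine
parameters this well.

## What the recovery experiment shows

The canonical experiment (seeded; noise CV 5% on the growth curve,
zero-variate observations exact; the AmP-style free set $\{\dot p_{Am}\},
\dot v, \kappa, [\dot p_M], E_H^b, E_H^p$ and $E_H^j$ for `abj`) recovers
$\kappa, [\dot p_M], \{\dot p_{Am}\}, \dot v$ within a few percent. Two
sensitivity facts, measured by linear error propagation through the
prediction Jacobian at default weights (the computation lives in the test
suite), bound what can be expected when the zero-variate data are noisy too:
with 5% noise on *all* 39 observations the intrinsic one-sigma errors of
$\{\dot p_{Am}\}$, $\dot v$ and $[\dot p_M]$ each exceed 5% even with only
the four core parameters free (while $\kappa$ stays well determined), and
with the maturity thresholds also free, $\dot v$ trades off against $E_H^b$
through the embryo observations, a classic sloppy direction. Recovery claims
should always be read against the experiment's own noise floor.

# Problem sizes in the tests

The test and acceptance runs use the generalized animal (maximum length
1 cm), 30-point growth curves, simplex budgets of 500 steps across up to 3
continuation rounds, $10^4$-case randomized sweeps for the loss and SMSE
properties, and a three-entry synthetic collection — sizes chosen so the
whole suite exercises every model type and the full estimation loop in a few
minutes on one core.

# Known limitations

* Mass balances beyond energy (dioxygen, carbon, nitrogen) are not computed;
  the respiration proxy is maintenance power, not a gas flux.
* Starvation has no rescue rule outside `ssj`'s programmed shrinking.
* Mean lifespan for h-model imagos that die of reserve exhaustion is the
  survival expectation up to that death, which understates the aging-only
  expectation.
* The `hep` (sub)imago is a single emergence event; the subimago/imago
  distinction is not quantified. For `abp`, the morphological metamorphosis
  at $E_H^j$ is recorded as an event with no dynamic effect.
* Batch spawning is not modelled; the reproduction buffer converts to
  offspring as a continuous trickle at efficiency $\kappa_R$.
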