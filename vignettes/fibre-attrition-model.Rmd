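---
title: "A mechanically gated model of fibre attrition during enzymatic hydrolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanically gated model of fibre attrition during enzymatic hydrolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibresim)
```

## The problem

When insoluble lignocellulosic biomass (for example cut flax fibre
bundles) is hydrolysed enzymatically at high dry-matter content, mixing
is indispensable: impacts between fibres break them into shorter pieces,
the suspension liquefies, and hydrolysis can proceed. A striking feature
of the measured fibre-length distributions is *stagnation*: lengths fall
rapidly early on, then the distribution freezes even though enzymes keep
working. `fibresim` implements a minimal mechanical explanation of that
behaviour and the machinery needed to exercise it: a stochastic breakage
simulator gated by beam mechanics, a random-segmentation null model, a
synthetic initial-population generator, length-weighted binning,
stagnation detection and schedule calibration.

## The mechanical model

A fibre of length $L$ is idealised as a simply supported beam loaded by a
transverse impact force $P$ at a random position. For a *fixed* load
position the bending-moment diagram is triangular; sweeping the load
point along the fibre, the largest moment attainable at relative position
$r = x/L$ is the parabolic envelope

$$M_{\max}(r) = P\,L\,r\,(1-r), \qquad 0 \le r \le 1,$$

with maximum $PL/4$ under a central load. The fibre wall fails where the
moment reaches the failure moment $M_u$. Only the ratio $M_u/P$ ever
enters the model; it has units of length and is carried in micrometres
throughout the package. Setting $M_{\max}(r) \ge M_u$ defines the
**probable failure region** (PFR), a central fraction of the fibre of
relative extent

$$e(L) = \sqrt{1 - \frac{4\,M_u/P}{L}}$$

whenever $4\,M_u/P < L$, and zero otherwise. Three consequences drive
everything else:

* **A breakability threshold.** A fibre shorter than $4\,M_u/P$ can never
  break, whatever the load position. This is the mechanism behind
  stagnation.
* **A break probability.** Impacts land uniformly at random, so a single
  impact breaks a breakable fibre with probability exactly $e(L)$.
* **A fragment floor.** Both ends of the PFR lie at least $M_u/P$ from
  the nearer fibre end (algebraically, $L(1-e)/2 \ge M_u/P$), so no
  fragment shorter than $M_u/P$ is ever created.

At the threshold itself ($L = 4\,M_u/P$, breakability ratio exactly 1)
the fibre counts as breakable but the PFR has zero extent, so it breaks
with probability zero; no special-casing is needed downstream. The extent
is computed as `sqrt(max(0, 1 - ratio))` so floating-point noise at the
threshold cannot produce a negative square-root argument.

## The step-wise simulation

`run_attrition()` iterates discrete mixing steps. In step $k$ every
active fibre, in stable input order, meets the current strength
$\left(M_u/P\right)_k$:

1. if its breakability ratio exceeds 1 it is **retired** — too short to
   break at this strength;
2. otherwise one uniform number $u \in [0,1)$ is drawn from the single
   seeded generator; the candidate break point is $uL$; if it falls in
   the closed PFR interval the fibre is **broken** in two at that point,
   the halves replacing it in place;
3. otherwise the fibre is **passed** unchanged.

Enzymatic weakening is represented by a geometric decay of the strength
ratio, `weakening_schedule()`:
$\left(M_u/P\right)_k = \max(\text{floor},\ \text{initial}\cdot
\text{decay}^{\,k-1})$, by default 400 µm at step 1, 25 % reduction per
step, clamped at a floor of 40 µm (the geometric sequence never hits the
floor exactly, so "until it reaches the floor" is implemented as a
clamp). The defaults are the reference parameterisation of the model; the
µm reading of the ratio makes the minimum breakable length run from
1.6 mm down to 0.16 mm, consistent with 3–7 mm starting material and
stabilisation of the sub-0.5 mm classes.

Two accounting choices matter and are deliberate:

* **Retired fibres persist.** "Excluded from the simulation" removes a
  fibre from the breakage loop only; physically the short fibres are
  still in the beaker, so every reported length distribution includes the
  retired pool. Total fibre length (active + retired) is conserved at
  every step.
* **Stop rule.** Before each step the run stops if fewer than
  `min_active_to_continue` (default 100) fibres would be forwarded into
  it — both halves of a break count as forwarded fibres. Termination is
  almost sure but not bounded, so a `max_steps` cap (default 500) backs
  the rule up; the trajectory records which rule fired.

One could instead re-examine retired fibres as the strength decays. That
would amount to running the whole simulation at the final, lowest
strength, and would drive every fibre into the shortest class — exactly
what measured distributions do not do. An equivalent reading of the
decaying schedule is between-fibre strength variation: fibres retired
early play the role of strong fibres that never break.

## The null model

`run_random_segmentation()` splits *every* fibre at a uniform point in
every step: no threshold, no retirement. Counts double and the mean
length halves exactly each step. It is the population-balance null
against which the mechanical model is judged: it produces an initial
shortening that looks similar, but it never settles at a nondegenerate
distribution — the length-share of the shortest class increases
monotonically towards 1, i.e. the null "converges" only by grinding
everything to dust. Because the fibre count grows as $2^{\text{steps}}$,
the function refuses runs past a `max_fibres` cap (default $2^{26}$);
matching the mechanical run's realised step count (typically 60–70 steps
from 10,000 fibres) is astronomically infeasible for the null, so
comparisons use a fixed window — 12 steps in the package's own checks,
comparable to the handful of steps over which the two models visibly
diverge and within which the window's count stays tractable.

## Synthetic initial populations

The measured initial population the model was originally driven by is
not distributed with the package, so `synthetic_population()` generates a
stand-in emulating razor-cut flax: a binomially sized intact fraction
(default 80 %) uniform on 3000–7000 µm — the documented 3–7 mm cut — plus
a log-normal fines fraction (median 500 µm, log-sd 0.8, capped at the top
of the intact range) representing debris already present before
hydrolysis. The intact range is the one documented experimental value;
the fines parameters are package choices fixed once to give a visible but
minority short-fibre tail, as image-analysis data of cut fibre typically
shows. What the generator does *not* emulate: measurement noise and the
instrument's lower detection limit, fibre width/curl, and any correlation
between length and strength. Tests passing on synthetic populations
therefore validate the simulator's mechanics and invariants, not the fit
to any particular measured data set.

## Reporting: length-weighted classes

`bin_length_weighted()` reports the share of **total fibre length** per
length class (a number-weighted option exists; both agree when all fibres
are equal). The default classes are 0–0.25, 0.25–0.5, 0.5–3 and 3–7 mm:
long intact segments, medium fragments and two short classes split below
0.5 mm. The interior 0.25 mm edge is a package default (the conventional
split of the sub-0.5 mm material is not standardised), and it is
configurable. Bins are half-open $[a, b)$ with the last bin closed;
lengths above the top edge are folded into the last bin and flagged,
since simulation inputs are user-supplied even though cut fibre starts at
or below 7 mm.

## Stagnation detection and calibration

`distribution_distance()` is the total-variation distance
$\tfrac12\sum_i |p_i - q_i|$ on the class shares: bounded, defined for
empty bins, and readable as the fraction of length-share that would have
to move between classes. (Chi-square and KL divergences fail on empty
bins; TV does not.) `detect_stagnation()` declares stagnation at the
first entry from which `patience` consecutive steps (default 2, so a
single-step coincidence cannot register) each move the distribution by
less than `tol` (default 0.01).

`calibrate_schedule()` automates the choice of the three schedule
parameters by brute-force grid search: each candidate schedule is
simulated under a few replicate seeds, binned on the observed series'
edges, aligned to the observed labels *by index* — the model has no
mapping from steps to hours, a deliberate modelling gap — with excess
steps truncated and missing steps padded by the terminal distribution,
and scored by the label-averaged TV distance. The self-consistency
requirement is parameter recovery: calibrating against a series the
simulator itself generated must return the generating schedule from a
grid containing it among decoys.

## Problem sizes and numerical checks

The package's own test suite and the `scripts/acceptance.R` report
exercise the model at the following sizes, chosen so the full suite runs
in a few minutes on one CPU: PFR closed form vs a $10^5$-point grid scan
of the envelope over 1000 parameter pairs (agreement to $10^{-4}$);
break-probability calibration with $10^5$ single-fibre trials (within
three binomial standard errors of $\sqrt{0.5}$); ten seeded mechanical
runs from 10,000 synthetic fibres for conservation ($\le 10^{-9}$
relative), the fragment floor, and termination; a 4,000-fibre population
for the stagnation dichotomy; and a $3^3$ grid with two replicates from
3,000 fibres for parameter recovery.

## Limitations

* Steps are abstract mixing rounds, not hours; no kinetics, adsorption or
  product inhibition are modelled, and mass loss to solubilisation is
  ignored — fibres change only by breaking.
* Strength is uniform along each fibre and across fibres within a step;
  dislocation-rich walls justify the first simplification, and the
  decaying schedule can be read as standing in for the second.
* The instrument-specific features of measured length tables (detection
  limits, width-dependent detection) are outside the generator's scope,
  so quantitative agreement with any particular measured series must be
  established by the user via `read_lengths()` and
  `calibrate_schedule()`.
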