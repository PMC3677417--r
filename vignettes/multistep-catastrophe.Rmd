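---
title: "Multistep catastrophe: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistep catastrophe: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtkinetics)
```

# The modeling problem

A growing microtubule end switches abruptly to rapid shrinkage
("catastrophe") when it loses the stabilizing structure built from
GTP-bound tubulin at its tip. Kinetic models strip this down to three rate
constants: the association rate $r = k_{on} c$ (proportional to free
tubulin concentration $c$), the GTP-tubulin dissociation rate $k$, and the
hydrolysis rate $h$ that converts GTP-tubulin to GDP-tubulin in the
lattice. The GDP-tubulin off-rate $k_D$ is two to three orders of
magnitude larger than $k$ and is often idealized as infinite; both the
finite value (290 s$^{-1}$) and the idealization are supported
(`k_D_infinite`).

Units are fixed package-wide: seconds, micromolar, and tubulin dimers
(8 nm per lattice layer). A 13-protofilament microtubule maps onto linear
filament models in two standard ways: as one helically growing filament
with the measured whole-microtubule rates and an effective subunit length
of 8/13 nm, or as 13 independent protofilaments each with rates
$r' = r/13$ and $k' = k/13$ and the full 8 nm subunit. The
single-protofilament simulators default to the helical mapping, which is
how the classical mechanism-comparison parameter sets are quoted; the
multi-protofilament model is inherently per-protofilament. Both are
exposed (`mapping`, `subunit_spacing_nm()`).

# Single-protofilament mechanisms

`simulate_protofilament()` is an exact continuous-time Gillespie
simulation: after every event all enabled exponential clocks are redrawn,
which is exact by memorylessness. The four hydrolysis mechanisms are

* **coupled** — a subunit hydrolyzes the instant it is buried; the cap is
  pinned at one subunit and catastrophe (terminal GDP) occurs at rate $k$,
  so lifetimes are exponential with mean $1/k$ and concentration
  independent;
* **vectorial** — hydrolysis only at the single GDP/GTP interface, at rate
  $h$; the filament is bounded iff the front can catch the tip,
  $h > r - k$ (`vectorial_bounded()`);
* **random** — every GTP subunit hydrolyzes at rate $h$, which creates GTP
  islands in the lattice and small caps;
* **coupled-random** — random with the terminal subunit exempt, the
  mechanism the multi-protofilament model builds on.

Catastrophe rules are pluggable (terminal GDP, $N$ terminal GDPs, total
depolymerization back to the seed, cap loss) because the literature pairs
each mechanism with a different operational definition. Simulations start
from a stable, non-hydrolyzable two-subunit seed; rescue is not modeled
(it is rarely observed in vitro with pure tubulin).

A note on the "unbounded" vectorial regime: even with $h$ well below
$r - k$, a substantial minority of filaments still catastrophes almost
immediately — starting from the seed the cap is one subunit deep and
gambler's ruin takes a fraction $\approx (h+k)/r$ of filaments before the
drift can rescue them. The boundedness criterion governs the fate of
*established* caps, which is what the censored-length fraction in the
tests measures.

# The multi-protofilament multistep model

Each of $N = 13$ independent protofilaments carries rates $r'$, $k'$ and
coupled-random hydrolysis $h$. A protofilament suffers a *destabilizing
event* when its terminal subunit dissociates while the subunit below is
GDP; the event is permanent (the protofilament is frozen in the
simulator — since destabilization is absorbing, whether it keeps growing
as all-GDP or stops cannot affect the lifetime). Catastrophe is the
$n$-th destabilization among the $N$ protofilaments, with $n = 3$ the
empirically supported default.

The subterminal GDP probability for a growing protofilament obeys
$\dot p_D = h(1 - p_D) - r' p_D$: hydrolysis converts a GTP subterminal at
rate $h$, and each addition buries the previous terminal — always GTP,
because the terminal cannot hydrolyze — as the fresh subterminal. Hence
$p_D = h/(h + r')$ in steady state, or $h/r'$ for small $h$. This master
equation deliberately neglects the $O(k'/r')$ correction from terminal
dissociations exposing a deeper, older and therefore likelier-GDP subunit;
the Monte-Carlo estimator `estimate_subterminal_gdp_prob()` contains the
full lattice physics and the tests verify the two agree to within that
correction (at 12 µM and the fitted constants, $k'/r' \approx 0.5\%$).

Steps then occur at rate $k' p_D$, step times are exponential with mean
$T' = 1/(k' p_D)$, and the lifetime is the $n$-th order statistic of $N$
iid exponentials:

$$f(t) = \frac{N!}{(n-1)!\,(N-n)!}\,
  \bigl(1 - e^{-t/T'}\bigr)^{n-1} e^{-(N-n+1)t/T'}/T',
\qquad
\mathbb{E}[T] = T' \sum_{i=N-n+1}^{N} \frac{1}{i}.$$

For $n \ge 2$ the density vanishes at $t = 0$ — the "aging" signature that
distinguishes multistep catastrophe from any single-step (exponential)
model. The closed forms are validated two ways: against numerical
quadrature of the density, and against the mechanistic 13-protofilament
simulator (`simulate_multipf_lifetimes()`), which shares no code with the
analytic path and agrees with the closed-form mean within Monte-Carlo
error (the acceptance suite requires 10% at 2000 replicates; observed
agreement is ~2%).

Inverting the mean-lifetime relation
$T(h) = H(n,N)\,(h + r')/(k' h)$ for $h$ (`solve_hydrolysis_rate()`) uses
bracketed root-finding on $[10^{-6}, 10^{3}]$ s$^{-1}$, expanded
geometrically if needed, to relative tolerance $10^{-10}$; $T(h)$ is
strictly decreasing with infimum $H(n,N)/k'$, so the root is unique and
inputs at or below the infimum are rejected with the bound reported. At
the classical inputs ($T = 232$ s, $r' = 3.75$ s$^{-1}$,
$k' = 0.02$ s$^{-1}$) this reconstruction yields
$h \approx 0.215$ s$^{-1}$, inside the experimentally measured
0.1–0.3 s$^{-1}$ window. Published treatments of the same inputs quote
values up to $0.26$ s$^{-1}$ depending on whether the exact
single-protofilament solution or the steady-state approximation stands in
for $p_D$; we use the approximation consistently and treat the measured
window as the meaningful check.

# Dilution

On rapid dilution to concentration $c_{post}$, the per-protofilament step
rate becomes $s = k' \, p_D(c_{post})$; at $c_{post} = 0$, $p_D \to 1$ and
$s = k'$ (with $h \gg k'$ the subterminal hydrolyzes long before the
terminal departs). A microtubule observed at a random moment of its growth
has already accrued $m$ destabilizations with probability proportional to
the mean dwell time in state $m$,
$P(m) = \frac{1/(N-m)}{H(n,N)}$, so the mean post-dilution lifetime is

$$\mathbb{E}[T_{dil}] = \sum_{m=0}^{n-1} P(m)
  \sum_{j=m}^{n-1} \frac{1}{(N-j)\,s}.$$

With $k' = 0.02$ s$^{-1}$ this gives 8.4 s — catastrophe within several
seconds of washout, as observed. Two generators emulate the experiment:
`simulate_dilution_experiment()` samples exactly from this law (and
matches the mean to 3 standard errors), while
`simulate_multipf_dilution()` is fully mechanistic — it grows the
surviving lattices at $c_{pre}$, switches the association rate off, and
waits for the remaining destabilizations. The mechanistic mean runs
higher than the zeroth-order analytic value by a lag of order $1/h$
(≈ 8 s at $h = 0.12$): immediately after dilution the subterminal is
GDP with probability only $p_D(c_{pre}) \approx 0.05$, so the earliest
first-of-13 departures — whose analytic wait $1/(13 k') \approx 4$ s is
*shorter* than the hydrolysis time — frequently fail to destabilize. The
tests bound the gap by $1/h$ rather than pretending the zeroth-order
formula is exact.

# Caps and decay lengths

The model separates three tip structures. The *stabilizing cap* is two
dimers per protofilament (a GTP terminal over a non-GDP subterminal) — its
loss is the destabilizing event. The *GTP cap* is the uninterrupted
terminal GTP run, which `cap_statistics()` measures from stationary-growth
snapshots: ~5–7 dimers per protofilament between 7 and 14 µM, growing
with concentration. The *decay length* is the depth over which the GTP
fraction falls $e$-fold, $r'/h$ dimers (the fraction at depth $d$ is
$\bigl(r'/(r'+h)\bigr)^{d-1} \approx e^{-h d / r'}$, the survival of a
subunit of age $d/r'$); at an in-cell growth speed of 160 nm/s and
$h = 0.2$ s$^{-1}$, `gtp_decay_length()` gives 100 dimers — why
end-binding-protein comets are much longer than the stabilizing cap. The
e-fold depth is estimated from the snapshot profile by
binomial-information-weighted log-linear regression over the
well-sampled depth window (GTP fraction 0.1–0.95), which removes the bias
an unweighted log fit picks up from the noisy deep-lattice tail.

If each protofilament grows as an independent Poisson process, a filament
averaging 1000 dimers has protofilament-length standard deviation
$\sqrt{1000} \approx 31.6$ dimers. At 8 nm per dimer that is 253 nm;
discussions of end raggedness sometimes quote "approximately 280 nm" for
the same argument, a value the square-root law does not reproduce
(possibly a different assumed spacing). `poisson_length_sd()` returns the
square-root-law value.

# Fitting

`fit_mle()` maximizes the censoring-aware log-likelihood
(`lifetime_loglik()`: log-density for observed catastrophes, log-survival
for right-censored records) over $T'$ separately for each candidate $n$,
then selects the $n$ with the highest maximized likelihood — a discrete
grid at fixed dimension, so no information criterion is involved; ties
break toward smaller $n$. The one-dimensional search runs on
$\log T'$ over a bracket of $\pm \log 50$ around the moment starting point
$T'_0 = \bar t / H(n, N)$, to relative tolerance $10^{-8}$. Uncertainty
is reported as a parametric-bootstrap standard error
(`parametric_bootstrap_se()`, ≥ 100 refits at the fitted parameters,
optionally mirroring the administrative censoring); published step-time
uncertainties of the "$\pm$" form do not state their method, so the
bootstrap SE is this package's defined meaning. Per-concentration
independent fits are the default; the analytic concentration curve
(`mean_lifetime_vs_concentration()`) links concentrations when a shared
$h$ is wanted.

At the fitted constants ($k_{on} = 3.2$, $k = 0.2$, $h = 0.12$) the
analytic step time at 12 µM is 1665 s, within ~6% of the 1580 s obtained
by fitting the lifetime distribution directly — a consistency check the
acceptance suite records, not a free parameter.

# Synthetic data

The generators produce exactly the statistical structure the analytic
model assumes — iid exponential step times, catastrophe at the $n$-th
order statistic — with no discretization: `sample_lifetimes()` draws all
$N$ exponentials and partially sorts for the $n$-th smallest;
censoring is administrative (a fixed observation end), matching how
imaging runs truncate. What passing tests on these data show is that the
estimators and the analytic pipeline are correct *given the model*; they
cannot show that real lifetime data follow the model (no measurement
noise on lengths, no nucleation delays, no rescue, no protofilament-number
variation, and mechanistic lattice effects enter only through the
simulators, not the generators).

# Reproducibility and problem sizes

All stochastic code runs on R's RNG; ensembles derive one substream seed
per replicate from the master seed by a fixed counter formula, so results
are reproducible and independent of replicate order. A fixed seed yields
bit-identical trajectories. Default censoring caps are 5000 s and $10^5$
dimers; censored replicates are flagged and excluded from mean-lifetime
estimates but reported.

The shipped checks use ensemble sizes chosen so Monte-Carlo error is well
below each assertion's tolerance while the whole suite stays interactive:
2000 replicates for the mechanistic-vs-analytic lifetime comparison
(~2% standard error against a 10% band), $10^4$ for coupled-mechanism
exponentiality and the dilution sampler, 5000 lifetimes for parameter
recovery (3% band), 100-replicate bootstraps (the enforced minimum), and
$2\times10^4$ s of simulated growth (~$10^5$ events) for the
subterminal-occupancy estimate.

# Known limitations

* No lateral-bond energetics, mechanics, sheet/tube closure or tapered-end
  geometry; protofilaments interact only through the shared catastrophe
  count.
* No rescue, no minus-end kinetics, no MAP regulation.
* The analytic $p_D$ neglects the $O(k'/r')$ dissociation correction;
  near the critical concentration (where $r' \sim k'$) the analytic and
  mechanistic models part company.
* The multistep law assumes protofilaments are exchangeable and steps
  irreversible; tip-fluctuation phenomena on millisecond timescales are
  outside the model.
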