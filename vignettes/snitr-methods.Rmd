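---
title: "The SNITR rumor-propagation model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SNITR rumor-propagation model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snitr)
```

## The model

snitr implements a five-compartment mean-field model of rumor spread on an
open social network. Users are susceptible (S, unaware of the rumor),
neglected (N, aware but undecided and silent), infected (I, believing and
spreading the rumor), transmitters (T, publicly countering it with the
truth), or recovered (R, no longer engaging). Users join and leave the
network at a common turnover rate $\mu$, and densities are normalised so
that $S+N+I+T+R=1$ at all times. The dynamics are

$$
\begin{aligned}
S' &= \mu - \alpha_1 I S - \alpha_2 T S - \alpha_3 S N - \mu S\\
N' &= \alpha_3 N S - \beta_1 I N - \beta_2 T N - \beta_3 N - \mu N\\
I' &= \alpha_1 S I + \beta_1 N I - (\epsilon + \gamma_1 + \mu) I\\
T' &= \alpha_2 S T + \beta_2 N T + \epsilon I - (\gamma_2 + \mu) T\\
R' &= \gamma_1 I + \gamma_2 T + \beta_3 N - \mu R
\end{aligned}
$$

with all rates in $(0,1)$ and the sum constraints
$\alpha_1+\alpha_2+\alpha_3 \le 1$, $\beta_1+\beta_2+\beta_3 \le 1$,
$\gamma_1+\epsilon \le 1$. The derivatives sum to $\mu(1 - S-N-I-T-R)$, so
the simplex is invariant; the $R$ equation decouples and all analysis is
done on the reduced $(S,N,I,T)$ system with $R$ recovered as the
remainder.

Two conventions in the published formulation needed a decision:

* The population identity is read as "the densities sum to the total
  population", normalised to 1; all equilibria and thresholds in the
  sources are on the density scale, which is consistent with this reading.
* $\epsilon = 0$ (no infected-to-transmitter conversion) appears in one
  published configuration although the rates are nominally in the open
  interval; validation accepts it with a warning rather than rejecting.
  Likewise, two published sweep baselines violate the $\alpha$ sum
  constraint ($\alpha_1+\alpha_2+\alpha_3 = 1.34$ and $1.25$); loading is
  strict by default, but `strict = FALSE` downgrades sum violations to
  warnings so those configurations remain usable, and `sweep_parameter()`
  flags (never drops) offending values.

## Thresholds and stability

Linearising at the rumor-free state $E_0=(1,0,0,0)$ and applying the
next-generation construction with infected compartments ordered $(I,T,N)$
gives a lower-triangular $K = FV^{-1}$ whose diagonal is

$$
R_{01} = \frac{\alpha_1}{\epsilon+\gamma_1+\mu},\qquad
R_{02} = \frac{\alpha_2}{\gamma_2+\mu},\qquad
R_{03} = \frac{\alpha_3}{\beta_3+\mu},
$$

the invasion thresholds of the infected, transmitter and neglected
compartments. `classify_stability()` evaluates the analytic Jacobian of
the reduced vector field — differentiated from the equations, not
transcribed from the published Jacobian displays, which contain subscript
slips — and classifies an equilibrium from the eigenvalue real parts with
a marginal band of $10^{-9}$ (configurable). As a cross-check it also
evaluates the quartic Routh–Hurwitz determinants
$\Delta_1=a_3$, $\Delta_2=a_3a_2-a_1$,
$\Delta_3=a_3a_2a_1-a_3^2a_0-a_1^2$, $\Delta_4=a_0\Delta_3$. At $E_0$ the
spectrum is exactly
$\{-\mu,\ \alpha_3-\beta_3-\mu,\ \alpha_1-\epsilon-\gamma_1-\mu,\
\alpha_2-\gamma_2-\mu\}$, so local stability of $E_0$ is equivalent to all
three $R_{0i}<1$; this equivalence is asserted property-style in the test
suite.

Global convergence to $E_0$ is checked empirically
(`global_convergence_check()`): seeded random simplex starts are
integrated and the fraction ending within $10^{-4}$ of $E_0$ is reported,
together with an eventual-decrease check of the energy
$\tfrac12\big(k_0 I^2 + k_1 (1-S)^2\big)$ (weights $k_0=k_1=1$; only
positivity matters). The published symbolic argument for global stability
mixes terms from two equations, so the package deliberately verifies this
property numerically rather than symbolically.

## Equilibria: closed forms as candidates, roots as truth

`closed_form_equilibria()` evaluates the seven published candidate steady
states exactly as printed. Several of these expressions are internally
inconsistent with the vector field (e.g. the transmitter-free candidate
$E_2$ uses $\alpha_2$ and $\gamma_2$, which belong to the transmitter
pathway, and the coexistence expressions reference ambiguous symbols), so
every candidate carries its residual $\max|f|$ and a feasibility flag, and
`consistency_report()` compares each candidate against numerically refined
roots. The numeric root-finder (`find_equilibrium_numeric()`, damped
Newton on the analytic Jacobian, residual tolerance $10^{-10}$) is the
source of truth; labels are assigned from a root's occupancy pattern
(which of $N, I, T$ are nonzero), not from the printed algebra. Degenerate
denominators yield an "undefined" candidate rather than an error.
Published numeric coordinates for most boundary equilibria satisfy neither
the printed closed forms nor the vector field, so they are not used as
test oracles; the package's tests rely on hand-substituted evaluations of
the printed expressions and on brute-force root scans instead.

## Numerical integration

Trajectories use adaptive-step `lsoda` (deSolve) with `rtol = 1e-8`,
`atol = 1e-10`, sampled on a uniform grid. Every trajectory is checked for
density conservation (drift below $10^{-6}$) and positivity within a
round-off band of $10^{-9}$, then clipped to $[0,1]$. The default initial
condition $(0.90, 0.04, 0.04, 0.02, 0)$ — most users susceptible, small
seeded rumor activity — is a package choice (the sources never state one);
closed-form quantities do not depend on it and the convergence claims are
asserted from random starts as well.

## Simulation experiments

`sweep_parameter()` re-runs the model over a value grid of one rate from
one shared initial condition (per-value re-normalisation is deliberately
forbidden) and summarises peak density, peak time and final density of a
chosen compartment. The bundled sweep configurations
(`snitr_sweep_configs()`) use five evenly spaced values across each
published range; the documented orderings (infected peak increasing in
$\alpha_1$ and $\beta_1$, decreasing in $\epsilon$; transmitter peak
increasing in $\alpha_2$, $\beta_2$, $\epsilon$) are asserted in the test
suite.

`delayed_transmitter_run()` models debunking that starts only at a chosen
time $t_{enter}$: on $[0, t_{enter})$ the transmitter-generating pathways
($\alpha_2$, $\beta_2$, $\epsilon$) are gated to zero; at $t_{enter}$ they
are re-enabled and a small fraction of susceptibles (default 1%) is moved
to T. The sources describe the scenario but not its mechanism; this
gating-plus-seed definition is the package's own, chosen because it
conserves total density, keeps the state continuous otherwise, and reduces
to the unmodified model at $t_{enter}=0$. Consequently only the orderings
(peak infected density non-decreasing, peak transmitter density
non-increasing in $t_{enter}$) are treated as reproducible claims, not any
specific peak values. The sources also never print the configuration
behind their timing figures, so the package ships its own demonstration
set (`snitr_example_params("intervention_demo")`): strong rumor growth
while debunking is absent, and transmitter spread driven by contact with
susceptibles rather than by infected-side conversion, so that both
orderings are exhibited cleanly. A "second peak" of the neglected density is a local
maximum with prominence at least 0.01 after $t_{enter}$.

## Synthetic repost series

No repost dataset is deposited with the sources, so `generate_series()`
emulates one: the model is integrated from known parameters (default: the
case-study least-squares estimates, the only data-derived set), the $I+T$
density is sampled at bin midpoints (default 10-minute bins over 65 h,
the first 30 h forming the fitting window), and seeded count noise is
applied — Poisson counts with mean `population × density` (default
population 12,372 reposting users) rescaled to densities, or Gaussian
noise clipped at zero. Model time maps to wall-clock hours 1:1 by default;
the sources do not state the correspondence, and the choice only scales
the rate units. What this emulation does **not** capture: network
topology, bursty diurnal activity, duplicate reposts and censoring in real
repost streams. Passing round-trip tests therefore demonstrates
self-consistency of the pipeline, not fidelity to Weibo data.

## Least-squares fitting

`fit_snitr()` estimates the ten rates by bounded least squares on the
fitting window only, minimising $\sum_t (I(t)+T(t)-y_t)^2$ with every rate
in $[0.001, 0.999]$. Three numerical choices matter:

* **Log-scale optimisation.** Rates are positive scale parameters whose
  plausible values span three decades (the case-study estimates include
  $\mu = 0.001$ and $\gamma_2 = 0.0023$ alongside $\beta_1 = 0.48$).
  Multi-start draws are Latin-hypercube samples of $\log$-rates and the
  Levenberg–Marquardt polish runs in log space; on this scale the small
  rates are sampled and conditioned properly, which uniform-scale
  sampling fails to do.
* **Restarted polishing.** The objective has long, sloppy valleys;
  a single Levenberg–Marquardt run stalls early. The best few starts (by
  initial objective) are polished with repeated LM restarts, each restart
  resetting the trust region, until the objective stops improving, the
  deterministic round budget (`max_rounds_total`) is exhausted, or the
  objective falls below `rss_tol` (a machine-precision fit for
  density-scale data).
* **Initial state.** By default the four initial densities are
  co-estimated on the simplex ($R_0$ the remainder), since an observer of
  a real repost stream does not know them. When fitting synthetic series
  whose generating protocol is known — as in the package's round-trip
  validation — the initial state can and should be pinned via `init`;
  with only the aggregate $I+T$ observable, freeing it adds a degeneracy
  that visibly degrades out-of-window prediction.

The "fit coefficient" reported throughout is the coefficient of
determination $R^2 = 1 - SS_{res}/SS_{tot}$; the sources use the term
without defining it, and $R^2$ is the standard quantity bounded near the
values they report. `fit_and_validate()` scores $R^2$ out of sample on
the validation window only.

**Identifiability.** With only $I+T$ observed over a window that ends
while the epidemic-like curve is still rising, the ten-rate model is
practically unidentifiable: parameter sets whose in-window curves differ
by $10^{-6}$ can diverge visibly after the window. The package therefore
treats *curve recovery* (RMSE of the fitted $I+T$ trajectory, out-of-window
$R^2$), never parameter recovery, as the fit's contract, and the test
suite asserts exactly that.

## Problem sizes used by the tests

The unit suite runs sweeps and convergence checks at reduced grids (tens
of trajectories, 100–400 output points each) and fits on shortened
synthetic series; the acceptance-scale checks use the full 65-hour,
10-minute-bin series, a noiseless round-trip fit with 24 multi-starts,
and 20 Poisson replicates with a lighter per-fit search. These sizes are
the package's choice of a desk-scale experiment; all quantitative claims
are computed fresh at test time.

## Known limitations

* The mean-field ODE ignores network structure and user heterogeneity.
* The published closed forms for the coexistence equilibria are evaluated
  as printed and will generally not be roots; rely on the numeric finder.
* Global stability is verified empirically over seeded random starts, not
  proven.
* Fitting quality on real repost data is bounded by the identifiability
  limits above; out-of-window $R^2$ near 0.95, as reported for the
  original case study, is plausible but depends on the data's curvature
  inside the fitting window.
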