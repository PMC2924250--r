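---
title: "A mass-action model of dual-cluster chemotaxis phosphotransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-action model of dual-cluster chemotaxis phosphotransfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosrelay)
```

## The system and the model

*Rhodobacter sphaeroides* runs its chemotaxis signaling from two spatially
separate clusters: a polar cluster whose kinase CheA2 autophosphorylates,
and a cytoplasmic cluster where CheA3 is phosphorylated by CheA4. Both
kinase phosphoforms hand their phosphoryl groups to a shared pool of five
response regulators (RRs): CheY3, CheY4, CheY6, CheB1 and CheB2. CheA2-P
can phosphorylate all five; CheA3-P only CheY6 and CheB2. Each RR-P
hydrolyzes its aspartyl-phosphate spontaneously (autodephosphorylation),
and CheY6-P is additionally dephosphorylated by CheA3, a bifunctional
kinase-phosphatase, in both its phosphorylated and unphosphorylated forms.

`phosrelay` implements this scheme as elementary mass-action kinetics over
the seven phosphoform concentrations

$$x = (A_2P,\; A_3P,\; Y_3P,\; Y_4P,\; Y_6P,\; B_1P,\; B_2P),$$

with every unphosphorylated partner derived from conservation,
$X = X_T - XP$. The derivative of, say, CheY3-P is

$$\frac{d\,Y_3P}{dt} = k_3\,A_2P\,Y_3 - k_{-3}\,A_2\,Y_3P - k_{10}\,Y_3P,$$

and the kinases gain phosphoryl groups at $k_1 A_2$ and $k_2 A_3$ and lose
them through the (reversible) transfer terms. The phosphatase channels are
catalytic: $-k_{15a} A_3\, Y_6P - k_{15b} A_3P\, Y_6P$, leaving CheA3
unchanged. Because the unphosphorylated forms are derived rather than
integrated, conservation $X + XP = X_T$ holds exactly along any
trajectory, not merely up to solver tolerance.

Three structural choices deserve a note, because the reaction list alone
does not fix them:

* **CheA4 is implicit.** The phosphorylation of CheA3 by CheA4 carries a
  first-order constant ($k_2$, s^-1^) and no CheA4 concentration is part of
  the parameterization, so reaction 2 is first-order in unphosphorylated
  CheA3 with CheA4's abundance absorbed into $k_2$.
* **ATP is not modeled.** CheA2 autophosphorylation is likewise first-order
  in unphosphorylated CheA2 ($k_1$, s^-1^), treating ATP as saturating.
* **Transfer is elementary and bimolecular.** Each direction of each
  phosphotransfer carries a single second-order constant; no
  enzyme-substrate complexes are formed. The reverse transfer from CheY6-P
  to CheA2 ($k_{-5}$) is zero — CheY6-P does not rephosphorylate CheA2 —
  but the term is present in the code with coefficient zero so that
  sensitivity scans can perturb it in principle (multiplicative scans skip
  it, see below).
* **The kinase phosphoforms have no autodephosphorylation channel**; the
  only hydrolysis routes are the five RR-P autodephosphorylation reactions
  and the two phosphatase channels.

## Units

Protein totals are printed in µM while second-order constants are
conventionally reported in (M s)^-1^. The user-facing parameter object
keeps the (M s)^-1^ scale; all solver code divides second-order constants
by 10^6 once, at model-build time, so the integrated state is in µM and
time in s. This avoids the poor conditioning of carrying concentrations at
the 10^-6^ M scale against rate constants at the 10^6 scale.

```{r}
p <- che_parameters()
p$k8        # (M s)^-1, as published
p$Y6T       # uM
```

## Steady states

Rate constants span six orders of magnitude ($k_{13} \approx 1.7\times
10^{-4}$ s^-1^ against transfer terms of order 1–10 (µM s)^-1^), so the
system is stiff and its slowest relaxation mode — CheB1-P — has a time
constant near $1/k_{13} \approx 5.8\times10^3$ s. `find_steady_state()`
therefore integrates 10^5^ s with `lsoda` (rtol 10^-8^–10^-10^, atol
10^-12^ µM) from the fully unphosphorylated state and then polishes the
endpoint with a damped Newton iteration (7×7 finite-difference Jacobian),
accepting only when $\lVert \dot x \rVert_\infty < 10^{-10}$ µM/s. The
model's equations do not specify an initial condition; the fully
unphosphorylated state is the natural choice, and the test-suite verifies
that restarting from the fully phosphorylated state reaches the same fixed
point, for the wild type and for the perturbed configurations used in the
protocols.

```{r}
steady_fractions(p)
```

## The shut-off protocol and half-times

Signal termination is measured by an in-silico shut-off experiment:
equilibrate with both kinase inputs active, set $k_1 = k_2 = 0$, and record
the time for each RR-P to fall to half of its steady level. The decay is
integrated with `vode` on a dense logarithmic grid (default 3000 points
from 10^-3^ s to the 10^5^ s horizon, about 370 points per decade) and the
half-level crossing is located by interpolating inside the bracketing
interval. At this grid density neighbouring points differ by 0.6% in time,
so the interpolation error is far below the 2–3 significant figures at
which half-times are meaningful; halving the grid changes no half-time by
more than 1% (tested). A species that never reaches half-level within the
horizon is reported censored at the horizon rather than dropped.

Perturbations are expressed as `scenario()` objects applied *before*
equilibration: a knockout sets the protein's total to zero, phosphatase
removal sets $k_{15a} = k_{15b} = 0$, and any single rate can be zeroed —
the combination `scenario(knockouts = "CheY6", rates_zeroed = "k6r")`
isolates CheB1-P from every phosphate sink and is packaged as
`sink_ablation_half_time()`.

```{r, eval = FALSE}
decay_half_times(p)                                   # wild type
decay_half_times(p, scenario(knockouts = "CheY6"))    # sink deletion
sink_ablation_half_time(p)                            # ~ ln(2)/k13 regime
```

## Stimulation timelines

`run_timeline()` emulates attractant stimulation by switching rate
constants at scheduled times, restarting the stiff solver at each event so
the trajectory is continuous across boundaries. The canonical four-event
sequence (polar input off, on; cytoplasmic input off, on) uses 4×10^4^ s
segments: long enough that every species — including CheB1-P — re-equilibrates
within each segment, which the tests verify by requiring a return to within
0.1% of the resting state after each restoration. The published description
of this experiment does not state segment durations; equilibration of each
segment is this package's choice and reproduces the described sequence of
steady states.

## Sensitivity scans

`run_scan()` perturbs one parameter at a time, multiplying it by factors
0.1, 0.5, 1.5 and 10 (totals and rate constants are treated identically,
matching the view of expression levels as parameters). Two metrics mirror
the published robustness questions: the CheB1-P shut-off half-time (does
the CheY6 sink keep terminating the slowest RR quickly?) and the steady
CheY4-P level with $k_1 = 0$ (does the CheB2-mediated relay still feed the
polar-cluster RRs?). $k_{-5}$ is excluded from the default scan because its
baseline is zero and a multiplicative factor cannot move it; the exclusion
is recorded in the scan's attributes. Rows whose perturbed system fails to
converge would be flagged `converged = FALSE` rather than dropped; with the
default parameterization all 29×4 cells converge.

## The synthetic assay generator and what it stands in for

The transfer constants were originally estimated from closed-system
radiolabel assays: a phosphorylated donor (either a kinase-P or a purified
P1 domain) mixed with an RR, sampled at discrete times, quenched, and
quantified as band intensities on phosphorimages. `simulate_assay()`
reproduces the two designs in mass-action form:

* **forward**: donor-P + RR with reversible transfer and RR-P
  autodephosphorylation;
* **reverse**: P1-donor + CheA2 + RR, where the donor feeds the RR (a
  dedicated nuisance constant `k_d`, since no constant is published for the
  P1 construct), the RR-P passes label to CheA2 reversibly, and the donor's
  direct transfer to CheA2 is fixed at zero, as the control experiments
  established. The appearance of CheA2-P therefore reads out reverse
  phosphotransfer alone.

Band intensity is taken proportional to concentration with unit gain — only
relative kinetics inform rate recovery, so the gain is not a fit parameter.
Measurement error is modeled as independent multiplicative lognormal noise
with unit mean and a chosen CV, applied per band per time point
(`noise_model()`); no error model is published for the phosphorimaging
step, so the CV is the generator's own knob (default studies use 5–10%,
typical of densitometry). The generator does **not** emulate gel-loading
variation correlated within a lane, background subtraction, label decay, or
detector saturation, so passing recovery tests here demonstrates
identifiability under well-behaved noise, not robustness to every artifact
of real gels.

Default sampling uses eight log-spaced points. Their window matters: at the
published CheA3-P→CheB2 constants the bimolecular transfer equilibrates in
well under a second at bench concentrations (30 µM donor, 10 µM RR), after
which only the equilibrium ratio and the slow hydrolysis drain remain
visible. The default design therefore spans 0.1–600 s so that the
pre-equilibration transient — which is what fixes the absolute magnitudes
of $k_f$ and $k_r$ rather than just their ratio — is sampled. With
sampling that misses the transient the two constants become practically
non-identifiable under noise, which is itself a useful property of the
testbed.

## Rate fitting

`fit_rates()` minimizes the squared residuals between `simulate_assay()`
and the data over every observed (time, species, replicate) triple. Two
routes run: bounded Levenberg–Marquardt from the initial guess, and a
differential-evolution global search (rand/1/bin, reflection at the
bounds, seed-deterministic) polished by Levenberg–Marquardt. The reported
estimate is the route with the lower residual sum; the routes' relative
disagreement is recorded so a rugged or degenerate objective surfaces as
`agreement = FALSE` instead of silently. Estimates are bounded below by
zero, so an irreversible transfer is recovered *at* the boundary rather
than as a small negative number. A candidate parameter set whose
integration fails contributes a large finite penalty to the objective, so
the search simply moves away from pathological corners of the box
(default upper bound 10^7^ (M s)^-1^, an order of magnitude above the
largest published transfer constant).

## Numerical choices, collected

| Quantity | Choice | Why |
|---|---|---|
| steady-state horizon | 10^5^ s | ~17 time constants of the slowest mode |
| steady acceptance | $\lVert \dot x\rVert_\infty < 10^{-10}$ µM/s | far below any reported flux |
| decay grid | 3000 log-spaced points, 10^-3^–10^5^ s | interpolation error ≪ printed precision |
| decay solver | `vode`, rtol 10^-10^, atol 10^-14^ | stiff; tiny atol so half-levels of small pools resolve |
| timeline solver | `vode`, rtol 10^-8^, atol 10^-12^ | segment restarts at events |
| Newton refinement | damped, box-projected, FD Jacobian | keeps iterates in $0 \le XP \le X_T$ |
| DE budget | pop 24, 60 generations (default) | small 2–3 parameter problems |

Degenerate inputs are handled explicitly: a knockout removes its species
from half-time tables (`absent`), a zero-input system refuses the shut-off
protocol with an error, a buffer-control assay (no RR) stays flat, and a
censored half-time carries the horizon value with `censored = TRUE`.

## Known limitations

* Receptor–kinase coupling, methylation/adaptation dynamics and motor
  switching are outside the model: it describes phosphotransfer among
  purified components at cellular concentrations in a well-mixed
  compartment. Localization of the two clusters enters only through which
  kinase phosphorylates which RR.
* The full original ODE listing behind the published simulation tables is
  not available; the right-hand side here is reconstructed from the
  reaction list and rate table. The reconstruction reproduces the
  steady-state fraction tables essentially exactly and the wild-type and
  single-deletion half-time columns to within a few percent, but the
  phosphatase-free half-times and the sink-ablation half-time computed
  here run 10–20% above the published simulation values (the package's
  own tests compute exactly this comparison). Structural variants that
  could close the gap — kinase-P hydrolysis, reverse transfer on total
  rather than free kinase, alternative shut-off orderings — were examined
  and each degrades the agreement elsewhere, so the faithful
  reconstruction is kept.
* The noise model is uncorrelated across bands and time points;
  systematic gel artifacts are not emulated.
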