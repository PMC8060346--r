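---
title: "Methods: a minimal PBPK drug-disease model of captopril"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a minimal PBPK drug-disease model of captopril}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captopbpk)
```

## The model

`captopbpk` implements a *minimal* PBPK model: instead of resolving every
organ, the body is lumped into a systemic (central) compartment, a single
adjusting compartment (SAC) that soaks up distributional delay, an oral
absorption depot, and bookkeeping states for eliminated drug and
first-pass loss. This structure suits captopril, a low-volume BCS class I
drug whose tissue concentrations track plasma closely. The governing
equations (amounts in mg) are

$$
\begin{aligned}
\dot A_{dep} &= -k_a A_{dep} && (t \ge t_{lag};\ A_{dep}(0) = f_a \cdot D
\text{ for oral, else } 0)\\
\dot A_c &= F_h k_a A_{dep} - \frac{CL}{V_c} A_c - k_{in} A_c +
k_{out} A_{sac}\\
\dot A_{sac} &= k_{in} A_c - k_{out} A_{sac}
\end{aligned}
$$

with systemic concentration $C = A_c / V_c$ and total plasma clearance
$CL = CL_h + CL_R$. Neither the model family's source description nor the
compiled parameter table writes these equations out; they are this
package's own concrete reading of "first-order absorption + minimal PBPK
with $k_{in}/k_{out}$ + clearance-based elimination", chosen so that:

* the central volume follows the steady-state partition rule
  $V_c = V_{ss} / (1 + k_{in}/k_{out})$, which reproduces the input
  $V_{ss}$ exactly at distributional steady state and collapses to a
  one-compartment model when $k_{in} = 0$;
* first-pass hepatic loss enters as the multiplicative well-stirred
  availability $F_h = 1 - CL_h/Q_h$ on the absorption flux (the compiled
  inputs contain no liver volume or intrinsic clearance that would
  support an explicit liver compartment), preserving
  $F = f_a \cdot F_h$ and the systemic meaning of $CL$;
* the lag time delays depot outflow exactly; since all states are
  constant before $t_{lag}$, the solver integrates in shifted time, so
  the discontinuity never reaches the integrator;
* mass balance
  $A_{dep} + A_c + A_{sac} + A_{elim} + A_{fp} = \text{delivered dose}$
  is tracked explicitly and asserted in the tests.

Gut availability is fixed at 1: no gut-extraction parameter exists in
the input set, and captopril's $f_a = 0.7$ already absorbs pre-systemic
loss at the gut wall.

## Drug parameters

All drug inputs live in `inst/extdata/captopril.yaml` and load via
`captopril_parameters()`: MW 217.29 g/mol, logP 0.34, pKa 4.02
(monoprotic acid), $k_a$ 1.75 h⁻¹, $t_{lag}$ 0.2 h, $f_a$ 0.7,
$k_{in} = k_{out} = 0.25$ h⁻¹, B/P 1, $f_u$ 0.73, $V_{ss}$ 0.267 L/kg,
$CL_{iv}$ 49.5 L/h, $CL_R$ 22.2 L/h (so hepatic clearance is 27.3 L/h).
The YAML stores $V_{ss}$ at its full stated precision (0.267) rather
than the 2-significant-figure display value (0.26) that appears in the
compiled input table, since the higher-precision value is what drives
simulation.

## Tissue partitioning and Vss

`compute_kp_rodgers_rowland()` implements the acids/neutrals branch of
the Rodgers-Rowland method: ionization-corrected water partitioning
(intracellular pH 7.0, plasma pH 7.4 — the method's standard
convention), neutral-lipid and neutral-phospholipid partitioning via
$P = 10^{\log P}$ (with the conventional $0.3P + 0.7$ phospholipid
surrogate), and albumin-type binding scaled from
$1/f_u - 1 - \text{plasma lipid terms}$ by the tissue-to-plasma albumin
ratio. Acidic-phospholipid binding does not apply to acids and is not
implemented; other ionization classes are dispatched but rejected
explicitly. The tissue composition constants and reference-man
fractional organ volumes are packaged as a versioned plain-text table
(`tissue_composition.csv`, source noted in its header), because the
reference analysis names only "prediction method 2" without stating the
composition vintage it used. The erythrocyte partition follows from
B/P = 1 and hematocrit 0.45 as $E\!:\!P = (B/P - (1-Hct))/Hct = 1$, and

$$V_{ss} = V_{plasma} + V_{ery}(E\!:\!P) + \textstyle\sum_t V_t K_{p,t}.$$

With the packaged constants this yields 0.2755 L/kg against the
reference prediction of 0.267 L/kg (+3.2%). Because the composition
vintage is unknowable, the acceptance band for this quantity is a
documented ±15%.

## Virtual populations

`sample_population()` draws demographics uniformly within study-reported
ranges and applies between-subject variability:

| quantity | distribution | default | rationale |
|---|---|---|---|
| total clearance | lognormal, median-preserving | CV 30% | conventional PK IIV; one shared multiplier on $CL_h$ and $CL_R$ so total CL carries the nominal CV |
| $V_{ss}$ | lognormal | CV 25% | conventional |
| $k_a$ | lognormal | CV 30% | absorption is the noisiest process |
| $Q_h$ | lognormal | CV 15% | moderate physiological spread around 90 L/h |
| $f_a$ | logit-normal | SD 0.4, median 0.7 | keeps $f_a \in (0,1)$; sized so the population bioavailability spread emulates the reported predicted spread (median 0.5, lower tail ≈ 0.3) |

The reference simulator's internal variability model is proprietary;
these defaults were fixed once, before any acceptance measurement, and
are all overridable per `population_spec()`. A subject's hepatic
clearance is capped at 95% of their hepatic flow so the well-stirred
contract never degenerates.

Note one structural limitation: because $F = f_a F_h \le f_a < 1$,
reaching the top of the reference-predicted bioavailability range
(up to 0.9) would require a subject with near-complete absorption *and*
hepatic extraction below 0.12 simultaneously — a joint tail that this
model family essentially never produces at n = 100 under defensible
variability. The simulated spread therefore reproduces the median and
the lower tail of the reference range, not its extreme upper tail.

Disease scaling (`apply_ckd_scaling()`, `apply_chf_scaling()`,
`apply_geriatric_scaling()`):

* **CKD** — GFR bands mild 60-90, moderate 30-60, severe 15-30 mL/min
  (uniform within band; the moderate/severe bands mirror the named
  renal-impairment populations of the reference platform, mild is
  standard staging); hepatic clearance × 0.80 / 0.55 / 0.35; renal
  clearance × GFR/120; $V_{ss}$ (and implicitly all $K_p$) × 2.51 in all
  three bands — the source wording ("in the kidney disease populations")
  suggests all severities, and that is the default here.
* **CHF** — evaluation population is a 50:50 moderate:severe mix (the
  reference study reports only "mixed"); hepatic flow × 0.54 / 0.46,
  hepatic clearance × 0.55; renal (0.55 / 0.63) and peripheral
  (0.44 / 0.28) flow fractions are recorded on the subject but do not
  alter $CL_R$ — the disease description names only the hepatic scaling
  factor, and $CL_R$ is an empirical input here, not a flow-limited
  model. A config switch for renal-flow propagation was considered and
  left out of the defaults.
* **Geriatric** — GFR, hepatic metabolic clearance and hepatic flow
  (cardiac output) all decline 1%/year above age 40, floored at 50%.
  Scaling metabolic clearance together with flow keeps the extraction
  ratio — hence oral bioavailability — age-invariant while absolute
  clearance falls, which is what produces the observed *decrease* in
  geriatric CL/F; scaling flow alone would paradoxically raise CL/F.
  The 1%/year rule is a deliberately simple, documented stand-in for a
  full geriatric physiology model.

Scaled subjects carry a flag, and applying a disease scaling twice is an
error.

## Simulation, NCA and evaluation

Trials follow the 10-trials-of-10-subjects convention
(`run_trial_set()`), integrated with `deSolve::lsoda` at rtol 1e-8 /
atol 1e-10 mg — tight because the mass-balance assertions demand it.
The default schedule spans 0-12 h with a 0.025 h grid over the first
two hours (captopril's absorption peak sits near 0.5 h) and 0.05 h
steps after; 12 h is about four terminal half-lives for the healthy
oral case, so closed-form recovery tests use a denser 24 h grid
instead. The five-half-life horizon check is opt-in
(`sampling_schedule(..., lambda_z =)`) because the terminal rate is not
knowable from the schedule alone.

NCA follows the conventional rules: $\lambda_z$ by log-linear
regression over the best terminal window (max adjusted R², ≥ 3 points,
ties to more points, Cmax excluded for oral profiles, zero
concentrations excluded from the regression but kept as zeros in the
trapezoid); linear trapezoidal AUC to the last observation plus
$C_{last}/\lambda_z$ (lin-log trapezoids were considered and left out:
linear is the simplest defensible reading and the packaged clearances
are dose/AUC-consistent under it); CL = dose/AUC with mg→ng and mL→L
bookkeeping, giving CL/F for oral routes.

Evaluation statistics: observed/predicted ratio and fold error are the
same formula under two conventional names and share one implementation;
AFE is $10^{\overline{\log_{10}}(\text{ratio})}$, i.e. the geometric
mean ratio with sign retained (not the absolute fold error — verified
against the packaged group summaries); the mean ratio carries a
Student-t 95% interval. `mean_ratio_ci(style = "printed")` reproduces
the display convention of the packaged reference tables — ratios at
2 dp before averaging, interval bounds truncated to 2 dp — which is the
only convention that regenerates all six published interval triples
exactly; the default `style = "exact"` computes at full precision. One
packaged row (severe-CKD CL/F) prints a ratio of 0.69 whose own printed
columns give 0.68496; the package keeps both and the tests hold that
row to one unit in the last printed digit. The oral CL/F mean is 1.0967
unrounded; the package reports 1.10 (the prose value 1.09 is its
truncation). The twofold interval is closed, $[0.5, 2]$; of the 57
packaged pairs exactly one (fed-state Cmax, ratio 0.43) falls outside,
the known unmodeled food effect — this model, like the reference one,
carries no food-effect mechanism, and fed scenarios are simulated
identically to fasted ones. VPC summaries report per-timepoint mean,
5th/95th percentiles (type-7 quantiles) and min/max.

## Synthetic observed data

Raw observed concentration profiles exist only as digitized figures and
are not redistributable, so `generate_synthetic_observed()` stands in:
it simulates a population under optionally perturbed parameters
(emulating model misspecification) and multiplies each observation by
lognormal residual error, returning the matched unperturbed set so
recovery pipelines can test against known ground truth. What passing
recovery tests show is that the pipeline (simulate → NCA → ratio
statistics) faithfully measures an injected clearance bias at iv
dosing; they do not show that the model matches real digitized
profiles, and residual error here is i.i.d. multiplicative — real
assay/digitization error is neither. Clearance recovery uses the iv
route by design: under oral dosing a clearance perturbation also moves
first-pass bioavailability, so CL/F scales by $p \cdot F/F'$ rather
than the injected $p$.

## Problem sizes and determinism

The packaged evaluation (`run_reference_scenarios()`) simulates all 19
study scenarios at the 10×10 design (1900 ODE solves) — sizes chosen to
match the reference trial convention. Every stochastic step flows from
one integer seed (scenario $i$ uses seed + $i$), and fixed seeds give
bit-identical outputs. Lognormal multipliers are median-preserving
($e^{\sigma Z}$ with $\sigma = \sqrt{\ln(1 + CV^2)}$), so zero-CV
populations hit the typical values exactly and medians are unbiased
under variability.

## Known limitations

* Absolute concentration-scale agreement with the reference platform is
  not expected: its population physiology is proprietary. The package's
  checks are therefore structural (closed-form limits, mass balance,
  monotonicity across CKD severity, twofold envelope against the
  reference-predicted parameters) rather than value-exact.
* iv-bolus Cmax is defined by the first sampling time ($C(0) = D/V_c$
  here), so it is compared across models only for oral routes.
* Single doses only; no infusions, multiple dosing, nonlinear
  clearance, mechanistic absorption, or the food-effect mechanism.
* The CHF model leaves $CL_R$ unscaled and the CKD model does not
  propagate plasma-protein or hematocrit changes into clearance
  (clearance is an empirical input, not $f_u \cdot CL_{int}$;
  propagating both would double-count the fitted hepatic scaling
  factors).
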