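---
title: "Methods: pilot bioequivalence analysis with the Cmax f2 factor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pilot bioequivalence analysis with the Cmax f2 factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bepilot)
```

## The problem

Before committing to a fully powered (pivotal) bioequivalence trial, a
sponsor often runs a downsized pilot: a 2×2×2 crossover with roughly 12–30
subjects, each receiving the Test and the Reference formulation once. For
highly variable drugs — intra-subject coefficients of variation (ISCV) of
40–60% on Cmax and AUC, as seen with pazopanib — such a pilot almost never
has the power to show average bioequivalence: the 90% confidence interval
for the geometric mean ratio (GMR) is simply too wide, even when the point
estimate is centred. `bepilot` implements the standard average-
bioequivalence analysis together with an alternative similarity statistic
for exactly this situation: the f2 factor applied to Cmax-normalised mean
concentration–time profiles, which summarises how closely the Test
absorption phase tracks the Reference one and maps, together with the
ISCV, to a confidence level for proceeding to a pivotal study.

## Average bioequivalence

For each metric (Cmax, AUC truncated at 72 h) the model is the
all-fixed-effects crossover ANOVA on the natural-log scale:

ln *y* ~ Sequence + Subject(Sequence) + Period + Formulation.

There is no random subject term: the nested subject effect absorbs all
between-subject variation, so the residual mean square *s²* is the
within-subject variance and

ISCV = 100·√(exp(*s²*) − 1).

Least-square means are equal-weight averages of the model prediction over
every subject × period cell with the formulation forced to each level;
their back-transformed ratio is the GMR, and the two-sided 90% CI comes
from the *t* distribution on the residual degrees of freedom (n − 2 for
complete data). Bioequivalence requires the whole CI inside the closed
interval [80.00, 125.00]%; the decision is taken on unrounded values.
Sequence is tested against the Subject(Sequence) mean square, the other
terms against the residual, the convention for crossover designs. With
unbalanced sequences the normal equations yield marginal (Type-III-style)
means; the test suite checks the fit against an independent
generalised-inverse normal-equations solve.

## The Cmax f2 factor

The arithmetic-mean Test and Reference profiles over completers are both
normalised to the maximum of the mean Reference profile (CmaxR) and
truncated at the time that maximum occurs (tmaxR):

C\^N\_t = 100·C̄\_t / CmaxR, for 0 ≤ t ≤ tmaxR,

and the similarity factor is

f2 = 50·log10[100·(1 + (1/n)·Σ (R\^N\_t − T\^N\_t)²)^−0.5],

with the sum over the post-dose grid points 0 < t ≤ tmaxR. Identical
curves give exactly 100; a constant 10-unit normalised offset gives
50·log10(100/√101) ≈ 49.89 regardless of n.

Decisions taken in this implementation where the formulation left room:

* **The pre-dose point is excluded from the sum.** Both normalised curves
  are identically zero at t = 0; counting an always-zero difference would
  inflate similarity. `n_points` therefore counts post-dose points only.
* **tmaxR is the tmax of the arithmetic-mean Reference profile**, not the
  median of individual tmax values, and maxima are located on the grid
  only (no interpolation); ties break to the earliest time.
* **One normalising constant.** Both curves are scaled by the Reference
  CmaxR, so the statistic is invariant to any common rescaling of the raw
  profiles but sensitive to a Test/Reference level difference.
* **Band gaps are resolved conservatively.** The stated bands are:
  f2 ≥ 50 → >90% confidence regardless of ISCV; f2 ≥ 41 with ISCV ≥ 50% →
  >80%; f2 ≥ 35 with ISCV > 40% → >60%; f2 < 35 → similarity not shown.
  A combination outside these rules (e.g. f2 ∈ [35, 50) with ISCV ≤ 40%)
  is reported at the weakest band and flagged `outside_tabulated`.

## Non-compartmental analysis

Cmax/tmax use the earliest-maximum convention. AUC(0–72) uses the
linear-up/log-down trapezoid; the log rule degenerates to linear for
equal, rising or zero-bounded segments, and an all-linear option exists.
BLQ observations before a subject's first quantifiable sample count as 0;
embedded and trailing BLQ are treated as missing (intervals bridge across
them; they never enter the terminal fit). λz comes from the ln-linear
regression over trailing point sets (k ≥ 3, strictly after tmax) that
maximises the adjusted R², ties within 10⁻⁴ going to the larger set;
non-positive slopes are inadmissible and leave λz absent. A profile
without a usable 72 h sample is truncated at the last quantifiable time
and flagged non-evaluable for bioequivalence. These are the widely used
"best-fit" NCA conventions; the originating analyses name their software
but not its point-selection rule, so the rule here is documented rather
than inherited.

## TOST power and sample size

On the ln scale the within-subject SD implied by an ISCV is
s = √(ln(1 + CV²)) — the inverse of the ISCV formula above — the standard
error of the formulation contrast is s·√(2/n) and the residual df is
n − 2. The power of the two one-sided tests procedure (equivalently, of
CI inclusion) is evaluated exactly by integrating the conditional normal
rejection probability over the scaled-χ distribution of the residual SD
(the Owen's-Q construction, as adaptive quadrature with relative
tolerance 10⁻¹¹), not by the shifted-*t* approximation. Sample sizes are
the smallest even n reaching the target power; a GMR given as a range is
evaluated at its worst-case endpoint (for a log-symmetric range either
endpoint suffices). Two consequences worth knowing:

* `sample_size(50, 105)` returns 96 and `sample_size(35, c(90, 111.11))`
  returns 106 — the exact computation reproduces the customary planning
  figures for these scenarios.
* At the acceptance boundary (true GMR = 125%) the procedure's size is
  *below* α whenever t·s·√(2/n) exceeds half the ln-width of the
  acceptance range, because the CI then rarely fits inside the limits at
  all. At n = 24 and ISCV 50% the exact size is 1.6%, approaching 5% only
  as n grows. The Monte Carlo facilities reproduce this conservatism.

## The synthetic-data generator

The raw studies this methodology was developed on are not public, so the
package carries a first-class simulator whose defaults encode the study
conditions the analysis assumes:

* **Model.** One-compartment, first-order absorption:
  C(t) = F·D·ka/(V(ka−ke))·(e^(−ke·t) − e^(−ka·t)), with closed-form
  tmax = ln(ka/ke)/(ka−ke) used as a testing oracle. The drug's kinetics
  have been described by both one- and two-compartment models; one
  compartment exercises every downstream statistic and keeps the oracle
  closed-form.
* **Pazopanib presets.** Apparent V = 25 L (V/F scale, so F defaults
  to 1), terminal half-life 42 h, ka = 1.25 h⁻¹ (tmax ≈ 3.5 h), dose 200
  or 400 mg, LLOQ 50 or 100 ng/mL, n = 24, and the 20-point 0–72 h
  sampling grid. The half-life follows the observed single-dose NCA scale
  (≈41–45 h) rather than the ~30 h literature average, since the
  generator emulates the studies being analysed; with sampling truncated
  at 72 h the NCA estimate is the quantity that matters downstream.
* **Variability.** Lognormal throughout, sdlog = √(ln(1+CV²)).
  Between-subject CVs (ka 30%, ke 25%, V 25%) are package choices —
  no published values exist for this design — and are exposed as
  configuration. The entire intra-subject CV target (default 50%) is
  placed on the occasion-level bioavailability deviate: since F scales a
  whole occasion's profile, the ANOVA's ISCV on ln-Cmax and ln-AUC then
  recovers the target exactly in expectation (calibration constant 1.0,
  verified by the parameter-recovery test at n = 1000). Occasion-level ka
  variability is available to decouple Cmax noise from AUC noise but
  defaults to 0.
* **Censoring and design.** Concentrations below the LLOQ are stored as
  BLQ with the value absent (they are censored, never resampled);
  sequences are balanced by construction and shuffled under the seed;
  a period effect is available (default off) to exercise the ANOVA's
  period term.

What passing simulation tests do **not** show about real data: the
generator has no enterohepatic recirculation, no saturable absorption
(the drug's known dose non-proportionality), no food effects, no
correlated BSV structure, and its BLQ pattern is confined to early and
late tails. Conclusions about the statistics' operating characteristics
transfer; conclusions about pazopanib biology do not.

## Problem sizes and numerical choices

The heavy acceptance checks use 2000 full simulate→NCA→ANOVA replicates
for CI coverage at the pilot design, and 5000/50,000 replicates of the
vectorised metric-level crossover Monte Carlo (`simulate_be_outcomes`,
proven algebraically identical to `run_abe` on balanced data) for
pass-rate checks — sizes chosen so the whole suite runs in a few minutes
on one CPU while keeping Monte-Carlo error well inside the asserted
bands. Quadrature tolerances (10⁻¹¹ relative) and the λz tie tolerance
(10⁻⁴ adjusted-R² units) are fixed constants. Degenerate inputs are
handled explicitly: ka = ke is refused (flip-flop), a zero residual MSE
yields a zero-width CI, all-BLQ occasions fail NCA per occasion rather
than aborting the study, and an empty candidate set leaves λz absent.

## Worked example

```{r example}
ps <- study_preset("pazopanib_200")
st <- simulate_study(ps$params, ps$var, ps$design, seed = 42,
                     label = "pilot 200 mg")
run_pipeline(st, mode = "pilot")
```

## Known limitations

Only 2×2×2 designs are supported (no replicate designs, no
reference-scaled average bioequivalence, although the drug's ISCV would
qualify); AUC is truncated at 72 h by design, with no extrapolation to
infinity; tmax is summarised descriptively, with no nonparametric test;
the f2 decision bands are taken as given rules and are not re-derived
here, and no bootstrap CI for f2 is provided.
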