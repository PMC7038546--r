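---
title: "Classifying type 1 and type 2 diabetes from EHR event tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying type 1 and type 2 diabetes from EHR event tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmtype)
```

## The problem

Administrative health databases record encounters, prescriptions and
laboratory results for whole populations, but they rarely record a reliable
diabetes *type*. Type 1 diabetes (T1D) is an autoimmune, insulin-deficient
disease that must be treated with insulin for life; type 2 diabetes (T2D)
is far more common, typically adult-onset, and often managed with oral
agents. Because their prognoses differ sharply -- especially among adults
under 40, where both types occur -- population research needs deterministic,
validated rules that assign a type from routinely collected data.

dmtype implements such rules for ICD-9-coded systems, together with
everything needed to validate them: cohort construction from raw event
tables, exact binomial intervals, Cohen's kappa, age stratification, and a
derivation/validation selection procedure. The rules come in two families:

* **Code rules.** ICD-9 fifth-digit conventions distinguish type 1 codes
  (`250.x1`, `250.x3`) from type 2 codes (`250.x0`, `250.x2`). A *code
  ratio* rule is positive when
  $\#\{\text{type 1 codes}\} / \#\{\text{type 2 codes}\} \ge r$
  for a threshold $r$; with no type 2 codes the ratio is taken as
  $+\infty$, so any type 1 code makes the rule positive, and a person with
  no typed codes is negative. Count rules ("at least one type 1 principal
  code", ...) are also provided.
* **Prescription rules.** Long-term insulin (prescriptions of at least 28
  days) initiated within a window of diagnosis marks T1D; *multiple daily
  injections* (MDI) -- long-acting plus short-acting insulin co-initiated
  within a month -- is the classic basal--bolus T1D regimen, optionally
  restricted to persons with no other glucose-lowering medication (GLM).

A positive rule classifies the person as T1D, a negative one as T2D; rules
never abstain. Boolean pairings ("B and C", "B or C") trade sensitivity
against positive predictive value (PPV).

## Cohort construction

Diabetes onset is the first occurrence of any of: outpatient HbA1c
$\ge$ 6.5 %, outpatient fasting plasma glucose $\ge$ 7 mmol/L, a
non-insulin GLM prescription, or long-term insulin ($\ge$ 28 days). Ties on
the same day resolve in that listing order. Inpatient glucose measurements
are ignored so acute stress hyperglycaemia is not mistaken for diabetes; we
apply the same exclusion to inpatient HbA1c by default because the onset
definition speaks of glucose measurements generally, but
`onset_config(exclude_inpatient_hba1c = FALSE)` exempts HbA1c, which is not
an acute-stress measure.

To avoid detecting gestational diabetes, candidate events are discarded
inside `[delivery - 9 months, delivery + 6 months]` around each delivery
and within $\pm$ 9 months of pregnancy-related encounters (chapter codes
630--676) outside those windows. "Months" are calendar months with
end-of-month clamping (Jan 31 + 1 month = Feb 28) rather than 30-day
blocks: clinical window phrasing is calendar-based, and the choice is
confined to `add_months()`. Delivery procedure codes (chapters 72--75) and
pregnancy diagnosis codes are matched on the integer chapter prefix only,
keeping the predicate axis-agnostic, since source systems differ in which
coding axis carries them.

Eligibility: onset between 2002-01-01 and 2015-12-31 (so at least one year
of follow-up to the end of 2016), age at diagnosis between 1.5 years
(excluding neonatal diabetes) and 100 years, and a binary reference label.
Age is the exact day difference divided by 365.25. Exclusions are counted
in a fixed order (no onset, out of window, age, monogenic/secondary,
missing label) and always sum to input minus cohort size.

The derivation/validation split is a per-person Bernoulli draw with
expected fraction 2/3. Rather than consuming R's RNG stream, the
assignment is a pure 32-bit hash of `(seed, person_id)` (FNV-1a with a
murmur-style finalizer, computed in exact double arithmetic), so it is
reproducible across machines, independent of row order, and unchanged when
other code draws random numbers. We chose unstratified randomisation; the
procedure it mirrors reported none.

## Evaluation conventions

All intervals are exact Clopper--Pearson, in the beta-quantile form
$\mathrm{lower} = B_{\alpha/2}(x,\, n-x+1)$,
$\mathrm{upper} = B_{1-\alpha/2}(x+1,\, n-x)$, with the conventional 0 and
1 endpoints at $x = 0$ and $x = n$. The test suite checks them against an
independent bisection on the binomial tail sums for every $x \le n \le 60$.

Cohen's kappa is $(p_o - p_e)/(1 - p_e)$; when both raters are constant
($p_e = 1$) we define it as 1 under perfect agreement and 0 otherwise, the
only two cases that arise. The 2x2 formula is symmetric in the positive
class, which the suite asserts.

Two display conventions matter when reproducing published tables. First,
rounding is half-up (95.25 renders 95.3), not banker's; internal values are
never rounded. Second, PPV can be flagged "undefined" under two
conventions: the default marks it undefined whenever *no true positive was
identified* (so a 0/1 cell displays as undefined even though 0.0 is
computable), matching the source tables; `ppv_convention = "standard"`
only does so when there are no positive calls at all.

The proportion-of-T1D-by-age curve uses a centred moving window (15 years
by default) evaluated on a unit age grid, truncated at the cohort age
range; grid and centring are our choices, as the original figures state
only the window width.

## The selection procedure

`select_algorithms()` screens candidates on the derivation cohort: the
highest-sensitivity code and prescription rules become A and C, the
highest-PPV ones B and D, with ties broken by the greatest sum of
sensitivity and PPV. The eight and/or pairings are then evaluated and the
arg-max by sensitivity, PPV and kappa across all twelve become the "high
sensitivity", "high PPV" and "optimized" algorithms.

One design choice deserves a note. Within the sensitivity arm, candidates
that are *time-window variants of the same prescription rule* and sit
within one reference-positive case of the family's best are treated as
tied and resolved by the sensitivity-plus-PPV sum. Windowed variants of
one rule capture the same clinical event at different lags and typically
disagree on a handful of people, so letting a single case decide between
them would be noise-driven; the pooled tiebreak instead prefers the window
with better PPV. Code rules have no window axis and keep strict ties. With
this rule the published candidate table selects "ratio $\ge$ 0.5" (A),
"ratio $\ge$ 4" (B), "insulin within 90 days" (C) and "MDI with no other
GLM" (D), and the twelve-algorithm table selects B$\lor$C, B$\land$D and
B$\land$C as the three headline algorithms -- which the acceptance tests
assert.

## The synthetic generator

Restricted registry data cannot ship with the package, so
`generate_ehr()` emits a synthetic register with the statistical structure
the rules exploit:

* a rare-T1D mix (0.8 % by default, the validation-cohort true
  proportion), with age at diagnosis drawn from truncated normals --
  T1D 22.7 (SD 12.6), T2D 55.9 (SD 11.4) years;
* negative-binomial post-diagnosis code counts, frozen at parameters that
  reproduce the observed medians and interquartile ranges exactly at the
  quantile level (T1D type 1 codes: $\mu = 3.5$, size 1.5; T1D type 2:
  $\mu = 0.8$, size 0.2; T2D type 1: $\mu = 0.05$, size 0.2; T2D type 2:
  $\mu = 2.9$, size 0.3), split principal/mixed binomially;
* per-type prescription probabilities (any insulin, insulin within 90
  days, MDI, metformin, other GLM) with nesting enforced by construction:
  the within-90-days and MDI draws are made conditionally on the
  any-insulin draw, so infeasible configurations are rejected at
  validation and nesting can never be violated in output;
* a single latent per-person severity draw that couples code counts and
  prescription events through a Gaussian copula (strength 0.4 by default).
  The copula preserves every marginal exactly -- which is what makes the
  3-standard-error recovery tests sharp -- while inducing the positive
  dependence between heavy type 1 coding and early insulin without which
  combination algorithms would look artificially weak. The joint
  distribution is *not* identified by any published marginal; the copula
  is an explicit modelling choice.

Every person carries an onset-qualifying event on their intended diagnosis
date (an outpatient lab, or a day-0 GLM prescription for
prescription-presenting persons), so rebuilding the cohort from the raw
tables recovers the intended diagnosis dates exactly; pre-diagnosis
sub-threshold screening labs and inpatient stress glucose are included
precisely because the onset logic must ignore them. Deliveries are placed
at least ten months after diagnosis: the generator exercises the
gestational shielding code without deliberately erasing onsets.

What the generator does **not** emulate: longitudinal disease progression,
comorbidity and mortality structure, coding drift over calendar time,
informative missingness, or any correlation between age and coding
intensity. Passing the recovery and pipeline tests therefore shows the
machinery is correct under the stated statistical structure -- not that the
algorithms would attain the same operating points on another real
population.

`generate_from_matrix()` is the complementary tool: given a confusion
matrix and a rule, it builds a minimal cohort of archetype persons (each
positive person carries the rule's satisfying event pattern, each negative
only the onset lab) that replays the matrix through the full
cohort-building, classification and evaluation path. The published
validation rows are asserted this way, end to end, rather than by
evaluating formulas on transcribed counts alone.

## Problem sizes and runtime choices

The recovery tests run the generator at $n = 50{,}000$ (about 400 true T1D
cases), where every configured prescription probability must land within
three binomial standard errors and the insulin-within-90-days rule must
recover its configured 96.7 % sensitivity on true T1D; unit tests use
smaller draws ($n$ = 12,000 and below) for speed. The full pipeline
demonstration uses a register-sized cohort of 15,297. These sizes were
chosen so each check's Monte-Carlo error is small relative to the
tolerance it asserts.

## Known limitations

* ICD-10 systems are out of scope; so are free-text prescription parsing
  and drug-name dictionaries (input uses a fixed drug-class enum).
* The rules assume a binary T1D/T2D world; monogenic and secondary
  diabetes must be excluded upstream by the reference label.
* Renal-function-conditioned prescription variants and externally
  developed algorithm adaptations are not implemented.
* Confidence intervals are provided for proportions only, not for kappa,
  and no multiplicity adjustment is applied -- matching the validation
  design the package reproduces.
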