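---
title: "Methods: a multiplicative breast cancer risk model and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multiplicative breast cancer risk model and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brisk)
```

## The model

The package implements a deliberately simple breast cancer risk model built
from the handful of risk factors with the largest and best-replicated
effects: family history of breast cancer, mammographic density, body mass
index (BMI) by menopausal status, and a polygenic risk score (PRS).  These
factors act approximately independently on the relative-risk scale, so the
model combines them multiplicatively,

$$\mathrm{RR}_i \;=\; \mathrm{RR}^{FH}_i \times \mathrm{RR}^{MD}_i \times
\mathrm{RR}^{BMI}_i \times \mathrm{PRS}_i ,$$

with every component *centered* so its population average is 1.  Centering
makes the population-average combined RR approximately 1, which lets the
population incidence hazard serve directly as the baseline: no separate
attributable-risk deflation step is applied.  This is a design choice, and
it is the reason the component tables carry prevalence weights — for a
categorical component with raw relative risks $r_k$ and category prevalences
$w_k$, the centered RR is $r_k / c$ with $c = \sum_k w_k r_k$, so
$\sum_k w_k (r_k/c) = 1$ by construction.

### Component parameterisation

* **Family history** — a category table keyed on the number of affected
  first-degree relatives, the age at diagnosis of the youngest affected
  first-degree relative, and the number of affected second-degree relatives.
  Band labels use a small wildcard language (`"0"`, `"1"`, `"2+"`, `"<50"`,
  `">=50"`, `"any"`), and the first matching row wins.  The shipped default
  table carries values in the flavor of the large pooled familial-risk
  analyses (RR about 1.8 for one affected first-degree relative, higher for
  young-onset or multiple relatives), with prevalences of roughly 14% for
  one or more affected first-degree relatives and 20% for second-degree
  history only.  These defaults are documented approximations, not a
  canonical fitted table; every value is configuration (YAML) and a fitted
  table can be dropped in without code changes.
* **Mammographic density** — either log-linear in percent density,
  $\exp\{\beta\,(PD - PD_0)\}$ with a default slope of 0.02 per percent and
  reference 25% (this gives an RR of about 4 between largely fatty and
  extremely dense breasts, consistent with the literature), or a categorical
  mode with prevalence-weighted centered RRs for radiologist-style density
  bands (default: a two-band <25% / ≥25% scheme with 60/40 prevalence).
* **BMI** — log-linear per kg/m² with separate slopes by menopausal status
  (default −0.02 premenopausal, +0.03 postmenopausal, reference 25 kg/m²),
  reflecting the inverse association before menopause and the positive one
  after.
* **PRS** — the multiplicative, Hardy–Weinberg-normalized score described
  below; it is already centered by construction and enters the product
  unchanged.

### The polygenic score

For a SNP with risk-allele frequency $p$ and per-allele odds ratio $r$, the
genotype factor $r^g$ ($g \in \{0,1,2\}$) is divided by its Hardy–Weinberg
population mean

$$\mu(p, r) = (1-p)^2 + 2p(1-p)\,r + p^2 r^2 ,$$

and the score is the product of the normalized factors across the weight
table.  Under HWE with independent loci, $E[\text{score}] = 1$ exactly; the
test suite verifies this by simulation at $n = 10^5$.  Missing genotypes
contribute a factor of exactly 1 (the population mean) rather than dropping
the sample — this keeps scores centered and the sample size constant, at the
cost of shrinking the scores of poorly genotyped women toward the mean.
Allele orientation against a VCF is resolved by matching the risk allele to
REF or ALT (complementing counts when it is REF); palindromic A/T and C/G
variants are accepted only when the allele frequency is informative
($|p - 0.5| > 0.1$), otherwise they are set missing with a warning.  An
optional rescaling of the log-score to a target OR per SD is provided but
off by default in every pipeline, since the raw normalized product is the
primary definition.

### Absolute risk projection

Relative risk is projected to absolute risk with the standard
cause-specific competing-risk cumulative incidence under piecewise-constant
annual hazards.  With baseline incidence $h_1(t)$ and competing
(non-breast-cancer) mortality $h_2(t)$ per woman-year and $\lambda(t) = rr\,
h_1(t) + h_2(t)$,

$$P(\text{onset by } a{+}\tau \mid \text{alive, free at } a) =
\sum_{t=a}^{a+\tau-1} \frac{rr\,h_1(t)}{\lambda(t)}
\bigl(1 - e^{-\lambda(t)}\bigr) \exp\Bigl\{-\sum_{u=a}^{t-1}\lambda(u)\Bigr\},$$

with the fraction defined as 0 when both rates vanish.  This per-year closed
form is exact for the declared hazard model, so there is no integration
step size to choose; the tests confirm agreement with a day-step Euler
integration to within $10^{-4}$ and exact interval-splitting
($P(a,\tau_1{+}\tau_2) = P(a,\tau_1) + S(a,\tau_1) P(a{+}\tau_1, \tau_2)$ to
$10^{-12}$).  Ages are handled as completed years; real-valued ages are
floored to index the hazard table.  Remaining lifetime risk runs to a
configurable horizon age, default 85 — common US practice for "lifetime"
risk communication; 80 or 90 are equally defensible and a configuration
away.  No truncation is applied to the combined RR by default.

The shipped hazard table is **synthetic**: smooth parametric curves (a
logistic-in-age incidence levelling near 4.4 per 1000 woman-years, and
Gompertz competing mortality doubling roughly every 8 years) chosen to
resemble contemporary US female rates in shape and magnitude.  It yields a
remaining lifetime risk from age 40 of about 11% at RR 1 — the familiar
"one in nine" figure — but it is illustrative, not a published life table;
population-specific projections should substitute jurisdictional rates via
`read_hazards()`.

## Validation statistics

All of the statistics used to validate such models on nested case–control
data are implemented directly (each is checked against an independent
brute-force oracle or a reference implementation in the tests):

* **OR per SD** — univariable logistic regression of case status on the
  score divided by the *control-arm* SD (denominator $n-1$), with Wald
  confidence limits.  Wald (rather than profile-likelihood) intervals were
  chosen as the conventional reporting form for large-sample case–control
  scores; at these sample sizes the difference is negligible.
* **AUC and the DeLong test** — Mann–Whitney AUC with midrank tie handling;
  variance and the 1-d.f. chi-square comparison of two correlated AUCs from
  DeLong's placement-value covariance.  The statistic is invariant under
  strictly monotone transforms of either score.
* **Risk categories and reclassification** — clinical category schemes for
  5-year risk (1%, 1.67%, 3%) and remaining lifetime risk (6%, 12%, 20%,
  25%).  Intervals are left-closed (a risk exactly at 1.67% falls in the
  higher category), resolving an inconsistency between interval notations in
  common table headings in favor of the "≥" form.
* **Categorical NRI** — per arm, net up-movers minus down-movers over the
  arm size, with the Pencina–Steyerberg standard error
  $\sqrt{[p_u + p_d - (p_u - p_d)^2]/n}$; the overall NRI adds the case and
  (sign-flipped) control terms and its SE is the root-sum-square of the arm
  SEs.
* **E/O calibration** — on controls (they represent the general
  population), per age band (<45, 5-year bands, 75+): expected = *median*
  model risk in the band × band size (median, because age-specific risk
  score distributions are strongly right-skewed), observed =
  population-rate-based risk over the same women; the 95% CI of $E/O$ is
  $E/O \cdot \exp(\mp 1.96/\sqrt{E})$.  This log-scale interval form is
  documented as reverse-engineered: it reproduces, at two decimals, all
  four published confidence intervals in the packaged calibration fixture,
  which is the strongest available evidence for the original rule.

### The packaged count tables

The published cross-classification count matrices and calibration columns
are shipped as plain-text fixtures and validated against their embedded row
and column totals at load time.  One transcription note: in the lifetime
reclassification table the controls' "20 to <25%" row is printed as an
undelimited digit run; the parse `(4, 1, 6, 2, 16)` is the unique one
consistent with the printed column totals, and is what the fixture carries.
One documented discrepancy: the published classification improvements for
that same lifetime table (0.381 cases, −0.094 controls, 0.287 overall) do
not equal the values recomputed from the table's own printed counts (0.396,
−0.106, 0.290).  Every other packaged table recomputes exactly, so the
package reports the count-derived values and `cmd_fixtures("table7")`
prints both side by side; the table's threshold-exceedance percentages,
which *do* agree with the counts, are asserted instead.

## The synthetic cohort generator

Because the original nested case–control data are access-controlled, the
pipeline is exercised end to end on synthetic cohorts whose *control* arm
matches the published marginals: age normal(59.3, 7.5) truncated to 40–75,
percent density logit-normal moment-matched to mean 24.7 / SD 18.1 (the
published table gives only mean and SD, so the logit-normal family — which
respects the 0–100 bounds and right skew — is a modelling choice), BMI
normal(25.9, 4.7), family-history categories at their prevalence weights,
menopausal status logistic in age (50% at 51, scale 2.5 years, giving about
85% postmenopausal at the control age distribution), and a lognormal PRS
with mean 1 and log-SD `log(1.61)` by default (the OR per SD of the
313-variant genome-wide score the model uses).

Cases are drawn from a large population pool (50× the requested number) by
weighted sampling with probability proportional to the combined relative
risk — the retrospective analogue of risk-proportional case occurrence in a
nested case–control design, and far cheaper than prospective follow-up
simulation.  Genotypes, when requested, are simulated under HWE with
independent loci (no linkage disequilibrium), matching the PRS model's own
assumptions.

What the generator does *not* emulate: covariance between risk factors
beyond what the multiplicative risk model induces (e.g. the density–BMI–age
correlations of real mammography data), hormone-therapy and biopsy history
(unused by the model), measurement error in density reading, and LD between
variants.  The case–control density difference in real data reflects both
risk and sampling design; the generator induces it solely through the RR
model, and the adequacy of that simplification is an assumption.  Passing
parameter-recovery tests therefore demonstrates internal statistical
correctness of the estimators and the sampling scheme — not transportability
of the shipped default parameters to any real population.

Under this design the generator has known closed-form operating
characteristics that the test suite verifies at scale: a lognormal combined
score with log-SD $\sigma$ yields a true-score AUC of
$\Phi(\sigma/\sqrt 2)$, and retrospective sampling proportional to the
score makes the logistic model for log-score exact with unit slope, so the
designed OR per control SD is $e^\sigma$.  The acceptance suite checks 95%
CI coverage of a designed OR/SD of 1.5 across 100 seeded replicates of
1000 cases / 1000 controls (requiring at least 90/100 covered) and the AUC
closed form on one 20,000-woman cohort to ±0.02 — sizes chosen so the whole
battery runs in a few minutes on one CPU while keeping Monte-Carlo error
well below the tolerances.

## Numerical and interface choices

* Risks are carried as fractions throughout; percentages appear only in
  printed output.
* Band boundaries everywhere are left-closed/right-open, and
  `categorize()` is monotone by construction (`findInterval`).
* Degenerate inputs fail loudly and early: empty arms for rank statistics,
  zero control SD for OR/SD, horizons past hazard coverage, weight tables
  whose prevalences do not sum to 1 (tolerance $10^{-9}$), fixture matrices
  whose margins disagree with their embedded totals.
* Cohort generation is deterministic from (spec, seed); the CLI logs seeds
  and a configuration hash so reported results are traceable to inputs.
* The command-line surface (`score`, `validate`, `simulate`, `fixtures`)
  is a thin wrapper over exported functions; exit codes distinguish
  configuration errors (2) from data errors (3).

## Known limitations

The shipped family-history and density parameters are placeholders at
realistic magnitudes, not fitted values; absolute risks produced with the
default configuration are therefore illustrative.  The engine supports only
two density schemes (continuous percent and one categorical table at a
time), ER-subtype-specific SNP effects are out of scope, and the comparator
clinical models (Gail-type, pedigree-based, and extended empirical models)
are deliberately *not* reimplemented — their risk columns are treated as
inputs wherever a comparison is made.
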