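---
title: "Modelling screen-preventable loss of life in breast cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling screen-preventable loss of life in breast cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenPLL)
```

## The quantity being modelled

Screen-preventable loss of life (screen-PLL) measures, month by month, how
much preventable loss of life a screening programme could still avert in a
cohort. For one woman it is defined on her *no-intervention* disease path:
if that path ends in a premature breast-cancer death — her tumor metastasizes
before it would surface clinically, and the resulting breast-cancer death
precedes her other-cause death — she carries

$$\text{screen-PLL} = 12 \times (t_4 - t_3) \ \text{life-months},$$

where $t_3$ is her breast-cancer death age and $t_4$ her other-cause death
age, over exactly the window in which screening could have changed the
outcome: from the month her tumor reaches the mammographic detectability
threshold of 0.2 cm until it is screen-detected or metastasizes. Outside
that window, and for every woman not on a premature-death path, the value is
zero. The cohort curve is the pointwise sum over women.

The single-woman arithmetic is worth internalising: a woman whose tumor
becomes detectable at 60, metastasizes at 65 and kills her at 72 when she
would otherwise have lived to 92 carries $(92-72)\times 12 = 240$
life-months of screen-PLL over ages $[60, 65)$ and zero elsewhere. This
closed-form case is frozen into the test suite and the acceptance script.

## Natural-history model

Each woman is simulated independently:

1. **Other-cause death.** A yearly Bernoulli walk down a period life table
   ($q_x$), uniform placement within the death year. The realized draw (not
   a deterministic expectancy) serves as $t_4$, so the population spread of
   death ages is preserved.
2. **Clinical surfacing.** A yearly Bernoulli walk against age-specific
   clinical incidence (rate per 100,000 $\to$ per-year probability), uniform
   within the year. The incidence hazard is applied to every woman
   regardless of vital status; a surfacing age past her death is retained in
   the record and resolved at evaluation time. This keeps the sampled
   history independent of anything a strategy can influence, which is what
   makes common-random-number comparisons exact.
3. **Growth geometry.** Tumor diameter follows a Gompertz law
   $d(t) = d_{\max} \exp\{\ln(d_{cell}/d_{\max})\, e^{-\alpha t}\}$. The
   surfacing *diameter* is drawn lognormal, and the first-malignant-cell
   (FMC) age is back-computed through the closed-form inverse of the growth
   law. Generating surfacing-first and inverting was chosen over a forward
   FMC-hazard process because clinical incidence is what calibration data
   actually constrain; an onset-rate table would be unidentifiable here. A
   draw implying a negative FMC age is rejected and the surfacing and growth
   draws are repeated on attempt-keyed substreams.
4. **Progression.** Disease progression is tied to tumor size through a
   per-woman lognormal metastasis-threshold diameter: metastasis occurs when
   the growth curve crosses it (never, if the threshold exceeds the growth
   asymptote). A volume-proportional metastasis hazard would be equivalent
   in distribution for a matched threshold law; the threshold form is
   deterministic given the curve, directly testable
   (`diameter_at(age_metastasis - age_fmc) == d_met`), and exposed in
   configuration. Metastatic disease is incurable: breast-cancer death
   follows after a lognormal survival. Detection of any kind before
   metastasis is curative.
5. **Non-progressive tumors.** A configurable proportion
   (`p_nonprogressive`, default 0.30) of all tumors are non-progressive:
   non-lethal lesions that never metastasize and never surface clinically,
   discoverable only by mammography. Their screen detection is
   overdiagnosis and contributes nothing to screen-PLL.

### Why non-progressive tumors are a separate onset process

A natural first implementation flags each clinically-sampled tumor as
non-progressive with probability $p$. That design cannot reproduce a key
validation property: since only women at risk of breast-cancer death carry
screen-PLL, the curve must be *invariant* to the overdiagnosis proportion —
yet flagging removes a $p$-fraction of destined-death women, scaling the
curve by roughly $(1-p)$. The property holds only if the lethal pathway is
untouched by $p$. We therefore model non-progressive disease as an
independent asymptomatic onset overlay whose per-year probability is the
clinical incidence scaled by a factor calibrated (by root-finding on the
lifetime-probability identity) so the expected non-progressive share of all
tumors equals $p$ exactly. This is also the epidemiologically coherent
reading: a tumor that would never progress is precisely one that would never
announce itself clinically, which is why overdiagnosis is only observable in
screened populations. Two consequences are deliberate: simulated clinical
incidence always matches the calibration table regardless of $p$, and
changing $p$ leaves every lethal-pathway draw — and hence every curve —
bit-identical. Detection of a reservoir lesion is bookkept as overdiagnosis
but does not interrupt screening of a co-existing progressive tumor; the
overlap is rare and letting it interact would break the exact invariance.

### Which women may carry positive screen-PLL

Fig-style trajectory definitions leave one genuine ambiguity: does a woman
whose metastasis draw falls *after* her surfacing age — she would be cured
by clinical detection even without screening — carry interim screen-PLL
while detectable? The package's default (`pll_counterfactual =
"destined_death"`) says no: screen-PLL is restricted to women who would
actually die prematurely, which is the reading under which each screen's
detection of destined-death women produces the characteristic sawtooth
(their positive plateaus drop to zero at the exam) while keeping the
accounting consistent with "only premature deaths contribute". The
alternative reading (`"any_progressive"`), which ends such a woman's window
at clinical detection, is implemented behind the switch for sensitivity
analysis.

## Screening model

Strategies are age segments plus an optional life-expectancy stopping rule:

- **ACS**: annual 45–54, biennial from 55 while remaining life expectancy is
  at least 10 years. The "annual 45 to 55, then biennial" boundary is
  implemented with the age-55 exam belonging to the biennial segment (no
  double exam at 55); the stop comparator is strict `<` by default with `<=`
  available, since "10-year or less life expectancy" can be read either way.
- **USPSTF**: biennial 50–74.
- **Triennial**: every 3 years from 50, i.e. 50, 53, ..., 68; a flag appends
  a terminal exam at 70 for users who read "50–70" as inclusive of a final
  exam.
- **None**: no exams.

Life expectancy uses the curtate-plus-half convention (expected whole years
remaining plus 0.5 for the mid-year death); any consistent convention
satisfies the stopping rule, and this one has simple closed forms for
degenerate tables, which the tests exploit.

Sensitivity is zero below 0.2 cm and otherwise
$s_{\max} \cdot \mathrm{logit}^{-1}\{k(\ln d - \ln d_{50})\}$ with a higher
asymptote after a deterministic menopause at 50. Women are 100% compliant.
Exams are walked in order while the woman is alive, unsurfaced and
undetected; each eligible exam detects with probability $s(d)$. Exams after
metastasis are still administered — a detection then is recorded (it is
staging, not life-saving) but has no effect on screen-PLL, whose window has
already closed at metastasis.

## Randomness and reproducibility

Every draw family sits on its own RNG substream seeded by a hash of
(master seed, woman id, purpose, and for exams the exam month). Cohorts are
therefore order-independent (woman 37 simulated alone is bit-identical to
woman 37 inside any cohort), strategies share natural histories under a
common master seed, and per-exam draws keyed by exam age mean that adding an
exam to a schedule can never delay detection — which makes the pointwise
dominance of no-screening an exact, not statistical, property.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `d_detect` | 0.2 | cm | assumed start of mammographic detectability |
| `d_cell` | 0.01 | cm | first malignant cell scale |
| `d_max` | 12.8 | cm | Gompertz asymptote |
| `alpha` | lognormal, median 0.0181, sdlog 0.35 | 1/month | median volume doubling time ≈ 5 months at 1 cm |
| surfacing diameter | lognormal, median 2.0, sdlog 0.4 | cm | typical symptomatic presentation size |
| metastasis threshold | lognormal, median 3.0, sdlog 0.6 | cm | places metastasis ≈ 5 years after detectability at median growth |
| `p_nonprogressive` | 0.30 | — | assumed overdiagnosis-reservoir share of tumors |
| post-metastasis survival | lognormal, median 84, sdlog 0.5 | months | ≈ 7 years metastasis-to-death at the median |
| `sens_max_pre`, `sens_max_post` | 0.75, 0.95 | probability | mammography less sensitive in dense premenopausal breasts |
| `sens_slope`, `sens_mid` | 2.5, 0.5 | —, cm | half-asymptote sensitivity at 0.5 cm, ≈ 0.9 of asymptote by 2 cm |
| `menopause_age` | 50 | years | deterministic switch |

The growth, surfacing, metastasis and survival laws are internal to the
natural-history model and not identifiable from the shipped tables; the
defaults were chosen once so that the canonical single-woman timeline
(detectable at 60, metastasis at 65, death at 72) is *typical* of the
simulated population, and are documented as package choices. With them, the
time from 0.2 cm to a median 2 cm surfacing diameter is about 45 months — a
mid-range mammography sojourn time.

## The synthetic calibration

`make_fixture_calibration()` provides a deterministic, closed-form stand-in
for registry calibration tables: a Gompertz–Makeham life table
($q_x = 1 - e^{-(A + Be^{Cx})}$, $A = 5\times10^{-4}$,
$B = 1.5\times10^{-5}$, $C = 0.1$, ages 0–100) chosen once to match a
contemporary US female profile (life expectancy at birth ≈ 81; remaining
expectancy first below 10 years at age 80, so ACS screening ends at 79), and
a logistic incidence curve ($380/(1+e^{-(x-53)/7})$ per 100,000) that is
negligible before 30 and plateaus late in life. Both are rounded to 7
significant digits so CSV round-trips are bit-exact.

What the fixture emulates: realistic orders of magnitude, the competing-risk
structure, and the qualitative incidence shape that drives the curve's rise.
What it does not: the true incidence *decline* in very old age, cohort (vs
period) mortality, risk heterogeneity, and the registry-calibrated parameter
set behind the published cohort curves. Passing tests therefore demonstrate
the mechanics, orderings and invariances of screen-PLL — dominance,
overdiagnosis invariance, sawtooth-and-convergence shape, calibration
recovery — not agreement with published absolute magnitudes, which the
package does not claim (its curve scale agrees with published
million-woman figures in order of magnitude only).

## Numerical conventions and degenerate inputs

- Internal time unit is the month; event ages are exact fractional months,
  discretized only at curve construction.
- The curve grid is fixed at months 0–1212 (ages 0–101) with half-open
  months $[m, m+1)$; an event at an exact boundary belongs to the later
  month, so a trajectory contributes at integer months
  $\lceil w_{start} \rceil \le m < w_{end}$.
- Lognormal draws are truncated by rejection where support demands it
  (surfacing diameter to $(d_{detect}, d_{\max})$, metastasis threshold to
  $(d_{cell}, \infty)$); rejection stays inside the draw's own substream so
  other draws are unaffected.
- A metastasis threshold below 0.2 cm yields a window that closes before it
  opens; the woman is premature but uncreditable (screening could never
  have seen her tumor) and contributes zero.
- The Bernoulli walks consume a fixed number of uniforms regardless of
  outcome, so substream positions never depend on realized events.
- `time_to_diameter` is the analytic inverse of the growth law; round-trips
  are accurate to well under $10^{-6}$ month across the clinically
  attainable range (inversion within ~0.8 cm of the asymptote is
  ill-conditioned in double precision and outside any sampled path).
- An empty strategy, an empty cohort, a zero incidence table and degenerate
  life tables (single death year; constant hazard) are all exercised in the
  tests with their closed-form answers.

## Problem sizes

Routine checks run at 1,000–30,000 women; the calibration-recovery and
curve-shape checks use 100,000, where per-exam curve drops are far larger
than Monte Carlo drift. The engine's default is 100,000 women per strategy,
with million-woman runs available by setting `n_women = 1e6`.

## Known limitations

- One progressive tumor per woman; no in-situ/invasive distinction, no
  staging, no treatment-effectiveness model beyond cure-before-metastasis.
- Menopause is a deterministic age-50 switch feeding only sensitivity.
- No attendance, recall, false-positive or diagnostic-delay modelling —
  none of these enter screen-PLL as defined, but they matter for harms and
  cost analyses, which are out of scope.
- The reservoir representation of non-progressive disease means such
  lesions keep growing along the same Gompertz law without a plateau; their
  only observable is screen detectability, so this choice affects
  overdiagnosis counts, not curves.
- Screen-PLL quantifies one benefit — preventable loss of life and its age
  distribution — and deliberately carries no cost-effectiveness content.
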