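# screenPLL

Individual-level Monte Carlo simulation of breast cancer natural history and
mammography screening, organised around **screen-preventable loss of life
(screen-PLL)**: the life-months a premature breast-cancer death would cost,
credited to a woman only while screening could still avert that death.

## Who this is for

Researchers in cancer-screening policy and medical decision modelling who
want to compare how mammography guidelines — ACS (annual 45–54, then biennial
until remaining life expectancy falls below 10 years), USPSTF (biennial
50–74), triennial 50–70, or no screening — *distribute* potential life
savings across ages, rather than only how much total mortality they avert.

## The model

Each simulated woman gets a complete no-intervention disease timeline:

- **Other-cause death** sampled from a period life table (`qx` by age).
- **Clinical surfacing**: the age at which her tumor would be found through
  signs and symptoms, sampled by yearly Bernoulli draws against an
  age-specific incidence table (per 100,000 woman-years).
- **Gompertzian growth**: tumor diameter
  `d(t) = d_max · exp( ln(d_cell/d_max) · e^(−αt) )` from the first
  malignant cell (`d_cell = 0.01` cm) toward an asymptote
  (`d_max = 12.8` cm), with per-woman rate α lognormal. The first-malignant-
  cell age is back-computed from the surfacing age and a lognormal surfacing
  diameter (median 2 cm); mammographic detectability begins at 0.2 cm.
- **Metastasis** when the diameter crosses a per-woman lognormal threshold
  (median 3 cm); metastatic disease is incurable, and breast-cancer death
  follows after a lognormal post-metastasis survival (median 84 months).
  Detection — by screen or clinical signs — before metastasis is curative.
- **Non-progressive tumors** (30% of all tumors by default) form an
  independent asymptomatic reservoir: they never surface, never metastasize,
  never kill, and are discoverable only by mammography; their screen
  detection is overdiagnosis and carries no screen-PLL.
- **Mammography sensitivity** is zero below 0.2 cm and otherwise logistic in
  log-diameter, with a higher asymptote after menopause (age 50). Compliance
  is 100%.

A woman whose no-intervention path ends in premature breast-cancer death
(metastasis before surfacing, breast-cancer death before other-cause death)
carries screen-PLL equal to

```
screen-PLL = (other-cause death age − breast-cancer death age) × 12   [life-months]
```

from the month her tumor reaches 0.2 cm until screen detection or
metastasis, and zero elsewhere. Everyone else carries zero at every age.
Summing over the cohort month by month gives the screen-PLL curve; each
screen visibly bites a notch out of it, and a flat curve means the guideline
spreads its life savings evenly across ages.

## Worked example

```r
library(screenPLL)
calib <- make_fixture_calibration()          # synthetic US-like calibration
cfg <- run_config(n_women = 20000, master_seed = 42,
                  strategies = c("none", "uspstf"))
cmp <- compare_strategies(cfg, calib)        # common random numbers

cmp$runs[["uspstf"]]$summary
#> peak_life_months    : 12571   (at age 49.8, just before screening starts)
#> n_bca_deaths        : 222
#> n_screen_detections : 1038
#> n_overdiagnosed     : 576
#> mean_exams_per_woman: 11

v <- cmp$curves[["none"]]$screen_pll_life_months
u <- cmp$curves[["uspstf"]]$screen_pll_life_months
max(v)                                       # 14740 life-months at age 52.2
c(v[721], u[721])                            # age 60: 9220 vs 2510
cmp$convergence_age_months[["uspstf"]] / 12  # 81.5 — curves merge after exams end
```

The unscreened curve rises with incidence, plateaus in midlife and falls
toward zero as remaining life expectancy shrinks; the USPSTF curve tracks it
until age 50, then drops at every biennial exam (each screen removes
destined-death women from the at-risk pool) and converges with the
unscreened curve shortly after the last exam at 74. Overdiagnosed women
never carry screen-PLL, so the curves are bit-identical under any
overdiagnosis proportion.

`plot_curves(cmp$curves)` draws all curves; `write_outputs(cmp, "out", cfg)`
exports per-strategy CSVs, a combined long CSV, a JSON summary and a PNG.

A command-line interface is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file(package="screenPLL"))')/exec/screenpll" \
  compare --strategies none,acs,uspstf,triennial --n 100000 --seed 1 --out out/
```

## Calibration

The shipped calibration is fully synthetic with known closed forms: a
Gompertz–Makeham life table (life expectancy at birth ≈ 81 years; remaining
expectancy first drops below 10 years at age 80, which ends ACS screening at
79) and a logistic incidence curve plateauing near 380 per 100,000 late in
life. Real incidence and life-table CSVs (headers `age,qx` and
`age,rate_per_100k`) are drop-in replacements via `load_calibration()`.
Because the original registry-calibrated parameters behind the published
curves are not reproduced here, absolute curve magnitudes from the synthetic
calibration agree with published cohort-scale figures only in order of
magnitude; the shapes, orderings and invariances are what the package
reproduces and tests.

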