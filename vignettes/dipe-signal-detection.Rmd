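---
title: "Signal detection for drug-induced pulmonary edema on FAERS-schema data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection for drug-induced pulmonary edema on FAERS-schema data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipesignal)
```

## The problem

Drug-induced pulmonary edema (DIPE) is a non-cardiogenic accumulation of
fluid in the alveolar space attributable to a medication — classically
opioid antagonists such as naloxone, tyrosine-kinase inhibitors such as
dasatinib, calcium-channel blockers, and thiazolidinediones.  Individual
cases are rare enough that pre-marketing trials cannot characterize the
risk; post-marketing spontaneous-report databases such as the FDA Adverse
Event Reporting System (FAERS) can.  `dipesignal` implements the standard
pharmacovigilance workflow for this question on FAERS-schema quarterly
ASCII data:

1. **Cohort construction** — parse the `$`-delimited DEMO/DRUG/REAC/THER/
   INDI tables, keep a configurable quarter window (default
   2004Q1–2024Q2), deduplicate case versions, keep healthcare-professional
   reports, and exclude reports whose suspect drug was *indicated for*
   pulmonary edema (those describe treatment of a pre-existing condition,
   not causation).
2. **Disproportionality screening** — for every drug that is the primary
   suspect in at least `min_cases` (default 10) pulmonary-edema reports,
   four statistics on the report-level 2×2 table, with a signal called
   only on four-method consensus.
3. **Confounder adjustment** — per-drug logistic regression of the event
   on exposure plus age, sex, weight and report year.
4. **Time to onset** — days from therapy start to event, compared across
   age (≥65 vs <65) and sex strata with a rank-sum test.

Because the real FAERS download is multi-gigabyte and its drug/event
coding depends on a licensed MedDRA version, the package bundles a
synthetic-FAERS generator with a known ground-truth manifest; every claim
the package makes about itself is tested against that truth.

## The statistics

Let the cleaned dataset have $N$ reports and, for a drug $D$ and the
target preferred term (PT):

|            | event PT | other events |
|------------|----------|--------------|
| $D$ as primary suspect | $a$ | $b$ |
| other drugs            | $c$ | $d$ |

**ROR** $= ad/bc$ with the Wald interval
$\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.  When any cell
is zero, the Haldane–Anscombe correction adds $0.5$ to all four cells for
the ratio estimators (never for the raw-count thresholds) and the result
is flagged.  An empty margin ($a+b=0$ or $c+d=0$) yields an explicit
undefined marker rather than a number.

**PRR** $= \frac{a/(a+b)}{c/(c+d)}$, accompanied by the Pearson
chi-square of the table with Yates continuity correction (clamped at
zero, exactly as `chisq.test(correct = TRUE)` computes it).

**BCPNN information component**, in the closed credibility-interval form:
$E = (a+b)(a+c)/N$, $\mathrm{IC} = \log_2\frac{a+0.5}{E+0.5}$, and
$\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} - 2(a+0.5)^{-3/2}$.
This form was chosen over the original variance-expansion version because
it is exactly testable against direct arithmetic; both shrink small
counts toward independence.

**EBGM / EB05** follow the multi-item gamma-Poisson shrinker: the
relative reporting rate $\lambda_i$ of pair $i$ has a two-component gamma
mixture prior, $a_i \mid \lambda_i \sim \mathrm{Pois}(\lambda_i E_i)$, so
the marginal is a negative-binomial mixture whose log-likelihood is
maximized over the five hyperparameters
$(\alpha_1, \beta_1, \alpha_2, \beta_2, w)$.  The posterior is again a
two-gamma mixture; $\mathrm{EBGM} = e^{\mathbb{E}[\ln\lambda]}$ via the
digamma identity and EB05 is the posterior 5th percentile by bisection.
Numerical choices:

* optimization is Nelder–Mead from 8 fixed starting points on the
  $(\log, \log, \log, \log, \mathrm{logit})$ scale, tolerance $10^{-10}$
  on the objective, best converged start wins;
* hyperparameters are boxed at $10^3$.  With only a few dozen
  (drug, event) pairs the unbounded MLE can park one component as a
  point mass on a cluster of strong signals; a shape of $10^3$ is already
  a ~3% coefficient of variation, and the box keeps the posterior
  quantile ordering $\mathrm{EB05} \le \mathrm{EBGM}$ meaningful;
* by default the prior is fitted to the target drugs × target event
  pairs, i.e. the scope of this analysis; fitting across all drug–event
  pairs is a switch.

**Consensus.**  Default per-method criteria are the conventional
published thresholds: ROR — $a \ge 3$ and lower CI $> 1$; PRR — PRR
$\ge 2$, $\chi^2 \ge 4$, $a \ge 3$; BCPNN — $\mathrm{IC}_{025} > 0$;
EBGM — $\mathrm{EB05} > 2$.  A drug is a signal only if all four fire;
any undefined statistic forces the consensus false with a reason code.
All thresholds are configurable.

**Adjusted regression.**  One model per drug (exposure = that drug only):
a joint model with all signal drugs as columns is available behind a
switch, but the per-drug form matches the per-drug forest-plot
presentation and avoids cross-drug collinearity.  Estimation is
Newton/IRLS on the Bernoulli likelihood, written out rather than
delegated so that its convergence rules (score $<10^{-8}$ or relative
log-likelihood change $<10^{-10}$, 100-iteration cap), separation
flagging (diverging coefficients), and Wald inference are explicit and
testable; `stats::glm` serves as an independent cross-check in the test
suite, never as the implementation.  Covariates are complete-case,
centred and scaled (the exposure OR is invariant to this); "report time"
is encoded as the report year, the simplest monotone encoding.  P-values
are two-sided Wald with no multiplicity correction, matching the
analysis this package reproduces.

**Onset.**  Onset is anchored to the *earliest day-precision* therapy
start among the report's primary-suspect entries of the drug; partial
dates are never imputed — records below day precision, or with the event
before the start, are dropped with reason codes.  The unspecified
"non-parametric test" is realized as the two-sided Mann–Whitney test:
exact enumeration of the null when the combined sample is ≤16 without
ties, otherwise a normal approximation with midranks, tie-corrected
variance and continuity correction (the worst exact-vs-approximate gap at
$n = 8+8$ is ~0.011).  The reported direction follows the rank
comparison; a flag marks drugs where the mean comparison points the other
way.

## Cohort-construction decisions

* **Deduplication** keeps the highest `primaryid` per `caseid` (ties by
  latest quarter, then report year) — the standard "latest case version"
  rule.  It is idempotent, and applied before any other filter.
* **Reporter filter** defaults to physicians, pharmacists and other
  health professionals.  Registered nurses have no dedicated occupation
  code in most FAERS years; the default dialect maps `RN` (and `HP`)
  into other-health-professional, and both the code map and the allowed
  set are configuration, because the equivalent choice in the original
  analyses is not recoverable from their descriptions.
* **Pre-existing-event exclusion** matches the indication PT
  case-insensitively, with the oedema spelling accepted as a synonym;
  only indications are examined (a report whose *reaction* is the target
  PT is, of course, retained).
* **Units**: LBS→kg by 0.45359237; age codes DEC = 10 y, YR, MON = 1/12,
  WK = 7/365.25, DY = 1/365.25, HR = 1/8766.  Unparseable values become
  missing, never errors.

## What the synthetic scenario emulates

`paper_shaped_scenario()` is the package's study fixture: 45 drugs over
40,000 unique cases (defaults), with

* four strong injected signals — naloxone-, dasatinib-, nifedipine- and
  anti-thymocyte-globulin-like drugs at odds ratios 12, 10, 9, 8 —
  plus four weaker ones (OR 2–3), echoing the published pattern that the
  top of the DIPE ranking is dominated by opioid antagonists, kinase
  inhibitors and vasoactive drugs;
* one **confounded null**: a pioglitazone-like drug with no true effect
  whose uptake is strongly tilted toward the elderly (selection tilt 2.5
  on standardized age) while age independently raises the event risk
  (0.7 log-odds per SD).  Its crude ROR is elevated, and its adjusted OR
  is null — the package's demonstration that regression removes
  channeling bias;
* log-normal onset distributions, with short-onset drugs (median ~12
  days) and two drugs carrying built-in stratum shifts (+1.2 on the log
  scale for the elderly in one, −1.2 for males in the other);
* FAERS-realistic noise: duplicate case versions (5%), partial dates
  (12%), mixed age/weight unit codes, a consumer/lawyer reporter share
  that the occupation filter must remove, concomitant drug rows that
  primary-suspect counting must ignore, and ~1% of reports whose
  indication is the target PT itself.

Magnitudes were set by power analysis before the test suite was written,
and two are deliberate:

* *Effect drugs are rare* (nominal exposure weights 0.0018–0.0027 versus
  0.024 for nulls).  Every per-drug regression uses all other reports as
  its comparator; if strong signals contributed a material share of all
  events — as they would at equal prevalence in a 40,000-report dataset —
  the confounded drug's adjusted OR would be biased downward by reference-
  group contamination.  Real FAERS has the same structure (a few dozen
  signal drugs among millions of reports), so rarity is the realistic
  regime, not a convenience.
* *The event model is logistic*, so the injected per-drug effects are
  odds ratios; at a 4% background rate they are within a few percent of
  the corresponding relative risks, and the analytic truth for every
  recovery test is exact rather than approximate.

What the generator does **not** emulate: drug-name misspellings and salt/
brand variants (normalization is exercised through an explicit synonym
map instead), MedDRA coding errors, free-text narratives, reporting-rate
secular trends, and event-dependent reporting (every case reaches the
database independently of its outcome).  Passing the bundled tests
therefore shows the *estimators and pipeline* behave as claimed under a
realistic data shape — it does not validate conclusions drawn from any
particular real FAERS extract, where nomenclature cleaning and
reporting biases dominate.

## Problem sizes used by the checks

The bundled checks run the scenario at 40,000 reports (100 replicates for
the confounding demonstration), fit the gamma-mixture prior on 5,000
simulated pairs, verify the closed-form statistics on every 2×2 table
with margins ≤30 against independently coded formulas, check EBGM/EB05
against adaptive quadrature on 100 pairs, and verify the rank-sum test
against the full Wilcoxon null for every split of ten ranks.  These sizes
keep each property at comfortable statistical resolution while the whole
suite stays desk-scale.

## Reproducing the published analysis at full scale

The pipeline accepts a directory of real FAERS quarterly ASCII files via
`pipeline_config(input_dir = ...)` (both the `primaryid`-era and the
legacy `ISR`-era column layouts are supported through `faers_dialect`).
The published headline numbers — 173 target drugs, 37 consensus signals,
the frequency ranking led by macitentan, and the pioglitazone adjusted OR
of 0.943 (0.719–1.236) — depend on the full download and a specific
MedDRA version, and are therefore a documented full-data mode rather than
something the bundled fixture can or should reproduce.  What the fixture
does reproduce is every qualitative finding: a consensus-signal set
recovering the injected risks, a confounded drug whose crude signal
dissolves under adjustment, short onsets for the drugs built that way,
and age/sex onset differences with their built-in directions.

## Known limitations

* The deduplication rule is standard practice but unverifiable against
  the original analyses, which do not describe theirs.
* Separation in the logistic model is flagged, not repaired (no Firth
  correction); affected drugs are reported as non-converged.
* The BCPNN is the closed-form approximation, not the full MCMC version.
* MedDRA hierarchy rollups (SOC/HLT) and RxNorm-grade drug normalization
  are out of scope; drug identity is normalized uppercase text plus a
  user-supplied synonym map.
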