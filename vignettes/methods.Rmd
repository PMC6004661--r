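---
title: "Disproportionality methods in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The case/non-case design

Spontaneous reporting systems (Japan's JADER, the US FAERS) collect
voluntary reports of suspected adverse drug reactions. They carry no
denominators, so risk cannot be estimated — but *disproportionality* can:
if reports that mention a target drug mention a target event more often
than the rest of the database does, the pair is disproportionally
reported. `pvsignal` implements this as a case/non-case analysis. Reports
with at least one event in the target preferred-term (PT) set are the
cases; every other report in the (filtered) database is a non-case. The
counting unit is always the report: a report with three matching PTs and
two suspect drugs of the class contributes exactly one count.

The 2×2 table for a drug (or drug class) × PT-set pair is

|            | event + | event − |
|------------|---------|---------|
| drug +     | a       | b       |
| drug −     | c       | d       |

with marginals $n_{1+} = a+b$ (all reports of the drug),
$n_{+1} = a+c$ (all reports of the event) and $N$ the database size.
Published signal tables print $n_{11} = a$, $n_{1+}$, $n_{+1}$ and $N$
rather than the four cells; `table_from_marginals()` inverts that, which
is how the shipped `incretin_gerd_tables()` fixture reproduces printed
estimates exactly.

Two conventions matter and are deliberate:

* **Exposure counts suspect drugs only.** Spontaneous reports distinguish
  suspect from concomitant medication; counting concomitants as exposure
  dilutes attribution. `include_concomitant = TRUE` switches the
  convention for sensitivity analyses.
* **The comparator is all other reports in the set passed in.**
  Class-wide analyses do *not* remove same-class drugs from the
  comparator; reconstructing printed per-drug estimates (e.g. the
  exenatide reporting odds ratio of 11.08 from $n_{11}=19$,
  $n_{1+}=122$) requires $d = N - n_{1+} - c$, i.e. other class members
  stay in the background.

## Estimators

**Reporting odds ratio (ROR).** $\mathrm{ROR} = ad/bc$ with the Woolf
(log-normal) interval
$\exp\!\big(\ln \mathrm{ROR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d}\big)$,
$z = 1.96$. Any zero cell leaves the ROR undefined; such rows are
rendered as dashes, the convention of published signal tables. No
continuity correction is applied to cells — the IC below handles sparse
counts by shrinkage, and a 0.5-corrected ROR would no longer reproduce
printed values.

**Proportional reporting ratio (PRR).**
$\big(a/(a+b)\big)\big/\big(c/(c+d)\big)$; used only inside the signal
value.

**Pearson chi-square.** $N(ad-bc)^2 / \big((a+b)(c+d)(a+c)(b+d)\big)$,
without Yates correction by default. Nothing in the reproduced tables
pins the variant; the Yates form is available via `yates = TRUE` and
shrinks the statistic, never enlarges it.

**Information component (IC).** The original closed-form BCPNN posterior
with Dirichlet pseudo-counts $\alpha_1 = \beta_1 = \gamma_{11} = 1$,
prior totals $\alpha = \beta = 2$, and a data-dependent joint prior total
$\gamma$ chosen so an unreported pair shrinks to 0 bits. Credible bounds
are $E(IC) \pm 2\sqrt{V(IC)}$ — two posterior standard deviations, not a
1.96 normal quantile. This exact configuration is what reproduces the
published IC values (2.17 with bounds 1.66–2.67 for the GLP-1-RA class;
−0.81 with −1.34 to −0.29 for the DPP-4-I class); the later 0.5-shrinkage
variant and $k = 1.96$ do not.

**Detection criteria.** A signal requires the interval to exclude the
null: lower ROR bound > 1, or lower IC bound > 0 ("both signals" when
both hold). An *inverse* signal — disproportionally few reports —
requires upper ROR bound < 1 *and* upper IC bound < 0.

**Signal value.** $\ln(\mathrm{PRR}) + \ln(\chi^2)$, a scalar for
comparing association strength between two strata. One stratum dominates
when its signal value strictly exceeds twice the other's
(`compare_signal_values()`); the inequality is strict as printed in the
source method, and exactly doubled values therefore read "no
difference".

### A note on IC monotonicity

Adding one joint report (increasing $a$ with $b, c, d$ fixed) always
increases the ROR and PRR, but not necessarily the IC: $a$ also inflates
both margins, and
$\tfrac{\partial}{\partial a} \ln \tfrac{aN}{(a+b)(a+c)} =
1/a + 1/N - 1/(a+b) - 1/(a+c)$
is negative when $a^2 > bc$. In the pharmacovigilance regime — the joint
count small relative to both margins, $a^2 < bc$ — the IC is monotone,
and the property suite asserts it exactly there.

## Filtering, stratification

`apply_exclusions()` mirrors the standard JADER cleaning step: reports
with missing sex, a missing or qualitative age ("youth", "elderly" —
JADER ages come only in decade buckets, and some reports carry words
instead), or no primary-disease entry are dropped; an optional disease
set restricts the database (e.g. to diabetic patients) before any signal
is computed. The filter is idempotent and reports its exclusion tally.

Stratified analyses (`split_reports()`, `stratified_signals()`) partition
by sex or by an age threshold that must sit on a decade boundary (default
70, mapping buckets 70-79 and above to the older stratum). Each stratum
is analysed standalone — its own stratum total is $N$ — because the
signal value compares two self-contained case/non-case analyses, not two
strata of a common table. Stratum tables therefore sum cell-wise to the
unstratified table, which the suite checks.

## Time-to-onset

`derive_times()` produces one survival record per exposed report: cases
get days from the earliest suspect start date of a target drug to the
earliest matching onset date (event); non-cases get days to the end of
drug use (censored). Times beyond 365 days become censored observations
at 365 — administrative censoring at one year. Zero or negative
differences clamp to 1 day (decade-rounded dates make same-day onsets
legitimate, and the product-limit estimator needs positive times).
Reports lacking the required dates are excluded and tallied, never
imputed. All exposed reports enter the analysis with the 365-day cap;
restricting to reports that stop within the year would condition on the
outcome, so it is not the default behaviour.

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package (`survfit`, `survdiff`); the test suite checks them
against a hand-computed product-limit table, the 1−ECDF identity in the
absence of censoring, and a label-permutation reference distribution for
the log-rank p-value on small fixtures.

## The synthetic generator

Report-level JADER data cannot be redistributed, so `simulate_reports()`
generates a database with known ground truth. Its defaults emulate the
filtered diabetic-patient analysis set this package's fixtures describe:
38,887-report scale, 60.9% male, the published decade age distribution,
class exposure probabilities 429/38,887 (GLP-1-RAs) and 3,276/38,887
(DPP-4-Is), GERD-related event baselines at the published per-PT totals,
and reporting-risk multipliers at the observed disproportionality (5.6
and 0.55). Where the emulated study states no value, defaults are chosen
once at field-realistic levels: Weibull onset latencies with shape 0.9
and median around 2-5 months (early-onset adverse events), log-normal
exposure durations with median 90 days, 5% missing sex/age, 28% missing
dates (the share of reports the onset analyses typically lose), 2%
qualitative ages.

Design points worth knowing:

* **Multipliers act on reporting probability, not incidence.** The
  generator produces spontaneous *reports*; disproportionality estimates
  relative reporting. The injected multiplier is therefore the estimand,
  and parameter-recovery tests compare the estimated ROR to it directly.
* **Every report carries at least one event.** A report that draws no
  event receives one sampled from its *own* per-event probability row
  (multipliers included, via Gumbel-max categorical sampling). Sampling
  from baseline probabilities instead would dilute injected multipliers
  toward the null — measurably, at the suite's sample sizes.
* **Determinism.** Given `seed`, output is byte-identical across runs;
  the caller's RNG stream is saved and restored.

What the generator does *not* emulate: free-text drug-name noise,
duplicate reporting across quarters, and reporting biases (Weber,
notoriety and ripple effects). Passing tests therefore show the
*machinery* is correct — filters count, tables match brute-force
oracles, injected effects are recovered — not that real spontaneous
data are free of the biases that make signal interpretation delicate.

## Problem sizes and numerical choices

The suite's stochastic checks run at sizes chosen to make their
tolerances meaningful at interactive run times: 200 null replicates of
10,000 reports for the type-I error of the ROR criterion (band
0.02–0.09 around the one-sided 2.5% nominal level), six replicates of
50,000 reports per multiplier in {1, 2, 5} for recovery within 15%,
30 seeds of 20,000 reports for Woolf coverage, and 1,000 label
permutations for the log-rank reference. Display rounding is 2 decimal
places, half away from zero, applied only at serialisation — internal
values keep full precision.

## Worked example

```{r example, eval = FALSE}
library(pvsignal)

# exact reproduction from printed marginals
fit <- dispro(incretin_gerd_tables()[["GLP-1-RAs (ALL)"]])
fit

# synthetic end-to-end run
cfg <- sim_config(n_reports = 20000, seed = 1)
rs <- apply_exclusions(simulate_reports(cfg),
                       require_primary_disease_in = "type 2 diabetes mellitus")
cls <- incretin_drug_classes()
dispro(build_table(rs, cls$glp1, gerd_pt_set()))
tt_g <- derive_times(rs, cls$glp1, gerd_pt_set(), group = "GLP-1-RAs")
tt_d <- derive_times(rs, cls$dpp4, gerd_pt_set(), group = "DPP-4-Is")
logrank_test(tt_g, tt_d)
```

## Limitations

* Counts-level fixtures reproduce printed class- and drug-level
  estimates; stratum-level published signal values cannot be recomputed
  because the underlying stratum counts were never printed — the
  stratified machinery is validated by simulation instead.
* The IC priors are fixed at the original BCPNN configuration; other
  shrinkage variants are deliberately out of scope.
* No duplicate-report detection, MedDRA hierarchy traversal, or
  EBGM/MGPS scores.
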