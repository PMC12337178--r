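---
title: "Disproportionality methods for spontaneous-report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods for spontaneous-report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect millions
of drug–event reports with no denominator: we never observe how many
patients took a drug without an event. Disproportionality analysis works
around this by comparing how often a drug–event pair is reported against
how often that event is reported for *all other* drugs in the same
database. For each stratum (a MedDRA preferred term, PT, or system organ
class, SOC) the unit of counting is the unique (report, term) pair, and the
2×2 table is

|                | target event | other events |
|----------------|--------------|--------------|
| target drug    | a            | b            |
| all other drugs| c            | d            |

with `N = a+b+c+d` and the independence expectation `E = (a+b)(a+c)/N`.

This package implements the full chain around that table for databases
distributed in the FAERS quarterly ASCII dialect: ingestion, case-level
deduplication, primary-suspect cohort selection by fuzzy drug-name
matching, PT/SOC mapping through a MedDRA-style vocabulary, four
disproportionality statistics with their conventional signal criteria,
descriptive cohort profiling, and time-to-onset analysis. A seeded
synthetic data generator with planted signals makes every stage testable
without access to (or licenses for) the real data.

## Report selection

FAERS re-submits cases across quarters under fresh PRIMARYIDs. Following
FDA guidance, `deduplicate_reports()` keeps exactly one report per CASEID —
the one with the numerically largest PRIMARYID — and removes every CASEID
on the deleted-cases list. The operation is idempotent and order-invariant,
and it runs *before* drug filtering so each case is judged on its latest
version.

Drug names in spontaneous reports are free text ("VONJO 200MG CAPSULE",
"pacritinib citrate", typos). `match_drug_name()` normalizes (case-fold,
whitespace collapse, stripping trailing dose/form tokens) and then accepts
either substring containment of a target name or a normalized Levenshtein
distance of at most 0.1 (one edit per ten characters — configurable; no
published threshold exists for this step, so it is exposed rather than
baked in). A report enters the cohort only when a matching row itself
carries role code 1 (primary suspect); the stricter same-row reading is
used because a concomitant mention of the target drug next to some other
suspect drug is not evidence about the target.

## The four statistics

Writing `a, b, c, d` as above:

* **ROR** (reporting odds ratio): `ROR = ad/bc`, with the Woolf 95% CI
  `exp(log ROR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`. Undefined cells (any zero)
  are reported as `NA`; a Haldane +0.5 correction is available behind a
  switch but is off by default, because inventing a correction silently is
  less auditable than refusing to.
* **PRR** (proportional reporting ratio):
  `PRR = [a/(a+b)] / [c/(c+d)]`, accompanied by the Yates-corrected
  Pearson chi-squared of the table (the convention in this literature; the
  uncorrected variant is a switch).
* **BCPNN IC** (information component): the default is the shrunk
  observed-to-expected form `IC = log2((a+½)/(E+½))` with `IC025` the 2.5th
  percentile of `log2 λ` under the conjugate posterior
  `λ·(E+½) ~ Gamma(a+½)` — an exact gamma tail quantile, no normal
  approximation. The original 1998 closed-form moment variant (Dirichlet
  priors on the margins, `E(IC) − 1.96·sd(IC)`) is selectable; both are
  validated against numerical integration.
* **MGPS EBGM** (multi-item gamma Poisson shrinker): `a ~ Poisson(λE)`
  with a two-component gamma mixture prior on λ whose five parameters
  `(α1, β1, α2, β2, P)` are estimated by maximizing the negative-binomial
  mixture marginal likelihood over *every* (suspect drug, event) cell of
  the database — the shrinkage strength is a property of the whole
  database, not of the target drug. The posterior is again a two-component
  gamma mixture; `EBGM = 2^{E[log2 λ | a, E]}` and `EBGM05` is its 5th
  percentile, found by monotone root-finding on the mixture CDF to 1e-6.

Signal criteria (all configurable): ROR flags when `a ≥ 3` and the lower
CI bound exceeds 1; PRR when `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`; BCPNN when
`IC025 > 0` (strict); MGPS when `EBGM05 > 2`. The combined rule is the
conjunction of all four — the most conservative choice, which trades
sensitivity for a very low false-flag rate (the suite measures it at 0 of
25 null replicates).

On any all-positive table the three point estimates are provably ordered:
`ROR > 1 ⟺ PRR > 1 ⟺ ROR > PRR` (and mirrored below 1), since
`ROR/PRR = (1 + a/b)/(1 + c/d)`. This invariant is property-tested on 10⁴
random tables.

### Numerical choices in the MGPS fit

Mixture likelihoods of this kind have local optima in which one component
degenerates (a spike at λ = 1 plus a dead component). This is not
hypothetical: when only a handful of cells carry real disproportionality,
the basin of attraction of the true mixture optimum is narrow, and a
single quasi-Newton run from the classic `(0.2, 0.1, 2, 4, 1/3)` start
reliably collapses. `mgps_fit_prior()` therefore runs BFGS from several
starts — the classic one, spread/reversed variants, and a data-driven
start whose second component is centered on the upper 0.1% tail of the
observed `a/E` ratios — keeps the best final likelihood, and polishes it.
Components are then relabelled so component 1 carries the larger weight;
the likelihood is label-invariant, so this only fixes an arbitrary
ordering for reproducibility. Convergence is declared at relative
log-likelihood change below 1e-8 (500 iterations cap).

Two further caveats are worth knowing. First, the five parameters are only
weakly identified — very different parameter vectors can give nearly
identical marginal likelihoods — so validation compares likelihoods and
implied shrinkage, never raw parameters. Second, when the generating prior
is a *single* gamma, the split of weight between two overlapping fitted
components is not identified at all (a flat likelihood ridge); the fitted
mixture is still predictively correct, which is what the tests assert.

Before cells are counted, suspect drug names are canonicalized and every
variant of the target drug collapses to a single drug. Without this, the
target's spelling variants fragment its cells, the database looks
homogeneous to the ML fit, and the fitted prior collapses to a spike at 1
that shrinks every true signal away. Name standardization before counting
is standard practice with real FAERS data for the same reason.

## SOC-level counting

At the SOC level the default counts unique (report, SOC) pairs — a report
with three gastrointestinal PTs contributes one gastrointestinal pair.
This is the field convention, and it is visibly what published FAERS
tables do (SOC totals there are smaller than the sum of their member PT
rows). The alternative convention, summing member PT pairs into their SOC
so that SOC counts partition PT counts exactly, is available as
`distinct_by_level = FALSE`.

## Descriptives and time-to-onset

Spontaneous-report demographics are mostly missing (in the regime emulated
here, roughly 82% of age and sex). `summarize_cohort()` therefore computes
every categorical block over its non-missing denominator and reports
`known + missing = cohort size` per block, so no percentage silently
changes meaning. A report is serious iff it carries at least one outcome
code; within serious reports the default assigns one category per report
by the precedence death > life-threatening > disability > hospitalization
> other, making the sub-shares a partition. Raw FAERS outcome tallies
instead count every code a report carries (shares can exceed 100%);
`multi_outcome = TRUE` reproduces that convention. Reporting year uses the
FDA receipt year, which is essentially complete, rather than the
frequently missing event year.

Time-to-onset is `event date − earliest therapy start` of the matching
primary-suspect rows, in days. FAERS dates are digit strings whose length
encodes precision (8/6/4 digits = day/month/year); pairs where either date
is missing, lacks day precision, or yields a negative difference are
excluded and counted by reason, never imputed. Day-0 (same-day) onsets are
retained — published onset IQRs reaching down to ~2 days imply small
values were kept. Quartiles use the linear-interpolation convention
(`stats::quantile` type 7), which is what fractional published quartiles
(e.g. ".75") imply. Bins are (0, 30], (30, 90], (90, 365], (365, ∞): "first
month" means ≤ 30 days, day 31 falls in the second bin, and the boundary
convention is fixed and tested.

## What the synthetic generator emulates — and what it does not

`faers_gen_config()` defines a complete reporting world; its defaults are
the study conditions the validation runs under, chosen once to mirror the
regime of a newly approved myelofibrosis drug and not tuned thereafter:

* 50,000 reports over ten quarters with a post-approval ramp
  (19% / 55% / 25% across years);
* a target drug reported under generic/brand/decorated/typo name variants,
  primary suspect in 90% of its mentions, ~5% of reports;
* a Zipf-like heavy tail over ~180 vocabulary PTs for background event
  frequencies — the frequency regime disproportionality methods actually
  face;
* planted signals as per-PT relative reporting ratios λ applied to reports
  where the target is primary suspect; under this scheme the cohort ROR of
  a planted PT is λ up to sampling noise, so planted strengths are
  recoverable end to end (λ = 1 plants a null term);
* duplicates (5%) as exact content copies under a higher PRIMARYID —
  deliberately, so that the key-based dedup rule is sufficient to resolve
  them — and deleted cases (2%) that remain in the tables, as in real
  extracts;
* missing sex 81.65%, missing age 82.58%, 75.78% of reports without a
  computable onset. `missing_tto_rate` is the *total* non-computable
  fraction; `partial_date_rate` controls what share of it is realized as
  truncated 4/6-digit tokens rather than blank fields. This keeps the
  evaluable fraction exactly `1 − missing_tto_rate` in expectation;
* onsets log-normal with median 27 days and σ = 2.5 on the log scale. The
  published regime states only a median and IQR, which no two-parameter
  log-normal can match simultaneously with its strongly asymmetric upper
  tail; the log-normal is a stand-in for shape, not an inference, and the
  onset-summary machinery does not depend on it.

The generator does not emulate reporting-over-time dynamics, country- or
reporter-specific reporting cultures, correlated events within a report
(beyond shared scaling), stimulated reporting after media attention, or
vocabulary version migration. Passing the synthetic recovery suite
therefore shows that the *pipeline arithmetic* is correct under a known
world — it does not show that real-data signals are causal, which no
disproportionality method can.

## Validation problem sizes

The test suite validates statistics against independent oracles
(closed-form arithmetic, `chisq.test`, and naive density-grid integration
for IC025/EBGM05 at 1e-3), and runs synthetic recovery at 50,000 reports:
exact cohort recovery on a file round-trip, a planted λ = 4 term flagged
by all four criteria, the null-term all-four flag rate over 25 replicates,
and ROR CI coverage of λ ∈ {1, 2, 4} over 100 replicates (nominal 95%,
required ≥ 90%). The MGPS prior-recovery check uses 10⁵ simulated cells.

```{r example}
library(faersignal)
cfg <- faers_gen_config(n_reports = 20000, seed = 42,
                        planted_signals = c(Diarrhoea = 4))
generate_package(cfg, "synth_faers")
res <- run_pipeline("synth_faers", "results",
                    target_names = c("pacritinib", "Vonjo"))
res$signals_pt[res$signals_pt$flag_all == TRUE, ]
```

## Known limitations

* Stratified/adjusted MGPS (age/sex strata) and multiple-comparison
  control across PTs are out of scope, as is the HLT/HLGT middle of the
  MedDRA hierarchy and SMQ groupings.
* The bundled vocabulary is synthetic (~180 PTs); real MedDRA is licensed
  and must be supplied by the user in the documented two-column format for
  real analyses. Multi-axial PTs resolve to a single primary SOC.
* EBGM05 root-finding is per-cell (`uniroot`); for databases with millions
  of distinct cells a vectorized implementation would be worth the
  complexity. At the tens of thousands of cells used here it is not the
  bottleneck.
* `IC025` in the Bate variant uses the normal approximation to the
  posterior of the IC, as in the original formulation; the default variant
  avoids the approximation entirely.
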