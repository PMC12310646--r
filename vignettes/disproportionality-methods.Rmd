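---
title: "Methods: disproportionality signal detection for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignals)
library(dplyr)
```

## The problem and the data model

Spontaneous reporting systems (FAERS, JADER) are passive collections of
suspected adverse-drug-reaction reports. A *case* consists of one
demographic record, one or more drug records each carrying a role code
(primary suspect PS, secondary suspect SS, concomitant C, interaction
I), one or more reactions coded as MedDRA preferred terms (PTs), and
zero or more outcome codes (DE death, LT life-threatening, HO
hospitalization, DS disability, CA congenital anomaly, RI required
intervention, OT other). Cases arrive in versions (follow-up reports),
and the same drug appears under brand and generic names.

`pvsignals` normalizes this into a `report_store` of four linked
tibbles. Three normalization rules matter downstream:

- **Deduplication.** For each case identifier exactly one version
  survives: the one with the maximal (receipt date, report-sequence)
  key, remaining ties resolved by last-read order. Partial dates
  (YYYYMM, YYYY) are zero-padded for this ordering but treated as
  unknown for interval arithmetic, so no fabricated day precision enters
  time-to-onset. The raw databases do not document a version-selection
  rule beyond the identifier; latest-version is the standard convention
  and is stated here as a package choice.
- **Exposure.** The study population is defined by role code, PS by
  default. Drug names are cleaned (case-fold, punctuation, dosage
  tokens) and mapped through a synonym dictionary to ingredients; rows
  naming the same ingredient collapse to one exposure keeping the
  earliest start date. The shipped dictionary covers the seven immune
  checkpoint inhibitors plus tremelimumab with common brand names; it is
  deliberately small and user-extendable, since no authoritative synonym
  list exists for free text in these databases. No fuzzy matching is
  attempted: PTs and ingredient names are controlled vocabulary, and
  silent fuzzy matches are worse than explicit misses.
- **Event grouping.** PTs that name the same clinical entity are pooled
  into composite categories (autoimmune encephalitis from four PTs, the
  myasthenia spectrum from five, etc.), each flagged as a neurological
  immune-mediated adverse event (NAE). A case with several PTs in one
  group counts **once** per (case, group) pair — report counts may
  exceed case counts, and all 2×2 cells are case counts. Groups with no
  expected signal (noninfectious myelitis as a PT, acute disseminated
  encephalomyelitis, multiple sclerosis) stay in the map so null
  findings are testable.

## The four algorithms

For a drug–event pair, a = cases with both, b = drug only, c = event
only, d = neither, N = a+b+c+d, and E = (a+b)(a+c)/N is the count
expected under independence.

**ROR** = ad/bc with the Woolf interval
exp(ln ROR ± z√(1/a+1/b+1/c+1/d)), z = 1.96. A zero cell leaves the
statistic undefined (`NA`) rather than applying a Haldane 0.5
correction by default: the minimum-count criterion (a ≥ 3) makes
corrected micro-signals irrelevant, and the correction is available as
`haldane = TRUE` for comparability with other software.

**PRR** = [a/(a+b)]/[c/(c+d)] with the Pearson χ² =
N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)), no continuity correction by default
(Yates available).

**MGPS.** The relative reporting rate λ of each pair is modeled as
drawn from a two-component gamma mixture
w·Γ(α₁,β₁) + (1−w)·Γ(α₂,β₂); counts are Poisson(λE). The prior is
fitted by maximizing the marginal likelihood — a two-component
negative-binomial mixture — over all cells of the analysis grid
(zero-count cells included, as the shrinkage model prescribes;
truncated fitting on a ≥ 1 is available). Optimization is bounded
L-BFGS-B from the canonical start (0.2, 0.1, 2.0, 4.0, 1/3) inside the
box [1e-4, 1e4] for shapes/rates and [1e-4, 1−1e-4] for w, with a
fixed, deterministic fallback start sequence — no stochastic restarts,
so fits are reproducible. The posterior per cell is again a
two-component gamma mixture by conjugacy; EBGM is its geometric mean
exp(E[ln λ]) computed from digamma functions, and EBGM05 the 5th
percentile of the mixture, solved by bisection between the two
component quantiles to relative tolerance 1e-8 (a normal-approximation
alternative EBGM·exp(−1.645/√a) is available as
`eb05_method = "normal_approx"`).

**BCPNN IC.** Two conventions:

- `"noren"` — self-contained: IC = log₂((a+0.5)/(E+0.5)), IC025 =
  IC − 3.3(a+0.5)^(−1/2) − 2.0(a+0.5)^(−3/4).
- `"mgps"` (default) — IC = log₂(EBGM) with IC025 =
  IC − 1.96/(√a·ln 2). This convention is motivated by published ICI
  signal tables in which the printed IC equals log₂ of the printed EBGM
  row for row to two decimals (e.g. EBGM 42.62 → IC 5.41), indicating
  both statistics derive from one shrunken estimate; the package
  encodes that relationship explicitly rather than claiming any
  particular publication's unpublished formula. The shipped reference
  table lets the consistency be checked at test time rather than
  asserted.

**Signal rule.** Literature-standard thresholds, all in configuration:
ROR flags when a ≥ 3 and the lower bound exceeds 1; PRR when a ≥ 3,
PRR ≥ 2 and χ² ≥ 4; BCPNN when IC025 > 0 (strict); MGPS when
EBGM05 > 2 (strict). Undefined statistics fail their flag. The overall
signal is the disjunction — "at least one algorithm" — which maximizes
sensitivity at a modest specificity cost; requiring all four is a
stricter alternative the flags support directly.

## Descriptive analytics

- **Annual trend**: cases per reporting year (year of the surviving
  version's receipt date — event year would be an alternative; report
  year is chosen because it is the dedup key's time scale and is almost
  always present), correlated with year by mid-rank Spearman. The
  p-value uses the exact null distribution for n ≤ 10 without ties and
  the t approximation otherwise.
- **Time to onset**: earliest matching reaction onset minus earliest
  suspect-drug start, in days; only fully dated, non-negative intervals
  are used and the exclusions are reported (usable + negative + undated
  = candidates, asserted in tests). Quartiles use linear interpolation
  between order statistics (`quantile` type 7), stated so IQRs are
  reproducible: the median of {10, 20, 30, 40, 50} is 30 with quartiles
  20 and 40.
- **Mortality**: deaths (outcome set contains DE) over cases per group,
  as a percentage.
- **Severity association**: per group, the 2×2 of (in-group vs other
  NAE cases) × (serious vs non-serious), Pearson χ² without correction;
  when any expected cell is below 5 the p-value comes from Fisher's
  exact test and the substitution is recorded per row. Cases with no
  outcome rows are excluded from this universe — the published tables
  this mirrors do not print their totals, so the universe definition
  (all NAE cases with known outcome) is an explicit assumption of this
  package.
- Severity itself is the trichotomy SERIOUS iff DE present,
  NON_SERIOUS iff outcomes present without DE, UNKNOWN iff none.

## The synthetic-report generator

`simulate_reports()` generates a ground-truthed database: one suspect
drug per case from power-law popularity weights (20 drugs by default,
the seven ICIs plus thirteen background agents), events included
independently with probability p·rr(drug, event) capped at 1, at least
one event per case by redrawing empty cases, demographics from
categorical distributions typical of ICI pharmacovigilance cohorts
(59% male, ~48% aged 65–84, physician-majority reporters), reporting
years with linearly growing weights over 2016–2024 (reporting growth),
a log-normal onset delay with median 30 days (μ = ln 30, σ = 0.8,
matching the onset scale reported for ICI neurotoxicity), 10% of start
and onset dates blanked, event-specific death probabilities (0.30 for
the myasthenia spectrum down to 0.02 for background events), and a 10%
duplicate-version rate. Everything is deterministic given the config
seed; identical configs produce byte-identical files.

What it emulates — case structure, versioning, synonymy, planted
disproportionality, missingness — is what the pipeline needs to be
validated end to end. What it does **not** emulate: pharmacological
correlation between events, drug–drug interaction structure, reporting
biases (stimulated reporting, notoriety effects), or the true marginal
distributions of a 16-million-report database. Passing tests therefore
demonstrate correctness of the machinery and calibration under the
stated model, not real-world operating characteristics.

Two generator subtleties surfaced by testing, kept as documented
behavior:

- The ≥1-event redraw conditions event margins upward slightly; this is
  harmless because expected counts are always computed from realized
  margins, and the null simulation shows no systematic bias (mean
  observed/expected ≈ 0.98 over cells with E ≥ 10, extremes consistent
  with exact Poisson tails).
- A planted relative risk rr on a drug with popularity share w realizes
  an observed-to-expected ratio of about rr/(1 + w(rr−1)), because the
  drug's own signal cases inflate the event margin and hence E. Clean
  log-scale recovery of planted rr (slope within [0.8, 1.2]) is
  therefore expected — and tested — on low-share drugs (~2%), which is
  also the realistic regime: any single drug is a small share of a real
  reporting database.

## Numerical and design choices

- Counting unit: the deduplicated case, everywhere. The background for
  every 2×2 is the full deduplicated database of one source (FAERS and
  JADER are never pooled).
- Expected counts use realized margins; cells are stored as tibble rows
  and all statistics are vectorized over them.
- The prior is fitted per database on the full drug×event grid
  (`contingency_grid(complete = TRUE)`), including a = 0 cells.
- Bisection for EBGM05 runs at most 200 halvings to relative tolerance
  1e-8 between the two component quantiles, which bracket every mixture
  quantile.
- Thresholds, z-quantiles, conventions and the zero-cell rule live in
  `signal_criteria()` and function arguments, never in code paths.
- Problem sizes in the validation suite (20,000-case pipelines over 20
  seeds, 2,000-case onset studies, 5,000-cell prior recoveries, 10⁶
  Monte-Carlo draws) were chosen as the smallest sizes at which the
  tested properties are stable, to keep the suite fast while retaining
  power.

## Known limitations

- Published headline signal tables from the full regulatory databases
  cannot be reproduced at desk scale: the raw extracts are tens of
  millions of reports, and published per-drug denominators are not
  always reconstructible from printed totals. Validation therefore
  combines (i) published arithmetic whose inputs are fully printed,
  (ii) internal-consistency checks against a shipped published signal
  table, and (iii) property-based simulation with known ground truth.
- The IC025/EBGM05 interval conventions vary across software; the two
  shipped conventions cover the common cases but no claim is made that
  they match any specific unpublished implementation.
- Disproportionality is association, not causation, and unadjusted:
  stratified or regression-adjusted variants are out of scope.
- The shipped MedDRA term list covers the curated NAE categories only;
  full dictionary traversal (SOC/HLGT) would require a MedDRA license
  and is represented instead by swappable grouping files.
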