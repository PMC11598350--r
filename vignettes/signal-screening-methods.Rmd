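---
title: "Methods: disproportionality screening of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvscreen)
```

## Scope and data model

pvscreen implements the analysis chain used to screen spontaneous
adverse-event reports for drug–event signals, organised around the FAERS
quarterly extract format: DEMO (demographics and administrative fields),
DRUG (one row per reported drug with a role code), REAC (MedDRA preferred
terms, PTs), INDI (indication PTs per drug), OUTC (outcome codes) and THER
(therapy start/end dates), all dollar-delimited with one header row. The
motivating application is malignancy risk under disease-modifying
antirheumatic drugs (DMARDs) in rheumatoid arthritis (RA), and the shipped
defaults (drug dictionary, SMQ universe, confounder watchlist) reflect that
setting, but every input is replaceable.

Spontaneous reporting data carry no denominators: all inference is about
*reporting* disproportionality, not incidence. Every estimate below is
conditional on a report having been submitted, and the package's vocabulary
("signal") deliberately means "disproportionally reported", nothing more.

## Deduplication

FAERS re-publishes a case every time it is revised; versions share a CASEID.
The FDA-recommended rule is applied: per CASEID keep the version with the
latest FDA_DT, ties broken by the higher PRIMARYID, and remove cases listed
in the quarterly deleted-case files. Two numerical choices are made
explicit:

- PRIMARYIDs that parse as integers are compared numerically (via
  fixed-width zero-padding), otherwise lexicographically — "higher" implies
  an ordinal comparison, and real PRIMARYIDs are numeric strings.
- A missing FDA_DT sorts below any valid date: a dated version carries more
  recent information than an undated one.

The operation is idempotent and order-independent, and conserves counts
(versions = survivors + superseded + deleted); the tests assert all three.

## Cohort definition

A case enters the analysis cohort when **any** drug in the case carries an
indication PT from the configured set (default `"Rheumatoid arthritis"`).
Restricting at report level rather than per-drug maximises sensitivity and
avoids depending on the reporter having linked the indication to the right
drug row. Cases without reactions are not analyzable and are dropped.

Exposure is the primary-suspect (PS) role only: the drug the reporter deemed
chiefly responsible. Verbatim drug names are normalised (case-folded,
dose/salt/formulation tokens stripped) and matched against a dictionary of
patterns by deterministic longest-match. The default dictionary covers the
twenty DMARDs of interest (4 conventional synthetic, 10 biologic, 6 targeted
synthetic, following the source classification, which lists iguratimod among
the targeted synthetics) with common brand synonyms; it is fully
user-overridable. Cases whose PS drug does not match stay in the cohort with
no exposure: the screening background for drug *D* is every cohort case not
exposed to *D*, including non-DMARD PS cases. If several PS entries map to
different ingredients, the case contributes to each ingredient's exposed set
(rare, but dropping such cases would silently bias margins).

## Signal statistics

For each (drug, event) pair a report-level 2×2 table (a, b, c, d) is built —
a case counts once regardless of repeated PTs — and two estimators are
computed:

- **ROR** = (a·d)/(b·c), Wald 95% bounds
  exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d)). With any zero cell the
  ROR is reported as undefined rather than Haldane-corrected: the signal
  rule's minimum-report condition makes corrected small-cell RORs
  irrelevant, and a correction would silently alter reported estimates.
- **IC** = log₂((a + 0.5)/(E + 0.5)), E = (a+b)(a+c)/N, with
  IC025 = IC − 3.3 (a+0.5)^(−1/2) − 2 (a+0.5)^(−3/2), the standard shrinkage
  form with Norén's credibility approximation used throughout the FAERS
  disproportionality literature. The +0.5 shrinkage keeps all cells defined;
  the correction terms are strictly positive, so IC025 < IC always.

A pair is a **signal** when a ≥ 3, ROR025 > 1 and IC025 > 0 — strict
inequalities, matching the usual phrasing "exceeded 1" / "greater than 0".
1.96 is used literally as the 95% normal quantile so results are
reproducible against published tables that do the same.

SMQ-level screening replaces the event indicator by membership of any
reaction PT in a Standardised MedDRA Query. SMQ content is licensed MedDRA
material, so the package ships only the nine cancer-related SMQ *names* as
the default universe; membership must be supplied as a (pt, smq) file.
Narrow/broad scope is not distinguished (encode scopes as separate SMQ names
if needed). Since membership is a union, a case counts once per SMQ, and an
SMQ's count is at least the largest member-PT count.

## Adjusted reporting odds ratios

To mitigate confounding by demographics and co-medication, the
malignancy-event indicator is regressed on exposure, age (years), sex
(F = 1, M = 0, unknown excluded) and 0/1 flags for the four watchlist
co-medications (methotrexate, tofacitinib, leflunomide, sulfasalazine),
restricted to cases whose PS drug is any dictionary DMARD. The adjusted ROR
is exp(β_drug) with Wald 95% bounds. The outcome pools all event-universe
PTs into one indicator (a per-event fit is available by passing a singleton
universe).

Estimation is maximum likelihood by iteratively reweighted least squares via
`stats::glm` (binomial family), tolerance 1e-8, at most 100 iterations —
delegating the solver while the package owns dataset construction,
covariate policy and reporting. Collapsibility is verified in the tests: an
intercept-plus-exposure fit reproduces the crude a·d/(b·c) to 1e-8.
Missing covariates are handled by complete-case analysis with the exclusion
count reported; constant covariate columns are dropped to keep the design
full rank; separation (fitted probabilities pinned at 0/1 with diverging
coefficients) is flagged. A case's own PS exposure never counts as its
co-medication; PS exposure to a *different* watched drug does, since that
use genuinely confounds the index contrast.

## Time to onset and descriptives

Onset is the interval from the **earliest** therapy start of the PS drug to
the adverse-event date (EVENT_DT, i.e. event occurrence, not report
receipt), in 365.25-day years. Both dates must be reported at full YYYYMMDD
precision; partial dates (YYYY, YYYYMM) are excluded with a reason code
because imputing days would fabricate precision — midpoint imputation is
available behind an explicit flag. Negative intervals are excluded as
`negative`; exclusions plus usable records always account for every
candidate (conservation, tested). Summaries use type-7 (linear
interpolation) quantiles so medians and IQRs are reproducible bit-for-bit.

Ages are converted from FAERS unit codes (DEC×10, YR, MON÷12, WK÷52.1786,
DY÷365.25, HR÷8766); results outside 0–120 years are treated as missing.
Percentage shares round half-up to two decimals, matching how published
share tables are printed. Outcome percentages are shown against two
denominators — outcome entries and exposed reports — because a case may
carry several outcome codes and published tables are often ambiguous about
which denominator they use.

## The synthetic-report generator

`generate_faers()` emits the full table set with known ground truth. What it
emulates:

- per-case report versions sharing CASEID (default 17% of cases get a
  second version, putting duplicates near 15% of raw rows, the magnitude
  seen in real five-year extracts), with later-or-tied FDA_DT and higher
  PRIMARYID, plus a deleted-case list (2%);
- PS assignment over the twenty DMARDs with shares shaped like the observed
  malignancy-report distribution (methotrexate ≈ 18% of exposed,
  adalimumab ≈ 16%, three agents at zero), 60% of cases DMARD-exposed, the
  rest non-DMARD PS background; a 90% RA indication mix;
- reaction PTs drawn per case with background probabilities, where an
  exposed case's odds for an event are multiplied by the configured RR —
  odds-based semantics so the ROR is the natural estimand and recovery can
  be judged against the generating value;
- demographics with FAERS age-unit codes (female fraction 0.72, age
  ~N(62, 13) truncated to 18–95, mixed YR/DEC/MON units), countries,
  outcome codes, and per-field missingness (10% age, 5% sex, 12% event
  date, 20% therapy start, 5% of emitted dates truncated to YYYYMM);
- therapy starts preceding the event by a log-normal class-specific time to
  onset (medians ≈ 4.5 y conventional synthetic, 2 y biologic, 1.2 y
  targeted synthetic), mirroring the long-vs-short onset contrast reported
  for those classes;
- verbatim drug strings as ingredient, brand, or dose-decorated variants to
  exercise dictionary normalisation.

What it does **not** emulate: misspelled verbatims, non-RA indication
hierarchies beyond a binary mix, reporting-source structure (RPSR),
duplicate cases with *conflicting* content, secular trends, or correlated
multi-event syndromes. Passing the recovery tests therefore shows the
pipeline is correct under its own assumptions — not that real FAERS signals
are causal or that real duplicates are always detectable by the CASEID rule.

The same seed yields byte-identical files. `roundtrip_check()` runs
generation → ingestion → dedup → cohort → screen and scores sensitivity
among injected pairs (those whose expected co-report count clears a
threshold, default 20), the false-signal fraction among RR = 1 pairs, mean
log-scale ROR bias on injected pairs, and exact dedup recovery. Injected
RORs are mildly attenuated (a few percent on the log scale) when two
injected drugs share an event, because each inflates the other's background
— an inherent property of the background definition, not an estimator bug.

`simulate_confounded()` draws regression-style data where age, sex and a
co-medication flag shift both exposure and outcome with a known conditional
odds ratio; it validates that the adjusted estimator removes the bias the
crude ROR shows (crude ≈ 3.9 when the conditional truth is 2.5 under the
default coefficients).

## Problem sizes and numerical conventions

The test suite exercises recovery at 200,000 generated cases (about 17 s)
and estimator calibration over 50 replicates of n = 20,000 logistic fits
(about 3 s); unit tests use cohorts of 5–60 hand-built cases whose 2×2
cells are enumerable by hand. Tie-breaks, rounding rules and quantile
conventions are fixed as described above so that every reported number is
bit-reproducible given the seed.

## Limitations

Disproportionality cannot separate reporting behaviour from risk; stimulated
reporting (e.g., after a regulatory warning) inflates RORs. The background
is the same-indication cohort, so class-wide effects shrink individual
signals. The adjusted model controls only measured covariates; channeling by
disease severity is invisible in spontaneous data. Absolute counts from real
extracts depend on which deleted-case lists were applied, so published
report totals are reproducible only to the extent the same deletion state is
available.
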