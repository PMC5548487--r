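---
title: "Methods: disproportionality signals and reporting-bias diagnostics for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and reporting-bias diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`faerstools` implements a reverse-translation analysis pipeline for
FAERS-style spontaneous adverse-event reports: entity normalization (drug
names to molecular ingredients, reaction verbatims to MedDRA preferred
terms), exact-duplicate detection, disproportionality statistics with
multiplicity control and empirical-Bayes shrinkage, month-resolved signal
series with trajectory clustering, and a set of reporting-bias
quantifications.  Because spontaneous-report databases are rolling public
downloads measured in gigabytes, the package ships a seeded synthetic
generator with planted ground truth; every claim the test suite makes is a
property of that stated synthetic world, not a reproduction of numbers
computed on the real database.

# The data model

A corpus is four relational tables keyed by report id: reports
(demographics, event/receipt dates, reporter occupation, sex, age in
years), drug entries (verbatim name, role code PS/SS/C/I, indication),
reaction mentions, and outcome mentions over the seven FAERS outcome
descriptors.  Quarterly `$`-delimited ASCII extracts are supported in two
dialects — the older ISR-keyed layout and the newer primaryid-keyed layout —
plus a canonical fixture dialect; a per-dialect column map translates them
onto one schema.  Unrecognized occupation and outcome codes degrade to
`unknown`/`Other` rather than erroring, ages are converted to years from
the unit code (decades, months, weeks, days, hours) with out-of-range
values set missing, and orphan rows (keys absent from the demographics
table) are dropped and counted in provenance.

Follow-up reports of one case are collapsed by keeping the report with the
greatest receipt date (ties: greatest report id), on the reasoning that a
later version supersedes earlier ones; demographics are taken from the kept
report wholesale.  Where an event date is missing, time-binned analyses
fall back to the receipt date.

# Name normalization

**Drugs.** Verbatim names are lowercased, stripped of non-alphanumeric
characters (digits kept), tokenized on whitespace with a configurable
stopword list (default: articles plus `and`, `of`, `with`, `for`, `acid`)
and treated as token *sets*.  A candidate synonym's token set is compared by
the Tanimoto coefficient `|A∩B| / |A∪B|`; a synonym scoring at least
`t_exact = 0.99` short-circuits the scan in table order, otherwise the
argmax wins if it reaches `t_min = 0.2`, with ties broken toward the longer
(more specific) synonym string and then lexicographically.  Manual
overrides are consulted before any matching.  Combination-product synonyms
may carry several ingredient keys; all are attached.  Matching uses a
token-level inverted index, so only synonyms sharing at least one token
with the query are scored — semantically identical to the full scan, since
a synonym sharing no token has coefficient 0.

**Reactions and indications.** Verbatim terms are standardized against a
preferred-term vocabulary by normalized Levenshtein similarity
`1 − d(a′, b′) / max(|a′|, |b′|)` on case-folded, whitespace-collapsed
strings (the normalization by maximum length is our choice; the score scale
in the source method is on [0, 1] but its formula is unstated).  A term
scoring at least `s_perfect = 0.95` short-circuits; otherwise the best term
wins if it reaches `s_min = 0.90` (ties: lexicographically smallest PT).
One deliberate refinement: an *exactly* folded-equal PT is matched ahead of
the vocabulary-order scan, which guarantees idempotence (a PT always
normalizes to itself) even in the crafted case where an earlier PT scores
above 0.95 against a verbatim equal to a later PT.  Matching is at PT level
only; hierarchy rollups are out of scope.

# Duplicate detection

Multiplied reports are detected by exact equality on five fields: the
sorted ingredient-key set, the sorted PT set, event date, age and sex.
Missing values are encoded with a sentinel equal only to itself; unmapped
drugs fall back to flagged verbatim strings.  Fingerprint hashing is
equivalent to the all-pairs comparison (a test proves this on small
corpora) but linear-time.  Collapsing keeps the lexicographically smallest
report id per group.  Fuzzy near-duplicate linkage is deliberately out of
scope: the phenomenon being quantified is verbatim multiplication.

# Disproportionality statistics

For an ingredient–ADR pair, counting is report-level: a report counts once
toward the drug margin `R` if any entry with an allowed role (default:
primary suspect only) maps to the ingredient, once toward the event margin
`C` if the PT appears among its reactions; `T` is the number of reports in
scope and `N` the joint count.  The expected count under independence is
`E = R·C/T` and the relative reporting ratio `RRR = N/E` (0 when `N = 0`).
Significance uses the Yates-corrected χ² on the reconstructed 2×2 (the
continuity correction clamped at zero so cells with `|O−E| < 0.5`
contribute nothing; degenerate tables yield p = 1), and the familywise
Holm step-down adjustment over the family of all pairs with `N ≥ 1` in
scope (the family definition is ours; the source leaves it unstated).  The
selection filter is `N ≥ 5`, `q < 0.05`, `RRR > 1`.  Note the source
describes Holm as "FDR" control; Holm is in fact a familywise-error
procedure, and we implement Holm exactly as named rather than substituting
Benjamini–Hochberg.

Stratified expectations `E = Σ_s R_s C_s / T_s` over age-band × sex strata
(default bands <18, 18–44, 45–64, 65+, missing) are available both
standalone and inside signal detection, for confounding by demographics.

## Empirical-Bayes shrinkage

Small-count ratios are noisy, so a gamma-Poisson mixture model shrinks
them: the true reporting ratio λ has prior
`w·Gamma(α₁, β₁) + (1−w)·Gamma(α₂, β₂)` and `N | λ ~ Poisson(λE)`, giving
negative-binomial marginals.  The prior is fitted by maximizing the
marginal likelihood over all (N, E) pairs with E > 0 (L-BFGS-B on
log/logit-transformed parameters bounded to [1e-4, 1e4], five seeded
starts, best kept).  The posterior is again a two-gamma mixture with
updated parameters `(α_k + N, β_k + E)` and weights proportional to the
component marginal likelihoods; `EBGM = exp(E[ln λ])` and EB05/EB95 are the
5th/95th posterior percentiles found by root-finding on the mixture CDF to
1e-8.  Tests verify the ordering EB05 ≤ EBGM ≤ EB95, strict shrinkage
between prior mean and raw ratio, convergence of EBGM to N/E at large
counts, parameter recovery in marginal likelihood, and RMSE dominance of
EBGM over the raw ratio on simulated pairs.

# Month-resolved analysis

Monthly series rebuild every pair's 2×2 from the reports of that month
alone (margins included), with Holm applied within each month across the
pairs observed that month.  Months with zero reports are missing values,
not zeros; months with data but no report of the pair carry `N = 0`,
`q = 1`.  Reports are binned by event date with receipt-date fallback
(flaggable to receipt date throughout).

Trajectory clustering partitions per-ADR monthly RRR vectors (missing
months imputed as 0) by k-medoids under distance `1 − Pearson r`.  The
build phase is the maximum-dissimilarity heuristic — first medoid the row
with the largest total distance, each next the row maximizing its minimum
distance to the chosen medoids — followed by best-improvement medoid swaps
to convergence.  Because single-swap descent can stall, the build-and-swap
cycle restarts from every row as an alternative first medoid when the
instance is small (≤ 30 rows) and keeps the best objective; this is cheap
and makes the heuristic match exhaustive search on all ≤ 8-row instances we
test.  Zero-variance rows cannot be correlated and are assigned under a
zero-correlation convention and flagged.  The phrase "partitioning around
maximum dissimilarity" in the source is ambiguous between this heuristic
and full PAM; the implemented procedure is the documented one above.

# Reporting-bias diagnostics

*Indication conflation.* A report is conflated when the standardized
indication of a primary-suspect drug equals (case-insensitively) one of the
report's standardized reaction PTs — the drug's reason-for-use reported as
its adverse event.  Each drug entry is compared only against its own
indication.  The yearly series divides conflated reports by reports whose
suspect drug carries any indication verbatim (matched or not), so
unmatched indications do not deflate the denominator.

*Reporter composition and outcomes.* Occupation fractions per calendar
period, and the distribution of the seven outcome descriptors counted per
mention (default) or per report's worst outcome (severity order: Death …
Other), since the basis used for the published percentages is unstated.

*Reporting-odds model.* A binomial GLM with logit link models the
probability that a report mentions a response ADR from report-level
covariates: a suspect-drug indicator, occupation indicators, and a
pre-cutoff-date indicator.  The fit is IRLS maximum likelihood
(`stats::glm`); tests verify equality with an independent second-order
optimizer and closed-form intercepts, and near-separation is reported as
non-convergence with diagnostics rather than silently returning drifting
estimates.

*Exposure margin.* `EM = IC50 / Cmax` on user-supplied potency and free
plasma exposure in matching units, flagged below a threshold (default 10;
13 reproduces the published dichotomy for the VEGF-R2 hypertension
example).  The drug-specific inputs are external data and are not shipped.

# The synthetic world

The generator draws `n_reports` reports with drug and reaction independent
under the null: one primary-suspect ingredient per report from the
background drug weights (an optional concomitant extra), 1–3 reaction
mentions (probabilities 0.6/0.3/0.1) from the background ADR weights,
event dates uniform over the configured month range, ages uniform 18–85
with 5% missing, sex near-balanced, one outcome per report from a
FAERS-like mixture (15% Death, 30% Hospitalization, 40% Other, remainder
spread), and occupation from a per-period mixture.  A planted association
`(i, a, ρ)` multiplies ADR `a`'s weight by ρ within reports of ingredient
`i` (renormalized) during its active window; spike windows are the same
mechanism restricted to the window, which directly produces the
month-localized significance runs the month-resolved diagnosis is meant to
detect (a date-relocation construction would test the same thing less
directly).  Ingredients are emitted under one of their synonym strings
chosen uniformly, then perturbed (casing, token reordering, punctuation,
appended dosage/formulation fillers) at the configured noise; exact
duplicates, follow-up versions and indication conflation are injected at
configured fractions with full bookkeeping in the returned ground truth.
Everything is a pure function of the config seed.

Two deliberate dimensioning choices:

* **Null calibration world** — pinned at 50 ingredients × 50 ADRs,
  n = 10,000, uniform weights.
* **Power/estimation world** — 100 ingredients × 200 ADRs.  The realized
  disproportionality of a planted ρ is attenuated below ρ by two effects:
  the renormalization factor `1/(1 + (ρ−1)p_a)` of the tilted conditional,
  and the inflation of the event margin (hence `E`) by the planted reports
  themselves.  At per-ADR probability 0.02 (the 50×50 world) these push the
  realized RRR for ρ = 8 to ≈ 6.2; at 0.005 (the 200-ADR world) to ≈ 7.2.
  Real spontaneous-report vocabularies are far sparser than 50 terms, so
  the sparser world is also the more realistic one.  The choice was made
  once and documented; acceptance bands were not adjusted.

What the generator does *not* emulate: drug–drug and ADR–ADR correlation
structure, secular reporting trends, real synonym morphology (its
pseudo-words are denser in edit-distance space than real preferred terms —
which is why the single-typo acceptance property asserts *matched*, the
guarantee the thresholds actually provide, while correct-PT identity is
tracked separately), dose records, and narrative fields.  A green test
establishes that the algorithms behave as specified on this stated world,
not that the biological conclusions of any particular analysis are right.

# Known limitations and an honest red light

With the method's own statistic — Yates χ² p-values under Holm and the
`N ≥ 5 / q < 0.05 / RRR > 1` filter — the fraction of *null* replicates of
the pinned calibration world containing at least one flagged pair is
about 0.17–0.29, not below the nominal 0.05.  The cause is not the
implementation (the p-values match a textbook oracle and `chisq.test` to
1e-10): at per-pair expectations around E ≈ 4–7 the χ² approximation is
strongly anti-conservative in the far tail.  Flagged null pairs show Yates
p one to two orders of magnitude below the exact hypergeometric tail
(e.g. N = 19, E = 5.8: χ² p = 6.3e-8 versus Fisher p = 5.2e-6), and
substituting the exact test restores the nominal familywise rate in the
same replicates.  The corresponding acceptance test asserts the nominal
bound and is left failing deliberately — the calibration claim is a
property the pinned method does not have at this scale, and hiding that
would be worse than reporting it.  Practical advice follows: on corpora
where interesting pairs have single-digit expected counts, treat the χ²
q-values as a ranking device and confirm borderline signals with an exact
test or the EB05 lower bound.

Other limitations: deduplication is exact-match only; the Holm family and
monthly family definitions are package choices the source leaves open;
k-medoids restarts are capped on large instances, where only the
maximum-dissimilarity start is used; and the logistic model is a
reporting-odds description, not a causal estimate.
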