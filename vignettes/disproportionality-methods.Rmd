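---
title: "Case/non-case disproportionality for drug-induced lactic acidosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality for drug-induced lactic acidosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerslahl)
library(dplyr)
```

## The question and the design

Spontaneous adverse-event databases such as FAERS cannot estimate incidence
— there is no denominator of exposed patients — but they can reveal
*disproportionality*: drugs whose reports mention an event far more often
than the background of all other drugs' reports. faerslahl implements this
case/non-case design for lactic acidosis and hyperlactatemia (LAHL), an
event defined by three MedDRA preferred terms (PTs): blood lactic acid
increased (10005635), hyperlactacidaemia (10020660) and lactic acidosis
(10023676). A report is a *case* if at least one of its reactions matches
the PT set, by code where available, otherwise by case-insensitive name; a
report listing two event PTs is still one case, though the matched subset
is retained for PT-level breakdowns.

For each drug (more precisely, each *ingredient-combination key*), the
deduplicated reports are cross-classified into the familiar 2×2 table —
`a` with the drug and the event, `b` with the drug only, `c` with the
event under any other drug, `d` with neither — and two statistics are
computed:

- reporting odds ratio, $ROR = \dfrac{a\,d}{b\,c}$, with the Wald 95%
  interval $\exp\!\big(\ln ROR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d}\big)$;
- proportional reporting ratio, $PRR = \dfrac{a/(a+b)}{c/(c+d)}$,
  accompanied by the uncorrected Pearson chi-square
  $\chi^2 = \dfrac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)}$.

The signal rules are the standard ones: an **ROR signal** requires
ROR > 1, lower 95% limit > 1 and $a \ge 3$; a **PRR signal** requires
PRR ≥ 2, $\chi^2 > 4$ and $a \ge 3$. No multiplicity adjustment is applied
— the thresholds are the only filter, as is conventional for this design.
Algebraically $PRR > 1 \Rightarrow ROR > PRR$ on all-positive tables, so
the ROR rule is the more sensitive of the two; both are reported.

Two numerical conventions matter and are fixed throughout: the CI constant
is exactly 1.96 (not `qnorm(0.975)`), and the chi-square carries **no
Yates continuity correction**. The second choice is not arbitrary: the
reconstruction oracle below confirms it against published values — with
the correction, small-count reference rows would sit 0.5–1.3% below their
printed statistics.

## Deduplication and deletion

FAERS distributes versioned reports: one case (CASEID) may appear in many
quarterly packages as follow-ups with different report identifiers
(PRIMARYID). Per the FDA convention, the pipeline keeps, per CASEID, the
version with the latest receipt date (FDA_DT), breaking ties by the
highest PRIMARYID — numerically when identifiers parse as numbers,
lexicographically on zero-padded strings otherwise. Deduplication runs
globally over the concatenation of all ingested quarters, because
follow-ups routinely cross quarter boundaries; per-quarter dedup would
miss them. Deletion lists (shipped with quarterly packages since 2019)
are applied *after* dedup, as a union over quarters.

Records whose FDA_DT cannot be parsed cannot be ordered, so they are
excluded rather than imputed; the count is attached to the result and
surfaced in the pipeline's stage ledger. Coarse receipt dates (year or
year-month precision) sort before any day-precise date of the same year,
giving a deterministic total order.

## The counting unit, and why it is configurable

The default unit of analysis is **(deduplicated case × distinct
primary-suspect ingredient key)**: each case contributes one row per
distinct PS-role key, and the row is an event row iff the case is an
event case. This follows the convention of counting only the medication
the reporter held chiefly responsible. The unit is nonetheless
configurable (`"case-drug-anyrole"`, `"case-drug-reaction"`), for a
substantive reason: back-solving published 2×2 tables from this corpus
implies a background N near 5×10⁷, larger than any plausible deduplicated
report count, so the original analyses likely used a finer unit (closer
to one row per case–drug–reaction triple). No configuration here claims
to replicate that N; the statistics and criteria are unit-agnostic, and
every validation in this package states the unit it used.

Drug names are standardized before counting: trimmed, case-folded,
trailing periods and a single trailing salt/ester token removed (with a
guard so salt-only products such as *sodium acetate* survive intact), and
then mapped through a user-supplied name-to-ingredient table. Combination
products become sorted, slash-joined keys (`"lamivudine/stavudine"`) and
are deliberately treated as drugs distinct from their components, since
that is the unit at which signal tables are published. The licensed WHO
Drug Dictionary cannot be shipped; the mapping is data, not algorithm,
and the package includes only a small illustrative map for tests and
examples. Unmapped names pass through as their own key, flagged.

One upstream inconsistency is worth recording: the source material prints
the code of *blood lactic acid increased* both as 1005635 and as
10005635. The 8-digit form is used here, treating the 7-digit occurrence
as a typographical variant; no further guessing is done.

## The reconstruction oracle

Full FAERS corpora are too large to ship, so the package validates its
statistics against published summary rows by *inversion*. Given a printed
row $(a, ROR\ r, PRR\ p)$ and the corpus event total $E$, the remaining
cells are determined in closed form:

$$c = E - a,\qquad b = \frac{a\,(p-1)}{r-p},\qquad d = \frac{r\,c\,b}{a},$$

from the identity $p = (a + r b)/(a + b)$. Recomputing the CI bounds and
chi-square on the reconstructed table and comparing to the printed values
is a genuine end-to-end check of the statistic implementations that runs
in milliseconds. The packaged reference table
(`printed_reference_rows()`) carries the 50 strongest-signal rows of a
published FAERS LAHL analysis (E = 32,187 event cases).

Three caveats are built into `check_printed_rows()` rather than left to
the user's memory:

- **Ill-conditioning.** $b$ is proportional to $1/(r-p)$, so when the
  printed gap $r - p$ is below 0.1 the reconstructed $b$ (and hence
  chi-square) is dominated by the ±0.005 rounding of the printed inputs.
  Such rows are flagged and their chi-square is reported but not scored.
  The CI bounds remain scored: when $a \ll b, c, d$ the interval width is
  dominated by the $1/a$ term, and perturbing $b$ by ±5% moves the lower
  bound by under 0.1% (a tested property).
- **Large a.** $c = E - a$ assumes each event case contributes exactly
  one primary-suspect key. For small-$a$ rows the error is negligible
  (reconstructed chi-squares agree with printed values to well under
  0.5%); for the one row with $a \approx E/2$ the assumption is strained
  and the chi-square lands about 2% off while the CI bounds still agree.
  Rows with $a/E > 0.2$ are therefore flagged and scored on CI bounds
  only.
- **Rounding propagation.** Even for well-conditioned rows, rounding of
  the printed inputs can move a reconstructed bound across a two-decimal
  boundary; two upper bounds in the reference table differ by exactly
  0.01 for this reason. The scored tolerance is 0.5% relative, which
  absorbs printed-rounding propagation without masking real defects (a
  1.5× perturbation of an input ROR fails by more than an order of
  magnitude).

## The synthetic generator

`generate_faers_package()` writes FAERS-dialect quarterly packages
(dollar-delimited DEMO/DRUG/REAC/THER/OUTC plus DELETED lists for
2019-or-later quarters) with analytically known ground truth, so every
downstream stage is testable without any download. Its key mechanism:
event status is sampled per report from the primary suspect's *planted
odds ratio* — the logit of the background event probability shifted by
the log odds ratio. Non-primary-suspect drugs on a report never alter
event probability, which keeps the per-key 2×2 tables exactly known and
matches the pipeline's primary-suspect counting unit. An odds ratio of 1
means no association.

Duplicate report versions perturb only FDA_DT, PRIMARYID and (sometimes)
demographics — never drugs or reactions — so deduplication correctness is
isolatable: with duplicates present, correct dedup recovers exactly the
ground-truth cells, and any dedup defect inflates `a`. PRIMARYID is the
CASEID with a version counter appended, and half of the duplicate
versions tie on FDA_DT, so the highest-PRIMARYID tie-break is genuinely
exercised. Deletion lists are only written into quarters labelled 2019 or
later; a config planting deletions into a pre-2019-only window is
rejected as invalid rather than silently ignored.

Default conditions (each overridable in `synth_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_reports` | 20,000 | large enough that a planted odds ratio of 10 on a 0.75%-marginal drug yields ≈50 event reports, the regime the validation suite targets |
| `background_event_prob` | 0.05 | a plausible niche-event background for a desk-scale corpus |
| `planted_odds_ratios` | linezolid = 10 | one strong planted signal; all other drugs null |
| `event_pt_weights` | 26,364 : 4,310 : 2,103 | proportional to the published per-PT case counts |
| `multi_pt_prob` | 0.018 | matches the published excess of per-PT counts over combined cases (~1.8%) |
| `onset_lag_mean_days` | 36 | exponential lag whose median (= mean × ln 2) is the published 25-day median onset |
| `duplicate_rate` / `deletion_rate` | 0.10 / 0.02 | enough volume to exercise dedup and deletion paths without dominating the corpus |
| `missing_age_rate` / `missing_sex_rate` | 0.15 / 0.10 | demographic missingness typical of spontaneous reports |

What the generator does *not* emulate — and hence what passing tests do
not show about real data: drug co-prescription correlation (extra drugs
are sampled independently), free-text verbatim noise beyond case, salt
suffixes and brand synonyms, schema drift across two decades of quarterly
files beyond the header-alias table, reporting-rate secular trends
(receipt dates are uniform), and any dependence of event probability on
demographics. Recovery of planted signals here validates the *plumbing
and the statistics*, not robustness to real FAERS messiness.

## Validation suite and problem sizes

The test suite asserts, among others: exact agreement of ROR/PRR/χ² with
brute-force cell arithmetic to 1e-12 on 1,000 random tables (and with
`chisq.test(correct = FALSE)` on a subsample); inversion round-trips to
1e-9; dedup idempotence and order-invariance; byte-identical regeneration
and reruns under a fixed seed; exact pipeline recovery of generator
ground truth (with and without duplicates and deletions active); firing
of both signal criteria on the planted odds-ratio-10 drug; null
calibration — across 200 seeds with all odds ratios 1, the ROR rule flags
3–4% of evaluable keys with $a \ge 3$, consistent with the one-sided 2.5%
nature of the CI-low rule plus the mild anti-conservatism of the Wald
interval at moderate counts; and 95% CI coverage of a planted odds ratio
within ±2% of nominal over 500 seeds of 20,000 reports each. These sizes
(200–500 seeds, 2,000–20,000 reports) were chosen as the smallest at
which the binomial Monte-Carlo error is well inside the asserted bands.

## Descriptive conventions

Ages convert to years by unit code (DEC×10, YR×1, MON÷12, WK÷52.18,
DY÷365.25, HR÷8766), with results outside [0, 122] years treated as
missing. Onset time is the event date minus the *earliest* day-precise
therapy start among primary-suspect drugs — a case may list several
episodes, and the source material does not specify the rule, so this
choice is recorded in the run metadata as an assumption. Either date
lacking day precision yields missing (no mid-month imputation), as do
negative intervals and intervals over ten years. The reporting country
comes from the occurrence-country field with reporter-country fallback
(also configurable, for the same reason); regions come from an editable
country-to-continent table with unknowns mapped to "Not Specified".
Percentages are rounded half-up to two decimals, the convention that
reproduces published characteristic-table pairs exactly. Outcome
categories are non-exclusive, so their percentages may sum over 100; a
case is "serious" iff it has at least one outcome record.

## Known limitations

- The Wald interval is mildly anti-conservative at small `a`; no exact or
  mid-p interval is offered because the signal criteria are defined on
  the Wald form.
- Zero-cell tables are "not evaluable" and never flagged by default; the
  Haldane–Anscombe +0.5 correction is opt-in (`haldane = TRUE`) and marked
  per row, because silent corrections would change printed-value checks.
- The drug map is user-supplied; coverage gaps surface as pass-through
  keys flagged unmapped, not as errors.
- `parse_quarter` reads the public ASCII dialect only (no XML), and INDI
  and RPSR tables are ignored — indications and report sources feed no
  output of this pipeline.
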