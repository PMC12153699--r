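---
title: "Methods: cardiovascular signal detection in FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiovascular signal detection in FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

`faersignal` implements a case/non-case disproportionality analysis of
cardiovascular adverse events (cAEs) under BRAF and MEK inhibitor
therapy for melanoma, from raw FAERS quarterly extracts to annotated
signals. This vignette is the package's account of the methods: the
models and rules, the parameters that matter, the numerical choices, and
what the synthetic validation does and does not establish.

## The data model

FAERS distributes quarterly ASCII extracts as six dollar-delimited
tables keyed by `primaryid`: DEMO (one row per report version: case
identifiers, dates, demographics, reporter), DRUG (one row per drug
mention with a role code — primary suspect PS, secondary suspect SS,
concomitant C, interacting I), INDI (indications per drug sequence),
THER (therapy episodes per drug sequence), REAC (MedDRA Preferred Terms,
PTs) and OUTC (outcome codes). `read_quarter()` parses all fields as
character because the payload is heterogeneous free text: dates arrive
as `YYYY`, `YYYYMM` or `YYYYMMDD`; ages in six different units; drug
names as brands, generics or salt forms.

Three conventions the format itself does not declare are fixed here:
the dialect is `$`-delimited with a header row and no quoting; input
bytes are decoded as Latin-1 (lossless for the non-UTF-8 bytes present
in some archive years); and header drift across years is absorbed by a
small alias table (e.g. `gndr_cod` → `sex`) while unrecognized columns
are carried through untouched. Rows with too few fields are completed
with missing trailing fields and surfaced as warnings — a malformed row
is a data-quality fact, not something to drop silently.

`build_combined()` concatenates quarters and produces the three analysis
tables: DEMO with outcome codes collapsed to a per-report set, DRUG with
INDI and THER attached strictly on matching drug sequence numbers, and
REAC as-is. Child rows whose `primaryid` has no DEMO parent are orphans:
kept out of the combined tables, counted in the run log.

## Deduplication

Duplicate submissions inflate disproportionality statistics, so cleaning
is a two-step procedure in a fixed order:

1. **By identifiers** (`dedup_by_ids()`): FAERS carries every version of
   a case; each `caseid` group collapses to its most recent version.
2. **By similarity** (`dedup_by_similarity()`): reports that agree
   exactly on six fields — the PT multiset, onset date, sex, age,
   reporting country, and the set of suspect (PS/SS) drugs — are treated
   as one case submitted under different identifiers, and collapse to
   the most recent.

"Most recent" needs a total order to be reproducible, so ties resolve
down a fixed ladder: highest `caseversion`, then latest `fda_dt`, then
lexicographically largest `primaryid`. Similarity matching is exact
equality with all six fields present; a report missing any field never
merges, and no fuzzy matching is attempted — approximate linkage would
introduce a tunable similarity threshold and make the cleaned universe
irreproducible. Both steps are idempotent and only ever shrink the
report set, which the test suite asserts as properties.

Three exclusion filters then remove (i) premarketing reports supported
by literature references (non-empty `lit_ref`; when a report-type column
is present, additionally gated on a configurable premarketing type set,
default `EXP` — without such a column the literature reference alone
decides), (ii) reports naming investigational, blinded or
unspecified-ingredient products (case-insensitive substring list,
configurable; a bare "biosimilar" token is deliberately not included
because it would also match marketed biosimilars), and (iii) the PT
"no adverse event", dropped from every report, with reports left empty
excluded. Every removal is logged separately so the run log reproduces a
selection flowchart.

## Exposure cohort and case definition

Exposure classification follows suspect roles only. A report joins a
combination group (D+T, V+C, E+B — the three approved BRAFi+MEKi pairs)
when one partner is the primary suspect and the other the secondary
suspect; a monotherapy group when a drug of interest is the lone
suspect of interest. Non-approved pairings (e.g. dabrafenib +
binimetinib), drugs of interest appearing only as concomitants, and
reports with conflicting multiple primary suspects of interest belong to
no group: the classification is a partition, each cleaned report landing
in exactly one of the nine groups or in the comparator.

Free-text drug names are normalized by a case- and
punctuation-insensitive dictionary with salt-suffix stripping
("Dabrafenib Mesylate" → dabrafenib); the default dictionary covers the
brand and generic names of the six drugs and is user-extensible.

To limit confounding by indication, reports whose suspect drug of
interest carries a stated non-melanoma indication are excluded. Missing
indications are retained: exclusion requires a stated conflicting
condition, since treating absence of information as evidence of
non-melanoma use would discard mostly-valid reports. The melanoma term
set is configurable and defaults to any PT containing "melanoma".

A cohort report is a cardiovascular case when at least one of its PTs
belongs to the narrow scope of one of seven cardiovascular SMQs
(bradyarrhythmias, cardiac failure, cardiomyopathy, embolic and
thrombotic events, ischaemic heart disease, noninfectious
myocarditis/pericarditis, tachyarrhythmias). Narrow scope maximizes
specificity — the case definition should not dilute the numerator with
possible-but-unlikely terms. MedDRA is licensed, so SMQ contents are
user-supplied configuration (`read_smq_config()`); the packaged
vocabularies are small synthetic stand-ins for testing, and results on
real data are only as good as the supplied PT lists. Event counting is
per (report, SMQ, PT) hit — a PT in two SMQs counts in both — while case
counting is per distinct report.

## Descriptive summaries

Ages convert to years with fixed factors (DEC ×10, YR ×1, MON ÷12,
WK ÷52.1775, DY ÷365.25, HR ÷8766); a unitless value is accepted as
years only up to 120. Age bands are ICH-style — Neonate < 28 days,
Child < 12, Adolescent 12–17, Adult 18–64, Elderly ≥ 65 — chosen because
the cohort's median ages in the mid-60s make 65 the natural elderly
boundary. Each report contributes one outcome, its most serious
(death > life-threatening > disability > hospitalization > intervention
required > other serious), so outcome percentages sum to 100.

Quartiles default to Tukey's median-of-halves hinges
(`stats::fivenum()`), with linear interpolation (type 7) as the
configurable alternative; on small samples the two differ only within
adjacent data values. Time-to-onset is the day difference between the
report's event date and the earliest therapy start of the primary
suspect drug, computed only when both dates are complete to the day.
Partial dates are never imputed — imputation would manufacture onset
signal — and incomplete or negative intervals are dropped and counted.
When a start date exists only for the secondary suspect the report is
likewise dropped and logged, keeping the onset anchored to the primary
suspect's therapy.

## Disproportionality

For each therapy group and each narrow-SMQ PT observed in the cleaned
universe, a report-level 2×2 table is built: `a` group reports with the
PT, `b` without, `c` other reports with the PT, `d` the remainder. The
comparator is the full cleaned universe minus the group — not the
melanoma cohort — because the reporting odds ratio is defined against
reporting of the same event under all other drugs:

$$\mathrm{ROR} = \frac{a\,d}{b\,c}, \qquad
\mathrm{CI}_{95\%} = \exp\!\left(\ln \mathrm{ROR} \pm z\,
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

with $z = 1.959964$ (a config argument; the printed-precision results
are insensitive to 1.96 vs 1.959964, but determinism demands one
value). Tables with a zero cell receive the Haldane–Anscombe correction
(+0.5 on all four cells) and are flagged `corrected`. An SDR requires
`ci_low > 1` and at least `min_n = 3` reports; corrected results are
eligible under the same rule, and `a = 0` can never qualify. Testing is
bounded to the SMQ PT scope, and no multiplicity adjustment is applied —
matching standard signal-detection practice, where SDRs are hypotheses
to investigate, not confirmatory findings; the number of tests is
attached to the output for post-hoc adjustment. Annotation marks IME
list membership ("clinically relevant"), DME membership, and label
expectedness (PT present in the group's labeled adverse reaction list;
groups without a list count as all-unexpected).

### Auditing printed results

Published disproportionality tables print (n, ROR, CI) but not the
underlying cells. Given the universe size $N$, the group total $G$ and
the printed ROR $r$, the comparator cell follows in closed form from
$r = \frac{a d}{b c}$ with $b = G - a$ and $c + d = N - G$:

$$c = \mathrm{round}\!\left(\frac{a\,(N - G)}{r\,b + a}\right)$$

`invert_ror()` solves this and `audit_printed_signals()` recomputes the
CI, passing a row when the recomputed ROR is within 1% of print and both
bounds within 0.02 on the log scale. Against the published combination
table (universe 14,077,067; D+T 8,895, V+C 2,111, E+B 3,097) every full
triplet passes, and the headline bounds reproduce to the printed two
decimals. Agreement beyond that is limited by the print precision
itself: a ROR printed to two decimals can shift a recomputed bound by
one unit in its second decimal, which the audit's log-scale tolerance
absorbs while the exact-decimal flags report it.

## The synthetic FAERS generator

`generate_faers()` emulates the features of real extracts that the
pipeline must survive: multi-quarter files with a shared schema,
id-duplicates (same case, new version) and similarity-duplicates (exact
clones under new case identifiers), partial dates, mixed age units,
per-field missingness, suspect/concomitant role structure, indications,
therapy dates, and planted drug–event associations. Duplicates are exact
clones by design: the similarity rule is exact-match, so noisy clones
would exercise a different method than the one implemented. Drug–event
occurrences are independent except for planted pairs, which keeps every
expected contingency cell analytic; a planted multiplier $m$ sets the
per-report probability to $p = m\,o_0/(1 + m\,o_0)$ with $o_0$ the
background odds, so the expected reporting odds ratio equals $m$.

Everything the pipeline should recover is written to a ledger:
per-report group, reactions, onset days and duplicate provenance, plus
group counts, cardiovascular case/event counts and per-(group, PT)
contingency cells. Independently generated reports can coincidentally
share a similarity key (single-PT reports with month-precision onset
dates are the usual culprits); the ledger computes its cohort-level
quantities on the survivor set of the exact-match rule, so recovery is
asserted exactly rather than approximately.

`emulate_paper_shape()` returns a configuration whose group shares
follow the published cohort (D+T 48.4%, E+B 16.9%, V 11.8%, V+C 11.5%,
D 4.6%, T 3.8%, C 1.4%, B 0.8%, E 0.7%) and whose expected
cardiovascular-case fraction is 8.7%, achieved by solving for a common
odds multiplier over the SMQ PT catalog. Two desk-scale choices are
explicit parameters rather than silent defaults: `scale` sizes the
of-interest cohort (scale = 1 ≈ 18,370 reports), and `background_ratio`
sizes the comparator, because a 14-million-report universe is not a
reasonable object to simulate locally. Onset medians per group follow
the published box-plot statistics where printed (E+B 12, V+C 30, V 33,
T 45, E 1212 days); for groups without a printed median (D+T, D, C, B)
the generator uses 30–60 days, in line with the early-onset pattern of
combination therapy, with a lognormal spread (`tto_sdlog = 1`).

## What the validation shows — and what it cannot

The test suite validates the machinery on three levels: hand-built
fixtures with enumerable answers; property checks (idempotence,
monotonicity, partition, translation invariance, CI coverage ~95% on
10,000 simulated tables, an exhaustive-counting oracle for the ROR);
and end-to-end recovery of the generator's ledger at 10³–5×10⁴ reports,
including planted odds ratios within ±3 standard errors. Problem sizes
were chosen so the whole suite runs in about a minute on one CPU while
keeping expected cells large enough for the sampling bands to be
meaningful.

None of this certifies results on real FAERS data. The generator's
background is independent drug–event noise: it has no confounding by
indication, no stimulated-reporting dynamics, no correlated drug
co-mentions, no coding drift across MedDRA versions. Passing tests show
the pipeline computes the defined statistics correctly and recovers
known structure; on real data the statistics remain reporting
associations, not incidence or causation — no denominator exists, and
channeling and notoriety biases are untouched by any of the cleaning
steps. The melanoma indication filter, the exact-match similarity rule
and the narrow SMQ scope are all specificity-over-sensitivity choices;
each can drop genuine cases, and each is configurable where a user's
trade-off differs.
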