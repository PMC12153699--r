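# faersignal

Pharmacovigilance signal detection on FAERS quarterly extracts, built
around the cardiovascular safety question for BRAF/MEK inhibitors in
melanoma.

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) are the main post-marketing source for adverse events too
rare, too delayed or too selected-against to surface in registration
trials. `faersignal` implements the full analysis path from the raw
quarterly ASCII extracts to disproportionality signals:

* **Ingestion** — parses the dollar-delimited DEMO / DRUG / INDI / OUTC /
  REAC / THER tables of each quarter, normalizes header drift across
  extract eras, and merges quarters into three combined analysis tables.
* **Cleaning** — two-step deduplication (most-recent case version by
  identifiers, then exact-match collapse of cross-case clones on event
  terms, onset date, sex, age, country and suspect drugs), followed by
  exclusion of premarketing literature reports, investigational/blinded
  products, and "no adverse event" reports.
* **Cohort** — suspect-role exposure classification into six BRAF/MEK
  inhibitor monotherapies (dabrafenib D, trametinib T, vemurafenib V,
  cobimetinib C, encorafenib E, binimetinib B) and the three approved
  combinations (D+T, V+C, E+B), restriction to melanoma indications, and
  cardiovascular case tagging via narrow-scope SMQ Preferred Term sets.
* **Descriptives** — characteristics tables (median/Q1–Q3, counts and
  percentages) and time-to-onset (days from therapy start to event date,
  complete dates only).
* **Signals** — case/non-case disproportionality per (therapy group, PT).
  The reporting odds ratio of a 2×2 table with cells *a, b, c, d* is

  ```
  ROR = (a·d)/(b·c),   95% CI = exp( ln ROR ± 1.959964·√(1/a + 1/b + 1/c + 1/d) )
  ```

  with the Haldane–Anscombe +0.5 correction for zero cells. A signal of
  disproportionate reporting (SDR) requires the lower CI bound to exceed
  1 with at least 3 reports. Signals are annotated with EMA IME/DME list
  membership and label expectedness.
* **Synthetic FAERS** — a generator that writes the same quarterly layout
  with a ground-truth ledger (group exposure, reaction sets, planted
  drug–event odds ratios, injected duplicates, partial dates), so every
  stage is testable without downloading the real archive.

MedDRA, the official SMQ contents and the EMA event lists are licensed;
the package ships small synthetic stand-in vocabularies under
`inst/extdata/` (marked `synthetic` in their names) and accepts the
licensed lists through `read_smq_config()` / `read_term_list()`.

## Worked example

Generate a synthetic universe shaped like the published melanoma cohort
(10% scale: ~1,837 of-interest reports among ~9,185 total), run the whole
pipeline, and look at the results:

```r
library(faersignal)

cfg <- emulate_paper_shape(scale = 0.1, background_ratio = 4, seed = 2024)
faers_dir <- file.path(tempdir(), "faers_sim")
ledger <- generate_faers(cfg, faers_dir)

ime    <- read_term_list(system.file("extdata", "ime_synthetic.txt", package = "faersignal"))
dme    <- read_term_list(system.file("extdata", "dme_synthetic.txt", package = "faersignal"))
labels <- yaml::read_yaml(system.file("extdata", "label_expected_synthetic.yaml",
                                      package = "faersignal"))$groups

res <- run_faers_pipeline(faers_dir, cfg$quarters,
                          ime_pts = ime, dme_pts = dme, label_map = labels)
res$log
```

```
# A tibble: 9 × 3
  step             detail                                                      n
  <chr>            <chr>                                                   <int>
1 input            DEMO rows across quarters                                9185
2 dedup_ids        duplicate case versions removed                             0
3 dedup_similarity similarity duplicates removed                               1
4 exclusion        premarketing literature reports removed                     0
5 exclusion        reports with investigational/blinded/unspecified produ…     0
6 exclusion        'no adverse event' PT rows dropped                          0
7 exclusion        reports with no remaining adverse event removed             0
8 cohort           reports of interest (melanoma)                           1804
9 cohort           cardiovascular AE cases                                   165
```

The log mirrors the selection flowchart of a FAERS analysis: 9,185 raw
rows survive as 9,184 cleaned reports, of which 1,804 form the melanoma
BRAF/MEKi cohort and 165 (9.1%, near the generator's 8.7% target) carry
at least one narrow-SMQ cardiovascular PT. The detected SDRs:

```r
dplyr::filter(res$signals, is_sdr)[, c("group", "pt", "n", "ror",
                                       "ci_low", "ci_high", "is_ime", "expected")]
```

```
# A tibble: 8 × 8
  group pt                                n   ror ci_low ci_high is_ime expected
  <chr> <chr>                         <int> <dbl>  <dbl>   <dbl> <lgl>  <lgl>
1 D     angina pectoris                   3 26.6    7.42    95.0 FALSE  FALSE
2 D+T   ejection fraction decreased       5  4.36   1.51    12.6 FALSE  TRUE
3 D+T   deep vein thrombosis              5  4.00   1.41    11.4 TRUE   TRUE
4 D+T   coronary artery stenosis          8  5.50   2.30    13.2 TRUE   FALSE
5 E+B   brugada syndrome                  3  5.94   1.70    20.8 TRUE   FALSE
6 E+B   bundle branch block right         3  4.89   1.43    16.8 FALSE  FALSE
7 E+B   disseminated intravascular c…     3  4.16   1.23    14.1 TRUE   FALSE
8 V+C   left ventricular failure          3  5.87   1.75    19.7 TRUE   FALSE
```

Each row is one drug-group/PT pair whose ROR lower confidence bound
exceeds 1 with n ≥ 3 reports; `is_ime` marks clinical relevance (IME list
membership) and `expected` whether the PT appears in that group's label
list. With the generator's background drug–event independence these are
the false-positive signals inherent to testing many pairs — planting a
true association (`planted_signals` in `sim_config()`) makes its ROR
recoverable within sampling error, which is exactly what the test suite
asserts. `res$tto$summary` gives the per-group time-to-onset five-number
summaries (box-plot statistics), and `res$table1` the characteristics
blocks.

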