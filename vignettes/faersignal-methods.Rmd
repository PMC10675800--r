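---
title: "Methods: disproportionality signals and two-way Ward clustering of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and two-way Ward clustering of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The data model

A spontaneous reporting database is a collection of *reports* (cases), each
associating one or more drugs with one or more adverse events coded as
MedDRA preferred terms. FAERS-style quarterly extracts split this into four
`$`-delimited tables — demographics (`DEMO`), drugs (`DRUG`), reactions
(`REAC`), indications (`INDI`) — linked by report identifiers. Two details
of this format drive the ingestion design:

* **Case versions.** A case (`caseid`) may be submitted repeatedly; each
  submission gets a new `primaryid` that encodes the version. We retain the
  numerically greatest `primaryid` per case, following the convention that
  later versions supersede earlier ones. The counting unit everywhere
  downstream is the *retained report*: a report contributes at most once to
  any contingency cell regardless of repeated drug or term mentions within
  it.
* **Drug roles.** Drug rows carry a role code: primary suspect (`PS`),
  secondary suspect (`SS`), concomitant (`C`), interacting (`I`). Only
  suspect roles enter the analysis; the retained set is configurable
  (`roles =` in `build_analysis_table()`).

Reports with no suspect drug or no reaction are kept in the denominator
with empty sets — they carry information about the background reporting
rates that the comparator cells need. Files are decoded as Latin-1 (FAERS
archives predate consistent UTF-8), malformed lines are skipped and
counted, and legacy identifier spellings (`ISR`/`CASE`) are handled by a
column-alias map.

## Drug-name normalization

Verbatim drug-name strings are mapped to canonical labels by
case-insensitive substring rules: a label applies when an include pattern is
contained in the string and no exclude pattern is. Substring containment
makes salt/hydrate forms ("MORPHINE SULFATE", "Fentanyl Citrate") match
without enumeration; exclusions resolve name collisions (APOMORPHINE
contains MORPHINE; DIHYDROCODEINE contains CODEINE) and always dominate.
The shipped rule set covers the eleven µ-opioid receptor agonists approved
in Japan and is an editable YAML file, so other panels can be analyzed with
the same machinery. A string naming two targets (a combination product)
counts the report for both labels — conservative under report-level
counting. We deliberately do not attempt RxNorm/ATC dictionary lookups or
fuzzy matching: substring rules are auditable and reproduce exactly the
inclusion/exclusion logic they encode.

## The disproportionality statistic

For drug $D$ and event $E$ the 2×2 table is $a$ = reports with both, $b$ =
reports with $D$ without $E$, and a comparator row $(c, d)$. Two comparator
conventions exist in the literature and both are implemented:

* `all_reports`: $c$ = all reports with $E$, $d$ = all without. This
  mirrors the contingency layout of the published opioid analysis this
  package re-implements (its comparator row is labelled "all of reports").
* `other_reports`: $c, d$ restricted to reports lacking $D$ — the
  convention of most published ROR tooling. The default in examples here;
  under it the four cells partition the database and the closed-form
  synthetic oracle is sharpest.

The reporting odds ratio is $\mathrm{ROR} = (a/b)/(c/d) = ad/bc$. Since a
zero cell makes the ROR undefined, the Haldane–Anscombe ½ correction adds
0.5 to **all** cells, unconditionally — not only when zeros occur — so the
estimator is the same smooth function of the data everywhere. The 95%
interval is the log-scale Wald interval on the corrected cells,
$\exp(\ln\mathrm{ROR} \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})$ with
$z_{0.975} = 1.959964$. The Fisher exact test runs on the *raw* integer
counts (the exact test is defined for integers; the correction is an
estimation device, not a data transformation), two-sided by the
point-probability rule: the p-value sums hypergeometric probabilities of
all tables with the observed margins whose probability does not exceed the
observed table's, probabilities compared with relative tolerance $10^{-7}$
(the dominant convention in scientific software). Significance is flagged
at $\alpha = 0.05$, with **no multiple-testing adjustment** — the analysis
this mirrors relies on report-count filtering rather than familywise
control, and the flag is a screen, not an inference.

A target drug with zero mapped reports is a legitimate degenerate margin:
its rows are emitted with a finite corrected lnROR, `p_value = NA` and
`significant = FALSE`, keeping the signal matrix rectangular.

## The signal matrix and its filters

`assemble_signal_matrix()` pivots the pair table into a drugs × events
lnROR grid with two per-event summaries: the database-wide report total and
the *unweighted* arithmetic mean lnROR over the drug panel (no weighting by
report counts — each drug's reporting profile counts equally, small panels
being the use case). The per-event summary table reports
$\exp(\overline{\ln\mathrm{ROR}})$ alongside; display columns round to two
decimals half away from zero, the rounding under which the published
summary's printed lnROR and ROR columns are mutually consistent.

Event filters apply in a fixed order, all strict:

1. report-count: keep events with total $>$ `min_event_reports` (the
   full-scale published analysis used 100,000 on a 2004–2020 FAERS extract;
   at desk scale you choose a proportionally smaller value);
2. positivity: keep events with mean lnROR $> 0$ (a mean of exactly 0 is
   excluded);
3. optional `top_n` by report total, ties broken lexicographically.

Filtering preserves column order, is idempotent, and records the count
surviving each stage (surfaced in the pipeline manifest, since the funnel
from all events to the clustered subset is itself a reported result).

## Two-way Ward clustering

Both axes of the filtered matrix are clustered by Ward's minimum-variance
method: drugs with their event-lnROR profiles as features, events with
their drug profiles. The implementation uses the Lance–Williams recurrence
on squared Euclidean distances with Ward.D2 heights (the square root of the
merged squared distance, so two singletons merge at their Euclidean
distance); a `height = "D1"` flag reports heights on the squared scale
instead. We wrote the linkage loop ourselves for one reason:
deterministic tie-breaking. Among equal-cost merges the pair with the
smallest (left, right) node indices is chosen, making results invariant to
the environment; `stats::hclust` serves as an independent cross-check in
the test suite, and an exhaustive ESS-minimization oracle verifies
step-wise optimality on small matrices. No standardization is applied
before clustering by default (all entries are already on the shared lnROR
scale); z-scoring per feature is available behind a flag. Trees are cut at
an explicit $k$ (the published opioid analysis corresponds to 5 drug and 7
event clusters on an 11 × 47 matrix); cutting, leaf ordering (depth-first,
lower-index child first) and exports (linkage TSV, memberships, Newick via
ape, reordered matrix, ggplot2 heatmap) are all deterministic. Raw lnROR
values are clustered, never the display-rounded ones.

## The synthetic generator and its oracle

`synthetic_config()` defines a generative model chosen to be exactly
analyzable rather than maximally realistic:

* each target drug $i$ enters a report independently with marginal
  probability $q_i$; distractor (non-target) suspect drugs likewise;
* event $j$ then enters with probability $\beta_j \cdot \theta_{\mathrm{eff}}$,
  where $\theta_{\mathrm{eff}}$ aggregates the planted multipliers
  $\theta_{ij}$ of the report's drugs — maximum by default (a report's risk
  is driven by its most implicated drug), product optionally — and is 1 for
  drug-free reports; probabilities above 1 are capped and counted;
* a configurable fraction of cases is re-emitted as a superseded earlier
  version differing only in demographics (so deduplication correctness is
  testable by counts alone); drug names are rendered with random
  salt/hydrate suffixes and case jitter; concomitant-role drugs are added
  for the role filter to remove.

Because inclusions are independent Bernoulli draws, the four cell
probabilities of any (drug, event) pair have an exact closed form —
`expected_lnror()` enumerates over the drugs whose multiplier for that
event differs from 1 — and the pipeline's estimate must converge on it.
Per-report drug and event counts are therefore *induced* (Poisson-binomial)
rather than directly specified; that is the price of the closed form, and
the main respect (besides realistic demographics, drug–drug interactions
and temporal trends) in which the generator does not emulate real
spontaneous-report data. Passing recovery tests consequently demonstrate
correctness of the counting and estimation machinery, not fidelity of any
real-world ROR.

The default study conditions (`synthetic_opioid_config()`) set the eleven
opioid marginals proportional to their published FAERS report counts scaled
to a database where the most-reported opioid appears in about 7.7% of
reports (oxycodone 0.0771 down to remifentanil 0.0010), plant 20
opioid-associated events with multipliers above 1 for every opioid but with
distinct profiles across five pharmacological groups (strong opioids, weak
opioids, loperamide, tapentadol, remifentanil), and add 30 multiplier-1
background events. Defaults were fixed once from these considerations.

## Numerical choices and degenerate inputs

* Fisher p-values: vectorized sums of `stats::dhyper` over the support;
  all-zero tables are an error; a zero drug margin yields `NA` in the pair
  table rather than an error, as above.
* Double correction is an error (`haldane_correct()` refuses corrected
  input), as is computing an ROR from a raw table with a zero cell.
* Ties in Ward merges: exact floating-point equality, resolved by node
  index; merge heights are monotone by construction of the recurrence.
* All row orders in outputs use locale-independent (radix) sorting, and all
  generation is seeded, so identical configurations give byte-identical
  output files.

## Validation problem sizes

The test suite validates the statistics at sizes chosen to make the checks
sharp while keeping the default run quick: exhaustive Fisher enumeration
over all 2×2 tables with margins ≤ 30 (164,175 tables); Ward step-wise
optimality on 100 random matrices of up to 7 rows; Wald coverage on 5,000
simulated tables with 2,000 reports per arm and odds ratios 0.5, 1 and 4;
null calibration on a 200,000-report database with 5,000 independent pairs;
recovery of planted lnRORs over 200 replicates of 50,000 reports; and
two-way cluster recovery (adjusted Rand index 1 on both axes) through the
full file pipeline on a 100,000-report database with two drug and two event
groups separated by a multiplier ratio of 4 (lnROR separation ≈ ln 4).

## Known limitations

* Disproportionality is reporting association, not incidence or causation;
  the package computes screens, and none of its outputs adjust for
  confounding, co-medication or reporting bias.
* Only ROR-based statistics are provided — no PRR, Bayesian shrinkage (IC,
  EBGM) or stratified/adjusted estimates.
* MedDRA preferred terms are treated as opaque strings; no hierarchy,
  synonym handling or dictionary licensing concerns enter the package.
* The ingestion covers DEMO/DRUG/REAC/INDI; THER/OUTC/RPSR tables, dose
  parsing and date arithmetic are out of scope.
* Name mapping is substring-based by design; genuinely ambiguous verbatim
  strings (misspellings beyond the shipped patterns) flow through
  unlabeled.
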