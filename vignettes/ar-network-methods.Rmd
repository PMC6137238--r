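---
title: "Methods: egocentric AR influence networks and the alter-density statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egocentric AR influence networks and the alter-density statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arnet)
```

## The design and its assumptions

`arnet` analyses *egocentric* networks: one focal participant (the ego),
the influences they nominate (alters), and the ego–alter ties only. There
are no alter–alter ties anywhere in the model — the elicitation records how
strongly each alter influences the ego's allergic-rhinitis (AR) management,
not whether the alters know each other. Tie strength is ordinal and comes
from a concentric-circle diagram with four rings: Circle One (innermost) is
"most influential", Circle Four "little influence". The circle count is
carried as configuration (`n_circles`) but everything ships with the
four-ring default.

Three assumptions are baked into the pipeline:

1. **Category-level analysis.** Alters are analysed as categories (a GP, not
   a particular GP). If an ego nominates two members of one category on
   different circles, the pair collapses to a single placement at the
   *innermost* circle — influence statements are "at least this strong", and
   cohort tabulations count participants, not individuals. This is a
   convention: whether the original interviews ever produced such duplicates
   is unknowable from the published record.
2. **Completers only.** An ego with zero placements is rejected at build
   time, mirroring the study's exclusion of the six non-completers.
3. **One tie per (ego, alter) pair.** Guaranteed by the collapse rule, and
   relied on by the aggregation invariant that an alter's per-circle counts
   sum to its number of nominating egos.

## Instruments

**Severity.** A single screening question with five canonical responses
maps bijectively onto the ARIA-style categories (none; mild /
moderate-to-severe × intermittent / persistent). Matching is
case-insensitive and whitespace-normalised but otherwise exact; we chose
rejection over fuzzy matching because a silently misclassified severity is
worse than a loud parse error.

**Quality of life.** The mini-RQLQ is summarised by the unweighted mean of
its items (0–6 scale; default 14 items, configurable, and a precomputed
mean is accepted when item-level data are absent, since the analysis uses
only the mean). The published QOL bins are "score zero", ">0–2", "3–4" and
"5–6" — which leaves (2,3) and (4,5) unmapped even though means are
continuous (the published cohort mean, 2.6, falls in the first gap). We
adopted the continuous half-open partition

ZERO = {0}, MILD = (0, 2], MOD = (2, 4], SEV = (4, 6]

which preserves every printed upper bound; the interior breaks are
configurable (`qol_breaks`) for sensitivity analyses.

## The alter-density statistic

For alter *a* with per-circle participant counts `n1..n4`:

* `alter_score(a) = 4·n1 + 3·n2 + 2·n3 + 1·n4`
* `density(a) = 100 · score(a) / Σ scores`

Weights default to the published 4/3/2/1 and generalise to `c..1` for `c`
circles. Useful consequences, all enforced as property tests:

* densities sum to 100 (tolerance 1e-9 pre-rounding);
* moving one placement inward strictly raises that alter's density and
  lowers every other alter's;
* scaling all counts by a positive integer leaves densities unchanged;
* the closed form agrees exactly with a brute-force loop over individual
  placements (the independent oracle used in the tests);
* an alter's whole-cohort score equals the sum of its four QOL-subgroup
  scores, because the subgroups partition the egos.

Density tables sort by descending density with an alphabetical tie-break —
the source analysis specifies no ordering, and determinism is worth more
than fidelity to an unstated convention.

**Rounding.** All printed percentages use one shared rule: half away from
zero at the requested precision. This reproduces every published worked
example except one — 12/41 egos is 29.27%, printed as "30%" in one figure —
which no single rounding rule can produce alongside the others; we keep the
consistent rule and flag the discrepancy rather than replicate it.

**Circle-One denominators.** "15 of 41 participants placed the GP in Circle
One" can be percentaged against the cohort (15/41 ≈ 37%) or against
Circle-One placements. The published figures are consistent with the cohort
denominator, which we adopt as `pct_of_cohort`, while also reporting
`pct_of_circle` so the alternative reading stays available.

**Network size.** The published summaries are internally inconsistent
("average 4, median 5" in one place; "average 4, mode 5" in another), so
`network_size_summary()` reports min, max, mean, median and *all* modes and
privileges none of them.

## Saturation

The name-generator technique stops recruiting when no new alter categories
appear. `saturation_index()` returns the index of the last participant who
introduced a first-appearance category — every later log entry is empty —
matching the published criterion ("no new alters nominated by the remaining
participants"). Appending egos who name only known categories provably never
raises the index.

## The synthetic cohort: what it emulates, what it does not

The study's raw data were never deposited, so the generator is the stated
world the tests run in. `default_study_params()` encodes the published
marginals as generating probabilities at n = 41:

| parameter | default | source of calibration |
|---|---|---|
| QOL probabilities | (1, 20, 12, 8)/41 | published QOL counts |
| severity probabilities | (1, 7, 14, 7, 12)/41 | published severity table |
| network-size means by QOL | 2 / 3.5 / 5 / 6.5 | range 1–11, mean ≈ 4–5, size growing with QOL impact |
| size distribution | 1 + Poisson(mean − 1), truncated to 1..11 | chosen; only range/centre were published |
| nomination propensities | GP 1.0, pharmacist 0.8, own experience 0.8, … | GP/pharmacist/own-experience dominance |
| circle distribution, own experience | (0.95, 0.03, 0.01, 0.01) | "almost entirely (except in one case)" on Circle One |
| `hcp_gradient` | 1.35 | HCP share of the network rises with QOL impact |
| mini-RQLQ items | binomial(6, m/6) around a target mean in the drawn bin | only the mean is analysed downstream |
| sex, region | 67% female, 34/41 metropolitan | published demographics |

Severity and QOL are drawn *independently*: the study reports only
marginals and itself notes that the two instruments disagree (>60%
moderate-to-severe severity against ~49% mild QOL impairment), so imposing
a joint distribution would invent information. A coupling can be configured
by replacing `severity_probs` per stratum in a custom parameter set.

What a green test therefore establishes: the pipeline's statistics recover
the generating parameters of a cohort with the published *marginal*
structure. What it does not establish: anything about real interview
dynamics, prompting effects, demographic joint distributions, or the actual
study's unpublished placement matrix.

A note on tolerances: the ±2-percentage-point recovery band at n = 5000 is
roughly 2.8 binomial standard deviations for the largest category, so a few
percent of seeds fail it on sampling noise alone. The recovery check
therefore runs at a fixed seed (chosen before measurement), while the exact
properties — oracle equivalence, round-trips, saturation — run under any
seed.

## File formats

**Cohort table**: tab-delimited long format, one row per placement with the
participant's fields repeated; participants appear in interview order, which
the saturation statistic consumes. `rqlq_items` uses `;`-separated item
scores; `rqlq_mean` is used when items are absent.

**VNA**: the NetDraw file format is named but not specified in the source
analysis, so the dialect here is one valid encoding, documented bit-exactly:
a `*node data` section with header `ID label group value`, then `*tie data`
with `from to strength`; space-delimited, labels quoted when they contain
spaces. Tie strength is the circle weight (circle 1 → 4, circle 4 → 1);
aggregate-mode node values are the placement-weighted mean circle weight,
our choice for "collating" individual maps into one. Write → read is
lossless for placements, and the reader rejects unknown sections,
out-of-range strengths, undeclared nodes and tie-less documents.

## Known limitations

* The alter taxonomy is reconstructed from the published inventory; the
  study's own prompt list was not printed. The taxonomy file is versioned
  and replaceable (`alter_taxonomy(path)`), never extended silently at
  runtime.
* The density statistic is descriptive; no inferential machinery is
  provided because none was used in the source analysis.
* Figures are out of scope: the package emits VNA files and plain tables,
  not rendered network maps.
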