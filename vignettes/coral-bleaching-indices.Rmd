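---
title: "Coral bleaching survey indices: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coral bleaching survey indices: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefbleach)
```

## The problem

Mass coral bleaching is monitored with repeated quadrat surveys: at each
station, observers deploy quadrats (here 1 m², 20 per station, placed
haphazardly and re-deployed in each sampling period), identify every coral
colony to genus, and score its condition in six ordered categories —
Healthy (C1, under 1% of the colony affected), Low (C2, 1–10%), Medium
(C3, 10–50%), High (C4, 50–90%), Extreme (C5, over 90%) and Dead (C6).
Surveys are run twice, during the thermal-stress event and again after it,
so that recovery and mortality can be separated.

`reefbleach` implements the full analysis chain for such surveys: a
validated long-format data model, the severity and susceptibility indices,
colony density and prevalence summaries, degree-heating-week (DHW) thermal
stress from daily sea-surface temperature (SST), matched-sample
period comparisons, and a synthetic survey generator so that every stage
is testable without field data.

## Severity and susceptibility indices

### Bleaching Response Index (BRI)

Each category carries an integer severity weight, 0 for C1 up to 5 for C6.
With $P_k$ the percentage of colonies in category $k$,

$$\mathrm{BRI} = \frac{0\,P_1 + 1\,P_2 + 2\,P_3 + 3\,P_4 + 4\,P_5 + 5\,P_6}{5},$$

which runs from 0 (every colony healthy) to 100 (every colony dead). The
index is linear in the category shares, so a site's BRI (all genera pooled)
equals the colony-count-weighted mean of its genus BRIs; the test suite
checks this pooling identity on random datasets.

A consequence worth knowing when comparing against published one-decimal
tables: for $n$ colonies the weighted sum is an integer $S$, so BRI can
only take values $20S/n$. At $n = 63$ the attainable values are about
0.32 apart — a printed one-decimal BRI may fall between attainable values,
and round-tripping through colony counts can differ from the printed value
by up to one unit in the last printed digit.

### Prevalence and mortality

Bleaching prevalence is the percentage of colonies in the live-bleaching
categories C2–C5. Dead colonies stay in the denominator but not in the
numerator: the analysis views colony status as a three-way split —
Healthy, Bleached (any live level), Dead — and prevalence is the middle
share. Mortality change between periods is the signed percentage-point
difference of the C6 share (after minus during).

### Bleaching Susceptibility Index (BSI)

Severity alone ignores how much of the community a susceptible taxon
represents. The BSI weights each genus BRI by the genus' relative
abundance $D_i$ and averages over genera:

$$\mathrm{BSI} = \sum_{i=1}^{N} \frac{\mathrm{BRI}_i \times D_i}{N}.$$

Two conventions are deliberately fixed here and exposed as parameters:

* **$D_i$ is in percent (0–100), not a fraction**, and is computed over
  *all* colonies recorded at the site-period. The percent scale is the one
  that produces BSI magnitudes in the tens-to-hundreds familiar from
  published site tables; `rel_abundance_scale = "fraction"` switches to the
  0–1 scale if needed.
* **Taxa with fewer than `min_n = 5` colonies are excluded from the sum**
  (a three-colony genus that happens to be fully bleached would otherwise
  swing the index) but still count in the relative-abundance denominator,
  so exclusion dilutes rather than redistributes.

### Density

Colony density is the mean over quadrats of colonies per m², with its
standard error over quadrats. Quadrats in which no colony was recorded
count as zeros against the *designed* quadrat count (20 per station)
unless an explicit surveyed-quadrat count overrides it; field datasets
rarely record empty quadrats as rows, and silently dropping them would
bias density upward.

## Thermal stress

DHW accumulation follows the standard satellite-monitoring convention.
From a daily SST series we compute a monthly climatology (mean per
calendar month, pooled across years) whose warmest month is the maximum
monthly mean (MMM). The daily HotSpot anomaly is `sst - MMM`; days with an
anomaly of at least `hotspot_floor` (default 1 °C) contribute
`anomaly / 7` to a trailing 84-day (12-week) window sum, giving DHW in
°C-weeks. Values of 4 °C-weeks and 8 °C-weeks mark the expected onset of
widespread bleaching and of bleaching-induced mortality (both thresholds
inclusive at the lower bound).

Numerical choices:

* With a constant anomaly $a \ge$ floor, the steady state is exactly
  $84a/7$ °C-weeks; the tests pin this closed form (e.g. a sustained +2 °C
  anomaly gives 24 °C-weeks).
* Days before a full 84-day window exists get a partial-window value,
  flagged in a `partial` column, rather than `NA` — plots of event onset
  then start at the series start without fabricating pre-series data.
* The climatology is computed from whatever SST history is supplied.
  Reproducing a satellite product's re-centred multi-decadal baseline is
  out of scope; `climatology(mmm = ...)` injects an external MMM directly.
* DHW refuses series with calendar gaps instead of interpolating.

```{r dhw-example}
ev <- list(list(start = "2023-03-01", duration_days = 84, peak_c = 2))
sst <- simulate_sst(26, 0, anomaly_events = ev, noise_sd = 0, years = 1)
max(dhw_series(sst, climatology(26))$dhw_cweeks)
```

## Period comparisons

Recovery and mortality by taxon are compared with a matched-sample
Student's *t* test on per-unit relative abundances of bleached (C2–C5) and
dead (C6) colonies within each main genus group. Choices:

* **Pairing unit is the station** (11 in the default design). Quadrats are
  re-deployed haphazardly each period and cannot be matched; stations are
  the finest unit that persists across periods. Pairing by site is
  available via `unit = "site"`.
* **Differences are taken as after minus during**, so negative *t* for
  bleached abundance means less bleaching after the event.
* **Main genera** are the smallest set of most-abundant taxa whose
  cumulative share *strictly exceeds* the coverage target (default 80%);
  the rest pool as "Others". A fixed genus list can override the automatic
  selection. Strictness matters at ties: a cumulative share of exactly 80%
  does not stop the scan.
* Units where a group was not recorded are missing, not zero, and
  incomplete pairs are dropped listwise with a message. Zero-variance
  differences are handled explicitly (t = 0, p = 1 when the mean is also
  zero; a flagged infinite statistic otherwise).

No multiple-testing correction is applied, matching common practice for
these descriptive genus tables; the p-values are reported per test.

## The synthetic survey generator

`simulate_survey()` emulates the statistical structure the analysis
assumes, not any particular reef:

* Per station, period and quadrat, the colony count is negative binomial
  with mean `quadrat_mean` (default 18 colonies/m², a typical hard-coral
  density on these reef slopes) and dispersion `quadrat_dispersion`
  (default 9.3, matching the overdispersion scale estimated by
  negative-binomial count models for such quadrat data).
* Each colony draws a genus from the community relative abundances and a
  during-event category from the genus' `category_probs_during`.
* Between periods each bleached colony independently recovers
  (`recovery_prob`), dies (`death_prob`), or keeps its category; healthy
  and dead colonies persist. The after-event survey re-draws fresh
  quadrats and samples from the transition-evolved community composition,
  mirroring the non-matched quadrat design.
* The default community (`default_genus_profiles()`) has nine named genera
  plus "Others", with branching thermally sensitive taxa (Acropora,
  Pocillopora, Seriatopora, Stylophora) carrying more bleaching mass than
  massive and encrusting taxa. It is illustrative, not fitted to any
  dataset.

What the generator deliberately does **not** model: spatial correlation
within or between quadrats, thermal forcing of bleaching probabilities
(DHW does not drive the category draws), observer error, or recruitment
between periods. Passing tests on simulated data therefore demonstrate the
correctness of the index arithmetic and pipeline plumbing under the stated
sampling model — they do not validate ecological realism of any particular
parameter set.

`expected_bri()` gives the population BRI implied by a category
probability vector ($20\sum_k w_k p_k$); at around 10,000 simulated
colonies the empirical BRI concentrates within one index unit of it, which
the tests use for parameter-recovery checks.

## Degenerate inputs and rounding

* Empty strata yield flagged (`empty`/`NA`) results, never silent zeros:
  a genus absent from one period appears with `n = 0` and `NA` BRI in the
  genus table. BRI, prevalence and BSI raise errors on empty input when
  called directly.
* Indices are computed at full precision; report tables round to six
  decimals on disk and presentation rounding to one decimal is left to the
  caller.
* Category labels are normalised case-insensitively (codes, digits, or
  names like "Healthy"); taxon names are whitespace-normalised and
  case-folded with the genus word capitalised, keeping growth-form
  qualifiers ("massive Porites") as distinct taxa. The hydrocoral
  Millepora is retained as a taxon, with an option to exclude it from
  hard-coral totals.

## Reconstructing colony tables from published summaries

When only published summary statistics of a survey are available (total
N, BRI, prevalence, dead share) and not the colony-level records,
`synthetic_category_counts()` builds one concrete six-category count
vector consistent with those summaries (to integer granularity), and
`counts_to_records()` expands it into quadrat records. The test suite uses
such synthetic stand-ins to exercise the full read–compute path against
seascape-scale summary values; they are stand-ins, not recovered data —
many colony tables share the same summaries.

## Problem sizes used in the tests

Property tests run on simulated datasets of roughly 3–8 thousand colonies
(11 stations × 20 quadrats × ~18 colonies, two periods), parameter
recovery on ~10,000 colonies, and the type-I-error check on 2,000
null replicates of 11 paired stations — sizes chosen to keep Monte-Carlo
error well below the asserted tolerances while the whole suite runs in
well under a minute per file.

## Known limitations

* GLMM-based inference on abundance (site × period × status interactions),
  model selection and post-hoc contrasts are out of scope; the package
  stops at the descriptive tables and matched-sample tests.
* The DHW module is a local computation from a supplied SST series; it
  does not retrieve satellite data or reproduce a specific product's
  baseline years.
* Published site densities and BSI values can depend on unstated
  denominators (surveyed-quadrat counts, abundance base); the package
  exposes these as parameters rather than guessing a convention, and its
  density/BSI checks are hand-computed or property-based.
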