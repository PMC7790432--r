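---
title: "Screening metabarcoding time series for host-parasitoid associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metabarcoding time series for host-parasitoid associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parascreen)
```

## The problem

Parasitoid protists -- Syndiniales, oomycetes such as *Olpidiopsis* and
*Lagenisma*, Cryomonadida and allies -- kill their planktonic hosts and can
terminate diatom and dinoflagellate blooms. Direct observation of an
infection is laborious, but a dense 18S metabarcoding time series carries an
indirect signature: when a host blooms, a parasitoid that exploits it either
rises *with* the host (an ongoing infection caught in the act) or rises a
few days *after* it (the classic lagged predator-prey pattern). `parascreen`
implements a screening workflow for exactly these two signatures, together
with the filtering, annotation and ordination machinery around it, and a
synthetic-data generator that plants known dynamics so the whole chain can
be benchmarked against ground truth.

The workflow operates at the OTU-table level. Upstream read processing
(trimming, merging, chimera removal, clustering, taxonomic classification)
is out of scope; the package starts from a count table, a ranked taxonomy
and an environmental record.

## Data model and filtering

An `otu_table` holds non-negative integer counts (OTUs x samples) with one
calendar date per sample, at day resolution. Two retention rules are
applied before any screening:

* **Sample depth.** Samples need at least 10,000 reads
  (`filter_samples_min_reads()`); shallower libraries give unreliable
  relative abundances.
* **Global OTU threshold.** An OTU must hold at least 0.001% of the total
  reads of the *unfiltered* dataset
  (`apply_global_threshold()`). The cut-off is
  `ceiling(fraction * total_reads)` -- with a grand total of 20,476,979
  reads this is 205 reads. Referring the fraction to the unfiltered grand
  total keeps the cut-off a property of the survey rather than of the
  retained sample set; a `total_reads` argument makes the reference total
  explicit and switchable.

Trophic modes come from an ordered literature rule table
(`trophic_lookup()`): each rule names a rank, a taxon-name pattern (exact
or prefix, so `Dino-Group` covers all Syndiniales groups), a label and a
citation key. Rules are applied most-specific-rank-first, then in file
order, so a genus-level exception always beats a class-level default and
the outcome is deterministic regardless of how the rule file is sorted.
OTUs matching no rule stay `unknown` -- in practice a large fraction, which
is itself a finding worth reporting (`annotation_summary()` prints counts
and percentages, rounded half-away-from-zero to one decimal as survey
tables conventionally do).

## Peaks, blooms and the two co-occurrence signatures

Relative-abundance series are screened with an operational peak
definition: a **peak** is an interior local maximum on the sampled grid
(`value > previous`, `value >= next`; the first sample of a flat-topped
run is the peak date) whose height reaches at least 10% of the series'
own maximum. The 10% rule makes the definition scale-free -- a taxon
whose maximum is 0.2% of reads can peak just as validly as one reaching
40% -- while discarding minor wiggles far below a taxon's own seasonal
range. The maximum is taken over the full series by default; "the maximum
during a window" is a supported variation through subsetting the series
first. Endpoints have no two-sided neighbourhood and are excluded unless
requested. A **bloom** is either a cluster of peaks in consecutive samples
(allowing one intervening non-peak sample by default) or any sample at
10% relative abundance or more.

Candidate pairs are classified from matched peaks (`match_peaks()`):

* **Case 2 (simultaneous).** Host and parasitoid peak on the same sampling
  date -- suggestive of a current infection. Strictly this means lag 0;
  `case2_tolerance_days` can widen it, because twice-weekly sampling
  cannot distinguish 0 from up to 3 days.
* **Case 1 (lagged).** The parasitoid peak follows the host peak by 1 to
  `max_lag_days` days -- the alternating Lotka-Volterra-like pattern. The
  default window of 14 days comfortably contains the 7- and 12-day delays
  observed for diatom-oomycete systems while staying short enough that
  successive bloom events do not cross-match.

Matching is greedy and one-to-one: parasitoid peaks are scanned in date
order and each takes the *latest* still-unmatched host peak within the
window. This mirrors the visual reading of a time-series plot ("a peak
followed N days later") and is deterministic; it is deliberately not a
globally optimal assignment, which could pair peaks across bloom events in
unintuitive ways. Lags are `parasitoid date - host date` on calendar days
(never sample indices), so results do not depend on sampling-phase
boundaries; negative lags never match, since the host-then-parasitoid
direction is part of the case-1 definition. A pair's representative lag is
the modal case-1 lag, ties towards the smallest -- the most conservative
single number to report. `screen_pairs()` orders output by match count,
then representative lag, then ids, making reruns byte-stable.

## Constrained ordination

`cca_fit()` implements canonical correspondence analysis in its classical
chi-square form: the count table becomes the matrix of standardized
chi-square residuals `q = (p - r c')/sqrt(r c')`, `q` is projected
row-weighted onto the constraint space, and the projection is decomposed by
SVD. Total inertia is `sum(q^2)` and splits exactly (Pythagoras) into
constrained and residual parts, which the package checks to 1e-8 on every
fit in its tests. Collinear constraints are dropped via pivoted QR and
reported as aliased. The community matrix may be counts or per-sample
relative abundances: the chi-square standardization divides by row
margins, so per-sample total rescaling does not change the decomposition.

Significance uses an ANOVA-like permutation test on the pseudo-F
statistic `(constrained/q)/(residual/(n-q-1))`, permuting rows of the
constraint matrix; the p-value is `(1 + #{F_perm >= F_obs})/(1 + n_perm)`.
The default scheme permutes rows freely; for strongly autocorrelated
series a block scheme would be more conservative, and the permutation
core is isolated so one can be added without touching the fit.

Forward selection is significance-then-criterion: every unselected
variable is tested marginally (its rows permuted on top of the current
model), and among those with `p < 0.05` the one minimizing a deviance-style
criterion `n*log(residual_inertia/n) + 2*(q_df + 1)` enters. "AIC" has no
canonical definition for ordination; this form behaves like one -- monotone
in residual inertia at fixed model size, charging 2 per constraint
dimension -- and is pluggable should a different criterion be preferred.
Categorical variables travel as blocks (season as three indicators with
Winter as reference; tide as one indicator) and enter or stay out as a
unit. Samples with any missing candidate value are dropped first
(complete-case analysis) and the dropped count is reported, so a 280-sample
record with seven incomplete dates enters the model with 273 samples.
Every evaluation is recorded in a trace sufficient to replay each decision,
and the permutation stream is derived deterministically from one seed.

## The synthetic generator

`scenario_config()` describes a study: a sampling calendar built from
phases (work-daily, twice-weekly Mon+Thu, thrice-weekly Mon/Wed/Fri, daily,
or explicit irregular dates; the default emulates a three-year coastal
survey with a work-daily spring, six irregular summer dates, and
twice-weekly sampling with an intensified early-summer window), a seasonal
log-normal background community, recurrently blooming hosts (flat baseline
plus Gaussian bumps), persistent Syndiniales-like parasitoids, and planted
pairs in which the parasitoid tracks `baseline + beta * host(day - lag)`.
The coupling is phenomenological by design: the screening targets lagged
and simultaneous peak signatures, not mechanistic Lotka-Volterra
parameters, so delayed proportional coupling is the simplest process that
produces exactly the signal under test. Latent abundances are observed
through fixed-depth multinomial sampling (70,000 reads per sample by
default, the order of a ~21M-read, ~300-sample survey), which reproduces
the compositional, counting-noise character of metabarcoding data. All
randomness flows from a single seed; identical configurations are bitwise
reproducible.

What the generator does *not* emulate: sequence-level artefacts (chimeras,
clustering noise, copy-number variation), species interactions beyond the
planted pairs, immigration events, or realistic noise magnitudes -- the
default log-scale noise sd of 0.3 is chosen for testability, not estimated
from nature. Passing benchmarks therefore demonstrates that the screening
recovers planted signatures under its own observation model, not that real
communities are this well behaved.

`planted_benchmark_scenario()` fixes the closed-loop benchmark: one year of
daily sampling at depth 50,000 with three hosts blooming three times each
and planted lags of 7, 12 and 0 days. Bloom events are staggered about 38
days apart -- beyond the matching window plus the longest lag -- so no
event of one pair can interact with another pair's blooms, either through
peak matching or through the shared compositional denominator; bloom bumps
are narrow (sd 2 days) so the multinomial counting noise cannot displace an
observed peak date. With latent noise off, the pipeline recovers every
planted label and lag exactly; with noise on, recovery is judged by whether
the planted signature appears among a pair's labels, since day-level jitter
can legitimately add a case-1 label to a simultaneous pair.

The companion environmental table carries a temperature sinusoid within
1.9-19.9 degC, salinity within 29.0-34.2, winter-high nutrients, a spring
chlorophyll bloom, sunshine hours and a tide category. In the study-style
missing pattern, seven sampling dates are incomplete: phosphate on four,
silicate and nitrate on one each, and temperature together with salinity
on one.

## Numerical choices

* `ceiling(fraction * total)` subtracts a 1e-9 slack first so products that
  are mathematically integral do not round up through floating point.
* Percentages round half-away-from-zero (base `round()` is half-to-even),
  matching how survey fractions are conventionally printed.
* Peak plateaus resolve to their first sample; series endpoints are not
  peak-eligible by default.
* Zero-denominator samples in relative abundance become `NA` with a
  warning and are skipped by the peak detector, never silently zeroed.
* A saturated ordination model (zero residual inertia) yields a degenerate
  criterion of `-Inf` with a warning; constrained axes with eigenvalues at
  numerical zero are dropped.
* Modal-lag ties break towards the smallest lag; pair tables sort by match
  count, representative lag, then ids.

## Problem sizes used in the checks

The package's own verification runs at deliberately compact sizes: peak
detection is compared against a brute-force scan over every series of
length up to 8 with values in {0,1,2,3}; inertia conservation is checked on
100 random tables and eigenvalues against a dense eigen-oracle on 8x6
tables; permutation calibration uses 200 replicates of 199 permutations on
30x20 tables; driver recovery uses 20 seeded runs of 50 samples by 25 taxa
with one planted temperature response among five noise covariates; and the
planted-pair benchmarks use the one-year daily scenario described above,
with 50 seeds for the noisy arm. These sizes were chosen so the full suite
exercises every claim in minutes while the statistical checks retain
useful power.

## Known limitations

* Co-occurrence is not causation: the screen proposes candidate pairs; it
  cannot exclude shared seasonal drivers, and it does not attempt
  cross-correlation or information-theoretic association measures.
* Lags are only representable up to the sampling resolution; twice-weekly
  calendars can only express lags that connect sampled dates.
* The permutation test treats samples as exchangeable; temporal
  autocorrelation makes it anti-conservative on strongly trended series.
* The trophic annotation is only as good as the rule table; prefix rules
  can over-match if patterns are chosen carelessly.
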