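---
title: "Models and methods behind nitroniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nitroniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroniche)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
generators do and do not emulate, and the numerical choices made where the
design was genuinely open. No empirical claim is made here that the test
suite does not itself compute.

## 1. Tracer kinetics

### Model

A ¹⁵N incubation adds labeled substrate (ammonium or urea) to seawater and
follows the appearance of ¹⁵N-nitrite over a handful of time points
(typically 0, 3, 6, 12, 24 h). Assuming the oxidation rate is constant over
the incubation and the labeling fraction of the substrate pool does not
change appreciably (short incubations, tracer in excess of turnover), the
¹⁵N-product concentration is linear in time:

$$ y(t) = y_0 + r \cdot f \cdot t + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma^2), $$

where $r$ is the gross oxidation rate (nM-N d⁻¹) and
$f = \mathrm{added} \times \mathrm{purity} / (\mathrm{ambient} +
\mathrm{added})$ is the ¹⁵N fraction of the substrate pool after tracer
addition. `fit_slope()` estimates $b = r f$ by OLS over all time points and
tests $H_1: b > 0$ one-sided with $n - 2$ degrees of freedom;
`correct_rate()` divides by $f$. Significance requires $p < 0.05$ *and* a
positive slope.

### Detection limit

The LOD is the minimum slope distinguishable from zero for the given time
design and measurement noise:

$$ \mathrm{LOD} = \frac{t_{1-\alpha,\,n-2}\ \sigma}
   {\sqrt{\sum_i (t_i - \bar t)^2}} \cdot \frac{24}{f}. $$

This is the standard minimum-detectable-slope construction; the exact
published formula for this quantity was not available, so the form above
is the package's definition, and published per-region LODs can be supplied
as overrides (`inst/extdata/published_rate_lods.tsv`). The noise SD
defaults to the pooled residual SD of all bottles in a batch
(`estimate_rates()`), matching the practice of reporting one LOD per
region and treatment; single-bottle residual SDs (3 df) are far too noisy
to set detection limits from.

### Censoring and reconciliation

Two field designs are supported and selected per region by configuration,
never inferred: single bottles with non-significant slopes censored to the
LOD (for rate-profile plotting) or to zero; and duplicate bottles
reconciled as *both significant → mean of rates; exactly one → mean of the
significant rate and the other's LOD; neither → zero*. The reconciled rate
is non-decreasing in each replicate's rate (a property test enforces
this), and `percent_urea_oxidation()` is undefined (reported missing) when
both rates are zero.

### Numerical choices

* Time is hours on input; rates and LODs are reported in nM-N d⁻¹.
* An exactly constant series returns slope 0 with $p = 0.5$: zero residual
  variance carries no evidence in either direction.
* In urea + unlabeled-ammonium incubations, ¹⁵N-ammonium is recovered by
  subtracting the separately measured ¹⁵N-nitrite from the combined
  measurement; negative differences are unphysical and are clipped to zero
  *with a flag*, preserving auditability.

## 2. Synthetic incubations

`gen_incubation()` draws $y(t) = r f t / 24 + \varepsilon$ with
$y_0 = 0$. Two things deserve emphasis:

* **Truncation happens at write time.** Isotope-excess measurements near
  the detection limit legitimately scatter below zero, and the in-memory
  series keep those raw values. Clipping before regression would bias null
  slopes: measured over 2000 null replicates, fitting clipped series
  inflates the one-sided type-I error from 0.05 to ≈ 0.11. Written
  concentration tables (`incubation_table()`) are truncated at zero with a
  `truncated` flag column, because a reported concentration cannot be
  negative.
* **Streams are independent.** Every generator seeds its own RNG stream
  from (seed, stream-name) and restores the caller's RNG state, so adding
  one generator to a workflow never changes another's draws, and identical
  scenarios are byte-identical.

Defaults describe a realistic oligotrophic experiment: tracer addition
500 nM-N at 98 % purity into ~50 nM-N ambient substrate (labeling fraction
> 0.9, matching the > 90 at% design aim of shipboard work), measurement
noise 0.05 nM-N, five time points over 24 h. The noise magnitude for
¹⁵N-nitrite is not a published constant, so it is an exposed scenario
parameter, not a hard-coded value.

The generator does *not* emulate instrument drift, abiotic urea
hydrolysis beyond a configurable linear leak term, tracer equilibration,
or bottle effects. A green recovery test therefore establishes that the
estimator chain is unbiased under the stated noise model — not that any
particular field dataset is reproduced.

## 3. Single-cell stable-isotope probing

A NanoSIMS region of interest accumulates ¹²C¹⁴N⁻ and ¹²C¹⁵N⁻ counts over
20–30 planes. The ratio $R = \Sigma^{15}N / (\Sigma^{14}N + \Sigma^{15}N)$
is computed from plane-summed counts, so it is exactly invariant to how
counts are partitioned across planes. Three QC gates precede any summary:

* **Counting error** $\sqrt{1/\Sigma^{15}N + 1/\Sigma^{14}N} < 5\,\%$.
  This is interpreted as the error of the plane-accumulated ratio: at
  1 ms dwell times individual planes would almost never pass a 5 % gate,
  so a per-plane reading would discard nearly everything. The threshold is
  a parameter.
* **Background window**: the session's unlabeled cells must average into
  $[3.4, 4.0] \times 10^{-3}$, a closed interval at both ends (the
  boundary value 4.0 × 10⁻³ passes).
* **Detection limit**: background mean + $k$ SD with $k = 3$ by default;
  published per-(group, treatment) LODs can be supplied as an override
  table (`inst/extdata/published_sip_lods.tsv`).

Enrichment is expressed as atom-percent excess,
$\mathrm{APE} = 100 (R - 3.7 \times 10^{-3})$; negative APE is retained
and flagged rather than clipped, so population summaries are not biased
upward. The N-based growth rate uses linear isotope incorporation,

$$ \mu = \frac{\mathrm{APE}_{\mathrm{cell}}}
   {\mathrm{APE}_{\mathrm{substrate}}} \cdot \frac{1}{t}, $$

with an exponential alternative $-\ln(1 - f_{\mathrm{new}})/t$ behind a
context switch; at the enrichments seen in day-scale incubations the two
differ by ~1.5 %. Published group means computed from these quantities are
slightly above the plain linear arithmetic (0.04 vs ≈ 0.031 d⁻¹ at 3.0 at%
and 97 at% labeling), suggesting an averaging-order or weighting
convention that was not printed; the package does not force agreement and
instead reports *both* the mean of per-cell rates and the rate of the mean
APE in `summarize_group()`. The two coincide for the linear model when no
cell is clipped at zero. No isotope-dilution correction for CARD-FISH is
applied, so enrichment estimates are conservative. Summaries are always
computed from full cell tables, never from plotted subsets.

The ion-count generator draws the per-plane total as Poisson and splits
¹⁵N as Binomial(total, true ratio) — the counting statistics of a SIMS
detector. It does not simulate pixels, dead time, or image alignment;
those belong to acquisition software.

## 4. Gene quantification

Reads pre-screened against a custom marker-gene database are accepted as
true positives iff bitscore ≥ 100, percent identity ≥ 90, and BLAST score
ratio (best custom score / best global score) ≥ 0.9. The BSR's role is to
discard reads that match the global protein space much better than the
marker database while *keeping* divergent sequences that match nothing
well — hence the design decision that a read with **no** global hit passes
the BSR criterion (there is no evidence it belongs elsewhere) and stands
or falls on score and identity alone. A strict mode that rejects such
reads is available. Best hits break score ties by higher identity, then
lexicographically smallest subject id, making classification invariant to
input row order.

Lineage fractions within an accepted family use a second BSR pass in which
the subset database plays the custom role and the full custom database the
global role. Abundances are RPKM,
$c / ((L/10^3)(N/10^6))$, with each accepted read assigned once to its
best subject (no multi-mapping fractions); whether $N$ counts read pairs
or individual reads is a labeled convention, not a hidden default. Group
gene ratios divide summed group RPKM of a family by the summed RPKM of the
single-copy marker *amoA*: a *ureC*:*amoA* ratio near 1 means essentially
the whole population encodes urease.

Probe coverage asks whether each group reference sequence contains the
probe's reverse complement as an exact, case-insensitive substring;
degenerate bases are not expanded. Because the ambiguity
"read-weighted vs sequence-weighted coverage" cannot be resolved from the
available description, `probe_coverage()` takes optional per-reference
weights: uniform weights give the sequence-weighted figure, read counts
give the read-weighted one.

## 5. Comparative statistics

The rank-sum statistic is the rank-sum-minus-minimum form
$W = \sum \mathrm{rank}(x) - n_1(n_1+1)/2 \in [0, n_1 n_2]$, matching the
convention of small printed statistics (e.g. W = 14 at $n \le 10$). The
p value is exact — null distribution by the classic count recursion,
equivalent to full enumeration of all $\binom{n_1+n_2}{n_1}$ labelings —
when there are no ties and $n_1 + n_2 \le 20$; otherwise a normal
approximation with tie correction and continuity correction is used. This
reproduces the defaults of the standard statistical environment, and the
test suite verifies agreement with `stats::wilcox.test` on both branches
as well as against brute-force enumeration.

Urea-N fractions substitute below-detection values with the analytical
LOD by default (conservative: it biases the fraction *downward* when
ammonium is the undetected analyte); LOD/2 and zero are selectable, and a
fraction with both analytes below detection is reported missing. All
quantiles use the linear-interpolation (type 7) definition; boxplot
summaries support both whisker conventions in circulation — 10th–90th
percentile whiskers and Tukey 1.5 × IQR whiskers — because published
figure panels use one or the other, and summaries must be comparable to
either.

## 6. Pipeline and provenance

`run_pipeline()` chains simulate → rates → SIP → genes → stats on a
validated YAML configuration. Unknown configuration keys are rejected by
name (a typo cannot silently become a default); all randomness flows from
the single config seed through named streams; outputs are built in memory
and written only after every stage succeeds, so partial outputs are never
left behind; and every derived table carries `stage` and `config_hash`
provenance columns. The hash deliberately excludes output paths: the same
analysis hashes identically wherever it lands. Depth cutoffs, censoring
policies and labeling purities are configuration, never hard-coded.

## 7. Known limitations

* The rate LOD and NanoSIMS LOD constructions are the package's own
  (standard) definitions of quantities whose published formulas were not
  available; override tables reproduce published values where needed.
* The synthetic world is deliberately simple (linear kinetics, Gaussian
  measurement noise, log-normal nutrients, Gaussian score distributions);
  green tests validate the estimators under that world, not the field
  data.
* Growth rates inherit every assumption of the linear incorporation model
  (no isotope dilution, constant labeling, balanced growth).
* No multiple-testing correction is applied anywhere; raw p values are
  reported.
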