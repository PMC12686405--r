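# nitroniche

Tools for quantifying how marine ammonia-oxidizing archaea (AOA) partition
their nitrogen sources. Nitrification — the oxidation of ammonia to nitrite
and on to nitrate — is dominated in the ocean by two AOA genera,
*Nitrosopumilus* (coastal) and *Nitrosopelagicus* (open ocean), and field
evidence indicates that urea becomes an increasingly important substrate
where ammonium is scarce. Resolving who uses which substrate requires
combining several very different measurements, and this package implements
the complete analysis chain for that comparison:

* **`tracer_kinetics`** — ammonia and urea oxidation rates from ¹⁵N
  dual-tracer incubations. For a bottle sampled at times *t* (hours), the
  raw quantity is the OLS slope *b* of ¹⁵N-nitrite vs. time, tested
  one-sided against zero (*t* distribution, *n* − 2 df). The gross rate is
  *r* = *b* / *f*, where *f* = added × purity / (ambient + added) is the
  ¹⁵N labeling fraction of the substrate pool. The detection limit is the
  minimum detectable slope, t₁₋α,ₙ₋₂ · σ / √Σ(tᵢ − t̄)², per day, divided
  by *f*. Non-significant rates are censored to the LOD or zero, and
  duplicate bottles are reconciled (both significant → mean; one → mean
  with the other's LOD; none → zero).
* **`single_cell_sip`** — single-cell ¹⁵N assimilation from NanoSIMS ion
  counts: the accumulated ratio R = Σ¹⁵N / (Σ¹⁴N + Σ¹⁵N) over all
  acquisition planes, its Poisson counting error √(1/Σ¹⁵N + 1/Σ¹⁴N) (<5 %
  to pass QC), background-window QC ([3.4, 4.0] × 10⁻³), detection limits
  (background mean + 3 SD), atom-percent excess APE = 100 (R − 3.7 × 10⁻³),
  and N-based growth rates μ = APE_cell / APE_substrate / t.
* **`gene_quantification`** — BLAST-score-ratio (BSR) read classification
  against custom marker-gene databases (accept iff bitscore ≥ 100, identity
  ≥ 90 %, and custom/global score ratio ≥ 0.9), RPKM gene abundances,
  *ureC*:*amoA* and *dur3*:*amoA* group ratios, and exact
  reverse-complement probe-coverage scoring for CARD-FISH probe design.
* **`niche_stats`** — urea-N fractions with below-detection policies,
  exact/approximate two-sided Mann–Whitney–Wilcoxon tests, means ± s.e.
  and boxplot summaries under both common whisker conventions.
* **`synthetic_data`** — seeded generators for every input (incubation
  time series, ROI ion counts, hit tables, nutrient profiles) with ground
  truth attached, so the entire chain is testable offline.
* **`pipeline_io`** — TSV/FASTA/BLAST-tabular readers with schema
  validation, YAML run configuration, and `run_pipeline()` /
  `pipeline_cli()` orchestration.

## Worked example

Duplicate ¹⁵N-urea bottles near the detection limit, reconciled
Angola-Gyre style:

```r
library(nitroniche)

sc <- incubation_scenario(true_rate = 0.8, ambient = 11, tracer_added = 500,
                          tracer_purity = 0.98, noise_sd = 0.05,
                          timepoints = c(0, 3, 6, 12, 24),
                          n_replicates = 2, seed = 42)
bottles <- gen_incubation(sc, treatment = "UREA_15N")
ests <- lapply(bottles, estimate_rate, noise_sd = 0.05)
reconcile_duplicates(ests[[1]], ests[[2]])
#> <rate_estimate> UREA_15N: rate 0.7899 nM-N/d (slope 0.7437, p1 = 0.000305, LOD 0.155)
```

Both slopes are individually significant (p₁ ≈ 3 × 10⁻⁴ ≪ 0.05), so the
reconciled rate is the mean of the two labeling-corrected rates
(0.7755 and 0.8042 nM-N d⁻¹ → 0.79 nM-N d⁻¹, close to the true simulated
0.8). Against an ammonia oxidation rate of 1.5 nM-N d⁻¹ this gives

```r
percent_urea_oxidation(0.7899, 1.5)
#> [1] 34.5   # percent of total nitrification fueled by urea
```

One NanoSIMS cell (30 planes, ~1.5 × 10⁶ total ion counts):

```r
ctx <- sip_context(substrate_at_percent = 97, incubation_time_days = 1)
cell_enrichment(roi_ion_counts("roi_001", "Nitrosopumilus", "NH4_15N",
                               rep(48000, 30), rep(1680, 30)),
                ctx, background_ratios = c(3.65e-3, 3.72e-3, 3.70e-3, 3.68e-3))
#> <cell_enrichment> roi_001 (Nitrosopumilus, NH4_15N): ratio 0.03382, APE 3.01 at%, mu 0.0312/d
```

The ratio 0.0338 sits far above natural abundance (3.7 × 10⁻³), giving
3.0 at% excess — a cell that built ~3 % of its nitrogen from the labeled
ammonium in one day (μ ≈ 0.031 d⁻¹). And a small exact rank-sum test:

```r
mann_whitney(c(0.9, 1.4, 2.1, 0.7), c(0.1, 0.3, 0.2, 0.05))
#> <rank_test> W = 16, p = 0.02857 (two.sided, exact; n = 4, 4)
```

The full synthetic chain (five output tables plus a JSON run report):

```r
run_pipeline(run_config(list(seed = 1, output_dir = "out")))
```

or from the shell: `exec/nitroniche report --out out`.

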