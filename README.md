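# gcoutput

Germinal-center output analytics for vaccinated cohorts.

Immunosuppressed patients — e.g. people with inflammatory bowel disease on
anti-TNF biologics — can mount quantitatively weaker germinal-center (GC)
responses to vaccination. The GC reaction leaves measurable fingerprints:
somatic hypermutation (SHM) accumulated in B-cell-receptor (BCR) variable
regions, class-switched memory B cell (MBC) subsets, clonal expansion, and
the avidity of circulating antibody. `gcoutput` packages the quantitative
pipeline needed to read those fingerprints from single-cell BCR
repertoires and serology plates, for immunologists comparing treatment
groups across vaccine doses.

## What it computes

- **QC / demultiplexing** — cell filtering (exclude if mitochondrial % > 10,
  features < 200 or > 6500; boundary values retained) and hashtag
  demultiplexing by centered log-ratio (CLR) normalization with a
  max-margin rule: assign the argmax hashtag iff
  `max(y) − secondmax(y) ≥ 2.0`, where `y_h = ln(x_h+1) − mean_h ln(x_h+1)`.
- **Clonal assignment** — partition heavy chains by V gene, J gene and
  junction (CDR3) length, then single-linkage clustering on normalized
  Hamming distance between junctions, cut at 0.15 (configurable).
- **SHM profiling** — per cell and region (FWR1…CDR3), replacement/silent
  mutation counts with frequency = mutations / comparable positions.
- **Diversity** — Hill numbers `D(q) = (Σ p_i^q)^{1/(1−q)}`, with
  `D(1) = exp(−Σ p_i ln p_i)`, over q ∈ [0, 4] with bootstrap bands.
- **Subset proportions** — permutation test of per-cluster
  `log2FD = log2(prop_b/prop_a)` with bootstrap CIs; significant iff
  FDR < 0.05 and |log2FD| > 0.58.
- **Serology** — 4-parameter-logistic EC50 (half-way between blank and a
  sample's top) and chaotrope-displacement avidity: RAI(c) = 100·m(c)/m(0),
  fractional RAI per elution category (very low / low / medium / high),
  and TRAI = RAI(0.5) + RAI(1) + RAI(2) in avidity units (AU; range 0–300).
- **Association** — covariate-adjusted OLS (optionally with a
  timepoint×group interaction and cluster-robust SEs), Kruskal–Wallis with
  Dunn's post-hoc tests, paired Wilcoxon.
- **Synthetic cohorts** — generators with known ground truth (subset
  proportions, SHM rates, clone-size law, isotypes, TRAI trajectories, HTO
  matrices) for parameter-recovery testing.

## Worked example

```r
library(gcoutput)

cc  <- cohort_config(seed = 42)              # 3 healthy / 4 anti-IL-12/23 / 5 anti-TNF
rc  <- repertoire_config(cells_per_subject = 40)
rec <- gen_repertoire(cc, rc)
heavy <- rec[rec$chain == "heavy", ]

prof <- shm_profiles(heavy)
round(tapply(prof$mu_freq, prof$group, mean), 4)
#> anti-IL-12/23      anti-TNF       healthy
#>        0.0465        0.0249        0.0455
```

The generator's stated world (SHM rate 0.045 for controls vs 0.025 under
anti-TNF) is recovered from the sequences themselves. Clonality and
diversity:

```r
cl <- assign_clones(heavy)
hill_diversity(table(cl$clones$clone_id), c(0, 1, 2))
#> [1] 679.0 556.9 404.9     # richness, exp-Shannon, inverse-Simpson
```

Avidity rises with dose and carries the configured 40 AU anti-TNF deficit:

```r
ser <- gen_serology_cohort(cc, serology_config())
av  <- score_avidity_table(ser$chaotrope)
round(tapply(av$trai, list(av$group, av$dose), mean), 1)
#>                   1     2     3     4
#> anti-IL-12/23 126.1 168.3 210.4 274.3
#> anti-TNF       85.0 129.2 179.7 222.0
#> healthy       124.9 171.0 208.4 254.7
```

And the SHM→avidity association is positive and significant, as the
generative model implies:

```r
fit <- ols_fit(subject_summary(prof, av), "trai", c("mean_shm", "dose"),
               cluster = "subject")
fit$coefficients
#>          term estimate std_error t_value  p_value
#> 1 (Intercept)     -6.6      4.20   -1.57 1.44e-01
#> 2    mean_shm   1821.2     80.74   22.56 1.46e-10
#> 3        dose     46.1      1.13   40.84 2.31e-13
```

A TRAI gain of ~18 AU per 0.01 SHM frequency, and ~46 AU per dose,
matching the configured trajectory (increment 45 AU/dose).

The whole pipeline (simulate → qc → repertoire → proportions → serology →
association) runs from one YAML config:

```r
run_pipeline("config.yaml", out_dir = "results/")
```

or from the CLI front-end:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gcoutput.R", package="gcoutput"))')" \
    run-all --config config.yaml --out results/
```

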