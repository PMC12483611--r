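---
title: "Methods and design notes for gcoutput"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gcoutput}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcoutput)
```

# Scope

`gcoutput` quantifies germinal-center (GC) outputs in vaccinated cohorts:
somatic hypermutation (SHM) in B-cell receptors, clonal structure and
diversity of memory B cells (MBCs), MBC subset composition, and the
avidity of circulating antibody measured by chaotrope-displacement ELISA.
It does not perform read alignment, transcriptome clustering or embedding,
germline inference, or lineage-tree reconstruction; annotated AIRR-style
records and tidy plate tables are its inputs, and a synthetic-cohort
generator stands in for real data in all tests.

# QC and hashtag demultiplexing

Cells are excluded when mitochondrial percentage exceeds 10, or unique
features fall below 200 or above 6500. The rules are strict inequalities,
so a cell at exactly 10.0% or exactly 6500 features is retained; the
exclusion tally attributes a dropped cell to every rule it violates.

Hashtag (HTO) counts are normalized per cell by centered log-ratio:
$y_h = \ln(x_h + 1) - \overline{\ln(x + 1)}$. A cell is assigned its
argmax hashtag iff the margin between the top two CLR values is at least
2.0, else excluded. Two conventions are not fixed by the protocol this rule follows and are
therefore explicit, configurable choices here: the CLR
pseudo-count is +1 with natural log, and the margin is evaluated on the
CLR scale (the margin rule is stated after the normalization step, so the
normalized scale is the natural reading). Exact ties give margin 0 and
are excluded; an all-zero row is excluded with reason `"no signal"`.

# Clonal assignment

Clones are defined as cells sharing heavy-chain V gene, J gene (both at
gene level, alleles stripped; IGHV1-69 and IGHV1-69D remain distinct) and
junction length, refined by single-linkage hierarchical clustering on the
normalized Hamming distance between junctions. The cut height defaults to
0.15, a conventional clonal cutoff for junction-based clustering; no
published threshold was available to anchor it, so it is exposed as
`distance_threshold`. Determinism: records are processed in lexicographic
`sequence_id` order and clones are numbered by their earliest member, so
clone ids are invariant to input order. The implementation is checked
against a brute-force all-pairs union-find oracle on random instances.

# SHM profiling

For an aligned observed/germline pair, every position where both carry an
unambiguous A/C/G/T base is *comparable*; the SHM frequency is the number
of differing comparable positions over the number of comparable positions.
Two ambiguities in the usual "mutations over total positions" phrasing are
resolved as follows and are configurable:

- **Denominator.** All comparable positions of the aligned V region
  *including* CDR3/junction are counted. Excluding CDR3 is available by
  passing a trimmed region layout.
- **R/S context.** A mutation is Replacement if translating the observed
  codon — with the *germline* bases at the other two codon positions —
  changes the amino acid, else Silent. Germline context is deterministic
  and order-independent when several mutations share a codon;
  observed-context is available via `context = "observed"`.
- **Untranslatable codons.** If the codon context contains a gap or N the
  mutation still counts (preserving the invariant that R + S equals the
  total mismatch count) and is classified Silent by convention. Synthetic
  data never reaches this branch; IMGT-gapped real data could.

Light chains are profiled identically and reported separately.

# Diversity

Hill numbers over clone proportions $p_i$:
$D(q) = (\sum_i p_i^q)^{1/(1-q)}$ for $q \ne 1$ and
$D(1) = \exp(-\sum_i p_i \ln p_i)$. The standard Hill convention is used
(q = 0 richness, q = 1 exponential Shannon, q = 2 inverse Simpson); some
published figure legends label these one order higher, which we read as
an off-by-one and do not reproduce. Confidence bands are
percentile intervals over 200 bootstrap resamples of cells. Bootstrap
resampling can only lose rare clones, so the band is biased low — at
q = 0 the upper band edge sits at or below the observed richness. This is
a documented property of the naive bootstrap for richness-like statistics,
not a defect; the band should be read as sampling variability, not as a
bias-corrected interval.

# Subset-proportion permutation test

For clusters (MBC subsets) and two groups a, b, the statistic per cluster
is $\mathrm{log2FD} = \log_2(\mathrm{prop}_b / \mathrm{prop}_a)$ on
pooled-cell proportions. The null distribution permutes group labels over
the pooled cells preserving group sizes (default 1000 permutations), with
the add-one correction $p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\})/(1 + n)$
so p is never 0. CIs bootstrap cells within group. Significance uses the
dual rule FDR < 0.05 (Benjamini–Hochberg across clusters, per comparison
pair) and |log2FD| > 0.58 (≈ 1.5-fold). A cluster with zero cells in one
group would give an infinite log2FD; it receives a pseudo-proportion of
$1/(2n_{\mathrm{group}})$ and is flagged `zero_substituted`. Per-subject
weighted proportions are a documented alternative; pooled proportions are
the default because the permutation scheme exchanges cells.

The companion DEG rule gates on adjusted p < 0.05 *and* log2FC > 0.6
(one-sided, as stated), with log2FC computed from mean expression with a
pseudo-count of 1.

# Serology

**EC50.** The dilution series is fit by a 4-parameter logistic in which
the lower asymptote is anchored at the blank mean:
$\mathrm{OD}(d) = b + (t - b) / (1 + (\mathrm{EC50}/d)^h)$, so the EC50 is
by construction the concentration halfway between blank and top, and is
invariant to rescaling all readouts. `nls` (port, bounded) does the
fitting with a Nelder–Mead fallback; flat series return status
`"no_signal"` rather than a number. Protocols for this assay often use `nlsLM`; that package is not a
dependency here and the bounded port algorithm recovers noiseless truth
to better than 1%.

**Avidity.** With replicate-mean ODs $m(0), m(0.5), m(1), m(2)$ across
ammonium thiocyanate concentrations, after a running-minimum monotonicity
repair (replicate noise can otherwise create negative category
fractions):

- $\mathrm{RAI}(c) = 100\, m(c)/m(0)$ (%),
- fractional RAI: very low $= 100(m(0)-m(0.5))/m(0)$, low
  $= 100(m(0.5)-m(1))/m(0)$, medium $= 100(m(1)-m(2))/m(0)$, high
  $= 100\, m(2)/m(0)$; the four categories sum to 100,
- $\mathrm{TRAI} = \mathrm{RAI}(0.5)+\mathrm{RAI}(1)+\mathrm{RAI}(2)$ (AU),
  identically $3\cdot\mathrm{high} + 2\cdot\mathrm{medium} +
  1\cdot\mathrm{low}$.

Published descriptions of this assay family leave the exact TRAI formula
to supplementary material that is not always available; the sum-of-RAIs
definition is adopted as
the package's convention because it yields the printed unit (AU, range
0–300 for three nonzero concentrations), matches the "total relative
avidity index" naming, and is a monotone weighted sum of the category
fractions. Which dilution of a multi-point avidity plate is scored is also
unstated; the generator scores a single effective dilution per sample, and
`score_avidity` accepts any single-dilution triplicate table.

# Association models

Cross-sectional comparisons use Kruskal–Wallis with Dunn's post-hoc
pairwise z statistics (tie-corrected; Bonferroni adjustment by default —
reports of "Dunn's multiple comparisons tests" rarely name the
adjustment, so the most conservative standard choice is the default). Paired timepoints use the two-sided Wilcoxon signed-rank test.
All-tied input returns p = 1 with a warning rather than an error.

The longitudinal model is reproduced as pooled OLS with a
timepoint×group interaction and CR1 cluster-robust standard errors by
subject. The targeted analysis specifies the mean structure — covariates age,
sex, BMI, vaccine type, interaction term — but not the covariance family
(GEE vs mixed); pooled OLS with cluster-robust inference honours that
mean structure without inventing a random-effects specification.

# The synthetic world

The generator's defaults describe a small vaccinated-cohort design: groups healthy /
anti-IL-12/23 / anti-TNF with 3/4/5 subjects, two timepoints (post-dose-2,
post-dose-3). Values that are not pinned down by published numbers are fixed once at
plausible field values and documented here:

- **SHM rates** 0.045 (controls) vs 0.025 (anti-TNF) per position —
  chosen effect sizes for power testing, not published numbers; real
  post-vaccination MBC heavy chains typically carry a few percent SHM.
- **Subset proportions** favour classical MBCs in controls (0.65/0.25/0.10
  over cMBC/MZ-like/aMBC) with a reduced classical share under anti-TNF
  (0.40/0.45/0.15), mirroring the qualitative shift reported for this treatment class.
- **Isotypes** are switched-dominant in cMBCs and IgM-dominant in MZ-like
  cells.
- **Clone sizes** follow a discrete power law $P(s) \propto s^{-2.5}$
  truncated at 10 cells, with the largest bin reported as 5 < n ≤ 10.
- **Mutations** are i.i.d. uniform substitutions; no indels, no hotspot
  or targeting (S5F-like) models, one heavy + one light chain per cell.
  The germline is a fixed, packaged 300-nt synthetic sequence with an
  IMGT-like region layout on codon boundaries.
- **Serology**: true TRAI = 80 + 45·dose − 40·[anti-TNF], clamped to
  [0, 300]; retention fractions geometric in concentration rank; OD noise
  multiplicative lognormal (σ = 0.05); plate geometry follows the assay
  (triplicates; 7-point 3-fold avidity dilutions from 1:100; 10-point
  EC50 series spanning 1:5–1:327,680).
- **HTO matrices**: singlet dominant counts Poisson(200) over
  Poisson(3) background (≥ 20:1 in expectation); doublets carry a second
  comparable hashtag.

A green test on this world establishes that the estimators recover known
truth under idealized noise — i.i.d. substitutions, lognormal OD error,
well-separated hashtags. It does not establish robustness to mutational
hotspots, clonal phylogenetic structure, plate-position effects, ambient
RNA, or hashtag cross-talk, none of which are simulated.

# Numerical conventions

- Hill D(1) switches to the Shannon limit within |q − 1| < 1e−12; the
  formula agrees with the numerical q→1 limit to 1e−6 relative.
- Clone clustering ties are broken lexicographically by sequence id.
- The permutation p add-one correction bounds p at 1/(n_perm + 1).
- EC50 fitting bounds the Hill slope to (1e−3, 50) and log-EC50 to the
  data's dilution range ± 10 log units.
- Negative ODs are clipped to zero with a warning before avidity scoring.
- All generators take a mandatory integer seed; identical (config, seed)
  gives byte-identical outputs end to end.

# Known limitations

- The clonal threshold (0.15) is a convention, not estimated per dataset
  (no distance-to-nearest threshold detection).
- The avidity TRAI definition is a convention chosen here (see above); a
  different convention
  would shift absolute AU values but not group contrasts, which are the
  quantities the pipeline tests.
- The bootstrap diversity band is biased low for richness-like orders.
- Proportion tests treat cells as exchangeable; subject-level
  autocorrelation is addressed only by the optional per-subject weighting.
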