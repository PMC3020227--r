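---
title: "Methods: population structure and LD for inbred SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and LD for inbred SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelpopgen)
```

This vignette records the statistical model behind each analysis stage,
the default parameter choices and their rationale, and the properties of
the built-in simulator that the test suite relies on.

## Data model

A `genotype_panel` is a lines × loci matrix of biallelic calls coded
`0` / `2` for the two homozygotes, `1` for heterozygotes and `NA` for
missing, together with line metadata (`population`, `growth_habit`) and a
genetic map (`genome`, `chromosome`, `position_cM`). The panel is aimed at
collections of (mostly) inbred lines, so all frequency-based statistics
first recode heterozygotes to missing and treat each line as a single
haploid allele draw. Loci are kept sorted by genome, chromosome and map
position so window and distance computations can assume ordered input.

## Diversity

For a biallelic locus with allele frequencies $p$ and $1-p$,
the polymorphism information content is
$\mathrm{PIC} = 1 - p^2 - (1-p)^2$, which for biallelic loci equals the
expected heterozygosity. `diversity_table()` reports, per stratum
(population, growth-habit group, or the whole panel): the proportion of
polymorphic loci, mean observed allele number, mean minor allele frequency
(MAF) and mean PIC. Monomorphic loci stay in the denominator with MAF and
PIC zero; loci with no observed calls in a stratum are excluded; strata
below `min_lines` are dropped with a warning, since frequency estimates
from a handful of inbred lines are dominated by sampling noise.
MAF spectra are compared between groups with a Pearson chi-square test on
binned counts (`stats::chisq.test`, no continuity correction), dropping
bins empty in both groups.

## Differentiation

### Per-locus estimator

`wc_theta()` implements the Weir–Cockerham ANOVA estimator specialised to
haploid (inbred) data. With $r$ groups of sizes $n_i$, group frequencies
$p_i$, $N = \sum n_i$ and $\bar p = \sum n_i p_i / N$:

$$
\mathrm{MSP} = \frac{\sum_i n_i (p_i - \bar p)^2}{r - 1}, \qquad
\mathrm{MSG} = \frac{\sum_i n_i p_i (1 - p_i)}{\sum_i (n_i - 1)}, \qquad
n_c = \frac{N - \sum_i n_i^2 / N}{r - 1},
$$

$$
\hat\theta = \frac{\mathrm{MSP} - \mathrm{MSG}}
                  {\mathrm{MSP} + (n_c - 1)\,\mathrm{MSG}}.
$$

$\hat\theta$ is undefined (returned as `NA`) when the denominator is zero,
which includes every monomorphic locus. The estimator is validated in the
test suite against an independent route through `stats::aov` mean squares.

### Hierarchical variance components

`hierarchical_components()` fits the unbalanced two-level nested ANOVA
(groups / populations within groups / lines within populations) per locus,
sums components across loci, truncates negative sums at zero and reports
percentages among groups, among populations within groups, and within
populations.

### Window scan

The scan averages $\hat\theta$ over sliding windows of `W = 5`
consecutive defined-$\hat\theta$ loci per chromosome (step 1). The null
reference distribution is built by drawing `B = 1000` random sets of `W`
loci genome-wide, ignoring linkage, and taking the 95th percentile of the
set means as the threshold. Windows above the threshold are merged into
elevated regions. Because the null resamples loci independently, the
calibration of this threshold is exact only when per-locus
$\hat\theta$ values are approximately exchangeable; residual
founder-sharing correlation between neighbouring loci widens the window
distribution slightly, which is deliberate — the scan is a screen, not a
formal test.

## Linkage disequilibrium

Haplotype counts for a locus pair use only lines with homozygous calls at
both loci (inbred assumption). With $D = f_{11} - p_i p_j$:

* $r^2 = D^2 / \big(p_i(1-p_i)\,p_j(1-p_j)\big)$, equal to the squared
  Pearson correlation of the allele indicators;
* $D' = |D| / D_{\max}$, with a 90% likelihood-based confidence interval
  obtained by profiling the multinomial likelihood over a grid of $D'$
  values (default 1001 points) and taking the 5%/95% cumulative bounds;
* significance by a two-sided Fisher exact test computed from the
  hypergeometric distribution, summing all tables with probability
  $\le p_\mathrm{obs}(1 + 10^{-7})$ (the small tolerance absorbs
  floating-point ties); corrected across all tested pairs with
  Benjamini–Hochberg FDR at `q = 0.01`.

LD summaries report the mean/median map distance of significant
intra-chromosomal pairs, the proportion of loci with at least one
significant linked partner, the proportion of inter-chromosomal pairs that
are significant, and *background LD*, defined as the 95th percentile of
inter-chromosomal $r^2$.

`decay_curve()` fits a degree-1 loess of $r^2$ on map distance for linked
pairs and reports the distance at which the fitted curve falls to half of
its fitted value at the minimum observed distance, interpolated linearly
on the prediction grid; if the curve never halves within the observed
range the result is flagged `NOT_REACHED`. The loess span trades variance
against flattening bias near the origin: wide spans overestimate the
half-decay distance when the decay is fast relative to the span window.

`gabriel_blocks()` classifies pairs by the $D'$ confidence bounds (strong
LD: lower bound ≥ 0.70 and upper bound ≥ 0.98; strong recombination:
upper bound < 0.90), then accepts maximal runs whose outermost pair is
strong and in which at least 95% of informative pairs are strong, up to a
30 cM span, resolving overlaps by span, then locus count.

## Simulator

`simulate_panel()` generates panels with known truth in five seeded
stages (positions, frequencies, genotypes, noise, ascertainment), each
using a seed derived deterministically from the master seed (all derived
seeds < 2^31):

1. **Map** — loci placed uniformly at random on each chromosome.
2. **Frequencies** — ancestral frequencies $p \sim U(0.05, 0.95)$;
   population frequencies from the Balding–Nichols model,
   $p_k \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$
   with `fst_target` $= F$; optional *planted regions* add $\pm\delta/2$
   to the two growth-habit groups inside a map interval (clipped to
   $[0.02, 0.98]$), giving localized differentiation with recorded truth.
3. **Genotypes** — each population receives `n_founders` founder
   haplotypes drawn from its frequencies; each line is a founder mosaic
   built with Haldane's map function
   $r = \tfrac12\big(1 - e^{-2d/100}\big)$ and switch probability
   $1 - (1-r)^{g}$ after `generations` $= g$ meioses.
4. **Noise** — mutually exclusive heterozygous (`het_rate`, default
   0.5%) and missing (`missing_rate`, default 0.9%) calls.
5. **Ascertainment** — loci with pooled MAF strictly above
   `ascertain_maf_min` are kept; the truth table flags dropped loci.

### What the founder stage adds

The founder pool is itself a finite sample, so realized differentiation
exceeds the Balding–Nichols target by roughly $(1-F)/n_\mathrm{founders}$:
with the default `n_founders = 10` and $F = 0.10$, genome-wide mean
$\hat\theta$ comes out near 0.19. This is intentional — breeding
populations really do sit on narrow founder bases, and the extra drift is
what makes within-population LD realistic. Consequences used throughout
the tests and the acceptance script:

* estimator-recovery checks (is mean $\hat\theta \approx F$?) simulate
  with a large founder pool (`n_founders = 1000`) so the founder term is
  negligible;
* the scan's null-calibration check also uses a large pool, because the
  bootstrap threshold assumes approximately independent loci;
* power checks for planted regions use the defaults, where both the
  signal and realistic locus-locus correlation are present.

Within a single population, the defaults (`n_founders = 10`,
`generations = 5`) give an LD half-decay in the 5–10 cM range; pooling
many populations dilutes LD by roughly the product of founder and
population counts, so decay analyses are most informative within
populations or modest groupings.

The simulator models neither mutation, selection within populations, nor
ascertainment bias beyond the single MAF cutoff; spectra from it are
smoother than real panels.

## Numerical and reproducibility choices

* All output tables are written by a deterministic TSV writer (fixed
  15-significant-digit formatting, `\n` line endings, `#` comment headers
  carrying the seed and an MD5 hash of the configuration), so identical
  configurations give byte-identical files; `run_pipeline()` writes a
  manifest of MD5 checksums that the tests compare across runs.
* Every stochastic step takes its seed from a single user seed; no
  analysis consults the global RNG state except through seeded entry
  points.
* The $D'$ likelihood CI uses a 1001-point grid; refining to 10001 points
  moves the bounds by less than 0.01 on random tables (tested).

## A small worked example

```{r example}
cfg <- sim_config(
  populations_per_group = c(2, 2),
  lines_per_population = list(c(25, 25), c(25, 25)),
  chromosomes = default_chromosomes()[1:3, ],
  loci_per_chromosome = 40,
  seed = 7)
sim <- simulate_panel(cfg)
sim$panel

filtered <- filter_loci(sim$panel, maf_min = 0.05)
scan <- fst_scan(filtered, "growth_habit", analysis_config(seed = 7))
summary(scan)

ld <- ld_analysis(filtered, analysis_config(seed = 7))
ld$summary$background_ld
```
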