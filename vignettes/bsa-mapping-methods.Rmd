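---
title: "Pool-seq bulked segregant mapping in a ZW backcross: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq bulked segregant mapping in a ZW backcross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mapping problem

`bsapool` implements bulked segregant analysis (BSA) for a monogenic,
incompletely dominant insecticide-resistance trait in a female-heterogametic
(ZW) insect such as the beet armyworm. The design exploits two Lepidopteran
peculiarities:

* **Achiasmatic female meiosis.** Females transmit chromosomes intact, so all
  mapping recombination arises in males.
* **ZW sex determination.** Males are ZZ, females ZW, which shifts the
  expected segregation ratio on Z.

A resistant female (RR at the causal locus) is crossed to a susceptible male
(SS). An F1 **male** — heterozygous at every site where the strains differ —
is backcrossed to a susceptible female. Backcross larvae are exposed to a
diagnostic dose that kills SS homozygotes, so survivors are enriched for the
resistant allele at the causal locus and, through linkage, around it.
Survivors are pooled and sequenced together with the two backcross parents.

## The statistic

An **informative SNP** is heterozygous in the F1 male and homozygous in the
dam; the resistant-founder allele is then the F1 allele the dam does not
carry. In *unselected* backcross progeny its expected frequency over all
chromosome copies is

* 1/4 on autosomes (the dam always contributes the susceptible allele; the
  sire contributes the resistant one with probability 1/2), and
* 1/3 on Z (the sire's two Z copies are one resistant- and one
  susceptible-origin; the dam gives her susceptible Z to sons and her W to
  daughters, so Z copies number three per mating pair of offspring).

The per-SNP statistic is the absolute deviation of the pooled read-level
frequency from this expectation, `|p_obs − p_exp|`. Deviations are averaged
in 1 Mb windows advanced in 100 kb steps; windows with fewer than 80
informative SNPs are discarded as noise; Z-window means are multiplied by
0.75 — held as the *exact* ratio (1/4)/(1/3), with the commonly printed 0.33
treated as display rounding — so they are comparable with autosomes. Windows
at or above the top-1% threshold of the corrected deviation are merged into
candidate regions. Because correction is a scalar multiplication it commutes
with window averaging; per-SNP correction is therefore equivalent and both
orderings are tested.

Under complete enrichment (no SS survivors, full penetrance in RS) the pooled
frequency at the causal locus is exactly 1/2, giving a deviation plateau of
0.25 that decays with recombination distance at the male map rate.

## The simulator and what it emulates

The generator reproduces the genetic structure the analysis assumes, so every
downstream stage is testable without external data:

* fully inbred founder strains differing at dense marker sites (default one
  marker per 2 kb);
* male crossovers Poisson with mean equal to the genetic length in Morgans
  (Haldane's no-interference model; the source design states no interference
  model, and Poisson is the standard neutral choice), breakpoints uniform;
* females transmitting intact chromosomes and a Z or W with probability 1/2;
* a single-locus survival model, default SS = 0, RS = 0.8, RR = 1 at the
  diagnostic dose — with a 336-larva backcross this gives an expected
  survivor count of 336 × 1/2 × 0.8 ≈ 134;
* pooling of 120 survivors drawn uniformly without replacement (all of them,
  with a warning, if fewer survive), sequenced at mean 240x with parents at
  30x; reads sample chromosome copies uniformly (2 per individual on
  autosomes, 2 per male and 1 per female on Z) with a symmetric per-read
  allele-flip error of 0.001;
* VCF 4.2 output with GT:AD:DP for the parents and the pool, and INFO
  annotations QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum drawn from
  distributions that satisfy the hard filter, except for a configurable
  fraction of sites marked failing (QD = 1.0) to exercise the filter.

It deliberately does **not** model read alignment, mapping bias, linkage
disequilibrium within founders, multi-locus resistance, or fitness costs; a
clean pass here shows the pipeline's statistical machinery is correct, not
that any particular real dataset is free of such artefacts.

### Default problem sizes

The default genome is desk-scale: a 17 Mb focal autosome carrying the causal
locus at 15.75 Mb, a 14 Mb neutral autosome and a 14 Mb Z (a full
31-chromosome layout is supported through `genome_layout()`). The male
recombination rate is a configurable 3 cM/Mb — a typical Lepidopteran
magnitude, not an inference about any particular species. At these sizes one
simulate–filter–scan replicate takes a few seconds, and the replicated
analyses (20-seed locus-recovery and null scans, 100-seed survivor counts,
200 probit fits) finish in minutes on one CPU.

## Numerical and design choices

* **Window anchoring.** Windows anchor at coordinate 0. When the last full
  window ends short of the chromosome, one clipped tail window (next start,
  chromosome end) is added; chromosomes shorter than the window get a single
  clipped window. A 17 Mb chromosome at 1 Mb / 100 kb yields exactly 161
  windows (starts 0, 0.1, …, 16.0 Mb).
* **Threshold.** The top-1% threshold is the m-th largest corrected deviation
  over retained windows pooled across chromosomes, with
  `m = max(1, floor(n × 0.01))` (nearest rank); ties at the threshold are all
  included (≥ comparison). Retained windows only: discarded sparse windows
  carry no usable mean.
* **Region merging.** Significant windows that overlap or abut merge; no gap
  tolerance.
* **Missing INFO annotations pass** the hard filter — the rank-sum
  annotations are undefined at sites without heterozygous calls, so treating
  absence as failure would discard clean sites wholesale.
* **Dam homozygous for either allele** is informative (resistant allele =
  REF when the dam is 1/1); sites with a missing parental genotype or zero
  pooled depth are excluded (the latter counted in a message).
* **Pooled frequencies are read-level**, computed from the AD field — the
  only option for a pooled sample.
* **Probit fitting** uses Fisher-scoring IRLS (`glm`, probit link,
  convergence 1e-8, ≤100 iterations) on log10 dose after Abbott's correction
  for control mortality; because corrected proportions are non-integer the
  fit is weighted by the number treated. LC50 = 10^(−intercept/slope); 95%
  limits by Fieller's theorem, verified in tests against the direct roots of
  the Fieller quadratic. When the Pearson chi-square/df over doses exceeds 1
  the variance is inflated by that heterogeneity factor and Student-t
  quantiles replace normal ones (Finney's convention). If Fieller's `g ≥ 1`
  the limits are unbounded and returned as `NA` with a warning rather than a
  fabricated interval.
* **Resistance ratios** are reported at the published printing convention
  (≥10 to the nearest integer, otherwise one decimal); exact quotients are
  available with `rounded = FALSE`. Note that published tables of this kind
  are not always internally consistent at that convention (rounding of the
  underlying LC50s), so equality checks use only self-consistent cells.
* **2^−ΔΔCt** normalises the target Ct to the arithmetic mean of two
  reference-gene Cts (the geometric mean on the linear scale), references
  the calibrator's mean ΔCt, and reports mean ± SE over biological
  replicates with a two-sided Student's t-test on ΔCt against the
  calibrator. Fold changes are invariant to any constant shift of a
  replicate's Cts and to common shifts of the reference genes.
* **Seeds.** All randomness flows through R's RNG; scripted analyses call
  `set.seed()` once at the top so every output is reproducible.

## Known limitations

* The survivor-count expectation assumes the RS survival probability applies
  independently per larva; density effects and assay mortality drift are not
  modelled.
* The naive parental genotype caller (read-fraction thresholds at 0.2/0.8)
  is adequate at 30x but would miscall at low depth; real data would come
  from a proper caller anyway — the package only consumes its VCF.
* Fiducial coverage of the LC50 is close to nominal at the default 6 × 24
  design but is a large-sample approximation; very steep or flat slopes at
  small n can push Fieller's `g` toward 1.
* The null scan calibrates the threshold per dataset (an empirical quantile),
  so "significance" is a ranking statement, not a controlled error rate;
  overlapping windows are strongly correlated and counts of significant
  windows are overdispersed relative to binomial.
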