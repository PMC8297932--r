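# bsapool

Pool-seq bulked segregant mapping of insecticide resistance in a ZW insect,
plus the bioassay statistics that accompany such a mapping study.

## What it is for

Mapping an incompletely dominant resistance locus in Lepidoptera by bulked
segregant analysis (BSA): a resistant female × susceptible male cross, an F1
**male** (all mapping recombination is male — females are achiasmatic)
backcrossed to a susceptible female, selection of backcross larvae at a
diagnostic dose that kills susceptible homozygotes, and pooled sequencing of
the survivors together with the two parents. The package provides

* a **ZW-aware cross simulator** (Poisson/Haldane male crossovers,
  intact-chromosome female meiosis, single-locus survival model, pooled
  sequencing with errors, VCF 4.2 output) so the whole pipeline is testable
  end to end;
* the **mapping scan**: GATK-style hard filtering
  (`QD < 2 || MQ < 40 || FS > 60 || SOR > 3 || MQRankSum < -12.5 ||
  ReadPosRankSum < -8`), informative-SNP selection (F1 heterozygous, dam
  homozygous), the per-SNP statistic `|p_pool − p_exp|` with `p_exp = 1/4`
  on autosomes and `1/3` on Z, 1 Mb / 100 kb sliding windows (≥ 80 SNPs,
  Z means × 0.75 = (1/4)/(1/3)), and top-1% candidate regions;
* **bioassay statistics**: maximum-likelihood probit dose–response fits with
  LC50 and 95% Fieller fiducial limits (heterogeneity-corrected), resistance
  ratios LC50(test)/LC50(susceptible), significance by fiducial-limit
  non-overlap, and 2^−ΔΔCt relative expression against the geometric mean of
  two reference genes.

## Worked example

```r
library(bsapool)
set.seed(1)

layout  <- default_layout()                 # 17 Mb focal autosome + 14 Mb autosome + 14 Mb Z
markers <- make_markers(layout)             # 1 SNP per 2 kb between the founder strains
sim <- simulate_bsa_experiment(layout = layout, markers = markers,
                               model = resistance_model())  # chr17:15.75 Mb; SS dies, RS 0.8
sim$n_survivors
#> [1] 133        # of 336 assayed; expectation 336 x 1/2 x 0.8 = 134.4

scan <- bsa_scan_vcf(sim$vcf_path, layout)  # filter -> informative SNPs -> windows -> regions
scan$regions
#> # A tibble: 1 × 5
#>   chrom    start      end peak_deviation n_windows
#> 1 chr17 15000000 16300000          0.244         4
```

The one candidate region contains the true locus: the pooled
resistant-allele frequency rises from the neutral 0.25 toward 0.5 around the
selected site, and the window scan's top-1% threshold isolates it.

Bioassay side:

```r
resistance_ratio(0.45, 0.0017)                         # 265 (resistant vs susceptible LC50)
fiducial_overlap_significant(c(0.37, 0.58), c(0.0014, 0.0022))  # TRUE: disjoint limits
rec <- simulate_dose_response(slope = 2.57, lc50 = 0.0017, n_per_dose = 24)
probit_fit(rec)
#> Probit fit on 6 doses
#>   slope     2.48 +/- 0.44
#>   LC50      0.001854  (95% FL 0.001052 - 0.003275)
#>   chi-square/df 1.60 on 4 df
```

The `analysis/` scripts run the full study as a narrative:
`01_simulate_cross.R` (simulate and write the VCF), `02_bsa_scan.R` (map the
locus, write window TSV / regions BED / genome-scan figure under
`results/`), `03_bioassays.R` (resistance ratios, probit refit, ΔΔCt).

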