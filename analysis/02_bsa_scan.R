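#!/usr/bin/env Rscript
# Map the resistance locus from the simulated VCF: GATK-style hard filter,
# informative-SNP selection (F1 het x dam hom), |frequency - expectation|
# per SNP, 1 Mb / 100 kb sliding windows (>= 80 SNPs, Z means x 0.75), and
# top-1% candidate regions. Run 01_simulate_cross.R first.

suppressMessages(library(bsapool))

layout_tsv <- "results/sim/layout.tsv"
vcf <- "results/sim/backcross_pool.vcf"
stopifnot(file.exists(layout_tsv), file.exists(vcf))
lay_df <- readr::read_tsv(layout_tsv, show_col_types = FALSE)
layout <- genome_layout(lay_df$name, lay_df$length_bp, lay_df$chrom_class,
                        lay_df$male_rate_cM_Mb)

scan <- bsa_scan_vcf(vcf, layout)
paths <- scan_report(scan, "results/scan")

cat(sprintf("informative SNPs: %d\n", nrow(scan$snps)))
cat(sprintf("retained windows: %d of %d; top-1%% threshold = %.4f\n",
            sum(scan$windows$retained), nrow(scan$windows), scan$threshold))
cat("candidate regions (ranked by peak corrected deviation):\n")
print(as.data.frame(scan$regions))
cat("report written to", dirname(paths$windows_tsv), "\n")
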