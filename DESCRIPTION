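Package: bsapool
Title: Pool-Seq Bulked Segregant Mapping of Insecticide Resistance in a ZW Backcross
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates and analyses bulked segregant analysis (BSA) experiments
    for mapping incompletely dominant insecticide resistance in Lepidoptera.
    Provides a ZW-aware backcross simulator with achiasmatic female meiosis,
    pooled-survivor sequencing to VCF, GATK-style hard filtering and
    informative-SNP selection, an allele-frequency-deviation sliding-window
    genome scan with Z-chromosome correction and top-quantile candidate-region
    calling, plus bioassay statistics: probit dose-response fits with LC50 and
    Fieller fiducial limits, resistance ratios, and 2^-ddCt relative expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    vcfR,
    readr
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
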