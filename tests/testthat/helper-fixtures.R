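# Shared fixtures. Simulations are deterministic given set.seed() in each
# test; the default-scale experiment is expensive enough to share via a
# per-run cache.

.fixture_cache <- new.env(parent = emptyenv())

# One default-scale selected experiment + scan (seed 1), shared across files.
cached_default_scan <- function() {
  if (!exists("scan", envir = .fixture_cache)) {
    set.seed(1)
    layout <- default_layout()
    markers <- make_markers(layout)
    sim <- simulate_bsa_experiment(layout = layout, markers = markers)
    scan <- suppressMessages(bsa_scan_vcf(sim$vcf_path, layout))
    assign("layout", layout, envir = .fixture_cache)
    assign("sim", sim, envir = .fixture_cache)
    assign("scan", scan, envir = .fixture_cache)
  }
  list(layout = get("layout", envir = .fixture_cache),
       sim = get("sim", envir = .fixture_cache),
       scan = get("scan", envir = .fixture_cache))
}

# Small fast genome for Monte-Carlo checks.
tiny_layout <- function(auto_len = 2e6, z_len = 1.5e6, rate = 3) {
  genome_layout(c("a1", "a2", "Z"), c(auto_len, auto_len, z_len),
                c("autosome", "autosome", "Z"), rate)
}

# A minimal variant-record tibble with nominal (clearly passing) annotations.
nominal_record <- function(n = 1, ...) {
  base <- tibble::tibble(
    chrom = "a1", pos = seq_len(n) * 1000L, ref = "A", alt = "G",
    gt_f1 = "0/1", gt_dam = "0/0", pool_ref = 60L, pool_alt = 20L,
    QD = 30, MQ = 60, FS = 1, SOR = 1, MQRankSum = 0, ReadPosRankSum = 0
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

# Heterozygous female: one resistant- and one susceptible-origin copy of each
# autosome, resistant-origin Z.
het_female <- function(layout) {
  haplos <- list()
  for (i in seq_len(nrow(layout))) {
    cn <- layout$name[i]
    cl <- layout$chrom_class[i]
    if (cl == "W") next
    len <- layout$length_bp[i]
    haplos[[cn]] <- if (cl == "Z") {
      list(constant_track("R", len))
    } else {
      list(constant_track("R", len), constant_track("S", len))
    }
  }
  new_individual("female", haplos, layout)
}
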