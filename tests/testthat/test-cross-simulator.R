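test_that("founders are homozygous with ZW-correct chromosome counts", {
  set.seed(11)
  layout <- tiny_layout()
  markers <- make_markers(layout, spacing_bp = 1e5)
  f <- make_founders(layout, markers)

  pos_a <- markers$pos[markers$chrom == "a1"]
  pos_z <- markers$pos[markers$chrom == "Z"]
  expect_true(all(resistant_dose(f$resistant_dam, "a1", pos_a) == 2L))
  expect_true(all(resistant_dose(f$resistant_dam, "Z", pos_z) == 1L))
  expect_length(f$resistant_dam$haplos[["Z"]], 1L)       # ZW female: one Z
  expect_length(f$susceptible_sire$haplos[["Z"]], 2L)    # ZZ male
  expect_true(all(resistant_dose(f$susceptible_sire, "a1", pos_a) == 0L))
  expect_true(all(resistant_dose(f$susceptible_sire, "Z", pos_z) == 0L))
  expect_identical(f$resistant_dam$sex, "female")
  expect_identical(f$susceptible_sire$sex, "male")
  expect_identical(f$susceptible_dam$sex, "female")

  # markers on W are rejected
  layout_w <- genome_layout(c("a1", "Z", "W1"), c(2e6, 1.5e6, 1e6),
                            c("autosome", "Z", "W"), 3)
  bad <- tibble::tibble(chrom = "W1", pos = 100L, ref = "A", alt = "C",
                        res_is_ref = TRUE)
  expect_error(make_founders(layout_w, bad), "W chromosome")
})

test_that("male crossover counts follow the Poisson-Haldane model", {
  set.seed(21)
  # 17 Mb at 100/17 cM/Mb is exactly 1 Morgan
  layout <- genome_layout(c("a1", "Z"), c(17e6, 1e6), c("autosome", "Z"),
                          c(100 / 17, 0))
  markers <- make_markers(layout, spacing_bp = 1e6)
  f <- make_founders(layout, markers)
  f1 <- make_f1_male(f, layout)

  n <- 10000
  counts <- integer(n)
  res_at_marker <- logical(n)
  probe <- markers$pos[markers$chrom == "a1"][5]
  for (i in seq_len(n)) {
    g <- meiosis_male(f1, layout)
    counts[i] <- attr(g, "n_crossovers")[["a1"]]
    res_at_marker[i] <- track_origin_at(g[["a1"]], probe) == "R"
  }
  # Monte-Carlo mean of the Poisson(1) crossover count
  expect_lt(abs(mean(counts) - 1), 3 / sqrt(n))
  # chi-square goodness of fit to Poisson(1), alpha = 0.01
  obs <- tabulate(pmin(counts, 5) + 1L, nbins = 6L)
  p <- c(stats::dpois(0:4, 1), 1 - stats::ppois(4, 1))
  stat <- sum((obs - n * p)^2 / (n * p))
  expect_gt(stats::pchisq(stat, df = 5, lower.tail = FALSE), 0.01)
  # Mendelian transmission of either haplotype at a single marker
  expect_lt(abs(mean(res_at_marker) - 0.5), 3 * 0.5 / sqrt(n))
  # zero recombination rate reproduces an intact parental haplotype
  g0 <- meiosis_male(f1, layout)
  expect_true(tracks_identical(g0[["Z"]], f1$haplos[["Z"]][[1]]) ||
                tracks_identical(g0[["Z"]], f1$haplos[["Z"]][[2]]))
  expect_error(meiosis_male(f$resistant_dam, layout), "male")
})

test_that("female meiosis is achiasmatic and transmits Z or W equally", {
  set.seed(31)
  layout <- tiny_layout()
  fem <- het_female(layout)
  z_bearing <- logical(10000)
  for (i in seq_len(10000)) {
    g <- meiosis_female(fem, layout)
    z_bearing[i] <- attr(g, "sex_chrom") == "Z"
    if (i <= 500) {
      # every autosomal gamete haplotype is bit-identical to a parental one
      for (cn in c("a1", "a2")) {
        expect_true(tracks_identical(g[[cn]], fem$haplos[[cn]][[1]]) ||
                      tracks_identical(g[[cn]], fem$haplos[[cn]][[2]]))
      }
    }
  }
  expect_lt(abs(mean(z_bearing) - 0.5), 3 * 0.5 / sqrt(10000))
  expect_error(meiosis_female(make_founders(layout, make_markers(layout, 1e5))$susceptible_sire,
                              layout), "female")
})

test_that("backcross progeny segregate 0.25 on autosomes and 1/3 on Z", {
  set.seed(41)
  layout <- tiny_layout()
  markers <- make_markers(layout, spacing_bp = 5e5)
  f <- make_founders(layout, markers)
  f1 <- make_f1_male(f, layout)
  n <- 10000
  bc <- make_backcross(f1, f$susceptible_dam, n, layout)

  probe_a <- markers$pos[markers$chrom == "a1"][2]
  probe_z <- markers$pos[markers$chrom == "Z"][2]
  res_a <- copies_a <- res_z <- copies_z <- 0
  min_s_per_autosome <- Inf
  for (ind in bc) {
    res_a <- res_a + resistant_dose(ind, "a1", probe_a)
    copies_a <- copies_a + 2
    res_z <- res_z + resistant_dose(ind, "Z", probe_z)
    copies_z <- copies_z + length(ind$haplos[["Z"]])
    min_s_per_autosome <- min(min_s_per_autosome,
                              2 - resistant_dose(ind, "a1", probe_a),
                              2 - resistant_dose(ind, "a2", probe_a))
  }
  # autosome: dam contributes S, sire R with p=1/2 -> freq 1/4
  expect_lt(abs(res_a / copies_a - 0.25), 3 / (4 * sqrt(n)))
  # Z: sires two Zs are R/S; dam's Z goes to sons only -> freq 1/3
  se_z <- sqrt((1 / 3) * (2 / 3) / copies_z)
  expect_lt(abs(res_z / copies_z - 1 / 3), 4 * se_z)
  # the dam is homozygous susceptible, so every offspring keeps an S copy
  expect_gte(min_s_per_autosome, 1)
  expect_error(make_backcross(f1, f$susceptible_dam, 0, layout), "positive")
})

test_that("survival selection acts through genotype at the causal locus", {
  set.seed(51)
  layout <- tiny_layout()
  markers <- make_markers(layout, spacing_bp = 5e5)
  f <- make_founders(layout, markers)
  f1 <- make_f1_male(f, layout)
  bc <- make_backcross(f1, f$susceptible_dam, 400, layout)
  locus <- resistance_model(chrom = "a1", pos = 1e6, s_SS = 0, s_RS = 1, s_RR = 1)

  surv <- select_survivors(bc, locus, layout)
  doses <- vapply(surv, resistant_dose, integer(1), chrom = "a1", pos = 1e6)
  # SS dies, RS always lives: every survivor carries exactly one R copy,
  # so the resistant-allele frequency at the locus is exactly 1/2
  expect_true(all(doses == 1L))
  expect_equal(sum(doses) / (2 * length(surv)), 0.5)

  all_live <- resistance_model(chrom = "a1", pos = 1e6, s_SS = 1, s_RS = 1, s_RR = 1)
  expect_identical(select_survivors(bc, all_live, layout), bc)
  off <- resistance_model(chrom = "a1", pos = 99e6)
  expect_error(select_survivors(bc, off, layout), "outside")
})

test_that("pool sequencing conserves reads and tracks pool allele frequency", {
  set.seed(61)
  layout <- tiny_layout()
  markers <- make_markers(layout, spacing_bp = 2e4)
  f <- make_founders(layout, markers)

  # monomorphic resistant pool, no error: every read is the resistant allele
  mono <- sequence_pool(list(f$resistant_dam, f$resistant_dam), markers, layout,
                        seq_spec(pool_depth_mean = 50, error_rate = 0))
  expect_true(all(mono$sus_reads == 0))
  expect_true(all(mono$res_reads == mono$depth))

  # unselected backcross pool: read-level resistant frequency near 0.25
  f1 <- make_f1_male(f, layout)
  bc <- make_backcross(f1, f$susceptible_dam, 120, layout)
  tab <- sequence_pool(bc, markers, layout, seq_spec(pool_depth_mean = 240))
  expect_true(all(tab$res_reads + tab$sus_reads == tab$depth))  # conservation
  auto <- tab[tab$chrom != "Z", ]
  freq <- sum(auto$res_reads) / sum(auto$depth)
  # the pool's true frequency dominates the error: 240 chromosome copies
  expect_lt(abs(freq - 0.25), 3 * sqrt(0.25 * 0.75 / 240))
  expect_error(sequence_pool(list(), markers, layout), "non-empty")
})

test_that("emitted VCF round-trips through the reader", {
  set.seed(71)
  layout <- tiny_layout()
  markers <- make_markers(layout, spacing_bp = 2e4)
  sim <- simulate_bsa_experiment(
    layout = layout, markers = markers,
    model = resistance_model(chrom = "a1", pos = 1e6),
    spec = seq_spec(pool_size = 60), n_progeny = 150
  )
  rec <- read_bsa_vcf(sim$vcf_path)
  expect_equal(nrow(rec), nrow(markers))
  key <- paste(rec$chrom, rec$pos)
  m_key <- paste(markers$chrom, markers$pos + 1L)  # VCF is 1-based
  expect_setequal(key, m_key)
  rec <- rec[match(m_key, key), ]
  expect_identical(rec$ref, markers$ref)
  expect_identical(rec$alt, markers$alt)
  # pooled allele depths re-read exactly as written
  truth <- sim$truth
  exp_ref <- ifelse(truth$res_is_ref, truth$res_reads, truth$sus_reads)
  expect_identical(rec$pool_ref, as.integer(exp_ref))
  expect_identical(rec$pool_alt + rec$pool_ref,
                   as.integer(truth$res_reads + truth$sus_reads))
  # parents at 30x: the F1 is heterozygous everywhere, the dam homozygous
  expect_gt(mean(rec$gt_f1 == "0/1"), 0.99)
  dam_expected <- ifelse(truth$res_is_ref, "1/1", "0/0")  # dam carries the sus allele
  expect_gt(mean(rec$gt_dam == dam_expected), 0.99)
})

test_that("the failing-site fraction controls hard-filter failures", {
  set.seed(81)
  layout <- tiny_layout()
  markers <- make_markers(layout, spacing_bp = 2e4)
  sim0 <- simulate_bsa_experiment(layout = layout, markers = markers,
                                  model = resistance_model(chrom = "a1", pos = 1e6),
                                  spec = seq_spec(pool_size = 60),
                                  n_progeny = 150, fail_fraction = 0)
  expect_true(all(hard_filter_pass(read_bsa_vcf(sim0$vcf_path))))
  sim1 <- simulate_bsa_experiment(layout = layout, markers = markers,
                                  model = resistance_model(chrom = "a1", pos = 1e6),
                                  spec = seq_spec(pool_size = 60),
                                  n_progeny = 150, fail_fraction = 1)
  expect_false(any(hard_filter_pass(read_bsa_vcf(sim1$vcf_path))))
  simh <- simulate_bsa_experiment(layout = layout, markers = markers,
                                  model = resistance_model(chrom = "a1", pos = 1e6),
                                  spec = seq_spec(pool_size = 60),
                                  n_progeny = 150, fail_fraction = 0.3)
  frac <- mean(!hard_filter_pass(read_bsa_vcf(simh$vcf_path)))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(markers)))
})
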