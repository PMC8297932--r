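# Pooled and parental short-read sequencing is modelled at the allele-count
# level: per site the depth is Poisson, each read samples a chromosome copy
# uniformly from the pool (2 copies per individual on autosomes; 2 per male
# and 1 per female on Z) and reports its allele, flipped with the per-read
# error probability. Sampling copies i.i.d. is equivalent to a binomial draw
# at the pool's true allele frequency, which is how it is vectorised.

pool_allele_counts <- function(pool, markers, layout) {
  out <- vector("list", length(unique(markers$chrom)))
  chroms <- unique(markers$chrom)
  for (j in seq_along(chroms)) {
    cn <- chroms[j]
    pos <- markers$pos[markers$chrom == cn]
    res <- integer(length(pos))
    copies <- 0L
    for (ind in pool) {
      res <- res + resistant_dose(ind, cn, pos)
      copies <- copies + length(ind$haplos[[cn]])
    }
    out[[j]] <- tibble::tibble(chrom = cn, pos = pos,
                               res_copies = res, total_copies = copies)
  }
  dplyr::bind_rows(out)
}

#' Sequence a pool of individuals at the marker set
#'
#' @param pool Non-empty list of `individual`s.
#' @param markers A [make_markers()] marker set.
#' @param layout The [genome_layout()].
#' @param spec A [seq_spec()].
#' @return Tibble with one row per marker: `chrom`, `pos`, `depth`,
#'   `res_reads`, `sus_reads` (reads supporting the resistant- and
#'   susceptible-founder alleles; they sum to `depth`) and `true_res_freq`,
#'   the pool's true resistant-origin chromosome-copy frequency.
#' @export
sequence_pool <- function(pool, markers, layout, spec = seq_spec()) {
  if (length(pool) == 0) stop("pool must be non-empty")
  counts <- pool_allele_counts(pool, markers, layout)
  p <- counts$res_copies / counts$total_copies
  p_read <- p * (1 - spec$error_rate) + (1 - p) * spec$error_rate
  depth <- stats::rpois(nrow(counts), spec$pool_depth_mean)
  res_reads <- stats::rbinom(nrow(counts), depth, p_read)
  tibble::tibble(chrom = counts$chrom, pos = counts$pos, depth = depth,
                 res_reads = res_reads, sus_reads = depth - res_reads,
                 true_res_freq = p)
}

# Sequence one parent and call naive genotypes from read counts.
sequence_parent <- function(ind, markers, layout, spec) {
  counts <- pool_allele_counts(list(ind), markers, layout)
  # alt-allele dosage: resistant-origin copies carry ref where res_is_ref
  p_res <- counts$res_copies / counts$total_copies
  p_alt <- ifelse(markers$res_is_ref, 1 - p_res, p_res)
  p_read <- p_alt * (1 - spec$error_rate) + (1 - p_alt) * spec$error_rate
  depth <- stats::rpois(nrow(counts), spec$parent_depth_mean)
  alt_reads <- stats::rbinom(nrow(counts), depth, p_read)
  ref_reads <- depth - alt_reads
  frac <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  gt <- dplyr::case_when(
    depth == 0 ~ "./.",
    frac < 0.2 ~ "0/0",
    frac > 0.8 ~ "1/1",
    TRUE ~ "0/1"
  )
  tibble::tibble(gt = gt, ref_reads = ref_reads, alt_reads = alt_reads, depth = depth)
}

# Site-level INFO annotations. "Clean" draws are guaranteed to satisfy the
# hard filter; failing sites are marked by QD = 1.0. A small fraction of
# sites omit the rank-sum annotations, as callers do at homozygous sites.
draw_info <- function(n, fail, missing_ranksum_fraction = 0.02) {
  qd <- pmax(stats::rnorm(n, 25, 5), 2.5)
  qd[fail] <- 1.0
  tibble::tibble(
    QD = qd,
    MQ = pmax(stats::rnorm(n, 60, 2), 41),
    FS = pmin(stats::rexp(n, 1 / 2), 55),
    SOR = pmin(abs(stats::rnorm(n, 1, 0.5)), 2.9),
    MQRankSum = ifelse(stats::runif(n) < missing_ranksum_fraction, NA_real_,
                       pmax(pmin(stats::rnorm(n), 12), -12)),
    ReadPosRankSum = ifelse(stats::runif(n) < missing_ranksum_fraction, NA_real_,
                            pmax(pmin(stats::rnorm(n), 8), -8))
  )
}

#' Sequence the backcross parents and write the three-sample VCF
#'
#' Emits one biallelic record per marker with called genotypes for the F1
#' male and the susceptible dam (depth Poisson at the parent depth), the
#' pooled allele depths, and INFO annotations QD, MQ, FS, SOR, MQRankSum and
#' ReadPosRankSum drawn from distributions that satisfy the downstream hard
#' filter, except for a configurable fraction of sites given a
#' filter-failing QD.
#'
#' @param f1_male,susceptible_dam `individual`s (the sequenced parents).
#' @param pool_table Output of [sequence_pool()].
#' @param markers,layout,spec As elsewhere.
#' @param path Output VCF path (plain text, VCF 4.2).
#' @param fail_fraction Fraction of sites given filter-failing annotations
#'   (default 0).
#' @return `path`, invisibly. Samples are named `F1_male`, `dam`, `pool`.
#' @export
sequence_parents_and_emit_vcf <- function(f1_male, susceptible_dam, pool_table,
                                          markers, layout, spec = seq_spec(),
                                          path, fail_fraction = 0) {
  stopifnot(nrow(pool_table) == nrow(markers))
  f1 <- sequence_parent(f1_male, markers, layout, spec)
  dam <- sequence_parent(susceptible_dam, markers, layout, spec)
  pool_ref <- ifelse(markers$res_is_ref, pool_table$res_reads, pool_table$sus_reads)
  pool_alt <- pool_table$depth - pool_ref

  n <- nrow(markers)
  fail <- stats::runif(n) < fail_fraction
  info <- draw_info(n, fail)
  fmt_f <- function(x) formatC(x, format = "f", digits = 3)
  opt <- function(key, x) ifelse(is.na(x), "", paste0(";", key, "=", fmt_f(x)))
  info_str <- paste0(
    "QD=", fmt_f(info$QD), ";MQ=", fmt_f(info$MQ),
    ";FS=", fmt_f(info$FS), ";SOR=", fmt_f(info$SOR),
    opt("MQRankSum", info$MQRankSum), opt("ReadPosRankSum", info$ReadPosRankSum)
  )

  sample_field <- function(gt, ref_reads, alt_reads, depth) {
    sprintf("%s:%d,%d:%d", gt, ref_reads, alt_reads, depth)
  }
  body <- paste(
    markers$chrom, markers$pos + 1L, ".", markers$ref, markers$alt, ".", "PASS",
    info_str, "GT:AD:DP",
    sample_field(f1$gt, f1$ref_reads, f1$alt_reads, f1$depth),
    sample_field(dam$gt, dam$ref_reads, dam$alt_reads, dam$depth),
    sample_field("./.", pool_ref, pool_alt, pool_table$depth),
    sep = "\t"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsapool",
    sprintf("##contig=<ID=%s,length=%d>", layout$name, as.integer(layout$length_bp)),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant quality by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Strand bias Fisher phred">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Strand odds ratio">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "F1_male", "dam", "pool"), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Run one full synthetic mapping experiment
#'
#' Founders -> F1 male -> backcross of size `n_progeny` -> survival selection
#' at the diagnostic dose -> pool of up to `pool_size` survivors sequenced at
#' the pooled depth -> three-sample VCF plus a truth table for oracle checks.
#'
#' @param layout,markers,model,spec Simulation components; see
#'   [genome_layout()], [make_markers()], [resistance_model()], [seq_spec()].
#' @param n_progeny Backcross family size (default 336).
#' @param vcf_path Where to write the VCF.
#' @param fail_fraction Fraction of filter-failing sites (default 0).
#' @param select Apply the survival model (default `TRUE`); `FALSE` gives the
#'   unselected null experiment (pool drawn from all progeny).
#' @return List: `vcf_path`, `n_survivors`, `pool_size_used`, `truth`
#'   (marker tibble with the pool's true resistant-origin frequency and
#'   `res_is_ref`).
#' @export
simulate_bsa_experiment <- function(layout = default_layout(),
                                    markers = NULL,
                                    model = resistance_model(),
                                    spec = seq_spec(),
                                    n_progeny = 336,
                                    vcf_path = tempfile(fileext = ".vcf"),
                                    fail_fraction = 0,
                                    select = TRUE) {
  if (is.null(markers)) markers <- make_markers(layout)
  founders <- make_founders(layout, markers)
  f1 <- make_f1_male(founders, layout)
  progeny <- make_backcross(f1, founders$susceptible_dam, n_progeny, layout)
  survivors <- if (select) select_survivors(progeny, model, layout) else progeny
  n_surv <- length(survivors)
  k <- min(spec$pool_size, n_surv)
  if (k < spec$pool_size) {
    warning(sprintf("only %d survivors available; pooling all of them", n_surv))
  }
  pool <- survivors[sample.int(n_surv, k)]
  pool_table <- sequence_pool(pool, markers, layout, spec)
  sequence_parents_and_emit_vcf(f1, founders$susceptible_dam, pool_table,
                                markers, layout, spec, vcf_path, fail_fraction)
  truth <- dplyr::bind_cols(
    markers[, c("chrom", "pos", "ref", "alt", "res_is_ref")],
    pool_table[, c("true_res_freq", "res_reads", "sus_reads")]
  )
  list(vcf_path = vcf_path, n_survivors = n_surv, pool_size_used = k,
       truth = truth)
}
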