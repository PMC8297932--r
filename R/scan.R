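#' Configuration for the sliding-window BSA scan
#'
#' Defaults are the published analysis settings: 1 Mb windows advanced in
#' 100 kb steps, windows with fewer than 80 informative SNPs discarded, a
#' top-1% threshold, and Z-window means multiplied by 0.75 — the exact ratio
#' of the autosomal and Z expected frequencies, 0.25 / (1/3).
#'
#' @param window_bp,step_bp Window width and step in bp.
#' @param min_snps Minimum informative SNPs for a window to be retained.
#' @param top_fraction Fraction of retained windows called significant.
#' @param z_correction Multiplier applied to Z-window means.
#' @return A list of class `bsa_config`.
#' @export
bsa_config <- function(window_bp = 1e6, step_bp = 1e5, min_snps = 80,
                       top_fraction = 0.01, z_correction = 0.75) {
  stopifnot(step_bp > 0, step_bp <= window_bp,
            top_fraction > 0, top_fraction < 1, min_snps >= 1)
  structure(list(window_bp = window_bp, step_bp = step_bp, min_snps = min_snps,
                 top_fraction = top_fraction, z_correction = z_correction,
                 expected_autosome = 0.25, expected_z = 1 / 3),
            class = "bsa_config")
}

#' Expected resistant-allele frequency under neutral backcross segregation
#'
#' In the (resistant dam x susceptible sire) F1-male x susceptible-dam
#' backcross, an informative SNP segregates 1:3 on autosomes and 1:2 on Z
#' among unselected progeny chromosome copies, so the resistant-founder
#' allele is expected at frequency 1/4 (autosome) or 1/3 (Z). The Z value is
#' held exact so that 0.25 / (1/3) equals the 0.75 correction factor.
#'
#' @param chrom_class Character vector of `"autosome"` or `"Z"`.
#' @return Numeric vector of expected frequencies. W is rejected: the F1
#'   male carries no W, so no informative SNP can exist there.
#' @export
expected_frequency <- function(chrom_class) {
  if (any(!chrom_class %in% c("autosome", "Z"))) {
    stop("expected frequency defined only for autosome and Z")
  }
  ifelse(chrom_class == "autosome", 0.25, 1 / 3)
}

#' Per-SNP frequency deviation
#'
#' The mapping statistic: the absolute deviation of the pooled
#' resistant-allele frequency from its neutral segregation expectation.
#'
#' @param snps Informative-SNP tibble from [select_informative()].
#' @param cfg A [bsa_config()] (unused beyond validation hooks; present so
#'   alternative expectations can be threaded through).
#' @return `snps` with a `deviation` column added.
#' @export
snp_deviation <- function(snps, cfg = bsa_config()) {
  snps$deviation <- abs(snps$pool_freq - expected_frequency(snps$chrom_class))
  snps
}

# Window start positions for one chromosome: full windows anchored at 0,
# `step` apart; if the last full window ends short of the chromosome, one
# clipped tail window is added; chromosomes shorter than the window get a
# single clipped window.
window_starts <- function(length_bp, window_bp, step_bp) {
  if (length_bp < window_bp) {
    return(tibble::tibble(start = 0, end = length_bp))
  }
  n_full <- floor((length_bp - window_bp) / step_bp) + 1
  starts <- (seq_len(n_full) - 1) * step_bp
  ends <- starts + window_bp
  if (ends[n_full] < length_bp) {
    starts <- c(starts, starts[n_full] + step_bp)
    ends <- c(ends, length_bp)
  }
  tibble::tibble(start = starts, end = ends)
}

#' Sliding-window scan of per-SNP deviations
#'
#' Computes the mean frequency deviation in overlapping windows along every
#' non-W chromosome, discards windows with fewer than `min_snps` informative
#' SNPs, and multiplies Z-window means by the Z correction so they are
#' comparable with autosomes.
#'
#' @param snps Informative SNPs with a `deviation` column (see
#'   [snp_deviation()]); positions 1-based as read from VCF.
#' @param layout The [genome_layout()].
#' @param cfg A [bsa_config()].
#' @return Tibble of window scores: `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `mean_deviation`, `corrected_deviation`,
#'   `retained`.
#' @export
window_scan <- function(snps, layout, cfg = bsa_config()) {
  if (!"deviation" %in% names(snps)) snps <- snp_deviation(snps, cfg)
  out <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    cn <- layout$name[i]
    cl <- layout$chrom_class[i]
    if (cl == "W") next
    win <- window_starts(layout$length_bp[i], cfg$window_bp, cfg$step_bp)
    s <- snps[snps$chrom == cn, , drop = FALSE]
    pos0 <- s$pos - 1  # to 0-based
    if (any(pos0 >= layout$length_bp[i] | pos0 < 0)) {
      stop("SNP position outside chromosome ", cn)
    }
    ord <- order(pos0)
    pos0 <- pos0[ord]
    dev <- s$deviation[ord]
    cum <- c(0, cumsum(dev))
    lo <- findInterval(win$start, pos0, left.open = TRUE)   # snps with pos < start
    hi <- findInterval(win$end, pos0, left.open = TRUE)     # snps with pos < end
    n_snps <- hi - lo
    mean_dev <- ifelse(n_snps > 0, (cum[hi + 1] - cum[lo + 1]) / n_snps, NA_real_)
    corr <- if (cl == "Z") cfg$z_correction else 1
    out[[i]] <- tibble::tibble(
      chrom = cn, start = win$start, end = win$end, n_snps = n_snps,
      mean_deviation = mean_dev,
      corrected_deviation = mean_dev * corr,
      retained = n_snps >= cfg$min_snps
    )
  }
  dplyr::bind_rows(out)
}

#' Call candidate regions above the top-quantile threshold
#'
#' The significance threshold is the smallest corrected deviation among the
#' top `top_fraction` of retained windows (the m-th largest value with
#' `m = max(1, floor(n * top_fraction))`); windows at or above it are
#' significant, and overlapping or abutting significant windows are merged
#' into candidate regions ranked by their peak window.
#'
#' @param windows Window tibble from [window_scan()].
#' @param cfg A [bsa_config()].
#' @return List: `threshold` (numeric), `windows` (input with a `significant`
#'   column on retained windows), `regions` (tibble `chrom`, `start`, `end`,
#'   `peak_deviation`, `n_windows`, ordered by decreasing peak).
#' @export
call_regions <- function(windows, cfg = bsa_config()) {
  ret <- windows[windows$retained, , drop = FALSE]
  if (nrow(ret) == 0) stop("no retained windows")
  vals <- sort(ret$corrected_deviation, decreasing = TRUE)
  if (length(unique(vals)) == 1) {
    warning("all retained windows have equal corrected deviation; all called significant")
  }
  m <- max(1L, floor(nrow(ret) * cfg$top_fraction))
  threshold <- vals[m]
  windows$significant <- windows$retained & windows$corrected_deviation >= threshold
  sig <- windows[windows$significant, , drop = FALSE]
  regions <- merge_windows(sig)
  list(threshold = threshold, windows = windows, regions = regions)
}

merge_windows <- function(sig) {
  if (nrow(sig) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          peak_deviation = numeric(), n_windows = integer()))
  }
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(sig))) {
    w <- sig[i, ]
    if (!is.null(cur) && w$chrom == cur$chrom && w$start <= cur$end) {
      cur$end <- max(cur$end, w$end)
      cur$peak_deviation <- max(cur$peak_deviation, w$corrected_deviation)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- list(chrom = w$chrom, start = w$start, end = w$end,
                  peak_deviation = w$corrected_deviation, n_windows = 1L)
    }
  }
  out[[length(out) + 1]] <- cur
  regions <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  regions[order(-regions$peak_deviation), , drop = FALSE]
}

#' Write the genome-scan report
#'
#' Writes the retained windows as TSV, candidate regions as BED (0-based
#' half-open), and a genome-wide deviation track with the threshold line.
#'
#' @param scan Result of [call_regions()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`windows_tsv`, `regions_bed`,
#'   `plot_png`).
#' @export
scan_report <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  win <- scan$windows[scan$windows$retained, , drop = FALSE]
  windows_tsv <- file.path(dir, "windows.tsv")
  readr::write_tsv(win, windows_tsv)
  regions_bed <- file.path(dir, "regions.bed")
  bed <- scan$regions
  readr::write_tsv(
    tibble::tibble(chrom = bed$chrom, start = format(bed$start, scientific = FALSE, trim = TRUE),
                   end = format(bed$end, scientific = FALSE, trim = TRUE),
                   name = sprintf("region_%d", seq_len(nrow(bed))),
                   score = bed$peak_deviation),
    regions_bed, col_names = FALSE
  )
  p <- ggplot2::ggplot(win, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                         y = .data$corrected_deviation)) +
    ggplot2::geom_point(size = 0.4, colour = "grey30") +
    ggplot2::geom_hline(yintercept = scan$threshold, colour = "red", linetype = "dashed") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Mean |frequency deviation| (corrected)") +
    ggplot2::theme_bw()
  plot_png <- file.path(dir, "scan.png")
  ggplot2::ggsave(plot_png, p, width = 9, height = 3, dpi = 150)
  invisible(list(windows_tsv = windows_tsv, regions_bed = regions_bed,
                 plot_png = plot_png))
}

#' Run filter, informative-SNP selection and scan on a VCF
#'
#' Convenience pipeline: read the three-sample VCF, apply the hard filter,
#' select informative SNPs, compute deviations, scan windows and call
#' candidate regions.
#'
#' @param vcf_path Path to the parent+pool VCF.
#' @param layout The [genome_layout()].
#' @param cfg A [bsa_config()].
#' @param ... Sample-name arguments passed to [read_bsa_vcf()].
#' @return As [call_regions()], plus `snps` (the informative SNPs with
#'   deviations).
#' @export
bsa_scan_vcf <- function(vcf_path, layout, cfg = bsa_config(), ...) {
  records <- read_bsa_vcf(vcf_path, ...)
  records <- records[hard_filter_pass(records), , drop = FALSE]
  snps <- snp_deviation(select_informative(records, layout), cfg)
  scan <- call_regions(window_scan(snps, layout, cfg), cfg)
  scan$snps <- snps
  scan
}
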