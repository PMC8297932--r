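#' Relative expression by the 2^-ddCt method
#'
#' Normalises the target gene's Ct to the geometric mean of two reference
#' genes (on the Ct scale the geometric mean of linear quantities is the
#' arithmetic mean of Cts), references each sample to the calibrator
#' sample's mean delta-Ct, and reports fold change `2^-ddCt` with mean and
#' standard error over biological replicates. A two-sided Student's t-test
#' on the per-replicate delta-Ct values against the calibrator accompanies
#' each non-calibrator sample.
#'
#' @param ct Tibble/data frame of `sample`, `gene`, `rep`, `ct`.
#' @param target Target gene name.
#' @param reference_genes Character vector of exactly two reference genes;
#'   both must be measured for every sample x replicate.
#' @param calibrator Calibrator sample name (fold change 1 by construction).
#' @return Tibble per sample: `sample`, `n_reps`, `mean_dct`, `ddct`,
#'   `fold_change`, `fold_se`, `p_value` (NA for the calibrator).
#' @export
ddct_fold_change <- function(ct, target, reference_genes, calibrator) {
  stopifnot(all(c("sample", "gene", "rep", "ct") %in% names(ct)))
  if (length(reference_genes) != 2) stop("exactly two reference genes are required")
  if (!calibrator %in% ct$sample) stop("calibrator sample not present")
  refs <- ct[ct$gene %in% reference_genes, , drop = FALSE]
  ref_mean <- dplyr::summarise(
    dplyr::group_by(refs, .data$sample, .data$rep),
    n_ref = dplyr::n(), ref_ct = mean(.data$ct), .groups = "drop"
  )
  if (any(ref_mean$n_ref != 2)) stop("both reference genes required for every sample x replicate")
  tg <- ct[ct$gene == target, , drop = FALSE]
  if (nrow(tg) == 0) stop("target gene not present")
  dct <- dplyr::inner_join(tg, ref_mean, by = c("sample", "rep"))
  dct$dct <- dct$ct - dct$ref_ct
  cal_dct <- dct$dct[dct$sample == calibrator]
  cal_mean <- mean(cal_dct)
  per_sample <- dplyr::summarise(
    dplyr::group_by(dct, .data$sample),
    n_reps = dplyr::n(),
    mean_dct = mean(.data$dct),
    fold_change = mean(2^-(.data$dct - cal_mean)),
    fold_se = stats::sd(2^-(.data$dct - cal_mean)) / sqrt(dplyr::n()),
    p_value = if (dplyr::first(.data$sample) == calibrator || dplyr::n() < 2) {
      NA_real_
    } else {
      # zero replicate variance (exact synthetic tables) has no defined t-test
      tryCatch(stats::t.test(.data$dct, cal_dct)$p.value,
               error = function(e) NA_real_)
    },
    .groups = "drop"
  )
  per_sample$ddct <- per_sample$mean_dct - cal_mean
  per_sample[, c("sample", "n_reps", "mean_dct", "ddct",
                 "fold_change", "fold_se", "p_value")]
}

#' Simulate a qPCR Ct table
#'
#' Two reference genes with stable Cts plus one target whose expression in
#' each sample is a fold change relative to the calibrator; replicate noise
#' is normal on the Ct scale.
#'
#' @param fold_changes Named numeric vector of true fold changes per sample
#'   (the calibrator should be 1).
#' @param target,reference_genes,calibrator Gene and sample names.
#' @param n_reps Biological replicates (default 4).
#' @param base_ct Target Ct in the calibrator (default 24).
#' @param ref_ct Reference-gene Cts (default c(18, 20)).
#' @param sd_ct Replicate SD on the Ct scale (default 0.15).
#' @return Tibble of `sample`, `gene`, `rep`, `ct`.
#' @export
simulate_ct_table <- function(fold_changes, target = "CYP9A186",
                              reference_genes = c("beta_actin", "GAPDH"),
                              calibrator = names(fold_changes)[1],
                              n_reps = 4, base_ct = 24, ref_ct = c(18, 20),
                              sd_ct = 0.15) {
  rows <- list()
  for (s in names(fold_changes)) {
    for (r in seq_len(n_reps)) {
      target_ct <- base_ct - log2(fold_changes[[s]]) + stats::rnorm(1, 0, sd_ct)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = s,
        gene = c(target, reference_genes),
        rep = r,
        ct = c(target_ct, ref_ct + stats::rnorm(2, 0, sd_ct))
      )
    }
  }
  dplyr::bind_rows(rows)
}
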