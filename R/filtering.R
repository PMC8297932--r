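#' Read a three-sample parent + pool VCF into variant records
#'
#' Parses a VCF 4.x (via vcfR) holding genotypes for the two backcross
#' parents and allele depths for the pooled sample. Multiallelic and non-SNP
#' records are dropped with a message giving the count.
#'
#' @param path VCF path.
#' @param f1_sample,dam_sample,pool_sample Sample names (defaults match the
#'   simulator's output).
#' @return Tibble of variant records: `chrom`, `pos` (1-based, as read),
#'   `ref`, `alt`, `gt_f1`, `gt_dam` (normalised to `0/0`, `0/1`, `1/1` or
#'   `NA`), `pool_ref`, `pool_alt`, and numeric `QD`, `MQ`, `FS`, `SOR`,
#'   `MQRankSum`, `ReadPosRankSum` (`NA` where absent).
#' @export
read_bsa_vcf <- function(path, f1_sample = "F1_male", dam_sample = "dam",
                         pool_sample = "pool") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(vcf@gt) == 0 && nrow(fix) == 0) {
    return(empty_records())
  }
  samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(c(f1_sample, dam_sample, pool_sample), samples)
  if (length(missing) > 0) {
    stop("samples not found in VCF: ", paste(missing, collapse = ", "))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  n_dropped <- sum(!is_snp)
  if (n_dropped > 0) {
    message(n_dropped, " multiallelic or non-SNP record(s) dropped")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  }
  pool_ad <- ad[, pool_sample]
  pool_ref <- suppressWarnings(as.integer(sub(",.*$", "", pool_ad)))
  rest <- sub("^[^,]*,?", "", pool_ad)
  pool_alt <- suppressWarnings(as.integer(sub(",.*$", "", rest)))
  rec <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref,
    alt = alt,
    gt_f1 = normalise_gt(gt[, f1_sample]),
    gt_dam = normalise_gt(gt[, dam_sample]),
    pool_ref = pool_ref,
    pool_alt = pool_alt,
    QD = info_num("QD"),
    MQ = info_num("MQ"),
    FS = info_num("FS"),
    SOR = info_num("SOR"),
    MQRankSum = info_num("MQRankSum"),
    ReadPosRankSum = info_num("ReadPosRankSum")
  )
  rec <- rec[is_snp, , drop = FALSE]
  rec[order(rec$chrom, rec$pos), , drop = FALSE]
}

empty_records <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gt_f1 = character(), gt_dam = character(),
    pool_ref = integer(), pool_alt = integer(),
    QD = numeric(), MQ = numeric(), FS = numeric(), SOR = numeric(),
    MQRankSum = numeric(), ReadPosRankSum = numeric()
  )
}

# "0|1" and "1/0" style genotypes collapse to unphased sorted form; any
# missing allele gives NA. Normalised per unique value, then broadcast.
normalise_gt <- function(gt) {
  uniq <- unique(gt)
  norm1 <- vapply(uniq, function(g) {
    if (is.na(g)) return(NA_character_)
    p <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (length(p) != 2 || anyNA(suppressWarnings(as.integer(p)))) return(NA_character_)
    paste(sort(as.integer(p)), collapse = "/")
  }, character(1))
  unname(norm1[match(gt, uniq)])
}

#' GATK-style hard filter
#'
#' A record fails when any present annotation violates its bound:
#' `QD < 2.0 || MQ < 40.0 || FS > 60.0 || SOR > 3.0 || MQRankSum < -12.5 ||
#' ReadPosRankSum < -8.0`. A missing annotation never causes failure (rank-sum
#' annotations are undefined at sites without heterozygous calls).
#'
#' @param records Variant-record tibble from [read_bsa_vcf()] (or any tibble
#'   with the six annotation columns).
#' @return Logical vector, `TRUE` where the record passes.
#' @export
hard_filter_pass <- function(records) {
  viol <- function(x, bad) !is.na(x) & bad(x)
  fails <- viol(records$QD, function(x) x < 2.0) |
    viol(records$MQ, function(x) x < 40.0) |
    viol(records$FS, function(x) x > 60.0) |
    viol(records$SOR, function(x) x > 3.0) |
    viol(records$MQRankSum, function(x) x < -12.5) |
    viol(records$ReadPosRankSum, function(x) x < -8.0)
  !fails
}

#' Select informative SNPs for the backcross design
#'
#' Informative sites are heterozygous in the F1 male and homozygous in the
#' susceptible dam, so the resistant-founder allele is the F1 allele the dam
#' does not carry: ALT when the dam is `0/0`, REF when she is `1/1`. Sites
#' with missing parental genotypes, on the W, or with zero pooled depth are
#' excluded (the latter with a message).
#'
#' @param records Variant records that passed [hard_filter_pass()].
#' @param layout The [genome_layout()] giving each chromosome's class.
#' @return Tibble of informative SNPs: `chrom`, `pos`, `chrom_class`
#'   (`autosome` or `Z`), `resistant_allele` (`"ref"`/`"alt"`), `res_reads`,
#'   `sus_reads`, `pool_freq` (pooled resistant-allele read frequency).
#' @export
select_informative <- function(records, layout) {
  cls <- layout$chrom_class[match(records$chrom, layout$name)]
  if (anyNA(cls)) stop("record chromosome not in layout")
  keep <- records$gt_f1 %in% "0/1" &
    records$gt_dam %in% c("0/0", "1/1") &
    cls != "W"
  rec <- records[keep, , drop = FALSE]
  cls <- cls[keep]
  res_is_alt <- rec$gt_dam == "0/0"
  res_reads <- ifelse(res_is_alt, rec$pool_alt, rec$pool_ref)
  sus_reads <- ifelse(res_is_alt, rec$pool_ref, rec$pool_alt)
  depth <- res_reads + sus_reads
  zero <- is.na(depth) | depth == 0
  if (any(zero)) message(sum(zero), " informative site(s) dropped for zero pooled depth")
  tibble::tibble(
    chrom = rec$chrom, pos = rec$pos, chrom_class = cls,
    resistant_allele = ifelse(res_is_alt, "alt", "ref"),
    res_reads = res_reads, sus_reads = sus_reads,
    pool_freq = res_reads / depth
  )[!zero, , drop = FALSE]
}
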