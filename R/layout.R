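#' Define a genome layout for the cross simulator
#'
#' The layout is the coordinate frame for everything downstream: chromosome
#' names, lengths, sex-chromosome class, and per-chromosome male recombination
#' rates. Lepidopteran females are achiasmatic, so only the male rate exists.
#' Coordinates are 0-based half-open internally; VCF output is 1-based.
#'
#' @param name Character vector of unique chromosome names.
#' @param length_bp Integer vector of chromosome lengths in bp (> 0).
#' @param chrom_class One of `"autosome"`, `"Z"`, `"W"` per chromosome.
#'   Exactly one Z is required; at most one W is allowed.
#' @param male_rate_cM_Mb Male recombination rate in cM/Mb per chromosome
#'   (recycled if scalar). The W rate is ignored.
#'
#' @return A tibble of class `genome_layout` with columns `name`, `length_bp`,
#'   `chrom_class`, `male_rate_cM_Mb`.
#' @export
#' @examples
#' genome_layout(c("chr1", "chrZ"), c(10e6, 14e6), c("autosome", "Z"), 3)
genome_layout <- function(name, length_bp, chrom_class, male_rate_cM_Mb = 3) {
  stopifnot(length(name) == length(length_bp), length(name) == length(chrom_class))
  male_rate_cM_Mb <- rep_len(male_rate_cM_Mb, length(name))
  layout <- tibble::tibble(
    name = as.character(name),
    length_bp = as.numeric(length_bp),
    chrom_class = as.character(chrom_class),
    male_rate_cM_Mb = as.numeric(male_rate_cM_Mb)
  )
  validate_layout(layout)
  class(layout) <- c("genome_layout", class(layout))
  layout
}

validate_layout <- function(layout) {
  stopifnot(all(layout$length_bp > 0))
  if (anyDuplicated(layout$name)) stop("chromosome names must be unique")
  if (!all(layout$chrom_class %in% c("autosome", "Z", "W"))) {
    stop("chrom_class must be one of 'autosome', 'Z', 'W'")
  }
  if (sum(layout$chrom_class == "Z") != 1) stop("layout must contain exactly one Z")
  if (sum(layout$chrom_class == "W") > 1) stop("layout may contain at most one W")
  if (any(layout$male_rate_cM_Mb < 0)) stop("male recombination rates must be >= 0")
  invisible(layout)
}

#' Desk-scale default genome layout
#'
#' Two autosomes plus Z: a 17 Mb focal autosome modelled on the resistance
#' chromosome (the causal locus defaults to 15.75 Mb on it), a 14 Mb neutral
#' autosome, and a 14 Mb Z. A full 31-chromosome genome is supported by
#' [genome_layout()]; the small default keeps simulations fast while leaving
#' every rule of the analysis (Z correction, windowing, min-SNP filter)
#' exercised.
#'
#' @param male_rate_cM_Mb Male recombination rate in cM/Mb (default 3).
#' @param with_w Include a markerless W chromosome (default `FALSE`).
#' @return A `genome_layout`.
#' @export
default_layout <- function(male_rate_cM_Mb = 3, with_w = FALSE) {
  nm <- c("chr17", "chr05", "chrZ")
  ln <- c(17e6, 14e6, 14e6)
  cl <- c("autosome", "autosome", "Z")
  if (with_w) {
    nm <- c(nm, "chrW")
    ln <- c(ln, 10e6)
    cl <- c(cl, "W")
  }
  genome_layout(nm, ln, cl, male_rate_cM_Mb)
}

#' Place strain-diagnostic markers on a layout
#'
#' Markers stand in for the fixed SNP differences between two fully inbred
#' founder strains: at every marker the resistant founder is homozygous for
#' one allele and the susceptible founder for the other. Which founder
#' carries the reference base is randomised per site (`res_is_ref`), so both
#' dam-genotype branches of informative-SNP selection are exercised. No
#' markers are placed on the W.
#'
#' @param layout A [genome_layout()].
#' @param spacing_bp Distance between adjacent markers in bp (default 2000,
#'   giving well over 80 markers per 1 Mb window).
#' @return A tibble of class `marker_set`: `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `res_is_ref`.
#' @export
make_markers <- function(layout, spacing_bp = 2000) {
  validate_layout(layout)
  keep <- layout[layout$chrom_class != "W", , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  per_chrom <- lapply(seq_len(nrow(keep)), function(i) {
    pos <- seq(spacing_bp / 2, keep$length_bp[i] - 1, by = spacing_bp)
    n <- length(pos)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    tibble::tibble(
      chrom = keep$name[i], pos = floor(pos), ref = ref, alt = unname(alt),
      res_is_ref = sample(c(TRUE, FALSE), n, replace = TRUE)
    )
  })
  markers <- dplyr::bind_rows(per_chrom)
  class(markers) <- c("marker_set", class(markers))
  markers
}

validate_markers <- function(markers, layout) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "res_is_ref") %in% names(markers)))
  w_names <- layout$name[layout$chrom_class == "W"]
  if (any(markers$chrom %in% w_names)) stop("markers on the W chromosome are not allowed")
  if (!all(markers$chrom %in% layout$name)) stop("marker chromosome not in layout")
  for (cn in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == cn]
    if (is.unsorted(p, strictly = TRUE)) stop("marker positions must be strictly increasing")
    if (any(p < 0) || any(p >= layout$length_bp[layout$name == cn])) {
      stop("marker position outside chromosome")
    }
  }
  invisible(markers)
}

#' Single-locus resistance model
#'
#' Survival probabilities at a diagnostic insecticide dose, by genotype class
#' at one causal locus. The default models incompletely dominant resistance
#' scored at a dose lethal to susceptible homozygotes: SS dies, RS survives
#' with probability 0.8, RR always survives.
#'
#' @param chrom,pos Causal locus (0-based bp).
#' @param s_SS,s_RS,s_RR Survival probabilities in `[0, 1]`.
#' @return A list of class `resistance_model`.
#' @export
resistance_model <- function(chrom = "chr17", pos = 15.75e6,
                             s_SS = 0, s_RS = 0.8, s_RR = 1) {
  s <- c(SS = s_SS, RS = s_RS, RR = s_RR)
  if (any(s < 0 | s > 1)) stop("survival probabilities must be in [0, 1]")
  structure(list(chrom = chrom, pos = pos, survival = s), class = "resistance_model")
}

#' Sequencing specification for the pooled design
#'
#' Defaults follow the experimental design the simulator emulates: parents at
#' 30x, a 120-survivor pool at 240x (2x per individual), and a symmetric
#' per-read allele-flip error.
#'
#' @param pool_depth_mean Mean pooled depth per site (default 240).
#' @param parent_depth_mean Mean per-parent depth per site (default 30).
#' @param error_rate Per-read allele-flip probability (default 0.001).
#' @param pool_size Individuals pooled (default 120).
#' @return A list of class `seq_spec`.
#' @export
seq_spec <- function(pool_depth_mean = 240, parent_depth_mean = 30,
                     error_rate = 0.001, pool_size = 120) {
  stopifnot(pool_depth_mean > 0, parent_depth_mean > 0,
            error_rate >= 0, error_rate < 0.5, pool_size >= 1)
  structure(list(pool_depth_mean = pool_depth_mean,
                 parent_depth_mean = parent_depth_mean,
                 error_rate = error_rate, pool_size = pool_size),
            class = "seq_spec")
}
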