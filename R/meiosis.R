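#' Male meiosis with Haldane (no-interference) crossovers
#'
#' Crossovers occur only in males in Lepidoptera. Per chromosome the
#' crossover count is Poisson with mean equal to the genetic length in
#' Morgans (`length_Mb * male_rate / 100`), breakpoints are uniform along the
#' chromosome, and the two recombination products segregate with probability
#' 1/2 each. The gamete carries one product per autosome plus one Z copy.
#'
#' @param ind A male `individual`.
#' @param layout The [genome_layout()].
#' @return A gamete: named list of tracks with attributes `sex_chrom = "Z"`
#'   and `n_crossovers` (named integer vector, for model checking).
#' @export
meiosis_male <- function(ind, layout) {
  if (ind$sex != "male") stop("meiosis_male() requires a male individual")
  gamete <- list()
  n_co <- integer(0)
  for (i in seq_len(nrow(layout))) {
    cn <- layout$name[i]
    if (layout$chrom_class[i] == "W") next
    len <- layout$length_bp[i]
    morgans <- (len / 1e6) * layout$male_rate_cM_Mb[i] / 100
    k <- stats::rpois(1L, morgans)
    breaks <- sort(stats::runif(k, 0, len))
    first <- sample.int(2L, 1L)
    gamete[[cn]] <- recombine_tracks(ind$haplos[[cn]][[first]],
                                     ind$haplos[[cn]][[3L - first]],
                                     breaks)
    n_co[cn] <- k
  }
  attr(gamete, "sex_chrom") <- "Z"
  attr(gamete, "n_crossovers") <- n_co
  gamete
}

# Alternate between tracks a and b at the given breakpoints, starting on a.
recombine_tracks <- function(a, b, breaks) {
  if (length(breaks) == 0) return(a)
  len <- a$ends[length(a$ends)]
  cuts <- c(breaks, len)
  ends <- numeric(0)
  origins <- character(0)
  lo <- 0
  src <- list(a, b)
  cur <- 1L
  for (hi in cuts) {
    tr <- src[[cur]]
    # segments of tr overlapping [lo, hi)
    i1 <- findInterval(lo, tr$ends) + 1L
    i2 <- findInterval(hi, tr$ends, left.open = TRUE) + 1L
    seg_ends <- pmin(tr$ends[i1:i2], hi)
    ends <- c(ends, seg_ends)
    origins <- c(origins, tr$origins[i1:i2])
    lo <- hi
    cur <- 3L - cur
  }
  simplify_track(new_track(ends, origins))
}

#' Achiasmatic female meiosis
#'
#' Females transmit chromosomes intact: per autosome one of the two parental
#' haplotypes is copied without recombination (p = 1/2), and the gamete
#' carries either the intact Z or the W (p = 1/2), which determines offspring
#' sex.
#'
#' @param ind A female `individual`.
#' @param layout The [genome_layout()].
#' @return A gamete: named list of intact tracks (autosomes, plus Z when the
#'   gamete is Z-bearing) with attribute `sex_chrom` of `"Z"` or `"W"`.
#' @export
meiosis_female <- function(ind, layout) {
  if (ind$sex != "female") stop("meiosis_female() requires a female individual")
  gamete <- list()
  for (i in seq_len(nrow(layout))) {
    cn <- layout$name[i]
    cl <- layout$chrom_class[i]
    if (cl == "autosome") {
      gamete[[cn]] <- ind$haplos[[cn]][[sample.int(2L, 1L)]]
    }
  }
  z_name <- layout$name[layout$chrom_class == "Z"]
  sex_chrom <- if (stats::runif(1) < 0.5) "Z" else "W"
  if (sex_chrom == "Z") gamete[[z_name]] <- ind$haplos[[z_name]][[1L]]
  attr(gamete, "sex_chrom") <- sex_chrom
  gamete
}

fertilize <- function(male_gamete, female_gamete, layout) {
  z_name <- layout$name[layout$chrom_class == "Z"]
  sex <- if (attr(female_gamete, "sex_chrom") == "W") "female" else "male"
  haplos <- list()
  for (i in seq_len(nrow(layout))) {
    cn <- layout$name[i]
    cl <- layout$chrom_class[i]
    if (cl == "W") next
    if (cl == "autosome") {
      haplos[[cn]] <- list(male_gamete[[cn]], female_gamete[[cn]])
    } else if (sex == "male") {
      haplos[[cn]] <- list(male_gamete[[z_name]], female_gamete[[z_name]])
    } else {
      haplos[[cn]] <- list(male_gamete[[z_name]])
    }
  }
  new_individual(sex, haplos, layout)
}

#' Generate backcross progeny
#'
#' Crosses the F1 male to the susceptible dam. With the founders of
#' [make_founders()], autosomal markers segregate so that the
#' resistant-founder allele has expected frequency 1/4 over all chromosome
#' copies, and Z markers 1/3 (the F1 male's two Z copies are one resistant-
#' and one susceptible-origin; the dam contributes her susceptible Z to sons
#' and her W to daughters).
#'
#' @param f1_male A male `individual` (typically resistant dam x susceptible
#'   sire offspring).
#' @param susceptible_dam A female `individual`.
#' @param n Number of offspring (> 0).
#' @param layout The [genome_layout()].
#' @return List of `individual`s of length `n`.
#' @export
make_backcross <- function(f1_male, susceptible_dam, n, layout) {
  if (n <= 0) stop("n must be positive")
  if (f1_male$sex != "male") stop("f1_male must be male")
  if (susceptible_dam$sex != "female") stop("susceptible_dam must be female")
  lapply(seq_len(n), function(i) {
    fertilize(meiosis_male(f1_male, layout),
              meiosis_female(susceptible_dam, layout),
              layout)
  })
}

#' Make the F1 male of the mapping design
#'
#' @param founders Output of [make_founders()].
#' @param layout The [genome_layout()].
#' @return A male `individual` heterozygous (resistant/susceptible origin) at
#'   every marker, including on Z.
#' @export
make_f1_male <- function(founders, layout) {
  repeat {
    mg <- meiosis_male(founders$susceptible_sire, layout)
    fg <- meiosis_female(founders$resistant_dam, layout)
    if (attr(fg, "sex_chrom") == "Z") return(fertilize(mg, fg, layout))
  }
}

#' Select survivors of the diagnostic dose
#'
#' Each individual survives independently with the survival probability of
#' its genotype class at the causal locus (resistant-allele dose 0, 1, 2 maps
#' to SS, RS, RR; a hemizygous female Z locus uses its single copy's class).
#'
#' @param progeny List of `individual`s.
#' @param model A [resistance_model()].
#' @param layout The [genome_layout()].
#' @return The surviving subset, in original order.
#' @export
select_survivors <- function(progeny, model, layout) {
  row <- which(layout$name == model$chrom)
  if (length(row) != 1) stop("resistance locus chromosome not in layout")
  if (model$pos < 0 || model$pos >= layout$length_bp[row]) {
    stop("resistance locus outside its chromosome")
  }
  survives <- vapply(progeny, function(ind) {
    dose <- resistant_dose(ind, model$chrom, model$pos)
    n_copies <- length(ind$haplos[[model$chrom]])
    cls <- if (n_copies == 1L) {
      if (dose == 1L) "RS" else "SS"
    } else {
      c("SS", "RS", "RR")[dose + 1L]
    }
    stats::runif(1) < model$survival[[cls]]
  }, logical(1))
  progeny[survives]
}
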