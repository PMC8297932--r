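# Individuals are lists of haplotype "tracks": piecewise-constant founder
# origin along a chromosome, stored as segment end positions (0-based
# half-open, the last end equals the chromosome length) plus an origin label
# "R" (resistant founder) or "S" (susceptible founder) per segment. Founders
# are fully inbred, so origin determines the allele at every marker.

new_track <- function(ends, origins) {
  stopifnot(length(ends) == length(origins), !is.unsorted(ends, strictly = TRUE))
  list(ends = as.numeric(ends), origins = as.character(origins))
}

constant_track <- function(origin, length_bp) new_track(length_bp, origin)

#' @keywords internal
track_origin_at <- function(track, pos) {
  # segment index of each position: first end strictly greater than pos
  idx <- findInterval(pos, track$ends, left.open = FALSE) + 1L
  # findInterval counts ends <= pos; half-open segments [prev_end, end)
  track$origins[idx]
}

# collapse runs of identical origin labels
simplify_track <- function(track) {
  keep <- c(track$origins[-1] != track$origins[-length(track$origins)], TRUE)
  new_track(track$ends[keep], track$origins[keep])
}

tracks_identical <- function(a, b) {
  identical(simplify_track(a), simplify_track(b))
}

#' Construct an individual
#'
#' @param sex `"male"` or `"female"`.
#' @param haplos Named list (by chromosome) of lists of tracks: autosomes carry
#'   two tracks for both sexes; Z carries two in males and one in females.
#' @param layout The [genome_layout()] the individual lives on.
#' @return A list of class `individual`.
#' @keywords internal
new_individual <- function(sex, haplos, layout) {
  ind <- structure(list(sex = sex, haplos = haplos), class = "individual")
  validate_individual(ind, layout)
  ind
}

validate_individual <- function(ind, layout) {
  stopifnot(ind$sex %in% c("male", "female"))
  for (i in seq_len(nrow(layout))) {
    cn <- layout$name[i]
    cl <- layout$chrom_class[i]
    if (cl == "W") next  # W carried implicitly by females; no mapped markers
    n_copies <- length(ind$haplos[[cn]])
    expected <- if (cl == "Z" && ind$sex == "female") 1L else 2L
    if (n_copies != expected) {
      stop(sprintf("%s %s must carry %d cop%s of %s, found %d",
                   ind$sex, cl, expected, if (expected == 1) "y" else "ies",
                   cn, n_copies))
    }
    for (tr in ind$haplos[[cn]]) {
      if (tr$ends[length(tr$ends)] != layout$length_bp[i]) {
        stop("haplotype track does not span its chromosome")
      }
    }
  }
  invisible(ind)
}

#' Create the three founders of the backcross design
#'
#' A resistant dam and a susceptible sire found the F1 family; a second
#' susceptible dam is the backcross parent. Each founder is fully homozygous
#' for its strain's allele at every marker (the strains are inbred), with
#' sexes fixed by the design: the resistant parent is the F0 female.
#'
#' @param layout A [genome_layout()].
#' @param markers A [make_markers()] marker set (checked against the layout;
#'   markers on W are rejected).
#' @return A list with elements `resistant_dam`, `susceptible_sire`,
#'   `susceptible_dam`, each an `individual`.
#' @export
make_founders <- function(layout, markers) {
  validate_layout(layout)
  validate_markers(markers, layout)
  founder <- function(origin, sex) {
    haplos <- list()
    for (i in seq_len(nrow(layout))) {
      cn <- layout$name[i]
      cl <- layout$chrom_class[i]
      if (cl == "W") next
      n <- if (cl == "Z" && sex == "female") 1L else 2L
      haplos[[cn]] <- replicate(n, constant_track(origin, layout$length_bp[i]),
                                simplify = FALSE)
    }
    new_individual(sex, haplos, layout)
  }
  list(
    resistant_dam = founder("R", "female"),
    susceptible_sire = founder("S", "male"),
    susceptible_dam = founder("S", "female")
  )
}

#' Count resistant-origin copies carried by an individual at positions
#'
#' @param ind An `individual`.
#' @param chrom Chromosome name.
#' @param pos Numeric vector of 0-based positions.
#' @return Integer vector: number of copies (0..2, or 0..1 on a female Z)
#'   carrying the resistant-founder origin at each position.
#' @export
resistant_dose <- function(ind, chrom, pos) {
  tracks <- ind$haplos[[chrom]]
  if (is.null(tracks)) stop("chromosome not carried: ", chrom)
  out <- integer(length(pos))
  for (tr in tracks) out <- out + (track_origin_at(tr, pos) == "R")
  out
}
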