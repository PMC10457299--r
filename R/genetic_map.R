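#' Define a genetic map for simulation
#'
#' A genetic map names the chromosomes of the simulated genome, gives their
#' physical (bp) and genetic (centimorgan) lengths, and lists the physical
#' positions of the segregating SNP sites (the sites that are fixed-different
#' between the two parents and will appear in the simulated VCF). Physical
#' and genetic coordinates are related by linear interpolation, i.e. a
#' uniform recombination rate along each chromosome.
#'
#' @param chromosomes data.frame with columns `name`, `length_bp`,
#'   `length_cm`. One row per chromosome.
#' @param marker_sites named list (one element per chromosome, names matching
#'   `chromosomes$name`) of strictly increasing integer vectors of 1-based
#'   physical positions of segregating sites. Elements may be missing for
#'   chromosomes without markers.
#' @return An object of class `genetic_map`.
#' @examples
#' gm <- genetic_map(
#'   data.frame(name = "A09", length_bp = 5e6, length_cm = 60),
#'   list(A09 = c(1000L, 250000L, 4999000L))
#' )
#' @export
genetic_map <- function(chromosomes, marker_sites = list()) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "length_cm") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L)
    stop("genetic map must declare at least one chromosome")
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (any(chromosomes$length_bp <= 0))
    stop("chromosome physical lengths must be positive")
  if (any(chromosomes$length_cm < 0))
    stop("chromosome genetic lengths must be non-negative")
  chromosomes$name <- as.character(chromosomes$name)
  for (nm in names(marker_sites)) {
    if (!nm %in% chromosomes$name)
      stop("marker sites declared for unknown chromosome: ", nm)
    pos <- marker_sites[[nm]]
    if (length(pos)) {
      if (is.unsorted(pos, strictly = TRUE))
        stop("marker positions must be strictly increasing on ", nm)
      L <- chromosomes$length_bp[chromosomes$name == nm]
      if (pos[1] < 1 || pos[length(pos)] > L)
        stop("marker positions out of range on ", nm)
    }
  }
  structure(list(chromosomes = chromosomes, marker_sites = marker_sites),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  n_mark <- sum(vapply(x$marker_sites, length, integer(1)))
  cat("Genetic map:", nrow(x$chromosomes), "chromosome(s),",
      round(sum(x$chromosomes$length_bp) / 1e6, 2), "Mbp,",
      sum(x$chromosomes$length_cm), "cM,", n_mark, "marker site(s)\n")
  invisible(x)
}

#' Scatter segregating sites uniformly along a map
#'
#' Convenience generator of marker positions: `n_sites` per chromosome drawn
#' uniformly (without replacement at bp resolution) and sorted.
#'
#' @param map a `genetic_map` (marker sites, if any, are replaced).
#' @param n_sites integer, sites per chromosome (recycled across chromosomes).
#' @return The map with `marker_sites` filled in.
#' @export
scatter_marker_sites <- function(map, n_sites) {
  stopifnot(inherits(map, "genetic_map"), all(n_sites > 0))
  n_sites <- rep_len(as.integer(n_sites), nrow(map$chromosomes))
  sites <- lapply(seq_len(nrow(map$chromosomes)), function(i) {
    L <- map$chromosomes$length_bp[i]
    sort(sample.int(L, min(n_sites[i], L)))
  })
  names(sites) <- map$chromosomes$name
  map$marker_sites <- sites
  map
}
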