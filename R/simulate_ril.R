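#' Simulation configuration for a bulked RIL experiment
#'
#' Bundles the design parameters of the emulated experiment: a biparental
#' cross advanced by single-seed-descent selfing to essentially homozygous
#' recombinant inbred lines (RILs), phenotypic extreme bulks, and pooled
#' short-read sequencing of the bulks and parents. Defaults reproduce the
#' seed-colour study design: 188 RILs at the F2:11 generation (one F1 meiosis
#' followed by 10 rounds of selfing), bulks of 25 lines each, bulk depths of
#' about 44x and 41x.
#'
#' @param n_lines number of RILs (default 188).
#' @param n_selfing_generations selfing rounds after the F1 (default 10).
#' @param bulk_size lines per extreme bulk (default 25).
#' @param depth_high,depth_low mean sequencing depth (reads/site) of the
#'   high- and low-trait bulk (defaults 44 and 41).
#' @param parent_depth mean depth of each parent (default 30).
#' @param error_rate per-read probability of reporting the wrong allele
#'   (default 0.002); applied symmetrically to both alleles.
#' @param artifact_fraction fraction of sites drawn as alignment/caller
#'   artifacts whose site annotations violate one hard-filter rule
#'   (default 0).
#' @param seed root integer seed; per-stage child seeds (population, trait,
#'   reads) are derived from it so stages are independently reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 188, n_selfing_generations = 10,
                       bulk_size = 25, depth_high = 44, depth_low = 41,
                       parent_depth = 30, error_rate = 0.002,
                       artifact_fraction = 0, seed = 1L) {
  stopifnot(n_lines >= 2, n_selfing_generations >= 0,
            bulk_size >= 1, 2 * bulk_size <= n_lines,
            depth_high > 0, depth_low > 0, parent_depth > 0,
            error_rate >= 0, error_rate < 0.5,
            artifact_fraction >= 0, artifact_fraction <= 1)
  structure(list(n_lines = as.integer(n_lines),
                 n_selfing_generations = as.integer(n_selfing_generations),
                 bulk_size = as.integer(bulk_size),
                 depth_high = depth_high, depth_low = depth_low,
                 parent_depth = parent_depth, error_rate = error_rate,
                 artifact_fraction = artifact_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Derive independent child seeds from a root seed, one per named stage.
child_seeds <- function(seed, stages = c("population", "trait", "reads")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  setNames(s, stages)
}

# A haplotype is a mosaic of parental-origin segments along one chromosome:
# `ends` strictly increasing segment end positions (bp, last == chromosome
# length) and `origin` integer labels (0 = black/REF parent, 1 = yellow/ALT
# parent). Segment j covers (ends[j-1], ends[j]].

# Extract the sub-mosaic of `hap` on the interval (lo, hi].
.hap_slice <- function(ends, origin, lo, hi) {
  j1 <- findInterval(lo, ends) + 1L                   # first segment after lo
  j2 <- findInterval(hi, ends, left.open = TRUE) + 1L # segment containing hi
  e <- ends[j1:j2]
  e[length(e)] <- hi
  list(ends = e, origin = origin[j1:j2])
}

# Merge adjacent segments with equal origin.
.hap_simplify <- function(ends, origin) {
  if (length(origin) > 1L) {
    keep <- c(origin[-length(origin)] != origin[-1L], TRUE)
    ends <- ends[keep]; origin <- origin[keep]
  }
  list(ends = ends, origin = origin)
}

# One meiosis under the Haldane model: crossover count ~ Poisson(length in
# Morgans), positions uniform (in genetic distance, mapped linearly to bp),
# no interference. Returns a gamete haplotype.
.meiosis <- function(h1, h2, length_bp, length_cm) {
  n_xo <- rpois(1L, length_cm / 100)
  first <- sample.int(2L, 1L)
  if (n_xo == 0L) return(if (first == 1L) h1 else h2)
  xo <- sort(runif(n_xo)) * length_bp           # uniform in cM == linear in bp
  bounds <- c(0, xo, length_bp)
  ends <- numeric(0); origin <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    active <- if ((first + i) %% 2L == 0L) h1 else h2
    piece <- .hap_slice(active$ends, active$origin, bounds[i], bounds[i + 1L])
    ends <- c(ends, piece$ends); origin <- c(origin, piece$origin)
  }
  .hap_simplify(ends, origin)
}

#' Simulate a recombinant inbred line population
#'
#' Each line descends from the F1 of the black-seeded (REF) x yellow-seeded
#' (ALT) cross: the F1 carries one intact haplotype from each parent, and each
#' of `n_selfing_generations` rounds of self-fertilisation draws two
#' independent gametes from the current plant by Haldane meiosis (Poisson
#' crossover count, uniform positions, no interference). After g rounds the
#' expected per-locus residual heterozygosity is (1/2)^g.
#'
#' @param map a [genetic_map()].
#' @param config a [sim_config()]. Only `n_lines`, `n_selfing_generations`
#'   and the root `seed` are used here.
#' @return An object of class `ril_population`: a list with the `map`, the
#'   config, and `lines` — per line, per chromosome, the two homologous
#'   haplotype mosaics.
#' @export
simulate_ril_population <- function(map, config) {
  stopifnot(inherits(map, "genetic_map"), inherits(config, "sim_config"))
  set.seed(child_seeds(config$seed)[["population"]])
  chrs <- map$chromosomes
  lines <- vector("list", config$n_lines)
  for (l in seq_len(config$n_lines)) {
    plant <- lapply(seq_len(nrow(chrs)), function(i) {
      L <- chrs$length_bp[i]
      list(h1 = list(ends = L, origin = 0L),   # black parent homolog
           h2 = list(ends = L, origin = 1L))   # yellow parent homolog
    })
    for (g in seq_len(config$n_selfing_generations)) {
      plant <- lapply(seq_len(nrow(chrs)), function(i) {
        ch <- plant[[i]]
        list(h1 = .meiosis(ch$h1, ch$h2, chrs$length_bp[i], chrs$length_cm[i]),
             h2 = .meiosis(ch$h1, ch$h2, chrs$length_bp[i], chrs$length_cm[i]))
      })
    }
    names(plant) <- chrs$name
    lines[[l]] <- plant
  }
  structure(list(map = map, config = config, lines = lines),
            class = "ril_population")
}

#' @export
print.ril_population <- function(x, ...) {
  cat("RIL population:", length(x$lines), "lines,",
      nrow(x$map$chromosomes), "chromosome(s), F2:",
      x$config$n_selfing_generations + 1, " generation\n", sep = "")
  invisible(x)
}

# Origin of one haplotype at given positions (vectorised over positions).
.hap_origin_at <- function(hap, pos) {
  hap$origin[findInterval(pos, hap$ends, left.open = TRUE) + 1L]
}

#' Query line genotypes at physical positions
#'
#' Returns the yellow-parent (ALT) allele dosage, 0/1/2, for every line at
#' the given positions of one chromosome.
#'
#' @param pop a `ril_population`.
#' @param chrom chromosome name.
#' @param positions integer vector of 1-based bp positions.
#' @return integer matrix, lines x positions.
#' @export
ril_genotypes <- function(pop, chrom, positions) {
  stopifnot(inherits(pop, "ril_population"))
  if (!chrom %in% pop$map$chromosomes$name)
    stop("unknown chromosome: ", chrom)
  g <- vapply(pop$lines, function(line) {
    ch <- line[[chrom]]
    .hap_origin_at(ch$h1, positions) + .hap_origin_at(ch$h2, positions)
  }, integer(length(positions)))
  m <- if (length(positions) == 1L) matrix(g, nrow = 1L) else g
  t(m)
}

#' Residual heterozygosity of a RIL population
#'
#' Fraction of (line, site) pairs whose two homologs carry different parental
#' origins, measured at the map's marker sites (or supplied positions).
#'
#' @param pop a `ril_population`.
#' @return Proportion heterozygous, a single number.
#' @export
residual_heterozygosity <- function(pop) {
  tot <- 0; het <- 0
  for (chrom in pop$map$chromosomes$name) {
    pos <- pop$map$marker_sites[[chrom]]
    if (is.null(pos) || !length(pos)) next
    g <- ril_genotypes(pop, chrom, pos)
    het <- het + sum(g == 1L)
    tot <- tot + length(g)
  }
  if (tot == 0) stop("map carries no marker sites")
  het / tot
}
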