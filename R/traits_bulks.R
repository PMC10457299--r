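#' Declare a QTL effect
#'
#' A QTL is a position on a declared chromosome with an additive effect on
#' the trait. RIL genotypes at the locus are coded g = dosage - 1 in
#' {-1, 0, +1} (black homozygote, residual heterozygote, yellow homozygote),
#' and the locus contributes `additive_effect * g` to the trait. Instead of
#' an absolute effect you may give `variance_explained`, the target fraction
#' of phenotypic variance the locus should account for; the effect is then
#' sized as `env_sd * sqrt(ve / (1 - ve))` at trait-assignment time (RIL
#' genotypic variance at a segregating locus is ~1 on the -1/+1 coding).
#'
#' @param chromosome chromosome name.
#' @param position 1-based bp position.
#' @param additive_effect trait units per allele substitution, or `NA` to
#'   size the effect from `variance_explained`.
#' @param variance_explained target fraction of trait variance in [0, 1).
#' @return A one-row data.frame; rows from several calls can be `rbind`-ed.
#' @export
qtl_effect <- function(chromosome, position, additive_effect = NA_real_,
                       variance_explained = NA_real_) {
  if (is.na(additive_effect) && is.na(variance_explained))
    stop("give either additive_effect or variance_explained")
  if (!is.na(variance_explained) &&
      (variance_explained < 0 || variance_explained >= 1))
    stop("variance_explained must be in [0, 1)")
  data.frame(chromosome = as.character(chromosome),
             position = as.numeric(position),
             additive_effect = additive_effect,
             variance_explained = variance_explained)
}

#' Assign trait values to simulated RILs
#'
#' Trait = sum over QTLs of a_i * g_i + e, with g_i in {-1, 0, +1} the
#' centred yellow-allele dosage at QTL i and e ~ Normal(0, env_sd^2)
#' environmental noise. Positive effects make the yellow allele increase the
#' trait, so the high bulk is the yellow-enriched bulk.
#'
#' @param pop a `ril_population`.
#' @param qtls data.frame of [qtl_effect()] rows (may be empty or NULL for a
#'   null trait).
#' @param env_sd environmental standard deviation, trait units.
#' @param seed integer seed for the noise draw; defaults to the population
#'   config's trait child stream.
#' @return data.frame with columns `line`, `trait`, and one genotype column
#'   `g_<i>` per QTL; attribute `realized_r2` holds the squared correlation
#'   between each QTL genotype and the trait in this population.
#' @export
assign_trait_values <- function(pop, qtls, env_sd, seed = NULL) {
  stopifnot(inherits(pop, "ril_population"), env_sd >= 0)
  if (is.null(seed)) seed <- child_seeds(pop$config$seed)[["trait"]]
  set.seed(seed)
  n <- length(pop$lines)
  if (is.null(qtls)) qtls <- qtl_effect("x", 1, 0)[0, ]
  if (nrow(qtls)) {
    bad <- !qtls$chromosome %in% pop$map$chromosomes$name
    if (any(bad))
      stop("QTL on undeclared chromosome: ",
           paste(qtls$chromosome[bad], collapse = ", "))
    lens <- pop$map$chromosomes$length_bp[
      match(qtls$chromosome, pop$map$chromosomes$name)]
    if (any(qtls$position < 1 | qtls$position > lens))
      stop("QTL position outside its chromosome")
  }
  eff <- qtls$additive_effect
  need <- is.na(eff)
  if (any(need)) {
    if (env_sd <= 0)
      stop("variance_explained sizing requires env_sd > 0")
    ve <- qtls$variance_explained[need]
    eff[need] <- env_sd * sqrt(ve / (1 - ve))
  }
  G <- matrix(0L, nrow = n, ncol = nrow(qtls))
  for (i in seq_len(nrow(qtls)))
    G[, i] <- ril_genotypes(pop, qtls$chromosome[i], qtls$position[i])[, 1] - 1L
  trait <- as.numeric(G %*% eff) + rnorm(n, 0, env_sd)
  out <- data.frame(line = seq_len(n), trait = trait)
  if (nrow(qtls)) {
    colnames(G) <- paste0("g_", seq_len(nrow(qtls)))
    out <- cbind(out, as.data.frame(G))
    r2 <- vapply(seq_len(ncol(G)), function(i) {
      if (var(G[, i]) == 0 || var(trait) == 0) return(0)
      stats::cor(G[, i], trait)^2
    }, numeric(1))
    attr(out, "realized_r2") <- r2
  }
  out
}

#' Select the two phenotypic extreme bulks
#'
#' The k largest trait values form the high bulk and the k smallest the low
#' bulk. Ties at a bulk boundary are broken deterministically by the smaller
#' line identifier, so repeated runs give identical bulks.
#'
#' @param traits data.frame with columns `line` and `trait`
#'   (from [assign_trait_values()]).
#' @param k lines per bulk; `2 * k` must not exceed the population size.
#' @return `traits` with an added factor column `bulk` with levels
#'   `high`, `low`, `none`.
#' @export
select_extreme_bulks <- function(traits, k) {
  stopifnot(is.data.frame(traits), all(c("line", "trait") %in% names(traits)))
  n <- nrow(traits)
  if (2 * k > n) stop("2 * k exceeds the number of lines")
  hi <- order(-traits$trait, traits$line)[seq_len(k)]
  lo <- order(traits$trait, traits$line)[seq_len(k)]
  if (length(intersect(hi, lo)))
    stop("trait ties make the two bulks overlap; k is too large for this trait")
  traits$bulk <- factor(rep("none", n), levels = c("high", "low", "none"))
  traits$bulk[hi] <- "high"
  traits$bulk[lo] <- "low"
  traits
}
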