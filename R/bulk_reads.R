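# Pooled sequencing of the bulks: per site and sample, depth ~ Poisson(mean)
# and ALT reads ~ Binomial(depth, p(1-e) + (1-p)e) with p the true ALT-allele
# fraction among the pooled haplotypes and e the symmetric error rate.

# Disjoint value ranges for "clean" sites and filter-violating artifacts, so
# planted artifact counts are exactly recoverable by the hard filters.
.clean_ranges <- list(QD = c(10, 35), FS = c(0, 20), MQ = c(40, 60),
                      MQRankSum = c(-3, 3), ReadPosRankSum = c(-3, 3))
.artifact_ranges <- list(QD = c(0.1, 1.9), FS = c(61, 150), MQ = c(1, 19.9),
                         MQRankSum = c(-20, -12.6),
                         ReadPosRankSum = c(-15, -8.1))

.runif_range <- function(n, r) runif(n, r[1], r[2])

#' Sample pooled bulk and parent read counts at every marker site
#'
#' Emulates shotgun sequencing of equal-ratio pooled DNA from the two extreme
#' bulks plus the two parents. Every marker site is fixed-different between
#' the parents: the black parent carries the REF allele (it plays the
#' reference-genome role) and the yellow parent the ALT allele, so the ALT
#' read fraction in a bulk estimates the yellow-allele frequency among its
#' pooled haplotypes. Site quality annotations (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum) are drawn from a clean/artifact mixture with disjoint
#' ranges; `artifact_fraction` of sites violate exactly one hard-filter rule.
#'
#' @param pop a `ril_population`.
#' @param bulks data.frame from [select_extreme_bulks()] (columns `line`,
#'   `bulk`).
#' @param config the [sim_config()]; depths, error rate, artifact fraction
#'   and the reads child seed are taken from it.
#' @param seed optional override of the reads child seed.
#' @return data.frame, one row per marker site: chrom, pos, ref, alt,
#'   per-sample ref/alt read counts and depths (parent_black, parent_yellow,
#'   bulk_high, bulk_low), true ALT fractions `p_high`/`p_low`, the five
#'   site annotations, and logical `artifact`.
#' @export
sample_bulk_reads <- function(pop, bulks, config, seed = NULL) {
  stopifnot(inherits(pop, "ril_population"), inherits(config, "sim_config"))
  if (!"bulk" %in% names(bulks)) stop("bulks must carry a 'bulk' column")
  if (!any(bulks$bulk == "high") || !any(bulks$bulk == "low"))
    stop("both bulks must be assigned before sequencing")
  if (is.null(seed)) seed <- child_seeds(config$seed)[["reads"]]
  set.seed(seed)
  eps <- config$error_rate
  hi_lines <- bulks$line[bulks$bulk == "high"]
  lo_lines <- bulks$line[bulks$bulk == "low"]
  out <- vector("list", nrow(pop$map$chromosomes))
  for (ci in seq_len(nrow(pop$map$chromosomes))) {
    chrom <- pop$map$chromosomes$name[ci]
    pos <- pop$map$marker_sites[[chrom]]
    if (is.null(pos) || !length(pos)) next
    m <- length(pos)
    g <- ril_genotypes(pop, chrom, pos)
    gh <- g[hi_lines, , drop = FALSE]
    gl <- g[lo_lines, , drop = FALSE]
    p_hi <- colSums(gh) / (2 * length(hi_lines))
    p_lo <- colSums(gl) / (2 * length(lo_lines))
    samp <- function(p, mean_depth) {
      dp <- rpois(m, mean_depth)
      alt <- rbinom(m, dp, p * (1 - eps) + (1 - p) * eps)
      list(dp = dp, alt = alt)
    }
    bh <- samp(p_hi, config$depth_high)
    bl <- samp(p_lo, config$depth_low)
    pb <- samp(rep(0, m), config$parent_depth)
    py <- samp(rep(1, m), config$parent_depth)
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    artifact <- runif(m) < config$artifact_fraction
    ann <- as.data.frame(lapply(names(.clean_ranges), function(key)
      .runif_range(m, .clean_ranges[[key]])))
    names(ann) <- names(.clean_ranges)
    if (any(artifact)) {
      rule <- sample(names(.artifact_ranges), sum(artifact), replace = TRUE)
      for (key in names(.artifact_ranges)) {
        idx <- which(artifact)[rule == key]
        ann[[key]][idx] <- .runif_range(length(idx), .artifact_ranges[[key]])
      }
    }
    out[[ci]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      p_high = p_hi, p_low = p_lo,
      dp_parent_black = pb$dp, alt_parent_black = pb$alt,
      dp_parent_yellow = py$dp, alt_parent_yellow = py$alt,
      dp_bulk_high = bh$dp, alt_bulk_high = bh$alt,
      dp_bulk_low = bl$dp, alt_bulk_low = bl$alt,
      ann, artifact = artifact)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.vcf_sample_field <- function(dp, alt_reads, truth_gt = NULL) {
  ref_reads <- dp - alt_reads
  gt <- if (!is.null(truth_gt)) rep(truth_gt, length(dp)) else
    ifelse(alt_reads == 0L, "0/0", ifelse(ref_reads == 0L, "1/1", "0/1"))
  gt[dp == 0L] <- "./."
  paste0(gt, ":", ref_reads, ",", alt_reads, ":", dp)
}

#' Write simulated bulk read counts as a VCF
#'
#' Emits an uncompressed VCF v4.2 with samples ordered
#' `parent_black, parent_yellow, bulk_high, bulk_low`, FORMAT `GT:AD:DP`, and
#' the five site-quality annotations in INFO. Parents are written with their
#' true homozygous genotypes (0/0 and 1/1); bulk genotypes are naive calls
#' from the pooled read counts (pools are not diploid individuals, and only
#' AD/DP are used downstream). Identical inputs produce byte-identical files.
#'
#' @param reads data.frame from [sample_bulk_reads()].
#' @param map the `genetic_map` (for contig header lines).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(reads, map, path) {
  stopifnot(is.data.frame(reads), inherits(map, "genetic_map"))
  info_keys <- names(.clean_ranges)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkscan",
    sprintf("##contig=<ID=%s,length=%d>", map$chromosomes$name,
            as.integer(map$chromosomes$length_bp)),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            info_keys, c("Quality by depth", "Fisher strand bias (phred)",
                         "RMS mapping quality", "Mapping quality rank sum",
                         "Read position rank sum")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "parent_black", "parent_yellow", "bulk_high", "bulk_low",
          sep = "\t"))
  info <- sprintf("QD=%.2f;FS=%.2f;MQ=%.2f;MQRankSum=%.2f;ReadPosRankSum=%.2f",
                  reads$QD, reads$FS, reads$MQ, reads$MQRankSum,
                  reads$ReadPosRankSum)
  body <- paste(reads$chrom, as.integer(reads$pos), ".", reads$ref, reads$alt,
                ".", ".", info, "GT:AD:DP",
                .vcf_sample_field(reads$dp_parent_black, reads$alt_parent_black, "0/0"),
                .vcf_sample_field(reads$dp_parent_yellow, reads$alt_parent_yellow, "1/1"),
                .vcf_sample_field(reads$dp_bulk_high, reads$alt_bulk_high),
                .vcf_sample_field(reads$dp_bulk_low, reads$alt_bulk_low),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a complete bulked-segregant experiment
#'
#' Convenience wrapper chaining [simulate_ril_population()],
#' [assign_trait_values()], [select_extreme_bulks()] and
#' [sample_bulk_reads()], optionally writing the VCF and a plain-text truth
#' sidecar (line, trait, bulk, QTL genotypes). All randomness flows from
#' `config$seed` through per-stage child streams.
#'
#' @param map a [genetic_map()] with marker sites.
#' @param config a [sim_config()].
#' @param qtls data.frame of [qtl_effect()] rows, or NULL for a null genome.
#' @param env_sd environmental standard deviation of the trait.
#' @param vcf optional path: write the simulated VCF here.
#' @param truth optional path: write the truth table here (TSV).
#' @return list with `pop`, `traits` (incl. bulk assignment), `reads`, and
#'   the paths written (if any).
#' @export
simulate_qtlseq_experiment <- function(map, config, qtls = NULL, env_sd = 1,
                                       vcf = NULL, truth = NULL) {
  pop <- simulate_ril_population(map, config)
  traits <- assign_trait_values(pop, qtls, env_sd)
  traits <- select_extreme_bulks(traits, config$bulk_size)
  reads <- sample_bulk_reads(pop, traits, config)
  if (!is.null(vcf)) write_bulk_vcf(reads, map, vcf)
  if (!is.null(truth))
    write.table(traits, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(pop = pop, traits = traits, reads = reads,
       vcf = vcf, truth = truth, qtls = qtls)
}
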