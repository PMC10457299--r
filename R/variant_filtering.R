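#' Read a four-sample bulked-segregant VCF
#'
#' Parses a VCF holding the two parents and the two bulks into a flat
#' variant table. Only bi-allelic records are kept; multi-allelic records
#' are dropped with a message (SNP-index is defined for a single ALT allele
#' in a biparental design). Site annotations absent from INFO are recorded
#' as `NA`, never as 0.
#'
#' @param path VCF file (plain or gzipped).
#' @param roles named character vector mapping the four analysis roles to
#'   sample names in the VCF; defaults match [write_bulk_vcf()] output.
#'   `parent_ref` is the parent whose genome is the alignment reference
#'   (black-seeded ZY821 in the seed-colour design), `parent_alt` the other
#'   parent; `bulk_high`/`bulk_low` the two extreme pools.
#' @return data.frame with one row per bi-allelic record: `chrom`, `pos`,
#'   `ref`, `alt`, `class` (snp/insertion/deletion), the five site
#'   annotations (`QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`), and per
#'   role `gt_<role>`, `ad_ref_<role>`, `ad_alt_<role>`, `dp_<role>`.
#' @export
read_bulk_variants <- function(path,
                               roles = c(parent_ref = "parent_black",
                                         parent_alt = "parent_yellow",
                                         bulk_high = "bulk_high",
                                         bulk_low = "bulk_low")) {
  need <- c("parent_ref", "parent_alt", "bulk_high", "bulk_low")
  if (!all(need %in% names(roles)))
    stop("roles must name: ", paste(need, collapse = ", "))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(roles[need], samples)
  if (length(missing))
    stop("VCF lacks sample(s) for declared roles: ",
         paste(missing, collapse = ", "))
  fix <- v@fix
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message("dropped ", sum(multi), " multi-allelic record(s)")
  keep <- !multi & !is.na(fix[, "ALT"]) & fix[, "ALT"] != "."
  v <- v[keep, ]
  fix <- v@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  cls <- ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1L, "snp",
                ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  out <- data.frame(chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = ref, alt = alt, class = cls)
  for (key in c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"))
    out[[key]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = key)))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP")
  for (role in need) {
    s <- roles[[role]]
    out[[paste0("gt_", role)]] <- unname(gt[, s])
    adr <- strsplit(ifelse(is.na(ad[, s]), "NA,NA", ad[, s]), ",", fixed = TRUE)
    out[[paste0("ad_ref_", role)]] <-
      suppressWarnings(as.integer(vapply(adr, `[`, character(1), 1L)))
    out[[paste0("ad_alt_", role)]] <-
      suppressWarnings(as.integer(vapply(adr, `[`, character(1), 2L)))
    out[[paste0("dp_", role)]] <- suppressWarnings(as.integer(dp[, s]))
  }
  ord <- order(out$chrom, out$pos)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Site-quality hard filter
#'
#' Removes records whose caller annotations indicate likely artifacts,
#' using the GATK-style rule: QD < 2.0, FS > 60.0, MQ < 20.0,
#' MQRankSum < -12.5 or ReadPosRankSum < -8.0. Inequalities are strict, so
#' boundary values pass; annotations absent from a record never cause
#' removal (rank-sum statistics are undefined at homozygous-only sites).
#'
#' @param variants variant table from [read_bulk_variants()].
#' @param thresholds named list overriding any of the five defaults.
#' @return data.frame with logical `kept` and character `reasons`
#'   (comma-separated identifiers of the violated rules, "" when kept).
#' @export
site_quality_filter <- function(variants,
                                thresholds = list(QD = 2.0, FS = 60.0,
                                                  MQ = 20.0,
                                                  MQRankSum = -12.5,
                                                  ReadPosRankSum = -8.0)) {
  th <- utils::modifyList(list(QD = 2.0, FS = 60.0, MQ = 20.0,
                               MQRankSum = -12.5, ReadPosRankSum = -8.0),
                          as.list(thresholds))
  n <- nrow(variants)
  fail <- cbind(
    QD = !is.na(variants$QD) & variants$QD < th$QD,
    FS = !is.na(variants$FS) & variants$FS > th$FS,
    MQ = !is.na(variants$MQ) & variants$MQ < th$MQ,
    MQRankSum = !is.na(variants$MQRankSum) & variants$MQRankSum < th$MQRankSum,
    ReadPosRankSum = !is.na(variants$ReadPosRankSum) &
      variants$ReadPosRankSum < th$ReadPosRankSum)
  reasons <- apply(fail, 1L, function(f)
    paste(colnames(fail)[f], collapse = ","))
  data.frame(kept = !apply(fail, 1L, any), reasons = reasons)
}

.is_hom_ref <- function(gt) !is.na(gt) & gt %in% c("0/0", "0|0")
.is_hom_alt <- function(gt) !is.na(gt) & gt %in% c("1/1", "1|1")
.gt_missing <- function(gt) is.na(gt) | gt %in% c("./.", ".", ".|.")

#' Bulk-genotyping filter
#'
#' The three criteria for an analysis-ready biparental bulk site:
#' (1) sequencing depth of each bulk and each parent is at least `min_depth`
#' (default 5); (2) the two parents are homozygous for different genotypes;
#' (3) the reference-role parent's genotype matches the reference genome
#' (homozygous REF). Depth uses the DP field when present, else the sum of
#' allele depths.
#'
#' Removal reasons: `depth`, `parent_missing`, `parent_heterozygous`,
#' `parent_identical`, `reference_mismatch`.
#'
#' @param variants variant table from [read_bulk_variants()].
#' @param min_depth minimum per-sample depth (default 5).
#' @return data.frame with logical `kept` and character `reasons`.
#' @export
bulk_genotyping_filter <- function(variants, min_depth = 5) {
  depth_of <- function(role) {
    dp <- variants[[paste0("dp_", role)]]
    adsum <- variants[[paste0("ad_ref_", role)]] +
      variants[[paste0("ad_alt_", role)]]
    ifelse(is.na(dp), adsum, dp)
  }
  roles <- c("parent_ref", "parent_alt", "bulk_high", "bulk_low")
  dps <- vapply(roles, depth_of, numeric(nrow(variants)))
  if (nrow(variants) == 1L) dps <- matrix(dps, nrow = 1L)
  fail_depth <- apply(is.na(dps) | dps < min_depth, 1L, any)
  gt_r <- variants$gt_parent_ref
  gt_a <- variants$gt_parent_alt
  miss <- .gt_missing(gt_r) | .gt_missing(gt_a)
  hom_r <- .is_hom_ref(gt_r) | .is_hom_alt(gt_r)
  hom_a <- .is_hom_ref(gt_a) | .is_hom_alt(gt_a)
  het <- !miss & (!hom_r | !hom_a)
  identical_gt <- !miss & hom_r & hom_a &
    (.is_hom_ref(gt_r) == .is_hom_ref(gt_a))
  ref_mismatch <- !miss & hom_r & !.is_hom_ref(gt_r)
  reasons <- character(nrow(variants))
  add <- function(reasons, flag, tag)
    ifelse(flag, ifelse(reasons == "", tag, paste(reasons, tag, sep = ",")),
           reasons)
  reasons <- add(reasons, fail_depth, "depth")
  reasons <- add(reasons, miss, "parent_missing")
  reasons <- add(reasons, het, "parent_heterozygous")
  reasons <- add(reasons, identical_gt, "parent_identical")
  reasons <- add(reasons, ref_mismatch, "reference_mismatch")
  data.frame(kept = reasons == "", reasons = reasons)
}

#' Apply both filters and tally removals
#'
#' Runs [site_quality_filter()] and [bulk_genotyping_filter()] (both
#' per-record predicates, so the kept set is order-independent) and returns
#' the analysis-ready variant table together with per-rule removal counts.
#'
#' @param variants variant table from [read_bulk_variants()].
#' @param thresholds passed to [site_quality_filter()].
#' @param min_depth passed to [bulk_genotyping_filter()].
#' @return list with `variants` (kept rows), `outcomes` (per input record:
#'   `kept`, `reasons`), and `summary` (data.frame rule/count).
#' @export
filter_variants <- function(variants,
                            thresholds = list(),
                            min_depth = 5) {
  q <- site_quality_filter(variants, thresholds)
  g <- bulk_genotyping_filter(variants, min_depth)
  reasons <- ifelse(q$reasons == "", g$reasons,
                    ifelse(g$reasons == "", q$reasons,
                           paste(q$reasons, g$reasons, sep = ",")))
  kept <- q$kept & g$kept
  tally <- table(unlist(strsplit(reasons[reasons != ""], ",", fixed = TRUE)))
  summary <- data.frame(rule = names(tally),
                        removed = as.integer(tally), row.names = NULL)
  list(variants = variants[kept, , drop = FALSE],
       outcomes = data.frame(kept = kept, reasons = reasons),
       summary = summary)
}

#' Re-emit a variant table as VCF with FILTER populated
#'
#' Writes the input records back to an uncompressed VCF, with the FILTER
#' column set to `PASS` for kept records and the semicolon-joined removal
#' reasons otherwise. Intended for audit trails of the filtering stage.
#'
#' @param variants variant table from [read_bulk_variants()].
#' @param outcomes outcomes data.frame from [filter_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filtered_vcf <- function(variants, outcomes, path) {
  stopifnot(nrow(variants) == nrow(outcomes))
  filt <- ifelse(outcomes$kept, "PASS",
                 gsub(",", ";", outcomes$reasons, fixed = TRUE))
  fmt_num <- function(x) ifelse(is.na(x), NA, sprintf("%.2f", x))
  info_parts <- mapply(function(qd, fs, mq, mqr, rpr) {
    kv <- c(QD = qd, FS = fs, MQ = mq, MQRankSum = mqr, ReadPosRankSum = rpr)
    kv <- kv[!is.na(kv)]
    if (!length(kv)) "." else paste(names(kv), kv, sep = "=", collapse = ";")
  }, fmt_num(variants$QD), fmt_num(variants$FS), fmt_num(variants$MQ),
     fmt_num(variants$MQRankSum), fmt_num(variants$ReadPosRankSum))
  samp <- function(role) {
    gt <- variants[[paste0("gt_", role)]]
    gt[is.na(gt)] <- "./."
    paste0(gt, ":",
           variants[[paste0("ad_ref_", role)]], ",",
           variants[[paste0("ad_alt_", role)]], ":",
           variants[[paste0("dp_", role)]])
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bulkscan filter",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "parent_black", "parent_yellow",
                 "bulk_high", "bulk_low", sep = "\t"))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", filt, info_parts, "GT:AD:DP",
                samp("parent_ref"), samp("parent_alt"),
                samp("bulk_high"), samp("bulk_low"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
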