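#' Run the full QTL-seq pipeline on a VCF
#'
#' End-to-end orchestration: read the four-sample VCF, apply the
#' site-quality and bulk-genotyping filters, optionally annotate against
#' gene models, compute the SNP-index profile, simulate null bands, call
#' candidate regions, and write every stage's artifact plus a machine-
#' readable run manifest to `out_dir`. Identical inputs, parameters and
#' seed produce byte-identical outputs.
#'
#' Artifacts written: `filtered.vcf` (FILTER column populated),
#' `filter_summary.tsv`, `snp_index.tsv`, `windows.tsv` (chrom, start, end,
#' n_snps, mean_delta, cutoffs), `regions.tsv` (chromosome, region start/end
#' in Mbp, peak delta SNP-index, peak difference value, peak window
#' start/end in Mbp), `regions.bed`, `annotation.tsv` (if `gff` given),
#' `scan.png` (if `plot`), `manifest.json`.
#'
#' @param vcf input VCF path.
#' @param out_dir output directory (created if missing).
#' @param roles sample-role mapping for [read_bulk_variants()].
#' @param gff optional GFF3 of gene models for annotation.
#' @param genome optional chromosome sequences for SNP codon effects.
#' @param thresholds,min_depth filter parameters.
#' @param window,step,min_snps,bulk_size,n_rep,levels,site_linkage,call_level,two_sided
#'   scan parameters (see [qtlseq_scan()]).
#' @param seed seed for the null simulation.
#' @param plot write the per-chromosome profile figure (default TRUE).
#' @return Invisibly, a list with the scan object, the filter result, the
#'   annotation (or NULL) and the manifest.
#' @export
run_qtlseq_pipeline <- function(vcf, out_dir,
                                roles = c(parent_ref = "parent_black",
                                          parent_alt = "parent_yellow",
                                          bulk_high = "bulk_high",
                                          bulk_low = "bulk_low"),
                                gff = NULL, genome = NULL,
                                thresholds = list(), min_depth = 5,
                                window = 1e6, step = 1e4, min_snps = 10,
                                bulk_size = 25, n_rep = 1e5,
                                levels = c(0.95, 0.99),
                                site_linkage = c("complete", "independent"),
                                call_level = 0.99,
                                two_sided = FALSE, seed = 1L, plot = TRUE) {
  site_linkage <- match.arg(site_linkage)
  if (!file.exists(vcf)) stop("input VCF not found: ", vcf)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name) {
    write.table(d, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    nrow(d)
  }
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  counts <- list()
  variants <- stage("read", read_bulk_variants(vcf, roles))
  counts$records_read <- nrow(variants)
  filt <- stage("filter", filter_variants(variants, thresholds, min_depth))
  counts$records_kept <- nrow(filt$variants)
  write_filtered_vcf(variants, filt$outcomes, file.path(out_dir, "filtered.vcf"))
  counts$filter_summary_rows <- tsv(filt$summary, "filter_summary.tsv")
  ann <- NULL
  if (!is.null(gff)) {
    models <- stage("annotate", read_gene_models(gff))
    ann <- annotate_variants(filt$variants, models, genome)
    counts$annotation_rows <- tsv(ann, "annotation.tsv")
  }
  scan <- stage("scan", qtlseq_scan(filt$variants, window = window,
                                    step = step, min_snps = min_snps,
                                    bulk_size = bulk_size, n_rep = n_rep,
                                    levels = levels,
                                    site_linkage = site_linkage,
                                    call_level = call_level,
                                    two_sided = two_sided, seed = seed))
  counts$snp_index_rows <- tsv(scan$points, "snp_index.tsv")
  counts$window_rows <- tsv(scan$windows, "windows.tsv")
  r <- scan$regions
  region_table <- data.frame(
    chromosome = r$chrom,
    region_start_mbp = round(r$start / 1e6, 2),
    region_end_mbp = round(r$end / 1e6, 2),
    peak_delta_snp_index = round(r$peak_delta, 3),
    peak_difference_value = round(r$peak_difference, 3),
    peak_window_start_mbp = round(r$peak_start / 1e6, 2),
    peak_window_end_mbp = round(r$peak_end / 1e6, 2))
  counts$region_rows <- tsv(region_table, "regions.tsv")
  bed <- data.frame(chrom = r$chrom, start = as.integer(r$start) - 1L,
                    end = as.integer(r$end))
  write.table(bed, file.path(out_dir, "regions.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (plot) {
    png(file.path(out_dir, "scan.png"), width = 900,
        height = max(300, 220 * length(unique(scan$windows$chrom))))
    plot(scan)
    dev.off()
  }
  manifest <- list(
    input = list(vcf = vcf, gff = gff,
                 vcf_md5 = unname(tools::md5sum(vcf))),
    parameters = list(roles = as.list(roles), min_depth = min_depth,
                      thresholds = thresholds, window = window, step = step,
                      min_snps = min_snps, bulk_size = bulk_size,
                      n_rep = n_rep, levels = levels,
                      site_linkage = site_linkage,
                      call_level = call_level, two_sided = two_sided,
                      seed = seed),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scan = scan, filter = filt, annotation = ann,
                 manifest = manifest))
}
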