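#' Genome scan for QTL by bulked-segregant sequencing
#'
#' The central fitting function: from filtered variants (or a precomputed
#' SNP-index table) it computes the sliding-window delta(SNP-index) profile,
#' simulates the null confidence bands at the requested levels, and calls
#' candidate regions. Returns a classed object with print, summary and plot
#' methods.
#'
#' @param x a filtered variant table (from [filter_variants()]) or a
#'   `snp_index` table (from [compute_snp_index()]).
#' @param window,step,min_snps sliding-window parameters
#'   (defaults 1 Mbp, 10 kbp, 10); see [sliding_window_profile()].
#' @param bulk_size lines per bulk for the null model (default 25).
#' @param n_rep null-band Monte-Carlo replicates (default 1e5).
#' @param levels confidence levels for the bands (default 0.95, 0.99).
#' @param site_linkage within-window linkage model for the null band,
#'   `"complete"` (default) or `"independent"`; see [simulate_null_band()].
#' @param call_level level used for region calling (default 0.99).
#' @param two_sided call regions on |mean delta| (default FALSE).
#' @param seed seed for the null simulation.
#' @return An object of class `qtlseq_scan` with components `points`,
#'   `profile`, `band`, `windows` (profile plus cutoffs), `regions`, and
#'   the call parameters.
#' @examples
#' \donttest{
#' set.seed(1)
#' gm <- scatter_marker_sites(
#'   genetic_map(data.frame(name = "A09", length_bp = 6e6, length_cm = 60)),
#'   600)
#' cfg <- sim_config(n_lines = 100, bulk_size = 20, seed = 7)
#' vcf <- tempfile(fileext = ".vcf")
#' simulate_qtlseq_experiment(
#'   gm, cfg, qtl_effect("A09", 3e6, variance_explained = 0.5),
#'   env_sd = 1, vcf = vcf)
#' v <- filter_variants(read_bulk_variants(vcf))$variants
#' scan <- qtlseq_scan(v, window = 1e6, step = 2e5, min_snps = 10,
#'                     bulk_size = 20, n_rep = 2000, seed = 7)
#' summary(scan)
#' }
#' @export
qtlseq_scan <- function(x, window = 1e6, step = 1e4, min_snps = 10,
                        bulk_size = 25, n_rep = 1e5,
                        levels = c(0.95, 0.99),
                        site_linkage = c("complete", "independent"),
                        call_level = 0.99, two_sided = FALSE, seed = NULL) {
  site_linkage <- match.arg(site_linkage)
  points <- if (inherits(x, "snp_index")) x else compute_snp_index(x)
  profile <- sliding_window_profile(points, window, step, min_snps)
  band <- simulate_null_band(profile, bulk_size = bulk_size, n_rep = n_rep,
                             levels = levels, site_linkage = site_linkage,
                             seed = seed)
  regions <- call_candidate_regions(profile, band, level = call_level,
                                    two_sided = two_sided)
  windows <- cbind(profile$windows, as.data.frame(band))
  structure(list(points = points, profile = profile, band = band,
                 windows = windows, regions = regions,
                 params = list(window = window, step = step,
                               min_snps = min_snps, bulk_size = bulk_size,
                               n_rep = n_rep, levels = levels,
                               site_linkage = site_linkage,
                               call_level = call_level,
                               two_sided = two_sided, seed = seed)),
            class = "qtlseq_scan")
}

#' @export
print.qtlseq_scan <- function(x, ...) {
  cat("QTL-seq scan\n")
  cat("  sites:  ", nrow(x$points), "\n")
  cat("  windows:", nrow(x$windows), " (", x$params$window / 1e6,
      "Mbp, step ", x$params$step / 1e3, "kbp, >=", x$params$min_snps,
      " SNPs)\n", sep = "")
  cat("  regions:", nrow(x$regions), "at the",
      x$params$call_level * 100, "% level\n")
  invisible(x)
}

#' @export
summary.qtlseq_scan <- function(object, ...) {
  span <- summarize_regions(
    data.frame(chrom = object$regions$chrom,
               start = object$regions$start / 1e6,
               end = object$regions$end / 1e6))
  structure(list(scan = object, regions = object$regions, span_mbp = span),
            class = "summary.qtlseq_scan")
}

#' @export
print.summary.qtlseq_scan <- function(x, ...) {
  print(x$scan)
  if (nrow(x$regions)) {
    cat("\nCandidate regions (Mbp):\n")
    r <- x$regions
    print(data.frame(chrom = r$chrom,
                     start = round(r$start / 1e6, 2),
                     end = round(r$end / 1e6, 2),
                     peak_delta = round(r$peak_delta, 3),
                     peak_difference = round(r$peak_difference, 3),
                     peak_start = round(r$peak_start / 1e6, 2),
                     peak_end = round(r$peak_end / 1e6, 2)))
    cat("\nTotal span:", x$span_mbp$total, "Mbp\n")
  } else cat("\nNo candidate regions called.\n")
  invisible(x)
}

#' Plot a QTL-seq scan
#'
#' One panel per chromosome: the window mean delta(SNP-index) profile (red)
#' with the symmetric null bands (green for the 99 percent level, pink for
#' 95) and called regions shaded. Axes are in Mbp.
#'
#' @param x a `qtlseq_scan`.
#' @param col_delta,col_99,col_95,col_region line/shade colours.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.qtlseq_scan <- function(x, col_delta = "red", col_99 = "darkgreen",
                             col_95 = "pink3", col_region = "#fee08b", ...) {
  w <- x$windows
  if (!nrow(w)) {
    warning("no emitted windows; nothing to plot")
    plot.new(); title("QTL-seq scan: no windows")
    return(invisible(x))
  }
  chroms <- unique(w$chrom)
  levels <- x$params$levels
  cut95 <- if (0.95 %in% levels) .cutoff_column(x$band, 0.95)
  cut99 <- if (0.99 %in% levels) .cutoff_column(x$band, 0.99)
  old <- par(mfrow = c(length(chroms), 1),
             mar = c(2.5, 4, 1.5, 1), oma = c(2, 0, 2, 0))
  on.exit(par(old))
  for (chrom in chroms) {
    i <- which(w$chrom == chrom)
    mid <- (w$start[i] + w$end[i]) / 2 / 1e6
    plot.new()
    plot.window(xlim = range(mid), ylim = c(-1, 1))
    axis(1); axis(2); box()
    title(ylab = expression(Delta * "(SNP-index)"))
    mtext(chrom, side = 3, line = 0.2, cex = 0.9)
    r <- x$regions[x$regions$chrom == chrom, , drop = FALSE]
    if (nrow(r))
      rect(r$start / 1e6, -1, r$end / 1e6, 1, col = col_region, border = NA)
    abline(h = 0, col = "grey70")
    if (!is.null(cut95)) {
      lines(mid, cut95[i], col = col_95)
      lines(mid, -cut95[i], col = col_95)
    }
    if (!is.null(cut99)) {
      lines(mid, cut99[i], col = col_99)
      lines(mid, -cut99[i], col = col_99)
    }
    lines(mid, w$mean_delta[i], col = col_delta)
  }
  mtext("position (Mbp)", side = 1, outer = TRUE, line = 0.5)
  invisible(x)
}
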