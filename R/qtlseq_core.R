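#' Per-site SNP-index and delta(SNP-index)
#'
#' The SNP-index of a bulk at a site is the fraction of its reads carrying
#' the ALT (yellow-parent) allele: 0 = fixed reference, 1 = fixed alternate,
#' ~0.5 at loci unlinked to the trait. Delta(SNP-index) is
#' index(high bulk) - index(low bulk); with the black parent as reference
#' the causal-locus signal is positive. Sites where either bulk has zero
#' allele-depth reads are skipped with a message.
#'
#' @param variants filtered variant table (from [filter_variants()];
#'   needs the bulk `ad_*` columns).
#' @return data.frame of class `snp_index`: `chrom`, `pos`, `index_high`,
#'   `index_low`, `delta`, `depth_high`, `depth_low` (allele-depth totals).
#' @export
compute_snp_index <- function(variants) {
  th <- variants$ad_ref_bulk_high + variants$ad_alt_bulk_high
  tl <- variants$ad_ref_bulk_low + variants$ad_alt_bulk_low
  bad <- is.na(th) | is.na(tl) | th == 0 | tl == 0
  if (any(bad))
    message("skipped ", sum(bad), " site(s) with zero allele depth in a bulk")
  v <- variants[!bad, , drop = FALSE]
  out <- data.frame(
    chrom = v$chrom, pos = v$pos,
    index_high = v$ad_alt_bulk_high / th[!bad],
    index_low = v$ad_alt_bulk_low / tl[!bad],
    depth_high = th[!bad], depth_low = tl[!bad])
  out$delta <- out$index_high - out$index_low
  rownames(out) <- NULL
  class(out) <- c("snp_index", "data.frame")
  out
}

#' Sliding-window profile of delta(SNP-index)
#'
#' Windows of width `window` are anchored at positions 1, 1+step, 1+2*step,
#' ... along each chromosome; a site at position p belongs to every window
#' `[a, a + window)` with a <= p < a + window. Windows holding fewer than
#' `min_snps` sites are skipped. The window statistic is the unweighted mean
#' of the member deltas.
#'
#' @param points a `snp_index` table ([compute_snp_index()]).
#' @param window window width, bp (default 1e6).
#' @param step window increment, bp (default 1e4); must satisfy
#'   0 < step <= window.
#' @param min_snps minimum member sites for a window to be emitted
#'   (default 10).
#' @return An object of class `window_profile`: list with `windows`
#'   (data.frame chrom, start, end, n_snps, mean_delta), `members` (per
#'   window, integer indices into `points`), `points`, and the parameters.
#' @export
sliding_window_profile <- function(points, window = 1e6, step = 1e4,
                                   min_snps = 10) {
  if (window <= 0 || step <= 0 || step > window)
    stop("need 0 < step <= window")
  points <- points[order(points$chrom, points$pos), , drop = FALSE]
  rownames(points) <- NULL
  res <- list(); members <- list()
  for (chrom in unique(points$chrom)) {
    idx <- which(points$chrom == chrom)
    pos <- points$pos[idx]
    cs <- cumsum(points$delta[idx])
    anchors <- seq(1, max(pos), by = step)
    # member sites of [a, a+window): positions a .. a+window-1
    lo <- findInterval(anchors - 1L, pos) + 1L
    hi <- findInterval(anchors + window - 1L, pos)
    n <- hi - lo + 1L
    keep <- which(n >= min_snps)
    if (!length(keep)) next
    cs0 <- c(0, cs)
    mean_delta <- (cs0[hi[keep] + 1L] - cs0[lo[keep]]) / n[keep]
    res[[chrom]] <- data.frame(chrom = chrom, start = anchors[keep],
                               end = anchors[keep] + window,
                               n_snps = n[keep], mean_delta = mean_delta)
    members <- c(members,
                 lapply(keep, function(w) idx[lo[w]:hi[w]]))
  }
  windows <- do.call(rbind, res)
  if (is.null(windows))
    windows <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), n_snps = integer(),
                          mean_delta = numeric())
  rownames(windows) <- NULL
  structure(list(windows = windows, members = members, points = points,
                 window = window, step = step, min_snps = min_snps),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat("Sliding-window profile:", nrow(x$windows), "window(s) (",
      x$window / 1e6, "Mbp wide, step", x$step / 1e3, "kbp, >=",
      x$min_snps, "SNPs) over", nrow(x$points), "site(s)\n")
  invisible(x)
}

#' Null confidence bands for window mean delta(SNP-index)
#'
#' Simulates, for every emitted window, the distribution of the window mean
#' delta under the null hypothesis of no QTL, conditioned on the observed
#' read depths: per replicate and member site each bulk draws its count of
#' ALT-carrying lines ~ Binomial(bulk_size, 1/2) (RILs homozygous; residual
#' heterozygosity < 0.1 percent at F2:11 is ignored), then ALT reads
#' ~ Binomial(observed depth, count/bulk_size). Cutoffs are nearest-rank
#' empirical percentiles of |window mean delta|, computed two-sided so the
#' band is symmetric. Windows sharing the same multiset of depth pairs
#' reuse one set of draws.
#'
#' `site_linkage` sets how the line draw relates to a window's member
#' sites. The default `"complete"` draws one line configuration per bulk
#' per replicate, shared by all member sites: a 1-Mbp window spans only a
#' few centimorgans in a typical crop map, so in the pooled RILs its sites
#' segregate essentially as one block, and this tight-linkage limit
#' reproduces the window-mean null variance (and the ~0.36-0.45 cutoff
#' scale seen at ~40x depth). `"independent"` redraws the line
#' configuration at every site, appropriate only when member sites are
#' effectively unlinked; for multi-site windows it yields much smaller
#' cutoffs. The two coincide for single-SNP windows.
#'
#' @param profile a [sliding_window_profile()] object.
#' @param bulk_size lines per bulk (default 25).
#' @param n_rep Monte-Carlo replicates (default 1e5).
#' @param levels confidence levels (default 0.95 and 0.99).
#' @param site_linkage `"complete"` (default) or `"independent"`; see
#'   Details.
#' @param seed optional seed for reproducible bands.
#' @return An object of class `null_band`: data.frame with one row per
#'   window and one `cutoff_<level>` column per level; attributes `n_rep`,
#'   `levels`.
#' @export
simulate_null_band <- function(profile, bulk_size = 25, n_rep = 1e5,
                               levels = c(0.95, 0.99),
                               site_linkage = c("complete", "independent"),
                               seed = NULL) {
  site_linkage <- match.arg(site_linkage)
  stopifnot(inherits(profile, "window_profile"))
  if (bulk_size <= 0) stop("bulk_size must be positive")
  if (!is.null(seed)) set.seed(seed)
  nw <- nrow(profile$windows)
  cuts <- matrix(NA_real_, nw, length(levels))
  cache <- new.env(parent = emptyenv())
  for (w in seq_len(nw)) {
    i <- profile$members[[w]]
    dh <- as.integer(profile$points$depth_high[i])
    dl <- as.integer(profile$points$depth_low[i])
    if (any(is.na(dh)) || any(is.na(dl)) || any(dh <= 0) || any(dl <= 0))
      stop("window ", w, " lacks valid depth information")
    o <- order(dh, dl)
    key <- paste(dh[o], dl[o], sep = ",", collapse = ";")
    if (is.null(cache[[key]])) {
      d <- null_window_deltas(dh, dl, as.integer(bulk_size),
                              as.integer(n_rep),
                              site_linkage == "complete")
      cache[[key]] <- unname(quantile(abs(d), levels, type = 1))
    }
    cuts[w, ] <- cache[[key]]
  }
  out <- as.data.frame(cuts)
  names(out) <- paste0("cutoff_", sub("^0\\.", "", format(levels)))
  structure(out, n_rep = n_rep, levels = levels, bulk_size = bulk_size,
            site_linkage = site_linkage,
            class = c("null_band", "data.frame"))
}

.cutoff_column <- function(band, level) {
  levels <- attr(band, "levels")
  j <- match(level, levels)
  if (is.na(j)) stop("level ", level, " not among the band's levels (",
                     paste(levels, collapse = ", "), ")")
  band[[j]]
}

#' Call candidate QTL regions
#'
#' A window is significant when its mean delta exceeds its null cutoff at
#' the chosen level (positive exceedance by default: with the black parent
#' as reference the causal configuration drives delta positive; set
#' `two_sided = TRUE` to call |mean delta| exceedance). Maximal runs of
#' consecutive significant emitted windows merge into one region spanning
#' the first window's start to the last window's end; skipped low-SNP
#' windows inside a run do not break it. Peak statistics come from the
#' member window with the largest mean delta.
#'
#' @param profile a [sliding_window_profile()].
#' @param band the matching [simulate_null_band()].
#' @param level confidence level for calling (default 0.99); must be one of
#'   the band's levels.
#' @param two_sided call on |mean delta| instead of positive exceedance.
#' @return data.frame of class `candidate_regions`: chrom, start, end,
#'   peak_delta, peak_threshold, peak_difference, peak_start, peak_end,
#'   n_windows.
#' @export
call_candidate_regions <- function(profile, band, level = 0.99,
                                   two_sided = FALSE) {
  stopifnot(inherits(profile, "window_profile"))
  w <- profile$windows
  if (nrow(w) != nrow(band)) stop("band does not match the profile")
  cut <- .cutoff_column(band, level)
  stat <- if (two_sided) abs(w$mean_delta) else w$mean_delta
  sig <- stat > cut
  regions <- list()
  for (chrom in unique(w$chrom)) {
    i <- which(w$chrom == chrom)
    i <- i[order(w$start[i])]
    run <- integer(0)
    flush <- function(run) {
      if (!length(run)) return(NULL)
      peak <- run[which.max(w$mean_delta[run])]
      data.frame(chrom = chrom,
                 start = w$start[run[1]], end = w$end[run[length(run)]],
                 peak_delta = w$mean_delta[peak],
                 peak_threshold = cut[peak],
                 peak_difference = w$mean_delta[peak] - cut[peak],
                 peak_start = w$start[peak], peak_end = w$end[peak],
                 n_windows = length(run))
    }
    for (j in i) {
      if (sig[j]) run <- c(run, j)
      else { regions <- c(regions, list(flush(run))); run <- integer(0) }
    }
    regions <- c(regions, list(flush(run)))
  }
  out <- do.call(rbind, regions)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peak_delta = numeric(), peak_threshold = numeric(),
                      peak_difference = numeric(), peak_start = numeric(),
                      peak_end = numeric(), n_windows = integer())
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Summarize candidate-region spans
#'
#' Total and per-chromosome span of a set of non-overlapping regions, in
#' the coordinate units of the input (bp for pipeline output, Mbp for
#' published region tables). Totals are reported to 2 decimals when the
#' input is in Mbp-scale units.
#'
#' @param regions data.frame with `chrom` (or `chromosome`), `start`, `end`.
#' @param digits decimals for the report (default 2).
#' @return list with `total` span and `per_chromosome` data.frame (chrom,
#'   span, n_regions), sorted by decreasing span.
#' @export
summarize_regions <- function(regions, digits = 2) {
  if (!nrow(regions))
    return(list(total = 0,
                per_chromosome = data.frame(chrom = character(),
                                            span = numeric(),
                                            n_regions = integer())))
  chrom <- if ("chrom" %in% names(regions)) regions$chrom else
    regions$chromosome
  if (any(regions$end < regions$start)) stop("region end before start")
  for (ch in unique(chrom)) {
    r <- regions[chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop("overlapping regions on ", ch, "; merge before summarizing")
  }
  width <- regions$end - regions$start
  per <- stats::aggregate(width, list(chrom = chrom), sum)
  names(per)[2] <- "span"
  per$n_regions <- as.integer(table(chrom)[per$chrom])
  per <- per[order(-per$span), ]
  per$span <- round(per$span, digits)
  rownames(per) <- NULL
  list(total = round(sum(width), digits), per_chromosome = per)
}
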