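#' Chi-square goodness-of-fit for a segregation ratio
#'
#' Tests observed phenotype class counts against an expected Mendelian
#' ratio (e.g. 1:3 yellow:black for a single recessive locus in an F2).
#' The statistic is sum((O - E)^2 / E) with E = total * ratio / sum(ratio),
#' df = classes - 1, and an upper-tail chi-square p-value. The ratio is
#' scale-invariant (1:3 and 2:6 are equivalent). A Yates continuity
#' correction is available for two classes and off by default.
#'
#' @param observed non-negative integer class counts.
#' @param ratio positive expected weights, same length as `observed`
#'   (default `c(1, 3)`).
#' @param correct apply the Yates correction (two classes only).
#' @return An object of class `htest`.
#' @examples
#' chi_square_gof(c(121, 292), c(1, 3))
#' @export
chi_square_gof <- function(observed, ratio = c(1, 3), correct = FALSE) {
  stopifnot(length(observed) == length(ratio), all(observed >= 0),
            sum(observed) > 0)
  if (any(ratio <= 0)) stop("expected ratio weights must be positive")
  expected <- sum(observed) * ratio / sum(ratio)
  dev <- abs(observed - expected)
  if (correct) {
    if (length(observed) != 2)
      stop("Yates correction applies to two classes only")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- length(observed) - 1
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df),
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 method = paste0("Chi-square goodness-of-fit (ratio ",
                                 paste(ratio, collapse = ":"),
                                 if (correct) ", Yates-corrected" else "",
                                 ")"),
                 data.name = deparse(substitute(observed)),
                 observed = observed, expected = expected),
            class = "htest")
}

#' Width of a physical interval
#'
#' @param start,end interval bounds in Mbp (vectorised); `end >= start`.
#' @param digits report precision (default 2 decimals).
#' @return Widths `end - start`, rounded.
#' @examples
#' interval_width(44.10, 45.19)  # 1.09
#' @export
interval_width <- function(start, end, digits = 2) {
  if (any(end < start)) stop("interval end before start")
  round(end - start, digits)
}

#' Span and mean adjacent spacing of a marker map
#'
#' @param positions centimorgan coordinates of >= 2 markers on one linkage
#'   group (any order).
#' @param digits report precision (default 2 decimals).
#' @return list with `n_markers`, `span_cm` (max - min) and
#'   `mean_spacing_cm` (span / (n - 1), the standard mean adjacent-marker
#'   distance).
#' @examples
#' marker_map_summary(seq(0, 76.30, length.out = 195))
#' @export
marker_map_summary <- function(positions, digits = 2) {
  if (length(positions) < 2) stop("need at least two markers")
  positions <- sort(positions)
  span <- max(positions) - min(positions)
  list(n_markers = length(positions),
       span_cm = round(span, digits),
       mean_spacing_cm = round(span / (length(positions) - 1), digits))
}
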