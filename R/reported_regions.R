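#' Reported candidate QTL regions for seed coat colour
#'
#' The eleven candidate regions called at the P < 0.01 level by the QTL-seq
#' scan of the GH06 (yellow-seeded) x ZY821 (black-seeded) B. napus RIL
#' bulks, aligned to the ZY821 genome. `peak_difference` is the peak
#' window's delta(SNP-index) minus its P < 0.01 threshold. The major locus
#' is the second ChrA09 region (peak delta 0.857 in the 44.19-45.19 Mbp
#' window); the remaining regions are minor. Useful as input for
#' [summarize_regions()] and as a reference shape for simulated scans.
#'
#' @return data.frame with columns `chromosome`, `start` and `end` (Mbp),
#'   `peak_delta`, `peak_difference`, `peak_start`, `peak_end` (Mbp).
#' @examples
#' summarize_regions(seed_color_candidate_regions())
#' @export
seed_color_candidate_regions <- function() {
  data.frame(
    chromosome = c("ChrA03", "ChrA03", "ChrA03", "ChrA03", "ChrA05",
                   "ChrA05", "ChrA05", "ChrA09", "ChrA09", "ChrA10",
                   "ChrC08"),
    start = c(28.99, 30.76, 32.57, 35.84, 9.08, 11.86, 17.26, 22.78, 32.70,
              18.86, 40.89),
    end = c(30.32, 31.80, 33.87, 37.91, 10.19, 16.38, 18.28, 31.00, 48.81,
            20.91, 44.18),
    peak_delta = c(0.363, 0.368, 0.388, 0.390, 0.446, 0.374, 0.384, 0.444,
                   0.857, 0.471, 0.472),
    peak_difference = c(0.002, 0.003, 0.031, 0.037, 0.087, 0.008, 0.024,
                        0.092, 0.497, 0.103, 0.112),
    peak_start = c(29.14, 30.76, 32.84, 36.18, 9.08, 12.14, 17.26, 25.97,
                   44.19, 19.91, 41.26),
    peak_end = c(30.23, 31.76, 33.87, 37.18, 10.08, 13.14, 18.27, 26.98,
                 45.19, 20.91, 42.26))
}
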