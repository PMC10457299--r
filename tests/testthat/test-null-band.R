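single_site_profile <- function(dh, dl) {
  pts <- data.frame(chrom = "c1", pos = 500L, index_high = 0.5,
                    index_low = 0.5, depth_high = dh, depth_low = dl,
                    delta = 0)
  class(pts) <- c("snp_index", "data.frame")
  sliding_window_profile(pts, window = 1000, step = 1000, min_snps = 1)
}

test_that("single-SNP-window cutoffs match a high-replicate two-stage binomial oracle", {
  # depths near the study's ~40x give the statistic a fine support, so the
  # 99th percentile is stable to Monte-Carlo error
  prof <- single_site_profile(41L, 38L)
  band <- simulate_null_band(prof, bulk_size = 25, n_rep = 1e5, seed = 101)
  set.seed(202)
  oracle <- r_null_window_deltas(41L, 38L, 25, 1e6)
  q_or <- unname(quantile(abs(oracle), c(0.95, 0.99), type = 1))
  expect_equal(band$cutoff_95[1], q_or[1], tolerance = 0.012)
  expect_equal(band$cutoff_99[1], q_or[2], tolerance = 0.012)
  # and the shared/independent models coincide for single-site windows
  band_i <- simulate_null_band(prof, bulk_size = 25, n_rep = 1e5,
                               site_linkage = "independent", seed = 101)
  expect_equal(band_i$cutoff_99[1], band$cutoff_99[1], tolerance = 1e-8)
})

test_that("multi-site window cutoffs match the vectorised R oracle in both linkage models", {
  set.seed(55)
  dh <- rpois(30, 40); dl <- rpois(30, 40)
  pts <- data.frame(chrom = "c1",
                    pos = as.integer(seq(1000, 30000, by = 1000)),
                    index_high = 0.5, index_low = 0.5,
                    depth_high = dh, depth_low = dl, delta = 0)
  class(pts) <- c("snp_index", "data.frame")
  prof <- sliding_window_profile(pts, window = 1e5, step = 1e5, min_snps = 10)
  expect_equal(nrow(prof$windows), 1)
  for (mode in c("complete", "independent")) {
    band <- simulate_null_band(prof, bulk_size = 25, n_rep = 4e4,
                               site_linkage = mode, seed = 66)
    set.seed(77)
    oracle <- r_null_window_deltas(dh, dl, 25, 4e4,
                                   shared = (mode == "complete"))
    q_or <- unname(quantile(abs(oracle), 0.99, type = 1))
    sd_or <- sd(oracle)
    # agreement within a few Monte-Carlo standard errors of a 99th pctile
    expect_lt(abs(band$cutoff_99[1] - q_or), 0.1 * sd_or + 4e-3)
  }
})

test_that("cutoffs shrink with depth and vanish in the degenerate limit", {
  shallow <- simulate_null_band(single_site_profile(10L, 10L),
                                bulk_size = 25, n_rep = 2e4, seed = 1)
  deep <- simulate_null_band(single_site_profile(100L, 100L),
                             bulk_size = 25, n_rep = 2e4, seed = 1)
  expect_lte(deep$cutoff_99[1], shallow$cutoff_99[1])
  expect_lte(deep$cutoff_95[1], shallow$cutoff_95[1])
  # degenerate-variance limit: with k and depth both 10^4 the statistic's
  # sd is 0.01, so the symmetric bands collapse towards zero
  # (2.58 sd ~ 0.026 at the 99% level, 1.96 sd < 0.02 at 95%)
  huge <- simulate_null_band(single_site_profile(10000L, 10000L),
                             bulk_size = 10000, n_rep = 2e4, seed = 1)
  expect_lt(huge$cutoff_95[1], 0.02)
  expect_lt(huge$cutoff_99[1], 0.03)
})

test_that("cutoff_95 <= cutoff_99 and both lie in [0, 1]", {
  set.seed(88)
  pts <- data.frame(chrom = "c1", pos = sort(sample.int(2e6, 200)),
                    index_high = 0.5, index_low = 0.5,
                    depth_high = rpois(200, 40) + 1L,
                    depth_low = rpois(200, 40) + 1L, delta = 0)
  class(pts) <- c("snp_index", "data.frame")
  prof <- sliding_window_profile(pts, 1e6, 5e5, 10)
  band <- simulate_null_band(prof, bulk_size = 25, n_rep = 3000, seed = 8)
  expect_true(all(band$cutoff_95 <= band$cutoff_99))
  expect_true(all(band$cutoff_95 >= 0 & band$cutoff_99 <= 1))
})

test_that("windows with identical depth multisets share cached draws", {
  pts <- data.frame(chrom = c("c1", "c1", "c2", "c2"),
                    pos = c(100L, 200L, 150L, 250L),
                    index_high = 0.5, index_low = 0.5,
                    depth_high = c(20L, 30L, 30L, 20L),
                    depth_low = c(10L, 15L, 15L, 10L), delta = 0)
  class(pts) <- c("snp_index", "data.frame")
  prof <- sliding_window_profile(pts, 1000, 1000, 2)
  expect_equal(nrow(prof$windows), 2)
  band <- simulate_null_band(prof, bulk_size = 25, n_rep = 2000, seed = 3)
  expect_identical(band$cutoff_99[1], band$cutoff_99[2])
  expect_identical(band$cutoff_95[1], band$cutoff_95[2])
})

test_that("band simulation is reproducible and validates inputs", {
  prof <- single_site_profile(10L, 10L)
  b1 <- simulate_null_band(prof, bulk_size = 25, n_rep = 5000, seed = 9)
  b2 <- simulate_null_band(prof, bulk_size = 25, n_rep = 5000, seed = 9)
  expect_identical(b1$cutoff_99, b2$cutoff_99)
  expect_error(simulate_null_band(prof, bulk_size = 0), "positive")
})
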