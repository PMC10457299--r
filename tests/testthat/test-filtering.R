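# Minimal hand-written VCF text for edge cases the simulator does not emit.
write_test_vcf <- function(records) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "parent_black", "parent_yellow",
                 "bulk_high", "bulk_low", sep = "\t"))
  writeLines(c(hdr, records), path)
  path
}

rec <- function(pos, info = "QD=20;FS=5;MQ=50;MQRankSum=0;ReadPosRankSum=0",
                pb = "0/0:20,0:20", py = "1/1:0,20:20",
                bh = "0/1:10,10:20", bl = "0/1:10,10:20",
                ref = "A", alt = "T") {
  paste("c1", pos, ".", ref, alt, ".", ".", info, "GT:AD:DP",
        pb, py, bh, bl, sep = "\t")
}

test_that("quality thresholds are strict and absent annotations pass", {
  vcf <- write_test_vcf(c(
    rec(100, "QD=1.9;FS=5;MQ=50;MQRankSum=0;ReadPosRankSum=0"),
    rec(200, "QD=2.0;FS=60.0;MQ=20.0;MQRankSum=-12.5;ReadPosRankSum=-8.0"),
    rec(300, "QD=20;FS=5;MQ=50"),
    rec(400, "QD=20;FS=61;MQ=19;MQRankSum=0;ReadPosRankSum=0")))
  v <- read_bulk_variants(vcf)
  out <- site_quality_filter(v)
  expect_equal(out$kept, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$reasons[1], "QD")
  expect_equal(out$reasons[4], "FS,MQ")
  # absence is NA, not zero
  expect_true(is.na(v$MQRankSum[3]))
})

test_that("the three bulk-genotyping criteria remove the right records", {
  vcf <- write_test_vcf(c(
    rec(100),                                         # clean
    rec(200, bl = "0/1:2,2:4"),                       # bulk_low depth 4
    rec(300, py = "0/1:10,10:20"),                    # parent het
    rec(400, pb = "1/1:0,20:20", py = "0/0:20,0:20"), # parents swapped
    rec(500, py = "./.:.:20"),                        # missing parent call
    rec(600, py = "0/0:20,0:20")))                    # parents identical
  v <- read_bulk_variants(vcf)
  out <- bulk_genotyping_filter(v)
  expect_equal(out$kept, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reasons[2], "depth")
  expect_equal(out$reasons[3], "parent_heterozygous")
  expect_equal(out$reasons[4], "reference_mismatch")
  expect_equal(out$reasons[5], "parent_missing")
  expect_equal(out$reasons[6], "parent_identical")
})

test_that("multi-allelic records are dropped on read", {
  vcf <- write_test_vcf(c(rec(100), rec(200, alt = "T,G"), rec(300)))
  expect_message(v <- read_bulk_variants(vcf), "1 multi-allelic")
  expect_equal(v$pos, c(100L, 300L))
})

test_that("missing sample roles are rejected", {
  vcf <- write_test_vcf(rec(100))
  expect_error(read_bulk_variants(vcf, roles = c(parent_ref = "nope",
                                                 parent_alt = "parent_yellow",
                                                 bulk_high = "bulk_high",
                                                 bulk_low = "bulk_low")),
               "lacks sample")
  expect_error(read_bulk_variants(vcf, roles = c(parent_ref = "parent_black")),
               "roles must name")
})

test_that("planted artifacts are recovered exactly and removals carry reasons", {
  gm <- genetic_map(data.frame(name = "c1", length_bp = 5e6, length_cm = 100))
  set.seed(31)
  gm <- scatter_marker_sites(gm, 1000)
  cfg <- sim_config(n_lines = 60, bulk_size = 25, seed = 31,
                    artifact_fraction = 0.15, depth_high = 40,
                    depth_low = 40, parent_depth = 40)
  sim <- simulate_qtlseq_experiment(gm, cfg, qtls = NULL, env_sd = 1,
                                    vcf = vcf <- tempfile(fileext = ".vcf"))
  v <- read_bulk_variants(vcf)
  q <- site_quality_filter(v)
  expect_equal(sum(!q$kept), sum(sim$reads$artifact))
  expect_identical(which(!q$kept), which(sim$reads$artifact))
  f <- filter_variants(v)
  expect_true(all(f$outcomes$reasons[!f$outcomes$kept] != ""))
  expect_gte(sum(f$summary$removed), sum(!f$outcomes$kept))
})

test_that("the kept set is independent of filter order", {
  vcf <- write_test_vcf(c(
    rec(100), rec(200, "QD=1;FS=5;MQ=50", bl = "0/1:2,2:4"),
    rec(300, py = "0/1:10,10:20"), rec(400, "QD=0.5;FS=70;MQ=10")))
  v <- read_bulk_variants(vcf)
  kept_qg <- site_quality_filter(v)$kept & bulk_genotyping_filter(v)$kept
  kept_gq <- bulk_genotyping_filter(v)$kept & site_quality_filter(v)$kept
  expect_identical(kept_qg, kept_gq)
  expect_identical(filter_variants(v)$outcomes$kept, kept_qg)
})

test_that("filtered VCF re-emission carries PASS / reason FILTER values", {
  vcf <- write_test_vcf(c(rec(100), rec(200, "QD=1.9;FS=5;MQ=50")))
  v <- read_bulk_variants(vcf)
  f <- filter_variants(v)
  out <- tempfile(fileext = ".vcf")
  write_filtered_vcf(v, f$outcomes, out)
  lines <- grep("^[^#]", readLines(out), value = TRUE)
  expect_match(lines[1], "\tPASS\t")
  expect_match(lines[2], "\tQD\t")
})
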