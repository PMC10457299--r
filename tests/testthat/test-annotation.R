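test_that("genomic context follows the strand-aware 1-kb flank rules", {
  gene <- make_synthetic_gene(strand = "+", seed = 11)
  models <- read_gene_models(gene$gff)
  expect_length(models, 1)
  variants <- data.frame(
    chrom = gene$chrom,
    pos = c(gene$tx_start - 500,        # upstream (plus strand)
            gene$tx_start - 1000,       # still upstream (inclusive edge)
            gene$tx_start - 1001,       # beyond the flank
            gene$tx_start - 1500,       # intergenic
            gene$cds[1, 1] + 3,         # CDS
            gene$tx_start + 5,          # 5' UTR (exon, not CDS)
            gene$cds[1, 2] + 10,        # intron
            gene$tx_end + 400,          # downstream
            gene$tx_end + 1500))        # intergenic
  ctx <- classify_genomic_context(variants, models)
  expect_equal(ctx$context,
               c("upstream", "upstream", "intergenic", "intergenic", "CDS",
                 "UTR", "intron", "downstream", "intergenic"))
  expect_equal(ctx$gene_id[5], "gene1")
  expect_true(is.na(ctx$gene_id[4]))
})

test_that("minus-strand flanks are mirrored", {
  gene <- make_synthetic_gene(strand = "-", seed = 12)
  models <- read_gene_models(gene$gff)
  variants <- data.frame(chrom = gene$chrom,
                         pos = c(gene$tx_end + 500, gene$tx_start - 500))
  ctx <- classify_genomic_context(variants, models)
  expect_equal(ctx$context, c("upstream", "downstream"))
})

test_that("variants on chromosomes without models warn and fall to intergenic", {
  gene <- make_synthetic_gene(seed = 13)
  models <- read_gene_models(gene$gff)
  expect_warning(
    ctx <- classify_genomic_context(data.frame(chrom = "chrZ", pos = 100),
                                    models),
    "chrZ")
  expect_equal(ctx$context, "intergenic")
})

test_that("every variant gets exactly one context and tallies sum to n", {
  gene <- make_synthetic_gene(seed = 14)
  models <- read_gene_models(gene$gff)
  set.seed(14)
  variants <- data.frame(chrom = gene$chrom,
                         pos = sample.int(9000, 300),
                         ref = "A", alt = "C", class = "snp")
  ann <- annotate_variants(variants, models, gene$genome)
  s <- annotation_summary(ann)
  expect_equal(sum(s$context), 300)
  expect_equal(sum(s$context_pct), 100, tolerance = 0.01)
})

test_that("SNP effects match a full-ORF translation oracle on both strands", {
  for (strand in c("+", "-")) {
    gene <- make_synthetic_gene(strand = strand, n_codons = 60,
                                seed = if (strand == "+") 21 else 22)
    models <- read_gene_models(gene$gff)
    model <- models[[1]]
    cds_positions <- unlist(lapply(1:2, function(j)
      gene$cds[j, 1]:gene$cds[j, 2]))
    set.seed(33)
    test_pos <- sample(cds_positions, 150, replace = FALSE)
    for (pos in test_pos) {
      ref <- substr(gene$genome[[gene$chrom]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- classify_snp_effect(gene$chrom, pos, ref, alt, model,
                                 gene$genome)
      want <- oracle_snp_effect(gene, pos, alt)
      expect_equal(got, want,
                   label = sprintf("effect at %s:%d %s>%s (%s strand)",
                                   gene$chrom, pos, ref, alt, strand))
    }
  }
})

test_that("third-position changes in 4-fold degenerate codons are synonymous", {
  # GC_ codons all encode alanine
  for (b in c("A", "C", "G", "T"))
    expect_equal(Biostrings::GENETIC_CODE[[paste0("GC", b)]], "A")
  gene <- make_synthetic_gene(strand = "+", n_codons = 40, seed = 41)
  # plant an alanine codon at codon 5 of the spliced CDS (inside exon 1)
  g <- gene$genome[[gene$chrom]]
  codon_start <- gene$cds[1, 1] + 12
  substr(g, codon_start, codon_start + 2) <- "GCA"
  gene$genome[[gene$chrom]] <- g
  model <- read_gene_models(gene$gff)[[1]]
  for (alt in c("C", "G", "T"))
    expect_equal(classify_snp_effect(gene$chrom, codon_start + 2, "A", alt,
                                     model, gene$genome), "synonymous")
})

test_that("indel effects depend on length mod 3 and CDS containment", {
  gene <- make_synthetic_gene(seed = 51)
  model <- read_gene_models(gene$gff)[[1]]
  p <- gene$cds[1, 1] + 5
  expect_equal(classify_indel_effect(p, "ACGT", "A", model),
               "nonframeshift_deletion")
  expect_equal(classify_indel_effect(p, "A", "AT", model),
               "frameshift_insertion")
  expect_equal(classify_indel_effect(p, "ACGTT", "A", model),
               "frameshift_deletion")
  expect_equal(classify_indel_effect(p, "A", "ATTT", model),
               "nonframeshift_insertion")
  # deletion running past the CDS end is not classifiable
  expect_warning(
    eff <- classify_indel_effect(gene$cds[1, 2] - 1, "ACGT", "A", model),
    "boundary")
  expect_equal(eff, "not_applicable")
})

test_that("the canonical transcript is the one with the longest CDS", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t100\t1000\t.\t+\t.\tID=gX",
    "chr1\tt\tmRNA\t100\t1000\t.\t+\t.\tID=gX.1;Parent=gX",
    "chr1\tt\texon\t100\t1000\t.\t+\t.\tID=e1;Parent=gX.1",
    "chr1\tt\tCDS\t100\t201\t.\t+\t0\tID=c1;Parent=gX.1",
    "chr1\tt\tmRNA\t100\t1000\t.\t+\t.\tID=gX.2;Parent=gX",
    "chr1\tt\texon\t100\t1000\t.\t+\t.\tID=e2;Parent=gX.2",
    "chr1\tt\tCDS\t100\t501\t.\t+\t0\tID=c2;Parent=gX.2"), gff)
  models <- read_gene_models(gff)
  expect_length(models, 1)
  expect_equal(models[[1]]$tx_id, "gX.2")
  expect_equal(models[[1]]$cds_len, 402)
})

test_that("incomplete CDS models refuse SNP effect calls", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t100\t300\t.\t+\t.\tID=gY",
    "chr1\tt\tmRNA\t100\t300\t.\t+\t.\tID=gY.1;Parent=gY",
    "chr1\tt\texon\t100\t300\t.\t+\t.\tID=e;Parent=gY.1",
    "chr1\tt\tCDS\t100\t299\t.\t+\t0\tID=c;Parent=gY.1"), gff)
  model <- read_gene_models(gff)[[1]]
  genome <- list(chr1 = paste(rep("A", 400), collapse = ""))
  expect_warning(eff <- classify_snp_effect("chr1", 150, "A", "G", model,
                                            genome),
                 "multiple of 3")
  expect_equal(eff, "not_applicable")
})
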