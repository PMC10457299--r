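# Independent reference implementations used to cross-check the package's
# computational paths. These deliberately use straightforward (vectorised or
# brute-force) R, not the code under test.

# Two-stage binomial null draws for one window, vectorised R.
r_null_window_deltas <- function(dh, dl, k, n_rep, shared = TRUE) {
  m <- length(dh)
  draw <- function() {
    if (shared) {
      ph <- rep(rbinom(n_rep, k, 0.5) / k, each = m)
      pl <- rep(rbinom(n_rep, k, 0.5) / k, each = m)
    } else {
      ph <- rbinom(n_rep * m, k, 0.5) / k
      pl <- rbinom(n_rep * m, k, 0.5) / k
    }
    ah <- rbinom(n_rep * m, rep(dh, times = n_rep), ph)
    al <- rbinom(n_rep * m, rep(dl, times = n_rep), pl)
    matrix(ah / rep(dh, times = n_rep) - al / rep(dl, times = n_rep),
           nrow = n_rep, byrow = TRUE)
  }
  rowMeans(draw())
}

# Brute-force sliding windows: explicit membership test per anchor.
brute_force_windows <- function(points, window, step, min_snps) {
  out <- list()
  for (chrom in unique(points$chrom)) {
    p <- points[points$chrom == chrom, ]
    for (a in seq(1, max(p$pos), by = step)) {
      inw <- p$pos >= a & p$pos < a + window
      if (sum(inw) >= min_snps)
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, start = a, end = a + window,
          n_snps = sum(inw), mean_delta = mean(p$delta[inw]))
    }
  }
  do.call(rbind, out)
}

# Brute-force region calls from a window table plus cutoffs.
brute_force_regions <- function(w, cut, two_sided = FALSE) {
  stat <- if (two_sided) abs(w$mean_delta) else w$mean_delta
  sig <- stat > cut
  out <- list()
  for (chrom in unique(w$chrom)) {
    i <- which(w$chrom == chrom)[order(w$start[w$chrom == chrom])]
    groups <- split(i[sig[i]], cumsum(!sig[i])[sig[i]])
    for (run in groups) {
      if (!length(run)) next
      peak <- run[which.max(w$mean_delta[run])]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = w$start[run[1]], end = w$end[run[length(run)]],
        peak_delta = w$mean_delta[peak],
        peak_difference = w$mean_delta[peak] - cut[peak])
    }
  }
  do.call(rbind, out)
}

# Random synthetic gene on a random genomic background, returned with its
# GFF3 file and genome, for annotation tests. Two exons; complete CDS of
# n_codons codons; optional UTR stubs.
make_synthetic_gene <- function(chrom = "chr1", chrom_len = 10000,
                                strand = "+", n_codons = 40,
                                gene_id = "gene1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome_seq <- paste(sample(c("A", "C", "G", "T"), chrom_len,
                             replace = TRUE), collapse = "")
  cds_len <- 3 * n_codons
  # layout (plus-strand coordinates): utr5(30) exon1-cds(a) intron(120)
  # exon2-cds(rest) utr3(30)
  # CDS split point deliberately off the codon grid so codons span the
  # exon junction
  a <- max(10, min(cds_len - 10, floor(cds_len * 0.4) + 1))
  tx_start <- 3001
  utr_len <- 30
  cds1 <- c(tx_start + utr_len, tx_start + utr_len + a - 1)
  intron_len <- 120
  cds2 <- c(cds1[2] + intron_len + 1, cds1[2] + intron_len + (cds_len - a))
  tx_end <- cds2[2] + utr_len
  exon1 <- c(tx_start, cds1[2])
  exon2 <- c(cds2[1], tx_end)
  # make a clean ORF on the coding strand: ATG ... sense codons ... stop
  body <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA")), n_codons - 2, replace = TRUE)
  orf <- paste(c("ATG", body, "TAA"), collapse = "")
  orf_genomic <- if (strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  else orf
  substr(genome_seq, cds1[1], cds1[2]) <- substr(orf_genomic, 1, a)
  substr(genome_seq, cds2[1], cds2[2]) <- substr(orf_genomic, a + 1, cds_len)
  gff <- tempfile(fileext = ".gff3")
  lines <- c(
    "##gff-version 3",
    sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, tx_start,
            tx_end, strand, gene_id),
    sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s", chrom,
            tx_start, tx_end, strand, gene_id, gene_id),
    sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.e1;Parent=%s.1",
            chrom, exon1[1], exon1[2], strand, gene_id, gene_id),
    sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.e2;Parent=%s.1",
            chrom, exon2[1], exon2[2], strand, gene_id, gene_id),
    sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.c1;Parent=%s.1",
            chrom, cds1[1], cds1[2], strand, gene_id, gene_id),
    sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.c2;Parent=%s.1",
            chrom, cds2[1], cds2[2], strand, gene_id, gene_id))
  writeLines(lines, gff)
  genome <- setNames(list(genome_seq), chrom)
  list(gff = gff, genome = genome, chrom = chrom, strand = strand,
       tx_start = tx_start, tx_end = tx_end,
       cds = rbind(cds1, cds2), exons = rbind(exon1, exon2),
       cds_len = cds_len, orf = orf)
}

# Full-ORF translation oracle for a SNP effect: rebuild the whole mutant
# spliced CDS, translate both with Biostrings, compare proteins.
oracle_snp_effect <- function(gene, pos, alt) {
  cds_coords <- unlist(lapply(seq_len(nrow(gene$cds)),
                              function(j) gene$cds[j, 1]:gene$cds[j, 2]))
  seq <- gene$genome[[gene$chrom]]
  mut_seq <- seq
  substr(mut_seq, pos, pos) <- alt
  splice <- function(s) {
    sp <- paste(vapply(cds_coords, function(i) substr(s, i, i), character(1)),
                collapse = "")
    if (gene$strand == "-")
      sp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sp)))
    sp
  }
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X", no.init.codon = TRUE))
  p0 <- tr(splice(seq)); p1 <- tr(splice(mut_seq))
  if (p0 == p1) return("synonymous")
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
  a0 <- substr(p0, d, d); a1 <- substr(p1, d, d)
  if (a1 == "*") "stop_gain" else if (a0 == "*") "stop_loss"
  else "nonsynonymous"
}

# Small simulated experiment -> filtered variant table, via the VCF round
# trip (the path real data takes).
sim_variants <- function(map, config, qtls = NULL, env_sd = 1,
                         min_depth = 5) {
  vcf <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcf))
  sim <- simulate_qtlseq_experiment(map, config, qtls, env_sd, vcf = vcf)
  v <- suppressMessages(read_bulk_variants(vcf))
  f <- filter_variants(v, min_depth = min_depth)
  list(sim = sim, variants = f$variants, all = v, filter = f)
}
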