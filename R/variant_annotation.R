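#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features and builds one canonical model per
#' gene (the transcript with the longest total CDS, so each variant receives
#' a single effect call). Coordinates are 1-based inclusive throughout, the
#' GFF3 convention.
#'
#' @param path GFF3 file.
#' @return An object of class `gene_models`: a list of models, each with
#'   `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `exons` and `cds`
#'   (two-column matrices of sorted start/end), plus TSS/TTS.
#' @export
read_gene_models <- function(path) {
  gff <- as.data.frame(rtracklayer::import(path))
  gff$seqnames <- as.character(gff$seqnames)
  gff$strand <- as.character(gff$strand)
  gff$type <- as.character(gff$type)
  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  models <- list()
  for (i in seq_len(nrow(mrna))) {
    tx <- mrna[i, ]
    tx_id <- tx$ID
    parent <- if (length(tx$Parent[[1]])) tx$Parent[[1]][1] else tx_id
    kids <- gff[vapply(gff$Parent, function(p) tx_id %in% p, logical(1)), ,
                drop = FALSE]
    exons <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cds <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    if (!nrow(exons)) exons <- tx[, c("start", "end"), drop = FALSE]
    exons <- as.matrix(exons[order(exons$start), , drop = FALSE])
    cds <- as.matrix(cds[order(cds$start), , drop = FALSE])
    models[[tx_id]] <- list(
      gene_id = parent, tx_id = tx_id,
      chrom = tx$seqnames, strand = tx$strand,
      tx_start = tx$start, tx_end = tx$end,
      exons = exons, cds = cds,
      cds_len = if (nrow(cds)) sum(cds[, 2] - cds[, 1] + 1) else 0L,
      tss = if (tx$strand == "-") tx$end else tx$start,
      tts = if (tx$strand == "-") tx$start else tx$end)
  }
  # canonical transcript per gene: longest CDS
  by_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  canonical <- lapply(by_gene, function(txs) {
    txs[[which.max(vapply(txs, `[[`, numeric(1), "cds_len"))]]
  })
  structure(unname(canonical), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", length(x), "gene(s) on",
      length(unique(vapply(x, `[[`, character(1), "chrom"))),
      "chromosome(s)\n")
  invisible(x)
}

.in_intervals <- function(pos, ivals) {
  nrow(ivals) > 0 && any(pos >= ivals[, 1] & pos <= ivals[, 2])
}

# Context of one position relative to one model; NA if unrelated.
.model_context <- function(pos, model, flank) {
  if (pos >= model$tx_start && pos <= model$tx_end) {
    if (.in_intervals(pos, model$cds)) return("CDS")
    if (.in_intervals(pos, model$exons)) return("UTR")
    return("intron")
  }
  up <- if (model$strand == "-")
    pos > model$tx_end && pos <= model$tx_end + flank
  else
    pos < model$tx_start && pos >= model$tx_start - flank
  if (up) return("upstream")
  down <- if (model$strand == "-")
    pos < model$tx_start && pos >= model$tx_start - flank
  else
    pos > model$tx_end && pos <= model$tx_end + flank
  if (down) return("downstream")
  NA_character_
}

.context_rank <- c(CDS = 1, UTR = 2, intron = 3, upstream = 4,
                   downstream = 5, intergenic = 6)

#' Classify the genomic context of variants
#'
#' Assigns each variant one of CDS, UTR, intron, upstream, downstream or
#' intergenic. Upstream/downstream are the 1-kb regions beyond the
#' transcription start/termination site, strand-aware and inclusive of the
#' 1000th base. When a position matches features of several genes the
#' highest-precedence context wins (CDS > UTR > intron > upstream >
#' downstream > intergenic). Variants on chromosomes absent from the models
#' are intergenic, with one warning.
#'
#' @param variants data.frame with `chrom` and `pos`
#'   (e.g. from [read_bulk_variants()]).
#' @param models a [read_gene_models()] object.
#' @param flank upstream/downstream flank width in bp (default 1000).
#' @return data.frame with columns `context` and `gene_id` (NA when
#'   intergenic), one row per variant.
#' @export
classify_genomic_context <- function(variants, models, flank = 1000) {
  stopifnot(inherits(models, "gene_models"))
  chroms <- vapply(models, `[[`, character(1), "chrom")
  unknown <- setdiff(unique(variants$chrom), chroms)
  if (length(unknown))
    warning("no gene models on chromosome(s): ",
            paste(unknown, collapse = ", "), "; variants there are intergenic")
  context <- rep("intergenic", nrow(variants))
  gene <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]
    for (m in models[chroms == variants$chrom[i]]) {
      ctx <- .model_context(pos, m, flank)
      if (!is.na(ctx) && .context_rank[ctx] < .context_rank[context[i]]) {
        context[i] <- ctx
        gene[i] <- m$gene_id
      }
    }
  }
  data.frame(context = context, gene_id = gene)
}

# CDS-coordinate (1-based, transcript orientation) of a genomic position.
.cds_coord <- function(pos, model) {
  cds <- model$cds
  hit <- which(pos >= cds[, 1] & pos <= cds[, 2])
  if (!length(hit)) return(NA_integer_)
  before <- if (hit > 1) sum(cds[seq_len(hit - 1), 2] -
                               cds[seq_len(hit - 1), 1] + 1) else 0
  fwd <- before + (pos - cds[hit, 1] + 1)
  if (model$strand == "-") model$cds_len - fwd + 1L else as.integer(fwd)
}

# Spliced CDS in transcript orientation from a genome (named character
# vector or Biostrings::DNAStringSet).
.spliced_cds <- function(model, genome) {
  seq <- as.character(genome[[model$chrom]])
  parts <- vapply(seq_len(nrow(model$cds)), function(j)
    substr(seq, model$cds[j, 1], model$cds[j, 2]), character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  toupper(s)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Coding effect of a SNP
#'
#' Reconstructs the affected codon from the spliced CDS in transcript
#' orientation (reverse-complementing minus-strand genes) and translates it
#' with the standard nuclear codon table. Stop-gain and stop-loss are
#' reported separately from other nonsynonymous changes.
#'
#' @param chrom,pos,ref,alt the SNP (plus-strand genomic alleles).
#' @param model one element of a [read_gene_models()] object whose CDS
#'   contains `pos`.
#' @param genome named list/vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return One of "synonymous", "nonsynonymous", "stop_gain", "stop_loss",
#'   or "not_applicable" (incomplete model; warned).
#' @export
classify_snp_effect <- function(chrom, pos, ref, alt, model, genome) {
  if (model$cds_len %% 3 != 0 || model$cds_len < 3) {
    warning("CDS length of ", model$gene_id,
            " not a positive multiple of 3; effect not applicable")
    return("not_applicable")
  }
  cpos <- .cds_coord(pos, model)
  if (is.na(cpos)) stop("position ", pos, " is not inside the CDS of ",
                        model$gene_id)
  cds <- .spliced_cds(model, genome)
  tref <- if (model$strand == "-") .complement[[toupper(ref)]] else toupper(ref)
  talt <- if (model$strand == "-") .complement[[toupper(alt)]] else toupper(alt)
  if (substr(cds, cpos, cpos) != tref)
    stop("reference allele mismatch at ", chrom, ":", pos)
  codon_i <- (cpos - 1) %/% 3
  codon <- substr(cds, codon_i * 3 + 1, codon_i * 3 + 3)
  mut <- codon
  substr(mut, (cpos - 1) %% 3 + 1, (cpos - 1) %% 3 + 1) <- talt
  aa0 <- Biostrings::GENETIC_CODE[[codon]]
  aa1 <- Biostrings::GENETIC_CODE[[mut]]
  if (aa0 == aa1) "synonymous"
  else if (aa1 == "*") "stop_gain"
  else if (aa0 == "*") "stop_loss"
  else "nonsynonymous"
}

#' Coding effect of an insertion or deletion
#'
#' Frameshift if the inserted/deleted length is not a multiple of 3. The
#' affected bases (VCF-anchored: the bases after the shared anchor base)
#' must lie fully inside one CDS interval; indels spanning a CDS boundary
#' are "not_applicable" with a warning.
#'
#' @param pos,ref,alt the indel record (anchored VCF representation).
#' @param model gene model whose CDS is tested.
#' @return One of "frameshift_insertion", "frameshift_deletion",
#'   "nonframeshift_insertion", "nonframeshift_deletion", "not_applicable".
#' @export
classify_indel_effect <- function(pos, ref, alt, model) {
  len <- abs(nchar(alt) - nchar(ref))
  if (len == 0) stop("record is not an indel")
  type <- if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
  cds <- model$cds
  span <- if (type == "deletion") c(pos + 1, pos + len) else c(pos, pos + 1)
  inside <- any(span[1] >= cds[, 1] & span[2] <= cds[, 2])
  if (!inside) {
    warning("indel at ", pos, " spans a CDS boundary of ", model$gene_id,
            "; effect not applicable")
    return("not_applicable")
  }
  shift <- if (len %% 3 != 0) "frameshift" else "nonframeshift"
  paste(shift, type, sep = "_")
}

#' Annotate a variant table against gene models
#'
#' Combines [classify_genomic_context()] with per-variant coding-effect
#' calls for CDS variants (SNP effects need `genome`; indel effects do not).
#'
#' @param variants variant table with `chrom`, `pos`, `ref`, `alt`, `class`.
#' @param models a [read_gene_models()] object.
#' @param genome optional chromosome sequences for SNP codon effects.
#' @param flank flank width for upstream/downstream (default 1000 bp).
#' @return `variants` with added `context`, `gene_id` and `coding_effect`
#'   ("not_applicable" outside CDS).
#' @export
annotate_variants <- function(variants, models, genome = NULL, flank = 1000) {
  ctx <- classify_genomic_context(variants, models, flank)
  effect <- rep("not_applicable", nrow(variants))
  gene_of <- vapply(models, `[[`, character(1), "gene_id")
  in_cds <- which(ctx$context == "CDS")
  for (i in in_cds) {
    model <- models[[match(ctx$gene_id[i], gene_of)]]
    if (variants$class[i] == "snp") {
      if (!is.null(genome))
        effect[i] <- classify_snp_effect(variants$chrom[i], variants$pos[i],
                                         variants$ref[i], variants$alt[i],
                                         model, genome)
    } else {
      effect[i] <- classify_indel_effect(variants$pos[i], variants$ref[i],
                                         variants$alt[i], model)
    }
  }
  cbind(variants, ctx, coding_effect = effect)
}

#' Tally annotation categories
#'
#' @param annotated output of [annotate_variants()].
#' @return list with `context` and `coding_effect` count tables (and the
#'   corresponding percentages of the input).
#' @export
annotation_summary <- function(annotated) {
  ctx <- table(annotated$context)
  eff <- table(annotated$coding_effect[annotated$coding_effect !=
                                         "not_applicable"])
  list(context = ctx,
       context_pct = round(100 * ctx / nrow(annotated), 2),
       coding_effect = eff)
}
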