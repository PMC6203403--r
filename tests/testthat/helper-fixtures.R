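# Deterministic in-code fixtures shared across tests.

# A hand-built 2-intron toy gene on a small genome.  Layout (0-based):
#   flank [0,30) | exon1 [30,75) | intron1 [75,115) | exon2 [115,160)
#   | intron2 [160,200) | exon3 [200,248) | flank [248,300)
# CDS = exons (no UTR); spliced CDS = 45+45+48 = 138 bases (46 codons),
# ATG start, TAA stop, GT..AG introns, no internal stop.
toy_gene <- function(strand = "+") {
  set.seed(4242)
  nonstop <- indelsync:::NONSTOP_CODONS
  cods <- c("ATG", sample(nonstop, 44, replace = TRUE), "TAA")
  cds <- paste(cods, collapse = "")
  seg <- c(substr(cds, 1, 45), substr(cds, 46, 90), substr(cds, 91, 138))
  intr <- vapply(1:2, function(i)
    paste0("GT", paste(sample(c("A", "C", "T"), 36, TRUE), collapse = ""),
           "AG"), character(1))
  gene_seq <- paste0(seg[1], intr[1], seg[2], intr[2], seg[3])
  stopifnot(nchar(gene_seq) == 218)
  flank5 <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), 52, TRUE), collapse = "")
  chrom_seq <- paste0(flank5, gene_seq, flank3)
  loc <- rbind(c(30L, 75L), c(115L, 160L), c(200L, 248L))
  if (strand == "-") {
    chrom_seq <- indelsync:::revcomp(chrom_seq)
    L <- nchar(chrom_seq)
    loc <- cbind(L - loc[, 2], L - loc[, 1])
    loc <- loc[order(loc[, 1]), , drop = FALSE]
  }
  genome <- ref_genome(stats::setNames(chrom_seq, "chrT"))
  model <- gene_model("toy", chrom = "chrT", strand = strand,
                      exons = loc, cds = loc)
  list(genome = genome, model = model)
}

no_variants <- function() indelsync:::empty_variants()

write_tmp_vcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), f)
  f
}
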