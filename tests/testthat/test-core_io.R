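test_that("FASTA reading uppercases, round-trips, and rejects duplicates", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt", ">chr2", "GGCC"), f)
  g <- read_reference(f)
  expect_equal(chrom_lengths(g), c(chr1 = 4L, chr2 = 4L))
  expect_equal(g$seqs[["chr1"]], "ACGT")
  f2 <- tempfile(fileext = ".fa")
  write_reference(g, f2)
  expect_equal(read_reference(f2)$seqs, g$seqs)
  writeLines(c(">chr1", "ACGT", ">chr1", "GGCC"), f)
  expect_error(read_reference(f), "duplicated")
  expect_error(ref_genome(c(chr1 = "ACGU")), "non-ACGTN")
})

test_that("VCF input strips anchors and converts to 0-based", {
  g <- ref_genome(c(chr1 = "ACGTAAGTAC"))
  f <- write_tmp_vcf(c("chr1\t2\t.\tCGT\tC\t.\tPASS\t.",
                       "chr1\t5\t.\tA\tC\t.\tPASS\tSUP=7",
                       "chr1\t7\t.\tG\tGTT\t.\tPASS\tSUP=1;HET"))
  v <- read_sample_vcf(f, "s1", g)
  del <- v[v$alt == "", ]
  expect_equal(del$pos, 2L)
  expect_equal(del$ref, "GT")
  snp <- v[v$ref == "A", ]
  expect_equal(snp$pos, 4L)
  expect_equal(snp$support, 7L)
  ins <- v[v$ref == "", ]
  expect_equal(ins$pos, 7L)   # inserted before base 7, follows base 6
  expect_equal(ins$alt, "TT")
  expect_true(ins$het)
})

test_that("overlapping calls within one sample are rejected", {
  g <- ref_genome(c(chr1 = "ACGTAAGTAC"))
  v <- variant_table("chr1", c(2L, 3L), c("GTA", "TA"), c("", ""), "s1")
  expect_error(validate_variants(g, v), "overlapping")
  f <- write_tmp_vcf(c("chr1\t2\t.\tCGTA\tC\t.\tPASS\t.",
                       "chr1\t4\t.\tTAA\tT\t.\tPASS\t."))
  expect_error(read_sample_vcf(f, "s1", g), "overlapping")
})

test_that("REF mismatches against the genome are errors", {
  g <- ref_genome(c(chr1 = "ACGTAAGTAC"))
  v <- variant_table("chr1", 2L, "T", "A", "s1")
  expect_error(validate_variants(g, v), "mismatch")
})

test_that("apply_variants edits left to right with a monotone map", {
  g <- ref_genome(c(chr1 = "ACGTACGT"))
  snp <- variant_table("chr1", 2L, "G", "T", "s1")
  expect_equal(apply_variants(g, snp, "chr1", 0, 8)$seq, "ACTTACGT")
  vs <- variant_table("chr1", c(2L, 6L), c("GT", ""), c("", "TT"), "s1")
  h <- apply_variants(g, vs, "chr1", 0, 8)
  expect_equal(h$seq, "ACACTTGT")
  expect_equal(h$ref2hap, c(0L, 1L, NA, NA, 2L, 3L, 6L, 7L))
  h0 <- apply_variants(g, no_variants(), "chr1", 2, 6)
  expect_equal(h0$seq, "GTAC")
  expect_equal(h0$ref2hap, 0:3)
})

test_that("coordinate maps invert to identity on unedited positions", {
  set.seed(71)
  for (rep in 1:20) {
    g <- ref_genome(c(c1 = indelsync:::random_dna(400)))
    pos <- sort(sample(seq(10, 380, by = 25), 6))
    kinds <- sample(c("snp", "del", "ins"), 6, TRUE)
    vt <- do.call(rbind, lapply(seq_along(pos), function(i) {
      p <- pos[i]
      if (kinds[i] == "snp") {
        rb <- ref_slice(g, "c1", p, p + 1)
        data.frame(chrom = "c1", pos = p, ref = rb,
                   alt = sample(setdiff(c("A", "C", "G", "T"), rb), 1),
                   sample = "s1")
      } else if (kinds[i] == "del") {
        data.frame(chrom = "c1", pos = p,
                   ref = ref_slice(g, "c1", p, p + sample(1:6, 1)),
                   alt = "", sample = "s1")
      } else {
        data.frame(chrom = "c1", pos = p, ref = "",
                   alt = indelsync:::random_dna(sample(1:6, 1)),
                   sample = "s1")
      }
    }))
    vt <- variant_table(vt$chrom, vt$pos, vt$ref, vt$alt, vt$sample)
    h <- apply_variants(g, vt, "c1", 0, 400)
    expect_true(all(diff(h$ref2hap[!is.na(h$ref2hap)]) > 0))
    # unedited reference positions carry their own base on the haplotype
    edited <- unlist(mapply(function(p, r) seq(p, length.out = max(1, nchar(r))),
                            vt$pos, vt$ref, SIMPLIFY = FALSE))
    for (p in setdiff(seq(0, 399, by = 17), edited)) {
      hp <- h$ref2hap[p + 1]
      expect_equal(substr(h$seq, hp + 1, hp + 1), ref_slice(g, "c1", p, p + 1))
    }
  }
})

test_that("gene models round-trip through GFF3 and enforce invariants", {
  tg <- toy_gene()
  f <- tempfile(fileext = ".gff3")
  write_gene_models(list(tg$model), f)
  m <- read_gene_models(f)
  expect_length(m, 1)
  expect_equal(m[["toy"]]$cds, tg$model$cds, ignore_attr = TRUE)
  expect_equal(m[["toy"]]$strand, "+")
  expect_error(gene_model("bad", chrom = "c", strand = "+",
                          exons = rbind(c(0, 10)), cds = rbind(c(0, 10))),
               "divisible by 3")
  expect_error(gene_model("bad", chrom = "c", strand = "+",
                          exons = rbind(c(0, 9)), cds = rbind(c(3, 12))),
               "contained")
})

test_that("phenotype and BED readers parse plain text", {
  f <- tempfile()
  writeLines(c("s1\t1.5", "s2\t-0.25"), f)
  ph <- read_phenotypes(f)
  expect_equal(ph$value, c(1.5, -0.25))
  b <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", b)
  bed <- read_bed(b)
  expect_equal(bed$start, 100L)
  expect_equal(bed$end, 200L)
})

test_that("single-sample VCF writing round-trips the internal representation", {
  g <- ref_genome(c(chr1 = "ACGTAAGTAC"))
  v <- variant_table("chr1", c(1L, 3L, 7L), c("C", "TA", ""),
                     c("G", "", "GG"), "s1")
  f <- tempfile(fileext = ".vcf")
  write_sample_vcf(v, g, f)
  v2 <- read_sample_vcf(f, "s1", g)
  expect_equal(v2[, c("chrom", "pos", "ref", "alt")],
               v[, c("chrom", "pos", "ref", "alt")], ignore_attr = TRUE)
})
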