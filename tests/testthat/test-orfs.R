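test_that("haplotype extraction matches the reference when no variants", {
  for (strand in c("+", "-")) {
    tg <- toy_gene(strand)
    hap <- extract_gene_haplotype(tg$genome, no_variants(), tg$model,
                                  flank = 30)
    expect_identical(hap$seq, hap$ref_seq)
    expect_equal(hap$ref2hap, seq_along(hap$ref2hap) - 1L)
    # coding-strand sequence starts with flank then ATG at the CDS start
    s <- hap$model$cds[1, 1]
    expect_equal(substr(hap$seq, s + 1, s + 3), "ATG")
    spliced <- paste(substring(hap$seq, hap$model$cds[, 1] + 1,
                               hap$model$cds[, 2]), collapse = "")
    expect_equal(substr(spliced, nchar(spliced) - 2, nchar(spliced)), "TAA")
  }
})

test_that("minus-strand extraction is the reverse complement of plus", {
  tgp <- toy_gene("+"); tgm <- toy_gene("-")
  hp <- extract_gene_haplotype(tgp$genome, no_variants(), tgp$model, flank = 30)
  hm <- extract_gene_haplotype(tgm$genome, no_variants(), tgm$model, flank = 30)
  expect_identical(hp$seq, hm$seq)   # same gene, coding orientation
  # an intronic deletion shifts downstream exons identically on both
  p_plus <- 80L    # inside intron1 on the plus build
  vplus <- variant_table("chrT", p_plus, ref_slice(tgp$genome, "chrT",
                                                   p_plus, p_plus + 2),
                         "", "sX")
  Lc <- chrom_lengths(tgm$genome)[[1]]
  p_minus <- Lc - p_plus - 2L
  vminus <- variant_table("chrT", p_minus,
                          ref_slice(tgm$genome, "chrT", p_minus, p_minus + 2),
                          "", "sX")
  h1 <- extract_gene_haplotype(tgp$genome, vplus, tgp$model, flank = 30)
  h2 <- extract_gene_haplotype(tgm$genome, vminus, tgm$model, flank = 30)
  expect_identical(h1$seq, h2$seq)
  expect_equal(nchar(h1$seq), nchar(h1$ref_seq) - 2L)
})

test_that("lift-over annotation tracks in-frame and frame-shift deletions", {
  tg <- toy_gene()
  p <- tg$model$cds[1, 1] + 9L
  for (L in c(3L, 6L)) {
    vs <- variant_table("chrT", p, ref_slice(tg$genome, "chrT", p, p + L),
                        "", "sX")
    hap <- extract_gene_haplotype(tg$genome, vs, tg$model, flank = 30)
    fl <- evaluate_criteria(annotate_by_liftover(hap), hap)
    expect_true(fl[["frame_ok"]], info = paste("L =", L))
  }
  vs1 <- variant_table("chrT", p, ref_slice(tg$genome, "chrT", p, p + 1),
                       "", "sX")
  hap1 <- extract_gene_haplotype(tg$genome, vs1, tg$model, flank = 30)
  fl1 <- evaluate_criteria(annotate_by_liftover(hap1), hap1)
  expect_false(fl1[["frame_ok"]])
})

test_that("deletion spanning an acceptor breaks the splice check for liftover", {
  tg <- toy_gene()
  acc <- 115L - 2L     # last two intron-1 bases (AG) on the plus layout
  vs <- variant_table("chrT", acc - 1L,
                      ref_slice(tg$genome, "chrT", acc - 1L, acc + 2L),
                      "", "sX")
  hap <- extract_gene_haplotype(tg$genome, vs, tg$model, flank = 30)
  fl <- evaluate_criteria(annotate_by_liftover(hap), hap)
  expect_false(fl[["splice_intact"]])
})

test_that("spliced alignment reproduces the reference exon structure", {
  tg <- toy_gene()
  hap <- extract_gene_haplotype(tg$genome, no_variants(), tg$model, flank = 30)
  for (mode in c("cds", "protein")) {
    ann <- annotate_by_spliced_alignment(hap, mode)
    expect_true(ann$evaluable)
    expect_equal(ann$cds, hap$model$cds, ignore_attr = TRUE)
    expect_true(all(evaluate_criteria(ann, hap)))
  }
  # a single intronic SNP leaves the exon structure identical
  p <- 130L + 10L  # misses exon2; actually inside exon2? choose intron2
  p <- 170L        # inside intron2 [160,200)
  rb <- ref_slice(tg$genome, "chrT", p, p + 1)
  vs <- variant_table("chrT", p, rb,
                      setdiff(c("A", "C", "G", "T"), rb)[1], "sX")
  hap2 <- extract_gene_haplotype(tg$genome, vs, tg$model, flank = 30)
  ann2 <- annotate_by_spliced_alignment(hap2, "cds")
  expect_equal(ann2$cds, hap2$model$cds, ignore_attr = TRUE)
  expect_true(all(evaluate_criteria(ann2, hap2)))
})

test_that("alignment scores below the floor make a route unevaluable", {
  tg <- toy_gene()
  hap <- extract_gene_haplotype(tg$genome, no_variants(), tg$model, flank = 30)
  ann <- annotate_by_spliced_alignment(hap, "cds", min_score = 1e9)
  expect_false(ann$evaluable)
})

test_that("splice criterion honors the reference pair and the whitelist", {
  tg <- toy_gene()
  don <- 75L   # first two bases of intron 1 on the plus layout
  acc <- 113L  # last two bases of intron 1
  bases <- c("A", "C", "G", "T")
  ref_don <- "GT"; ref_acc <- "AG"
  for (d1 in bases) for (d2 in bases) {
    pair <- paste0(d1, d2, "-", ref_acc)
    vs <- NULL
    muts <- list()
    if (substr(ref_don, 1, 1) != d1)
      muts[[length(muts) + 1]] <- c(don, substr(ref_don, 1, 1), d1)
    if (substr(ref_don, 2, 2) != d2)
      muts[[length(muts) + 1]] <- c(don + 1L, substr(ref_don, 2, 2), d2)
    if (length(muts) == 0) next
    m <- do.call(rbind, muts)
    vs <- variant_table("chrT", as.integer(m[, 1]), m[, 2], m[, 3], "sX")
    hap <- extract_gene_haplotype(tg$genome, vs, tg$model, flank = 30)
    fl <- evaluate_criteria(annotate_by_liftover(hap), hap)
    expect_equal(unname(fl[["splice_intact"]]),
                 pair %in% indelsync:::SPLICE_WHITELIST,
                 info = pair)
  }
})

test_that("the ORFS decision rule is conservative", {
  pass <- c(start_stop_intact = TRUE, splice_intact = TRUE,
            no_premature_stop = TRUE, frame_ok = TRUE)
  fail <- replace(pass, "frame_ok", FALSE)
  expect_equal(call_orfs(list(fail, pass, fail)), "conserved")
  expect_equal(call_orfs(list(fail, fail, fail)), "interrupted")
  expect_equal(call_orfs(list(NULL, NULL, NULL)), "missing")
  expect_equal(call_orfs(list(NULL, fail, NULL)), "interrupted")
  # monotone conservativeness: adding a passing route never interrupts
  expect_equal(call_orfs(list(fail, fail, pass)), "conserved")
})

test_that("premature stop SNPs interrupt through every route", {
  tg <- toy_gene()
  # force a TAA early in exon 1: codon 5 starts at CDS offset 12
  p <- 30L + 12L
  ref3 <- ref_slice(tg$genome, "chrT", p, p + 3)
  muts <- which(strsplit(ref3, "")[[1]] != c("T", "A", "A"))
  vs <- variant_table("chrT", p + muts - 1L,
                      substring(ref3, muts, muts),
                      c("T", "A", "A")[muts], "sX")
  r <- orfs_call_gene(tg$genome, vs, tg$model, flank = 30)
  expect_equal(r$state, "interrupted")
  for (f in Filter(Negate(is.null), r$routes$flags))
    expect_false(f[["no_premature_stop"]])
})

test_that("reference against itself is conserved for planted genes", {
  sr <- sim_reference(chrom_len = 30000, n_genes = 3, seed = 2)
  for (gm in sr$models) {
    r <- orfs_call_gene(sr$genome, no_variants(), gm)
    expect_equal(r$state, "conserved")
    expect_true(all(vapply(r$routes$flags, all, logical(1))))
  }
})

test_that("orfs_matrix codes interrupted=1, conserved=0 against truth", {
  sr <- sim_reference(chrom_len = 30000, n_genes = 3, seed = 21)
  gm1 <- sr$models[[1]]; gm2 <- sr$models[[2]]
  p1 <- gm1$cds[1, 1] + 10L
  p2 <- gm2$cds[1, 1] + 10L
  v <- rbind(
    variant_table(gm1$chrom, p1,
                  ref_slice(sr$genome, gm1$chrom, p1, p1 + 1), "", "sA"),
    variant_table(gm2$chrom, p2,
                  ref_slice(sr$genome, gm2$chrom, p2, p2 + 3), "", "sB"))
  m <- orfs_matrix(sr$genome, v, sr$models, samples = c("sA", "sB"))
  expect_equal(m["gene001", "sA"], 1L)   # frame shift
  expect_equal(m["gene001", "sB"], 0L)
  expect_equal(m["gene002", "sB"], 0L)   # in-frame deletion
  expect_equal(m["gene003", "sA"], 0L)
})

test_that("trustability follows coverage and confirmation rules", {
  expect_true(flag_trustable(rep(3, 100), c(TRUE, TRUE)))
  expect_false(flag_trustable(c(rep(3, 99), 0), c(TRUE, TRUE)))
  expect_false(flag_trustable(rep(2, 10), c(TRUE, FALSE)))
  expect_true(flag_trustable())
})

test_that("an alternative reference sample can stand in for a broken one", {
  tg <- toy_gene()
  # break the reference copy: overwrite codon 10 (CDS offsets 27-29,
  # genome 57-59 on the plus layout) with a premature TAA
  seq0 <- tg$genome$seqs[[1]]
  old_cod <- substr(seq0, 58, 60)
  seq_broken <- paste0(substr(seq0, 1, 57), "TAA",
                       substr(seq0, 61, nchar(seq0)))
  gb <- ref_genome(stats::setNames(seq_broken, "chrT"))
  expect_equal(orfs_call_gene(gb, no_variants(), tg$model, flank = 30)$state,
               "interrupted")
  # sFix reverts the stop to the original sense codon
  muts <- which(strsplit(old_cod, "")[[1]] != c("T", "A", "A"))
  fix <- variant_table("chrT", 57L + muts - 1L, c("T", "A", "A")[muts],
                       strsplit(old_cod, "")[[1]][muts], "sFix")
  r_fix <- orfs_call_gene(gb, fix, tg$model, flank = 30)
  expect_equal(r_fix$state, "conserved")
  # with sFix as the gene's reference, queries come from its functional
  # haplotype; a carrier of the fix stays conserved, the broken reference
  # haplotype stays interrupted
  r_fix_alt <- orfs_call_gene(gb, fix, tg$model, flank = 30,
                              alt_reference = fix)
  expect_equal(r_fix_alt$state, "conserved")
  expect_true(all(vapply(Filter(Negate(is.null), r_fix_alt$routes$flags),
                         all, logical(1))))
  r_plain_alt <- orfs_call_gene(gb, no_variants(), tg$model, flank = 30,
                                alt_reference = fix)
  expect_equal(r_plain_alt$state, "interrupted")
})
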