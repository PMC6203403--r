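samples4 <- c("s1", "s2", "s3", "s4")

test_that("SNP encoding keeps biallelic sites and applies missing rules", {
  v <- rbind(
    variant_table("c1", 10L, "A", "G", "s1", support = 5L, het = FALSE),
    variant_table("c1", 10L, "A", "G", "s2", support = 1L, het = FALSE),
    variant_table("c1", 20L, "C", "T", "s1", support = 9L, het = TRUE),
    variant_table("c1", 30L, "G", "A", "s3"),
    variant_table("c1", 30L, "G", "C", "s4"),          # multi-allelic site
    variant_table("c1", 40L, "T", "A", "s2"),
    variant_table("c1", 38L, "TTTT", "", "s3"))        # deletion over 40
  gm <- encode_snps(v, samples4)
  expect_equal(gm$markers$pos, c(10L, 20L, 40L))        # site 30 dropped
  expect_equal(gm$G[, gm$markers$pos == 10][["s1"]], 1L)
  expect_true(is.na(gm$G[, gm$markers$pos == 10][["s2"]]))  # support < 2
  expect_true(is.na(gm$G[, gm$markers$pos == 20][["s1"]]))  # heterozygous
  expect_true(is.na(gm$G[, gm$markers$pos == 40][["s3"]]))  # INDEL overlap
  expect_equal(gm$G[, gm$markers$pos == 40][["s2"]], 1L)
  expect_equal(gm$G[, gm$markers$pos == 40][["s4"]], 0L)
})

test_that("INDEL identity is position+length+type; overlap sets missing", {
  v <- rbind(
    variant_table("c1", 100L, "NN", "", c("s1", "s2")),   # same deletion
    variant_table("c1", 99L, "NNNN", "", "s3"),           # different deletion
    variant_table("c1", 200L, "", "TT", "s1"),
    variant_table("c1", 200L, "", "GG", "s2"),            # same ins marker
    variant_table("c1", 200L, "", "GGG", "s4"))           # other ins length
  gm <- encode_indels(v, samples4)
  k100 <- which(gm$markers$pos == 100 & gm$markers$len == 2)
  expect_equal(unname(gm$G[c("s1", "s2"), k100]), c(1L, 1L))
  expect_true(is.na(gm$G["s3", k100]))                # partial overlap
  k99 <- which(gm$markers$pos == 99)
  expect_equal(gm$G[["s3", k99]], 1L)
  expect_true(is.na(gm$G["s1", k99]))
  k200.2 <- which(gm$markers$pos == 200 & gm$markers$len == 2)
  expect_equal(unname(gm$G[c("s1", "s2"), k200.2]), c(1L, 1L))   # D15
  expect_true(is.na(gm$G["s4", k200.2]))              # other ins at anchor
  expect_equal(gm$G[["s3", k200.2]], 0L)              # reference haplotype
  # dominant inserted sequence recorded as descriptor
  expect_true(gm$markers$alt[k200.2] %in% c("TT", "GG"))
})

test_that("marker filtering matches a brute-force oracle", {
  set.seed(33)
  n <- 40
  G <- matrix(rbinom(n * 200, 1, runif(200, 0.02, 0.6)), n, 200,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  G[sample(length(G), 800)] <- NA
  gm <- structure(list(G = G,
                       markers = data.frame(chrom = "c1",
                                            pos = seq(0, by = 50,
                                                      length.out = 200),
                                            class = "snp")),
                  class = "genotype_matrix")
  for (preset in c("athaliana", "dmelanogaster")) {
    thr <- if (preset == "athaliana") c(0.1, 0.5, 5) else c(0.05, 0.2, 8)
    f <- filter_markers(gm, preset = preset)
    oracle <- vapply(seq_len(ncol(G)), function(k) {
      x <- G[, k]
      nm <- sum(is.na(x)); x <- x[!is.na(x)]
      if (length(x) == 0) return(FALSE)
      p <- mean(x); maf <- min(p, 1 - p); mac <- min(sum(x), sum(1 - x))
      maf >= thr[1] && nm / n <= thr[2] && mac >= thr[3]
    }, logical(1))
    expect_equal(f$markers$pos, gm$markers$pos[oracle])
  }
  # explicit threshold examples (n = 40)
  x1 <- c(rep(1, 3), rep(0, 37))       # maf 0.075 -> dropped by MAF
  x2 <- c(rep(1, 4), rep(0, 36))       # maf 0.1 ok, mac 4 -> dropped by MAC
  gm2 <- structure(list(G = cbind(m1 = x1, m2 = x2),
                        markers = data.frame(chrom = "c1", pos = c(1L, 2L),
                                             class = "snp")),
                   class = "genotype_matrix")
  f2 <- filter_markers(gm2, maf_min = 0.1, miss_max = 0.5, mac_min = 5)
  expect_equal(ncol(f2$G), 0L)
  expect_equal(attr(f2, "filter_log")[["dropped_maf"]], 1L)
  expect_equal(attr(f2, "filter_log")[["dropped_mac"]], 2L)
})

test_that("region exclusion drops markers inside BED intervals", {
  G <- matrix(rep(c(0L, 1L), 10), 4, 5)
  gm <- structure(list(G = G, markers = data.frame(chrom = "c1",
                                                   pos = c(10L, 100L, 150L,
                                                           200L, 300L),
                                                   class = "snp")),
                  class = "genotype_matrix")
  f <- filter_markers(gm, maf_min = 0, miss_max = 1, mac_min = 0,
                      exclude = data.frame(chrom = "c1", start = 90L,
                                           end = 160L))
  expect_equal(f$markers$pos, c(10L, 200L, 300L))
})

test_that("filtering is idempotent", {
  set.seed(12)
  G <- matrix(rbinom(200, 1, 0.3), 20, 10)
  G[sample(200, 15)] <- NA
  gm <- structure(list(G = G, markers = data.frame(chrom = "c1",
                                                   pos = 1:10 * 100L,
                                                   class = "snp")),
                  class = "genotype_matrix")
  f1 <- filter_markers(gm, 0.1, 0.5, 2)
  f2 <- filter_markers(f1, 0.1, 0.5, 2)
  expect_equal(f1$G, f2$G)
})

test_that("IBS matches a brute-force pairwise count", {
  set.seed(8)
  G <- matrix(rbinom(250, 1, 0.5), 5, 50,
              dimnames = list(paste0("s", 1:5), NULL))
  G[sample(250, 20)] <- NA
  gm <- structure(list(G = G, markers = data.frame(chrom = "c1",
                                                   pos = 1:50 * 10L,
                                                   class = "snp")),
                  class = "genotype_matrix")
  M <- ibs_matrix(gm)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    both <- !is.na(G[i, ]) & !is.na(G[j, ])
    expect_equal(M[i, j], sum(G[i, both] == G[j, both]) / sum(both))
  }
  # identical samples -> 1; half-discordant -> 0.5
  G2 <- rbind(a = rep(c(0L, 1L), 10), b = rep(c(0L, 1L), 10),
              c = rep(c(0L, 1L, 1L, 0L), 5))
  gm2 <- structure(list(G = G2, markers = data.frame(chrom = "c1",
                                                     pos = 1:20, class = "snp")),
                   class = "genotype_matrix")
  M2 <- ibs_matrix(gm2)
  expect_equal(M2["a", "b"], 1)
  expect_equal(M2["a", "c"], 0.5)
})

test_that("LD pruning keeps the earlier marker of correlated pairs", {
  set.seed(2)
  x <- rbinom(30, 1, 0.5)
  G <- cbind(m1 = x, m2 = x, m3 = rbinom(30, 1, 0.5))
  gm <- structure(list(G = G, markers = data.frame(chrom = "c1",
                                                   pos = c(100L, 500L, 900L),
                                                   class = "snp")),
                  class = "genotype_matrix")
  pr <- ld_prune(gm, window = 2000, step = 1000, r2_max = 0.9)
  expect_equal(pr$markers$pos, c(100L, 900L))
})

test_that("homogeneous groups keep one highest-quality sample", {
  ibs <- diag(1, 4)
  rownames(ibs) <- colnames(ibs) <- c("A", "B", "C", "D")
  ibs["A", "B"] <- ibs["B", "A"] <- 0.95
  kept <- remove_homogeneous(ibs, quality = c(14000, 13000, 5, 6))
  expect_setequal(kept, c("A", "C", "D"))
  # all below threshold -> everyone kept
  expect_setequal(remove_homogeneous(diag(1, 4) |>
                                       `dimnames<-`(list(LETTERS[1:4],
                                                         LETTERS[1:4])),
                                     quality = 1:4), LETTERS[1:4])
  # chain A-B, B-C forms one component even though A-C is weak
  ibs2 <- diag(1, 3)
  rownames(ibs2) <- colnames(ibs2) <- c("A", "B", "C")
  ibs2["A", "B"] <- ibs2["B", "A"] <- 0.92
  ibs2["B", "C"] <- ibs2["C", "B"] <- 0.93
  ibs2["A", "C"] <- ibs2["C", "A"] <- 0.85
  expect_length(remove_homogeneous(ibs2, quality = c(10, 20, 15)), 1L)
  expect_equal(remove_homogeneous(ibs2, quality = c(10, 20, 15)), "B")
  # duplicate-id samples removed preferentially
  kept3 <- remove_homogeneous(ibs2, quality = c(10, 20, 15),
                              dup_ids = c(FALSE, TRUE, FALSE))
  expect_equal(kept3, "C")
})
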