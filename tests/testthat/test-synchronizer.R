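test_that("window tiling covers the chromosome with exact overlap", {
  w <- make_windows(120000)
  expect_equal(w$start, c(0L, 49000L, 98000L))
  expect_equal(w$end, c(50000L, 99000L, 120000L))
  expect_equal(w$center, c(25000, 74000, 109000))
  expect_equal(make_windows(100)$start, 0L)
  expect_equal(make_windows(100)$end, 100L)
  expect_error(make_windows(100, window = 10, overlap = 10), "exceed")
  for (len in c(5001, 12345, 99999)) {
    w <- make_windows(len, 5000, 700)
    expect_equal(w$start[1], 0L)
    expect_equal(w$end[nrow(w)], len)
    if (nrow(w) > 1) expect_equal(unique(w$start[-1] - w$start[-nrow(w)]),
                                  4300L)
  }
})

test_that("window alignment preserves gap-stripped rows for any engine", {
  set.seed(5)
  ref <- indelsync:::random_dna(600)
  haps <- c(s1 = paste0(substr(ref, 1, 99), substr(ref, 103, 600)),
            s2 = paste0(substr(ref, 1, 300), "TTAC", substr(ref, 301, 600)),
            s3 = ref)
  aln <- align_window(ref, haps)
  expect_equal(gsub("-", "", aln$rows[1]), ref)
  for (k in 1:3) expect_equal(gsub("-", "", aln$rows[k + 1]), unname(haps[k]))
  expect_equal(unique(nchar(aln$rows)), nchar(aln$rows[1]))
  # identical haplotypes give identical rows and no gap columns
  aln0 <- align_window(ref, c(a = ref, b = ref))
  expect_equal(aln0$rows, rep(ref, 3))
})

test_that("atomic calls follow the per-column rules", {
  aln <- list(rows = c("AC-GT", "ACTGT"), samples = "s1")
  a <- call_atomic(aln, chrom = "c")
  expect_equal(a$kind, "ins1")
  expect_equal(a$ref_pos, 1L)  # anchored after reference offset 1
  expect_equal(a$base, "T")
  a2 <- call_atomic(list(rows = c("ACGT", "A--T"), samples = "s1"))
  expect_equal(a2$kind, c("del1", "del1"))
  expect_equal(a2$ref_pos, c(1L, 2L))
  a3 <- call_atomic(list(rows = c("ACGT", "AGGT"), samples = "s1"))
  expect_equal(a3$kind, "snp")
  expect_equal(a3$base, "G")
  # both rows gapped emits nothing
  a4 <- call_atomic(list(rows = c("A-CT", "A-CT"), samples = "s1"))
  expect_equal(nrow(a4), 0L)
})

test_that("random pairs round-trip through call_atomic + merge_atomic", {
  set.seed(9)
  g_all <- list()
  for (rep in 1:40) {
    ref <- indelsync:::random_dna(200)
    # random edits of the reference
    hap <- ref
    for (k in 1:3) {
      p <- sample(20:150, 1)
      hap <- switch(sample(3, 1),
                    paste0(substr(hap, 1, p), indelsync:::random_dna(3),
                           substr(hap, p + 1, nchar(hap))),
                    paste0(substr(hap, 1, p),
                           substr(hap, p + sample(1:4, 1) + 1, nchar(hap))),
                    paste0(substr(hap, 1, p - 1),
                           sample(c("A", "C", "G", "T"), 1),
                           substr(hap, p + 1, nchar(hap))))
    }
    aln <- align_window(ref, c(sX = hap))
    atom <- call_atomic(aln, chrom = "cR")
    genome <- ref_genome(c(cR = ref))
    atom <- indelsync:::attach_snp_ref(atom, genome)
    vs <- merge_atomic(atom)
    back <- apply_variants(genome, vs, "cR", 0, nchar(ref))$seq
    expect_equal(back, hap)
  }
})

test_that("overlap conflicts resolve toward the nearer window center", {
  wins <- make_windows(99000)
  at <- function(w, pos, kind = "del1", base = "A")
    data.frame(chrom = "c", ref_pos = pos, kind = kind, base = base,
               ins_offset = NA_integer_, sample = "s1",
               stringsAsFactors = FALSE)
  # conflicting calls at 49100: window A center 25000 (distance 24100),
  # window B center 74000 (distance 24900) -> A wins
  r <- resolve_overlaps(list(at(1, 49100L, "del1"), at(2, 49100L, "snp", "G")),
                        wins)
  expect_equal(r$kind, "del1")
  # identical calls deduplicate
  r2 <- resolve_overlaps(list(at(1, 49100L), at(2, 49100L)), wins)
  expect_equal(nrow(r2), 1L)
  # equidistant conflict: position 49500 is 24500 from both centers -> A
  r3 <- resolve_overlaps(list(at(1, 49500L, "del1"), at(2, 49500L, "snp", "G")),
                         wins)
  expect_equal(r3$kind, "del1")
  # a call seen by only one window survives
  r4 <- resolve_overlaps(list(at(1, 49900L),
                              data.frame(chrom = character(0),
                                         ref_pos = integer(0),
                                         kind = character(0),
                                         base = character(0),
                                         ins_offset = integer(0),
                                         sample = character(0))), wins)
  expect_equal(nrow(r4), 1L)
})

test_that("atomic runs merge into full variant records", {
  at <- data.frame(chrom = "c", ref_pos = c(100L, 101L), kind = "del1",
                   base = c("A", "C"), ins_offset = NA_integer_,
                   sample = "s1", stringsAsFactors = FALSE)
  m <- merge_atomic(at)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, 100L)
  expect_equal(m$ref, "AC")
  ins <- data.frame(chrom = "c", ref_pos = 55L, kind = "ins1",
                    base = c("T", "A"), ins_offset = c(0L, 1L),
                    sample = "s1", stringsAsFactors = FALSE)
  m2 <- merge_atomic(ins)
  expect_equal(m2$alt, "TA")
  expect_equal(m2$pos, 56L)   # inserted before base 56, follows anchor 55
  # deletion run with an insertion anchored inside stays two records
  mix <- data.frame(chrom = "c",
                    ref_pos = c(10L, 11L, 12L, 10L), kind = c(rep("del1", 3), "ins1"),
                    base = c("A", "A", "A", "G"),
                    ins_offset = c(NA, NA, NA, 0L), sample = "s1",
                    stringsAsFactors = FALSE)
  m3 <- merge_atomic(mix)
  expect_equal(nrow(m3), 2L)
  expect_equal(sort(nchar(m3$ref)), c(0L, 3L))
})

test_that("a population identical to the reference synchronizes to nothing", {
  g <- ref_genome(c(c1 = indelsync:::random_dna(3000)))
  s <- synchronize_population(g, no_variants(), samples = c("a", "b"),
                              window = 1000, overlap = 200)
  expect_equal(nrow(s$variants), 0L)
  expect_equal(s$report$n_input_indels, c(0L, 0L))
})

test_that("shared isomorph alleles collapse to one representation", {
  iso <- sim_isomorph_population(n_samples = 8, n_families = 12, seed = 31)
  sync <- synchronize_population(iso$genome, iso$variants,
                                 samples = iso$samples,
                                 window = 4000, overlap = 500)
  v <- sync$variants
  for (f in seq_len(nrow(iso$truth))) {
    loc <- iso$truth$pos[f]
    carriers <- strsplit(iso$truth$carriers[f], ",")[[1]]
    sig <- vapply(carriers, function(smp) {
      sv <- v[v$sample == smp & v$pos >= loc - 5 & v$pos <= loc + 15, ,
              drop = FALSE]
      paste(sv$pos, sv$ref, sv$alt, collapse = "|")
    }, character(1))
    expect_length(unique(sig), 1L)
    # non-carriers have no call at the family locus
    outs <- setdiff(iso$samples, carriers)
    expect_equal(sum(v$sample %in% outs & v$pos >= loc - 5 & v$pos <= loc + 15),
                 0L)
  }
})

test_that("synchronization round-trips every sample haplotype", {
  pop <- sim_population(n_samples = 6, chrom_len = 20000, n_snps = 40,
                        n_indels = 20, seed = 13, window = 6000,
                        overlap = 800)
  sync <- synchronize_population(pop$genome, pop$variants,
                                 samples = pop$samples,
                                 window = 6000, overlap = 800)
  len <- chrom_lengths(pop$genome)[[1]]
  for (smp in pop$samples) {
    hin <- apply_variants(pop$genome,
                          pop$variants[pop$variants$sample == smp, ],
                          "chr1", 0, len)$seq
    hout <- apply_variants(pop$genome,
                           sync$variants[sync$variants$sample == smp, ],
                           "chr1", 0, len)$seq
    expect_identical(hout, hin)
  }
})

test_that("synchronizing synchronized output is the identity", {
  pop <- sim_population(n_samples = 5, chrom_len = 15000, n_snps = 25,
                        n_indels = 12, seed = 17, window = 5000,
                        overlap = 600)
  key <- function(v) {
    v <- v[order(v$sample, v$chrom, v$pos, v$ref, v$alt), ]
    paste(v$sample, v$chrom, v$pos, v$ref, v$alt, collapse = "\n")
  }
  s1 <- synchronize_population(pop$genome, pop$variants,
                               samples = pop$samples, window = 5000,
                               overlap = 600)
  s2 <- synchronize_population(pop$genome, s1$variants,
                               samples = pop$samples, window = 5000,
                               overlap = 600)
  expect_identical(key(s2$variants), key(s1$variants))
})

test_that("multi-sample VCF output encodes synchronized genotypes", {
  iso <- sim_isomorph_population(n_samples = 4, n_families = 3, seed = 3)
  sync <- synchronize_population(iso$genome, iso$variants,
                                 samples = iso$samples,
                                 window = 4000, overlap = 500)
  f <- tempfile(fileext = ".vcf")
  write_population_vcf(sync, iso$genome, iso$samples, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_gt(length(body), 0)
  gt <- do.call(rbind, lapply(strsplit(body, "\t"), function(z) z[10:13]))
  expect_true(all(gt %in% c("0", "1")))
})
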