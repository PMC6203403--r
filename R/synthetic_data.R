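# Synthetic data with known truth: reference genomes with planted
# multi-exon genes, inbred populations whose shared INDEL alleles are
# emitted as alternative alignment isomorphs, phenotypes with an additive
# genetic architecture plus polygenic background, and the power simulation
# for burden testing of independent loss-of-function alleles.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NONSTOP_CODONS <- local({
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
})

#' Simulate a reference genome with planted genes
#'
#' Genes have three CDS exons separated by GT..AG introns, an ATG start, a
#' canonical stop, no internal in-frame stop, and phase-0 (codon-boundary)
#' introns; roughly half are placed on the minus strand.  Every planted
#' gene satisfies all four ORF criteria against the reference itself.
#'
#' @param chrom_len chromosome length (default 100000)
#' @param n_genes number of genes (default 10)
#' @param seed optional RNG seed
#' @param flank clearance kept gene-free on both sides of each gene
#'   (default 1200, beyond the annotation flank of 1000)
#' @param codons range of CDS codon counts to draw from
#' @param intron_len range of intron lengths
#' @return list: `genome` (a `ref_genome`), `models` (list of
#'   `gene_model`).
#' @export
sim_reference <- function(chrom_len = 100000L, n_genes = 10L, seed = NULL,
                          flank = 1200L, codons = c(40L, 80L),
                          intron_len = c(40L, 90L)) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- "chr1"
  seqv <- strsplit(random_dna(chrom_len), "")[[1]]
  models <- list()
  cursor <- flank
  for (g in seq_len(n_genes)) {
    nc <- sample(codons[1]:codons[2], 1)
    body <- c("ATG", sample(NONSTOP_CODONS, nc - 2L, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1))
    cds_seq <- paste(body, collapse = "")
    rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L
    c1 <- rint(6L, nc - 12L)               # >= 6 codons per exon
    c2 <- rint(c1 + 6L, nc - 6L)
    cuts <- 3L * c(c1, c2)
    segs <- c(substr(cds_seq, 1, cuts[1]),
              substr(cds_seq, cuts[1] + 1, cuts[2]),
              substr(cds_seq, cuts[2] + 1, nchar(cds_seq)))
    introns <- vapply(1:2, function(i) {
      L <- sample(intron_len[1]:intron_len[2], 1)
      paste0("GT", random_dna(L - 4L), "AG")
    }, character(1))
    gene_seq <- paste0(segs[1], introns[1], segs[2], introns[2], segs[3])
    L <- nchar(gene_seq)
    if (cursor + L + flank > chrom_len) break
    b <- cursor
    # gene-local coding intervals of the three CDS segments
    s1 <- nchar(segs[1]); i1 <- nchar(introns[1])
    s2 <- nchar(segs[2]); i2 <- nchar(introns[2]); s3 <- nchar(segs[3])
    loc <- rbind(c(0L, s1),
                 c(s1 + i1, s1 + i1 + s2),
                 c(s1 + i1 + s2 + i2, L))
    strand <- if (g %% 2 == 0) "-" else "+"
    if (strand == "-") {
      ins_seq <- revcomp(gene_seq)
      cds <- cbind(b + L - loc[, 2], b + L - loc[, 1])
      cds <- cds[order(cds[, 1]), , drop = FALSE]
    } else {
      ins_seq <- gene_seq
      cds <- cbind(b + loc[, 1], b + loc[, 2])
    }
    seqv[(b + 1):(b + L)] <- strsplit(ins_seq, "")[[1]]
    models[[length(models) + 1L]] <-
      gene_model(gene_id = sprintf("gene%03d", g), chrom = chrom,
                 strand = strand, exons = cds, cds = cds)
    cursor <- b + L + 2L * flank
  }
  genome <- ref_genome(stats::setNames(paste(seqv, collapse = ""), chrom))
  list(genome = genome, models = models)
}

# positions of window boundaries on a chromosome (for edge guards)
window_boundaries <- function(chrom_len, window, overlap) {
  w <- make_windows(chrom_len, window, overlap)
  sort(unique(c(w$start, w$end)))
}

#' Simulate a population carrying isomorph-represented shared alleles
#'
#' Every family plants one underlying allele shared by its carriers, but
#' emits it under two different sequence-equivalent representations:
#' scenario (a) a deletion inside a homopolymer tract, emitted left- or
#' right-shifted; scenario (b) a base change emitted as a SNP or as a
#' 1-bp deletion plus 1-bp insertion; scenario (c) a complex substitution
#' emitted as two SNPs or as a deletion plus insertion.  Families are kept
#' clear of window-edge neighbourhoods (the operating condition under
#' which representation collapse is guaranteed).  Sequence equivalence of
#' every representation pair is asserted during generation.
#'
#' @param n_samples samples in the population (default 10)
#' @param n_families isomorph families (default 50)
#' @param seed optional RNG seed
#' @param scenarios scenarios to cycle through (subset of a, b, c)
#' @param window,overlap window geometry the population will be
#'   synchronized with (for edge guards)
#' @param guard clearance from any window boundary (default 1200)
#' @return list: `genome`, `variants` (all samples), `truth` (per family:
#'   scenario, position, carriers, representations), `samples`.
#' @export
sim_isomorph_population <- function(n_samples = 10L, n_families = 50L,
                                    seed = NULL,
                                    scenarios = c("a", "b", "c"),
                                    window = 50000L, overlap = 1000L,
                                    guard = 1200L) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- "chr1"
  samples <- sprintf("s%03d", seq_len(n_samples))
  spacing <- 150L
  # provisional length, then extend so the last family fits
  pos <- integer(0); p <- 1500L
  chrom_len_guess <- 1500L + n_families * spacing * 2L + 3000L
  bnd <- window_boundaries(chrom_len_guess, window, overlap)
  while (length(pos) < n_families) {
    if (all(abs(p - bnd) > guard)) pos <- c(pos, p)
    p <- p + spacing
  }
  chrom_len <- max(pos) + 2000L
  seqv <- strsplit(random_dna(chrom_len), "")[[1]]
  truth <- list(); vars <- list()
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  for (f in seq_len(n_families)) {
    sc <- scenarios[(f - 1L) %% length(scenarios) + 1L]
    loc <- pos[f]
    carriers <- sort(sample(samples, max(2L, n_samples %/% 2L)))
    reps <- list()
    if (sc == "a") {
      b <- sample(c("A", "C", "G", "T"), 1)
      k <- 8L; d <- 3L
      seqv[(loc + 1):(loc + k)] <- b
      seqv[loc] <- other(b); seqv[loc + k + 1L] <- other(b)
      reps[[1]] <- data.frame(pos = loc, ref = strrep(b, d), alt = "")
      reps[[2]] <- data.frame(pos = loc + (k - d), ref = strrep(b, d),
                              alt = "")
    } else if (sc == "b") {
      x <- sample(c("A", "C", "G", "T"), 1); y <- other(x)
      seqv[loc + 1L] <- x
      reps[[1]] <- data.frame(pos = loc, ref = x, alt = y)
      reps[[2]] <- data.frame(pos = c(loc, loc + 1L), ref = c(x, ""),
                              alt = c("", y))
    } else {
      seqv[(loc + 1):(loc + 4)] <- c("A", "A", "G", "T")
      reps[[1]] <- data.frame(pos = c(loc + 1L, loc + 2L), ref = c("A", "G"),
                              alt = c("G", "T"))
      reps[[2]] <- data.frame(pos = c(loc + 1L, loc + 4L), ref = c("A", ""),
                              alt = c("", "T"))
    }
    for (ci in seq_along(carriers)) {
      r <- reps[[(ci - 1L) %% length(reps) + 1L]]
      vars[[length(vars) + 1L]] <-
        data.frame(chrom = chrom, pos = r$pos, ref = r$ref, alt = r$alt,
                   sample = carriers[ci], stringsAsFactors = FALSE)
    }
    truth[[f]] <- data.frame(family = f, scenario = sc, pos = loc,
                             n_reps = length(reps),
                             carriers = paste(carriers, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  genome <- ref_genome(stats::setNames(paste(seqv, collapse = ""), chrom))
  vdf <- do.call(rbind, vars)
  vdf <- variant_table(vdf$chrom, vdf$pos, vdf$ref, vdf$alt, vdf$sample)
  validate_variants(genome, vdf)
  # assert sequence equivalence of each family's representations
  tdf <- do.call(rbind, truth)
  for (f in seq_len(nrow(tdf))) {
    loc <- tdf$pos[f]
    cset <- strsplit(tdf$carriers[f], ",")[[1]]
    ed <- vapply(cset, function(smp) {
      sv <- vdf[vdf$sample == smp & vdf$pos >= loc - 2L & vdf$pos <= loc + 12L,
                , drop = FALSE]
      apply_variants(genome, sv, chrom, max(0L, loc - 10L),
                     min(chrom_len, loc + 20L))$seq
    }, character(1))
    if (length(unique(ed)) != 1L)
      stop("internal: family ", f, " representations are not equivalent")
  }
  list(genome = genome, variants = vdf, truth = tdf, samples = samples)
}

#' Simulate an inbred population with shared SNP/INDEL alleles
#'
#' Markers get a population frequency and carrier sets; all carriers share
#' one representation (no isomorphs), so the output doubles as ground
#' truth for round-trip and idempotence checks.  Marker positions keep a
#' minimum spacing (no overlapping spans within a sample) and stay clear
#' of window-edge neighbourhoods.
#'
#' @param n_samples population size (default 20)
#' @param chrom_len chromosome length (default 200000)
#' @param n_snps,n_indels marker counts
#' @param max_indel maximum INDEL length (default 12)
#' @param seed optional RNG seed
#' @param window,overlap window geometry (for edge guards)
#' @param guard clearance from window boundaries (default 1200)
#' @return list: `genome`, `variants`, `markers` (truth), `samples`.
#' @export
sim_population <- function(n_samples = 20L, chrom_len = 200000L,
                           n_snps = 300L, n_indels = 120L, max_indel = 12L,
                           seed = NULL, window = 50000L, overlap = 1000L,
                           guard = 1200L) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- "chr1"
  samples <- sprintf("s%03d", seq_len(n_samples))
  genome <- ref_genome(stats::setNames(random_dna(chrom_len), chrom))
  bnd <- window_boundaries(chrom_len, window, overlap)
  cand <- seq(100L, chrom_len - 100L, by = max_indel * 2L + 16L)
  cand <- cand[vapply(cand, function(p) all(abs(p - bnd) > guard), logical(1))]
  n_mark <- n_snps + n_indels
  if (length(cand) < n_mark) stop("chromosome too short for marker count")
  mpos <- sort(sample(cand, n_mark))
  kinds <- sample(c(rep("snp", n_snps), rep("del", ceiling(n_indels / 2)),
                    rep("ins", floor(n_indels / 2))))
  vars <- list(); marks <- list()
  for (k in seq_len(n_mark)) {
    p <- mpos[k]; kind <- kinds[k]
    freq <- stats::runif(1, 0.1, 0.9)
    carriers <- samples[stats::runif(n_samples) < freq]
    if (length(carriers) == 0) carriers <- sample(samples, 1)
    if (kind == "snp") {
      rb <- ref_slice(genome, chrom, p, p + 1L)
      ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      ref <- rb; alt <- ab
    } else if (kind == "del") {
      len <- sample.int(max_indel, 1)
      ref <- ref_slice(genome, chrom, p, p + len); alt <- ""
    } else {
      ref <- ""; alt <- random_dna(sample.int(max_indel, 1))
    }
    marks[[k]] <- data.frame(chrom = chrom, pos = p, kind = kind, ref = ref,
                             alt = alt, freq = length(carriers) / n_samples,
                             stringsAsFactors = FALSE)
    vars[[k]] <- data.frame(chrom = chrom, pos = p, ref = ref, alt = alt,
                            sample = carriers, stringsAsFactors = FALSE)
  }
  vdf <- do.call(rbind, vars)
  vdf <- variant_table(vdf$chrom, vdf$pos, vdf$ref, vdf$alt, vdf$sample)
  validate_variants(genome, vdf)
  list(genome = genome, variants = vdf, markers = do.call(rbind, marks),
       samples = samples)
}

#' Simulate phenotypes with a known architecture
#'
#' `y = sum_c beta_c x_c + u + e` with `u ~ MVN(0, h2_poly * K)` and
#' `e ~ N(0, se2 I)`; each causal marker's coefficient is scaled so its
#' expected variance share equals the requested value, and `se2` absorbs
#' the remainder so `Var(y)` is about 1.
#'
#' @param G genotype matrix (samples x markers, 0/1; NA treated as 0)
#' @param causal column indices of causal markers
#' @param shares variance share per causal marker (same length)
#' @param h2_poly polygenic background share (default 0.2; 0 disables)
#' @param K kinship matrix for the polygenic term (required if
#'   `h2_poly > 0`)
#' @param seed optional RNG seed
#' @return list: `y` (named by sample), `beta`, `shares`, `h2_poly`.
#' @export
sim_phenotypes <- function(G, causal = integer(0), shares = numeric(0),
                           h2_poly = 0.2, K = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(causal) == length(shares))
  if (sum(shares) + h2_poly >= 1)
    stop("variance shares exceed 1")
  n <- nrow(G)
  g <- 0
  beta <- numeric(length(causal))
  for (i in seq_along(causal)) {
    x <- G[, causal[i]]
    x[is.na(x)] <- 0
    vx <- stats::var(x)
    if (vx == 0) stop("causal marker is monomorphic")
    beta[i] <- sqrt(shares[i] / vx)
    g <- g + beta[i] * x
  }
  u <- 0
  if (h2_poly > 0) {
    if (is.null(K)) stop("K required for a polygenic background")
    R <- chol(psd_adjust(K) + diag(1e-8, n))
    u <- sqrt(h2_poly) * drop(crossprod(R, stats::rnorm(n)) /
                                sqrt(mean(diag(K))))
  }
  se2 <- 1 - sum(shares) - h2_poly
  y <- g + u + stats::rnorm(n, sd = sqrt(se2))
  names(y) <- rownames(G)
  list(y = y, beta = beta, shares = shares, h2_poly = h2_poly)
}

#' Power simulation for burden testing of independent loss-of-function
#' alleles
#'
#' Three allele groups of one gene: a functional allele and two
#' loss-of-function alleles caused by different INDELs.  Per replicate the
#' functional group's phenotypes are drawn as N(mu_functional, var) and
#' each loss-of-function group's as N(mu_lof, var), `n_per_allele` samples
#' per group.  The single-INDEL test compares carriers of one
#' loss-of-function INDEL against everyone else; the ORF-state (burden)
#' test compares the union of both loss-of-function groups against the
#' functional group.  Both use the two-sided Wilcoxon rank-sum test.
#'
#' @param n_per_allele samples per allele group (default 70)
#' @param mu_functional,mu_lof group means (defaults 2 and 1)
#' @param variance phenotype variance per group (default 1.44)
#' @param reps replicates (default 10000)
#' @param threshold_log10p genome-wide significance line on the -log10
#'   scale (default 7.8)
#' @param seed optional RNG seed
#' @return data.frame with `p_single` and `p_orfs` per replicate;
#'   attribute `summary` holds the median -log10 p of both tests and their
#'   exceedance rates over the threshold.
#' @export
simulate_lof_power <- function(n_per_allele = 70L, mu_functional = 2,
                               mu_lof = 1, variance = 1.44, reps = 10000L,
                               threshold_log10p = 7.8, seed = NULL) {
  if (reps < 1) stop("reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  sdv <- sqrt(variance)
  p_single <- p_orfs <- numeric(reps)
  for (r in seq_len(reps)) {
    a1 <- stats::rnorm(n_per_allele, mu_functional, sdv)
    a2 <- stats::rnorm(n_per_allele, mu_lof, sdv)
    a3 <- stats::rnorm(n_per_allele, mu_lof, sdv)
    p_single[r] <- stats::wilcox.test(a2, c(a1, a3), exact = FALSE)$p.value
    p_orfs[r] <- stats::wilcox.test(c(a2, a3), a1, exact = FALSE)$p.value
  }
  out <- data.frame(p_single = p_single, p_orfs = p_orfs)
  attr(out, "summary") <- c(
    median_log10p_single = stats::median(-log10(p_single)),
    median_log10p_orfs = stats::median(-log10(p_orfs)),
    exceed_single = mean(-log10(p_single) > threshold_log10p),
    exceed_orfs = mean(-log10(p_orfs) > threshold_log10p))
  out
}
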