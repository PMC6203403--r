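# Encoding of synchronized variants and ORFS calls into {0,1,NA} genotype
# matrices, marker filtering, IBS-based detection of homogeneous lines.

#' Encode biallelic SNP genotypes
#'
#' One column per SNP site that is biallelic within the population
#' (reference plus one alternative base); sites with two or more distinct
#' alternative bases are dropped.  A sample is set missing at a SNP when
#' its call has read support below 2, is heterozygous, or the site is
#' physically overlapped by one of the sample's INDEL deletions.  Absent
#' support/heterozygosity fields pass those rules vacuously.
#'
#' @param variants synchronized variant data.frame (all samples)
#' @param samples sample ids defining the row order
#' @return list of class `genotype_matrix`: `G` (samples x markers, 0/1/NA),
#'   `markers` (data.frame chrom, pos, class, ref, alt).
#' @export
encode_snps <- function(variants, samples) {
  v <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1, ,
                drop = FALSE]
  key <- paste(v$chrom, v$pos)
  alts <- tapply(v$alt, key, function(a) length(unique(a)))
  keep_sites <- names(alts)[alts == 1]
  v <- v[key %in% keep_sites, , drop = FALSE]
  key <- paste(v$chrom, v$pos)
  usites <- unique(v[, c("chrom", "pos")])
  usites <- usites[order(usites$chrom, usites$pos), , drop = FALSE]
  ukey <- paste(usites$chrom, usites$pos)
  G <- matrix(0L, length(samples), length(ukey),
              dimnames = list(samples, NULL))
  mk <- data.frame(chrom = usites$chrom, pos = usites$pos, class = "snp",
                   ref = "", alt = "", stringsAsFactors = FALSE)
  idx <- match(key, ukey)
  sidx <- match(v$sample, samples)
  ok <- !is.na(sidx)
  G[cbind(sidx[ok], idx[ok])] <- 1L
  mk$ref[idx] <- v$ref
  mk$alt[idx] <- v$alt
  # missing rule 1/2: low support or heterozygous carrier calls
  low <- ok & ((!is.na(v$support) & v$support < 2L) | (!is.na(v$het) & v$het))
  G[cbind(sidx[low], idx[low])] <- NA_integer_
  # missing rule 3: site inside one of the sample's deletions
  dels <- variants[nchar(variants$ref) > nchar(variants$alt), , drop = FALSE]
  if (nrow(dels) > 0 && nrow(usites) > 0) {
    dgr <- GenomicRanges::GRanges(dels$chrom,
                                  IRanges::IRanges(dels$pos + 1L,
                                                   dels$pos + nchar(dels$ref)))
    sgr <- GenomicRanges::GRanges(usites$chrom,
                                  IRanges::IRanges(usites$pos + 1L,
                                                   usites$pos + 1L))
    ov <- GenomicRanges::findOverlaps(dgr, sgr)
    if (length(ov)) {
      di <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      rows <- match(dels$sample[di], samples)
      keep <- !is.na(rows)
      G[cbind(rows[keep], si[keep])] <- NA_integer_
    }
  }
  structure(list(G = G, markers = mk), class = "genotype_matrix")
}

#' Encode INDEL genotypes
#'
#' Marker identity is (position, length, type): two INDELs at the same
#' position with the same length are one variant even when the inserted
#' sequences differ (the most frequent inserted sequence is recorded as
#' the allele descriptor).  A sample is set missing at an INDEL marker when
#' a *different* INDEL of that sample occupies part of the marker's
#' positions: deletions overlap when their reference spans share a base,
#' an insertion conflicts with another insertion at the same anchor or
#' with a deletion whose span strictly contains its anchor point.
#'
#' @param variants synchronized variant data.frame (all samples)
#' @param samples sample ids defining the row order
#' @return A `genotype_matrix` (class `indel`).
#' @export
encode_indels <- function(variants, samples) {
  v <- variants[nchar(variants$ref) != nchar(variants$alt), , drop = FALSE]
  v$type <- ifelse(nchar(v$ref) > nchar(v$alt), "del", "ins")
  v$len <- abs(nchar(v$ref) - nchar(v$alt))
  key <- paste(v$chrom, v$pos, v$type, v$len)
  um <- v[!duplicated(key), c("chrom", "pos", "type", "len"), drop = FALSE]
  um <- um[order(um$chrom, um$pos, um$type, um$len), , drop = FALSE]
  ukey <- paste(um$chrom, um$pos, um$type, um$len)
  G <- matrix(0L, length(samples), nrow(um), dimnames = list(samples, NULL))
  idx <- match(key, ukey)
  sidx <- match(v$sample, samples)
  ok <- !is.na(sidx)
  G[cbind(sidx[ok], idx[ok])] <- 1L
  # dominant allele descriptor
  desc <- vapply(seq_len(nrow(um)), function(k) {
    a <- v$alt[idx == k]
    a <- a[a != ""]
    if (!length(a)) "" else names(sort(table(a), decreasing = TRUE))[1]
  }, character(1))
  mk <- data.frame(chrom = um$chrom, pos = um$pos, class = "indel",
                   ref = ifelse(um$type == "del", strrep("N", um$len), ""),
                   alt = desc, type = um$type, len = um$len,
                   stringsAsFactors = FALSE)
  # missing where a different INDEL of the sample overlaps the marker
  span <- function(chrom, pos, type, len) {
    # deletions occupy [pos, pos+len); insertions the anchor boundary point,
    # encoded as a zero-width position at pos
    s <- ifelse(type == "del", pos, pos)
    e <- ifelse(type == "del", pos + len, pos)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, pmax(e, s + 1L)))
  }
  mgr <- span(um$chrom, um$pos, um$type, um$len)
  vgr <- span(v$chrom, v$pos, v$type, v$len)
  ov <- GenomicRanges::findOverlaps(vgr, mgr)
  if (length(ov)) {
    vi <- S4Vectors::queryHits(ov); mi <- S4Vectors::subjectHits(ov)
    same <- idx[vi] == mi
    ins_vs_del <- (v$type[vi] == "ins") != (um$type[mi] == "ins")
    # an insertion's anchor only conflicts with a deletion strictly
    # containing the boundary (not merely abutting it)
    strict <- rep(TRUE, length(vi))
    insv <- v$type[vi] == "ins" & um$type[mi] == "del"
    strict[insv] <- v$pos[vi][insv] > um$pos[mi][insv] &
      v$pos[vi][insv] < um$pos[mi][insv] + um$len[mi][insv]
    insm <- um$type[mi] == "ins" & v$type[vi] == "del"
    strict[insm] <- um$pos[mi][insm] > v$pos[vi][insm] &
      um$pos[mi][insm] < v$pos[vi][insm] + v$len[vi][insm]
    hit <- !same & strict
    if (any(hit)) {
      rows <- match(v$sample[vi][hit], samples)
      cols <- mi[hit]
      cur <- G[cbind(rows, cols)]
      keep <- !is.na(rows) & !is.na(cur) & cur == 0L
      G[cbind(rows[keep], cols[keep])] <- NA_integer_
    }
  }
  structure(list(G = G, markers = mk), class = "genotype_matrix")
}

#' Build a genotype matrix from an ORFS matrix
#'
#' @param orfs matrix from [orfs_matrix()] (genes x samples, 0/1/NA)
#' @param models list of gene models (for marker coordinates)
#' @return A `genotype_matrix` with one marker per gene (0 conserved,
#'   1 interrupted).
#' @export
encode_orfs <- function(orfs, models = NULL) {
  G <- t(orfs)
  pos <- rep(NA_integer_, nrow(orfs)); chrom <- rep(NA_character_, nrow(orfs))
  if (!is.null(models)) {
    mm <- models[match(rownames(orfs),
                       vapply(models, `[[`, character(1), "gene_id"))]
    pos <- vapply(mm, function(g) as.integer(min(g$cds[, 1])), integer(1))
    chrom <- vapply(mm, `[[`, character(1), "chrom")
  }
  mk <- data.frame(chrom = chrom, pos = pos, class = "orfs",
                   ref = "", alt = rownames(orfs), stringsAsFactors = FALSE)
  colnames(G) <- NULL
  structure(list(G = G, markers = mk), class = "genotype_matrix")
}

#' Filter genotype markers
#'
#' Keeps markers with minor allele frequency (over non-missing samples) of
#' at least `maf_min`, missing rate at most `miss_max`, minor allele count
#' at least `mac_min`, and outside the excluded regions.  Presets:
#' `"athaliana"` = (0.1, 0.5, 5), `"dmelanogaster"` = (0.05, 0.2, 8).
#'
#' @param gm a `genotype_matrix`
#' @param maf_min,miss_max,mac_min thresholds (or use `preset`)
#' @param preset `"athaliana"` or `"dmelanogaster"` (overrides thresholds)
#' @param exclude optional data.frame chrom/start/end of regions to drop
#' @return Filtered `genotype_matrix` with attribute `filter_log` (counts
#'   dropped per rule).
#' @export
filter_markers <- function(gm, maf_min = 0.1, miss_max = 0.5, mac_min = 5,
                           preset = NULL, exclude = NULL) {
  if (!is.null(preset)) {
    p <- match.arg(preset, c("athaliana", "dmelanogaster"))
    if (p == "athaliana") { maf_min <- 0.1; miss_max <- 0.5; mac_min <- 5 }
    else { maf_min <- 0.05; miss_max <- 0.2; mac_min <- 8 }
  }
  G <- gm$G
  n <- nrow(G)
  nmiss <- colSums(is.na(G))
  nobs <- n - nmiss
  n1 <- colSums(G == 1L, na.rm = TRUE)
  f <- ifelse(nobs > 0, n1 / nobs, 0)
  maf <- pmin(f, 1 - f)
  mac <- pmin(n1, nobs - n1)
  missrate <- nmiss / n
  drop_maf <- maf < maf_min
  drop_miss <- missrate > miss_max
  drop_mac <- mac < mac_min
  drop_excl <- rep(FALSE, ncol(G))
  if (!is.null(exclude) && nrow(exclude) > 0 && !all(is.na(gm$markers$pos))) {
    egr <- GenomicRanges::GRanges(exclude$chrom,
                                  IRanges::IRanges(exclude$start + 1L,
                                                   exclude$end))
    mgr <- GenomicRanges::GRanges(gm$markers$chrom,
                                  IRanges::IRanges(gm$markers$pos + 1L,
                                                   gm$markers$pos + 1L))
    drop_excl <- GenomicRanges::countOverlaps(mgr, egr) > 0
  }
  keep <- !(drop_maf | drop_miss | drop_mac | drop_excl)
  out <- structure(list(G = G[, keep, drop = FALSE],
                        markers = gm$markers[keep, , drop = FALSE]),
                   class = "genotype_matrix")
  attr(out, "filter_log") <- c(n_in = ncol(G), dropped_maf = sum(drop_maf),
                               dropped_missing = sum(drop_miss),
                               dropped_mac = sum(drop_mac),
                               dropped_excluded = sum(drop_excl),
                               n_out = sum(keep))
  out
}

#' Prune nearby highly linked SNPs
#'
#' Sliding windows of `window` bases stepping by `step`; within a window,
#' for any marker pair with squared correlation above `r2_max` (pairwise
#' complete observations) the later-position marker is dropped.
#'
#' @param gm a `genotype_matrix`
#' @param window,step,r2_max pruning parameters (defaults 2000 / 1000 /
#'   0.9)
#' @return Pruned `genotype_matrix`.
#' @export
ld_prune <- function(gm, window = 2000L, step = 1000L, r2_max = 0.9) {
  keep <- rep(TRUE, ncol(gm$G))
  mk <- gm$markers
  for (chrom in unique(mk$chrom)) {
    ci <- which(mk$chrom == chrom)
    ci <- ci[order(mk$pos[ci])]
    if (length(ci) < 2) next
    pos <- mk$pos[ci]
    starts <- seq(min(pos), max(pos), by = step)
    for (ws in starts) {
      inw <- which(pos >= ws & pos < ws + window & keep[ci])
      if (length(inw) < 2) next
      for (a in seq_len(length(inw) - 1L)) {
        ia <- ci[inw[a]]
        if (!keep[ia]) next
        for (b in (a + 1L):length(inw)) {
          ib <- ci[inw[b]]
          if (!keep[ib]) next
          r <- suppressWarnings(stats::cor(gm$G[, ia], gm$G[, ib],
                                           use = "pairwise.complete.obs"))
          if (!is.na(r) && r * r > r2_max) keep[ib] <- FALSE
        }
      }
    }
  }
  structure(list(G = gm$G[, keep, drop = FALSE],
                 markers = mk[keep, , drop = FALSE]),
            class = "genotype_matrix")
}

#' Identity-by-state matrix
#'
#' IBS between two samples is the fraction of co-typed markers at which
#' they carry the same allele.  Apply [ld_prune()] first when following the
#' published pipeline.
#'
#' @param gm a `genotype_matrix`
#' @return Symmetric samples x samples matrix with unit diagonal.
#' @export
ibs_matrix <- function(gm) {
  G <- gm$G
  n <- nrow(G)
  M <- matrix(1, n, n, dimnames = list(rownames(G), rownames(G)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(G[i, ]) & !is.na(G[j, ])
      M[i, j] <- M[j, i] <-
        if (any(both)) mean(G[i, both] == G[j, both]) else NA_real_
    }
  }
  M
}

#' Remove homogeneous lines
#'
#' Samples linked by pairwise IBS above `threshold` form homogeneous
#' groups (connected components of the IBS graph); each group keeps
#' exactly one sample.  Samples flagged as duplicate identifiers are
#' removed preferentially; among the rest the sample with the highest
#' quality score (number of trustable ORFS calls) wins, ties going to the
#' earlier sample.
#'
#' @param ibs IBS matrix from [ibs_matrix()]
#' @param quality numeric vector of per-sample quality (trustable-ORFS
#'   counts), aligned with the matrix rows
#' @param dup_ids optional logical vector flagging duplicate-identifier
#'   samples
#' @param threshold IBS threshold (default 0.9)
#' @return Character vector of retained sample names.
#' @export
remove_homogeneous <- function(ibs, quality, dup_ids = NULL, threshold = 0.9) {
  n <- nrow(ibs)
  samples <- rownames(ibs)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  if (is.null(dup_ids)) dup_ids <- rep(FALSE, n)
  adj <- !is.na(ibs) & ibs > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep <- logical(n)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    cand <- idx[!dup_ids[idx]]
    if (length(cand) == 0) cand <- idx
    best <- cand[order(-quality[cand], cand)][1]
    keep[best] <- TRUE
  }
  samples[keep]
}

#' Subset a genotype matrix to samples
#' @param gm a `genotype_matrix`
#' @param samples sample names to keep
#' @return Subsetted `genotype_matrix`.
#' @export
subset_samples <- function(gm, samples) {
  structure(list(G = gm$G[samples, , drop = FALSE], markers = gm$markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$G), "samples x", ncol(x$G), "markers (",
      paste(unique(x$markers$class), collapse = "/"), ")\n")
  invisible(x)
}
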