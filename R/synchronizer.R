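# Windowed multiple-sequence-alignment variant synchronization.
#
# The population's haplotypes are rebuilt window by window, aligned jointly
# with the reference, and variants re-called column by column from the MSA,
# so that alignment isomorphs of one underlying allele collapse to a single
# shared representation.

#' Tile a chromosome with overlapping windows
#'
#' Consecutive windows overlap by exactly `overlap` bases (step =
#' `window - overlap`); the last window is truncated at the chromosome end.
#'
#' @param chrom_len chromosome length
#' @param window window size (default 50000)
#' @param overlap overlap between consecutive windows (default 1000)
#' @return data.frame with columns `start`, `end`, `center` (0-based
#'   half-open spans).
#' @export
make_windows <- function(chrom_len, window = 50000L, overlap = 1000L) {
  if (window <= overlap) stop("window must exceed overlap")
  if (chrom_len < 1) stop("chrom_len must be positive")
  step <- window - overlap
  starts <- 0L
  while (utils::tail(starts, 1) + window < chrom_len)
    starts <- c(starts, utils::tail(starts, 1) + step)
  ends <- pmin(starts + window, chrom_len)
  data.frame(start = as.integer(starts), end = as.integer(ends),
             center = (as.integer(starts) + as.integer(ends)) / 2)
}

# --- alignment engines -----------------------------------------------------

#' Align one window's haplotypes against the reference slice
#'
#' The builtin engine aligns each distinct haplotype to the reference with a
#' banded affine-gap global pairwise alignment and merges the pairwise
#' alignments into an MSA by taking the union of insertion columns at each
#' reference position (reference-guided progressive alignment).  Identical
#' haplotypes are aligned once and the result reused, so fully shared
#' alleles cost one alignment.  An external MAFFT adapter (`engine =
#' "mafft"`) shells out to `mafft --auto`.
#'
#' Stripping gaps from any row always reproduces that row's input sequence,
#' whichever engine is used.
#'
#' @param reference_slice reference window sequence
#' @param haplotypes character vector of sample haplotype sequences (an
#'   empty string denotes a fully deleted window and becomes an all-gap row)
#' @param engine `"builtin"` or `"mafft"`
#' @param band_extra band half-width margin for the builtin engine
#' @param mafft_path path to the mafft executable
#' @return list with `rows` (aligned strings, row 1 = reference) and
#'   `samples` (names of `haplotypes`).
#' @export
align_window <- function(reference_slice, haplotypes,
                         engine = c("builtin", "mafft"),
                         band_extra = 100L, mafft_path = "mafft") {
  engine <- match.arg(engine)
  samples <- names(haplotypes)
  if (is.null(samples)) samples <- paste0("s", seq_along(haplotypes))
  if (nchar(reference_slice) == 0) stop("empty reference slice")
  if (engine == "mafft")
    return(align_window_mafft(reference_slice, haplotypes, samples, mafft_path))
  # pairwise align each distinct haplotype to the reference
  uh <- unique(haplotypes)
  pw <- lapply(uh, function(h) {
    if (nchar(h) == 0)
      list(ref = reference_slice,
           hap = strrep("-", nchar(reference_slice)))
    else cpp_banded_align(reference_slice, h, band_extra = band_extra)
  })
  names(pw) <- uh
  L <- nchar(reference_slice)
  # per-haplotype: substitution char per reference base + insertion strings
  # keyed by number of reference bases already consumed (0..L)
  parsed <- lapply(pw, function(al) parse_pairwise(al$ref, al$hap, L))
  ins_len <- integer(L + 1L)
  for (p in parsed) {
    nz <- which(p$ins_len > 0L)
    ins_len[nz] <- pmax(ins_len[nz], p$ins_len[nz])
  }
  refchars <- strsplit(reference_slice, "", fixed = TRUE)[[1]]
  build_row <- function(sub, ins) {
    segs <- character(2L * L + 1L)
    for (i in 0:L) {
      if (ins_len[i + 1L] > 0L) {
        s <- if (is.na(ins[i + 1L])) "" else ins[i + 1L]
        segs[2L * i + 1L] <- paste0(s, strrep("-", ins_len[i + 1L] - nchar(s)))
      }
      if (i < L) segs[2L * i + 2L] <- sub[i + 1L]
    }
    paste(segs, collapse = "")
  }
  ref_row <- build_row(refchars, rep(NA_character_, L + 1L))
  hap_rows <- vapply(haplotypes, function(h) {
    p <- parsed[[h]]
    build_row(p$sub, p$ins)
  }, character(1))
  list(rows = c(ref_row, unname(hap_rows)), samples = samples)
}

# Decompose one pairwise alignment into, per reference base, the aligned
# haplotype character ('-' if deleted) and, per inter-base slot (0..L), the
# inserted haplotype string.
parse_pairwise <- function(aref, ahap, L) {
  ra <- strsplit(aref, "", fixed = TRUE)[[1]]
  ha <- strsplit(ahap, "", fixed = TRUE)[[1]]
  isref <- ra != "-"
  refidx <- cumsum(isref)           # reference bases consumed through column
  sub <- ha[isref]
  ins <- character(L + 1L)
  gapcols <- which(!isref)
  if (length(gapcols)) {
    slot <- refidx[gapcols]         # 0..L bases consumed before this column
    for (s in unique(slot))
      ins[s + 1L] <- paste(ha[gapcols[slot == s]], collapse = "")
  }
  ins[ins == ""] <- NA_character_
  list(sub = sub, ins_len = ifelse(is.na(ins), 0L, nchar(ins)), ins = ins)
}

align_window_mafft <- function(reference_slice, haplotypes, samples,
                               mafft_path = "mafft") {
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  seqs <- c(REF = reference_slice, stats::setNames(haplotypes,
                                                   paste0("H", seq_along(haplotypes))))
  seqs[seqs == ""] <- "N"  # mafft cannot take empty records; N row ~ deletion
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fin)
  status <- system2(mafft_path, c("--auto", "--quiet", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status)
  aln <- Biostrings::readDNAStringSet(fout)
  rows <- toupper(as.character(aln))
  list(rows = unname(rows), samples = samples)
}

# --- atomic variant calling ------------------------------------------------

#' Call atomic variants from a window alignment
#'
#' Walks the MSA column by column.  Against the reference row, a sample gap
#' under a reference base is a 1-bp deletion, a sample base over a reference
#' gap is a 1-bp insertion anchored to the preceding reference base, and a
#' base mismatch is a SNP.  Columns where both rows are gaps emit nothing.
#' Multi-base events are deliberately decomposed (a 10-bp deletion becomes
#' ten atomic deletions) so that window-overlap conflicts can be resolved
#' per position; [merge_atomic()] reassembles them.
#'
#' @param aln result of [align_window()]
#' @param offset reference offset of the window start (added to positions)
#' @param chrom chromosome name
#' @return data.frame of atomic variants: `chrom`, `ref_pos` (0-based; for
#'   insertions the anchor = preceding reference base, -1 before the first),
#'   `kind` (snp/del1/ins1), `base`, `ins_offset`, `sample`.
#' @export
call_atomic <- function(aln, offset = 0L, chrom = "chr") {
  rr <- strsplit(aln$rows[1], "", fixed = TRUE)[[1]]
  isref <- rr != "-"
  refpos <- cumsum(isref) - 1L + offset      # ref offset per base column
  anchor <- cumsum(isref) - 1L + offset      # preceding ref base per column
  out <- vector("list", length(aln$samples))
  for (k in seq_along(aln$samples)) {
    hr <- strsplit(aln$rows[k + 1L], "", fixed = TRUE)[[1]]
    if (length(hr) != length(rr)) stop("alignment rows differ in length")
    hgap <- hr == "-"
    snp <- which(isref & !hgap & hr != rr)
    del <- which(isref & hgap)
    ins <- which(!isref & !hgap)
    recs <- list()
    if (length(snp))
      recs$snp <- data.frame(chrom = chrom, ref_pos = refpos[snp], kind = "snp",
                             base = hr[snp], ins_offset = NA_integer_,
                             sample = aln$samples[k], stringsAsFactors = FALSE)
    if (length(del))
      recs$del <- data.frame(chrom = chrom, ref_pos = refpos[del], kind = "del1",
                             base = rr[del], ins_offset = NA_integer_,
                             sample = aln$samples[k], stringsAsFactors = FALSE)
    if (length(ins)) {
      a <- anchor[ins]
      off <- stats::ave(seq_along(a), a, FUN = seq_along) - 1L
      recs$ins <- data.frame(chrom = chrom, ref_pos = a, kind = "ins1",
                             base = hr[ins], ins_offset = as.integer(off),
                             sample = aln$samples[k], stringsAsFactors = FALSE)
    }
    out[[k]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), ref_pos = integer(0),
                      kind = character(0), base = character(0),
                      ins_offset = integer(0), sample = character(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Resolve atomic-call conflicts in window overlaps
#'
#' For each sample and reference position in an overlap region where the
#' two covering windows both call and disagree, the call from the window
#' whose center is nearer that position is kept (ties: the earlier window).
#' Positions where the windows agree deduplicate to one call, and a call
#' seen by only one window (e.g. from a deletion straddling the window
#' edge, which is owned by the window holding its leftmost base) is kept.
#'
#' @param calls_by_window list of atomic-call data.frames, one per window,
#'   in window order
#' @param windows data.frame from [make_windows()]
#' @return Conflict-free atomic-call data.frame.
#' @export
resolve_overlaps <- function(calls_by_window, windows) {
  stopifnot(length(calls_by_window) == nrow(windows))
  empty_atomic <- data.frame(chrom = character(0), ref_pos = integer(0),
                             kind = character(0), base = character(0),
                             ins_offset = integer(0), sample = character(0),
                             stringsAsFactors = FALSE)
  calls_by_window <- lapply(calls_by_window, function(x)
    if (is.null(x)) empty_atomic else x)
  sig <- function(df)   # one signature per (sample, position): the call set
    vapply(split(paste(df$kind, df$base, df$ins_offset),
                 paste(df$sample, df$ref_pos)),
           function(z) paste(sort(z), collapse = "|"), character(1))
  for (w in seq_len(nrow(windows) - 1L)) {
    s <- windows$start[w + 1]; e <- windows$end[w]
    if (s >= e) next
    A <- calls_by_window[[w]]; B <- calls_by_window[[w + 1]]
    inA <- A$ref_pos >= s & A$ref_pos < e
    inB <- B$ref_pos >= s & B$ref_pos < e
    if (!any(inA) && !any(inB)) next
    keyA <- paste(A$sample, A$ref_pos)
    keyB <- paste(B$sample, B$ref_pos)
    both <- intersect(unique(keyA[inA]), unique(keyB[inB]))
    if (length(both)) {
      sa <- sig(A[inA & keyA %in% both, , drop = FALSE])
      sb <- sig(B[inB & keyB %in% both, , drop = FALSE])
      sb <- sb[names(sa)]
      pos <- as.integer(sub("^.* ", "", names(sa)))
      a_wins <- sa == sb |
        abs(pos - windows$center[w]) <= abs(pos - windows$center[w + 1])
      dropB <- names(sa)[a_wins]
      dropA <- names(sa)[!a_wins]
      calls_by_window[[w]] <- A[!(inA & keyA %in% dropA), , drop = FALSE]
      calls_by_window[[w + 1]] <- B[!(inB & keyB %in% dropB), , drop = FALSE]
    }
  }
  res <- do.call(rbind, calls_by_window)
  if (nrow(res) == 0) return(empty_atomic)
  res <- res[order(res$sample, res$chrom, res$ref_pos,
                   match(res$kind, c("snp", "del1", "ins1")), res$ins_offset),
             , drop = FALSE]
  # dedup identical atomic calls that can remain from agreeing windows
  key <- paste(res$sample, res$chrom, res$ref_pos, res$kind, res$base,
               res$ins_offset)
  res <- res[!duplicated(key), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge atomic variants into full variant records
#'
#' Maximal runs of 1-bp deletions at consecutive reference offsets merge
#' into one deletion; all 1-bp insertions at one anchor merge, in
#' `ins_offset` order, into one insertion (placed before the base following
#' the anchor); SNPs stay atomic.  An insertion anchored inside a deleted
#' span remains an independent record alongside the deletion.
#'
#' @param atomics conflict-free atomic-call data.frame
#' @return Variant data.frame (internal representation).
#' @export
merge_atomic <- function(atomics) {
  if (nrow(atomics) == 0) return(empty_variants())
  parts <- list()
  sp <- split(atomics, paste0(atomics$sample, "\r", atomics$chrom))
  for (grp in sp) {
    smp <- grp$sample[1]; chr <- grp$chrom[1]
    snp <- grp[grp$kind == "snp", , drop = FALSE]
    if (nrow(snp)) {
      if (is.null(snp$ref_base))
        stop("merge_atomic needs a ref_base column for SNPs (attach_snp_ref)")
      parts[[length(parts) + 1L]] <-
        data.frame(chrom = chr, pos = snp$ref_pos, ref = snp$ref_base,
                   alt = snp$base, sample = smp, stringsAsFactors = FALSE)
    }
    del <- grp[grp$kind == "del1", , drop = FALSE]
    if (nrow(del)) {
      del <- del[order(del$ref_pos), , drop = FALSE]
      run <- cumsum(c(1L, diff(del$ref_pos) != 1L))
      for (r in split(del, run))
        parts[[length(parts) + 1L]] <-
          data.frame(chrom = chr, pos = r$ref_pos[1],
                     ref = paste(r$base, collapse = ""), alt = "",
                     sample = smp, stringsAsFactors = FALSE)
    }
    ins <- grp[grp$kind == "ins1", , drop = FALSE]
    if (nrow(ins)) {
      for (a in split(ins, ins$ref_pos)) {
        a <- a[order(a$ins_offset), , drop = FALSE]
        parts[[length(parts) + 1L]] <-
          data.frame(chrom = chr, pos = a$ref_pos[1] + 1L, ref = "",
                     alt = paste(a$base, collapse = ""), sample = smp,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, parts)
  variant_table(res$chrom, res$pos, res$ref, res$alt, res$sample)
}

# merge_atomic needs the reference base for SNP records; callers attach it
# as column `ref_base` (call_atomic emits the sample base in `base`).
attach_snp_ref <- function(atomics, genome) {
  if (nrow(atomics) == 0) { atomics$ref_base <- character(0); return(atomics) }
  atomics$ref_base <- ""
  issnp <- atomics$kind == "snp"
  if (any(issnp))
    atomics$ref_base[issnp] <- substr(genome$seqs[atomics$chrom[issnp]],
                                      atomics$ref_pos[issnp] + 1L,
                                      atomics$ref_pos[issnp] + 1L)
  atomics
}

#' Left-align INDELs against the reference
#'
#' Shifts every deletion and insertion to its leftmost sequence-equivalent
#' reference position (the canonical placement inside repeat tracts), never
#' crossing another variant of the same sample.  Applying the normalized
#' set yields exactly the same haplotype.
#'
#' @param varset variant data.frame (any number of samples)
#' @param genome a `ref_genome`
#' @return Normalized, re-sorted variant data.frame.
#' @export
left_normalize <- function(varset, genome) {
  if (nrow(varset) == 0) return(varset)
  out <- vector("list", 0)
  for (grp in split(varset, paste0(varset$sample, "\r", varset$chrom))) {
    grp <- grp[order(grp$pos, nchar(grp$ref) > 0L), , drop = FALSE]
    g <- genome$seqs[[grp$chrom[1]]]
    prev_end <- 0L
    for (k in seq_len(nrow(grp))) {
      p <- grp$pos[k]; r <- grp$ref[k]; a <- grp$alt[k]
      if (r != "" && a == "") {            # deletion
        L <- nchar(r)
        while (p - 1L >= prev_end &&
               substr(g, p, p) == substr(r, L, L)) {
          r <- paste0(substr(g, p, p), substr(r, 1, L - 1L))
          p <- p - 1L
        }
        grp$pos[k] <- p; grp$ref[k] <- r
        prev_end <- p + L
      } else if (r == "") {                # insertion (before base p)
        L <- nchar(a)
        while (p - 1L >= prev_end &&
               substr(g, p, p) == substr(a, L, L)) {
          a <- paste0(substr(g, p, p), substr(a, 1, L - 1L))
          p <- p - 1L
        }
        grp$pos[k] <- p; grp$alt[k] <- a
        prev_end <- max(prev_end, p)
      } else {
        prev_end <- p + nchar(r)
      }
    }
    out[[length(out) + 1L]] <- grp
  }
  res <- do.call(rbind, out)
  res[order(res$sample, res$chrom, res$pos, nchar(res$ref) > 0L), ,
      drop = FALSE]
}

#' Synchronize variant calls across a population
#'
#' Runs the full window pipeline: tile each chromosome with overlapping
#' windows, rebuild each sample's haplotype per window, align all distinct
#' haplotypes with the reference, re-call atomic variants from the MSA,
#' resolve window-overlap conflicts by distance to window centers, and merge
#' atomic runs back into full INDEL/SNP records.  A sample with no calls in
#' a window contributes the plain reference slice.
#'
#' @param genome a `ref_genome`
#' @param varsets variant data.frame covering all samples (or a list of
#'   per-sample data.frames, which is row-bound)
#' @param samples sample identifiers (defaults to those present; samples
#'   with no calls at all can be forced in here)
#' @param window,overlap window tiling parameters (defaults 50000 / 1000)
#' @param engine alignment engine passed to [align_window()]
#' @param band_extra builtin aligner band margin
#' @return list with `variants` (synchronized variant data.frame across all
#'   samples) and `report` (per sample: `n_input_indels`, `n_reassigned` —
#'   INDELs whose synchronized representation differs at all —,
#'   `n_reassigned_poslen` — differing in position or length —, `fraction`).
#' @export
synchronize_population <- function(genome, varsets, samples = NULL,
                                   window = 50000L, overlap = 1000L,
                                   engine = "builtin", band_extra = 100L) {
  if (is.list(varsets) && !is.data.frame(varsets))
    varsets <- do.call(rbind, varsets)
  if (is.null(samples)) samples <- sort(unique(varsets$sample))
  validate_variants(genome, varsets)
  all_out <- list()
  for (chrom in names(genome$seqs)) {
    clen <- nchar(genome$seqs[[chrom]])
    wins <- make_windows(clen, window, overlap)
    cv <- varsets[varsets$chrom == chrom, , drop = FALSE]
    calls_by_window <- vector("list", nrow(wins))
    bysample <- split(cv, cv$sample)
    for (w in seq_len(nrow(wins))) {
      hv <- lapply(samples, function(smp) {
        sv <- bysample[[smp]]
        if (is.null(sv)) sv <- empty_variants()
        apply_variants(genome, sv, chrom, wins$start[w], wins$end[w])
      })
      # a deletion straddling the window edge (owned here via its leftmost
      # base) extends the window; pad all rows to the common extent
      eff_end <- max(wins$end[w], vapply(hv, `[[`, numeric(1), "end"))
      rslice <- ref_slice(genome, chrom, wins$start[w], eff_end)
      haps <- vapply(hv, function(h)
        paste0(h$seq, ref_slice(genome, chrom, h$end, eff_end)), character(1))
      names(haps) <- samples
      if (all(haps == rslice)) next
      aln <- align_window(rslice, haps, engine = engine,
                          band_extra = band_extra)
      calls_by_window[[w]] <- call_atomic(aln, offset = wins$start[w],
                                          chrom = chrom)
    }
    resolved <- resolve_overlaps(calls_by_window, wins)
    resolved <- attach_snp_ref(resolved, genome)
    all_out[[chrom]] <- left_normalize(merge_atomic(resolved), genome)
  }
  merged <- do.call(rbind, all_out)
  if (is.null(merged)) merged <- empty_variants()
  rownames(merged) <- NULL
  list(variants = merged, report = reassignment_report(varsets, merged, samples))
}

reassignment_report <- function(input, output, samples) {
  rep_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  poslen_key <- function(df)
    paste(df$chrom, df$pos,
          ifelse(nchar(df$ref) > 0, nchar(df$ref), -nchar(df$alt)))
  out <- lapply(samples, function(smp) {
    iv <- input[input$sample == smp & nchar(input$ref) != nchar(input$alt), ,
                drop = FALSE]
    ov <- output[output$sample == smp & nchar(output$ref) != nchar(output$alt), ,
                 drop = FALSE]
    n_in <- nrow(iv)
    n_re <- sum(!(rep_key(iv) %in% rep_key(ov)))
    n_pl <- sum(!(poslen_key(iv) %in% poslen_key(ov)))
    data.frame(sample = smp, n_input_indels = n_in, n_reassigned = n_re,
               n_reassigned_poslen = n_pl,
               fraction = if (n_in > 0) n_re / n_in else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a synchronized population as a multi-sample VCF
#'
#' Markers are the distinct (chrom, pos, ref, alt) records of the
#' synchronized table; genotypes are haploid 0/1 with `.` never emitted
#' (synchronization re-calls every sample, so absence means reference).
#'
#' @param sync result of [synchronize_population()]
#' @param genome a `ref_genome`
#' @param samples sample order for the columns
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(sync, genome, samples, path) {
  v <- sync$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=indelsync",
           paste0("##contig=<ID=", names(genome$seqs), ",length=",
                  chrom_lengths(genome), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(0)
  if (nrow(v) > 0) {
    key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
    uk <- unique(key[order(v$chrom, v$pos)])
    rows <- vapply(uk, function(k) {
      sel <- v[key == k, , drop = FALSE]
      p <- sel$pos[1]; r <- sel$ref[1]; a <- sel$alt[1]; chr <- sel$chrom[1]
      if (r == "" || a == "") {
        ap <- p - 1L
        anchor <- if (ap >= 0) ref_slice(genome, chr, ap, ap + 1L) else "N"
        r <- paste0(anchor, r); a <- paste0(anchor, a); p <- ap
      }
      gt <- ifelse(samples %in% sel$sample, "1", "0")
      paste(c(chr, p + 1L, ".", r, a, ".", "PASS", ".", "GT", gt),
            collapse = "\t")
    }, character(1), USE.NAMES = FALSE)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
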