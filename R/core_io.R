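#' @useDynLib indelsync, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Coordinate conventions (used throughout the package):
#   * all internal positions are 0-based, intervals half-open [start, end)
#   * a SNP or deletion has `pos` = offset of the first reference base it
#     consumes; `ref` holds the consumed bases, `alt` the replacement
#     ("" for a pure deletion)
#   * an insertion has `ref` = "", and `pos` = offset of the reference base
#     BEFORE which the new sequence is inserted, i.e. it follows (is
#     anchored to) reference base pos - 1
#   * VCF input/output converts to/from 1-based anchored representation at
#     the boundary and nowhere else
# ---------------------------------------------------------------------------

#' Construct an in-memory reference genome
#'
#' @param seqs named character vector of uppercase DNA sequences
#'   (chromosome name -> sequence).
#' @return An object of class `ref_genome`.
#' @export
ref_genome <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique chromosome names")
  nm <- names(seqs)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence for ", names(seqs)[bad][1], " contains non-ACGTN characters")
  structure(list(seqs = seqs), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome with", length(x$seqs), "sequence(s):\n")
  for (nm in names(x$seqs)) cat(" ", nm, nchar(x$seqs[[nm]]), "bp\n")
  invisible(x)
}

#' Chromosome lengths of a reference genome
#' @param genome a `ref_genome`
#' @return Named integer vector.
#' @export
chrom_lengths <- function(genome) {
  vapply(genome$seqs, nchar, integer(1))
}

#' Extract a reference slice (0-based half-open)
#' @param genome a `ref_genome`
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @return Character scalar.
#' @export
ref_slice <- function(genome, chrom, start, end) {
  s <- genome$seqs[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > nchar(s) || start > end)
    stop("interval [", start, ",", end, ") outside ", chrom)
  substr(s, start + 1, end)
}

#' Read a multi-record FASTA reference
#'
#' Sequences are uppercased; duplicate record names and non-ACGTN characters
#' are errors.
#'
#' @param path FASTA file.
#' @return A `ref_genome`.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicated sequence name in ", path)
  seqs <- as.character(ss)
  names(seqs) <- nm
  ref_genome(seqs)
}

#' Write a reference genome to FASTA
#' @param genome a `ref_genome`
#' @param path output file
#' @param width line width
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

empty_variants <- function(sample = character(0)) {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), sample = character(0),
             support = integer(0), het = logical(0),
             stringsAsFactors = FALSE)
}

#' Assemble a variant table
#'
#' Normalizes a set of variant calls for one or more samples into the
#' internal 0-based representation (see package conventions) and sorts it.
#'
#' @param chrom,pos,ref,alt,sample vectors of equal length (`pos` 0-based).
#' @param support optional read support counts (NA = unknown).
#' @param het optional heterozygosity flags (NA = unknown).
#' @return A sorted data.frame of variant calls.
#' @export
variant_table <- function(chrom, pos, ref, alt, sample,
                          support = NA_integer_, het = NA) {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   sample = as.character(sample),
                   support = rep_len(as.integer(support), n),
                   het = rep_len(as.logical(het), n),
                   stringsAsFactors = FALSE)
  if (any(df$ref == "" & df$alt == ""))
    stop("variant with both alleles empty")
  df[order(df$sample, df$chrom, df$pos, nchar(df$ref) > 0L), , drop = FALSE]
}

#' Validate a per-sample variant set against a reference
#'
#' Checks that every `ref` allele matches the reference sequence, that spans
#' stay inside the chromosome, and that no two reference-consuming calls of
#' one sample overlap (an input error for inbred haploid calls).  Two
#' insertions of one sample at the same position are rejected as ambiguous.
#'
#' @param genome a `ref_genome`
#' @param varset variant data.frame (one or more samples)
#' @return `varset`, invisibly, if valid.
#' @export
validate_variants <- function(genome, varset) {
  if (nrow(varset) == 0) return(invisible(varset))
  lens <- chrom_lengths(genome)
  if (!all(varset$chrom %in% names(lens)))
    stop("variant on unknown chromosome")
  rl <- nchar(varset$ref)
  if (any(varset$pos < 0 | varset$pos + rl > lens[varset$chrom]))
    stop("variant outside chromosome bounds")
  obs <- substr(genome$seqs[varset$chrom], varset$pos + 1, varset$pos + rl)
  bad <- rl > 0 & obs != varset$ref
  if (any(bad))
    stop("reference allele mismatch at ", varset$chrom[bad][1], ":",
         varset$pos[bad][1], " (expected ", obs[bad][1], ", got ",
         varset$ref[bad][1], ")")
  for (sp in split(varset, paste(varset$sample, varset$chrom))) {
    sp <- sp[order(sp$pos), , drop = FALSE]
    cons <- sp[nchar(sp$ref) > 0, , drop = FALSE]
    if (nrow(cons) > 1) {
      ends <- cons$pos + nchar(cons$ref)
      if (any(cons$pos[-1] < ends[-nrow(cons)]))
        stop("overlapping reference spans within sample ", sp$sample[1])
    }
    ins <- sp[nchar(sp$ref) == 0, , drop = FALSE]
    if (anyDuplicated(ins$pos))
      stop("two insertions at one position within sample ", sp$sample[1])
  }
  invisible(varset)
}

#' Read one sample's variant calls from a VCF file
#'
#' Coordinates are converted to the internal 0-based convention and the
#' VCF anchor base of INDELs is stripped, so that `ref` and `alt` share no
#' common prefix.  Read support is taken from an integer `SUP` INFO key and
#' heterozygosity from a `HET` flag when present.
#'
#' @param path single-sample VCF 4.x file.
#' @param sample sample identifier to assign.
#' @param genome optional `ref_genome`; when given, REF alleles are
#'   validated and mismatches are errors.
#' @return Variant data.frame for the sample.
#' @export
read_sample_vcf <- function(path, sample, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0) return(empty_variants())
  if (any(grepl(",", fx[, "ALT"])))
    stop("multi-allelic ALT in per-sample VCF: ", path)
  info <- v@fix[, "INFO"]
  sup <- suppressWarnings(as.integer(sub("^.*SUP=([0-9]+).*$", "\\1",
                                         ifelse(grepl("SUP=", info), info, NA))))
  het <- grepl("(^|;)HET(;|$|=1)", ifelse(is.na(info), "", info))
  pos1 <- as.integer(fx[, "POS"])
  refs <- toupper(fx[, "REF"]); alts <- toupper(fx[, "ALT"])
  alts[is.na(alts) | alts == "."] <- ""
  # strip the longest common prefix of REF/ALT
  out <- mapply(function(p, r, a) {
    k <- 0L
    while (k < nchar(r) && k < nchar(a) &&
           substr(r, k + 1, k + 1) == substr(a, k + 1, k + 1)) k <- k + 1L
    c(pos = p - 1L + k, ref = substr(r, k + 1, nchar(r)),
      alt = substr(a, k + 1, nchar(a)))
  }, pos1, refs, alts, SIMPLIFY = FALSE)
  df <- variant_table(chrom = fx[, "CHROM"],
                      pos = vapply(out, function(z) as.integer(z[["pos"]]), integer(1)),
                      ref = vapply(out, `[[`, character(1), "ref"),
                      alt = vapply(out, `[[`, character(1), "alt"),
                      sample = sample, support = sup, het = het)
  if (!is.null(genome)) validate_variants(genome, df)
  df
}

#' Apply a sample's variants to a reference interval
#'
#' Edits the reference slice `[start, end)` left to right with the sample's
#' calls and returns the haplotype together with a monotone coordinate map.
#' A variant whose leftmost reference base lies inside the interval is
#' applied in full even if it extends past `end` (the interval then grows;
#' see `$end` of the result).  An insertion is owned by the interval holding
#' the base it follows (the first interval when it precedes the chromosome).
#'
#' @param genome a `ref_genome`
#' @param varset variant data.frame for ONE sample
#' @param chrom chromosome
#' @param start,end 0-based half-open interval
#' @return list with `seq` (haplotype string), `ref2hap` (integer vector,
#'   one entry per reference base of `[start, $end)`, 0-based haplotype
#'   offset or NA for deleted bases), `chrom`, `start`, `end` (possibly
#'   extended), `requested_end`.
#' @export
apply_variants <- function(genome, varset, chrom, start, end) {
  refseq <- genome$seqs[[chrom]]
  if (is.null(refseq)) stop("unknown chromosome: ", chrom)
  end <- min(end, nchar(refseq))
  vs <- varset[varset$chrom == chrom, , drop = FALSE]
  if (nrow(vs) > 0 && length(unique(vs$sample)) > 1)
    stop("apply_variants expects a single sample")
  cons <- nchar(vs$ref) > 0
  own <- (cons & vs$pos >= start & vs$pos < end) |
         (!cons & (vs$pos - 1L >= start | (start == 0L & vs$pos == 0L)) &
            vs$pos - 1L < end)
  vs <- vs[own, , drop = FALSE]
  eff_end <- end
  if (nrow(vs) > 0)
    eff_end <- max(end, max(vs$pos + nchar(vs$ref)))
  width <- eff_end - start
  ref2hap <- rep(NA_integer_, width)
  if (nrow(vs) == 0) {
    if (width > 0) ref2hap <- seq_len(width) - 1L
    return(list(seq = substr(refseq, start + 1, eff_end), ref2hap = ref2hap,
                chrom = chrom, start = start, end = eff_end,
                requested_end = end))
  }
  # insertions before base p sort ahead of events consuming base p
  vs <- vs[order(vs$pos, nchar(vs$ref) > 0L), , drop = FALSE]
  pieces <- character(0)
  cur <- start; haplen <- 0L
  emit_ref <- function(upto) {
    if (upto > cur) {
      pieces[[length(pieces) + 1L]] <<- substr(refseq, cur + 1, upto)
      idx <- (cur - start + 1L):(upto - start)
      ref2hap[idx] <<- haplen + seq_along(idx) - 1L
      haplen <<- haplen + (upto - cur)
      cur <<- upto
    }
  }
  for (k in seq_len(nrow(vs))) {
    p <- vs$pos[k]; r <- vs$ref[k]; a <- vs$alt[k]
    if (r == "") {                       # insertion before base p
      emit_ref(min(p, eff_end))
      if (nchar(a) > 0) {
        pieces[[length(pieces) + 1L]] <- a
        haplen <- haplen + nchar(a)
      }
    } else {
      if (p < cur) stop("overlapping reference-consuming variants")
      emit_ref(p)
      obs <- substr(refseq, p + 1, p + nchar(r))
      if (obs != r)
        stop("reference mismatch at ", chrom, ":", p)
      if (nchar(a) > 0) {
        pieces[[length(pieces) + 1L]] <- a
        nmap <- min(nchar(r), nchar(a))
        if (nmap > 0)
          ref2hap[(p - start + 1L):(p - start + nmap)] <- haplen + 0:(nmap - 1L)
        haplen <- haplen + nchar(a)
      }
      cur <- p + nchar(r)
    }
  }
  emit_ref(eff_end)
  list(seq = paste(pieces, collapse = ""), ref2hap = ref2hap,
       chrom = chrom, start = start, end = eff_end, requested_end = end)
}

#' Lift a reference position through a haplotype coordinate map
#'
#' A position deleted on the haplotype maps to the left edge of its
#' deletion (the haplotype offset where the deleted block collapsed).
#'
#' @param hap result of [apply_variants()]
#' @param pos 0-based reference position(s) within `[hap$start, hap$end]`;
#'   `hap$end` maps to the haplotype length.
#' @return Integer vector of 0-based haplotype offsets.
#' @export
lift_position <- function(hap, pos) {
  haplen <- nchar(hap$seq)
  vapply(pos, function(p) {
    if (p >= hap$end) return(haplen)
    if (p < hap$start) return(0L)
    v <- hap$ref2hap[p - hap$start + 1L]
    if (!is.na(v)) return(v)
    prior <- hap$ref2hap[seq_len(p - hap$start)]
    prior <- prior[!is.na(prior)]
    if (length(prior) == 0) 0L else max(prior) + 1L
  }, integer(1))
}

#' Read gene models from a GFF3 file
#'
#' Expects gene / mRNA / exon / CDS features with ID/Parent attributes.
#' Intervals are converted to the internal 0-based half-open convention.
#' One transcript per gene is assumed (the first, by position).
#'
#' @param path GFF3 file.
#' @return A named list of `gene_model` objects (names = gene ids).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  out <- list()
  mrnas <- which(typ %in% c("mRNA", "transcript"))
  for (i in mrnas) {
    tid <- as.character(md$ID[i])
    par <- as.character(unlist(md$Parent[i]))
    kids_exon <- which(typ == "exon" &
                         vapply(md$Parent, function(p) tid %in% as.character(p), logical(1)))
    kids_cds <- which(typ == "CDS" &
                        vapply(md$Parent, function(p) tid %in% as.character(p), logical(1)))
    iv <- function(idx) {
      m <- cbind(start = BiocGenerics::start(gr)[idx] - 1L,
                 end = BiocGenerics::end(gr)[idx])
      m[order(m[, 1]), , drop = FALSE]
    }
    gm <- gene_model(gene_id = if (length(par)) par else tid,
                     transcript_id = tid,
                     chrom = as.character(GenomicRanges::seqnames(gr)[i]),
                     strand = as.character(BiocGenerics::strand(gr)[i]),
                     exons = iv(kids_exon), cds = iv(kids_cds))
    if (!gm$gene_id %in% names(out)) out[[gm$gene_id]] <- gm
  }
  out
}

#' Construct a gene model
#'
#' @param gene_id,transcript_id identifiers
#' @param chrom chromosome
#' @param strand "+" or "-"
#' @param exons,cds two-column matrices of 0-based half-open intervals,
#'   sorted, non-overlapping; CDS must be contained in exons and the spliced
#'   CDS length divisible by 3.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, transcript_id = gene_id, chrom, strand,
                       exons, cds) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.integer(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  chk <- function(m, what) {
    if (nrow(m) == 0) stop(gene_id, ": no ", what, " intervals")
    if (any(m[, 2] <= m[, 1])) stop(gene_id, ": empty ", what, " interval")
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2]))
      stop(gene_id, ": overlapping ", what, " intervals")
  }
  chk(exons, "exon"); chk(cds, "CDS")
  inside <- vapply(seq_len(nrow(cds)), function(k)
    any(exons[, 1] <= cds[k, 1] & cds[k, 2] <= exons[, 2]), logical(1))
  if (!all(inside)) stop(gene_id, ": CDS not contained in exons")
  if (sum(cds[, 2] - cds[, 1]) %% 3L != 0L)
    stop(gene_id, ": spliced CDS length not divisible by 3")
  if (!strand %in% c("+", "-")) stop(gene_id, ": strand must be + or -")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "(", x$chrom, x$strand, ")",
      nrow(x$exons), "exons,", nrow(x$cds), "CDS segments\n")
  invisible(x)
}

#' Write gene models to GFF3
#' @param models list of `gene_model`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- c("##gff-version 3")
  for (gm in models) {
    span <- range(c(gm$exons, gm$cds))
    g <- function(type, s, e, attr)
      paste(gm$chrom, "indelsync", type, s + 1L, e, ".", gm$strand, ".",
            attr, sep = "\t")
    lines <- c(lines,
               g("gene", span[1], span[2], paste0("ID=", gm$gene_id)),
               g("mRNA", span[1], span[2],
                 paste0("ID=", gm$transcript_id, ";Parent=", gm$gene_id)))
    for (k in seq_len(nrow(gm$exons)))
      lines <- c(lines, g("exon", gm$exons[k, 1], gm$exons[k, 2],
                          paste0("ID=", gm$transcript_id, ".exon", k,
                                 ";Parent=", gm$transcript_id)))
    for (k in seq_len(nrow(gm$cds)))
      lines <- c(lines, g("CDS", gm$cds[k, 1], gm$cds[k, 2],
                          paste0("ID=", gm$transcript_id, ".cds", k,
                                 ";Parent=", gm$transcript_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column phenotype table
#' @param path TSV with columns sample id and phenotype value (header
#'   optional).
#' @return data.frame with columns `sample`, `value`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype table needs two columns")
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  data.frame(sample = as.character(df[, 1]),
             value = as.numeric(df[, 2]), stringsAsFactors = FALSE)
}

#' Read a BED file of regions
#' @param path BED file (0-based half-open, as the format specifies).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
}

#' Write per-sample variants as a single-sample VCF
#' @param varset variant data.frame for one sample
#' @param genome a `ref_genome` (for anchor bases)
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(varset, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=indelsync"),
           paste0("##contig=<ID=", names(genome$seqs), ",length=",
                  chrom_lengths(genome), ">"),
           '##INFO=<ID=SUP,Number=1,Type=Integer,Description="Read support">',
           '##INFO=<ID=HET,Number=0,Type=Flag,Description="Heterozygous call">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(varset) > 0) {
    vs <- varset[order(varset$chrom, varset$pos), , drop = FALSE]
    rows <- vapply(seq_len(nrow(vs)), function(k) {
      p <- vs$pos[k]; r <- vs$ref[k]; a <- vs$alt[k]
      if (r == "" || a == "") {          # re-anchor INDELs on the prior base
        anchor_pos <- p - 1L
        anchor <- if (anchor_pos >= 0)
          ref_slice(genome, vs$chrom[k], anchor_pos, anchor_pos + 1L) else "N"
        r <- paste0(anchor, r); a <- paste0(anchor, a)
        p <- anchor_pos
      }
      info <- character(0)
      if (!is.na(vs$support[k])) info <- c(info, paste0("SUP=", vs$support[k]))
      if (isTRUE(vs$het[k])) info <- c(info, "HET")
      paste(vs$chrom[k], p + 1L, ".", r, a, ".", "PASS",
            if (length(info)) paste(info, collapse = ";") else ".",
            sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
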