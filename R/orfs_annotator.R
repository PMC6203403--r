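# Per-gene, per-sample open reading frame state (ORFS) annotation.
#
# A gene's ORFS in a sample is decided from up to three annotation routes
# (coordinate lift-over, spliced alignment of the reference CDS, spliced
# alignment of the reference protein) evaluated against four criteria
# (start/stop codons intact, splice motifs intact, no premature stop,
# spliced CDS length divisible by 3).  The call is conservative: the ORFS
# is interrupted only when EVERY evaluable route violates at least one
# criterion; a single fully passing route keeps the gene conserved.

STOP_CODONS <- c("TAA", "TAG", "TGA")
SPLICE_WHITELIST <- c("GT-AG", "GC-AG", "GG-AG", "GT-TG", "GT-CG", "CT-AG")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a gene's haplotype with flanks
#'
#' Rebuilds the sample's sequence over the gene span plus `flank` bases on
#' each side and expresses model coordinates, sequence and coordinate map
#' on the coding strand (minus-strand genes are reverse-complemented).
#'
#' @param genome a `ref_genome`
#' @param varset variant data.frame for one sample (may be empty)
#' @param model a [gene_model()]
#' @param flank flank size on each side (default 1000)
#' @return An object of class `gene_hap`: fields `seq` (haplotype, coding
#'   strand), `ref_seq` (reference sequence of the same span, coding
#'   strand), `model` (exon/CDS intervals in coding-strand local
#'   coordinates of `ref_seq`), `ref2hap` (per `ref_seq` base: haplotype
#'   offset or NA if deleted), `gene_id`, `sample`, `strand`, `span`.
#' @export
extract_gene_haplotype <- function(genome, varset, model, flank = 1000L) {
  clen <- chrom_lengths(genome)[[model$chrom]]
  lo <- min(model$exons[, 1], model$cds[, 1])
  hi <- max(model$exons[, 2], model$cds[, 2])
  s0 <- lo - flank; e0 <- hi + flank
  if (s0 < 0 || e0 > clen) {
    warning(model$gene_id, ": flanked span clipped to chromosome")
    s0 <- max(0L, s0); e0 <- min(clen, e0)
  }
  smp <- if (nrow(varset)) varset$sample[1] else NA_character_
  hv <- apply_variants(genome, varset, model$chrom, s0, e0)
  W <- hv$end - s0
  rseq <- ref_slice(genome, model$chrom, s0, hv$end)
  loc <- function(m) cbind(start = m[, 1] - s0, end = m[, 2] - s0)
  exons <- loc(model$exons); cds <- loc(model$cds)
  seq <- hv$seq; map <- hv$ref2hap
  if (model$strand == "-") {
    seq <- revcomp(seq); rseq <- revcomp(rseq)
    haplen <- nchar(hv$seq)
    map <- rev(ifelse(is.na(hv$ref2hap), NA_integer_,
                      haplen - 1L - hv$ref2hap))
    flip <- function(m) {
      out <- cbind(start = W - m[, 2], end = W - m[, 1])
      out[rev(seq_len(nrow(out))), , drop = FALSE]
    }
    exons <- flip(exons); cds <- flip(cds)
  }
  structure(list(gene_id = model$gene_id, sample = smp, seq = seq,
                 ref_seq = rseq, model = list(exons = exons, cds = cds),
                 ref2hap = map, strand = model$strand, flank = flank,
                 span = c(start = s0, end = hv$end)),
            class = "gene_hap")
}

# lift a coding-strand local reference position through the haplotype map;
# a deleted position maps to the left edge of its deletion on the haplotype
lift_local <- function(hap, pos) {
  haplen <- nchar(hap$seq)
  W <- length(hap$ref2hap)
  vapply(pos, function(p) {
    if (p >= W) return(haplen)
    if (p < 0) return(0L)
    v <- hap$ref2hap[p + 1L]
    if (!is.na(v)) return(as.integer(v))
    prior <- hap$ref2hap[seq_len(p)]
    prior <- prior[!is.na(prior)]
    if (length(prior) == 0) 0L else as.integer(max(prior) + 1L)
  }, integer(1))
}

merge_intervals <- function(m) {
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) < 2) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (k in 2:nrow(m)) {
    if (m[k, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[k, 2])
    } else out <- rbind(out, m[k, , drop = FALSE])
  }
  out
}

new_annotation <- function(route, cds, score = NA_real_, evaluable = TRUE) {
  cds <- matrix(as.integer(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  list(route = route, cds = merge_intervals(cds), score = score,
       evaluable = evaluable && nrow(merge_intervals(cds)) > 0)
}

#' Annotate a gene haplotype by coordinate lift-over
#'
#' Maps every reference CDS boundary through the haplotype coordinate map;
#' a boundary deleted on the haplotype maps to the left edge of the
#' deletion.  Intervals emptied by deletions are dropped and abutting
#' intervals merged.
#'
#' @param hap a `gene_hap`
#' @return A candidate annotation (route `"liftover"`).
#' @export
annotate_by_liftover <- function(hap) {
  cds <- hap$model$cds
  m <- cbind(lift_local(hap, cds[, 1]), lift_local(hap, cds[, 2]))
  new_annotation("liftover", m)
}

#' Annotate a gene haplotype by spliced alignment
#'
#' Aligns the reference spliced CDS (mode `"cds"`, nucleotide level) or
#' reference protein (mode `"protein"`, codon level over all frames)
#' against the haplotype with an est2genome-style dynamic program: exon
#' match/mismatch with affine gaps plus an intron state (flat entry
#' penalty, minimum length 10).  Only the best-scoring alignment is kept;
#' an alignment scoring below `min_score` renders the route unevaluable.
#' In protein mode the final aligned codon is extended by one codon so the
#' stop codon participates in the criteria.
#'
#' @param hap a `gene_hap`
#' @param mode `"cds"` or `"protein"`
#' @param min_score minimum alignment score (default 10, below which the
#'   route reports unevaluable)
#' @param intron_penalty,min_intron,max_intron intron state parameters
#' @return A candidate annotation (route `"cds_align"` or
#'   `"protein_align"`).
#' @export
annotate_by_spliced_alignment <- function(hap, mode = c("cds", "protein"),
                                          min_score = 10,
                                          intron_penalty = 10,
                                          min_intron = 10,
                                          max_intron = 30000) {
  mode <- match.arg(mode)
  query <- hap$query_cds
  if (is.null(query)) {
    cds_iv <- hap$model$cds
    query <- paste(substring(hap$ref_seq, cds_iv[, 1] + 1, cds_iv[, 2]),
                   collapse = "")
  }
  if (mode == "cds") {
    al <- cpp_spliced_align_nt(hap$seq, query,
                               intron_penalty = intron_penalty,
                               min_intron = min_intron)
    route <- "cds_align"
  } else {
    prot <- cpp_translate(query)
    prot <- sub("\\*$", "", prot)
    if (nchar(prot) == 0)
      return(new_annotation("protein_align", matrix(integer(0), ncol = 2),
                            evaluable = FALSE))
    al <- cpp_spliced_align_aa(hap$seq, prot,
                               intron_penalty = intron_penalty,
                               min_intron = min_intron)
    route <- "protein_align"
  }
  ex <- al$exons
  if (route == "protein_align" && nrow(ex) > 0)
    ex[nrow(ex), 2] <- min(nchar(hap$seq), ex[nrow(ex), 2] + 3L)
  ok <- al$score >= min_score
  if (nrow(al$introns) > 0 &&
      any(al$introns[, 2] - al$introns[, 1] > max_intron))
    ok <- FALSE
  new_annotation(route, ex, score = al$score, evaluable = ok)
}

#' Evaluate the four ORF criteria for one candidate annotation
#'
#' @param ann a candidate annotation (see [annotate_by_liftover()])
#' @param hap the `gene_hap` it annotates
#' @return Named logical vector: `start_stop_intact` (first codon ATG, last
#'   codon a canonical stop), `splice_intact` (every donor-acceptor pair
#'   equals the reference pair for that intron or is one of GT-AG, GC-AG,
#'   GG-AG, GT-TG, GT-CG, CT-AG), `no_premature_stop`, `frame_ok` (spliced
#'   CDS length divisible by 3).
#' @export
evaluate_criteria <- function(ann, hap) {
  cds <- ann$cds
  spliced <- paste(substring(hap$seq, cds[, 1] + 1, cds[, 2]), collapse = "")
  n <- nchar(spliced)
  frame_ok <- n > 0 && n %% 3L == 0L
  start_ok <- n >= 6 && substr(spliced, 1, 3) == "ATG"
  stop_ok <- n >= 6 && substr(spliced, n - 2, n) %in% STOP_CODONS
  aa <- if (n >= 3) cpp_translate(substr(spliced, 1, 3 * (n %/% 3))) else ""
  ncod <- nchar(aa)
  no_premature <- !(ncod > 1 && grepl("\\*", substr(aa, 1, ncod - 1L)))
  if (ncod >= 1 && frame_ok) {
    # a stop in the last codon is the terminator, not premature
  } else if (ncod >= 1 && substr(aa, ncod, ncod) == "*") {
    no_premature <- FALSE              # frame lost: trailing stop is spurious
  }
  pairs <- splice_pairs(hap$seq, cds)
  ref_pairs <- hap$ref_pairs
  if (is.null(ref_pairs)) ref_pairs <- splice_pairs(hap$ref_seq, hap$model$cds)
  splice_ok <- TRUE
  if (length(pairs)) {
    for (t in seq_along(pairs)) {
      ok <- pairs[t] %in% SPLICE_WHITELIST ||
        (t <= length(ref_pairs) && pairs[t] == ref_pairs[t])
      if (!ok) { splice_ok <- FALSE; break }
    }
  }
  c(start_stop_intact = start_ok && stop_ok, splice_intact = splice_ok,
    no_premature_stop = no_premature, frame_ok = frame_ok)
}

splice_pairs <- function(seq, cds) {
  if (nrow(cds) < 2) return(character(0))
  vapply(seq_len(nrow(cds) - 1L), function(t) {
    s <- cds[t, 2]; e <- cds[t + 1L, 1]     # intron [s, e)
    if (e - s < 4) return("--")
    paste0(substr(seq, s + 1, s + 2), "-", substr(seq, e - 1, e))
  }, character(1))
}

#' Decide a gene's ORF state from evaluated routes
#'
#' The conservative rule: the ORFS is `interrupted` only if every evaluable
#' route violates at least one criterion; if any route passes all criteria
#' the gene is `conserved`; if no route is evaluable the state is
#' `missing`.
#'
#' @param route_flags list of named logical vectors from
#'   [evaluate_criteria()] (unevaluable routes excluded by the caller, or
#'   passed as NULL entries)
#' @return Character scalar: `"conserved"`, `"interrupted"` or
#'   `"missing"`.
#' @export
call_orfs <- function(route_flags) {
  route_flags <- Filter(Negate(is.null), route_flags)
  if (length(route_flags) == 0) return("missing")
  passes <- vapply(route_flags, all, logical(1))
  if (any(passes)) "conserved" else "interrupted"
}

#' Full ORFS call for one gene in one sample
#'
#' Extracts the haplotype, runs the three annotation routes and applies the
#' conservative decision rule.  When `alt_reference` names another sample,
#' that sample's haplotype of the gene supplies the query CDS/protein and
#' reference splice pairs (used when the reference genome itself carries a
#' non-functional copy of the gene).
#'
#' @param genome a `ref_genome`
#' @param varset variant data.frame for the target sample
#' @param model a [gene_model()]
#' @param flank flank size (default 1000)
#' @param alt_reference optional variant data.frame of the replacement
#'   reference sample for this gene
#' @param min_score spliced-alignment score floor
#' @return list with `state`, `routes` (per-route criterion flags and
#'   scores), `hap`.
#' @export
orfs_call_gene <- function(genome, varset, model, flank = 1000L,
                           alt_reference = NULL, min_score = 10) {
  hap <- extract_gene_haplotype(genome, varset, model, flank)
  if (!is.null(alt_reference)) {
    # the replacement sample supplies the query CDS/protein and reference
    # splice pairs; lift-over still maps the reference-coordinate model
    alt <- extract_gene_haplotype(genome, alt_reference, model, flank)
    alt_ann <- annotate_by_liftover(alt)
    hap$query_cds <- paste(substring(alt$seq, alt_ann$cds[, 1] + 1,
                                     alt_ann$cds[, 2]), collapse = "")
    hap$ref_pairs <- splice_pairs(alt$seq, alt_ann$cds)
  }
  anns <- list(liftover = annotate_by_liftover(hap),
               cds_align = annotate_by_spliced_alignment(hap, "cds",
                                                         min_score = min_score),
               protein_align = annotate_by_spliced_alignment(hap, "protein",
                                                             min_score = min_score))
  flags <- lapply(anns, function(a)
    if (isTRUE(a$evaluable)) evaluate_criteria(a, hap) else NULL)
  list(state = call_orfs(flags),
       routes = list(annotations = anns, flags = flags), hap = hap)
}

#' ORFS matrix over genes and samples
#'
#' @param genome a `ref_genome`
#' @param varsets variant data.frame for all samples
#' @param models list of `gene_model`
#' @param samples sample ids (default: those in `varsets`)
#' @param flank,min_score see [orfs_call_gene()]
#' @param alt_reference optional named list: gene id -> sample id whose
#'   haplotype replaces the reference copy for that gene
#' @return Integer matrix genes x samples: 0 conserved, 1 interrupted, NA
#'   missing.
#' @export
orfs_matrix <- function(genome, varsets, models, samples = NULL,
                        flank = 1000L, min_score = 10,
                        alt_reference = NULL) {
  if (is.null(samples)) samples <- sort(unique(varsets$sample))
  bysample <- split(varsets, varsets$sample)
  m <- matrix(NA_integer_, length(models), length(samples),
              dimnames = list(vapply(models, `[[`, character(1), "gene_id"),
                              samples))
  for (gi in seq_along(models)) {
    gm <- models[[gi]]
    altvs <- NULL
    if (!is.null(alt_reference) && gm$gene_id %in% names(alt_reference)) {
      alt_smp <- alt_reference[[gm$gene_id]]
      altvs <- bysample[[alt_smp]]
      if (is.null(altvs)) altvs <- empty_variants()
    }
    for (si in seq_along(samples)) {
      sv <- bysample[[samples[si]]]
      if (is.null(sv)) sv <- empty_variants()
      st <- orfs_call_gene(genome, sv, gm, flank = flank,
                           alt_reference = altvs,
                           min_score = min_score)$state
      m[gi, si] <- switch(st, conserved = 0L, interrupted = 1L,
                          missing = NA_integer_)
    }
  }
  m
}

#' Trustability of an ORFS call
#'
#' An ORFS call is trustable when every CDS base has read coverage of at
#' least one and every INDEL inside the CDS is confirmed by both assembly
#' routes.  Absent inputs count as passing, so the pipeline runs without
#' read-level data.
#'
#' @param cds_coverage optional numeric vector of per-base CDS coverage
#' @param indel_confirmed optional logical vector, one per CDS INDEL
#' @return Logical scalar.
#' @export
flag_trustable <- function(cds_coverage = NULL, indel_confirmed = NULL) {
  cov_ok <- is.null(cds_coverage) || all(cds_coverage >= 1)
  conf_ok <- is.null(indel_confirmed) || all(indel_confirmed)
  cov_ok && conf_ok
}

#' Write an ORFS matrix as TSV
#' @param m matrix from [orfs_matrix()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_orfs_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
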