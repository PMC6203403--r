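# Detection of genes whose loss of function arose from independent
# mutations.  ORFS-shifting haplotype classes of a gene (samples sharing an
# identical set of ORFS-shifting variants) are graph nodes; an edge links
# two nodes whose variant sets overlap in genomic position.  Alleles of
# common ancestry all carry the founding variant, so shared ancestry forms
# a complete graph; a graph at least one edge short of complete indicates
# independently arisen loss-of-function alleles.

#' Build the ORFS-shift overlap graph for one gene
#'
#' Nodes are haplotype classes: samples whose ORFS-shifting variant sets
#' have the same signature collapse into one node (identical-by-descent
#' alleles must count once).  An edge joins two nodes when any variant of
#' one overlaps any variant of the other: reference-consuming variants
#' overlap when their spans share at least one base; two insertions
#' overlap only at the same anchor (an insertion shares no reference
#' base with any other variant).
#'
#' @param gene_id gene identifier
#' @param variant_sets named list (by sample) of data.frames with columns
#'   `pos`, `ref`, `alt` — that sample's ORFS-shifting variants
#' @return list of class `orfshift_graph`: `gene_id`, `nodes` (data.frame
#'   `signature`, `n_carriers`), `edges` (2-column matrix of node
#'   indices), `carriers` (total samples).
#' @export
build_orfshift_graph <- function(gene_id, variant_sets) {
  variant_sets <- Filter(function(v) !is.null(v) && nrow(v) > 0, variant_sets)
  if (length(variant_sets) == 0)
    return(structure(list(gene_id = gene_id,
                          nodes = data.frame(signature = character(0),
                                             n_carriers = integer(0)),
                          edges = matrix(integer(0), ncol = 2),
                          carriers = 0L), class = "orfshift_graph"))
  sig <- vapply(variant_sets, function(v) {
    v <- v[order(v$pos, v$ref, v$alt), , drop = FALSE]
    paste(v$pos, v$ref, v$alt, sep = ":", collapse = ";")
  }, character(1))
  usig <- unique(sig)
  nodes <- data.frame(signature = usig,
                      n_carriers = as.integer(table(sig)[usig]))
  sets <- lapply(usig, function(s) variant_sets[[which(sig == s)[1]]])
  n <- length(usig)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    ov <- function(a, b) {
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        ai <- nchar(a$ref[i]) == 0; bj <- nchar(b$ref[j]) == 0
        if (ai && bj) { if (a$pos[i] == b$pos[j]) return(TRUE) }
        else if (!ai && !bj) {
          if (a$pos[i] < b$pos[j] + nchar(b$ref[j]) &&
              b$pos[j] < a$pos[i] + nchar(a$ref[i])) return(TRUE)
        }
      }
      FALSE
    }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (ov(sets[[i]], sets[[j]])) edges <- rbind(edges, c(i, j))
  }
  structure(list(gene_id = gene_id, nodes = nodes, edges = edges,
                 carriers = length(variant_sets)),
            class = "orfshift_graph")
}

#' Independence verdict for an ORFS-shift graph
#'
#' A gene's loss-of-function alleles are called independent when the ORFS
#' was shifted in more than `min_carriers` samples, the graph has at least
#' `min_distinct` haplotype-class nodes, and the graph is at least one
#' edge short of complete.
#'
#' @param g an `orfshift_graph`
#' @param min_carriers carrier-count threshold (default 130, matching the
#'   published population scale; scale down for small populations)
#' @param min_distinct minimum number of distinct variant-set nodes
#' @return list: `independent` (logical), `n_nodes`, `n_edges`,
#'   `n_missing_edges`, `carriers`.
#' @export
is_independent <- function(g, min_carriers = 130L, min_distinct = 2L) {
  n <- nrow(g$nodes)
  ne <- nrow(g$edges)
  full <- if (n >= 2) n * (n - 1L) / 2L else 0L
  list(independent = g$carriers > min_carriers && n >= min_distinct &&
         ne <= full - 1L,
       n_nodes = n, n_edges = ne, n_missing_edges = full - ne,
       carriers = g$carriers)
}

#' Independence table over genes
#'
#' @param gene_variant_sets named list (by gene) of per-sample ORFS-shift
#'   variant-set lists (see [build_orfshift_graph()])
#' @param min_carriers,min_distinct passed to [is_independent()]
#' @return data.frame: gene, n_nodes, n_edges, n_missing_edges, carriers,
#'   independent.
#' @export
independence_table <- function(gene_variant_sets, min_carriers = 130L,
                               min_distinct = 2L) {
  rows <- lapply(names(gene_variant_sets), function(gid) {
    g <- build_orfshift_graph(gid, gene_variant_sets[[gid]])
    v <- is_independent(g, min_carriers, min_distinct)
    data.frame(gene = gid, n_nodes = v$n_nodes, n_edges = v$n_edges,
               n_missing_edges = v$n_missing_edges, carriers = v$carriers,
               independent = v$independent, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
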