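# Stage orchestration: simulate -> synchronize -> orfs -> encode ->
# associate -> decompose -> independence, with a serialized configuration,
# a checksum manifest, and deterministic behaviour under a fixed seed.

#' Default pipeline configuration
#'
#' All defaults follow the published pipeline where one exists: windows of
#' 50000 bases overlapping by 1000, marker-filter presets
#' (athaliana/dmelanogaster), 1000 permutations, marginal F-test threshold
#' 1e-4, IBS threshold 0.9, carrier threshold 130.
#'
#' @param ... overrides (name = value)
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(window_size = 50000L, window_overlap = 1000L,
              aligner = "builtin", mafft_path = "mafft",
              flank = 1000L, min_align_score = 10,
              filter_preset = "athaliana",
              maf_min = NULL, miss_max = NULL, mac_min = NULL,
              ibs_threshold = 0.9,
              alpha = 0.05, n_perm = 1000L, f_threshold = 1e-4,
              min_carriers = 130L, seed = 1L,
              n_samples = 12L, chrom_len = 60000L, n_genes = 4L,
              n_snps = 60L, n_indels = 24L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Run pipeline stages
#'
#' Stages depend on their predecessors' outputs inside `out_dir`; a missing
#' prerequisite is an error naming the absent artifact.  The configuration
#' and a checksum manifest of every produced file are written alongside
#' the outputs.
#'
#' @param stages subset of simulate, synchronize, orfs, encode, associate,
#'   decompose, independence (in any order; executed in pipeline order)
#' @param out_dir output directory (created if needed)
#' @param config list from [pipeline_config()]
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
run_pipeline <- function(stages = c("simulate", "synchronize", "orfs",
                                    "encode", "associate"),
                         out_dir, config = pipeline_config()) {
  order_all <- c("simulate", "synchronize", "orfs", "encode", "associate",
                 "decompose", "independence")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  need <- function(path, stage)
    if (!file.exists(path))
      stop("stage '", stage, "' needs missing artifact: ", path)
  pth <- function(...) file.path(out_dir, ...)

  if ("simulate" %in% stages) {
    simref <- sim_reference(chrom_len = config$chrom_len,
                            n_genes = config$n_genes, seed = config$seed)
    pop <- sim_population(n_samples = config$n_samples,
                          chrom_len = config$chrom_len,
                          n_snps = config$n_snps,
                          n_indels = config$n_indels,
                          seed = config$seed + 1L,
                          window = config$window_size,
                          overlap = config$window_overlap)
    # merge: same chromosome sequence carries the genes
    pop$genome <- simref$genome
    # re-derive SNP/DEL ref alleles from the gene-carrying genome
    v <- pop$variants
    rl <- nchar(v$ref)
    v$ref <- ifelse(rl > 0,
                    substr(pop$genome$seqs[v$chrom], v$pos + 1, v$pos + rl),
                    v$ref)
    drop <- v$ref == v$alt
    v <- v[!drop, , drop = FALSE]
    validate_variants(pop$genome, v)
    write_reference(pop$genome, pth("reference.fa"))
    write_gene_models(simref$models, pth("genes.gff3"))
    for (smp in pop$samples)
      write_sample_vcf(v[v$sample == smp, , drop = FALSE], pop$genome,
                       pth(paste0(smp, ".vcf")))
    writeLines(pop$samples, pth("samples.txt"))
    K0 <- NULL
    ph <- stats::rnorm(length(pop$samples))
    utils::write.table(data.frame(pop$samples, ph), pth("phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  genome <- NULL; samples <- NULL
  load_base <- function(stage) {
    need(pth("reference.fa"), stage); need(pth("samples.txt"), stage)
    genome <<- read_reference(pth("reference.fa"))
    samples <<- readLines(pth("samples.txt"))
  }
  read_vcfs <- function(stage) {
    do.call(rbind, lapply(samples, function(smp) {
      need(pth(paste0(smp, ".vcf")), stage)
      read_sample_vcf(pth(paste0(smp, ".vcf")), smp, genome)
    }))
  }
  if ("synchronize" %in% stages) {
    load_base("synchronize")
    vdf <- read_vcfs("synchronize")
    sync <- synchronize_population(genome, vdf, samples = samples,
                                   window = config$window_size,
                                   overlap = config$window_overlap,
                                   engine = config$aligner)
    write_population_vcf(sync, genome, samples, pth("synchronized.vcf"))
    utils::write.table(sync$variants, pth("synchronized.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sync$report, pth("reassignment_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("orfs" %in% stages) {
    load_base("orfs")
    need(pth("genes.gff3"), "orfs"); need(pth("synchronized.tsv"), "orfs")
    models <- read_gene_models(pth("genes.gff3"))
    sv <- utils::read.table(pth("synchronized.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(ref = "character",
                                           alt = "character"))
    sv$ref[is.na(sv$ref)] <- ""; sv$alt[is.na(sv$alt)] <- ""
    om <- orfs_matrix(genome, sv, models, samples = samples,
                      flank = config$flank,
                      min_score = config$min_align_score)
    write_orfs_matrix(om, pth("orfs_matrix.tsv"))
  }
  if ("encode" %in% stages) {
    load_base("encode")
    need(pth("synchronized.tsv"), "encode")
    sv <- utils::read.table(pth("synchronized.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(ref = "character",
                                           alt = "character"))
    sv$ref[is.na(sv$ref)] <- ""; sv$alt[is.na(sv$alt)] <- ""
    filt <- function(gm) {
      if (!is.null(config$maf_min))
        filter_markers(gm, maf_min = config$maf_min,
                       miss_max = config$miss_max, mac_min = config$mac_min)
      else filter_markers(gm, preset = config$filter_preset)
    }
    snp <- filt(encode_snps(sv, samples))
    ind <- filt(encode_indels(sv, samples))
    wr <- function(gm, file) {
      df <- cbind(gm$markers[, c("chrom", "pos", "class")], t(gm$G))
      utils::write.table(df, pth(file), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wr(snp, "genotypes_snp.tsv"); wr(ind, "genotypes_indel.tsv")
  }
  if ("associate" %in% stages) {
    load_base("associate")
    for (f in c("genotypes_snp.tsv", "genotypes_indel.tsv",
                "phenotypes.tsv")) need(pth(f), "associate")
    rd <- function(file, cls) {
      df <- utils::read.table(pth(file), sep = "\t", header = TRUE,
                              check.names = FALSE)
      G <- t(as.matrix(df[, -(1:3), drop = FALSE]))
      rownames(G) <- colnames(df)[-(1:3)]
      structure(list(G = G,
                     markers = data.frame(chrom = df$chrom, pos = df$pos,
                                          class = rep(cls, nrow(df)))),
                class = "genotype_matrix")
    }
    snp <- rd("genotypes_snp.tsv", "snp")
    ind <- rd("genotypes_indel.tsv", "indel")
    ph <- read_phenotypes(pth("phenotypes.tsv"))
    y <- ph$value[match(rownames(snp$G), ph$sample)]
    K <- kinship_bn(snp)
    fit <- fit_null(y, K)
    res <- rbind(assoc_scan(snp, fit), assoc_scan(ind, fit))
    utils::write.table(res, pth("association.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    th <- assoc_thresholds(list(snp, ind), fit, n_perm = config$n_perm,
                           alpha = config$alpha, seed = config$seed)
    jsonlite::write_json(list(bonferroni_p = th$bonferroni_p,
                              permutation_p = th$permutation_p,
                              n_tests = th$n_tests,
                              n_permutations = th$n_permutations),
                         pth("thresholds.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  # configuration + manifest
  writeLines(paste0(names(config), ": ", vapply(config, as.character,
                                                character(1))),
             pth("config.txt"))
  files <- setdiff(list.files(out_dir), "manifest.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))))
  utils::write.table(manifest, pth("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
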