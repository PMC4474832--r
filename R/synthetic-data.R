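#' @include AllClasses.R
NULL

#' Specification of a synthetic GWAS study
#'
#' Bundles the knobs of the synthetic-data generators: the number of genes,
#' the mean per-gene SNP count, the planted associated pathways, the number
#' of true interaction partners, and the master seed. All generators are
#' pure functions of this spec (and their other arguments): a fixed seed
#' reproduces every output exactly.
#'
#' @param nGenes number of genes (> 0).
#' @param snpsPerGeneMean mean of the zero-truncated Poisson from which
#'   per-gene SNP counts are drawn (minimum 1 SNP per gene).
#' @param plantedSets list of \code{list(set_id=, effect_delta=,
#'   fraction_affected=)} entries describing pathways that carry a planted
#'   association: in each affected gene one random SNP's p-value is
#'   replaced by \eqn{1 - \Phi(z)}, \eqn{z \sim N(\delta, 1)}.
#' @param nIgenes number of true interaction partners of the seed gene.
#' @param seed master integer seed; per-generator streams are derived from
#'   it by fixed offsets.
#' @return A validated \code{SimulationSpec} (classed list).
#' @examples
#' spec <- simulationSpec(nGenes = 100, nIgenes = 20, seed = 1)
#' @export
simulationSpec <- function(nGenes, snpsPerGeneMean = 5, plantedSets = list(),
                           nIgenes = 0, seed = 1) {
  stopifnot(nGenes > 0, snpsPerGeneMean > 0, nIgenes >= 0,
            is.numeric(seed), length(seed) == 1)
  for (ps in plantedSets) {
    stopifnot(!is.null(ps$set_id), ps$effect_delta >= 0,
              ps$fraction_affected > 0, ps$fraction_affected <= 1)
  }
  structure(list(nGenes = as.integer(nGenes),
                 snpsPerGeneMean = snpsPerGeneMean,
                 plantedSets = plantedSets,
                 nIgenes = as.integer(nIgenes),
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

# Derived per-generator seeds keep the streams independent of call order.
.subSeed <- function(spec, offset) (spec$seed + offset) %% .Machine$integer.max

#' Generate a synthetic gene annotation
#'
#' Lays \code{nGenes} non-overlapping 20-kb gene intervals on synthetic
#' chromosomes (500 genes per chromosome, 200 kb start-to-start spacing, so
#' even the default +/-20 kb SNP-assignment windows stay disjoint) and
#' draws each gene's SNP capacity from a zero-truncated Poisson with mean
#' \code{snpsPerGeneMean}.
#'
#' @param spec a [simulationSpec()].
#' @return A \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{n_snps}.
#' @export
generateGeneAnnotation <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(.subSeed(spec, 11L))
  n <- spec$nGenes
  perChrom <- 500L
  chromIdx <- (seq_len(n) - 1L) %/% perChrom + 1L
  within <- (seq_len(n) - 1L) %% perChrom
  start <- within * 200000L + 50001L
  width <- 20000L
  nSnps <- stats::rpois(n, spec$snpsPerGeneMean)
  while (any(nSnps == 0L))
    nSnps[nSnps == 0L] <- stats::rpois(sum(nSnps == 0L), spec$snpsPerGeneMean)
  gene_id <- sprintf("GENE%04d", seq_len(n))
  gr <- GenomicRanges::GRanges(
    seqnames = paste0("chr", chromIdx),
    ranges = IRanges::IRanges(start = start, width = width),
    strand = rep(c("+", "-"), length.out = n),
    gene_id = gene_id,
    n_snps = as.integer(nSnps))
  names(gr) <- gene_id
  gr
}

#' Generate null GWAS summary statistics
#'
#' One SNP row per unit of each gene's capacity, positions uniform within
#' the gene interval, p-values independent Uniform(0, 1) -- the global null
#' used for permutation-calibration studies.
#'
#' @param annotation GRanges from [generateGeneAnnotation()].
#' @param spec the matching [simulationSpec()].
#' @return validated association data.frame (\code{snp_id}, \code{chrom},
#'   \code{pos}, \code{pvalue}).
#' @export
generateNullAssoc <- function(annotation, spec) {
  stopifnot(inherits(spec, "SimulationSpec"), length(annotation) > 0)
  set.seed(.subSeed(spec, 23L))
  m <- annotation$n_snps
  geneIdx <- rep(seq_along(annotation), m)
  lo <- GenomicRanges::start(annotation)[geneIdx]
  hi <- GenomicRanges::end(annotation)[geneIdx]
  pos <- lo + floor(stats::runif(length(geneIdx)) * (hi - lo + 1))
  snpOrd <- unlist(lapply(m, seq_len), use.names = FALSE)
  assoc <- data.frame(
    snp_id = sprintf("rs_%s_%02d", annotation$gene_id[geneIdx], snpOrd),
    chrom = as.character(GenomicRanges::seqnames(annotation))[geneIdx],
    pos = as.integer(pos),
    pvalue = stats::runif(length(geneIdx)),
    stringsAsFactors = FALSE)
  validateAssocTable(assoc, "generated association table")
  assoc
}

#' Plant gene-level association signals
#'
#' For each gene in \code{genes}, one randomly chosen SNP inside the gene
#' interval gets its p-value replaced by \eqn{1 - \Phi(z)} with
#' \eqn{z \sim N(\delta, 1)}; all other rows are untouched. With
#' \code{delta = 0} the output is distributionally identical to the null.
#'
#' @param assoc association data.frame.
#' @param annotation gene GRanges.
#' @param genes character vector of affected gene ids (must exist in the
#'   annotation).
#' @param delta non-negative mean shift on the z-scale.
#' @param spec the [simulationSpec()] supplying the seed.
#' @return the modified association data.frame.
#' @export
plantAssociation <- function(assoc, annotation, genes, delta, spec) {
  stopifnot(inherits(spec, "SimulationSpec"), delta >= 0)
  unknown <- setdiff(genes, annotation$gene_id)
  if (length(unknown))
    stop("gene(s) absent from annotation: ", paste(unknown, collapse = ", "))
  set.seed(.subSeed(spec, 37L))
  chrom <- as.character(GenomicRanges::seqnames(annotation))
  for (g in genes) {
    i <- match(g, annotation$gene_id)
    inGene <- which(assoc$chrom == chrom[i] &
                    assoc$pos >= GenomicRanges::start(annotation)[i] &
                    assoc$pos <= GenomicRanges::end(annotation)[i])
    if (length(inGene) == 0L)
      stop("gene '", g, "' has no SNPs in the association table")
    hit <- inGene[sample.int(length(inGene), 1L)]
    z <- stats::rnorm(1L, mean = delta, sd = 1)
    assoc$pvalue[hit] <- stats::pnorm(z, lower.tail = FALSE)
  }
  assoc
}

#' Generate a synthetic interaction-partner table
#'
#' Draws \code{nIgenes} true partners with evidence Uniform(0.4, 1) and the
#' same number of decoy partners with evidence Uniform(0, 0.4), so that
#' strict filtering at 0.4 recovers exactly the true partners.
#'
#' @param annotation gene GRanges.
#' @param seedGene identifier of the seed gene (in the annotation; never a
#'   partner of itself).
#' @param spec the [simulationSpec()].
#' @return An [InteractionPartners-class] holding both true and decoy
#'   partners with their evidence scores.
#' @export
generatePpi <- function(annotation, seedGene, spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (!seedGene %in% annotation$gene_id)
    stop("seed gene '", seedGene, "' absent from annotation")
  if (spec$nIgenes >= spec$nGenes)
    stop("nIgenes must be smaller than nGenes")
  set.seed(.subSeed(spec, 53L))
  pool <- setdiff(annotation$gene_id, seedGene)
  chosen <- sample(pool, 2L * spec$nIgenes)
  evidence <- c(stats::runif(spec$nIgenes, 0.4, 1.0),
                stats::runif(spec$nIgenes, 0.0, 0.4))
  InteractionPartners(seedGene,
                      data.frame(gene_id = chosen, evidence = evidence,
                                 stringsAsFactors = FALSE))
}

#' Generate a gene-set catalogue with controlled I-Gene fractions
#'
#' Builds \code{nSets} sets with sizes uniform in \code{sizeRange}; set
#' \code{k} targets I-Gene fraction \code{igeneFracs[(k-1) \%\% L + 1]}
#' and realizes it to within one gene (the I-Gene count is the rounded
#' product of fraction and size).
#'
#' @param annotation gene GRanges supplying the gene universe.
#' @param igenes character vector of I-Gene ids.
#' @param nSets number of sets.
#' @param sizeRange integer vector \code{c(lo, hi)}, \code{hi <= nGenes}.
#' @param igeneFracs fractions in [0, 1], recycled over sets.
#' @param spec the [simulationSpec()].
#' @return A [GeneSetCatalog-class] with source \code{"synthetic"}.
#' @export
generateCatalog <- function(annotation, igenes, nSets, sizeRange,
                            igeneFracs, spec) {
  stopifnot(inherits(spec, "SimulationSpec"), length(sizeRange) == 2,
            sizeRange[1] >= 1, sizeRange[1] <= sizeRange[2],
            all(igeneFracs >= 0), all(igeneFracs <= 1), nSets >= 1)
  if (sizeRange[2] > length(annotation))
    stop("maximum set size exceeds the number of genes")
  set.seed(.subSeed(spec, 71L))
  universe <- annotation$gene_id
  igenes <- intersect(igenes, universe)
  nonIg <- setdiff(universe, igenes)
  sets <- vector("list", nSets)
  sizeChoices <- seq.int(sizeRange[1], sizeRange[2])
  for (k in seq_len(nSets)) {
    size <- sizeChoices[sample.int(length(sizeChoices), 1L)]
    frac <- igeneFracs[(k - 1L) %% length(igeneFracs) + 1L]
    nIg <- as.integer(round(frac * size))
    if (nIg > length(igenes))
      stop(sprintf("set %d: fraction %.2f of size %d needs %d I-Genes but only %d exist",
                   k, frac, size, nIg, length(igenes)))
    if (size - nIg > length(nonIg))
      stop(sprintf("set %d: not enough non-I-Genes for size %d", k, size))
    members <- c(if (nIg > 0L) sample(igenes, nIg) else character(),
                 if (size - nIg > 0L) sample(nonIg, size - nIg) else character())
    sets[[k]] <- sample(members)  # shuffle so I-Genes are not positional
  }
  names(sets) <- sprintf("SET%04d", seq_len(nSets))
  GeneSetCatalog(sets, "synthetic")
}
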