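#' @include synthetic-data.R gene-scoring.R enrichment.R molecular-evolution.R
NULL

.logLine <- function(level, stage, msg) {
  message(sprintf("[%s] %s: %s", level, stage, msg))
}

.fileDigests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  ex <- vapply(paths, file.exists, logical(1))
  as.list(tools::md5sum(unlist(paths[ex])))
}

#' Simulate a full synthetic study
#'
#' Generates the four pipeline inputs -- association TSV, gene BED,
#' interaction TSV and gene-set GMT -- plus a ground-truth JSON (planted
#' genes, true I-Genes, spec echo). The seed gene is the first annotated
#' gene; it is inserted into \code{nSeedSets} catalogue sets (replacing one
#' random non-I-Gene member) so the seed-gene-containing collection is
#' non-empty. Planted pathways listed in the spec get \code{effect_delta}
#' signals planted in a \code{fraction_affected} share of their genes.
#'
#' @param spec a [simulationSpec()].
#' @param outDir output directory (created); when \code{NULL} nothing is
#'   written and the objects are returned only.
#' @param nSets,sizeRange,igeneFracs catalogue shape, passed to
#'   [generateCatalog()].
#' @param nSeedSets number of sets the seed gene is inserted into.
#' @return list with elements \code{annotation}, \code{assoc}, \code{ppi},
#'   \code{catalog}, \code{seedGene}, \code{truth}, and (when writing)
#'   \code{files}.
#' @export
simulateStudy <- function(spec, outDir = NULL, nSets = 100,
                          sizeRange = c(10, 60),
                          igeneFracs = seq(0, 0.7, by = 0.1),
                          nSeedSets = max(1L, round(nSets / 10))) {
  stopifnot(inherits(spec, "SimulationSpec"))
  annotation <- generateGeneAnnotation(spec)
  assoc <- generateNullAssoc(annotation, spec)
  seedGene <- annotation$gene_id[1]
  ppi <- generatePpi(annotation, seedGene, spec)
  igenes <- iGenes(ppi)
  catalog <- generateCatalog(annotation, igenes, nSets, sizeRange,
                             igeneFracs, spec)
  # insert the seed gene into the first nSeedSets sets
  set.seed(.subSeed(spec, 89L))
  sets <- geneSets(catalog)
  for (k in seq_len(min(nSeedSets, length(sets)))) {
    if (seedGene %in% sets[[k]]) next
    swappable <- which(!(sets[[k]] %in% c(igenes, seedGene)))
    pos <- if (length(swappable)) sample(swappable, 1L)
           else sample(length(sets[[k]]), 1L)
    sets[[k]][pos] <- seedGene
  }
  catalog <- GeneSetCatalog(sets, setSource(catalog))
  plantedGenes <- list()
  for (ps in spec$plantedSets) {
    if (!ps$set_id %in% setIds(catalog))
      stop("planted set '", ps$set_id, "' not in the generated catalogue")
    members <- geneSets(catalog)[[ps$set_id]]
    members <- intersect(members, annotation$gene_id)
    nAff <- max(1L, round(ps$fraction_affected * length(members)))
    set.seed(.subSeed(spec, 97L))
    affected <- sample(members, nAff)
    assoc <- plantAssociation(assoc, annotation, affected,
                              ps$effect_delta, spec)
    plantedGenes[[ps$set_id]] <- affected
  }
  truth <- list(spec = unclass(spec), seed_gene = seedGene,
                igenes = igenes, planted_genes = plantedGenes)
  out <- list(annotation = annotation, assoc = assoc, ppi = ppi,
              catalog = catalog, seedGene = seedGene, truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- list(assoc = file.path(outDir, "assoc.tsv"),
                  genes = file.path(outDir, "genes.bed"),
                  ppi = file.path(outDir, "ppi.tsv"),
                  gmt = file.path(outDir, "sets.gmt"),
                  truth = file.path(outDir, "truth.json"))
    writeAssocTable(assoc, files$assoc)
    writeGeneBed(annotation, files$genes)
    writeInteractionTable(ppi, files$ppi)
    writeGmt(catalog, files$gmt)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA)
    out$files <- files
    .logLine("INFO", "simulate",
             sprintf("wrote %d SNPs, %d genes, %d partners, %d sets to %s",
                     nrow(assoc), length(annotation), nrow(partners(ppi)),
                     length(catalog), outDir))
  }
  out
}

.readConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file '", config, "' not found")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.cfg <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) stop("config misses required key '", key, "'")
  default
}

#' Run the full pathway-analysis pipeline
#'
#' Orchestrates reading the inputs, gene scoring, pathway curation,
#' enrichment testing and report writing. The config (YAML file or named
#' list) mirrors the flag names: \code{assoc}, \code{genes}, \code{gmt},
#' \code{ppi}, \code{seed_gene} (required); \code{igene_threshold} (0.10),
#' \code{min_evidence} (0.4), \code{min_size} (10), \code{max_size} (380),
#' \code{window_kb} (20), \code{method} ("sumstat"), \code{permutations}
#' (15000), \code{igene_weight} (2), \code{seed} (1), \code{out}
#' (directory; when given, \code{report.tsv} and \code{manifest.json} are
#' written). Two runs with identical config and seed produce byte-identical
#' outputs; the manifest therefore records no wall-clock times.
#'
#' @param config path to a YAML config or a named list.
#' @return list with \code{results} (an [EnrichmentResult-class]),
#'   \code{curated} (the [CuratedCatalog-class]), \code{scores} and
#'   \code{manifest}.
#' @export
runFull <- function(config) {
  config <- .readConfig(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- .cfg(config, "seed", 1L)
  method <- .cfg(config, "method", "sumstat")
  B <- .cfg(config, "permutations", 15000L)
  assoc <- stage("read_assoc", readAssocTable(.cfg(config, "assoc", required = TRUE)))
  annotation <- stage("read_genes", readGeneBed(.cfg(config, "genes", required = TRUE)))
  catalog <- stage("read_gmt", readGmt(.cfg(config, "gmt", required = TRUE)))
  ppi <- stage("read_ppi", readInteractionTable(
    .cfg(config, "ppi", required = TRUE),
    seedGene = .cfg(config, "seed_gene", required = TRUE),
    minEvidence = .cfg(config, "min_evidence", 0.4)))
  igenes <- iGenes(ppi, .cfg(config, "min_evidence", 0.4))
  .logLine("INFO", "inputs",
           sprintf("seed=%s, %d SNPs, %d genes, %d I-Genes, %d sets",
                   seed, nrow(assoc), length(annotation), length(igenes),
                   length(catalog)))
  scores <- stage("gene_scoring",
                  scoreGenes(assoc, annotation,
                             windowKb = .cfg(config, "window_kb", 20)))
  curated <- stage("curation", {
    cc <- newCuratedCatalog(catalog, igenes)
    cc <- selectSeedPathways(cc, seedGene(ppi))
    cc <- selectIgenePathways(cc, .cfg(config, "igene_threshold", 0.10))
    filterBySize(cc, .cfg(config, "min_size", 10),
                 .cfg(config, "max_size", 380))
  })
  info <- curationInfo(curated)
  .logLine("INFO", "curation",
           sprintf("%d seed-pw, %d igene-pw, %d examined (family for BH)",
                   sum(info$seed_pw & info$retained),
                   sum(info$igene_pw & info$retained),
                   length(examinedSets(curated))))
  results <- stage("enrichment", runPathwayAnalysis(
    scores, curated, igenes,
    weights = weightScheme(igeneWeight = .cfg(config, "igene_weight", 2)),
    B = B, seed = seed, method = method,
    minMapped = .cfg(config, "min_mapped", 5)))
  manifest <- list(
    config = config,
    inputs = .fileDigests(config[c("assoc", "genes", "gmt", "ppi")]),
    seed = seed,
    counts = list(
      n_snps = nrow(assoc), n_genes = length(annotation),
      n_scored_genes = nrow(scores), n_igenes = length(igenes),
      n_sets = length(catalog),
      n_seed_pw = sum(info$seed_pw & info$retained),
      n_igene_pw = sum(info$igene_pw & info$retained),
      bh_family_size = length(examinedSets(curated))))
  outDir <- .cfg(config, "out")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage("write_report",
          writeReport(results, file.path(outDir, "report.tsv"),
                      method = method))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, curated = curated, scores = scores,
       manifest = manifest)
}

#' Run the molecular-evolution pipeline
#'
#' Reads ortholog protein (and optionally CDS) FASTA files, computes the
#' pairwise trimmed-identity matrix, the NG86 dN/dS table (CDS required)
#' and the neighbor-joining tree on 1 - identity distances, and writes
#' \code{identity.tsv}, \code{dnds.tsv}, \code{tree.nwk} and
#' \code{manifest.json} under \code{out}.
#'
#' @param config path to a YAML config or a named list with keys
#'   \code{fasta} (protein FASTA, required), \code{cds} (CDS FASTA,
#'   required for dN/dS), \code{out} (optional directory).
#' @return list with \code{identity} (percent matrix), \code{dnds}
#'   (data.frame or NULL), \code{tree} (phylo), \code{manifest}.
#' @export
runEvo <- function(config) {
  config <- .readConfig(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  prot <- stage("read_fasta",
                readFasta(.cfg(config, "fasta", required = TRUE), "protein"))
  if (length(prot) < 2L) stop("stage 'read_fasta' failed: need >= 2 sequences")
  dmat <- stage("identity", pdistanceMatrix(prot))
  identity <- 100 * (1 - dmat)
  diag(identity) <- 100
  dnds <- NULL
  if (!is.null(.cfg(config, "cds"))) {
    cds <- stage("read_cds", readFasta(config$cds, "nucleotide"))
    missing_ids <- setdiff(names(prot), names(cds))
    if (length(missing_ids))
      stop("stage 'read_cds' failed: no CDS for ",
           paste(missing_ids, collapse = ", "))
    dnds <- stage("dnds", ng86Pairwise(cds[names(prot)]))
  }
  tree <- stage("nj_tree", njTree(dmat))
  manifest <- list(
    config = config,
    inputs = .fileDigests(config[c("fasta", "cds")]),
    counts = list(n_sequences = length(prot),
                  n_pairs = length(prot) * (length(prot) - 1L) / 2L,
                  distance_model = "p-distance (1 - trimmed identity)"))
  outDir <- .cfg(config, "out")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(round(identity, 2), file.path(outDir, "identity.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(dnds))
      utils::write.table(dnds, file.path(outDir, "dnds.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    writeNewick(tree, file.path(outDir, "tree.nwk"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(identity = identity, dnds = dnds, tree = tree, manifest = manifest)
}
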