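#' @include AllClasses.R AllGenerics.R
NULL

#' I-Gene percentage of a gene set
#'
#' @param members non-empty character vector of member genes.
#' @param igenes character vector of I-Gene ids.
#' @return \eqn{100 \cdot |members \cap igenes| / |members|}.
#' @examples
#' igeneFraction(paste0("G", 1:20), paste0("G", 1:14))  # 70
#' @export
igeneFraction <- function(members, igenes) {
  if (length(members) == 0L) stop("empty gene set")
  100 * length(intersect(members, igenes)) / length(members)
}

#' Annotate a catalogue for curation
#'
#' Computes per-set gene counts, I-Gene counts and percentages, and
#' initialises the curation labels (none set) and the retention flag (all
#' retained). The labelling and filtering operations below update the
#' annotation; they are idempotent and order-independent.
#'
#' @param catalog a [GeneSetCatalog-class].
#' @param igenes character vector of I-Gene ids.
#' @return A [CuratedCatalog-class].
#' @export
newCuratedCatalog <- function(catalog, igenes) {
  stopifnot(is(catalog, "GeneSetCatalog"))
  nGenes <- setSizes(catalog)
  nIg <- vapply(geneSets(catalog),
                function(g) length(intersect(g, igenes)), integer(1))
  info <- data.frame(
    set_id = setIds(catalog),
    source = unname(setSource(catalog)),
    n_genes = unname(nGenes),
    n_igenes = unname(nIg),
    pct_igenes = round(100 * unname(nIg) / unname(nGenes), 2),
    seed_pw = FALSE, igene_pw = FALSE, retained = TRUE,
    stringsAsFactors = FALSE, row.names = NULL)
  new("CuratedCatalog", catalog = catalog, igenes = as.character(igenes),
      info = info)
}

#' Label pathways containing the seed gene
#'
#' Every set whose members include \code{seedGene} is labelled
#' \emph{seed-pw} (the seed-gene-involving collection). If the seed occurs
#' in no set, a warning is emitted and no label is set.
#'
#' @param curated a [CuratedCatalog-class].
#' @param seedGene seed gene identifier.
#' @return the updated [CuratedCatalog-class].
#' @export
selectSeedPathways <- function(curated, seedGene) {
  stopifnot(is(curated, "CuratedCatalog"))
  hit <- vapply(geneSets(curated), function(g) seedGene %in% g, logical(1))
  if (!any(hit))
    warning("seed gene '", seedGene, "' occurs in no catalogue set")
  curated@info$seed_pw <- unname(hit)
  validObject(curated)
  curated
}

#' Label I-Gene-enriched pathways
#'
#' Sets with an I-Gene fraction \emph{strictly} greater than
#' \code{threshold} are labelled \emph{igene-pw}; a fraction exactly equal
#' to the threshold does not qualify.
#'
#' @param curated a [CuratedCatalog-class].
#' @param threshold fraction in [0, 1]; default 0.10.
#' @return the updated [CuratedCatalog-class].
#' @export
selectIgenePathways <- function(curated, threshold = 0.10) {
  stopifnot(is(curated, "CuratedCatalog"), threshold >= 0, threshold <= 1)
  frac <- curated@info$n_igenes / curated@info$n_genes
  curated@info$igene_pw <- frac > threshold
  validObject(curated)
  curated
}

#' Filter pathways by size
#'
#' Retains sets whose gene count lies in \code{[minSize, maxSize]}
#' inclusive; sets with more than \code{maxSize} or fewer than
#' \code{minSize} genes are excluded (too-small sets behave stochastically,
#' too-large ones describe overly general processes).
#'
#' @param curated a [CuratedCatalog-class].
#' @param minSize smallest retained size; default 10.
#' @param maxSize largest retained size; default 380.
#' @return the updated [CuratedCatalog-class].
#' @export
filterBySize <- function(curated, minSize = 10, maxSize = 380) {
  stopifnot(is(curated, "CuratedCatalog"), minSize <= maxSize)
  n <- curated@info$n_genes
  curated@info$retained <- n >= minSize & n <= maxSize
  validObject(curated)
  curated
}

#' Merge two labelled pathway collections
#'
#' Union by set identifier of two sub-catalogues drawn from one parent
#' catalogue, with the overlap count; \eqn{|union| = |A| + |B| -
#' n_{overlap}}. A set id occurring in both inputs with different members
#' is an error.
#'
#' @param a,b [GeneSetCatalog-class] objects.
#' @return list with elements \code{catalog} (the union
#'   [GeneSetCatalog-class]) and \code{nOverlap}.
#' @export
mergeExamined <- function(a, b) {
  stopifnot(is(a, "GeneSetCatalog"), is(b, "GeneSetCatalog"))
  shared <- intersect(setIds(a), setIds(b))
  for (id in shared) {
    if (!setequal(geneSets(a)[[id]], geneSets(b)[[id]]))
      stop("set id '", id, "' has different members in the two collections")
  }
  onlyB <- setdiff(setIds(b), setIds(a))
  sets <- c(geneSets(a), geneSets(b)[onlyB])
  src <- c(setSource(a), setSource(b)[onlyB])
  list(catalog = GeneSetCatalog(sets, src), nOverlap = length(shared))
}

#' Examined pathways of a curated catalogue
#'
#' The family over which enrichment p-values are adjusted: retained sets
#' carrying at least one curation label, or -- when no label has been set --
#' all retained sets.
#'
#' @param curated a [CuratedCatalog-class].
#' @return character vector of set identifiers.
#' @export
examinedSets <- function(curated) {
  stopifnot(is(curated, "CuratedCatalog"))
  info <- curated@info
  labelled <- info$seed_pw | info$igene_pw
  if (any(labelled)) info$set_id[info$retained & labelled]
  else info$set_id[info$retained]
}

#' Size summary of a catalogue
#'
#' Median (midpoint of the two central values for even counts), minimum and
#' maximum of the set sizes.
#'
#' @param x a [GeneSetCatalog-class], [CuratedCatalog-class] or numeric
#'   vector of sizes.
#' @return named numeric vector \code{c(median=, min=, max=)}.
#' @export
sizeSummary <- function(x) {
  sizes <- if (is.numeric(x)) x else setSizes(x)
  if (length(sizes) == 0L) stop("no sets to summarise")
  c(median = stats::median(sizes), min = min(sizes), max = max(sizes))
}
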