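#' @include AllGenerics.R
NULL

#' @describeIn GeneSetCatalog set identifiers
#' @param x a \code{GeneSetCatalog}
#' @export
setMethod("setIds", "GeneSetCatalog", function(x) names(x@sets))

#' @describeIn GeneSetCatalog gene sets as a named list
#' @export
setMethod("geneSets", "GeneSetCatalog", function(x) x@sets)

#' @describeIn GeneSetCatalog per-set source annotations
#' @export
setMethod("setSource", "GeneSetCatalog", function(x) x@source)

#' @describeIn GeneSetCatalog per-set gene counts
#' @export
setMethod("setSizes", "GeneSetCatalog", function(x)
  vapply(x@sets, length, integer(1)))

#' @describeIn GeneSetCatalog number of sets
#' @export
setMethod("length", "GeneSetCatalog", function(x) length(x@sets))

#' @describeIn GeneSetCatalog subset by set identifier or index
#' @param i set identifiers or indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "GeneSetCatalog", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    missing_ids <- setdiff(i, names(x@sets))
    if (length(missing_ids))
      stop("unknown set id(s): ", paste(missing_ids, collapse = ", "))
  }
  GeneSetCatalog(x@sets[i], x@source[i])
})

setMethod("show", "GeneSetCatalog", function(object) {
  sz <- setSizes(object)
  cat(sprintf("GeneSetCatalog with %d sets (sizes %d-%d, median %.1f)\n",
              length(object), min(sz), max(sz), stats::median(sz)))
  cat("  sources:", paste(unique(object@source), collapse = ", "), "\n")
})

#' @describeIn InteractionPartners seed gene identifier
#' @param x an \code{InteractionPartners}
#' @export
setMethod("seedGene", "InteractionPartners", function(x) x@seedGene)

#' @describeIn InteractionPartners partner table
#' @export
setMethod("partners", "InteractionPartners", function(x) x@partners)

#' @describeIn InteractionPartners partners with evidence strictly above
#'   \code{threshold}
#' @param threshold evidence cut-off, default 0.4
#' @export
setMethod("iGenes", "InteractionPartners", function(x, threshold = 0.4) {
  stopifnot(threshold >= 0, threshold <= 1)
  x@partners$gene_id[x@partners$evidence > threshold]
})

setMethod("show", "InteractionPartners", function(object) {
  cat(sprintf("InteractionPartners: seed '%s', %d partners (%d with evidence > 0.4)\n",
              object@seedGene, nrow(object@partners),
              length(iGenes(object))))
})

#' @describeIn CuratedCatalog curation annotation table
#' @param x a \code{CuratedCatalog}
#' @export
setMethod("curationInfo", "CuratedCatalog", function(x) x@info)

#' @describeIn CuratedCatalog set identifiers
#' @export
setMethod("setIds", "CuratedCatalog", function(x) names(x@catalog@sets))

#' @describeIn CuratedCatalog gene sets of the underlying catalogue
#' @export
setMethod("geneSets", "CuratedCatalog", function(x) x@catalog@sets)

#' @describeIn CuratedCatalog per-set source annotations
#' @export
setMethod("setSource", "CuratedCatalog", function(x) x@catalog@source)

#' @describeIn CuratedCatalog per-set gene counts
#' @export
setMethod("setSizes", "CuratedCatalog", function(x) setSizes(x@catalog))

#' @describeIn CuratedCatalog number of sets
#' @export
setMethod("length", "CuratedCatalog", function(x) length(x@catalog))

setMethod("show", "CuratedCatalog", function(object) {
  info <- object@info
  cat(sprintf("CuratedCatalog with %d sets (%d retained by size filter)\n",
              nrow(info), sum(info$retained)))
  cat(sprintf("  seed-pw: %d   igene-pw: %d   examined: %d\n",
              sum(info$seed_pw & info$retained),
              sum(info$igene_pw & info$retained),
              length(examinedSets(object))))
})

#' @describeIn EnrichmentResult result table
#' @param x an \code{EnrichmentResult}
#' @export
setMethod("resultTable", "EnrichmentResult", function(x) x@table)

setMethod("show", "EnrichmentResult", function(object) {
  tab <- object@table
  cat(sprintf("EnrichmentResult: %d pathways x %s, %d permutations\n",
              length(unique(tab$set_id)),
              paste(unique(tab$method), collapse = "/"),
              object@params$B))
  sig <- tab[tab$p_adj < 0.05, , drop = FALSE]
  cat(sprintf("  %d rows with adjusted p < 0.05\n", nrow(sig)))
})
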