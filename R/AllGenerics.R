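#' @include AllClasses.R
NULL

#' Set identifiers of a catalogue
#' @param x a [GeneSetCatalog-class] or [CuratedCatalog-class].
#' @return character vector of set identifiers.
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' Gene sets as a named list
#' @param x a [GeneSetCatalog-class] or [CuratedCatalog-class].
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Per-set source annotations
#' @param x a [GeneSetCatalog-class] or [CuratedCatalog-class].
#' @return named character vector.
#' @export
setGeneric("setSource", function(x) standardGeneric("setSource"))

#' Per-set gene counts
#' @param x a [GeneSetCatalog-class] or [CuratedCatalog-class].
#' @return named integer vector of set sizes.
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' Seed gene of an interaction table
#' @param x an [InteractionPartners-class].
#' @return single character gene identifier.
#' @export
setGeneric("seedGene", function(x) standardGeneric("seedGene"))

#' Partner table of an interaction set
#' @param x an [InteractionPartners-class].
#' @return data.frame with columns \code{gene_id}, \code{evidence}.
#' @export
setGeneric("partners", function(x) standardGeneric("partners"))

#' I-Genes: partners above an evidence threshold
#'
#' Returns the identifiers of interaction partners whose evidence score is
#' strictly greater than \code{threshold}. A score exactly equal to the
#' threshold is excluded.
#'
#' @param x an [InteractionPartners-class].
#' @param threshold evidence cut-off in [0, 1]; default 0.4 (the
#'   medium-confidence cut of the source interaction database).
#' @return character vector of gene identifiers.
#' @export
setGeneric("iGenes", function(x, threshold = 0.4) standardGeneric("iGenes"))

#' Curation annotation table
#' @param x a [CuratedCatalog-class].
#' @return data.frame with one row per set.
#' @export
setGeneric("curationInfo", function(x) standardGeneric("curationInfo"))

#' Result table of an enrichment run
#' @param x an [EnrichmentResult-class].
#' @return data.frame with one row per (pathway, weighting).
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
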