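#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

#' Catalogue of named gene sets
#'
#' Container for a collection of named gene sets (pathways), as read from a
#' GMT file or produced by the synthetic-data generator. Each set has an
#' identifier, a free-text source annotation (e.g. the originating pathway
#' database) and a non-empty vector of member gene identifiers with no
#' within-set duplicates.
#'
#' @slot sets named list of character vectors; names are set identifiers.
#' @slot source named character vector parallel to \code{sets}.
#'
#' @seealso [readGmt()], [generateCatalog()], [newCuratedCatalog()]
#' @export
setClass("GeneSetCatalog",
  representation(sets = "list", source = "character"))

setValidity("GeneSetCatalog", function(object) {
  msg <- character()
  ids <- names(object@sets)
  if (length(object@sets) == 0L)
    msg <- c(msg, "catalogue contains no sets")
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "every set must have a non-empty identifier")
  if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate set identifier(s): %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@source) != length(object@sets))
    msg <- c(msg, "'source' must be parallel to 'sets'")
  for (i in seq_along(object@sets)) {
    members <- object@sets[[i]]
    if (!is.character(members) || length(members) == 0L) {
      msg <- c(msg, sprintf("set '%s' has no members", ids[i]))
    } else if (anyDuplicated(members)) {
      msg <- c(msg, sprintf("set '%s' contains duplicate genes", ids[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCatalog
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param source character vector of per-set source annotations, recycled to
#'   the number of sets.
#' @return A [GeneSetCatalog-class] object.
#' @examples
#' cat <- GeneSetCatalog(list(PW1 = c("G1", "G2"), PW2 = c("G2", "G3")))
#' setSizes(cat)
#' @export
GeneSetCatalog <- function(sets, source = "unknown") {
  source <- rep_len(as.character(source), length(sets))
  names(source) <- names(sets)
  new("GeneSetCatalog", sets = sets, source = source)
}

#' Interaction partners of a seed gene
#'
#' Stores the protein-protein interaction partners of a seed gene together
#' with their interaction evidence scores in [0, 1]. The I-Genes of the
#' study are the partners whose evidence score is strictly greater than a
#' confidence threshold (0.4, the medium-confidence cut of the source
#' database).
#'
#' @slot seedGene single gene identifier.
#' @slot partners data.frame with columns \code{gene_id}, \code{evidence}.
#'
#' @seealso [readInteractionTable()], [iGenes()], [generatePpi()]
#' @export
setClass("InteractionPartners",
  representation(seedGene = "character", partners = "data.frame"))

setValidity("InteractionPartners", function(object) {
  msg <- character()
  if (length(object@seedGene) != 1L || is.na(object@seedGene) ||
      object@seedGene == "")
    msg <- c(msg, "'seedGene' must be a single non-empty gene id")
  p <- object@partners
  if (!all(c("gene_id", "evidence") %in% names(p)))
    msg <- c(msg, "'partners' needs columns gene_id and evidence")
  else {
    if (anyNA(p$evidence) || any(p$evidence < 0) || any(p$evidence > 1))
      msg <- c(msg, "evidence scores must lie in [0, 1]")
    if (object@seedGene %in% p$gene_id)
      msg <- c(msg, sprintf("seed gene '%s' listed as its own partner",
                            object@seedGene))
    if (anyDuplicated(p$gene_id))
      msg <- c(msg, "duplicate partner gene ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionPartners object
#'
#' @param seedGene single gene identifier.
#' @param partners data.frame with columns \code{gene_id} and
#'   \code{evidence} (scores in [0, 1]).
#' @return An [InteractionPartners-class] object.
#' @export
InteractionPartners <- function(seedGene, partners) {
  partners <- as.data.frame(partners)
  rownames(partners) <- NULL
  new("InteractionPartners", seedGene = seedGene, partners = partners)
}

#' Curated pathway catalogue
#'
#' A [GeneSetCatalog-class] annotated for analysis: per-set gene counts,
#' I-Gene counts and percentages, the two (non-exclusive) curation labels --
#' \emph{seed-pw} (the set contains the seed gene) and \emph{igene-pw} (the
#' set holds strictly more than a threshold fraction of I-Genes) -- and a
#' retention flag from the pathway-size filter.
#'
#' @slot catalog the underlying [GeneSetCatalog-class].
#' @slot igenes character vector of I-Gene identifiers used for annotation.
#' @slot info data.frame with one row per set: \code{set_id}, \code{source},
#'   \code{n_genes}, \code{n_igenes}, \code{pct_igenes}, \code{seed_pw},
#'   \code{igene_pw}, \code{retained}.
#'
#' @seealso [newCuratedCatalog()], [selectSeedPathways()],
#'   [selectIgenePathways()], [filterBySize()], [examinedSets()]
#' @export
setClass("CuratedCatalog",
  representation(catalog = "GeneSetCatalog", igenes = "character",
                 info = "data.frame"))

setValidity("CuratedCatalog", function(object) {
  msg <- character()
  need <- c("set_id", "source", "n_genes", "n_igenes", "pct_igenes",
            "seed_pw", "igene_pw", "retained")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "'info' is missing required columns")
  else {
    if (!identical(object@info$set_id, names(object@catalog@sets)))
      msg <- c(msg, "'info' rows must be parallel to the catalogue sets")
    pct <- round(100 * object@info$n_igenes / object@info$n_genes, 2)
    if (any(abs(pct - object@info$pct_igenes) > 1e-9))
      msg <- c(msg, "pct_igenes inconsistent with n_igenes/n_genes")
  }
  if (length(msg)) msg else TRUE
})

#' Pathway enrichment results
#'
#' One row per (pathway, weighting) combination of a pathway-analysis run:
#' the observed statistic, the permutation p-value and its
#' Benjamini-Hochberg adjustment, along with bookkeeping columns.
#'
#' @slot table data.frame with columns \code{set_id}, \code{source},
#'   \code{n_genes}, \code{n_mapped}, \code{pct_igenes}, \code{method},
#'   \code{weighted}, \code{score}, \code{es}, \code{p_perm}, \code{p_adj},
#'   \code{n_permutations}.
#' @slot params list echoing the run parameters (seed, B, method, weights).
#'
#' @seealso [runPathwayAnalysis()], [writeReport()]
#' @export
setClass("EnrichmentResult",
  representation(table = "data.frame", params = "list"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  need <- c("set_id", "source", "n_genes", "n_mapped", "pct_igenes",
            "method", "weighted", "score", "es", "p_perm", "p_adj",
            "n_permutations")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "'table' is missing required columns")
  else {
    p <- object@table$p_perm
    if (anyNA(p) || any(p <= 0) || any(p > 1))
      msg <- c(msg, "p_perm must lie in (0, 1]")
    if (any(object@table$p_adj > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "p_adj must not exceed 1")
  }
  if (length(msg)) msg else TRUE
})
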