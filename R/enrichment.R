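#' @include AllClasses.R geneset-curation.R
NULL

#' I-Gene weighting scheme
#'
#' The pathway statistics can up-weight genes whose products interact with
#' the seed gene: by default I-Genes receive twice the weight of the
#' remaining genes.
#'
#' @param igeneWeight weight of I-Genes (> 0); default 2.
#' @param otherWeight weight of the remaining genes (> 0); default 1.
#' @param enabled when \code{FALSE} every gene receives
#'   \code{otherWeight}.
#' @return classed list \code{WeightScheme}.
#' @export
weightScheme <- function(igeneWeight = 2, otherWeight = 1, enabled = TRUE) {
  stopifnot(igeneWeight > 0, otherWeight > 0)
  structure(list(igeneWeight = igeneWeight, otherWeight = otherWeight,
                 enabled = isTRUE(enabled)),
            class = "WeightScheme")
}

.geneWeights <- function(genes, weights, igenes) {
  if (!weights$enabled) return(rep(weights$otherWeight, length(genes)))
  ifelse(genes %in% igenes, weights$igeneWeight, weights$otherWeight)
}

#' Self-contained SumStat pathway score
#'
#' Sum over the pathway's scored (mapped) genes of
#' \code{weight(g) * stat(g)}, where the weight is
#' \code{igeneWeight} for I-Genes when weighting is enabled and
#' \code{otherWeight} otherwise. Pathways with fewer than
#' \code{minMapped} scored members are skipped (returned as \code{NA} with
#' a message): permutation quantiles of near-empty sets are meaningless.
#'
#' @param scores gene score data.frame from [scoreGenes()].
#' @param members character vector of pathway member genes.
#' @param weights a [weightScheme()].
#' @param igenes character vector of I-Gene ids.
#' @param minMapped minimum number of scored members; default 5.
#' @return the score, or \code{NA} when the pathway is skipped.
#' @export
sumstatScore <- function(scores, members, weights = weightScheme(),
                         igenes = character(), minMapped = 5) {
  mapped <- intersect(members, scores$gene_id)
  if (length(mapped) < minMapped) {
    message(sprintf("pathway skipped: %d mapped gene(s) < minMapped = %d",
                    length(mapped), minMapped))
    return(NA_real_)
  }
  stat <- scores$stat[match(mapped, scores$gene_id)]
  sum(.geneWeights(mapped, weights, igenes) * stat)
}

#' GSEA enrichment score
#'
#' Walks the genes in decreasing order of their statistic, adding
#' \eqn{stat(g) / \sum_{members} stat} at each member gene and subtracting
#' \eqn{1 / (N - N_{hit})} at each non-member (the statistic-proportional,
#' exponent-1 form). The enrichment score is the running-sum value of
#' greatest absolute magnitude, signed; it always lies in [-1, 1].
#'
#' With I-Gene weighting enabled, each member's increment uses
#' \code{weight(g) * stat(g)} (normalised over members), the weighted
#' analogue of the weighted SumStat; the ranking itself is by the
#' unweighted statistic.
#'
#' @param scores gene score data.frame covering all scored genes.
#' @param members character vector of pathway member genes (the ones
#'   present among the scored genes are used; must be non-empty).
#' @param weights a [weightScheme()]; the default is unweighted
#'   (\code{enabled = FALSE}).
#' @param igenes character vector of I-Gene ids (used when weighting is
#'   enabled).
#' @return the signed enrichment score.
#' @export
gseaEs <- function(scores, members,
                   weights = weightScheme(enabled = FALSE),
                   igenes = character()) {
  ord <- order(scores$stat, decreasing = TRUE)
  stat <- scores$stat[ord]
  gid <- scores$gene_id[ord]
  isHit <- gid %in% members
  w <- rep(1, length(stat))
  w[isHit] <- .geneWeights(gid[isHit], weights, igenes)
  .esFromRanked(stat, isHit, w)
}

.esFromRanked <- function(stat, isHit, w = rep(1, length(stat))) {
  if (!any(isHit)) stop("no pathway member among the scored genes")
  hitSum <- sum(w[isHit] * stat[isHit])
  if (hitSum <= 0) stop("all member statistics are zero")
  nMiss <- sum(!isHit)
  step <- ifelse(isHit, w * stat / hitSum,
                 if (nMiss > 0) -1 / nMiss else 0)
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Permutation null distribution of a pathway statistic
#'
#' Gene-label resampling: each replicate draws \code{setSize} genes
#' uniformly without replacement from all scored genes, applies the
#' observed weight multiset in random order, and computes the chosen
#' statistic. Only summary statistics are available, so the null permutes
#' gene labels rather than phenotypes; preserving the weight multiset keeps
#' the weighted statistic's null matched to its observed construction.
#'
#' @param scores gene score data.frame.
#' @param setSize number of genes per null set (<= number of scored genes).
#' @param weightMultiset numeric weights applied (in random order) to the
#'   drawn genes; recycled/checked to length \code{setSize}.
#' @param B number of replicates; the study default is 15000.
#' @param seed integer seed.
#' @param method \code{"sumstat"} or \code{"gsea"}.
#' @return numeric vector of \code{B} null statistics.
#' @export
permutationNull <- function(scores, setSize, weightMultiset = rep(1, setSize),
                            B = 15000, seed = 1, method = c("sumstat", "gsea")) {
  method <- match.arg(method)
  stopifnot(B >= 1)
  n <- nrow(scores)
  if (setSize > n)
    stop("setSize (", setSize, ") exceeds the number of scored genes (", n, ")")
  if (length(weightMultiset) != setSize)
    stop("weight multiset length must equal setSize")
  set.seed(seed)
  idx <- replicate(B, sample.int(n, setSize))
  idx <- matrix(idx, nrow = setSize)
  .nullFromIndex(scores, idx, weightMultiset, method)
}

# shared by permutationNull and runPathwayAnalysis: null statistics from a
# precomputed setSize x B index matrix
.nullFromIndex <- function(scores, idx, weightMultiset, method,
                           shuffleWeights = TRUE) {
  B <- ncol(idx)
  setSize <- nrow(idx)
  if (method == "sumstat") {
    statM <- matrix(scores$stat[idx], nrow = setSize)
    if (length(unique(weightMultiset)) == 1L) {
      weightMultiset[1] * colSums(statM)
    } else {
      W <- if (shuffleWeights)
        vapply(seq_len(B), function(b) sample(weightMultiset),
               numeric(setSize))
      else matrix(weightMultiset, setSize, B)
      colSums(W * statM)
    }
  } else {
    ord <- order(scores$stat, decreasing = TRUE)
    stat <- scores$stat[ord]
    rankOf <- integer(nrow(scores))
    rankOf[ord] <- seq_along(ord)
    vapply(seq_len(B), function(b) {
      isHit <- logical(length(stat))
      isHit[rankOf[idx[, b]]] <- TRUE
      w <- rep(1, length(stat))
      w[isHit] <- if (shuffleWeights) sample(weightMultiset)
                  else weightMultiset
      .esFromRanked(stat, isHit, w)
    }, numeric(1))
  }
}

#' Empirical permutation p-value
#'
#' The +1/(B+1) convention keeps the p-value valid and never zero. SumStat
#' is one-sided (large scores are extreme); the GSEA enrichment score is
#' compared in absolute value.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics.
#' @param method \code{"sumstat"} or \code{"gsea"}.
#' @return p-value in (0, 1].
#' @export
empiricalP <- function(observed, null, method = c("sumstat", "gsea")) {
  method <- match.arg(method)
  if (length(null) == 0L) stop("empty null distribution")
  exceed <- if (method == "sumstat") sum(null >= observed)
            else sum(abs(null) >= abs(observed))
  (exceed + 1) / (length(null) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across the examined pathway
#' family, returned in input order and clamped to at most 1.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Run the pathway analysis
#'
#' For every examined pathway of the curated catalogue (see
#' [examinedSets()]) computes the observed statistic and its gene-label
#' permutation p-value twice -- unweighted, and with the I-Gene weighting
#' scheme -- from the \emph{same} null gene draws, then applies
#' Benjamini-Hochberg adjustment across pathways separately within each
#' (method, weighting) column. With a fixed seed the full table is
#' reproducible, and a pathway without I-Genes gets identical weighted and
#' unweighted p-values.
#'
#' Two null models are available. \code{"composition"} (the default)
#' preserves each pathway's I-Gene composition: a null set draws the same
#' number of I-Genes from the scored I-Genes and the remainder from the
#' other scored genes, with weights aligned to membership. This keeps the
#' test exact conditional on the realized I-Gene statistics; with a plain
#' label resample, every I-Gene-rich pathway inherits any chance deviation
#' of the (small, shared) I-Gene pool and the p-values drift off nominal
#' together. \code{"multiset"} draws null sets uniformly from all scored
#' genes and applies the observed weight multiset in random order.
#'
#' @param scores gene score data.frame from [scoreGenes()].
#' @param curated a [CuratedCatalog-class].
#' @param igenes character vector of I-Gene ids.
#' @param weights a [weightScheme()] used for the weighted pass.
#' @param B permutation replicates; the study default is 15000.
#' @param seed master seed; pathway \code{i} uses stream \code{seed + i}.
#' @param method \code{"sumstat"} or \code{"gsea"}.
#' @param minMapped minimum scored members for a pathway to be tested.
#' @param nullModel \code{"composition"} or \code{"multiset"} (see above).
#' @return An [EnrichmentResult-class].
#' @export
runPathwayAnalysis <- function(scores, curated, igenes,
                               weights = weightScheme(), B = 15000,
                               seed = 1, method = c("sumstat", "gsea"),
                               minMapped = 5,
                               nullModel = c("composition", "multiset")) {
  method <- match.arg(method)
  nullModel <- match.arg(nullModel)
  stopifnot(is(curated, "CuratedCatalog"))
  ids <- examinedSets(curated)
  if (length(ids) == 0L) stop("curated catalogue has no examined pathway")
  info <- curationInfo(curated)
  sets <- geneSets(curated)
  igIdx <- which(scores$gene_id %in% igenes)
  nonIdx <- setdiff(seq_len(nrow(scores)), igIdx)
  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    members <- sets[[id]]
    mapped <- intersect(members, scores$gene_id)
    k <- length(mapped)
    if (k < minMapped) {
      message(sprintf("pathway '%s' skipped: %d mapped gene(s) < %d",
                      id, k, minMapped))
      next
    }
    stat <- scores$stat[match(mapped, scores$gene_id)]
    wObs <- .geneWeights(mapped, weights, igenes)
    obsU <- sum(stat)
    obsW <- sum(wObs * stat)
    subseed <- (seed + i) %% .Machine$integer.max
    set.seed(subseed)
    isIg <- mapped %in% igenes
    kIg <- sum(isIg)
    if (nullModel == "composition" && kIg > 0L && kIg < k) {
      # stratified resample preserving the pathway's I-Gene composition;
      # rows 1..kIg are I-Genes, so the aligned weight vector is fixed
      idx <- matrix(replicate(B, c(
        igIdx[sample.int(length(igIdx), kIg)],
        nonIdx[sample.int(length(nonIdx), k - kIg)])), nrow = k)
      wNull <- c(rep(if (weights$enabled) weights$igeneWeight
                     else weights$otherWeight, kIg),
                 rep(weights$otherWeight, k - kIg))
      shuffle <- FALSE
    } else if (nullModel == "composition" && kIg == k && kIg > 0L) {
      idx <- matrix(replicate(B, igIdx[sample.int(length(igIdx), k)]),
                    nrow = k)
      wNull <- rep(if (weights$enabled) weights$igeneWeight
                   else weights$otherWeight, k)
      shuffle <- FALSE
    } else {
      idx <- matrix(replicate(B, sample.int(nrow(scores), k)), nrow = k)
      wNull <- wObs
      shuffle <- TRUE
    }
    if (method == "sumstat") {
      nullU <- .nullFromIndex(scores, idx, rep(1, k), "sumstat")
      nullW <- .nullFromIndex(scores, idx, wNull, "sumstat",
                              shuffleWeights = shuffle)
      pU <- empiricalP(obsU, nullU, "sumstat")
      pW <- empiricalP(obsW, nullW, "sumstat")
      esU <- esW <- NA_real_
    } else {
      esU <- gseaEs(scores, mapped)
      esW <- gseaEs(scores, mapped, weights, igenes)
      nullU <- .nullFromIndex(scores, idx, rep(1, k), "gsea")
      nullW <- .nullFromIndex(scores, idx, wNull, "gsea",
                              shuffleWeights = shuffle)
      pU <- empiricalP(esU, nullU, "gsea")
      pW <- empiricalP(esW, nullW, "gsea")
      obsU <- esU; obsW <- esW
    }
    ir <- match(id, info$set_id)
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = id, source = info$source[ir], n_genes = info$n_genes[ir],
      n_mapped = k, pct_igenes = info$pct_igenes[ir], method = method,
      weighted = c(FALSE, TRUE), score = c(obsU, obsW), es = c(esU, esW),
      p_perm = c(pU, pW), p_adj = NA_real_, n_permutations = B,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no pathway passed the minMapped filter")
  tab <- do.call(rbind, rows)
  for (w in c(FALSE, TRUE)) {
    sel <- tab$weighted == w
    tab$p_adj[sel] <- bhAdjust(tab$p_perm[sel])
  }
  rownames(tab) <- NULL
  new("EnrichmentResult", table = tab,
      params = list(B = B, seed = seed, method = method, weights = weights,
                    minMapped = minMapped))
}
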