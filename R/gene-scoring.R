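#' @include formats-io.R
NULL

#' Assign SNPs to genes by windowed overlap
#'
#' A SNP is assigned to every gene whose interval, extended by
#' \code{windowKb} kilobases on both sides, contains its position; a SNP in
#' two overlapping windows counts for both genes. SNPs on chromosomes
#' absent from the annotation are left unassigned with a warning.
#'
#' @param assoc association data.frame (1-based positions).
#' @param annotation gene GRanges with a \code{gene_id} column.
#' @param windowKb non-negative window in kilobases; default 20.
#' @return named list mapping \code{gene_id} to integer row indices of
#'   \code{assoc}; genes with no assigned SNP are absent.
#' @export
assignSnpsToGenes <- function(assoc, annotation, windowKb = 20) {
  stopifnot(windowKb >= 0)
  validateAssocTable(assoc)
  lost <- setdiff(unique(assoc$chrom), unique(as.character(
    GenomicRanges::seqnames(annotation))))
  if (length(lost))
    warning(sprintf("%d SNP(s) on chromosome(s) %s absent from the annotation left unassigned",
                    sum(assoc$chrom %in% lost),
                    paste(lost, collapse = ", ")))
  keep <- !(assoc$chrom %in% lost)
  snps <- GenomicRanges::GRanges(
    seqnames = assoc$chrom[keep],
    ranges = IRanges::IRanges(start = assoc$pos[keep], width = 1L))
  win <- as.integer(round(windowKb * 1000))
  windows <- suppressWarnings(GenomicRanges::trim(
    annotation + win))  # extend both flanks; clip at chromosome bounds
  hits <- GenomicRanges::findOverlaps(windows, snps, ignore.strand = TRUE)
  rows <- which(keep)[S4Vectors::subjectHits(hits)]
  split(rows, annotation$gene_id[S4Vectors::queryHits(hits)])
}

#' First-order-statistic (FOSCO) gene-size correction
#'
#' Corrects a gene's minimum SNP p-value for the number of SNPs tested in
#' the gene: under independence the minimum of \eqn{m} Uniform(0,1)
#' p-values has distribution function \eqn{1 - (1 - p)^m}, so the
#' corrected value is itself Uniform(0,1) under the null whatever the gene
#' size.
#'
#' @param pMin minimum p-value(s) in [0, 1].
#' @param m SNP count(s), integer >= 1 (recycled).
#' @return corrected p-value(s) \eqn{1 - (1 - p_{min})^m}.
#' @examples
#' foscoCorrect(0.01, 10)  # 1 - 0.99^10
#' @export
foscoCorrect <- function(pMin, m) {
  if (any(m < 1)) stop("'m' must be >= 1")
  if (any(pMin < 0 | pMin > 1)) stop("'pMin' must lie in [0, 1]")
  # expm1 formulation keeps precision for tiny pMin
  -expm1(m * log1p(-pMin))
}

#' Per-gene association statistic
#'
#' Maps a gene's corrected p-value to the upper-tail chi-square(1) quantile
#' (the value \eqn{x} with \eqn{P(X \ge x) = p}), so that the SumStat
#' pathway score is a sum of 1-df chi-square variates under the null.
#' A corrected p of exactly 0 is capped at the quantile for 1e-300 with a
#' warning.
#'
#' @param pFosco corrected p-value(s) in (0, 1].
#' @return non-negative statistic(s), strictly decreasing in \code{pFosco}.
#' @export
geneStatistic <- function(pFosco) {
  if (any(pFosco < 0 | pFosco > 1)) stop("'pFosco' must lie in [0, 1]")
  if (any(pFosco == 0)) {
    warning("p-value of 0 capped at 1e-300 before the chi-square transform")
    pFosco[pFosco == 0] <- 1e-300
  }
  stats::qchisq(pFosco, df = 1, lower.tail = FALSE)
}

#' Score genes from SNP summary statistics
#'
#' Composes SNP-to-gene assignment, the FOSCO gene-size correction and the
#' chi-square(1) transform: per gene, \code{m_snps} assigned SNPs,
#' \code{p_min} their smallest p-value, \code{p_fosco =
#' foscoCorrect(p_min, m_snps)} and \code{stat = geneStatistic(p_fosco)}.
#' Genes with no assigned SNP are absent from the table.
#'
#' @inheritParams assignSnpsToGenes
#' @return data.frame with columns \code{gene_id}, \code{m_snps},
#'   \code{p_min}, \code{p_fosco}, \code{stat}.
#' @export
scoreGenes <- function(assoc, annotation, windowKb = 20) {
  assignment <- assignSnpsToGenes(assoc, annotation, windowKb)
  if (length(assignment) == 0L)
    stop("no gene received any SNP; check chromosomes and window size")
  m <- vapply(assignment, length, integer(1))
  pMin <- vapply(assignment, function(rows) min(assoc$pvalue[rows]),
                 numeric(1))
  pFosco <- foscoCorrect(pMin, m)
  out <- data.frame(gene_id = names(assignment), m_snps = m,
                    p_min = pMin, p_fosco = pFosco,
                    stat = geneStatistic(pFosco),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$gene_id), , drop = FALSE]
}
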