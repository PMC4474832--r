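#' @include formats-io.R
NULL

.DEFAULT_SCORING <- list(
  protein = list(matrix = "BLOSUM62", gapOpening = 11, gapExtension = 1),
  nucleotide = list(match = 2, mismatch = -3, gapOpening = 5,
                    gapExtension = 2))

.alphabetOf <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) "nucleotide"
  else if (is(x, "AAString") || is(x, "AAStringSet")) "protein"
  else stop("sequences must be DNAString(Set) or AAString(Set) objects")
}

#' Global pairwise alignment
#'
#' Optimal Needleman-Wunsch global alignment with affine gap penalties via
#' the Biostrings aligner. Defaults follow the classic local-search-tool
#' parameterisation: BLOSUM62 with gap open 11 / extend 1 for proteins,
#' match +2 / mismatch -3 with gap open 5 / extend 2 for nucleotides.
#'
#' @param a,b \code{DNAString}/\code{AAString} (or 1-element sets) of the
#'   same alphabet; non-empty.
#' @param scoring optional list overriding the defaults (\code{matrix} or
#'   \code{match}/\code{mismatch}, \code{gapOpening}, \code{gapExtension}).
#' @return classed list \code{PairwiseAln} with fields \code{id_a},
#'   \code{id_b}, \code{row_a}, \code{row_b} (equal-length gapped strings),
#'   \code{alphabet}, \code{score}.
#' @export
globalAlign <- function(a, b, scoring = NULL) {
  idA <- if (!is.null(names(a))) names(a)[1] else "seq_a"
  idB <- if (!is.null(names(b))) names(b)[1] else "seq_b"
  if (is(a, "XStringSet")) a <- a[[1]]
  if (is(b, "XStringSet")) b <- b[[1]]
  alpha <- .alphabetOf(a)
  if (alpha != .alphabetOf(b))
    stop("cannot align a ", alpha, " sequence to a ", .alphabetOf(b),
         " sequence")
  if (length(a) == 0L || length(b) == 0L)
    stop("cannot align an empty sequence")
  # canonical input order makes the traceback tie-break, and hence the
  # reported identity, symmetric in the two sequences
  if (as.character(a) > as.character(b)) {
    sw <- globalAlign(stats::setNames(
      if (alpha == "protein") Biostrings::AAStringSet(as.character(b))
      else Biostrings::DNAStringSet(as.character(b)), idB),
      stats::setNames(
        if (alpha == "protein") Biostrings::AAStringSet(as.character(a))
        else Biostrings::DNAStringSet(as.character(a)), idA),
      scoring)
    out <- list(id_a = idA, id_b = idB, row_a = sw$row_b, row_b = sw$row_a,
                alphabet = alpha, score = sw$score)
    class(out) <- "PairwiseAln"
    return(out)
  }
  def <- .DEFAULT_SCORING[[alpha]]
  if (!is.null(scoring)) def[names(scoring)] <- scoring
  if (alpha == "protein") {
    submat <- def$matrix
    if (is.character(submat)) {
      # substitution matrices shipped with Biostrings (e.g. BLOSUM62)
      e <- new.env()
      utils::data(list = submat, package = "Biostrings", envir = e)
      submat <- get(def$matrix, envir = e)
    }
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = def$match, mismatch = def$mismatch, baseOnly = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = submat,
    gapOpening = def$gapOpening, gapExtension = def$gapExtension)
  out <- list(id_a = idA, id_b = idB,
              row_a = as.character(Biostrings::alignedPattern(aln)),
              row_b = as.character(Biostrings::alignedSubject(aln)),
              alphabet = alpha, score = Biostrings::score(aln))
  stopifnot(nchar(out$row_a) == nchar(out$row_b))
  class(out) <- "PairwiseAln"
  out
}

#' Percent identity of a pairwise alignment
#'
#' \eqn{100 \times} matching columns over counted columns. In
#' \code{trimmed} mode (the default) terminal-gap columns -- the leading
#' and trailing runs where either row is gapped -- are excluded, which
#' approximates the identity a local-alignment search reports; in
#' \code{global} mode every column counts and gap columns count as
#' mismatches.
#'
#' @param aln a \code{PairwiseAln} from [globalAlign()].
#' @param mode \code{"trimmed"} or \code{"global"}.
#' @return identity percentage.
#' @export
percentIdentity <- function(aln, mode = c("trimmed", "global")) {
  mode <- match.arg(mode)
  a <- strsplit(aln$row_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$row_b, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, length(a))
  if (mode == "trimmed") {
    gap <- a == "-" | b == "-"
    interior <- which(!gap)
    if (length(interior) == 0L) stop("alignment has no counted columns")
    keep[seq_along(a) < interior[1] | seq_along(a) > interior[length(interior)]] <- FALSE
  }
  if (!any(keep)) stop("alignment has no counted columns")
  100 * sum(a[keep] == b[keep] & a[keep] != "-") / sum(keep)
}

# --- codon alignments -------------------------------------------------------

.GENETIC_CODE <- Biostrings::GENETIC_CODE

.translateCodon <- function(codon) {
  unname(.GENETIC_CODE[codon])  # NA for gapped/ambiguous codons
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned amino-acid column to the corresponding codon pair of
#' the two coding sequences; protein gaps become \code{"---"} codons. Each
#' ungapped protein row must translate exactly from its CDS under the
#' standard genetic code (a single trailing stop codon on the CDS is
#' allowed and stripped); any mismatch is an error naming the residue
#' position.
#'
#' @param protAln a protein \code{PairwiseAln}.
#' @param cdsA,cdsB \code{DNAString}(Set) coding sequences for rows a/b.
#' @return classed list \code{CodonAln} with character vectors
#'   \code{codons_a}, \code{codons_b} of equal length.
#' @export
backtranslate <- function(protAln, cdsA, cdsB) {
  stopifnot(inherits(protAln, "PairwiseAln"), protAln$alphabet == "protein")
  prep <- function(cds, gappedRow, label) {
    if (is(cds, "XStringSet")) cds <- cds[[1]]
    s <- as.character(cds)
    if (nchar(s) %% 3 != 0L)
      stop("CDS length of ", label, " is not a multiple of 3")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- .translateCodon(codons)
    prot <- gsub("-", "", gappedRow, fixed = TRUE)
    nAA <- nchar(prot)
    if (length(codons) == nAA + 1L && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (length(codons) != nAA)
      stop(sprintf("CDS of %s encodes %d residues but the protein has %d",
                   label, length(codons), nAA))
    protChars <- strsplit(prot, "", fixed = TRUE)[[1]]
    bad <- which(aa != protChars)
    if (length(bad))
      stop(sprintf("translation mismatch for %s at residue %d: codon %s encodes %s, protein has %s",
                   label, bad[1], codons[bad[1]], aa[bad[1]],
                   protChars[bad[1]]))
    codons
  }
  codA <- prep(cdsA, protAln$row_a, protAln$id_a)
  codB <- prep(cdsB, protAln$row_b, protAln$id_b)
  rowA <- strsplit(protAln$row_a, "", fixed = TRUE)[[1]]
  rowB <- strsplit(protAln$row_b, "", fixed = TRUE)[[1]]
  outA <- character(length(rowA)); outB <- character(length(rowB))
  iA <- iB <- 0L
  for (j in seq_along(rowA)) {
    if (rowA[j] == "-") outA[j] <- "---"
    else { iA <- iA + 1L; outA[j] <- codA[iA] }
    if (rowB[j] == "-") outB[j] <- "---"
    else { iB <- iB + 1L; outB[j] <- codB[iB] }
  }
  structure(list(codons_a = outA, codons_b = outB), class = "CodonAln")
}

# synonymous site count of one codon: over the 3 positions, the fraction of
# the 3 single-base mutants that preserve the amino acid (mutants to stop
# codons count as nonsynonymous)
.synSites <- function(codon) {
  aa <- .translateCodon(codon)
  if (is.na(aa) || aa == "*") return(NA_real_)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (pos in 1:3) {
    for (nb in setdiff(bases, chars[pos])) {
      mut <- chars; mut[pos] <- nb
      if (identical(.translateCodon(paste(mut, collapse = "")), aa))
        s <- s + 1 / 3
    }
  }
  s
}

# enumerate the orderings of the differing positions between two codons;
# returns c(sd, nd) averaged with equal weight over pathways that avoid
# stop codons (all pathways if every ordering hits a stop)
.pathwayCounts <- function(ca, cb) {
  chA <- strsplit(ca, "", fixed = TRUE)[[1]]
  chB <- strsplit(cb, "", fixed = TRUE)[[1]]
  diffPos <- which(chA != chB)
  d <- length(diffPos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  orderings <- switch(d,
    list(diffPos),
    list(diffPos, rev(diffPos)),
    {
      perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(perms, function(p) diffPos[p])
    })
  walk <- function(ord) {
    cur <- chA
    sd <- nd <- 0
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- chB[pos]
      aaCur <- .translateCodon(paste(cur, collapse = ""))
      aaNxt <- .translateCodon(paste(nxt, collapse = ""))
      if (aaNxt == "*") return(NULL)     # pathway through a stop codon
      if (aaCur == aaNxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  counts <- lapply(orderings, walk)
  viable <- counts[!vapply(counts, is.null, logical(1))]
  if (length(viable) == 0L) {
    # every ordering passes a stop codon; fall back to counting through them
    walkAny <- function(ord) {
      cur <- chA; sd <- nd <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- chB[pos]
        if (identical(.translateCodon(paste(cur, collapse = "")),
                      .translateCodon(paste(nxt, collapse = ""))))
          sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    viable <- lapply(orderings, walkAny)
  }
  Reduce(`+`, viable) / length(viable)
}

#' Nei-Gojobori (1986) dN/dS from a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon (the fraction of the
#' three single-base mutants at each position that preserve the amino
#' acid), averages the site totals between the two sequences, counts
#' synonymous/nonsynonymous differences along minimal mutation pathways
#' between differing codons (equal weights over pathways avoiding stop
#' codons), and applies the Jukes-Cantor correction
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)} to the proportions.
#' Codon pairs containing a gap or ambiguity code, or where either codon is
#' a stop, are removed (pairwise deletion) before counting.
#'
#' @param caln a \code{CodonAln} from [backtranslate()].
#' @return classed list \code{Ng86} with fields \code{S_sites},
#'   \code{N_sites}, \code{Sd}, \code{Nd}, \code{pS}, \code{pN}, \code{dS},
#'   \code{dN}, \code{omega} (\code{NA} unless \code{dS > 0}),
#'   \code{n_codons}, \code{saturated} (TRUE when a proportion reached 3/4
#'   and the correction is undefined).
#' @export
ng86 <- function(caln) {
  stopifnot(inherits(caln, "CodonAln"))
  ca <- caln$codons_a; cb <- caln$codons_b
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  aaA <- .translateCodon(ca); aaB <- .translateCodon(cb)
  ok <- ok & !is.na(aaA) & !is.na(aaB) & aaA != "*" & aaB != "*"
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L)
    stop("no comparable (gap- and ambiguity-free) codon pair")
  sA <- vapply(ca, .synSites, numeric(1))
  sB <- vapply(cb, .synSites, numeric(1))
  S <- (sum(sA) + sum(sB)) / 2
  N <- 3 * length(ca) - S
  counts <- mapply(function(x, y) .pathwayCounts(x, y), ca, cb)
  Sd <- sum(counts["sd", ])
  Nd <- sum(counts["nd", ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log1p(-4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  saturated <- is.na(dS) || is.na(dN)
  omega <- if (!saturated && dS > 0) dN / dS else NA_real_
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
                 n_codons = length(ca), saturated = saturated),
            class = "Ng86")
}

#' Pairwise dN/dS over a set of orthologous coding sequences
#'
#' For every sequence pair: translate, globally align the proteins,
#' back-translate to codons, and run [ng86()].
#'
#' @param cds named \code{DNAStringSet} of coding sequences.
#' @return data.frame with one row per unordered pair: \code{id_a},
#'   \code{id_b}, \code{S_sites}, \code{N_sites}, \code{Sd}, \code{Nd},
#'   \code{dS}, \code{dN}, \code{omega}.
#' @export
ng86Pairwise <- function(cds) {
  stopifnot(is(cds, "DNAStringSet"), length(cds) >= 2)
  prot <- .translateCds(cds)
  ids <- names(cds)
  rows <- list()
  for (i in seq_len(length(cds) - 1L)) {
    for (j in seq.int(i + 1L, length(cds))) {
      aln <- globalAlign(prot[i], prot[j])
      res <- ng86(backtranslate(aln, cds[[i]], cds[[j]]))
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = ids[i], id_b = ids[j], S_sites = res$S_sites,
        N_sites = res$N_sites, Sd = res$Sd, Nd = res$Nd,
        dS = res$dS, dN = res$dN, omega = res$omega,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# translate CDS to proteins, stripping one trailing stop codon when present
.translateCds <- function(cds) {
  out <- lapply(seq_along(cds), function(i) {
    aa <- as.character(suppressWarnings(Biostrings::translate(cds[[i]])))
    sub("\\*$", "", aa)
  })
  set <- Biostrings::AAStringSet(unlist(out))
  names(set) <- names(cds)
  set
}

#' Pairwise p-distance matrix from global alignments
#'
#' Entry (i, j) is \eqn{1 -} identity fraction of the trimmed global
#' alignment of sequences i and j -- the distance input handed to the
#' neighbor-joining tree builder.
#'
#' @param seqs named \code{DNAStringSet} or \code{AAStringSet} with >= 2
#'   sequences.
#' @param scoring optional scoring overrides for [globalAlign()].
#' @return symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
pdistanceMatrix <- function(seqs, scoring = NULL) {
  stopifnot(length(seqs) >= 2)
  n <- length(seqs)
  ids <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- globalAlign(seqs[i], seqs[j], scoring)
      d[i, j] <- d[j, i] <- 1 - percentIdentity(aln, "trimmed") / 100
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining (Q-criterion agglomeration with the standard
#' branch-length formulas, via \code{ape::nj}); two taxa are joined by a
#' single edge split evenly. Negative estimated branch lengths are retained
#' but flagged with a warning and an attribute.
#'
#' @param d symmetric numeric matrix with zero diagonal and taxa dimnames.
#' @return an \code{ape} \code{phylo} tree (unrooted for > 2 taxa); the
#'   attribute \code{negative_branches} counts flagged edges.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(d))) stop("distance matrix must carry taxa labels")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (nrow(d) == 2L) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2),
                 edge.length = rep(d[1, 2] / 2, 2),
                 tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
  } else {
    tree <- ape::nj(stats::as.dist(d))
  }
  nNeg <- sum(tree$edge.length < 0)
  if (nNeg > 0)
    warning(nNeg, " negative estimated branch length(s) retained")
  attr(tree, "negative_branches") <- nNeg
  tree
}
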