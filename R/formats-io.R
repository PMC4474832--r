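#' @include AllClasses.R
NULL

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT dialect used by pathway databases: one set
#' per line, fields \code{set_id <TAB> description <TAB> gene1 <TAB> ...}.
#' Duplicate genes within a line are removed with a warning (they are common
#' in public catalogues); a line with fewer than three fields is a format
#' error.
#'
#' @param path path to a GMT file.
#' @return A [GeneSetCatalog-class]; the GMT description field becomes the
#'   per-set source annotation.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("PW1\tKEGG\tG1\tG2\tG3", f)
#' readGmt(f)
#' @export
readGmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop("GMT file '", path, "' is empty")
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  src <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate gene(s) removed",
                      i, fields[1], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    ids[i] <- fields[1]
    src[i] <- fields[2]
    sets[[i]] <- genes
  }
  names(sets) <- ids
  GeneSetCatalog(sets, src)
}

#' Write a catalogue to GMT
#'
#' @param catalog a [GeneSetCatalog-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(catalog, path) {
  stopifnot(is(catalog, "GeneSetCatalog"))
  lines <- vapply(seq_along(catalog@sets), function(i) {
    paste(c(names(catalog@sets)[i], catalog@source[i], catalog@sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a protein-protein interaction partner table
#'
#' Reads a tab-separated table of \code{gene_id <TAB> evidence} rows (a
#' header line is detected and skipped) describing predicted interaction
#' partners of a seed gene, and retains only partners whose evidence score
#' is \emph{strictly} greater than \code{minEvidence}; the retained set is
#' the I-Gene list. Evidence supplied on the common 0-1000 integer scale
#' (any value > 1) is auto-detected and divided by 1000.
#'
#' @param path path to the TSV file.
#' @param seedGene identifier of the seed gene the partners interact with.
#' @param minEvidence retention threshold in [0, 1]; default 0.4, the
#'   medium-confidence cut. A score exactly equal to the threshold is
#'   dropped.
#' @return An [InteractionPartners-class] holding the retained partners.
#' @export
readInteractionTable <- function(path, seedGene, minEvidence = 0.4) {
  stopifnot(minEvidence >= 0, minEvidence <= 1)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", col.names = c("gene_id", "evidence"),
                           colClasses = c("character", "character"))
  # header detection: first row with a non-numeric evidence field
  if (nrow(raw) > 0L && is.na(suppressWarnings(as.numeric(raw$evidence[1]))))
    raw <- raw[-1L, , drop = FALSE]
  ev <- suppressWarnings(as.numeric(raw$evidence))
  if (anyNA(ev))
    stop("non-numeric evidence score at row ",
         which(is.na(ev))[1], " of '", path, "'")
  # 0-1000 integer dialect: rescale only when the values clearly live on
  # that scale; an isolated score like 1.2 is an input error, not a dialect
  if (max(ev) > 10 && all(ev <= 1000)) ev <- ev / 1000
  bad <- which(ev < 0 | ev > 1)
  if (length(bad))
    stop(sprintf("evidence score out of [0, 1] at row %d (value %g)",
                 bad[1], ev[bad[1]]))
  keep <- ev > minEvidence
  InteractionPartners(seedGene,
                      data.frame(gene_id = raw$gene_id[keep],
                                 evidence = ev[keep],
                                 stringsAsFactors = FALSE))
}

#' Write an interaction partner table
#'
#' @param ppi an [InteractionPartners-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeInteractionTable <- function(ppi, path) {
  stopifnot(is(ppi, "InteractionPartners"))
  utils::write.table(partners(ppi), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.ASSOC_ALIASES <- list(
  snp_id = c("snp", "snp_id", "snpid", "rsid", "marker"),
  chrom  = c("chrom", "chr", "chromosome"),
  pos    = c("pos", "position", "bp", "base_pair"),
  pvalue = c("p", "pvalue", "p_value", "pval"))

#' Read a SNP association summary-statistic table
#'
#' Reads a tab-separated table of per-SNP association results with a header
#' naming the SNP id, chromosome, position and p-value columns (common
#' aliases such as \code{snp}/\code{rsid}, \code{chr}, \code{bp},
#' \code{pval} are recognised). Positions are 1-based base pairs.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{snp_id}, \code{chrom} (character),
#'   \code{pos} (integer), \code{pvalue} (numeric in [0, 1]); SNP ids are
#'   unique.
#' @export
readAssocTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  lower <- tolower(names(tab))
  pick <- function(role) {
    hit <- which(lower %in% .ASSOC_ALIASES[[role]])
    if (length(hit) == 0L)
      stop("association table '", path, "' has no column naming the ",
           role, " field")
    hit[1]
  }
  out <- data.frame(
    snp_id = as.character(tab[[pick("snp_id")]]),
    chrom  = as.character(tab[[pick("chrom")]]),
    pos    = tab[[pick("pos")]],
    pvalue = tab[[pick("pvalue")]],
    stringsAsFactors = FALSE)
  validateAssocTable(out, where = path)
  out$pos <- as.integer(out$pos)
  out
}

#' Validate a SNP association table
#'
#' Checks the invariants of the association-table type: numeric
#' non-negative positions, p-values in [0, 1], unique SNP ids. Errors name
#' the offending row or id.
#'
#' @param assoc data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{pvalue}.
#' @param where label used in error messages.
#' @return invisibly, \code{assoc}.
#' @export
validateAssocTable <- function(assoc, where = "association table") {
  pos <- suppressWarnings(as.numeric(assoc$pos))
  if (anyNA(pos))
    stop(sprintf("%s: non-numeric position at row %d", where,
                 which(is.na(pos))[1]))
  if (any(pos < 0))
    stop(sprintf("%s: negative position at row %d", where,
                 which(pos < 0)[1]))
  p <- suppressWarnings(as.numeric(assoc$pvalue))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad))
    stop(sprintf("%s: p-value outside [0, 1] at row %d", where, bad[1]))
  if (anyDuplicated(assoc$snp_id)) {
    dup <- assoc$snp_id[duplicated(assoc$snp_id)][1]
    stop(sprintf("%s: duplicate SNP id '%s'", where, dup))
  }
  invisible(assoc)
}

#' Write a SNP association table
#' @param assoc validated association data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeAssocTable <- function(assoc, path) {
  validateAssocTable(assoc)
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene annotation from BED
#'
#' Wraps the rtracklayer BED importer: the file's 0-based half-open
#' intervals become 1-based closed GRanges. The BED name column supplies
#' gene identifiers, which must be unique.
#'
#' @param path path to a BED file.
#' @return A \code{GRanges} with metadata column \code{gene_id}.
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name) || any(gr$name == ""))
    stop("BED file '", path, "' must carry gene identifiers in the name column")
  if (anyDuplicated(gr$name))
    stop("BED file '", path, "' has duplicate gene id '",
         gr$name[duplicated(gr$name)][1], "'")
  gr$gene_id <- gr$name
  gr$name <- NULL
  names(gr) <- gr$gene_id
  gr
}

#' Write gene annotation to BED
#' @param annotation GRanges with a \code{gene_id} metadata column.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGeneBed <- function(annotation, path) {
  gr <- annotation
  gr$name <- gr$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Reads a FASTA file into a Biostrings string set of the declared
#' alphabet, uppercasing residues. Empty files, empty sequences and
#' malformed records are rejected.
#'
#' @param path path to a FASTA file.
#' @param alphabet \code{"nucleotide"} or \code{"protein"}.
#' @return A \code{DNAStringSet} or \code{AAStringSet}.
#' @export
readFasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file '", path, "' does not exist")
  if (file.size(path) == 0L) stop("FASTA file '", path, "' is empty")
  first <- readLines(path, n = 1L)
  if (!startsWith(trimws(first), ">"))
    stop("FASTA format error in '", path, "': sequence data before header")
  set <- tryCatch({
    if (alphabet == "nucleotide")
      Biostrings::readDNAStringSet(path)
    else
      Biostrings::readAAStringSet(path)
  }, error = function(e)
    stop("FASTA format error in '", path, "': ", conditionMessage(e)))
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no records")
  if (any(Biostrings::width(set) == 0L))
    stop("empty sequence for record '",
         names(set)[Biostrings::width(set) == 0L][1], "' in '", path, "'")
  chars <- as.character(set)
  names(chars) <- sub("\\s.*$", "", names(set))  # id = first header token
  chars <- toupper(chars)
  if (alphabet == "nucleotide") Biostrings::DNAStringSet(chars)
  else Biostrings::AAStringSet(chars)
}

#' Serialise a phylogenetic tree to Newick
#'
#' @param tree an \code{ape} \code{phylo} object with >= 2 uniquely
#'   labelled leaves.
#' @param path optional output path; when \code{NULL} the Newick string is
#'   returned.
#' @return the Newick string (invisibly when \code{path} is given).
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L)
    stop("tree must have at least 2 leaves")
  if (anyNA(tree$tip.label) || any(tree$tip.label == ""))
    stop("tree has unnamed leaves")
  if (anyDuplicated(tree$tip.label))
    stop("tree leaf labels must be unique")
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Write the pathway-analysis report
#'
#' Tab-separated report with one row per pathway and the fixed column order
#' \code{pathway, source, n_genes, n_mapped, pct_igenes, p_unweighted,
#' p_weighted, p_adj_unweighted, p_adj_weighted}; the I-Gene percentage is
#' printed with two decimals. Expects an [EnrichmentResult-class] holding
#' both the unweighted and the weighted run of one method.
#'
#' @param results an [EnrichmentResult-class].
#' @param path output path.
#' @param method which method's rows to report when the result holds
#'   several; default the first present.
#' @return invisibly, the report data.frame.
#' @export
writeReport <- function(results, path, method = NULL) {
  stopifnot(is(results, "EnrichmentResult"))
  tab <- resultTable(results)
  if (nrow(tab) == 0L) stop("cannot write a report from empty results")
  if (is.null(method)) method <- tab$method[1]
  tab <- tab[tab$method == method, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for method '", method, "'")
  un <- tab[!tab$weighted, , drop = FALSE]
  wt <- tab[tab$weighted, , drop = FALSE]
  if (nrow(un) == 0L || nrow(wt) == 0L)
    stop("report needs both unweighted and weighted rows")
  stopifnot(identical(un$set_id, wt$set_id))
  out <- data.frame(
    pathway = un$set_id,
    source = un$source,
    n_genes = un$n_genes,
    n_mapped = un$n_mapped,
    pct_igenes = sprintf("%.2f", un$pct_igenes),
    p_unweighted = un$p_perm,
    p_weighted = wt$p_perm,
    p_adj_unweighted = un$p_adj,
    p_adj_weighted = wt$p_adj,
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(out)
}
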